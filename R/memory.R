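#' Signal-detection discriminability (d')
#'
#' `d' = z(hit rate) - z(false-alarm rate)`.  Rates computed from counts use
#' the log-linear correction (0.5 added to every cell) so that perfect or
#' zero rates stay finite.
#'
#' @param hits,n_old Hit count and number of old items.
#' @param fas,n_new False-alarm count and number of new items.
#' @return Scalar d'.
#' @export
dprime <- function(hits, n_old, fas, n_new) {
  stopifnot(n_old >= 1, n_new >= 1)
  qnorm((hits + 0.5) / (n_old + 1)) - qnorm((fas + 0.5) / (n_new + 1))
}

#' Score recognition memory per subject
#'
#' Counts hits, misses, false alarms and correct rejections from old/new
#' judgements, and computes the hit rate (hits / (hits + misses)), the
#' false-alarm rate, and the log-linear-corrected d'.
#'
#' @param recognition Tibble with `subject`, `status` ("old"/"new") and
#'   binary `response` (1 = judged "old").  If an `immediate_subset` column
#'   is present, only flagged rows are scored.
#' @return Tibble with one row per subject: counts, `hit_rate`, `fa_rate`,
#'   `dprime`.
#' @export
score_recognition <- function(recognition) {
  if ("immediate_subset" %in% names(recognition)) {
    recognition <- recognition[as.logical(recognition$immediate_subset), ]
  }
  out <- lapply(split(recognition, recognition$subject), function(d) {
    old <- d$status == "old"
    n_old <- sum(old)
    n_new <- sum(!old)
    if (n_old == 0 || n_new == 0) {
      stop("subject ", d$subject[1], " has no ",
           if (n_old == 0) "old" else "new", " trials")
    }
    hits <- sum(d$response[old] == 1)
    fas <- sum(d$response[!old] == 1)
    tibble(
      subject = d$subject[1],
      hits = hits, misses = n_old - hits,
      false_alarms = fas, correct_rejections = n_new - fas,
      hit_rate = hits / n_old, fa_rate = fas / n_new,
      dprime = dprime(hits, n_old, fas, n_new)
    )
  })
  dplyr::bind_rows(out)
}

#' Permutation-based exclusion of at-chance recognizers
#'
#' For each subject, builds a null distribution of d' by permuting the
#' subject's response vector against the old/new item labels, and includes
#' the subject only if the observed d' reaches the upper percentile of
#' their own null distribution (default the 95th, i.e. a 5\% false-inclusion
#' rate for true at-chance responders).
#'
#' @inheritParams score_recognition
#' @param n_perm Number of permutations (default 5000).
#' @param percentile Null-distribution percentile the observed d' must
#'   reach (default 95).
#' @param seed Integer seed.
#' @return Tibble per subject: `dprime`, `threshold` (null percentile),
#'   `p_perm` (permutation p-value) and `included` flag; the per-subject
#'   null distributions are attached as the `null_distributions` attribute.
#' @export
permutation_exclusion <- function(recognition, n_perm = 5000,
                                  percentile = 95, seed = 1L) {
  stopifnot(n_perm >= 1)
  if ("immediate_subset" %in% names(recognition)) {
    recognition <- recognition[as.logical(recognition$immediate_subset), ]
  }
  subjects <- unique(recognition$subject)
  nulls <- vector("list", length(subjects))
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    d <- recognition[recognition$subject == subjects[i], ]
    old <- d$status == "old"
    n_old <- sum(old)
    n_new <- sum(!old)
    obs <- dprime(sum(d$response[old] == 1), n_old,
                  sum(d$response[!old] == 1), n_new)
    set.seed(derive_seed(seed, i))
    null <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      perm <- sample(d$response)
      null[p] <- dprime(sum(perm[old] == 1), n_old,
                        sum(perm[!old] == 1), n_new)
    }
    thr <- quantile(null, percentile / 100, names = FALSE)
    # Inclusion via the mid-p permutation p-value: half weight on null d'
    # values tied with the observed one.  For a continuous null this is the
    # >=-threshold rule; for the discrete null that permutation of binary
    # responses produces, the plain rule is conservative (ties inflate the
    # p-value), while mid-p keeps the false-inclusion rate of true
    # at-chance responders at the nominal level.  A degenerate responder
    # (same answer to every item) has a null concentrated at its observed
    # d', giving mid-p 0.5: excluded.
    p_perm <- mean(null > obs) + 0.5 * mean(null == obs)
    nulls[[i]] <- null
    rows[[i]] <- tibble(subject = subjects[i], dprime = obs,
                        threshold = thr, p_perm = p_perm,
                        included = p_perm <= 1 - percentile / 100)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "null_distributions") <- setNames(nulls, subjects)
  out
}
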
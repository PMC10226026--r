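#' Derive trial-level prediction errors at best-fitting parameters
#'
#' Replays a fitted model over each subject's pooled choice data (the
#' per-subject best-fitting parameters from [fit_study()]) to obtain the
#' trial-level PE records used in the subsequent-memory analysis.
#'
#' @param trials Pooled trial table with choices (all subjects).
#' @param fits Tibble from [fit_study()].
#' @param model Which model's fitted parameters to replay (default
#'   `"fLRI"`).
#' @return Per-trial trajectory table (see [run_model()]) for all subjects.
#' @export
derive_pe <- function(trials, fits, model = "fLRI") {
  spec <- model_spec(model)
  fits <- fits[fits$model == model, ]
  out <- lapply(unique(trials$subject), function(s) {
    f <- fits[fits$subject == s, ]
    if (nrow(f) != 1) stop("no unique ", model, " fit for subject ", s)
    params <- c(alpha = f$alpha, beta = f$beta)
    dat <- trials[trials$subject == s, ]
    run_model(dat, dat$category_chosen, spec, params)
  })
  dplyr::bind_rows(out)
}

#' Build the item-level subsequent-memory analysis table
#'
#' Joins the encoding-phase trajectory of each unique (non-filler) object
#' with its later recognition outcome.  Filler items never enter; for
#' designs with an immediate-test subsample only flagged old items are
#' kept.  Prediction outcome is contrast-coded +0.5 (correct) / -0.5
#' (incorrect) and experiment +0.5 (EXP1) / -0.5 (EXP2); each subject's
#' best-fitting fLRI learning rate is attached, and PE quartile bins are
#' computed within subject.
#'
#' @param trajectories Trajectory table from [derive_pe()].
#' @param recognition Recognition records (`subject`, `object_id`,
#'   `status`, `response`, optional `immediate_subset`).
#' @param fits Tibble from [fit_study()] containing fLRI fits.
#' @param included_subjects Optional vector of subjects that passed
#'   exclusion; `NULL` keeps everyone.
#' @return Tibble with one row per analysed old item: `subject`,
#'   `object_id`, `hit`, `pe`, `pe_signed`, `po`, `alpha`,
#'   `experiment`, `experiment_code`, `pe_bin`.
#' @export
build_analysis_table <- function(trajectories, recognition, fits,
                                 included_subjects = NULL) {
  items <- trajectories[trajectories$phase == "ENCODING" &
                          !trajectories$is_filler, ]
  old <- recognition[recognition$status == "old", ]
  if ("immediate_subset" %in% names(old)) {
    old <- old[as.logical(old$immediate_subset), ]
  }
  if (!is.null(included_subjects)) {
    items <- items[items$subject %in% included_subjects, ]
    old <- old[old$subject %in% included_subjects, ]
  }
  joined <- dplyr::inner_join(
    old[, c("subject", "object_id", "response")],
    items[, c("subject", "object_id", "experiment", "pe_unsigned",
              "pe_signed", "outcome")],
    by = c("subject", "object_id")
  )
  unmatched <- setdiff(paste(old$subject, old$object_id),
                       paste(joined$subject, joined$object_id))
  if (length(unmatched)) {
    stop("old items with no encoding record: ",
         paste(utils::head(unmatched, 5), collapse = ", "),
         if (length(unmatched) > 5) " ...")
  }
  flri <- fits[fits$model == "fLRI", c("subject", "alpha")]
  joined <- dplyr::left_join(joined, flri, by = "subject")
  if (anyNA(joined$alpha)) {
    stop("missing fLRI learning rate for subject(s): ",
         paste(unique(joined$subject[is.na(joined$alpha)]), collapse = ", "))
  }
  out <- tibble(
    subject = joined$subject,
    object_id = joined$object_id,
    hit = as.integer(joined$response),
    pe = joined$pe_unsigned,
    pe_signed = joined$pe_signed,
    po = ifelse(joined$outcome, 0.5, -0.5),
    alpha = joined$alpha,
    experiment = joined$experiment,
    experiment_code = ifelse(joined$experiment == "EXP1", 0.5, -0.5)
  )
  out <- dplyr::group_by(out, .data$subject)
  out <- dplyr::mutate(out, pe_bin = dplyr::ntile(.data$pe, 4))
  dplyr::ungroup(out)
}

# Formula presets for the mixed logistic subsequent-memory model.  The
# random part is always within-subject (intercept, PE, PO and their
# interaction) with an unstructured covariance; between-subject covariates
# (learning rate, experiment) enter as fixed effects only.
mixed_formula <- function(formula_spec, response = "hit") {
  if (inherits(formula_spec, "formula")) return(formula_spec)
  fixed <- switch(match.arg(formula_spec, c("basic", "full")),
    basic = "pe * po",
    full = "pe * po * alpha * experiment_code"
  )
  as.formula(paste(response, "~", fixed, "+ (1 + pe * po | subject)"))
}

check_random_part <- function(formula) {
  bars <- lme4::findbars(formula)
  for (b in bars) {
    vars <- all.vars(b[[2]])
    bad <- intersect(vars, c("alpha", "experiment", "experiment_code"))
    if (length(bad)) {
      stop("between-subject covariate(s) in random slopes: ",
           paste(bad, collapse = ", "))
    }
  }
  invisible(formula)
}

# Shared glmer backend + coefficient table extraction.
glmer_fit <- function(formula, data, nAGQ = 1) {
  check_random_part(formula)
  ctrl <- lme4::glmerControl(optimizer = "nloptwrap", calc.derivs = FALSE)
  model <- lme4::glmer(formula, data = data, family = stats::binomial,
                       control = ctrl, nAGQ = nAGQ)
  est <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(vcov(model))))
  z <- est / se
  ci <- qnorm(0.975) * se
  fixed <- tibble(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    ci_lower = unname(est - ci),
    ci_upper = unname(est + ci),
    z = unname(z),
    wald_chisq = unname(z^2),
    p = unname(2 * pnorm(-abs(z))),
    odds_ratio = unname(exp(est))
  )
  vc <- lme4::VarCorr(model)$subject
  structure(list(
    fixed = fixed,
    ranef_vcov = matrix(as.numeric(vc), nrow = nrow(vc),
                        dimnames = dimnames(vc)),
    ranef_sd = attr(vc, "stddev"),
    singular = lme4::isSingular(model),
    n_obs = nrow(data),
    n_subjects = length(unique(data$subject)),
    formula = formula,
    model = model
  ), class = "mixed_logistic_fit")
}

#' @export
print.mixed_logistic_fit <- function(x, ...) {
  cat("<mixed_logistic_fit>", deparse(x$formula), "\n",
      x$n_obs, "items,", x$n_subjects, "subjects",
      if (x$singular) "(singular random-effect fit)", "\n")
  print(as.data.frame(x$fixed), digits = 3)
  invisible(x)
}

#' Mixed-effects logistic subsequent-memory model
#'
#' Fits the item-level logistic model of recognition success: fixed effects
#' of unsigned PE, prediction outcome (+/-0.5) and their interaction --
#' optionally crossed with the subject's learning rate and experiment
#' (+/-0.5) up to the four-way interaction -- with by-subject random
#' intercepts and random slopes for PE, PO and PE:PO under an unstructured
#' covariance.  Estimation is by Laplace-approximated maximum likelihood
#' (lme4); each coefficient gets a Wald z test (chi-square = z^2, 1 df), a
#' 95\% Wald CI, and an odds ratio exp(beta).
#'
#' @param analysis_table Table from [build_analysis_table()] (needs at
#'   least 2 subjects and within-subject variation in `pe` and `po`).
#' @param formula_spec `"basic"` (PE * PO), `"full"` (PE * PO * learning
#'   rate * experiment), or a custom formula whose random slopes must all
#'   be within-subject variables.
#' @return A `mixed_logistic_fit`: `fixed` coefficient table, random-effect
#'   covariance matrix and SDs, singularity flag, and the underlying lme4
#'   model.
#' @export
fit_mixed_logistic <- function(analysis_table, formula_spec = "basic") {
  if (length(unique(analysis_table$subject)) < 2) {
    stop("at least 2 subjects are required")
  }
  glmer_fit(mixed_formula(formula_spec), analysis_table)
}

#' Simple slopes of PE by prediction outcome
#'
#' Breaks the PE-by-outcome interaction down by refitting the PE effect
#' separately in the correct-prediction and incorrect-prediction subsets,
#' each with a by-subject random intercept and PE slope.
#'
#' @inheritParams fit_mixed_logistic
#' @return List with elements `correct` and `incorrect`, each a
#'   `mixed_logistic_fit` of `hit ~ pe + (1 + pe | subject)`.
#' @export
simple_slopes <- function(analysis_table) {
  out <- lapply(c(correct = 0.5, incorrect = -0.5), function(code) {
    sub <- analysis_table[analysis_table$po == code, ]
    if (nrow(sub) == 0) stop("empty prediction-outcome subset")
    if (length(unique(sub$subject)) < 2) {
      stop("prediction-outcome subset with fewer than 2 subjects")
    }
    glmer_fit(hit ~ pe + (1 + pe | subject), sub)
  })
  out
}

#' Signed-PE subsequent-memory model
#'
#' Variant of the memory model using the signed PE of the chosen category
#' (positive after correct, negative after incorrect predictions) as the
#' predictor, with a by-subject random intercept and slope.
#'
#' @inheritParams fit_mixed_logistic
#' @return A `mixed_logistic_fit` of `hit ~ pe_signed +
#'   (1 + pe_signed | subject)`.
#' @export
signed_pe_analysis <- function(analysis_table) {
  glmer_fit(hit ~ pe_signed + (1 + pe_signed | subject), analysis_table)
}

#' Binned-PE hit-rate analysis
#'
#' Bins each subject's PE values into within-subject quartiles, computes
#' the hit rate per subject, bin and prediction outcome, fits a linear
#' mixed model of hit rate on bin-by-outcome with a by-subject random
#' intercept, and tests all pairwise bin contrasts with Bonferroni
#' correction (p multiplied by the number of comparisons, capped at 1).
#' Subjects with fewer than 4 distinct PE values are dropped with a
#' warning.
#'
#' @inheritParams fit_mixed_logistic
#' @return List with `bin_table` (subject x bin x outcome hit rates),
#'   `model` (lmer fit), and `contrasts` (pairwise bin contrasts with raw
#'   and Bonferroni-corrected p values).
#' @export
binned_pe_analysis <- function(analysis_table) {
  n_distinct_pe <- tapply(analysis_table$pe, analysis_table$subject,
                          function(x) length(unique(x)))
  drop <- names(n_distinct_pe)[n_distinct_pe < 4]
  if (length(drop)) {
    warning("dropping subject(s) with fewer than 4 distinct PE values: ",
            paste(drop, collapse = ", "))
    analysis_table <-
      analysis_table[!analysis_table$subject %in% drop, ]
  }
  tab <- dplyr::group_by(analysis_table, .data$subject)
  tab <- dplyr::mutate(tab, pe_bin = dplyr::ntile(.data$pe, 4))
  tab <- dplyr::group_by(tab, .data$subject, .data$pe_bin, .data$po)
  bin_table <- dplyr::summarise(
    tab, n_items = dplyr::n(), hit_rate = mean(.data$hit), .groups = "drop"
  )
  bin_table$pe_bin <- factor(bin_table$pe_bin)
  bin_table$po_f <- factor(ifelse(bin_table$po > 0, "correct", "incorrect"))
  model <- lme4::lmer(hit_rate ~ pe_bin * po_f + (1 | subject),
                      data = bin_table)
  em <- emmeans::emmeans(model, ~pe_bin)
  ct <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "none"))
  ct$p_corrected <- pmin(ct$p.value * nrow(ct), 1)
  list(bin_table = bin_table, model = model, contrasts = as_tibble(ct))
}
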
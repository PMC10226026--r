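#' Build the design of a contingency-learning experiment
#'
#' Returns the full specification of one of the two study designs: six scene
#' contexts, each probabilistically predictive of one object category.
#' Experiment 1 uses three object categories with 0.80--0.20 contingencies in
#' half of the contexts and uniform (0.33) contingencies in the other half.
#' Experiment 2 uses two object categories with 0.90--0.10, 0.70--0.30 and
#' 0.50--0.50 contingencies (two contexts each).  The design also carries the
#' filler-object rules that realize each contingency during the encoding
#' phase without inflating the number of unique to-be-remembered objects, and
#' the composition of the recognition test.
#'
#' @param experiment_id `"EXP1"` or `"EXP2"`.
#'
#' @return An object of class `experiment_design`: a list with elements
#'   `experiment_id`, `n_categories`, `contexts` (tibble with `context`,
#'   `condition`, `p_dominant`), `filler_rules` (tibble with per-condition
#'   unique-object and filler counts), and `recognition_rules` (list with
#'   `n_new` distractors and `immediate_fraction` of old items tested
#'   immediately).
#'
#' @examples
#' d1 <- build_design("EXP1")
#' d1$contexts
#' @export
build_design <- function(experiment_id) {
  experiment_id <- match.arg(experiment_id, c("EXP1", "EXP2"))
  if (experiment_id == "EXP1") {
    contexts <- tibble(
      context = 1:6,
      condition = rep(c("0.80-0.20", "0.33"), each = 3),
      p_dominant = rep(c(0.80, NA_real_), each = 3)
    )
    # 0.80-contexts: 24 unique objects (8 per category) plus 8 dominant
    # fillers repeated 7 times -> 64/8/8 trials = 0.80/0.10/0.10.
    filler_rules <- tibble(
      condition = c("0.80-0.20", "0.33"),
      n_unique = c(24L, 24L),
      n_fillers = c(8L, 0L),
      filler_repeats = c(7L, 0L),
      filler_target = c("dominant", "none")
    )
    design <- list(
      experiment_id = experiment_id,
      n_categories = 3L,
      contexts = contexts,
      filler_rules = filler_rules,
      recognition_rules = list(n_new = 144L, immediate_fraction = 0.5)
    )
  } else {
    contexts <- tibble(
      context = 1:6,
      condition = rep(c("0.90-0.10", "0.70-0.30", "0.50-0.50"), each = 2),
      p_dominant = rep(c(0.90, 0.70, NA_real_), each = 2)
    )
    # 0.90: 20 unique (10/10) + 5 fillers x16 -> 90/10 of 100 trials.
    # 0.70: 20 unique (10/10) + 5 fillers x3  -> 25/10 of 35 trials.
    # 0.50: 10 unique (5/5) + 10 fillers x2 split across categories -> 15/15.
    filler_rules <- tibble(
      condition = c("0.90-0.10", "0.70-0.30", "0.50-0.50"),
      n_unique = c(20L, 20L, 10L),
      n_fillers = c(5L, 5L, 10L),
      filler_repeats = c(16L, 3L, 2L),
      filler_target = c("dominant", "dominant", "all")
    )
    design <- list(
      experiment_id = experiment_id,
      n_categories = 2L,
      contexts = contexts,
      filler_rules = filler_rules,
      recognition_rules = list(n_new = 80L, immediate_fraction = 1)
    )
  }
  class(design) <- "experiment_design"
  design
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design> ", x$experiment_id,
      ": ", x$n_categories, " categories, ",
      nrow(x$contexts), " contexts\n", sep = "")
  print(x$contexts)
  invisible(x)
}

#' Counterbalance the context-to-dominant-category assignment
#'
#' Assigns, for a given participant, which object category is dominant in
#' each non-uniform context.  The assignment is a deterministic Latin-square
#' rotation over participant index, so that across a full rotation cycle
#' every category is dominant in every context of a contingency condition
#' equally often.  Uniform-contingency contexts have no dominant category
#' (`NA`).
#'
#' @param participant_index Zero-based participant index.
#' @param design An `experiment_design`.
#'
#' @return Integer vector of length 6: dominant category per context (`NA`
#'   for uniform contexts), with attribute `rotation_length` (3 for EXP1, 2
#'   for EXP2).
#' @examples
#' counterbalance_assignment(0, build_design("EXP1"))
#' @export
counterbalance_assignment <- function(participant_index, design) {
  stopifnot(inherits(design, "experiment_design"),
            length(participant_index) == 1, participant_index >= 0)
  J <- design$n_categories
  out <- rep(NA_integer_, nrow(design$contexts))
  for (cond in unique(design$contexts$condition)) {
    idx <- which(design$contexts$condition == cond)
    if (is.na(design$contexts$p_dominant[idx[1]])) next
    # rotate categories across the contexts of this condition
    out[idx] <- as.integer(((seq_along(idx) - 1 + participant_index) %% J) + 1)
  }
  structure(out, rotation_length = J)
}

# Nominal category-probability vector for one context under an assignment.
context_probs <- function(design, assignment, context) {
  J <- design$n_categories
  dom <- assignment[context]
  if (is.na(dom)) return(rep(1 / J, J))
  p_dom <- design$contexts$p_dominant[design$contexts$context == context]
  p <- rep((1 - p_dom) / (J - 1), J)
  p[dom] <- p_dom
  p
}

# Largest-remainder (Hamilton) apportionment of n trials to probabilities p.
largest_remainder <- function(p, n) {
  stopifnot(abs(sum(p) - 1) < 1e-8, n >= 0)
  raw <- p * n
  base <- floor(raw)
  k <- n - sum(base)
  if (k > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(k)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}
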
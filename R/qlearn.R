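#' Model specifications for the four delta-rule learning models
#'
#' The four models share a delta-rule update of context-specific expected
#' values Q and a softmax choice rule, and differ in the effective learning
#' rate and the feedback they use:
#' \describe{
#'   \item{dLRI}{decreasing learning rate 1/t, instructive feedback; the
#'     delta-rule form of the optimal running-mean learner.  One free
#'     parameter (beta).}
#'   \item{dfLRI}{individual decreasing rate alpha/t, instructive.  Two free
#'     parameters.}
#'   \item{fLRI}{individual constant rate alpha, instructive.  Two free
#'     parameters.}
#'   \item{fLRE}{individual constant rate alpha, evaluative: only the chosen
#'     category's value is updated, towards 1 after a correct prediction and
#'     towards 0 after an incorrect one.  Two free parameters.}
#' }
#' Instructive feedback updates all categories of the current context from
#' the one-hot vector of the presented category, regardless of the choice.
#'
#' @param name One of `"dLRI"`, `"dfLRI"`, `"fLRI"`, `"fLRE"`.
#' @return A `model_spec` list: `name`, `feedback` ("instructive" or
#'   "evaluative"), `free` (names of free parameters), `k` (their number),
#'   and `bounds` (alpha in \[0,1\], beta in \[0,10\]).
#' @examples
#' model_spec("fLRI")
#' @export
model_spec <- function(name = c("dLRI", "dfLRI", "fLRI", "fLRE")) {
  name <- match.arg(name)
  free <- if (name == "dLRI") "beta" else c("alpha", "beta")
  structure(list(
    name = name,
    feedback = if (name == "fLRE") "evaluative" else "instructive",
    free = free,
    k = length(free),
    bounds = list(alpha = c(0, 1), beta = c(0, 10))
  ), class = "model_spec")
}

#' All four model names in their canonical order
#' @return Character vector `c("dLRI", "dfLRI", "fLRI", "fLRE")`.
#' @export
model_names <- function() c("dLRI", "dfLRI", "fLRI", "fLRE")

# integer code used by the compiled likelihood
model_code <- function(name) match(name, model_names()) - 1L

#' Initialize a Q table
#'
#' Expected values are stored as a categories-by-contexts matrix, every
#' entry initialized to the uniform probability 1/J (1/3 with three
#' categories, 0.5 with two), with per-context trial counters at zero.
#'
#' @param n_categories Number of object categories J.
#' @param n_contexts Number of contexts C.
#' @return A `q_table` list with `values` (J-by-C matrix) and integer
#'   counters `t` (length C).
#' @export
init_q_table <- function(n_categories, n_contexts) {
  stopifnot(n_categories >= 1, n_contexts >= 1)
  structure(list(
    values = matrix(1 / n_categories, nrow = n_categories, ncol = n_contexts),
    t = integer(n_contexts)
  ), class = "q_table")
}

#' One-hot feedback vector for the presented category
#'
#' @param presented_category Index of the category shown on this trial.
#' @param n_categories Number of categories J.
#' @return Numeric vector of length J with a single 1 at the presented
#'   category.
#' @export
feedback_vector <- function(presented_category, n_categories) {
  if (presented_category < 1 || presented_category > n_categories) {
    stop("presented category index out of range")
  }
  r <- numeric(n_categories)
  r[presented_category] <- 1
  r
}

#' Instructive delta-rule update of one context's Q row
#'
#' Updates every category's value in the current context towards the one-hot
#' feedback vector of the presented category, with effective learning rate
#' 1/t (dLRI), alpha/t (dfLRI), or alpha (fLRI).  The context's trial
#' counter must have been advanced to the current trial index first.
#'
#' @param q_table A `q_table` whose counter for `context` is already at the
#'   current trial.
#' @param spec A `model_spec` with instructive feedback.
#' @param context Context index.
#' @param presented_category Category shown on this trial.
#' @param alpha Learning rate (ignored by dLRI).
#' @return The updated `q_table`, with attribute `delta` holding the full
#'   prediction-error vector r - Q used in the update.
#' @export
step_instructive <- function(q_table, spec, context, presented_category,
                             alpha = NA_real_) {
  stopifnot(inherits(q_table, "q_table"), spec$feedback == "instructive")
  t_cur <- q_table$t[context]
  if (t_cur < 1) stop("context counter is 0; advance it before updating")
  rate <- switch(spec$name,
    dLRI = 1 / t_cur,
    dfLRI = alpha / t_cur,
    fLRI = alpha
  )
  r <- feedback_vector(presented_category, nrow(q_table$values))
  delta <- r - q_table$values[, context]
  q_table$values[, context] <- q_table$values[, context] + rate * delta
  attr(q_table, "delta") <- delta
  q_table
}

#' Evaluative delta-rule update of the chosen category only
#'
#' Only the chosen category's value is updated, towards 1 if the prediction
#' was correct and towards 0 if not; all other entries are unchanged.
#'
#' @inheritParams step_instructive
#' @param chosen_category Category the agent chose.
#' @param correct Logical: was the choice correct?
#' @return Updated `q_table` with attribute `delta` (scalar r - Q of the
#'   chosen category).
#' @export
step_evaluative <- function(q_table, context, chosen_category, correct,
                            alpha) {
  stopifnot(inherits(q_table, "q_table"))
  if (chosen_category < 1 || chosen_category > nrow(q_table$values)) {
    stop("chosen category index out of range")
  }
  r <- as.numeric(correct)
  delta <- r - q_table$values[chosen_category, context]
  q_table$values[chosen_category, context] <-
    q_table$values[chosen_category, context] + alpha * delta
  attr(q_table, "delta") <- delta
  q_table
}

#' Softmax choice probabilities
#'
#' Translates a row of expected values into choice probabilities,
#' \eqn{P^j = \exp(\beta Q^j) / \sum_n \exp(\beta Q^n)}.  Computed with a
#' max-shift so it is overflow-safe and invariant to adding a constant to
#' all values; beta = 0 yields the uniform distribution.
#'
#' @param q_row Numeric vector of expected values for one context.
#' @param beta Inverse temperature (>= 0); larger values give more
#'   deterministic choices.
#' @return Probability vector summing to 1.
#' @export
softmax_probs <- function(q_row, beta) {
  stopifnot(beta >= 0)
  z <- beta * q_row
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Unsigned prediction error of the presented category
#'
#' One minus the pre-update expected value of the category that was
#' presented: large when the presented category was unexpected.
#'
#' @param q_row Pre-update expected values for the current context.
#' @param presented_category Category shown on this trial.
#' @return Scalar in \[0, 1\].
#' @export
unsigned_pe <- function(q_row, presented_category) {
  1 - q_row[presented_category]
}

#' Signed prediction error of the chosen category
#'
#' Incorporates the prediction outcome: r - Q of the chosen category, with
#' r = 1 for a correct and 0 for an incorrect prediction.  Positive after
#' correct predictions, negative after incorrect ones.
#'
#' @param q_row Pre-update expected values for the current context.
#' @param chosen_category Category the participant chose.
#' @param correct Logical prediction outcome.
#' @return Scalar in \[-1, 1\].
#' @export
signed_pe <- function(q_row, chosen_category, correct) {
  as.numeric(correct) - q_row[chosen_category]
}

#' Replay a learning model over a trial sequence
#'
#' Runs one model with fixed parameters over a subject's pooled
#' learning-plus-encoding schedule and observed choices, emitting per-trial
#' quantities evaluated on the *pre-update* Q values: the expected value and
#' softmax probability of the chosen category, the unsigned PE of the
#' presented category, the signed PE of the chosen category, and the
#' prediction outcome.  All trials -- including fillers -- update Q; filler
#' exclusion happens later, in the memory analysis.
#'
#' @param schedule Pooled schedule tibble (with `context`, `context_trial`,
#'   `category_shown`).
#' @param choices Integer vector of chosen categories, aligned to the
#'   schedule rows, or a data frame with a `category_chosen` column.
#' @param spec A `model_spec`.
#' @param params Named numeric vector with `beta` and (except dLRI)
#'   `alpha`.
#' @return The schedule with added columns `category_chosen`, `accuracy`,
#'   `q_shown`, `q_chosen`, `p_chosen`, `pe_unsigned`, `pe_signed`,
#'   `outcome`.
#' @export
run_model <- function(schedule, choices, spec, params) {
  if (is.data.frame(choices)) choices <- choices$category_chosen
  if (length(choices) != nrow(schedule)) {
    stop("choices are misaligned with the schedule: ", length(choices),
         " choices for ", nrow(schedule), " trials")
  }
  J <- max(schedule$category_shown, choices)
  n_ctx <- max(schedule$context)
  alpha <- unname(params["alpha"])
  beta <- unname(params["beta"])
  q <- init_q_table(J, n_ctx)
  n <- nrow(schedule)
  q_shown <- q_chosen <- p_chosen <- pe_u <- pe_s <- numeric(n)
  outcome <- logical(n)
  for (i in seq_len(n)) {
    ctx <- schedule$context[i]
    shown <- schedule$category_shown[i]
    chosen <- choices[i]
    row <- q$values[, ctx]
    probs <- softmax_probs(row, beta)
    correct <- chosen == shown
    q_shown[i] <- row[shown]
    q_chosen[i] <- row[chosen]
    p_chosen[i] <- probs[chosen]
    pe_u[i] <- unsigned_pe(row, shown)
    pe_s[i] <- signed_pe(row, chosen, correct)
    outcome[i] <- correct
    q$t[ctx] <- q$t[ctx] + 1L
    if (spec$feedback == "instructive") {
      q <- step_instructive(q, spec, ctx, shown, alpha)
    } else {
      q <- step_evaluative(q, ctx, chosen, correct, alpha)
    }
  }
  out <- schedule
  out$category_chosen <- choices
  out$accuracy <- as.integer(outcome)
  out$q_shown <- q_shown
  out$q_chosen <- q_chosen
  out$p_chosen <- p_chosen
  out$pe_unsigned <- pe_u
  out$pe_signed <- pe_s
  out$outcome <- outcome
  out
}
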
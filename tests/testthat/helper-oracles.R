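# Independent oracles, deliberately written from the defining formulas and
# kept separate from the package's code paths.

# Plain-R recursion for the choice negative log-likelihood of every model.
nll_oracle <- function(model, alpha, beta, context, shown, chosen, J, n_ctx) {
  Q <- matrix(1 / J, J, n_ctx)
  tc <- rep(0, n_ctx)
  nll <- 0
  for (i in seq_along(context)) {
    cc <- context[i]
    p <- exp(beta * Q[, cc]) / sum(exp(beta * Q[, cc]))
    nll <- nll - log(max(p[chosen[i]], 1e-12))
    tc[cc] <- tc[cc] + 1
    if (model == "fLRE") {
      r <- as.numeric(chosen[i] == shown[i])
      Q[chosen[i], cc] <- Q[chosen[i], cc] +
        alpha * (r - Q[chosen[i], cc])
    } else {
      rate <- switch(model, dLRI = 1 / tc[cc], dfLRI = alpha / tc[cc],
                     fLRI = alpha)
      r <- as.numeric(seq_len(J) == shown[i])
      Q[, cc] <- Q[, cc] + rate * (r - Q[, cc])
    }
  }
  nll
}

# Running-mean oracle: empirical presentation frequencies per context after
# each trial (what the 1/t delta rule must reproduce).
running_freq_oracle <- function(context, shown, J, n_ctx) {
  counts <- matrix(0, J, n_ctx)
  out <- matrix(NA_real_, length(context), J)
  for (i in seq_along(context)) {
    cc <- context[i]
    counts[shown[i], cc] <- counts[shown[i], cc] + 1
    out[i, ] <- counts[, cc] / sum(counts[, cc])
  }
  out
}

# Reach the internal context-probability helper.
context_probs_for_test <- function(design, assignment, ctx) {
  getFromNamespace("context_probs", "pemem")(design, assignment, ctx)
}

# Small arbitrary schedule over a couple of contexts for property tests.
random_toy_schedule <- function(n, J, n_ctx, seed) {
  set.seed(seed)
  tibble::tibble(
    subject = 1L,
    context = sample.int(n_ctx, n, replace = TRUE),
    category_shown = sample.int(J, n, replace = TRUE)
  )
}
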
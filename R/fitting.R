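#' Negative log-likelihood of a subject's choices under a learning model
#'
#' The likelihood of the data is the product over trials of the softmax
#' probability of the observed choice given the model-updated expected
#' values; this returns its negative log, the objective minimized during
#' fitting.  Learning and encoding trials (fillers included) are modelled
#' identically.  Probabilities are floored at `prob_floor` inside the log so
#' the objective stays finite even for extreme parameters.
#'
#' @param params Named numeric vector with `beta` and (except dLRI)
#'   `alpha`.
#' @param spec A [model_spec()].
#' @param subject_data Pooled schedule with choices: needs columns
#'   `context`, `category_shown`, `category_chosen`, rows in presentation
#'   order.
#' @param prob_floor Lower bound applied to choice probabilities
#'   (default `1e-12`).
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(params, spec, subject_data,
                                    prob_floor = 1e-12) {
  alpha <- if ("alpha" %in% names(params)) unname(params["alpha"]) else 0
  beta <- unname(params["beta"])
  # J must cover every category that was shown *or* chosen: a short
  # sequence need not present all categories.
  rl_nll_cpp(model_code(spec$name), alpha, beta,
             as.integer(subject_data$context),
             as.integer(subject_data$category_shown),
             as.integer(subject_data$category_chosen),
             max(subject_data$category_shown,
                 subject_data$category_chosen),
             max(subject_data$context),
             prob_floor)
}

# Draw (alpha, beta) from the fitting priors: alpha ~ U(0,1),
# beta ~ Exp(1) truncated to the fitting bound by resampling.
sample_prior_params <- function(n = 1, beta_max = 10) {
  alpha <- runif(n)
  beta <- rexp(n)
  while (any(beta > beta_max)) {
    beta[beta > beta_max] <- rexp(sum(beta > beta_max))
  }
  data.frame(alpha = alpha, beta = beta)
}

#' Bayesian information criterion
#'
#' `-2 * LL_max + k * ln(T)`: penalizes the maximized log-likelihood by the
#' number of free parameters scaled by the (natural) log of the number of
#' modelled trials.  Lower is better.
#'
#' @param ll_max Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n_trials Number of modelled choice trials T.
#' @return Scalar BIC.
#' @examples
#' bic(-100, 2, 312)
#' @export
bic <- function(ll_max, k, n_trials) {
  stopifnot(n_trials >= 1)
  -2 * ll_max + k * log(n_trials)
}

#' Fit one model to one subject by maximum likelihood
#'
#' Bounded optimization (L-BFGS-B) of the negative log-likelihood from
#' several starting points drawn from the parameter priors (alpha ~ U(0,1),
#' beta ~ Exp(1) truncated at the bound); the restart with the smallest
#' objective wins.  Bounds are alpha in \[0,1\], beta in \[0,10\].
#'
#' @inheritParams negative_log_likelihood
#' @param n_restarts Number of random restarts (default 5).
#' @param seed Integer seed for the starting points.
#' @return A `fit_result` list: `subject`, `model`, `alpha` (NA for dLRI),
#'   `beta`, `ll` (maximized log-likelihood), `bic`, `n_trials`,
#'   `n_restarts`, and a `restarts` data frame with each start, objective
#'   and convergence code.
#' @export
fit_mle <- function(subject_data, spec, n_restarts = 5, seed = 1L,
                    prob_floor = 1e-12) {
  stopifnot(n_restarts >= 1)
  set.seed(seed)
  starts <- sample_prior_params(n_restarts)
  lower <- c(alpha = 0, beta = 0)[spec$free]
  upper <- c(alpha = 1, beta = 10)[spec$free]
  obj <- function(par) {
    negative_log_likelihood(setNames(par, spec$free), spec, subject_data,
                            prob_floor)
  }
  rows <- vector("list", n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    par0 <- unlist(starts[r, spec$free, drop = FALSE])
    fit <- tryCatch(
      optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      rows[[r]] <- data.frame(restart = r, t(par0), value = NA_real_,
                              convergence = NA_integer_)
      next
    }
    rows[[r]] <- data.frame(restart = r, t(setNames(fit$par, spec$free)),
                            value = fit$value, convergence = fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("all ", n_restarts, " restarts failed for model ", spec$name,
         " (subject ", subject_data$subject[1], ")")
  }
  par <- setNames(best$par, spec$free)
  n_trials <- nrow(subject_data)
  ll <- -best$value
  structure(list(
    subject = subject_data$subject[1],
    model = spec$name,
    alpha = if ("alpha" %in% spec$free) unname(par["alpha"]) else NA_real_,
    beta = unname(par["beta"]),
    ll = ll,
    bic = bic(ll, spec$k, n_trials),
    n_trials = n_trials,
    n_restarts = n_restarts,
    restarts = dplyr::bind_rows(rows)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> subject", x$subject, "model", x$model,
      sprintf("alpha=%.3f beta=%.3f LL=%.2f BIC=%.2f (%d restarts)\n",
              x$alpha, x$beta, x$ll, x$bic, x$n_restarts))
  invisible(x)
}

#' Fit all models to all subjects of a trial table
#'
#' Convenience wrapper looping [fit_mle()] over subjects and models.
#'
#' @param trials Pooled trial table with choices for one or more subjects.
#' @param models Character vector of model names (default all four).
#' @param n_restarts,seed,prob_floor Passed to [fit_mle()]; each
#'   subject-model pair gets its own derived seed.
#' @return Tibble with one row per subject and model: `subject`, `model`,
#'   `alpha`, `beta`, `ll`, `bic`, `n_trials`.
#' @export
fit_study <- function(trials, models = model_names(), n_restarts = 5,
                      seed = 1L, prob_floor = 1e-12) {
  subjects <- unique(trials$subject)
  out <- list()
  for (s in subjects) {
    dat <- trials[trials$subject == s, ]
    for (m in models) {
      f <- fit_mle(dat, model_spec(m), n_restarts = n_restarts,
                   seed = derive_seed(seed, match(s, subjects),
                                      match(m, model_names())),
                   prob_floor = prob_floor)
      out[[length(out) + 1]] <- tibble(
        subject = f$subject, model = f$model, alpha = f$alpha,
        beta = f$beta, ll = f$ll, bic = f$bic, n_trials = f$n_trials
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Evidence strength from a BIC difference
#'
#' Grades the difference between the best and second-best model's BIC:
#' weak below 2, positive in \[2, 6), strong in \[6, 10), very strong at 10
#' or above.
#'
#' @param delta_bic Non-negative BIC difference(s).
#' @return Factor with levels weak, positive, strong, very strong.
#' @export
evidence_band <- function(delta_bic) {
  stopifnot(all(delta_bic >= 0))
  cut(delta_bic, breaks = c(-Inf, 2, 6, 10, Inf), right = FALSE,
      labels = c("weak", "positive", "strong", "very strong"))
}

#' Compare fitted models across subjects
#'
#' Per model: mean BIC across subjects with its standard error, the number
#' of subjects best fit by the model, and the number among those with very
#' strong evidence (BIC margin over the runner-up above 10).  Within a
#' subject, BIC ties are broken in favour of fewer parameters, then
#' canonical model order.
#'
#' @param fits Tibble from [fit_study()] (all models fitted for every
#'   subject).
#' @return A `model_comparison` list with `table` (per-model summary) and
#'   `per_subject` (best model, runner-up, delta BIC and evidence label per
#'   subject).
#' @export
compare_models <- function(fits) {
  models <- model_names()
  by_subj <- split(fits, fits$subject)
  incomplete <- names(by_subj)[vapply(by_subj, function(d) {
    !all(models %in% d$model)
  }, logical(1))]
  if (length(incomplete)) {
    stop("missing model fits for subject(s): ",
         paste(incomplete, collapse = ", "))
  }
  per_subject <- dplyr::bind_rows(lapply(by_subj, function(d) {
    k <- ifelse(d$model == "dLRI", 1L, 2L)
    ord <- order(d$bic, k, match(d$model, models))
    delta <- d$bic[ord[2]] - d$bic[ord[1]]
    tibble(
      subject = d$subject[1],
      best_model = d$model[ord[1]],
      runner_up = d$model[ord[2]],
      delta_bic = delta,
      evidence = evidence_band(delta)
    )
  }))
  table <- dplyr::bind_rows(lapply(models, function(m) {
    b <- fits$bic[fits$model == m]
    best <- per_subject$best_model == m
    tibble(
      model = m,
      mean_bic = mean(b),
      se_bic = sd(b) / sqrt(length(b)),
      n_best = sum(best),
      n_very_strong = sum(best & per_subject$evidence == "very strong")
    )
  }))
  structure(list(table = table, per_subject = per_subject),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> over", nrow(x$per_subject), "subjects\n")
  print(x$table)
  invisible(x)
}
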
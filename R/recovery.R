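#' Parameter recovery for one learning model
#'
#' Simulates agents with known parameters drawn from the fitting priors on
#' the learnable (non-uniform) contingency conditions of a design, refits
#' the same model to each simulated choice sequence, and reports paired
#' true/fitted parameters with their correlations.  High correlations mean
#' the fitting procedure can distinguish different parameter values.
#'
#' @param spec A [model_spec()].
#' @param design An `experiment_design`.
#' @param n_agents Number of simulated agents.
#' @param seed Master seed.
#' @param n_restarts Restarts per fit (default 5).
#' @param learning_trials_per_context Length of the learning phase.
#' @return A `recovery_report` list with `results` (tibble of true and
#'   fitted parameters per agent) and `correlations` (named vector, one
#'   entry per free parameter; empty report for `n_agents = 0`).
#' @export
parameter_recovery <- function(spec, design, n_agents, seed = 1L,
                               n_restarts = 5,
                               learning_trials_per_context = 40) {
  rows <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    sched <- learnable_schedule(design, subject = i,
                                seed = derive_seed(seed, i, 1),
                                learning_trials_per_context)
    set.seed(derive_seed(seed, i, 2))
    pars <- sample_prior_params(1)
    params <- c(alpha = pars$alpha, beta = pars$beta)[spec$free]
    sim <- simulate_agent(spec, params, sched,
                          seed = derive_seed(seed, i, 3))
    fit <- fit_mle(sim, spec, n_restarts = n_restarts,
                   seed = derive_seed(seed, i, 4))
    rows[[i]] <- tibble(
      agent = i,
      alpha_true = if ("alpha" %in% spec$free) pars$alpha else NA_real_,
      beta_true = pars$beta,
      alpha_fit = fit$alpha,
      beta_fit = fit$beta
    )
  }
  results <- dplyr::bind_rows(rows)
  correlations <- numeric(0)
  if (n_agents >= 3) {
    correlations <- vapply(spec$free, function(p) {
      cor(results[[paste0(p, "_true")]], results[[paste0(p, "_fit")]])
    }, numeric(1))
  }
  structure(list(model = spec$name, results = results,
                 correlations = correlations),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$model, "-", nrow(x$results), "agents\n")
  if (length(x$correlations)) print(round(x$correlations, 3))
  invisible(x)
}

#' Model recovery confusion matrix
#'
#' For each repetition and each generating model: simulate an agent with
#' parameters drawn from the priors on the learnable conditions, fit all
#' four models, and record which has the lowest BIC (ties broken by fewer
#' parameters, then canonical order).  A diagonal-dominant matrix means the
#' models are mutually identifiable.
#'
#' @inheritParams parameter_recovery
#' @param n_reps Repetitions per generating model (default 100).
#' @return A 4-by-4 integer matrix (generating model in rows, best-fitting
#'   model in columns); each row sums to `n_reps`.
#' @export
model_recovery <- function(design, n_reps = 100, seed = 1L, n_restarts = 5,
                           learning_trials_per_context = 40) {
  models <- model_names()
  conf <- matrix(0L, 4, 4, dimnames = list(generated = models,
                                           fitted = models))
  for (rep in seq_len(n_reps)) {
    for (g in seq_along(models)) {
      gspec <- model_spec(models[g])
      sched <- learnable_schedule(design, subject = rep,
                                  seed = derive_seed(seed, rep, g, 1),
                                  learning_trials_per_context)
      set.seed(derive_seed(seed, rep, g, 2))
      pars <- sample_prior_params(1)
      params <- c(alpha = pars$alpha, beta = pars$beta)[gspec$free]
      sim <- simulate_agent(gspec, params, sched,
                            seed = derive_seed(seed, rep, g, 3))
      fits <- lapply(seq_along(models), function(m) {
        fit_mle(sim, model_spec(models[m]), n_restarts = n_restarts,
                seed = derive_seed(seed, rep, g, 4, m))
      })
      bics <- vapply(fits, `[[`, numeric(1), "bic")
      k <- ifelse(models == "dLRI", 1L, 2L)
      best <- order(bics, k, seq_along(models))[1]
      conf[g, best] <- conf[g, best] + 1L
    }
  }
  conf
}

# Pooled schedule restricted to the learnable (non-uniform) contingency
# conditions, used by the recovery diagnostics; counters recomputed after
# the restriction.
learnable_schedule <- function(design, subject, seed,
                               learning_trials_per_context = 40) {
  assignment <- counterbalance_assignment(subject - 1, design)
  learn <- generate_learning_schedule(design, assignment,
                                      learning_trials_per_context,
                                      seed = derive_seed(seed, 1),
                                      subject = subject)
  enc <- generate_encoding_schedule(design, assignment,
                                    seed = derive_seed(seed, 2),
                                    subject = subject)
  pooled <- pool_phases(learn, enc)
  keep <- design$contexts$context[!is.na(design$contexts$p_dominant)]
  pooled <- pooled[pooled$context %in% keep, ]
  pooled$trial <- seq_len(nrow(pooled))
  add_context_counter(pooled)
}
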
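#' Simulate a softmax learning agent on a trial schedule
#'
#' Walks the schedule in order; on each trial the agent samples a category
#' prediction from the softmax over the current context's expected values,
#' then updates the values according to the model's rule after the
#' presented category is revealed.
#'
#' @param spec A [model_spec()].
#' @param params Named vector with `beta` and (except dLRI) `alpha`, within
#'   bounds.
#' @param schedule Pooled schedule tibble in presentation order.
#' @param seed Integer seed; same seed and parameters give identical
#'   choices.
#' @return The schedule with `category_chosen`, `accuracy` (0/1) and
#'   `p_chosen` (softmax probability of the sampled choice) columns added.
#' @export
simulate_agent <- function(spec, params, schedule, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  alpha <- if ("alpha" %in% names(params)) unname(params["alpha"]) else NA
  beta <- unname(params["beta"])
  if (!is.na(alpha) && (alpha < 0 || alpha > 1)) stop("alpha out of bounds")
  if (beta < 0 || beta > 10) stop("beta out of bounds")
  J <- max(schedule$category_shown)
  n_ctx <- max(schedule$context)
  q <- init_q_table(J, n_ctx)
  n <- nrow(schedule)
  chosen <- integer(n)
  p_chosen <- numeric(n)
  set.seed(seed)
  for (i in seq_len(n)) {
    ctx <- schedule$context[i]
    shown <- schedule$category_shown[i]
    probs <- softmax_probs(q$values[, ctx], beta)
    ch <- sample.int(J, 1L, prob = probs)
    chosen[i] <- ch
    p_chosen[i] <- probs[ch]
    q$t[ctx] <- q$t[ctx] + 1L
    if (spec$feedback == "instructive") {
      q <- step_instructive(q, spec, ctx, shown, alpha)
    } else {
      q <- step_evaluative(q, ctx, ch, ch == shown, alpha)
    }
  }
  out <- schedule
  out$category_chosen <- chosen
  out$accuracy <- as.integer(chosen == schedule$category_shown)
  out$p_chosen <- p_chosen
  out
}

#' Simulate recognition outcomes from the generative memory model
#'
#' Each old (non-filler encoding) item is recognized with probability
#' `plogis(b0 + b1 PE + b2 PO + b3 PE*PO)` where the four coefficients each
#' receive a subject-specific random effect drawn from independent normal
#' distributions with the supplied standard deviations, PE is the unsigned
#' prediction error at encoding and PO the prediction outcome coded +0.5
#' (correct) / -0.5 (incorrect).  New distractor items are answered "old"
#' with a constant false-alarm probability.
#'
#' @param pe_records Tibble with one row per old item: `subject`,
#'   `object_id`, `pe` (unsigned PE) and `po` (+/-0.5).
#' @param coefficients Numeric vector `c(intercept, pe, po, pe_po)`.
#' @param random_effect_sds Standard deviations of the four subject-level
#'   random effects, same order (default all 0).
#' @param fa_rate False-alarm probability for distractors, in (0, 1).
#' @param seed Integer seed.
#' @param n_new Number of new distractor items per subject (0 for none).
#' @return Tibble with `subject`, `object_id`, `status` ("old"/"new") and
#'   `response` (1 = "old" judgement); attribute `random_effects` holds the
#'   per-subject draws.
#' @export
simulate_recognition <- function(pe_records, coefficients,
                                 random_effect_sds = c(0, 0, 0, 0),
                                 fa_rate = 0.3, seed = 1L, n_new = 0L) {
  needed <- c("subject", "object_id", "pe", "po")
  missing <- setdiff(needed, names(pe_records))
  if (length(missing)) {
    stop("pe_records lacks column(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(length(coefficients) == 4, length(random_effect_sds) == 4,
            fa_rate > 0, fa_rate < 1)
  subjects <- unique(pe_records$subject)
  set.seed(seed)
  re <- matrix(rnorm(4 * length(subjects), 0, rep(random_effect_sds,
                                                  each = length(subjects))),
               ncol = 4, dimnames = list(NULL, c("b0", "b1", "b2", "b3")))
  idx <- match(pe_records$subject, subjects)
  eta <- (coefficients[1] + re[idx, 1]) +
    (coefficients[2] + re[idx, 2]) * pe_records$pe +
    (coefficients[3] + re[idx, 3]) * pe_records$po +
    (coefficients[4] + re[idx, 4]) * pe_records$pe * pe_records$po
  old <- tibble(
    subject = pe_records$subject,
    object_id = pe_records$object_id,
    status = "old",
    response = rbinom(length(eta), 1, plogis(eta))
  )
  new <- NULL
  if (n_new > 0) {
    new <- tibble(
      subject = rep(subjects, each = n_new),
      object_id = sprintf("N_%03d", rep(seq_len(n_new), length(subjects))),
      status = "new",
      response = rbinom(n_new * length(subjects), 1, fa_rate)
    )
  }
  out <- dplyr::bind_rows(old, new)
  attr(out, "random_effects") <- tibble(subject = subjects,
                                        as_tibble(re))
  out
}

#' Simulate an item-level memory dataset directly from the memory model
#'
#' Bypasses the learning task: draws item-level PE values and prediction
#' outcomes, then generates hits from the generative logistic memory model.
#' Used for recovery and calibration studies of the mixed-model machinery
#' at arbitrary sizes.  PE is uniform on (0, 1); the probability of a
#' correct prediction decreases linearly with PE (0.9 at PE = 0 down to 0.1
#' at PE = 1), mimicking the task's coupling between expectation strength
#' and accuracy.
#'
#' @param n_subjects,n_items Numbers of subjects and old items per subject.
#' @param coefficients,random_effect_sds As in [simulate_recognition()].
#' @param seed Integer seed.
#' @return Analysis-ready tibble: `subject`, `object_id`, `hit`, `pe`, `po`.
#' @export
simulate_memory_dataset <- function(n_subjects, n_items, coefficients,
                                    random_effect_sds = c(0, 0, 0, 0),
                                    seed = 1L) {
  set.seed(seed)
  pe <- runif(n_subjects * n_items)
  correct <- rbinom(length(pe), 1, 0.9 - 0.8 * pe)
  rec <- tibble(
    subject = rep(seq_len(n_subjects), each = n_items),
    object_id = sprintf("I_%04d", rep(seq_len(n_items), n_subjects)),
    pe = pe,
    po = ifelse(correct == 1, 0.5, -0.5)
  )
  out <- simulate_recognition(rec, coefficients, random_effect_sds,
                              fa_rate = 0.5, seed = derive_seed(seed, 1),
                              n_new = 0L)
  rec$hit <- out$response
  rec[, c("subject", "object_id", "hit", "pe", "po")]
}

# Default generative memory coefficients and random-effect SDs for the
# synthetic study: the subsequent-memory effect pattern with a strong
# positive PE x prediction-outcome interaction and near-zero main effects.
default_memory_coefficients <- function() {
  c(intercept = 0.66, pe = -0.12, po = 0.10, pe_po = 1.87)
}

default_memory_re_sds <- function() {
  c(intercept = 0.55, pe = 0.17, po = 0.03, pe_po = 0.18)
}

#' Generate a complete synthetic study
#'
#' End-to-end fixture for the whole pipeline: for each subject it builds a
#' counterbalanced learning + encoding schedule, samples agent parameters
#' from the fitting priors (alpha ~ U(0,1), beta ~ Exp(1) truncated to the
#' bound), simulates the agent's choices, derives trial-level prediction
#' errors at the generative parameters, and simulates recognition responses
#' for all old items and new distractors from the generative logistic
#' memory model.  Every random stream is derived from the master seed with
#' fixed per-subject offsets, so the output is fully reproducible and
#' adding subjects leaves existing ones unchanged.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param design An `experiment_design`.
#' @param seed Master seed.
#' @param model Generating model name (default `"fLRI"`).
#' @param memory_coefficients,random_effect_sds Generative memory model,
#'   defaults to a strong positive PE-by-outcome interaction with weak main
#'   effects.
#' @param fa_rate Distractor false-alarm probability.
#' @param learning_trials_per_context Length of the learning phase.
#' @return A `synthetic_study` list: `design`, `trials` (pooled schedules
#'   with choices, all subjects), `trajectories` (per-trial PE records at
#'   the generative parameters), `recognition` (old + new responses with an
#'   `immediate_subset` flag), `agents` (true parameters per subject), and
#'   the generative settings.
#' @export
make_synthetic_study <- function(n_subjects, design, seed = 1L,
                                 model = "fLRI",
                                 memory_coefficients =
                                   default_memory_coefficients(),
                                 random_effect_sds = default_memory_re_sds(),
                                 fa_rate = 0.3,
                                 learning_trials_per_context = 40) {
  stopifnot(n_subjects >= 1, inherits(design, "experiment_design"))
  spec <- model_spec(model)
  trials <- traj <- recog <- vector("list", n_subjects)
  agents <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    assignment <- counterbalance_assignment(i - 1, design)
    learn <- generate_learning_schedule(
      design, assignment, learning_trials_per_context,
      seed = derive_seed(seed, i, 1), subject = i
    )
    enc <- generate_encoding_schedule(design, assignment,
                                      seed = derive_seed(seed, i, 2),
                                      subject = i)
    pooled <- pool_phases(learn, enc)
    set.seed(derive_seed(seed, i, 3))
    pars <- sample_prior_params(1)
    params <- c(alpha = pars$alpha, beta = pars$beta)
    sim <- simulate_agent(spec, params, pooled,
                          seed = derive_seed(seed, i, 4))
    tr <- run_model(pooled, sim$category_chosen, spec, params)
    old_items <- tr[tr$phase == "ENCODING" & !tr$is_filler, ]
    pe_rec <- tibble(
      subject = i,
      object_id = old_items$object_id,
      pe = old_items$pe_unsigned,
      po = ifelse(old_items$outcome, 0.5, -0.5)
    )
    rec <- simulate_recognition(pe_rec, memory_coefficients,
                                random_effect_sds, fa_rate,
                                seed = derive_seed(seed, i, 5),
                                n_new = design$recognition_rules$n_new)
    set.seed(derive_seed(seed, i, 6))
    n_old <- nrow(pe_rec)
    n_imm <- round(design$recognition_rules$immediate_fraction * n_old)
    imm_ids <- sample(pe_rec$object_id, n_imm)
    rec$immediate_subset <- rec$status == "new" |
      rec$object_id %in% imm_ids
    trials[[i]] <- sim
    traj[[i]] <- tr
    recog[[i]] <- rec
    agents[[i]] <- tibble(subject = i, model = model,
                          alpha = params[["alpha"]], beta = params[["beta"]])
  }
  structure(list(
    design = design,
    trials = dplyr::bind_rows(trials),
    trajectories = dplyr::bind_rows(traj),
    recognition = dplyr::bind_rows(recog),
    agents = dplyr::bind_rows(agents),
    memory_coefficients = memory_coefficients,
    random_effect_sds = random_effect_sds,
    fa_rate = fa_rate,
    seed = seed
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>", x$design$experiment_id, "-",
      nrow(x$agents), "subjects,", nrow(x$trials), "trials,",
      nrow(x$recognition), "recognition records\n")
  invisible(x)
}
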
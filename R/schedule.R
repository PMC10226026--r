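#' Generate a learning-phase trial schedule
#'
#' Builds the contingency-learning phase for one participant: each context
#' contributes `n_trials_per_context` trials whose category counts realize
#' the nominal contingencies by largest-remainder apportionment; trial order
#' is a seeded uniform permutation over all contexts pooled.
#'
#' @param design An `experiment_design`.
#' @param assignment Context-to-dominant-category assignment from
#'   [counterbalance_assignment()].
#' @param n_trials_per_context Trials per context (default 40).
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @param subject Subject identifier stored in the table.
#'
#' @return A tibble with one row per trial: `subject`, `experiment`, `phase`,
#'   `trial`, `context`, `context_trial`, `condition`, `category_shown`,
#'   `is_filler`, `object_id`.
#' @export
generate_learning_schedule <- function(design, assignment,
                                       n_trials_per_context = 40,
                                       seed = 1L, subject = 1L) {
  stopifnot(inherits(design, "experiment_design"), n_trials_per_context >= 1)
  rows <- lapply(design$contexts$context, function(ctx) {
    p <- context_probs(design, assignment, ctx)
    counts <- largest_remainder(p, n_trials_per_context)
    if (any(counts < 0)) {
      stop("infeasible trial allocation in context ", ctx)
    }
    cat_shown <- rep(seq_along(counts), counts)
    tibble(
      context = ctx,
      condition = design$contexts$condition[design$contexts$context == ctx],
      category_shown = cat_shown,
      is_filler = FALSE,
      object_id = sprintf("L_c%d_%03d", ctx, seq_along(cat_shown))
    )
  })
  sched <- dplyr::bind_rows(rows)
  set.seed(seed)
  sched <- sched[sample.int(nrow(sched)), ]
  finalize_schedule(sched, design, subject, phase = "LEARNING")
}

#' Generate an encoding-phase trial schedule
#'
#' Builds the encoding phase for one participant.  Each context presents a
#' fixed set of unique, never-repeated objects (equally many per category)
#' plus filler objects repeated several times to realize the contingency:
#' e.g. in the 0.80-contexts of Experiment 1, 24 unique objects (8 per
#' category) are mixed with 8 dominant-category fillers shown 7 times each,
#' so 64 of 80 presentations (80\%) are of the dominant category.  Unique
#' (non-filler) objects appear exactly once and are the items later probed
#' in the recognition test.
#'
#' @inheritParams generate_learning_schedule
#' @return A tibble with the same columns as
#'   [generate_learning_schedule()], plus a `realized_contingency` attribute
#'   recording the per-context empirical category proportions.
#' @export
generate_encoding_schedule <- function(design, assignment, seed = 1L,
                                       subject = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  J <- design$n_categories
  rows <- lapply(design$contexts$context, function(ctx) {
    cond <- design$contexts$condition[design$contexts$context == ctx]
    rule <- design$filler_rules[design$filler_rules$condition == cond, ]
    if (rule$n_unique %% J != 0) {
      stop("infeasible unique-object split across categories in context ", ctx)
    }
    per_cat <- rule$n_unique / J
    uniq <- tibble(
      category_shown = rep(seq_len(J), each = per_cat),
      is_filler = FALSE
    )
    uniq$object_id <- sprintf("E_c%d_j%d_u%02d", ctx, uniq$category_shown,
                              sequence(rep(per_cat, J)))
    fill <- NULL
    if (rule$n_fillers > 0) {
      if (rule$filler_target == "dominant") {
        filler_cat <- rep(assignment[ctx], rule$n_fillers)
      } else {
        if (rule$n_fillers %% J != 0) {
          stop("infeasible filler split across categories in context ", ctx)
        }
        filler_cat <- rep(seq_len(J), each = rule$n_fillers / J)
      }
      fill <- tibble(
        category_shown = rep(filler_cat, each = rule$filler_repeats),
        is_filler = TRUE,
        object_id = rep(sprintf("F_c%d_f%02d", ctx, seq_len(rule$n_fillers)),
                        each = rule$filler_repeats)
      )
    }
    out <- dplyr::bind_rows(uniq, fill)
    out$context <- ctx
    out$condition <- cond
    out
  })
  sched <- dplyr::bind_rows(rows)
  set.seed(seed)
  sched <- sched[sample.int(nrow(sched)), ]
  sched <- finalize_schedule(sched, design, subject, phase = "ENCODING")
  realized <- dplyr::summarise(
    dplyr::group_by(sched, .data$context, .data$category_shown),
    n = dplyr::n(), .groups = "drop_last"
  )
  realized <- dplyr::ungroup(dplyr::mutate(realized, prop = n / sum(n)))
  attr(sched, "realized_contingency") <- realized
  sched
}

# Common column layout + trial / per-context counters for one phase.
finalize_schedule <- function(sched, design, subject, phase) {
  sched$subject <- subject
  sched$experiment <- design$experiment_id
  sched$phase <- phase
  sched$trial <- seq_len(nrow(sched))
  sched <- sched[, c("subject", "experiment", "phase", "trial", "context",
                     "condition", "category_shown", "is_filler", "object_id")]
  add_context_counter(sched)
}

#' Recompute the per-context trial counter
#'
#' The counter `context_trial` indexes, within each subject and context, how
#' many trials of that context have been seen so far (1-based), pooling all
#' phases in row order.  It is the `t` that drives the decreasing learning
#' rates, so it must be recomputed whenever phases are concatenated.
#'
#' @param sched A schedule tibble (rows in presentation order).
#' @return The schedule with a fresh `context_trial` column.
#' @export
add_context_counter <- function(sched) {
  sched <- dplyr::group_by(sched, .data$subject, .data$context)
  sched <- dplyr::mutate(sched, context_trial = dplyr::row_number())
  dplyr::ungroup(sched)
}

#' Pool learning and encoding phases into one modelled sequence
#'
#' Concatenates the two phases in order (learning first), renumbers `trial`
#' and recomputes `context_trial` across the pooled sequence, since the
#' learning models treat both phases as one continuing experience.
#'
#' @param learning,encoding Schedules for the two phases (same subject).
#' @return Pooled schedule tibble.
#' @export
pool_phases <- function(learning, encoding) {
  pooled <- dplyr::bind_rows(learning, encoding)
  pooled <- dplyr::group_by(pooled, .data$subject)
  pooled <- dplyr::mutate(pooled, trial = dplyr::row_number())
  pooled <- dplyr::ungroup(pooled)
  add_context_counter(pooled)
}
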
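#' Run the full analysis pipeline
#'
#' Executes the stages simulate -> fit -> compare -> derive-PE -> analyze
#' for the configured experiments, writing every table as delimited text
#' plus a JSON run manifest to `config$out_dir`.  The run is a pure
#' function of the configuration (including its master seed): re-running
#' the same configuration reproduces byte-identical outputs.  A failing
#' stage aborts with the stage named.
#'
#' @param config A [study_config()] (or a path handled by
#'   [read_study_config()] upstream).
#' @return The run manifest (list), invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "study_config"))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir must be set")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate ------------------------------------------------------------
  sim <- stage("simulate", {
    studies <- lapply(seq_along(config$experiments), function(k) {
      exp_id <- config$experiments[k]
      study <- make_synthetic_study(
        n_subjects = config$n_subjects,
        design = build_design(exp_id),
        seed = derive_seed(config$seed, k),
        model = config$agent_model,
        memory_coefficients = config$memory_coefficients,
        random_effect_sds = config$random_effect_sds,
        fa_rate = config$fa_rate,
        learning_trials_per_context = config$learning_trials_per_context
      )
      relabel <- function(d) {
        d$subject <- sprintf("%s_%02d", exp_id, as.integer(d$subject))
        d
      }
      list(trials = relabel(study$trials),
           recognition = relabel(study$recognition),
           agents = relabel(study$agents))
    })
    list(
      trials = dplyr::bind_rows(lapply(studies, `[[`, "trials")),
      recognition = dplyr::bind_rows(lapply(studies, `[[`, "recognition")),
      agents = dplyr::bind_rows(lapply(studies, `[[`, "agents"))
    )
  })
  write_trial_table(sim$trials, file.path(out_dir, "trials.csv"))
  write_trial_table(sim$recognition, file.path(out_dir, "recognition.csv"))
  write_trial_table(sim$agents, file.path(out_dir, "agents.csv"))

  # -- fit -----------------------------------------------------------------
  fits <- stage("fit", {
    fit_study(sim$trials, models = config$models,
              n_restarts = config$n_restarts,
              seed = derive_seed(config$seed, 101),
              prob_floor = config$prob_floor)
  })
  write_trial_table(fits, file.path(out_dir, "fits.csv"))

  # -- compare -------------------------------------------------------------
  comparison <- NULL
  if (all(model_names() %in% config$models)) {
    comparison <- stage("compare", compare_models(fits))
    write_trial_table(comparison$table, file.path(out_dir, "comparison.csv"))
    write_trial_table(comparison$per_subject,
                      file.path(out_dir, "comparison_per_subject.csv"))
  }

  # -- derive PE -----------------------------------------------------------
  trajectories <- stage("derive-PE", derive_pe(sim$trials, fits, "fLRI"))
  write_trial_table(
    trajectories[, c(table_schema("trials"), "q_shown", "pe_unsigned",
                     "pe_signed", "p_chosen")],
    file.path(out_dir, "trajectories.csv")
  )

  # -- analyze -------------------------------------------------------------
  analysis <- stage("analyze", {
    included <- NULL
    exclusion <- NULL
    if (isTRUE(config$exclusion)) {
      exclusion <- permutation_exclusion(sim$recognition,
                                         n_perm = config$n_perm,
                                         seed = derive_seed(config$seed, 201))
      included <- exclusion$subject[exclusion$included]
    }
    tab <- build_analysis_table(trajectories, sim$recognition, fits,
                                included_subjects = included)
    fspec <- config$formula_spec %||%
      (if (length(config$experiments) > 1) "full" else "basic")
    fit <- if (config$pe_variant == "signed") {
      signed_pe_analysis(tab)
    } else {
      fit_mixed_logistic(tab, fspec)
    }
    slopes <- simple_slopes(tab)
    list(exclusion = exclusion, table = tab, fit = fit, slopes = slopes)
  })
  write_trial_table(analysis$table, file.path(out_dir, "analysis_table.csv"))
  if (!is.null(analysis$exclusion)) {
    write_trial_table(analysis$exclusion[, c("subject", "dprime",
                                             "threshold", "p_perm",
                                             "included")],
                      file.path(out_dir, "exclusion.csv"))
  }
  write_trial_table(analysis$fit$fixed, file.path(out_dir, "coefficients.csv"))
  slopes_tab <- dplyr::bind_rows(
    dplyr::mutate(analysis$slopes$correct$fixed, subset = "correct"),
    dplyr::mutate(analysis$slopes$incorrect$fixed, subset = "incorrect")
  )
  write_trial_table(slopes_tab, file.path(out_dir, "slopes.csv"))

  # -- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "pemem",
    version = as.character(packageVersion("pemem")),
    master_seed = config$seed,
    derived_seeds = list(simulate = derive_seed(config$seed, 1),
                         fit = derive_seed(config$seed, 101),
                         exclusion = derive_seed(config$seed, 201)),
    config = config[setdiff(names(config), "out_dir")],
    file_digests = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$file_digests) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
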
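#' Canonical column schemas for the delimited trial formats
#'
#' All tables are comma-separated UTF-8 text with a header row, one row per
#' trial, booleans written as 0/1.
#'
#' @param schema `"trials"` or `"recognition"`.
#' @return Character vector of required canonical column names.
#' @export
table_schema <- function(schema = c("trials", "recognition")) {
  switch(match.arg(schema),
    trials = c("subject", "experiment", "phase", "trial", "context",
               "condition", "category_shown", "category_chosen",
               "accuracy", "is_filler", "object_id", "context_trial"),
    recognition = c("subject", "object_id", "status", "response",
                    "immediate_subset")
  )
}

#' Write a per-trial table as delimited text
#'
#' @param x Data frame to write; logical columns are converted to 0/1.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(x, path) {
  is_lgl <- vapply(x, is.logical, logical(1))
  x[is_lgl] <- lapply(x[is_lgl], as.integer)
  readr::write_csv(x, path)
  invisible(path)
}

#' Read and validate a per-trial table
#'
#' Reads a delimited table, optionally renames externally-named columns to
#' the canonical schema via `column_mapping`, and validates that all
#' required columns are present and that categorical codes are legal.
#'
#' @param path File to read (comma-separated with header).
#' @param schema Which schema to validate against ([table_schema()]).
#' @param column_mapping Optional named character vector mapping canonical
#'   names to the file's column names, e.g.
#'   `c(category_shown = "obj_cat")`.
#' @return Validated tibble in canonical form (logical columns restored).
#' @export
read_trial_table <- function(path, schema = c("trials", "recognition"),
                             column_mapping = NULL) {
  schema <- match.arg(schema)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_mapping)) {
    miss_src <- setdiff(unname(column_mapping), names(x))
    if (length(miss_src)) {
      stop("mapped column(s) not in file: ", paste(miss_src, collapse = ", "))
    }
    names(x)[match(column_mapping, names(x))] <- names(column_mapping)
  }
  required <- table_schema(schema)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (schema == "trials") {
    bad <- setdiff(unique(x$phase), c("LEARNING", "ENCODING"))
    if (length(bad)) stop("unknown phase label(s): ",
                          paste(bad, collapse = ", "))
    x$is_filler <- as.logical(x$is_filler)
  } else {
    bad <- setdiff(unique(x$status), c("old", "new"))
    if (length(bad)) stop("unknown status label(s): ",
                          paste(bad, collapse = ", "))
    x$immediate_subset <- as.logical(x$immediate_subset)
  }
  x
}

#' Default pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()], with the
#' fitting bounds, restart count and probability floor at their standard
#' values.  Any field can be overridden by name.
#'
#' @param ... Named overrides of the defaults.
#' @return A `study_config` list.
#' @export
study_config <- function(...) {
  cfg <- list(
    experiments = "EXP2",
    n_subjects = 10,
    seed = 1L,
    models = model_names(),
    n_restarts = 5,
    prob_floor = 1e-12,
    bounds = list(alpha = c(0, 1), beta = c(0, 10)),
    learning_trials_per_context = 40,
    agent_model = "fLRI",
    memory_coefficients = default_memory_coefficients(),
    random_effect_sds = default_memory_re_sds(),
    fa_rate = 0.3,
    exclusion = TRUE,
    n_perm = 1000,
    pe_variant = "unsigned",
    formula_spec = NULL,
    out_dir = NULL
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(override)] <- override
  structure(cfg, class = "study_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [study_config()] fields.
#' @return A `study_config` list.
#' @export
read_study_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}
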
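trial_cols <- function() readr::cols(
  subject_id = readr::col_character(),
  administration = readr::col_integer(),
  trial_index = readr::col_integer(),
  condition = readr::col_character(),
  action = readr::col_character(),
  outcome = readr::col_integer(),
  rt = readr::col_double())

goal_cols <- function() readr::cols(
  subject_id = readr::col_character(),
  day = readr::col_integer(),
  activity_id = readr::col_character(),
  category = readr::col_character(),
  R_pre = readr::col_double(), P_pre = readr::col_double(),
  r = readr::col_double(), p = readr::col_double(),
  R_post1 = readr::col_double(), P_post1 = readr::col_double())

symptom_cols <- function() readr::cols(
  subject_id = readr::col_character(),
  week = readr::col_integer(),
  ids_total = readr::col_double(),
  item19 = readr::col_integer(),
  item21 = readr::col_integer())

#' Read and write the pipeline's CSV tables
#'
#' Comma-separated, header row mandatory, `.` decimal separator, UTF-8,
#' missing values as empty fields. Trial tables carry `subject_id`,
#' `administration`, `trial_index`, `condition`, `action`, `outcome`,
#' `rt`; diary tables `subject_id`, `day`, `activity_id`, `category`,
#' `R_pre`, `P_pre`, `r`, `p`, `R_post1`, `P_post1`; symptom tables
#' `subject_id`, `week`, `ids_total`, `item19`, `item21`.
#'
#' @param path File path.
#' @param x Table to write.
#' @return Readers return a tibble; writers return `x` invisibly.
#' @name gng_io
NULL

#' @rdname gng_io
#' @export
read_trials <- function(path) {
  readr::read_csv(path, col_types = trial_cols(), na = "")
}

#' @rdname gng_io
#' @export
write_trials <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(x)
}

#' @rdname gng_io
#' @export
read_goal_diary <- function(path) {
  readr::read_csv(path, col_types = goal_cols(), na = "")
}

#' @rdname gng_io
#' @export
write_goal_diary <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(x)
}

#' @rdname gng_io
#' @export
read_symptoms <- function(path) {
  readr::read_csv(path, col_types = symptom_cols(), na = "")
}

#' @rdname gng_io
#' @export
write_symptoms <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(x)
}

violation <- function(table, row, column, problem) {
  tibble::tibble(table = table, row = as.integer(row), column = column,
                 problem = problem)
}

check_range <- function(x, lo, hi, table, column) {
  bad <- which(!is.na(x) & (x < lo | x > hi))
  if (!length(bad)) return(NULL)
  violation(table, bad, column,
            sprintf("value %s outside [%s, %s]", x[bad], lo, hi))
}

check_values <- function(x, allowed, table, column) {
  bad <- which(!is.na(x) & !x %in% allowed)
  if (!length(bad)) return(NULL)
  violation(table, bad, column,
            sprintf("value '%s' not one of {%s}", x[bad],
                    paste(allowed, collapse = ", ")))
}

check_columns <- function(x, required, table) {
  missing <- setdiff(required, names(x))
  if (!length(missing)) return(NULL)
  violation(table, NA_integer_, missing, "missing column")
}

#' Validate a trial, diary or symptom table
#'
#' Schema (required columns), range (allowed values) and ordering checks.
#' Every violation is reported with its row number; an empty result means
#' the table is valid.
#'
#' @param x The table to validate.
#' @param scale_max Upper bound of the diary rating scale (default 10).
#' @return A tibble of violations (`table`, `row`, `column`, `problem`).
#' @name gng_validate
NULL

#' @rdname gng_validate
#' @export
validate_trials <- function(x) {
  v <- list(check_columns(x, c("subject_id", "administration", "trial_index",
                               "condition", "action", "outcome"), "trials"))
  if (!is.null(v[[1]])) return(dplyr::bind_rows(v))
  v <- c(v, list(
    check_values(x$condition, condition_levels(), "trials", "condition"),
    check_values(x$action, c("go", "nogo", "missed"), "trials", "action"),
    check_values(x$outcome, c(-1L, 0L, 1L), "trials", "outcome"),
    check_range(x$administration, 1, 5, "trials", "administration")))
  ord <- x |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$subject_id, .data$administration) |>
    dplyr::filter(c(FALSE, diff(.data$trial_index) <= 0)) |>
    dplyr::ungroup()
  if (nrow(ord)) {
    v <- c(v, list(violation("trials", ord$.row, "trial_index",
                             "not strictly increasing within administration")))
  }
  dup <- x |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$subject_id, .data$administration,
                    .data$trial_index) |>
    dplyr::filter(dplyr::n() > 1, dplyr::row_number() > 1) |>
    dplyr::ungroup()
  if (nrow(dup)) {
    v <- c(v, list(violation("trials", dup$.row, "trial_index",
                             "duplicate within subject x administration")))
  }
  dplyr::bind_rows(v)
}

#' @rdname gng_validate
#' @export
validate_goal <- function(x, scale_max = 10) {
  v <- list(check_columns(x, c("subject_id", "day", "activity_id", "R_pre",
                               "P_pre", "r", "p", "R_post1", "P_post1"),
                          "goal"))
  if (!is.null(v[[1]])) return(dplyr::bind_rows(v))
  for (col in c("R_pre", "P_pre", "r", "p", "R_post1", "P_post1")) {
    v <- c(v, list(check_range(x[[col]], 0, scale_max, "goal", col)))
  }
  v <- c(v, list(check_range(x$day, 1, 56, "goal", "day")))
  dplyr::bind_rows(v)
}

#' @rdname gng_validate
#' @export
validate_symptoms <- function(x) {
  v <- list(check_columns(x, c("subject_id", "week", "ids_total"),
                          "symptoms"))
  if (!is.null(v[[1]])) return(dplyr::bind_rows(v))
  v <- c(v, list(check_range(x$ids_total, 0, 84, "symptoms", "ids_total")))
  for (col in intersect(c("item19", "item21"), names(x))) {
    v <- c(v, list(check_range(x[[col]], 0, 3, "symptoms", col)))
  }
  ord <- x |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::filter(c(FALSE, diff(.data$week) <= 0)) |>
    dplyr::ungroup()
  if (nrow(ord)) {
    v <- c(v, list(violation("symptoms", ord$.row, "week",
                             "weeks not strictly increasing")))
  }
  dplyr::bind_rows(v)
}

#' Validate a set of table files
#'
#' @param paths Named character vector with any of `trials`, `goal`,
#'   `symptoms` pointing at CSV files.
#' @param scale_max Diary rating-scale bound.
#' @return Combined violation tibble (empty when all tables are valid).
#' @export
validate_tables <- function(paths, scale_max = 10) {
  out <- list()
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      stop("file not found: ", paths[[nm]], call. = FALSE)
    }
    out[[nm]] <- switch(nm,
      trials = validate_trials(read_trials(paths[[nm]])),
      goal = validate_goal(read_goal_diary(paths[[nm]]), scale_max),
      symptoms = validate_symptoms(read_symptoms(paths[[nm]])),
      stop("unknown table kind: ", nm, call. = FALSE))
  }
  dplyr::bind_rows(out)
}

#' Run configuration
#'
#' A validated list of the pipeline's knobs with the standard defaults:
#' task dimensions, the feedback probability and outcome-rule variant,
#' the diary rating scale, the therapy-phase weeks, fitting tolerances
#' and the master seed. `read_config()` merges a YAML or JSON file over
#' the defaults; unknown keys error.
#'
#' @param ... Overrides of the default entries.
#' @return A named list of class `"gng_config"` with an `hash` attribute
#'   identifying the resolved configuration.
#' @export
#' @examples
#' gng_config(n_per_condition = 10, seed = 1)
gng_config <- function(...) {
  defaults <- list(
    n_per_condition = 60, n_administrations = 5, dominant_prob = 0.8,
    outcome_rule_variant = "paper_text", scale_max = 10, n_days = 56,
    t3_week = 4, t7_week = 7, em_tol = 1e-3, em_max_iter = 100,
    n_restarts = 10, ibic_samples = 2000, seed = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  if (!cfg$outcome_rule_variant %in% c("paper_text", "conventional")) {
    stop("outcome_rule_variant must be 'paper_text' or 'conventional'",
         call. = FALSE)
  }
  structure(cfg, hash = rlang::hash(cfg), class = "gng_config")
}

#' @rdname gng_config
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(gng_config, raw)
}

#' Percentage from a count pair
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @return `100 * numerator / denominator`, rounded to one decimal.
#' @export
#' @examples
#' rate_from_counts(18, 80)
rate_from_counts <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    stop("`denominator` must be positive", call. = FALSE)
  }
  round(100 * numerator / denominator, 1)
}

#' Treatment-response flags from a symptom series
#'
#' Per subject: at least 25% reduction from baseline to endpoint, at
#' least 50% reduction, and remission (endpoint score strictly below 14).
#' Baseline is the score at the subject's first recorded week and the
#' endpoint the score at `final_week` (default: the subject's last
#' recorded week). Subjects missing either endpoint get `NA` flags.
#'
#' @param series Symptom tibble (`subject_id`, `week`, `ids_total`).
#' @param final_week Optional fixed endpoint week.
#' @param remission_cutoff Strict remission threshold (default 14).
#' @return Tibble with `subject_id`, `baseline`, `final`, `responder_25`,
#'   `responder_50`, `remission`.
#' @export
responder_flags <- function(series, final_week = NULL,
                            remission_cutoff = 14) {
  series |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      baseline = .data$ids_total[which.min(.data$week)],
      final = if (is.null(final_week)) {
        .data$ids_total[which.max(.data$week)]
      } else if (any(.data$week == final_week)) {
        .data$ids_total[.data$week == final_week]
      } else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(
      reduction = (.data$baseline - .data$final) / .data$baseline,
      responder_25 = .data$reduction >= 0.25,
      responder_50 = .data$reduction >= 0.50,
      remission = .data$final < remission_cutoff) |>
    dplyr::select(-"reduction")
}
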
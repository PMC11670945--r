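# CSV readers/writers for the two table schemas. Missing rates are
# written as empty fields.

summary_csv_columns <- c(
  "rank", "name", "median_score", "cooperation_rating", "wins",
  "initial_C", "CC_rate", "CD_rate", "DC_rate", "DD_rate",
  "CC_to_C", "CD_to_C", "DC_to_C", "DD_to_C")

#' Write / read a tournament result summary
#'
#' One CSV per tournament with columns `rank, name, median_score,
#' cooperation_rating, wins, initial_C, CC_rate, CD_rate, DC_rate,
#' DD_rate, CC_to_C, CD_to_C, DC_to_C, DD_to_C`; missing rates are
#' empty fields.
#'
#' @param summary A [run_tournament()] summary (or any tibble with the
#'   summary columns).
#' @param path File path.
#' @return `write_result_summary()` returns `summary` invisibly;
#'   `read_result_summary()` returns a tibble.
#' @export
write_result_summary <- function(summary, path) {
  missing_cols <- setdiff(summary_csv_columns, names(summary))
  if (length(missing_cols)) {
    stop("summary is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(summary[, summary_csv_columns], path, na = "")
  invisible(summary)
}

#' @rdname write_result_summary
#' @export
read_result_summary <- function(path) {
  readr::read_csv(path, col_types = "icdddddddddddd", na = "")
}

#' Write / read a feature table
#'
#' One CSV per campaign with one row per (trial, tournament type,
#' strategy) and the full feature schema; missing values are empty
#' fields.
#'
#' @param features A feature table ([trial_features()] or
#'   [generate_feature_table()] output).
#' @param path File path.
#' @return `write_feature_table()` returns `features` invisibly;
#'   `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(features, path) {
  missing_cols <- setdiff(feature_columns(), names(features))
  if (length(missing_cols)) {
    stop("feature table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(features[, feature_columns()], path, na = "")
  invisible(features)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      trial = "i", tournament_type = "c", name = "c", rank = "i",
      normalized_rank = "d", median_score = "d", C_r = "d",
      CC_to_C = "d", CD_to_C = "d", DC_to_C = "d", DD_to_C = "d",
      C_max = "d", C_min = "d", C_mean = "d", C_median = "d",
      C_r_over_C_max = "d", C_min_over_C_r = "d",
      C_r_over_C_median = "d", C_r_over_C_mean = "d", SSE = "d",
      sse_imputed = "l", memory_usage = "d", stochastic = "l",
      makes_use_of_game = "l", makes_use_of_length = "l",
      N = "i", k = "i", n = "i", p_n = "d", p_e = "d"
    ),
    na = ""
  )
}

read_trial_table <- function(path) {
  readr::read_csv(path, col_types = "iiiiiddc", na = "")
}

#' Load strategies from a config file
#'
#' Reads a YAML file defining strategies from the generic families and
#' returns instantiated [strategy()] objects. The schema is a top-level
#' `strategies:` list whose entries have a `name`, a `type` (one of
#' `memory_one`, `fsm`, `lookup`), and the family's parameters:
#'
#' * `memory_one`: `vector` (four probabilities, order CC, CD, DC, DD)
#'   and optional `initial` (default `"C"`).
#' * `fsm`: `initial_state`, `initial_action`, and `transitions`, a list
#'   of `{state, input, next_state, action}` records.
#' * `lookup`: `depth`, `opening` (list of actions), and `table`, a map
#'   from `"<own>|<opp>"` history keys to actions.
#'
#' Validation errors name the offending strategy.
#'
#' @param path Path to the YAML file. See
#'   `system.file("extdata", "example-strategies.yaml", package = "ipdsim")`
#'   for a worked example.
#' @return Named list of `ipd_strategy` objects.
#' @export
read_strategy_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(cfg$strategies)) {
    stop("config must have a top-level `strategies:` list", call. = FALSE)
  }
  out <- purrr::map(cfg$strategies, function(entry) {
    name <- entry$name
    if (is.null(name) || is.null(entry$type)) {
      stop("every strategy entry needs `name` and `type`", call. = FALSE)
    }
    tryCatch(
      switch(entry$type,
        memory_one = memory_one_strategy(
          name, unlist(entry$vector), initial = entry$initial %||% "C"),
        fsm = fsm_strategy(
          name, dplyr::bind_rows(purrr::map(entry$transitions, tibble::as_tibble)),
          initial_state = entry$initial_state,
          initial_action = entry$initial_action),
        lookup = lookup_strategy(
          name, unlist(entry$table), depth = entry$depth,
          opening = unlist(entry$opening)),
        stop("unknown strategy type: ", entry$type, call. = FALSE)
      ),
      error = function(e) {
        stop("invalid strategy `", name, "`: ", conditionMessage(e),
             call. = FALSE)
      }
    )
  })
  names(out) <- purrr::map_chr(out, "name")
  if (anyDuplicated(names(out))) {
    stop("duplicate strategy name in config: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "),
         call. = FALSE)
  }
  out
}
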
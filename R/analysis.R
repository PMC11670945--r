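# The statistical layer: feature-performance correlations, multivariate
# regression of the normalized rank, and winner-feature distributions.

default_correlation_features <- function() {
  c("CC_to_C", "CD_to_C", "DC_to_C", "DD_to_C", "C_r",
    "C_max", "C_min", "C_median", "C_mean",
    "C_r_over_C_max", "C_min_over_C_r", "C_r_over_C_median",
    "C_r_over_C_mean", "N", "k", "n", "p_n", "p_e",
    "makes_use_of_game", "makes_use_of_length", "SSE", "stochastic",
    "memory_usage")
}

#' Spearman correlations of features with performance
#'
#' For every tournament type present in the feature table, computes the
#' Spearman rank correlation of each feature with each target column
#' (the normalized rank and the median score by default). Missing values
#' are pairwise-deleted; a feature that is constant (or entirely
#' missing) for a type — e.g. memory usage under probabilistic ending —
#' yields no row, mirroring the dashes of a results table.
#'
#' @param features A feature table ([trial_features()],
#'   [run_campaign()], or [generate_feature_table()]).
#' @param targets Target column names.
#' @param feature_cols Feature column names; defaults to all behavioral,
#'   contextual, and classifier features present.
#' @return A tibble of class `ipd_correlations` with columns
#'   `tournament_type`, `feature`, `target`, `estimate`, `n_pairs`.
#' @export
correlate_features <- function(features,
                               targets = c("normalized_rank",
                                           "median_score"),
                               feature_cols = NULL) {
  stopifnot(is.data.frame(features), "tournament_type" %in% names(features))
  missing_targets <- setdiff(targets, names(features))
  if (length(missing_targets)) {
    stop("targets not in `features`: ",
         paste(missing_targets, collapse = ", "), call. = FALSE)
  }
  feature_cols <- feature_cols %||%
    intersect(default_correlation_features(), names(features))
  grid <- tidyr::expand_grid(
    tournament_type = unique(features$tournament_type),
    feature = feature_cols,
    target = targets
  )
  out <- purrr::pmap(grid, function(tournament_type, feature, target) {
    rows <- features[features$tournament_type == tournament_type, ]
    x <- as.numeric(rows[[feature]])
    y <- as.numeric(rows[[target]])
    ok <- !is.na(x) & !is.na(y)
    n_ok <- sum(ok)
    if (n_ok < 3 || length(unique(x[ok])) < 2 ||
        length(unique(y[ok])) < 2) {
      return(NULL)
    }
    tibble::tibble(
      tournament_type = tournament_type, feature = feature, target = target,
      estimate = cor(x[ok], y[ok], method = "spearman"),
      n_pairs = n_ok
    )
  })
  out <- purrr::list_rbind(purrr::compact(out))
  class(out) <- c("ipd_correlations", class(out))
  out
}

#' Per-type feature lists for the rank regression
#'
#' The default design of [fit_rank_regression()]: a common core
#' (conditional cooperation rates, SSE, cooperation aggregates and
#' ratios, `k`) plus, per tournament type, the parameters that are
#' defined there — `n` and memory usage only with a fixed match length,
#' `p_n` only with noise, `p_e` only with probabilistic ending.
#'
#' @return Named list of character vectors, one per tournament type.
#' @export
regression_feature_lists <- function() {
  core <- c("CC_to_C", "CD_to_C", "DC_to_C", "SSE", "C_max", "C_min",
            "C_mean", "C_min_over_C_r", "C_r_over_C_mean", "k")
  list(
    standard = c(core, "n", "memory_usage"),
    noisy = c(core, "memory_usage", "C_r_over_C_median", "p_n"),
    probabilistic_ending = c(core, "C_r_over_C_median", "p_e"),
    noisy_probabilistic_ending = c(core, "p_n", "p_e")
  )
}

#' Multivariate linear regression of the normalized rank on features
#'
#' Fits, per tournament type, an ordinary least-squares regression of
#' the response (normalized rank by default; set
#' `response = "median_score"` for the score model) on that type's
#' feature list, with an intercept. Rows with missing values in the
#' model columns are dropped. A rank-deficient design is an error that
#' names the collinear columns.
#'
#' @param features A feature table.
#' @param response Response column name.
#' @param feature_lists Named list of per-type feature vectors; defaults
#'   to [regression_feature_lists()]. Types absent from the table are
#'   skipped.
#' @return An object of class `ipd_rank_regression`; use [tidy()] for
#'   coefficients and p-values, [glance()] for adjusted R-squared per
#'   model, and [autoplot()] for a coefficient plot.
#' @export
fit_rank_regression <- function(features, response = "normalized_rank",
                                feature_lists = regression_feature_lists()) {
  stopifnot(is.data.frame(features), response %in% names(features))
  types <- intersect(names(feature_lists),
                     unique(features$tournament_type))
  if (!length(types)) {
    stop("no tournament type in `features` matches `feature_lists`",
         call. = FALSE)
  }
  models <- purrr::map(stats::setNames(types, types), function(type) {
    cols <- feature_lists[[type]]
    missing_cols <- setdiff(cols, names(features))
    if (length(missing_cols)) {
      stop("feature list for ", type, " names absent columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    rows <- features[features$tournament_type == type,
                     c(response, cols)]
    rows <- rows[complete.cases(rows), ]
    # logical classifiers enter as 0/1
    rows <- dplyr::mutate(rows, dplyr::across(dplyr::where(is.logical),
                                              as.numeric))
    if (nrow(rows) < length(cols) + 2) {
      stop("not enough complete rows for the ", type, " model (",
           nrow(rows), " rows, ", length(cols), " features)",
           call. = FALSE)
    }
    X <- stats::model.matrix(
      as.formula(paste0("`", response, "` ~ .")), data = rows)
    qr_X <- qr(X)
    if (qr_X$rank < ncol(X)) {
      bad <- colnames(X)[qr_X$pivot[(qr_X$rank + 1L):ncol(X)]]
      stop("rank-deficient design for the ", type, " model; collinear: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    lm(as.formula(paste0("`", response, "` ~ .")), data = rows)
  })
  structure(
    list(models = models, response = response,
         feature_lists = feature_lists[types]),
    class = "ipd_rank_regression"
  )
}

#' @export
print.ipd_rank_regression <- function(x, ...) {
  cat("<ipd_rank_regression> response:", x$response, "\n")
  g <- glance(x)
  for (i in seq_len(nrow(g))) {
    cat("  ", format(g$tournament_type[i], width = 28),
        " adj R^2 = ", format(round(g$adj.r.squared[i], 3), nsmall = 3),
        "  (n = ", g$nobs[i], ")\n", sep = "")
  }
  invisible(x)
}

#' Feature distributions of tournament winners
#'
#' Filters the feature table to the rank-0 rows (the strategies that
#' ranked first) and summarizes, per tournament type, the distribution
#' of each winner feature: the cooperation rating, its ratio to the
#' tournament mean, the SSE, and the four conditional cooperation
#' rates.
#'
#' @param features A feature table.
#' @param cols Feature columns to profile.
#' @return An object of class `ipd_winner_profiles`: a list with
#'   `winners` (the rank-0 rows, long format) and `summary` (per type
#'   and feature: `n`, `mean`, `sd`, quartiles, range). Supports
#'   [autoplot()].
#' @export
winner_profiles <- function(features,
                            cols = c("C_r", "C_r_over_C_mean", "SSE",
                                     "CC_to_C", "CD_to_C", "DC_to_C",
                                     "DD_to_C")) {
  stopifnot(is.data.frame(features),
            all(c("rank", "tournament_type") %in% names(features)))
  cols <- intersect(cols, names(features))
  winners <- features[features$rank == 0L, ]
  long <- tidyr::pivot_longer(
    winners[, c("tournament_type", cols)],
    cols = dplyr::all_of(cols),
    names_to = "feature", values_to = "value"
  )
  summary <- long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$tournament_type, .data$feature) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sd(.data$value),
      min = min(.data$value),
      q25 = quantile(.data$value, 0.25, names = FALSE),
      median = median(.data$value),
      q75 = quantile(.data$value, 0.75, names = FALSE),
      max = max(.data$value),
      .groups = "drop"
    )
  structure(list(winners = long, summary = summary),
            class = "ipd_winner_profiles")
}

#' @export
print.ipd_winner_profiles <- function(x, ...) {
  cat("<ipd_winner_profiles>\n")
  print(x$summary, n = Inf)
  invisible(x)
}
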
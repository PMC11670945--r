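# Synthetic feature tables with planted feature-rank relationships.
# They share the schema of real campaign output, so every analysis
# operation can be validated against known ground truth without running
# tournaments.

#' Specification of a synthetic feature table
#'
#' Describes tables of per-(tournament, strategy) feature rows in which
#' the normalized rank is generated from a known linear model:
#' `r = clip(intercept + sum(beta_i * feature_i) + eps, 0, 1)` with
#' `eps ~ Normal(0, sigma)`. Rate-type features are drawn from a
#' Beta(`beta_shape`) marginal (interior-concentrated by default, which
#' avoids degenerate ratio denominators); tournament sizes and
#' parameters are drawn from `ranges`. Within each synthetic tournament
#' the cooperation aggregates and ratio features are recomputed from the
#' generated cooperation ratings, so the table is internally consistent,
#' and integer ranks are assigned in the order of `r`.
#'
#' The defaults keep the linear predictor well inside `[0, 1]`, so
#' clipping is rare and ordinary least squares recovers the planted
#' coefficients to its theoretical accuracy.
#'
#' @param n_tournaments Number of synthetic tournaments per type.
#' @param types Tournament types to generate.
#' @param intercept Intercept of the planted model.
#' @param betas Named numeric vector of planted coefficients; names must
#'   be feature columns.
#' @param sigma Standard deviation of the Gaussian noise, `>= 0`.
#' @param n_strategies Range `c(lo, hi)` of strategies per tournament.
#' @param ranges An [trial_ranges()] object for the tournament
#'   parameters `k`, `n`, `p_n`, `p_e`.
#' @param beta_shape Two shape parameters of the Beta marginal for
#'   rate-type features.
#' @param seed Optional integer seed.
#' @return A list of class `ipd_synthetic_spec`.
#' @export
synthetic_spec <- function(n_tournaments = 50L,
                           types = c("standard", "noisy",
                                     "probabilistic_ending",
                                     "noisy_probabilistic_ending"),
                           intercept = 0.45,
                           betas = c(CD_to_C = 0.15, DD_to_C = 0.12,
                                     SSE = 0.12, CC_to_C = -0.12,
                                     C_r_over_C_mean = -0.10),
                           sigma = 0.05,
                           n_strategies = c(3L, 20L),
                           ranges = trial_ranges(),
                           beta_shape = c(2, 2),
                           seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0) {
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  }
  stopifnot(is.numeric(betas), !is.null(names(betas)), all(nzchar(names(betas))),
            length(beta_shape) == 2, all(beta_shape > 0),
            length(n_strategies) == 2, n_strategies[1] >= 2,
            n_strategies[1] <= n_strategies[2],
            inherits(ranges, "ipd_trial_ranges"))
  n_tournaments <- as.integer(n_tournaments)
  stopifnot(n_tournaments >= 1)
  structure(
    list(n_tournaments = n_tournaments, types = types,
         intercept = intercept, betas = betas, sigma = sigma,
         n_strategies = as.integer(n_strategies), ranges = ranges,
         beta_shape = beta_shape,
         seed = if (!is.null(seed)) as.integer(seed)),
    class = "ipd_synthetic_spec"
  )
}

# One synthetic tournament block of N strategies for one type.
synthetic_block <- function(spec, type, block_id, N) {
  rng <- spec$ranges
  fixed_length <- type %in% c("standard", "noisy")
  noisy <- type %in% c("noisy", "noisy_probabilistic_ending")
  k <- sample(rng$k[1]:rng$k[2], 1L)
  n <- if (fixed_length) sample(rng$n[1]:rng$n[2], 1L) else NA_integer_
  p_n <- if (noisy) runif(1, rng$p_n[1], rng$p_n[2]) else 0
  p_e <- if (fixed_length) NA_real_ else {
    rng$p_e[2] - runif(1) * (rng$p_e[2] - rng$p_e[1])
  }
  draw <- function() rbeta(N, spec$beta_shape[1], spec$beta_shape[2])
  c_r <- draw()
  agg <- cooperation_aggregates(c_r)
  rows <- tibble::tibble(
    trial = as.integer(block_id),
    tournament_type = type,
    name = sprintf("synthetic-%03d", seq_len(N)),
    C_r = c_r,
    CC_to_C = draw(), CD_to_C = draw(), DC_to_C = draw(), DD_to_C = draw(),
    C_max = agg$C_max, C_min = agg$C_min,
    C_mean = agg$C_mean, C_median = agg$C_median,
    C_r_over_C_max = agg$C_r_over_C_max,
    C_min_over_C_r = agg$C_min_over_C_r,
    C_r_over_C_median = agg$C_r_over_C_median,
    C_r_over_C_mean = agg$C_r_over_C_mean,
    SSE = draw(),
    sse_imputed = FALSE,
    memory_usage = if (fixed_length) draw() else NA_real_,
    stochastic = runif(N) < 0.3,
    makes_use_of_game = runif(N) < 0.2,
    makes_use_of_length = runif(N) < 0.2,
    N = as.integer(N), k = as.integer(k), n = n, p_n = p_n, p_e = p_e
  )
  eta <- spec$intercept
  for (feat in names(spec$betas)) {
    if (!feat %in% names(rows)) {
      stop("planted coefficient names unknown feature: ", feat,
           call. = FALSE)
    }
    x <- as.numeric(rows[[feat]])
    if (anyNA(x)) {
      stop("planted feature `", feat, "` is undefined for type ", type,
           call. = FALSE)
    }
    eta <- eta + spec$betas[[feat]] * x
  }
  r <- eta + if (spec$sigma > 0) rnorm(N, 0, spec$sigma) else 0
  rows$normalized_rank <- pmin(pmax(r, 0), 1)
  rows$rank <- score_ranks(-rows$normalized_rank, rows$name)
  rows$median_score <- 2.5 - 1.5 * rows$normalized_rank + rnorm(N, 0, 0.1)
  rows[, feature_columns()]
}

#' Generate a synthetic feature table
#'
#' Realizes an [synthetic_spec()]: a feature table with the campaign
#' schema whose normalized rank follows the planted linear model. With
#' `sigma = 0` the planted coefficients are recovered exactly by
#' [fit_rank_regression()] (up to clipping, which the defaults make
#' rare).
#'
#' @param spec An [synthetic_spec()] object.
#' @return A feature tibble, schema-identical to [trial_features()]
#'   output. The spec is attached as attribute `"spec"`.
#' @examples
#' tab <- generate_feature_table(synthetic_spec(n_tournaments = 5, seed = 1))
#' @export
generate_feature_table <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "ipd_synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  blocks <- list()
  for (type in spec$types) {
    for (b in seq_len(spec$n_tournaments)) {
      N <- sample(spec$n_strategies[1]:spec$n_strategies[2], 1L)
      blocks[[length(blocks) + 1L]] <- synthetic_block(spec, type, b, N)
    }
  }
  out <- purrr::list_rbind(blocks)
  attr(out, "spec") <- spec
  out
}

#' Generate a schema-valid tournament summary fixture
#'
#' Builds an internally consistent random [run_tournament()]-style
#' summary — ranks a permutation of `0:(N-1)`, scores descending in
#' rank, state rates summing to one — for reader/writer round-trip
#' tests. The rows describe no real strategies.
#'
#' @param N Number of rows (players), `>= 2`.
#' @param seed Optional integer seed.
#' @return A tibble with the [run_tournament()] summary columns.
#' @export
generate_summary_fixture <- function(N, seed = NULL) {
  N <- as.integer(N)
  stopifnot(N >= 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  states <- matrix(stats::rgamma(4L * N, shape = 1.5), N, 4L)
  states <- states / rowSums(states)
  cond <- matrix(rbeta(4L * N, 2, 2), N, 4L)
  # Leave one conditional rate missing to exercise the empty-field path.
  cond[sample.int(N, 1L), sample.int(4L, 1L)] <- NA_real_
  tibble::tibble(
    rank = 0:(N - 1L),
    name = sprintf("synthetic-%03d", sample.int(999L, N)),
    median_score = sort(runif(N, 1, 3), decreasing = TRUE),
    cooperation_rating = rbeta(N, 2, 2),
    wins = as.numeric(sample(0:(N - 1L), N, replace = TRUE)),
    initial_C = rbeta(N, 2, 2),
    CC_rate = states[, 1L], CD_rate = states[, 2L],
    DC_rate = states[, 3L], DD_rate = states[, 4L],
    CC_to_C = cond[, 1L], CD_to_C = cond[, 2L],
    DC_to_C = cond[, 3L], DD_to_C = cond[, 4L]
  )
}
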
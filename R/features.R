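#' Normalized tournament rank
#'
#' `r = R / (N - 1)`, where `R` is the 0-based rank: 0 denotes the winner
#' and 1 the last place, regardless of tournament size.
#'
#' @param rank Integer vector of 0-based ranks in `[0, N - 1]`.
#' @param n_players Tournament size `N >= 2` (scalar or vector).
#' @return Numeric vector of normalized ranks in `[0, 1]`.
#' @examples
#' normalized_rank(0, 10)  # the winner: 0
#' normalized_rank(1, 3)   # 0.5
#' @export
normalized_rank <- function(rank, n_players) {
  if (any(n_players < 2)) stop("`n_players` must be >= 2", call. = FALSE)
  if (any(rank < 0 | rank > n_players - 1)) {
    stop("`rank` must lie in [0, n_players - 1]", call. = FALSE)
  }
  rank / (n_players - 1)
}

#' Median normalized rank
#'
#' A strategy's overall performance across the tournaments it entered:
#' the median of its normalized ranks. 0 means the strategy won every
#' tournament.
#'
#' @param r Numeric vector of normalized ranks for one strategy (and
#'   typically one tournament type).
#' @return The median, a single number.
#' @export
median_normalized_rank <- function(r) {
  if (length(r) == 0) stop("`r` must not be empty", call. = FALSE)
  median(r)
}

#' Tournament-level cooperation aggregates and per-strategy ratios
#'
#' From the cooperation ratings of all `N` strategies of one tournament,
#' computes the tournament aggregates `C_max`, `C_min`, `C_mean`,
#' `C_median` and each strategy's ratios against them:
#' `C_r / C_max`, `C_min / C_r`, `C_r / C_median`, `C_r / C_mean`.
#' A ratio with a zero denominator is `NA` (missing), never `Inf`.
#'
#' @param c_r Numeric vector of per-strategy cooperation ratings in
#'   `[0, 1]`.
#' @return A tibble with one row per strategy: `C_r`, the four
#'   aggregates (constant within the tournament), and the four ratios.
#' @examples
#' cooperation_aggregates(c(0.9, 0.5, 0.1))
#' @export
cooperation_aggregates <- function(c_r) {
  stopifnot(is.numeric(c_r), length(c_r) >= 1)
  if (any(!is.na(c_r) & (c_r < 0 | c_r > 1))) {
    stop("cooperation ratings must lie in [0, 1]", call. = FALSE)
  }
  agg <- list(C_max = max(c_r, na.rm = TRUE),
              C_min = min(c_r, na.rm = TRUE),
              C_mean = mean(c_r, na.rm = TRUE),
              C_median = median(c_r, na.rm = TRUE))
  safe_div <- function(num, den) {
    out <- num / den
    out[rep_len(den <= 0, length(out))] <- NA_real_
    out
  }
  tibble::tibble(
    C_r = c_r,
    C_max = agg$C_max, C_min = agg$C_min,
    C_mean = agg$C_mean, C_median = agg$C_median,
    C_r_over_C_max = safe_div(c_r, agg$C_max),
    C_min_over_C_r = safe_div(agg$C_min, c_r),
    C_r_over_C_median = safe_div(c_r, agg$C_median),
    C_r_over_C_mean = safe_div(c_r, agg$C_mean)
  )
}

#' Memory usage of a strategy in a fixed-length match
#'
#' The number of past rounds a strategy conditions on, divided by the
#' number of turns, capped at 1. Strategies with infinite memory score 1.
#' Undefined (`NA`) when the number of turns is unknown, as in
#' probabilistic-ending tournaments.
#'
#' @param memory_size Numeric vector of memory sizes (may contain `Inf`).
#' @param n Number of turns (scalar or vector; `NA` allowed).
#' @return Numeric vector of fractions in `[0, 1]`, `NA` where `n` is
#'   unknown.
#' @examples
#' memory_usage(2, 100)   # 0.02
#' memory_usage(Inf, 50)  # 1
#' @export
memory_usage <- function(memory_size, n) {
  stopifnot(is.numeric(memory_size))
  if (any(memory_size < 0, na.rm = TRUE)) {
    stop("`memory_size` must be non-negative", call. = FALSE)
  }
  if (any(!is.na(n) & n < 1)) stop("`n` must be >= 1", call. = FALSE)
  out <- pmin(memory_size / n, 1)
  out[is.infinite(memory_size) & !is.na(n)] <- 1
  out[is.na(n)] <- NA_real_
  out
}

#' Distance of a memory-one vector to the zero-determinant family (SSE)
#'
#' Projects an observed memory-one cooperation vector
#' `p = (p_CC, p_CD, p_DC, p_DD)` onto the extortionate zero-determinant
#' family and reports the residual sum of squared errors. In tilde
#' coordinates `p~ = (p_CC - 1, p_CD - 1, p_DC, p_DD)` the family is
#' `a * u - b * v` with `u = S_x - P`, `v = S_y - P` (the stage-payoff
#' vectors of the two players over the states `CC, CD, DC, DD`, shifted
#' by the punishment payoff), `a = phi` and `b = phi * chi`. The fit
#' solves the two-parameter least-squares problem, constrained to
#' `a, b >= 0` by default (degenerate fits land on the boundary). An SSE
#' of 0 means the strategy's observed behavior is exactly that of a
#' zero-determinant strategy.
#'
#' @param p Numeric vector of four conditional cooperation probabilities
#'   in `[0, 1]`, ordered `CC, CD, DC, DD`.
#' @param payoffs An [payoff_matrix()] object.
#' @param constrained Keep the fit inside the extortionate cone
#'   `a, b >= 0` (default)? Set `FALSE` for the unconstrained
#'   least-squares solution.
#' @return An object of class `ipd_zd_fit`: a list with the fitted
#'   coefficients `a`, `b`, the extortion parameters `phi = a` and
#'   `chi = b / a` (`NA` when `a = 0`), the residual `sse`, and a clipped
#'   variant `sse_clipped = min(sse, 1)`. Supports [tidy()] and
#'   [glance()].
#' @examples
#' sse_to_zd(zd_vector(0.1, 2))$sse   # 0: exactly extortionate
#' sse_to_zd(c(1, 0, 1, 0))$sse       # 0: TFT lies in the family
#' sse_to_zd(c(1, 1, 1, 1))$sse       # > 1: unconditional cooperation
#' @export
sse_to_zd <- function(p, payoffs = payoff_matrix(), constrained = TRUE) {
  p <- as.numeric(p)
  if (length(p) != 4 || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("`p` must be four probabilities (p_CC, p_CD, p_DC, p_DD)",
         call. = FALSE)
  }
  basis <- zd_basis(payoffs)
  u <- basis$x
  v <- basis$y
  p_tilde <- p + c(-1, -1, 0, 0)
  sse_at <- function(a, b) sum((a * u - b * v - p_tilde)^2)
  # Normal equations for X = [u, -v], coefficients (a, b).
  G <- matrix(c(sum(u * u), -sum(u * v), -sum(u * v), sum(v * v)), 2L, 2L)
  h <- c(sum(u * p_tilde), -sum(v * p_tilde))
  unconstrained <- drop(solve(G, h))
  if (!constrained || all(unconstrained >= 0)) {
    ab <- unconstrained
  } else {
    # Active-set over the two boundary faces of the cone.
    candidates <- list(
      c(max(0, h[1] / G[1, 1]), 0),
      c(0, max(0, h[2] / G[2, 2])),
      c(0, 0)
    )
    sses <- purrr::map_dbl(candidates, function(cc) sse_at(cc[1], cc[2]))
    ab <- candidates[[which.min(sses)]]
  }
  a <- ab[1]
  b <- ab[2]
  sse <- sse_at(a, b)
  structure(
    list(p = stats::setNames(p, IPD_STATES), p_tilde = p_tilde,
         u = u, v = v, a = a, b = b,
         phi = a, chi = if (a > 0) b / a else NA_real_,
         sse = sse, sse_clipped = min(sse, 1),
         constrained = constrained, payoffs = payoffs),
    class = "ipd_zd_fit"
  )
}

#' @export
print.ipd_zd_fit <- function(x, ...) {
  cat("<ipd_zd_fit> p = (", paste(format(x$p, digits = 4), collapse = ", "),
      ")\n", sep = "")
  cat("  phi = ", format(x$phi, digits = 6),
      ", chi = ", format(x$chi, digits = 6),
      ", SSE = ", format(x$sse, digits = 6), "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------

feature_columns <- function() {
  c("trial", "tournament_type", "name", "rank", "normalized_rank",
    "median_score", "C_r", "CC_to_C", "CD_to_C", "DC_to_C", "DD_to_C",
    "C_max", "C_min", "C_mean", "C_median",
    "C_r_over_C_max", "C_min_over_C_r", "C_r_over_C_median",
    "C_r_over_C_mean", "SSE", "sse_imputed", "memory_usage",
    "stochastic", "makes_use_of_game", "makes_use_of_length",
    "N", "k", "n", "p_n", "p_e")
}

empty_feature_table <- function() {
  tibble::tibble(
    trial = integer(), tournament_type = character(), name = character(),
    rank = integer(), normalized_rank = double(), median_score = double(),
    C_r = double(), CC_to_C = double(), CD_to_C = double(),
    DC_to_C = double(), DD_to_C = double(), C_max = double(),
    C_min = double(), C_mean = double(), C_median = double(),
    C_r_over_C_max = double(), C_min_over_C_r = double(),
    C_r_over_C_median = double(), C_r_over_C_mean = double(),
    SSE = double(), sse_imputed = logical(), memory_usage = double(),
    stochastic = logical(), makes_use_of_game = logical(),
    makes_use_of_length = logical(), N = integer(), k = integer(),
    n = integer(), p_n = double(), p_e = double()
  )
}

#' Feature rows from one tournament summary
#'
#' Derives the per-strategy feature record from a tournament result: the
#' normalized rank, cooperation aggregates and ratios, the SSE distance
#' of the pooled conditional cooperation rates to the zero-determinant
#' family, memory usage (fixed-length tournaments only), the strategy
#' classifiers, and the tournament parameters. Conditional rates that
#' were never observed are imputed at the neutral value 0.5 before the
#' SSE fit and flagged in `sse_imputed`.
#'
#' @param summary An [run_tournament()] result.
#' @param trial_id Integer trial identifier stored in the `trial` column.
#' @return A tibble with one row per strategy; see `vignette("ipd-tournaments")`
#'   for the column glossary.
#' @export
summary_features <- function(summary, trial_id = NA_integer_) {
  stopifnot(inherits(summary, "ipd_result_summary"))
  cfg <- attr(summary, "config")
  players <- attr(summary, "players")
  N <- cfg$n_players
  fixed_length <- cfg$type %in% c("standard", "noisy")
  spec <- players[match(summary$name, players$name), ]
  agg <- cooperation_aggregates(summary$cooperation_rating)
  cond <- as.matrix(summary[, c("CC_to_C", "CD_to_C", "DC_to_C", "DD_to_C")])
  imputed <- apply(cond, 1L, anyNA)
  sse <- purrr::map_dbl(seq_len(nrow(cond)), function(i) {
    p <- cond[i, ]
    p[is.na(p)] <- 0.5
    sse_to_zd(p, cfg$payoffs)$sse
  })
  tibble::tibble(
    trial = as.integer(trial_id),
    tournament_type = cfg$type,
    name = summary$name,
    rank = as.integer(summary$rank),
    normalized_rank = normalized_rank(summary$rank, N),
    median_score = summary$median_score,
    C_r = summary$cooperation_rating,
    CC_to_C = summary$CC_to_C,
    CD_to_C = summary$CD_to_C,
    DC_to_C = summary$DC_to_C,
    DD_to_C = summary$DD_to_C,
    C_max = agg$C_max, C_min = agg$C_min,
    C_mean = agg$C_mean, C_median = agg$C_median,
    C_r_over_C_max = agg$C_r_over_C_max,
    C_min_over_C_r = agg$C_min_over_C_r,
    C_r_over_C_median = agg$C_r_over_C_median,
    C_r_over_C_mean = agg$C_r_over_C_mean,
    SSE = sse,
    sse_imputed = imputed,
    memory_usage = if (fixed_length) {
      memory_usage(spec$memory_size, cfg$n)
    } else {
      NA_real_
    },
    stochastic = spec$stochastic,
    makes_use_of_game = spec$makes_use_of_game,
    makes_use_of_length = spec$makes_use_of_length,
    N = as.integer(N),
    k = as.integer(cfg$k),
    n = if (fixed_length) as.integer(cfg$n) else NA_integer_,
    p_n = cfg$p_n,
    p_e = if (is.null(cfg$p_e)) NA_real_ else cfg$p_e
  )
}
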
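tournament_type <- function(p_e, p_n) {
  if (is.null(p_e)) {
    if (p_n > 0) "noisy" else "standard"
  } else {
    if (p_n > 0) "noisy_probabilistic_ending" else "probabilistic_ending"
  }
}

#' Assign tournament ranks from scores
#'
#' Ranks are 0-based: rank 0 is the winner (highest score), rank `N - 1`
#' is last place. Ties are broken by lexicographic name so rankings are
#' deterministic.
#'
#' @param scores Numeric vector, one score per player.
#' @param names Optional character vector of player names used for tie
#'   breaking (defaults to the score order).
#' @return Integer vector of ranks aligned with `scores`, a permutation
#'   of `0:(N-1)`.
#' @examples
#' score_ranks(c(3.2, 1.95, 1.5))  # 0 1 2
#' @export
score_ranks <- function(scores, names = NULL) {
  stopifnot(is.numeric(scores), length(scores) >= 1)
  names <- names %||% sprintf("player %06d", seq_along(scores))
  ord <- order(-scores, names)
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores) - 1L
  ranks
}

# Per-role behavioral counts for one match: focal plays f, opponent o.
role_counts <- function(f, o) {
  L <- length(f)
  s <- paste0(f, o)
  si <- match(s, IPD_STATES)
  out <- list(
    plays_C = sum(f == "C"),
    plays = L,
    first_C = as.integer(f[1L] == "C"),
    states = tabulate(si, 4L)
  )
  if (L > 1L) {
    prev <- si[-L]
    next_C <- f[-1L] == "C"
    out$trans_den <- tabulate(prev, 4L)
    out$trans_num <- tabulate(prev[next_C], 4L)
  } else {
    out$trans_den <- integer(4L)
    out$trans_num <- integer(4L)
  }
  out
}

#' Run a round-robin tournament
#'
#' Every unordered pair of distinct players meets once per repetition;
#' self-pairs are also played when `self_play = TRUE` (they contribute to
#' the behavior statistics but never to scores, wins, or ranks). A
#' player's score in one repetition is its mean per-turn payoff averaged
#' over its `N - 1` matches; the reported `median_score` is the median of
#' these over the `k` repetitions, and ranks are assigned by descending
#' score (median by default; see `rank_by`).
#'
#' @param players Character vector of catalog names and/or a list of
#'   [strategy()] objects, length `N >= 2`. Duplicate names are
#'   disambiguated with [make.unique()].
#' @param n Turns per match (fixed-length tournaments).
#' @param p_e Per-turn ending probability (probabilistic-ending
#'   tournaments); exactly one of `n`, `p_e` must be given.
#' @param p_n Action-flip probability.
#' @param k Number of repetitions of the full round robin.
#' @param seed Integer master seed; every match derives its own child
#'   seed from `(seed, repetition, pair)`, so results do not depend on
#'   execution order.
#' @param payoffs An [payoff_matrix()] object.
#' @param self_play Play self-pairs (pooled into behavior statistics,
#'   excluded from scoring)? `FALSE` skips them entirely.
#' @param rank_by Rank players by the `"median"` (default) or `"mean"`
#'   over repetitions of their per-repetition mean per-turn score.
#' @param length_cap Upper bound on probabilistic-ending match lengths.
#' @return A tibble of class `ipd_result_summary`, one row per player
#'   ordered by rank, with columns `rank`, `name`, `median_score`,
#'   `cooperation_rating`, `wins` (mean match wins per repetition),
#'   `initial_C`, the four state occupancy rates `CC_rate` ... `DD_rate`,
#'   and the four conditional cooperation rates `CC_to_C` ... `DD_to_C`
#'   (`NA` when a state was never visited with a successor round).
#'   Attributes `config` and `players` carry the tournament settings and
#'   the players' classifier metadata.
#' @examples
#' run_tournament(c("Cooperator", "Defector", "Tit For Tat"),
#'                n = 10, k = 1, seed = 1)
#' @export
run_tournament <- function(players, n = NULL, p_e = NULL, p_n = 0, k = 1,
                           seed = NULL, payoffs = payoff_matrix(),
                           self_play = TRUE,
                           rank_by = c("median", "mean"),
                           length_cap = 10000L) {
  rank_by <- match.arg(rank_by)
  if (is.character(players)) players <- as.list(players)
  strat <- purrr::map(players, make_strategy)
  N <- length(strat)
  if (N < 2) stop("a tournament needs at least 2 players", call. = FALSE)
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("`k` must be a positive integer", call. = FALSE)
  base_config <- match_config(n = n, p_e = p_e, p_n = p_n,
                              length_cap = length_cap)
  seed <- seed %||% sample.int(2147483647L, 1L)
  player_names <- make.unique(purrr::map_chr(strat, "name"), sep = " #")

  plays_C <- numeric(N); plays <- numeric(N)
  first_C <- numeric(N); first_n <- numeric(N)
  wins <- numeric(N)
  state_counts <- matrix(0, 4L, N)
  trans_num <- matrix(0, 4L, N)
  trans_den <- matrix(0, 4L, N)
  rep_scores <- matrix(0, k, N)

  pool <- function(idx, rc) {
    plays_C[idx] <<- plays_C[idx] + rc$plays_C
    plays[idx] <<- plays[idx] + rc$plays
    first_C[idx] <<- first_C[idx] + rc$first_C
    first_n[idx] <<- first_n[idx] + 1
    state_counts[, idx] <<- state_counts[, idx] + rc$states
    trans_num[, idx] <<- trans_num[, idx] + rc$trans_num
    trans_den[, idx] <<- trans_den[, idx] + rc$trans_den
  }

  for (r in seq_len(k)) {
    for (i in seq_len(N)) {
      for (j in i:N) {
        if (i == j && !self_play) next
        cfg <- base_config
        cfg$seed <- derive_seed(seed, r, i, j)
        m <- play_match(strat[[i]], strat[[j]], cfg, payoffs)
        pool(i, role_counts(m$actions_a, m$actions_b))
        pool(j, role_counts(m$actions_b, m$actions_a))
        if (i != j) {
          rep_scores[r, i] <- rep_scores[r, i] + m$total_a / m$length
          rep_scores[r, j] <- rep_scores[r, j] + m$total_b / m$length
          if (m$total_a > m$total_b) {
            wins[i] <- wins[i] + 1
          } else if (m$total_b > m$total_a) {
            wins[j] <- wins[j] + 1
          }
        }
      }
    }
  }

  rep_scores <- rep_scores / (N - 1L)
  median_score <- apply(rep_scores, 2L, median)
  rank_score <- if (rank_by == "median") median_score else colMeans(rep_scores)
  ranks <- score_ranks(rank_score, player_names)

  cond <- ifelse(trans_den > 0, trans_num / trans_den, NA_real_)
  out <- tibble::tibble(
    rank = ranks,
    name = player_names,
    median_score = median_score,
    cooperation_rating = plays_C / plays,
    wins = wins / k,
    initial_C = first_C / first_n,
    CC_rate = state_counts[1L, ] / plays,
    CD_rate = state_counts[2L, ] / plays,
    DC_rate = state_counts[3L, ] / plays,
    DD_rate = state_counts[4L, ] / plays,
    CC_to_C = cond[1L, ],
    CD_to_C = cond[2L, ],
    DC_to_C = cond[3L, ],
    DD_to_C = cond[4L, ]
  )
  out <- out[order(out$rank), ]
  specs <- dplyr::bind_rows(purrr::map(strat, classify))
  specs$name <- player_names
  attr(out, "players") <- specs
  attr(out, "config") <- list(
    type = tournament_type(p_e, p_n), n = n, p_e = p_e, p_n = p_n, k = k,
    seed = seed, self_play = self_play, rank_by = rank_by,
    length_cap = length_cap, n_players = N, payoffs = payoffs
  )
  class(out) <- c("ipd_result_summary", class(out))
  out
}

#' @export
print.ipd_result_summary <- function(x, ...) {
  cfg <- attr(x, "config")
  if (!is.null(cfg)) {
    cat("# ", gsub("_", " ", cfg$type), " tournament: ", cfg$n_players,
        " players, k = ", cfg$k,
        if (!is.null(cfg$n)) paste0(", n = ", cfg$n),
        if (!is.null(cfg$p_e)) paste0(", p_e = ", format(cfg$p_e)),
        if (cfg$p_n > 0) paste0(", p_n = ", format(cfg$p_n)),
        "\n", sep = "")
  }
  NextMethod()
}

#' Pooled behavior statistics from a set of matches
#'
#' Pools raw counts over matches (both roles of every match) by player
#' name and reports, per player: the cooperation rating `C_r` (fraction
#' of all plays that were C), the fraction of matches opened with C, the
#' occupancy of the four joint states (focal action first), the
#' conditional cooperation rate after each state, and match wins
#' (strictly greater total; drawn matches count for neither player).
#' Conditional rates whose state was never visited with a successor
#' round are `NA`, not 0.
#'
#' @param matches A single [play_match()] result or a list of them.
#' @return A tibble with one row per distinct player name.
#' @examples
#' m <- play_match("Tit For Tat", "Defector", match_config(n = 5))
#' summarize_behavior(m)
#' @export
summarize_behavior <- function(matches) {
  if (inherits(matches, "ipd_match")) matches <- list(matches)
  stopifnot(length(matches) >= 1,
            all(purrr::map_lgl(matches, inherits, "ipd_match")))
  nm <- unique(unlist(purrr::map(matches, function(m) c(m$name_a, m$name_b))))
  N <- length(nm)
  plays_C <- plays <- first_C <- first_n <- wins <- n_matches <- numeric(N)
  state_counts <- matrix(0, 4L, N)
  trans_num <- trans_den <- matrix(0, 4L, N)
  for (m in matches) {
    ia <- match(m$name_a, nm); ib <- match(m$name_b, nm)
    for (role in list(list(idx = ia, f = m$actions_a, o = m$actions_b),
                      list(idx = ib, f = m$actions_b, o = m$actions_a))) {
      rc <- role_counts(role$f, role$o)
      idx <- role$idx
      plays_C[idx] <- plays_C[idx] + rc$plays_C
      plays[idx] <- plays[idx] + rc$plays
      first_C[idx] <- first_C[idx] + rc$first_C
      first_n[idx] <- first_n[idx] + 1
      state_counts[, idx] <- state_counts[, idx] + rc$states
      trans_num[, idx] <- trans_num[, idx] + rc$trans_num
      trans_den[, idx] <- trans_den[, idx] + rc$trans_den
      n_matches[idx] <- n_matches[idx] + 1
    }
    if (ia != ib) {
      if (m$total_a > m$total_b) wins[ia] <- wins[ia] + 1
      if (m$total_b > m$total_a) wins[ib] <- wins[ib] + 1
    }
  }
  cond <- ifelse(trans_den > 0, trans_num / trans_den, NA_real_)
  tibble::tibble(
    name = nm,
    n_matches = n_matches,
    cooperation_rating = plays_C / plays,
    wins = wins,
    initial_C = first_C / first_n,
    CC_rate = state_counts[1L, ] / plays,
    CD_rate = state_counts[2L, ] / plays,
    DC_rate = state_counts[3L, ] / plays,
    DD_rate = state_counts[4L, ] / plays,
    CC_to_C = cond[1L, ],
    CD_to_C = cond[2L, ],
    DC_to_C = cond[3L, ],
    DD_to_C = cond[4L, ]
  )
}
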
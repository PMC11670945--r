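#' Configuration of a single match
#'
#' A match either has a fixed number of turns `n`, or ends after each turn
#' with probability `p_e`, giving a geometrically distributed length.
#' Exactly one of `n` and `p_e` must be supplied. Each turn, each player's
#' realized action is independently flipped with probability `p_n`.
#'
#' @param n Positive integer number of turns, or `NULL` when the match has
#'   a probabilistic ending.
#' @param p_e Per-turn probability in `(0, 1]` that the match ends, or
#'   `NULL` for a fixed-length match.
#' @param p_n Probability in `[0, 1]` that a player's action is flipped
#'   before being played and recorded.
#' @param length_cap Hard upper bound on the sampled length of a
#'   probabilistic-ending match, guarding against tiny `p_e`.
#' @param seed Optional integer seed fixing the whole match (noise,
#'   stochastic strategies, and the sampled length).
#' @return An object of class `ipd_match_config`.
#' @examples
#' match_config(n = 100)
#' match_config(p_e = 0.05, p_n = 0.01)
#' @export
match_config <- function(n = NULL, p_e = NULL, p_n = 0, length_cap = 10000L,
                         seed = NULL) {
  if (is.null(n) && is.null(p_e)) {
    stop("one of `n` and `p_e` must be given", call. = FALSE)
  }
  if (!is.null(n) && !is.null(p_e)) {
    stop("exactly one of `n` and `p_e` may govern the match length",
         call. = FALSE)
  }
  if (!is.null(n)) {
    n <- as.integer(n)
    if (is.na(n) || n < 1) stop("`n` must be a positive integer", call. = FALSE)
  }
  if (!is.null(p_e)) {
    check_probability(p_e, "p_e", open_min = TRUE)
  }
  check_probability(p_n, "p_n")
  length_cap <- as.integer(length_cap)
  if (is.na(length_cap) || length_cap < 1) {
    stop("`length_cap` must be a positive integer", call. = FALSE)
  }
  structure(
    list(n = n, p_e = p_e, p_n = p_n, length_cap = length_cap,
         seed = if (!is.null(seed)) as.integer(seed)),
    class = "ipd_match_config"
  )
}

#' @export
print.ipd_match_config <- function(x, ...) {
  len <- if (is.null(x$p_e)) paste0("n = ", x$n)
         else paste0("p_e = ", format(x$p_e), " (cap ", x$length_cap, ")")
  cat("<ipd_match_config> ", len, ", p_n = ", format(x$p_n),
      if (!is.null(x$seed)) paste0(", seed = ", x$seed), "\n", sep = "")
  invisible(x)
}

#' Sample the length of a probabilistic-ending match
#'
#' Match lengths follow the geometric law on the positive integers,
#' `P(L = l) = (1 - p_e)^(l - 1) * p_e`, so the expected length is
#' `1 / p_e`. Draws are truncated at `cap`.
#'
#' @param p_e Per-turn ending probability in `(0, 1]`.
#' @param cap Upper truncation bound.
#' @param n Number of lengths to draw.
#' @return Integer vector of `n` match lengths, each in `[1, cap]`.
#' @examples
#' set.seed(1)
#' mean(sample_match_length(0.2, n = 1000))  # close to 5
#' @export
sample_match_length <- function(p_e, cap = 10000L, n = 1L) {
  check_probability(p_e, "p_e", open_min = TRUE)
  cap <- as.integer(cap)
  if (is.na(cap) || cap < 1) stop("`cap` must be a positive integer", call. = FALSE)
  # rgeom counts failures before the first success, hence the + 1.
  pmin(rgeom(n, p_e) + 1L, cap)
}

#' Flip intended actions with probability p_n
#'
#' Implements per-turn action noise: each element of `action` is replaced
#' by its opposite independently with probability `p_n`. With `p_n = 0`
#' this consumes no random numbers.
#'
#' @param action Character vector of intended `"C"`/`"D"` actions.
#' @param p_n Flip probability in `[0, 1]`.
#' @return Character vector of realized actions.
#' @export
apply_noise <- function(action, p_n) {
  action <- check_actions(action)
  check_probability(p_n, "p_n")
  if (p_n <= 0) return(action)
  if (p_n >= 1) return(flip_action(action))
  flip <- runif(length(action)) < p_n
  ifelse(flip, flip_action(action), action)
}

# Turn a strategy's play (an action, or a cooperation probability) into a
# realized action, drawing from the current RNG stream when needed.
# Probabilities of exactly 0 or 1 consume no randomness.
realize_play <- function(play) {
  if (is.character(play)) {
    return(check_actions(play, arg = "play"))
  }
  p <- as.numeric(play)
  if (is.na(p) || p < 0 || p > 1) {
    stop("a strategy must play \"C\", \"D\", or a cooperation probability",
         call. = FALSE)
  }
  if (p >= 1) "C" else if (p <= 0) "D" else if (runif(1) < p) "C" else "D"
}

#' Play a single match between two strategies
#'
#' Runs the iterated game: each turn both strategies compute an intended
#' action from the realized (post-noise) history visible to them, noise is
#' applied to each intended action independently, and the realized actions
#' are recorded, scored, and become the history both players observe in
#' later turns. Strategies are given the number of turns in their context
#' only for fixed-length matches.
#'
#' @param a,b Strategies ([strategy()] objects or catalog names, see
#'   [make_strategy()]).
#' @param config An [match_config()] object.
#' @param payoffs An [payoff_matrix()] object.
#' @return An object of class `ipd_match` with fields `name_a`, `name_b`,
#'   `actions_a`, `actions_b` (realized actions), `payoffs_a`, `payoffs_b`
#'   (per-turn scores), `total_a`, `total_b`, and `length`. Use
#'   [tibble::as_tibble()] for a per-turn view.
#' @examples
#' m <- play_match("Tit For Tat", "Defector", match_config(n = 5, seed = 1))
#' m$actions_a  # C D D D D
#' m$total_a / m$length
#' @export
play_match <- function(a, b, config, payoffs = payoff_matrix()) {
  a <- make_strategy(a)
  b <- make_strategy(b)
  if (!inherits(config, "ipd_match_config")) {
    stop("`config` must be created by match_config()", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- if (is.null(config$p_e)) config$n
       else sample_match_length(config$p_e, config$length_cap)
  n_visible <- if (is.null(config$p_e)) config$n else NA_integer_
  p_n <- config$p_n
  # pay[focal, opponent]
  pay <- matrix(c(payoffs$R, payoffs$T, payoffs$S, payoffs$P), 2L, 2L,
                dimnames = list(IPD_ACTIONS, IPD_ACTIONS))
  hist_a <- character(L)
  hist_b <- character(L)
  pay_a <- numeric(L)
  pay_b <- numeric(L)
  state_a <- a$init()
  state_b <- b$init()
  for (t in seq_len(L)) {
    seen <- seq_len(t - 1L)
    ctx <- list(payoffs = payoffs, n = n_visible, turn = t)
    res_a <- a$choose(state_a, hist_a[seen], hist_b[seen], ctx)
    res_b <- b$choose(state_b, hist_b[seen], hist_a[seen], ctx)
    state_a <- res_a$state
    state_b <- res_b$state
    act_a <- realize_play(res_a$play)
    act_b <- realize_play(res_b$play)
    if (p_n > 0) {
      if (runif(1) < p_n) act_a <- if (act_a == "C") "D" else "C"
      if (runif(1) < p_n) act_b <- if (act_b == "C") "D" else "C"
    }
    hist_a[t] <- act_a
    hist_b[t] <- act_b
    pay_a[t] <- pay[act_a, act_b]
    pay_b[t] <- pay[act_b, act_a]
  }
  structure(
    list(name_a = a$name, name_b = b$name,
         actions_a = hist_a, actions_b = hist_b,
         payoffs_a = pay_a, payoffs_b = pay_b,
         total_a = sum(pay_a), total_b = sum(pay_b),
         length = L, config = config, payoffs = payoffs),
    class = "ipd_match"
  )
}

#' @export
print.ipd_match <- function(x, ...) {
  cat("<ipd_match> ", x$name_a, " vs ", x$name_b, ", ", x$length,
      " turns\n", sep = "")
  cat("  totals: ", x$total_a, " vs ", x$total_b,
      "  (per turn ", round(x$total_a / x$length, 3), " vs ",
      round(x$total_b / x$length, 3), ")\n", sep = "")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble ipd_match
#' @export
as_tibble.ipd_match <- function(x, ...) {
  tibble::tibble(
    turn = seq_len(x$length),
    action_a = x$actions_a,
    action_b = x$actions_b,
    payoff_a = x$payoffs_a,
    payoff_b = x$payoffs_b
  )
}
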
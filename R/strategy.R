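#' Define an IPD strategy
#'
#' A strategy couples a decision rule with the static classifier metadata
#' used by the feature analysis. The decision rule is a function
#' `choose(state, own, opp, ctx)` where `own` and `opp` are the realized
#' (post-noise) action histories visible to the player, and
#' `ctx = list(payoffs, n, turn)`; `ctx$n` is `NA` unless the match has a
#' fixed, known length. It must return `list(play = , state = )`, where
#' `play` is `"C"`, `"D"`, or a cooperation probability in `[0, 1]`
#' (stochastic strategies draw through the match RNG stream, so a seeded
#' match is fully reproducible). `init()` builds the per-match mutable
#' state, so a strategy object can be reused across matches.
#'
#' @param name Display name; must be unique within a catalog.
#' @param choose Decision rule, see Details.
#' @param init Zero-argument function returning the initial per-match
#'   state (default `NULL` state for stateless rules).
#' @param stochastic Does the rule randomize?
#' @param uses_game Does the rule read the payoff matrix?
#' @param uses_length Does the rule read the number of turns?
#' @param memory Number of past rounds the rule conditions on; `Inf` for
#'   strategies that condition on unboundedly old events (triggers,
#'   counters, automata).
#' @return An object of class `ipd_strategy`.
#' @examples
#' tft <- strategy("My TFT",
#'   stateless(function(own, opp, ctx) {
#'     if (ctx$turn == 1L) "C" else opp[ctx$turn - 1L]
#'   }),
#'   memory = 1)
#' @export
strategy <- function(name, choose, init = function() NULL,
                     stochastic = FALSE, uses_game = FALSE,
                     uses_length = FALSE, memory = 0) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name),
            is.function(choose), is.function(init))
  structure(
    list(name = name, choose = choose, init = init,
         stochastic = isTRUE(stochastic),
         makes_use_of_game = isTRUE(uses_game),
         makes_use_of_length = isTRUE(uses_length),
         memory_size = as.numeric(memory)),
    class = "ipd_strategy"
  )
}

#' Wrap a history-only decision rule as a full strategy rule
#'
#' Convenience for strategies without per-match state: `f(own, opp, ctx)`
#' returns a play, and the (null) state is threaded automatically.
#'
#' @param f Function of `(own, opp, ctx)` returning `"C"`, `"D"`, or a
#'   cooperation probability.
#' @return A `choose` function suitable for [strategy()].
#' @export
stateless <- function(f) {
  force(f)
  function(state, own, opp, ctx) list(play = f(own, opp, ctx), state = state)
}

#' @export
print.ipd_strategy <- function(x, ...) {
  cat("<ipd_strategy> ", x$name, "\n", sep = "")
  cat("  stochastic: ", x$stochastic,
      ", uses game: ", x$makes_use_of_game,
      ", uses length: ", x$makes_use_of_length,
      ", memory: ", x$memory_size, "\n", sep = "")
  invisible(x)
}

#' Classifier metadata of a strategy
#'
#' Returns the static properties recorded for each strategy: whether it is
#' stochastic, whether it makes use of the game payoffs or of the number
#' of turns, and its memory size (`Inf` for full-history strategies).
#'
#' @param x A strategy object or catalog name.
#' @return One-row tibble with columns `name`, `stochastic`,
#'   `makes_use_of_game`, `makes_use_of_length`, `memory_size`.
#' @examples
#' classify("Grudger")
#' @export
classify <- function(x) {
  s <- make_strategy(x)
  tibble::tibble(
    name = s$name,
    stochastic = s$stochastic,
    makes_use_of_game = s$makes_use_of_game,
    makes_use_of_length = s$makes_use_of_length,
    memory_size = s$memory_size
  )
}
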
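# The catalog of canonical, fully specified strategies. Each constructor
# is a zero-argument (or defaulted) function returning a fresh
# ipd_strategy. Rules are stated in the roxygen for ipd_catalog().

st_cooperator <- function() {
  strategy("Cooperator", stateless(function(own, opp, ctx) "C"), memory = 0)
}

st_defector <- function() {
  strategy("Defector", stateless(function(own, opp, ctx) "D"), memory = 0)
}

st_alternator <- function() {
  strategy("Alternator", stateless(function(own, opp, ctx) {
    t <- ctx$turn
    if (t == 1L) "C" else if (own[t - 1L] == "C") "D" else "C"
  }), memory = 1)
}

st_random <- function(p = 0.5) {
  check_probability(p, "p")
  strategy("Random", stateless(function(own, opp, ctx) p),
           stochastic = TRUE, memory = 0)
}

st_tft <- function() {
  strategy("Tit For Tat", stateless(function(own, opp, ctx) {
    t <- ctx$turn
    if (t == 1L) "C" else opp[t - 1L]
  }), memory = 1)
}

st_suspicious_tft <- function() {
  strategy("Suspicious Tit For Tat", stateless(function(own, opp, ctx) {
    t <- ctx$turn
    if (t == 1L) "D" else opp[t - 1L]
  }), memory = 1)
}

# Defects only after two consecutive opponent defections.
st_tf2t <- function() {
  strategy("Tit For 2 Tats", stateless(function(own, opp, ctx) {
    t <- ctx$turn
    if (t > 2L && opp[t - 1L] == "D" && opp[t - 2L] == "D") "D" else "C"
  }), memory = 2)
}

# Answers a defection with two defections.
st_two_tits_for_tat <- function() {
  strategy("Two Tits For Tat", stateless(function(own, opp, ctx) {
    t <- ctx$turn
    if (t > 1L && "D" %in% opp[max(1L, t - 2L):(t - 1L)]) "D" else "C"
  }), memory = 2)
}

#' Generosity of Generous Tit For Tat
#'
#' The standard generosity level: after an opponent defection, Generous
#' Tit For Tat still cooperates with probability
#' `g = min(1 - (T - R) / (R - S), (R - P) / (T - P))`, which evaluates to
#' 1/3 under the default payoffs.
#'
#' @param payoffs An [payoff_matrix()] object.
#' @return The forgiveness probability `g`.
#' @examples
#' gtft_generosity()  # 1/3
#' @export
gtft_generosity <- function(payoffs = payoff_matrix()) {
  min(1 - (payoffs$T - payoffs$R) / (payoffs$R - payoffs$S),
      (payoffs$R - payoffs$P) / (payoffs$T - payoffs$P))
}

st_generous_tft <- function() {
  strategy("Generous Tit For Tat", stateless(function(own, opp, ctx) {
    t <- ctx$turn
    if (t == 1L) return("C")
    if (opp[t - 1L] == "C") "C" else gtft_generosity(ctx$payoffs)
  }), stochastic = TRUE, uses_game = TRUE, memory = 1)
}

# Cooperates until the opponent's first defection, then defects forever.
st_grudger <- function() {
  strategy("Grudger",
    choose = function(state, own, opp, ctx) {
      t <- ctx$turn
      if (t > 1L && opp[t - 1L] == "D") state$grudge <- TRUE
      list(play = if (state$grudge) "D" else "C", state = state)
    },
    init = function() list(grudge = FALSE),
    memory = Inf)
}

# TFT until the opponent defects twice in a row, then defects forever.
st_spiteful_tft <- function() {
  strategy("Spiteful Tit For Tat",
    choose = function(state, own, opp, ctx) {
      t <- ctx$turn
      if (t > 2L && opp[t - 1L] == "D" && opp[t - 2L] == "D") {
        state$spite <- TRUE
      }
      play <- if (state$spite) "D" else if (t == 1L) "C" else opp[t - 1L]
      list(play = play, state = state)
    },
    init = function() list(spite = FALSE),
    memory = Inf)
}

# Forgives a single defection; defects forever once the opponent has
# defected twice in total.
st_fool_me_once <- function() {
  strategy("Fool Me Once",
    choose = function(state, own, opp, ctx) {
      t <- ctx$turn
      if (t > 1L && opp[t - 1L] == "D") state$defections <- state$defections + 1L
      list(play = if (state$defections >= 2L) "D" else "C", state = state)
    },
    init = function() list(defections = 0L),
    memory = Inf)
}

# Win-Stay Lose-Shift: repeat C after agreement, D after disagreement.
st_pavlov <- function() {
  strategy("Win-Stay Lose-Shift", stateless(function(own, opp, ctx) {
    t <- ctx$turn
    if (t == 1L) "C" else if (own[t - 1L] == opp[t - 1L]) "C" else "D"
  }), memory = 1)
}

# Punishes the opponent's k-th defection with k consecutive defections,
# then cooperates twice (calming) before resuming cooperation.
st_gradual <- function() {
  strategy("Gradual",
    choose = function(state, own, opp, ctx) {
      t <- ctx$turn
      if (t > 1L && opp[t - 1L] == "D") {
        state$opp_defections <- state$opp_defections + 1L
      }
      if (state$punishing > 0L) {
        state$punishing <- state$punishing - 1L
        play <- "D"
      } else if (state$calming > 0L) {
        state$calming <- state$calming - 1L
        play <- "C"
      } else if (t > 1L && opp[t - 1L] == "D") {
        state$punishing <- state$opp_defections - 1L
        state$calming <- 2L
        play <- "D"
      } else {
        play <- "C"
      }
      list(play = play, state = state)
    },
    init = function() list(opp_defections = 0L, punishing = 0L, calming = 0L),
    memory = Inf)
}

# Exponentially smoothed estimate w of the opponent's cooperation;
# cooperates while w >= 1/2.
st_adaptive_tft <- function(theta = 0.5) {
  check_probability(theta, "theta")
  strategy("Adaptive Tit For Tat",
    choose = function(state, own, opp, ctx) {
      t <- ctx$turn
      if (t > 1L) {
        state$w <- (1 - theta) * state$w + theta * (opp[t - 1L] == "C")
      }
      list(play = if (state$w >= 0.5) "C" else "D", state = state)
    },
    init = function() list(w = 0.5),
    memory = Inf)
}

# TFT plus deadlock breaking: after `deadlock` successive rounds of
# disagreement it cooperates to break a CD/DC cycle; once an opponent
# randomness score reaches `randomness` it defects forever.
st_omega_tft <- function(deadlock = 3L, randomness = 8L) {
  deadlock <- as.integer(deadlock)
  randomness <- as.integer(randomness)
  stopifnot(deadlock >= 1L, randomness >= 1L)
  strategy("Omega TFT",
    choose = function(state, own, opp, ctx) {
      t <- ctx$turn
      if (t == 1L) return(list(play = "C", state = state))
      if (t == 2L) return(list(play = opp[1L], state = state))
      if (state$defect_forever) return(list(play = "D", state = state))
      if (state$deadlock >= deadlock) {
        state$deadlock <- 0L
        return(list(play = "C", state = state))
      }
      if (opp[t - 1L] != opp[t - 2L]) state$randomness <- state$randomness + 1L
      if (own[t - 1L] != opp[t - 1L]) state$randomness <- state$randomness + 1L
      if (state$randomness >= randomness) {
        state$defect_forever <- TRUE
        return(list(play = "D", state = state))
      }
      if (own[t - 1L] != opp[t - 1L]) {
        state$deadlock <- state$deadlock + 1L
      } else {
        state$deadlock <- 0L
      }
      list(play = opp[t - 1L], state = state)
    },
    init = function() list(deadlock = 0L, randomness = 0L,
                           defect_forever = FALSE),
    memory = Inf)
}

# Opens D, C, C; if the opponent cooperated on turns 2 and 3 it defects
# forever (the probe found an exploitable opponent), otherwise plays TFT.
st_prober <- function() {
  strategy("Prober",
    choose = function(state, own, opp, ctx) {
      t <- ctx$turn
      if (t <= 3L) {
        return(list(play = c("D", "C", "C")[t], state = state))
      }
      if (is.na(state$exploit)) {
        state$exploit <- opp[2L] == "C" && opp[3L] == "C"
      }
      play <- if (state$exploit) "D" else opp[t - 1L]
      list(play = play, state = state)
    },
    init = function() list(exploit = NA),
    memory = Inf)
}

# Forgives the first three opponent defections, defects forever on the
# fourth; unconditionally defects in the last two rounds when the number
# of turns is known.
st_backstabber <- function() {
  strategy("BackStabber",
    choose = function(state, own, opp, ctx) {
      t <- ctx$turn
      if (t > 1L && opp[t - 1L] == "D") {
        state$defections <- state$defections + 1L
      }
      endgame <- !is.null(ctx$n) && !is.na(ctx$n) && t > ctx$n - 2L
      play <- if (endgame || state$defections >= 4L) "D" else "C"
      list(play = play, state = state)
    },
    init = function() list(defections = 0L),
    uses_length = TRUE, memory = Inf)
}

st_zd_extort_2 <- function() {
  memory_one_strategy("ZD-Extort-2", c(8 / 9, 1 / 2, 1 / 3, 0))
}

st_zd_gtft_2 <- function() {
  memory_one_strategy("ZD-GTFT-2", c(1, 1 / 8, 1, 1 / 4))
}

st_meta_majority <- function() meta_majority()

st_meta_winner <- function() meta_winner()

# ---------------------------------------------------------------------------

build_catalog_constructors <- function() {
  reg <- list()
  add <- function(name, ctor) {
    if (name %in% names(reg)) {
      stop("duplicate strategy name: ", name, call. = FALSE)
    }
    reg[[name]] <<- ctor
  }
  add("Cooperator", st_cooperator)
  add("Defector", st_defector)
  add("Alternator", st_alternator)
  add("Random", st_random)
  add("Tit For Tat", st_tft)
  add("Suspicious Tit For Tat", st_suspicious_tft)
  add("Tit For 2 Tats", st_tf2t)
  add("Two Tits For Tat", st_two_tits_for_tat)
  add("Generous Tit For Tat", st_generous_tft)
  add("Grudger", st_grudger)
  add("Spiteful Tit For Tat", st_spiteful_tft)
  add("Fool Me Once", st_fool_me_once)
  add("Win-Stay Lose-Shift", st_pavlov)
  add("Gradual", st_gradual)
  add("Adaptive Tit For Tat", st_adaptive_tft)
  add("Omega TFT", st_omega_tft)
  add("Prober", st_prober)
  add("BackStabber", st_backstabber)
  add("ZD-Extort-2", st_zd_extort_2)
  add("ZD-GTFT-2", st_zd_gtft_2)
  add("Meta Majority", st_meta_majority)
  add("Meta Winner", st_meta_winner)
  reg
}

catalog_constructors <- function() {
  if (is.null(the_ipdsim_env$constructors)) {
    the_ipdsim_env$constructors <- build_catalog_constructors()
  }
  the_ipdsim_env$constructors
}

#' The catalog of built-in strategies
#'
#' Lists every registered strategy with its classifier metadata. The
#' catalog covers the canonical deterministic and stochastic strategies of
#' the tournament literature (reciprocators, triggers, probers,
#' memory-one zero-determinant strategies, and two ensemble strategies),
#' each with an unambiguous rule; see the package vignette for the full
#' rule statements. Generic families — [memory_one_strategy()],
#' [fsm_strategy()], [lookup_strategy()], [meta_majority()],
#' [meta_winner()] — let users register further strategies, including
#' published rule tables loaded from a config file
#' ([read_strategy_config()]).
#'
#' @return A tibble with columns `name`, `stochastic`,
#'   `makes_use_of_game`, `makes_use_of_length`, `memory_size`, and a
#'   list-column `constructor` of zero-argument constructors.
#' @examples
#' ipd_catalog()
#' @export
ipd_catalog <- function() {
  ctors <- catalog_constructors()
  specs <- purrr::map(ctors, function(ctor) classify(ctor()))
  out <- dplyr::bind_rows(specs)
  out$constructor <- unname(ctors)
  out
}

#' Instantiate a strategy by name
#'
#' @param x A catalog name, or an existing [strategy()] object (returned
#'   unchanged).
#' @param ... Passed to the catalog constructor (e.g. `theta` for
#'   Adaptive Tit For Tat).
#' @return An `ipd_strategy` object.
#' @examples
#' make_strategy("Tit For Tat")
#' @export
make_strategy <- function(x, ...) {
  if (inherits(x, "ipd_strategy")) return(x)
  if (!is.character(x) || length(x) != 1) {
    stop("`x` must be a strategy object or a single catalog name",
         call. = FALSE)
  }
  ctor <- catalog_constructors()[[x]]
  if (is.null(ctor)) stop("unknown strategy: ", x, call. = FALSE)
  ctor(...)
}
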
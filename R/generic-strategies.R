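# Generic strategy families: memory-one vectors, finite state machines,
# lookup tables, and ensemble (meta) strategies. These provide the
# machinery to express published rule tables without hard-coding them.

#' Memory-one strategy from a cooperation vector
#'
#' A memory-one strategy is characterized by four conditional cooperation
#' probabilities `(p_CC, p_CD, p_DC, p_DD)`: the probability of
#' cooperating after each joint outcome of the previous round, focal
#' action listed first. The vector `(1, 0, 1, 0)` is exactly Tit For Tat;
#' probabilities strictly between 0 and 1 make the strategy stochastic.
#'
#' @param name Strategy name.
#' @param probs Numeric vector of four probabilities in `[0, 1]`, ordered
#'   `CC, CD, DC, DD`.
#' @param initial Opening play: `"C"`, `"D"`, or a cooperation
#'   probability.
#' @return An `ipd_strategy`.
#' @examples
#' tft_clone <- memory_one_strategy("M1 TFT", c(1, 0, 1, 0))
#' @seealso [zd_vector()] for building zero-determinant vectors.
#' @export
memory_one_strategy <- function(name, probs, initial = "C") {
  probs <- as.numeric(probs)
  if (length(probs) != 4 || any(is.na(probs)) ||
      any(probs < 0) || any(probs > 1)) {
    stop("`probs` must be four probabilities (p_CC, p_CD, p_DC, p_DD)",
         call. = FALSE)
  }
  init_prob <- if (is.character(initial)) {
    if (check_actions(initial, "initial") == "C") 1 else 0
  } else {
    check_probability(initial, "initial")
  }
  stochastic <- any(probs > 0 & probs < 1) ||
    (init_prob > 0 && init_prob < 1)
  strategy(name, stateless(function(own, opp, ctx) {
    t <- ctx$turn
    if (t == 1L) return(init_prob)
    state <- paste0(own[t - 1L], opp[t - 1L])
    probs[[match(state, IPD_STATES)]]
  }), stochastic = stochastic, memory = 1)
}

#' Memory-one cooperation vector of a zero-determinant strategy
#'
#' Zero-determinant (ZD) strategies enforce a linear relation between the
#' two players' long-run payoffs. In the tilde coordinates
#' `p~ = (p_CC - 1, p_CD - 1, p_DC, p_DD)` the extortionate family is
#' `p~ = phi * ((S_x - P) - chi * (S_y - P))`, where `S_x = (R, S, T, P)`
#' and `S_y = (R, T, S, P)` are the focal and opponent stage payoffs over
#' the states `CC, CD, DC, DD`, `chi >= 1` is the extortion factor, and
#' `phi > 0` scales the vector into the probability simplex.
#'
#' @param phi Scale parameter, `phi > 0`.
#' @param chi Extortion factor.
#' @param payoffs An [payoff_matrix()] object.
#' @return Numeric vector `(p_CC, p_CD, p_DC, p_DD)`.
#' @examples
#' zd_vector(0.1, 2)  # (0.8, 0.1, 0.6, 0)
#' @seealso [sse_to_zd()] for the inverse problem: projecting an observed
#'   vector onto this family.
#' @export
zd_vector <- function(phi, chi, payoffs = payoff_matrix()) {
  stopifnot(is.numeric(phi), length(phi) == 1, phi > 0,
            is.numeric(chi), length(chi) == 1)
  u <- zd_basis(payoffs)
  p_tilde <- phi * (u$x - chi * u$y)
  p <- p_tilde + c(1, 1, 0, 0)
  if (any(p < -1e-9) || any(p > 1 + 1e-9)) {
    stop("phi = ", phi, ", chi = ", chi,
         " maps outside the probability simplex; reduce phi", call. = FALSE)
  }
  stats::setNames(pmin(pmax(p, 0), 1), IPD_STATES)
}

# Stage payoff vectors over the states CC, CD, DC, DD, shifted by P so
# that the mutual-defection component vanishes.
zd_basis <- function(payoffs) {
  list(x = c(payoffs$R, payoffs$S, payoffs$T, payoffs$P) - payoffs$P,
       y = c(payoffs$R, payoffs$T, payoffs$S, payoffs$P) - payoffs$P)
}

#' Finite-state-machine strategy
#'
#' A Mealy machine over the opponent's last action: the first turn plays
#' `initial_action` from `initial_state`; every later turn the pair
#' (current state, opponent's previous action) determines the emitted
#' action and the next state.
#'
#' @param name Strategy name.
#' @param transitions Data frame with columns `state`, `input` (`"C"` or
#'   `"D"`), `next_state`, `action`; one row per (state, input) pair.
#' @param initial_state,initial_action Starting state and opening action.
#' @return An `ipd_strategy` (deterministic, infinite memory).
#' @examples
#' # Grudger as a two-state machine
#' fsm_strategy("FSM Grudger",
#'   transitions = data.frame(
#'     state = c(1, 1, 2, 2), input = c("C", "D", "C", "D"),
#'     next_state = c(1, 2, 2, 2), action = c("C", "D", "D", "D")),
#'   initial_state = 1, initial_action = "C")
#' @export
fsm_strategy <- function(name, transitions, initial_state, initial_action) {
  transitions <- as.data.frame(transitions)
  needed <- c("state", "input", "next_state", "action")
  if (!all(needed %in% names(transitions))) {
    stop("`transitions` needs columns state, input, next_state, action",
         call. = FALSE)
  }
  check_actions(transitions$input, "transitions$input")
  check_actions(transitions$action, "transitions$action")
  key <- paste(transitions$state, transitions$input)
  if (anyDuplicated(key)) {
    stop("duplicate (state, input) pair in `transitions`", call. = FALSE)
  }
  lut <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(transitions))) {
    assign(key[i], list(next_state = transitions$next_state[i],
                        action = transitions$action[i]), envir = lut)
  }
  states <- unique(transitions$state)
  if (!initial_state %in% states) {
    stop("`initial_state` does not appear in `transitions`", call. = FALSE)
  }
  missing <- setdiff(paste(rep(states, each = 2), c("C", "D")), key)
  if (length(missing)) {
    stop("incomplete transition table; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  initial_action <- check_actions(initial_action, "initial_action")
  strategy(name,
    choose = function(state, own, opp, ctx) {
      if (ctx$turn == 1L) {
        return(list(play = initial_action, state = state))
      }
      tr <- get(paste(state$s, opp[ctx$turn - 1L]), envir = lut)
      state$s <- tr$next_state
      list(play = tr$action, state = state)
    },
    init = function() list(s = initial_state),
    memory = Inf)
}

#' Lookup-table strategy
#'
#' Plays a fixed opening, then looks up its action from the joint history
#' of the last `depth` rounds. Keys have the form `"<own>|<opp>"`, e.g.
#' for `depth = 2` the key `"CD|DC"` means the focal player played C then
#' D while the opponent played D then C over the last two rounds.
#'
#' @param name Strategy name.
#' @param table Named character vector or list mapping every one of the
#'   `4^depth` keys to `"C"` or `"D"`.
#' @param depth Number of past rounds in the key.
#' @param opening Character vector of plays for the first turns; must be
#'   at least `depth` long so the key is always complete.
#' @return An `ipd_strategy` (deterministic, memory `depth`).
#' @examples
#' # TFT as a depth-1 table
#' lookup_strategy("LU TFT",
#'   table = c("C|C" = "C", "C|D" = "D", "D|C" = "C", "D|D" = "D"),
#'   depth = 1, opening = "C")
#' @export
lookup_strategy <- function(name, table, depth, opening) {
  depth <- as.integer(depth)
  stopifnot(depth >= 1L)
  opening <- check_actions(opening, "opening")
  if (length(opening) < depth) {
    stop("`opening` must cover at least `depth` turns", call. = FALSE)
  }
  table <- unlist(table)
  check_actions(table, "table")
  combos <- expand.grid(rep(list(IPD_ACTIONS), 2L * depth),
                        stringsAsFactors = FALSE)
  own_part <- apply(combos[, seq_len(depth), drop = FALSE], 1, paste0,
                    collapse = "")
  opp_part <- apply(combos[, depth + seq_len(depth), drop = FALSE], 1,
                    paste0, collapse = "")
  wanted <- paste0(own_part, "|", opp_part)
  missing <- setdiff(wanted, names(table))
  if (length(missing)) {
    stop("lookup table is missing keys: ",
         paste(utils::head(missing, 8), collapse = ", "),
         if (length(missing) > 8) ", ...", call. = FALSE)
  }
  n_open <- length(opening)
  strategy(name, stateless(function(own, opp, ctx) {
    t <- ctx$turn
    if (t <= n_open) return(opening[t])
    window <- (t - depth):(t - 1L)
    key <- paste0(paste0(own[window], collapse = ""), "|",
                  paste0(opp[window], collapse = ""))
    table[[key]]
  }), memory = depth)
}

#' Default team for the ensemble strategies
#'
#' Five deterministic catalog members spanning reciprocation, triggers,
#' and the two unconditional strategies.
#'
#' @return List of `ipd_strategy` objects.
#' @export
default_meta_team <- function() {
  list(st_tft(), st_pavlov(), st_grudger(), st_cooperator(), st_defector())
}

team_classifiers <- function(team) {
  specs <- dplyr::bind_rows(purrr::map(team, classify))
  list(stochastic = any(specs$stochastic),
       uses_game = any(specs$makes_use_of_game),
       uses_length = any(specs$makes_use_of_length))
}

# Run every member one step against the shared history; returns realized
# member proposals and the updated member states.
meta_proposals <- function(team, states, own, opp, ctx) {
  proposals <- character(length(team))
  for (i in seq_along(team)) {
    res <- team[[i]]$choose(states[[i]], own, opp, ctx)
    states[i] <- list(res$state)  # [[<- would drop a NULL state
    proposals[i] <- realize_play(res$play)
  }
  list(proposals = proposals, states = states)
}

#' Majority-vote ensemble strategy
#'
#' Each team member observes the same history as the ensemble and
#' proposes an action; the ensemble plays the majority proposal, with
#' ties broken towards cooperation.
#'
#' @param team List of member strategies.
#' @param name Strategy name.
#' @return An `ipd_strategy`.
#' @export
meta_majority <- function(team = default_meta_team(), name = "Meta Majority") {
  team <- purrr::map(team, make_strategy)
  stopifnot(length(team) >= 1)
  cl <- team_classifiers(team)
  strategy(name,
    choose = function(state, own, opp, ctx) {
      step <- meta_proposals(team, state$members, own, opp, ctx)
      state$members <- step$states
      n_c <- sum(step$proposals == "C")
      list(play = if (n_c >= length(team) - n_c) "C" else "D", state = state)
    },
    init = function() list(members = purrr::map(team, function(s) s$init())),
    stochastic = cl$stochastic, uses_game = cl$uses_game,
    uses_length = cl$uses_length, memory = Inf)
}

#' Best-running-score ensemble strategy
#'
#' Each member proposes an action every turn; the ensemble tracks the
#' hypothetical cumulative payoff each member's proposals would have
#' earned against the opponent's realized actions and plays the proposal
#' of the member with the highest running score (earliest member on
#' ties).
#'
#' @inheritParams meta_majority
#' @return An `ipd_strategy` (makes use of the game payoffs).
#' @export
meta_winner <- function(team = default_meta_team(), name = "Meta Winner") {
  team <- purrr::map(team, make_strategy)
  stopifnot(length(team) >= 1)
  cl <- team_classifiers(team)
  strategy(name,
    choose = function(state, own, opp, ctx) {
      t <- ctx$turn
      if (t > 1L) {
        state$scores <- state$scores +
          focal_payoff(state$last, rep(opp[t - 1L], length(team)),
                       ctx$payoffs)
      }
      step <- meta_proposals(team, state$members, own, opp, ctx)
      state$members <- step$states
      state$last <- step$proposals
      best <- which.max(state$scores)
      list(play = step$proposals[best], state = state)
    },
    init = function() list(members = purrr::map(team, function(s) s$init()),
                           scores = rep(0, length(team)),
                           last = rep("C", length(team))),
    stochastic = cl$stochastic, uses_game = TRUE,
    uses_length = cl$uses_length, memory = Inf)
}
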
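#' Stage-game payoff matrix
#'
#' The one-shot Prisoner's Dilemma is parameterized by four payoffs: the
#' reward `R` for mutual cooperation, the sucker payoff `S` for cooperating
#' against a defector, the temptation `T` for defecting against a
#' cooperator, and the punishment `P` for mutual defection. A valid dilemma
#' requires `T > R > P > S` (defection dominates in one shot) and
#' `2R > T + S` (mutual cooperation beats alternating exploitation). The
#' defaults `R = 3, S = 0, T = 5, P = 1` are the values most commonly used
#' in the literature.
#'
#' @param R,S,T,P Numeric payoffs per turn.
#' @return An object of class `ipd_payoffs`: a named list with elements
#'   `R`, `S`, `T`, `P`.
#' @examples
#' payoff_matrix()
#' @seealso [stage_payoff()]
#' @export
payoff_matrix <- function(R = 3, S = 0, T = 5, P = 1) {
  vals <- c(R = R, S = S, T = T, P = P)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("payoffs must be finite numbers", call. = FALSE)
  }
  if (!(T > R && R > P && P > S)) {
    stop("payoffs must satisfy T > R > P > S", call. = FALSE)
  }
  if (!(2 * R > T + S)) {
    stop("payoffs must satisfy 2R > T + S", call. = FALSE)
  }
  structure(list(R = R, S = S, T = T, P = P), class = "ipd_payoffs")
}

#' @export
print.ipd_payoffs <- function(x, ...) {
  cat("<ipd_payoffs> R =", x$R, " S =", x$S, " T =", x$T, " P =", x$P, "\n")
  invisible(x)
}

#' Payoffs of a single stage game
#'
#' Scores one (or several) simultaneous action pairs: mutual cooperation
#' pays `(R, R)`, mutual defection `(P, P)`, and unilateral defection pays
#' the defector `T` and the cooperator `S`.
#'
#' @param focal,opponent Character vectors of `"C"`/`"D"` actions, equal
#'   length.
#' @param payoffs An [payoff_matrix()] object.
#' @return A tibble with columns `focal` and `opponent` holding each
#'   player's payoff per action pair.
#' @examples
#' stage_payoff("C", "C")  # (3, 3)
#' stage_payoff("D", "C")  # (5, 0)
#' @export
stage_payoff <- function(focal, opponent, payoffs = payoff_matrix()) {
  focal <- check_actions(focal)
  opponent <- check_actions(opponent)
  if (length(focal) != length(opponent)) {
    stop("`focal` and `opponent` must have the same length", call. = FALSE)
  }
  pay_focal <- focal_payoff(focal, opponent, payoffs)
  pay_opponent <- focal_payoff(opponent, focal, payoffs)
  tibble::tibble(focal = pay_focal, opponent = pay_opponent)
}

# Vectorized payoff for the first-named player only.
focal_payoff <- function(focal, opponent, payoffs) {
  ifelse(focal == "C",
         ifelse(opponent == "C", payoffs$R, payoffs$S),
         ifelse(opponent == "C", payoffs$T, payoffs$P))
}
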
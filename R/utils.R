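#' The two stage-game actions
#'
#' Actions are plain characters: `"C"` (cooperate) and `"D"` (defect).
#' @keywords internal
#' @noRd
IPD_ACTIONS <- c("C", "D")

IPD_STATES <- c("CC", "CD", "DC", "DD")

check_actions <- function(x, arg = deparse(substitute(x))) {
  x <- as.character(x)
  if (length(x) == 0 || !all(x %in% IPD_ACTIONS)) {
    stop("`", arg, "` must contain only \"C\" and \"D\"", call. = FALSE)
  }
  x
}

#' Flip an action
#'
#' `flip_action("C")` is `"D"` and vice versa; flipping twice returns the
#' original action. Vectorized.
#'
#' @param action Character vector of `"C"`/`"D"` actions.
#' @return Character vector of the opposite actions.
#' @examples
#' flip_action(c("C", "D"))
#' @export
flip_action <- function(action) {
  action <- check_actions(action)
  ifelse(action == "C", "D", "C")
}

check_probability <- function(x, arg, min = 0, max = 1,
                              open_min = FALSE, open_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    stop("`", arg, "` must be a single number", call. = FALSE)
  }
  lo_ok <- if (open_min) x > min else x >= min
  hi_ok <- if (open_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    stop("`", arg, "` must lie in ", if (open_min) "(" else "[", min, ", ",
         max, if (open_max) ")" else "]", call. = FALSE)
  }
  x
}

# Deterministic child-seed derivation: one master seed per tournament or
# campaign, child streams keyed by integer indices so that results are
# reproducible and independent of execution order. Mixes with a
# multiplicative LCG step; all arithmetic is exact in doubles (< 2^53).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed %% 2147483629L)
  for (v in idx) {
    h <- (h * 48271 + as.double(v) + 11) %% 2147483629
  }
  as.integer(h)
}

`%na%` <- function(x, y) if (is.null(x) || all(is.na(x))) y else x
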
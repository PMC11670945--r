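# broom-style tidiers for the fitted objects.

#' @describeIn fit_rank_regression Coefficient table: one row per
#'   (tournament type, term) with estimate, standard error, t statistic,
#'   and two-sided p-value.
#' @param x An `ipd_rank_regression` object.
#' @param ... Unused.
#' @method tidy ipd_rank_regression
#' @export
tidy.ipd_rank_regression <- function(x, ...) {
  purrr::imap(x$models, function(m, type) {
    cf <- summary(m)$coefficients
    tibble::tibble(
      tournament_type = type,
      term = sub("^`|`$", "", rownames(cf)),
      estimate = unname(cf[, "Estimate"]),
      std.error = unname(cf[, "Std. Error"]),
      statistic = unname(cf[, "t value"]),
      p.value = unname(cf[, "Pr(>|t|)"])
    )
  }) |> purrr::list_rbind()
}

#' @describeIn fit_rank_regression Model-level statistics: R-squared,
#'   adjusted R-squared, residual sigma, and the number of rows used.
#' @method glance ipd_rank_regression
#' @export
glance.ipd_rank_regression <- function(x, ...) {
  purrr::imap(x$models, function(m, type) {
    s <- summary(m)
    tibble::tibble(
      tournament_type = type,
      r.squared = s$r.squared,
      adj.r.squared = s$adj.r.squared,
      sigma = s$sigma,
      nobs = length(m$residuals),
      df.residual = m$df.residual
    )
  }) |> purrr::list_rbind()
}

#' @describeIn sse_to_zd Per-state view of the fit: the observed
#'   cooperation vector, its tilde transform, the fitted family member,
#'   and the residual.
#' @param x An `ipd_zd_fit` object.
#' @param ... Unused.
#' @method tidy ipd_zd_fit
#' @export
tidy.ipd_zd_fit <- function(x, ...) {
  fitted <- x$a * x$u - x$b * x$v
  tibble::tibble(
    state = IPD_STATES,
    p = unname(x$p),
    p_tilde = x$p_tilde,
    fitted = fitted,
    residual = x$p_tilde - fitted
  )
}

#' @describeIn sse_to_zd One-row summary: `phi`, `chi`, `sse`,
#'   `sse_clipped`, `constrained`.
#' @method glance ipd_zd_fit
#' @export
glance.ipd_zd_fit <- function(x, ...) {
  tibble::tibble(
    phi = x$phi, chi = x$chi, sse = x$sse,
    sse_clipped = x$sse_clipped, constrained = x$constrained
  )
}
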
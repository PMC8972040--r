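#' Tidy a FRAP recovery fit
#'
#' @param x A `frap_fit` from [fit_recovery()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`Mf`, `b`, `c`) and its
#'   estimate.
#' @export
tidy.frap_fit <- function(x, ...) {
  est <- c(Mf = x$Mf, b = x$b, c = x$c)
  se <- rep(NA_real_, 3)
  if (!is.null(x$fit)) {
    s <- tryCatch(summary(x$fit)$coefficients, error = function(e) NULL)
    if (!is.null(s)) se <- s[c("Mf", "b", "c"), "Std. Error"]
  }
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se))
}

#' One-row summary of a FRAP recovery fit
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `Mf`, `b`, `c`, `t_half`, `residual_rms`,
#'   `converged` and `n`.
#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(Mf = x$Mf, b = x$b, c = x$c, t_half = x$t_half,
                 residual_rms = x$residual_rms, converged = x$converged,
                 n = x$n)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
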
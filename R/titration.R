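# Hill-equation pH titration fitting for side-chain pKa determination.

#' Hill titration model
#'
#' Chemical shift as a function of pH for a single titrating group with
#' cooperativity:
#' `delta(pH) = (delta_a + delta_b * 10^(n * (pKa - pH))) / (1 + 10^(n * (pKa - pH)))`.
#' `delta_b` is the limiting shift reached at low pH and `delta_a` the
#' limiting shift at high pH; at `pH = pKa` the model value is their mean
#' for any Hill coefficient `n`.
#'
#' @param pH pH values (vectorized).
#' @param pKa Midpoint.
#' @param n Hill coefficient (> 0).
#' @param delta_a,delta_b Limiting shifts (ppm) at high / low pH.
#' @return Model chemical shifts (ppm).
#' @export
titration_model <- function(pH, pKa, n, delta_a, delta_b) {
  q <- 10^(n * (pKa - pH))
  (delta_a + delta_b * q) / (1 + q)
}

#' Fit a pH titration curve
#'
#' Nonlinear least-squares fit of [titration_model()] to shift-vs-pH data.
#' Initialization is deterministic: the plateau estimates come from the
#' shifts at the pH extremes (10% quantile positions), and pKa is started
#' from a coarse grid (4-9, step 0.5, plus the data midpoint) with `n = 1`,
#' at each grid point solving the plateaus by linear least squares and
#' keeping the best start.  Standard errors come from the curvature of the
#' sum of squares at the optimum (the fit covariance).
#'
#' @param pH,delta Titration data; at least 5 points spanning >= 1.5 pH
#'   units are required.
#' @param init Optional named list overriding the starting values
#'   (`pKa`, `n`, `delta_a`, `delta_b`).
#' @param noise Optional noise estimate (ppm) used for the degeneracy
#'   check; default is the residual RMS of the fit.
#' @return Object of class `titration_fit`: list with `pKa`, `n`,
#'   `delta_a`, `delta_b`, `se` (named vector), `rms`, `fitted`, `fit`
#'   (the underlying `nls` object).
#' @examples
#' pH <- seq(4.5, 8.5, length.out = 25)
#' d  <- titration_model(pH, 6.16, 0.98, 8.60, 7.70)
#' fit_titration(pH, d)$pKa
#' @export
fit_titration <- function(pH, delta, init = NULL, noise = NULL) {
  stopifnot(length(pH) == length(delta))
  if (length(pH) < 5L) stop("need at least 5 titration points")
  if (diff(range(pH)) < 1.5) stop("pH range must span at least 1.5 units")
  dat <- data.frame(pH = pH, delta = delta)

  if (is.null(init)) {
    lo <- stats::quantile(pH, 0.1); hi <- stats::quantile(pH, 0.9)
    db0 <- mean(delta[pH <= lo]); da0 <- mean(delta[pH >= hi])
    grid <- unique(c(seq(4, 9, by = 0.5), mean(range(pH))))
    best <- NULL
    for (p in grid) {
      q <- 10^(1 * (p - pH))
      # model is linear in (delta_a, delta_b) at fixed (pKa, n)
      X <- cbind(1 / (1 + q), q / (1 + q))
      co <- tryCatch(stats::lm.fit(X, delta)$coefficients, error = function(e) NULL)
      if (is.null(co) || any(!is.finite(co))) next
      ss <- sum((delta - X %*% co)^2)
      if (is.null(best) || ss < best$ss) {
        best <- list(ss = ss, pKa = p, delta_a = co[[1]], delta_b = co[[2]])
      }
    }
    if (is.null(best)) best <- list(pKa = mean(range(pH)), delta_a = da0,
                                    delta_b = db0)
    init <- list(pKa = best$pKa, n = 1, delta_a = best$delta_a,
                 delta_b = best$delta_b)
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      delta ~ titration_model(pH, pKa, n, delta_a, delta_b),
      data = dat, start = init,
      lower = c(pKa = min(pH) - 2, n = 1e-3, delta_a = -Inf, delta_b = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop(sprintf("titration fit did not converge: %s", conditionMessage(fit)))
  }
  co <- stats::coef(fit)
  res <- stats::resid(fit)
  rms <- sqrt(mean(res^2))
  if (is.null(noise)) noise <- rms
  if (abs(co[["delta_a"]] - co[["delta_b"]]) < 3 * noise) {
    stop(sprintf(
      "degenerate titration: plateau separation %.4g ppm < 3 x noise (%.4g ppm)",
      abs(co[["delta_a"]] - co[["delta_b"]]), noise))
  }
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 4))
  structure(
    list(pKa = co[["pKa"]], n = co[["n"]], delta_a = co[["delta_a"]],
         delta_b = co[["delta_b"]], se = se, rms = rms,
         fitted = stats::fitted(fit), fit = fit),
    class = "titration_fit"
  )
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("<titration_fit> pKa = %.3f +/- %.3f, Hill n = %.3f +/- %.3f\n",
              x$pKa, x$se[["pKa"]], x$n, x$se[["n"]]))
  cat(sprintf("  plateaus: %.3f (high pH) / %.3f (low pH) ppm, residual rms %.2g ppm\n",
              x$delta_a, x$delta_b, x$rms))
  invisible(x)
}
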
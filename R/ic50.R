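#' Fit an IC50 from a dose-response series
#'
#' Fits the single-exponential inhibition model
#' `A(c) = A0 * exp(-k * c)` to (inhibitor concentration, activity) pairs
#' by unweighted nonlinear least squares and reports
#' `IC50 = ln(2) / k`, the concentration at which the fitted curve crosses
#' `A0 / 2`. Initial values come from a log-linear regression of the
#' positive activities (exact for noiseless data). A model-free estimate —
#' log-linear interpolation between the two observed points bracketing half
#' the zero-dose activity — is reported alongside as `ic50_interp`.
#'
#' @param concentration Inhibitor concentrations, mM (>= 0, >= 3 distinct).
#' @param activity Non-negative activities (U/g or rate units; the model is
#'   invariant to the overall scale, so residual percentages work too).
#' @return List of class `ic50_fit`: `ic50`, `se_ic50` (delta-method,
#'   `ln2 * se_k / k^2`), `A0`, `k`, `se_A0`, `se_k`, `rss`,
#'   `ic50_interp`, `n`, `converged`.
#' @export
fit_ic50 <- function(concentration, activity) {
  if (length(concentration) != length(activity))
    stop("concentration and activity must have equal length")
  if (any(concentration < 0)) stop("concentrations must be >= 0")
  if (any(activity < 0)) stop("activities must be >= 0")
  ord <- order(concentration)
  conc <- concentration[ord]
  act <- activity[ord]
  if (length(unique(conc)) < 3L)
    stop("need at least 3 distinct inhibitor concentrations")
  if (act[1] < max(act))
    warning("activity at the lowest concentration is not the maximum")

  # log-linear start values; exact for noiseless exponential data
  pos <- act > 0
  if (sum(pos) >= 2L && length(unique(conc[pos])) >= 2L) {
    ll <- stats::lm(log(act[pos]) ~ conc[pos])
    A0_0 <- exp(unname(stats::coef(ll)[1]))
    k_0 <- -unname(stats::coef(ll)[2])
  } else {
    A0_0 <- max(act)
    k_0 <- NA_real_
  }
  if (!is.finite(k_0) || k_0 <= 0) {
    if (stats::var(act) == 0 || k_0 <= 0)
      stop("no inhibition detected: activities do not decay with concentration")
  }

  rss0 <- sum((act - A0_0 * exp(-k_0 * conc))^2)
  if (rss0 <= 1e-18 * max(1, sum(act^2))) {
    # the log-linear start already reproduces the data (noiseless input);
    # Gauss-Newton has nothing to improve and would stall on zero residuals
    fit <- NULL
    A0 <- A0_0; k <- k_0; rss <- rss0
    se <- c(0, 0)
    converged <- TRUE
  } else if (is.null(fit <- tryCatch(
    stats::nls(act ~ A0 * exp(-k * conc),
               start = list(A0 = A0_0, k = k_0),
               control = stats::nls.control(maxiter = 200)),
    error = function(e) NULL))) {
    # Gauss-Newton-hostile data: direct RSS minimization from the same start
    obj <- function(p) sum((act - p[1] * exp(-p[2] * conc))^2)
    op <- stats::optim(c(A0_0, k_0), obj, method = "Nelder-Mead")
    A0 <- op$par[1]; k <- op$par[2]
    rss <- op$value
    se <- c(NA_real_, NA_real_)
    converged <- op$convergence == 0
  } else {
    cf <- stats::coef(fit)
    A0 <- unname(cf["A0"]); k <- unname(cf["k"])
    rss <- sum(stats::resid(fit)^2)
    se <- tryCatch(unname(sqrt(diag(stats::vcov(fit)))),
                   error = function(e) c(NA_real_, NA_real_))
    converged <- fit$convInfo$isConv
  }
  if (!is.finite(k) || k <= 0)
    stop("no inhibition detected: fitted decay constant is not positive")

  ic50 <- log(2) / k
  se_ic50 <- if (is.finite(se[2])) log(2) * se[2] / k^2 else NA_real_

  structure(list(ic50 = ic50, se_ic50 = se_ic50,
                 A0 = A0, k = k, se_A0 = se[1], se_k = se[2],
                 rss = rss,
                 ic50_interp = .ic50_interp(conc, act),
                 n = length(conc), converged = converged),
            class = "ic50_fit")
}

# model-free IC50: log-linear interpolation between the adjacent points
# bracketing half the activity at the lowest concentration
.ic50_interp <- function(conc, act) {
  half <- act[1] / 2
  if (half <= 0) return(NA_real_)
  for (i in seq_len(length(conc) - 1L)) {
    if (act[i] >= half && act[i + 1L] <= half && act[i + 1L] > 0) {
      if (act[i] == act[i + 1L]) return(conc[i])
      f <- (log(act[i]) - log(half)) / (log(act[i]) - log(act[i + 1L]))
      return(conc[i] + f * (conc[i + 1L] - conc[i]))
    }
  }
  NA_real_
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 = %.4g mM (SE %.2g); A0 = %.4g, k = %.4g /mM; n = %d\n",
              x$ic50, x$se_ic50, x$A0, x$k, x$n))
  invisible(x)
}

#' Correlate ln(IC50) with binding (free) energies
#'
#' Ordinary least squares of `ln(IC50)` on the binding energy, the working
#' linear bridge `ln(IC50) ~ a + b * dG_bind` between computed complex
#' stabilities and measured inhibitory potencies.
#'
#' @param ic50 IC50 values, mM (> 0), length >= 3.
#' @param energy Binding energies `dG_bind` (or `dE_bind`), kJ/mol.
#' @return List of class `ic50_correlation`: intercept `a` (ln mM), slope
#'   `b` (per kJ/mol), `r_squared`, `n`, standard errors `se_a`, `se_b`,
#'   and the underlying `lm` fit.
#' @export
correlate_ic50_dg <- function(ic50, energy) {
  if (length(ic50) != length(energy))
    stop("ic50 and energy must have equal length")
  if (length(ic50) < 3L) stop("need at least 3 (IC50, energy) pairs")
  if (any(ic50 <= 0)) stop("all IC50 values must be > 0")
  if (length(unique(energy)) < 2L)
    stop("degenerate energies: all values equal")
  fit <- stats::lm(log(ic50) ~ energy)
  cf <- stats::coef(fit)
  # closed-form R^2 and coefficient errors (stable for noiseless input)
  y <- log(ic50)
  n <- length(y)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  sxx <- sum((energy - mean(energy))^2)
  s2 <- rss / (n - 2)
  structure(list(a = unname(cf[1]), b = unname(cf[2]),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 n = n,
                 se_a = sqrt(s2 * (1 / n + mean(energy)^2 / sxx)),
                 se_b = sqrt(s2 / sxx),
                 fit = fit),
            class = "ic50_correlation")
}

#' @export
print.ic50_correlation <- function(x, ...) {
  cat(sprintf("ln(IC50) = %.4g + %.4g * E;  R^2 = %.3f (n = %d)\n",
              x$a, x$b, x$r_squared, x$n))
  invisible(x)
}
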
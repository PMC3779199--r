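#' Lag-phase progress-curve model for zymogen activation
#'
#' In the coupled continuous assay, nascent mature protease hydrolyses a
#' fluorogenic reporter substrate while the activating protease converts
#' zymogen at a pseudo-first-order rate `k_obs`. Product release then
#' follows
#' `P(t) = v_s * t + (v_i - v_s) * (1 - exp(-k_obs * t)) / k_obs`:
#' an upward-curving trace starting at the initial rate `v_i` (basal
#' activity of the unprocessed zymogen pool) and relaxing to the
#' steady-state rate `v_s` of the fully matured enzyme with rate
#' constant `k_obs`. At `k_obs = 0` the analytic limit `P = v_i * t`
#' is used; as `k_obs -> Inf`, `P -> v_s * t`.
#'
#' @param t Time(s), s (>= 0). Vectorised.
#' @param v_i Initial product-release rate, uM/s.
#' @param v_s Steady-state product-release rate, uM/s.
#' @param k_obs Pseudo-first-order activation rate constant, 1/s (>= 0).
#' @return Product released, uM.
#' @export
progress_value <- function(t, v_i, v_s, k_obs) {
  stopifnot(all(t >= 0), k_obs >= 0)
  if (k_obs == 0) return(v_i * t)
  v_s * t - (v_i - v_s) * expm1(-k_obs * t) / k_obs
}

#' Progress curve container
#'
#' @param time_s Increasing time grid, s.
#' @param product_uM Product released (blank-subtracted), uM; must start
#'   at (or within rounding of) zero.
#' @param substrate_uM,activator_nM,zymogen_nM Assay metadata: reporter
#'   substrate, activating protease and zymogen concentrations.
#' @return Object of class `"progress_curve"` (a data frame).
#' @export
progress_curve <- function(time_s, product_uM, substrate_uM = 10,
                           activator_nM = NA_real_, zymogen_nM = 12.5) {
  stopifnot(length(time_s) == length(product_uM))
  if (any(diff(time_s) <= 0)) stop("time grid must be strictly increasing")
  if (any(product_uM < -1e-9)) stop("product concentrations must be non-negative")
  structure(data.frame(time_s = time_s, product_uM = product_uM),
            substrate_uM = substrate_uM, activator_nM = activator_nM,
            zymogen_nM = zymogen_nM,
            class = c("progress_curve", "data.frame"))
}

#' Fit the activation progress-curve model
#'
#' Levenberg-Marquardt least squares of `(v_i, v_s, k_obs)` in
#' [progress_value]. Start values come from the early slope (`v_i`),
#' the late slope (`v_s`) and the curvature timescale. A fitted
#' `v_s < v_i` is reported with a "no activation detected" warning; a
#' curve much shorter than `3 / k_obs` triggers an identifiability
#' warning.
#'
#' @param curve A [progress_curve].
#' @return Object of class `"progress_fit"`: list with `v_i`, `v_s`,
#'   `k_obs`, `se` (named standard errors), `residual_sd`,
#'   `convergence`.
#' @export
fit_progress <- function(curve) {
  stopifnot(inherits(curve, "progress_curve"))
  d <- data.frame(t = curve$time_s, P = curve$product_uM)
  n <- nrow(d)
  k <- max(3L, ceiling(0.15 * n))
  vi0 <- max(unname(stats::coef(stats::lm(P ~ t, d[seq_len(k), ]))[2]), 1e-8)
  vs0 <- max(unname(stats::coef(stats::lm(P ~ t, d[seq(n - k + 1L, n), ]))[2]), 2e-8)
  k0 <- 3 / max(d$t)                    # curvature on the observation timescale
  fit <- tryCatch(
    minpack.lm::nlsLM(
      P ~ vs * t + (vi - vs) * (1 - exp(-kobs * t)) / kobs, data = d,
      start = list(vi = vi0, vs = vs0, kobs = k0),
      lower = c(vi = 0, vs = 0, kobs = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("progress fit did not converge: ", conditionMessage(fit),
            "; returning start values as best iterate")
    out <- list(v_i = vi0, v_s = vs0, k_obs = k0, se = NULL,
                residual_sd = NA_real_, convergence = FALSE)
    class(out) <- "progress_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  out <- list(v_i = cf[["vi"]], v_s = cf[["vs"]], k_obs = cf[["kobs"]],
              se = c(v_i = unname(se[1]), v_s = unname(se[2]),
                     k_obs = unname(se[3])),
              residual_sd = sqrt(mean(stats::resid(fit)^2)),
              convergence = TRUE)
  class(out) <- "progress_fit"
  if (out$v_s < out$v_i) warning("no activation detected: fitted v_s < v_i")
  if (max(d$t) * out$k_obs < 3)
    warning("curve shorter than ~3/k_obs: k_obs weakly identified")
  out
}

#' @export
print.progress_fit <- function(x, ...) {
  cat(sprintf("<progress_fit> k_obs = %.4g 1/s, v_i = %.3g, v_s = %.3g uM/s\n",
              x$k_obs, x$v_i, x$v_s))
  if (!is.null(x$se))
    cat(sprintf("  se(k_obs) = %.2g; residual sd %.3g uM; converged: %s\n",
                x$se[["k_obs"]], x$residual_sd, x$convergence))
  invisible(x)
}

#' Linear dependence of k_obs on activator concentration
#'
#' Under pseudo-first-order conditions (zymogen far below the Michaelis
#' constant of the activating protease), `k_obs` grows linearly with
#' activator concentration; the slope is the apparent specificity
#' constant of activation and the intercept captures any basal signal.
#' Ordinary least squares with a free intercept.
#'
#' @param activator_uM Activator concentrations, uM (>= 3 values,
#'   ideally including ~0).
#' @param k_obs Fitted rate constants, 1/s.
#' @return List with `slope` (uM^-1 s^-1), `intercept` (1/s), their
#'   standard errors, and the underlying `lm` fit.
#' @export
fit_kobs_linear <- function(activator_uM, k_obs) {
  stopifnot(length(activator_uM) == length(k_obs))
  if (length(activator_uM) < 3) stop("need at least 3 activator concentrations")
  fit <- stats::lm(k_obs ~ activator_uM)
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       se_slope = unname(se[2]), se_intercept = unname(se[1]), fit = fit)
}

#' Fluorogenic-product calibration
#'
#' Linear standard curve mapping raw fluorescence to product
#' concentration, built from >= 2 standards (e.g. 0 to 1.8 uM of the
#' free fluorophore).
#'
#' @param standard_uM Standard concentrations, uM.
#' @param standard_signal Measured signals, a.u.
#' @return Calibration list with `slope` (a.u. per uM) and `intercept`.
#' @export
mca_calibration <- function(standard_uM, standard_signal) {
  stopifnot(length(standard_uM) >= 2,
            length(standard_uM) == length(standard_signal))
  fit <- stats::lm(standard_signal ~ standard_uM)
  slope <- unname(stats::coef(fit)[2])
  if (abs(slope) < .Machine$double.eps^0.5)
    stop("calibration slope is zero: standards do not span a signal range")
  list(slope = slope, intercept = unname(stats::coef(fit)[1]))
}

#' Convert raw fluorescence to product concentration
#'
#' Inverts a [mca_calibration]; small negative results (blank noise)
#' are clipped to zero with a warning.
#'
#' @param signal Raw signal(s), a.u.
#' @param calibration A [mca_calibration] (or any list with `slope`,
#'   `intercept`).
#' @return Concentration(s), uM.
#' @export
fluorescence_to_concentration <- function(signal, calibration) {
  if (abs(calibration$slope) < .Machine$double.eps^0.5)
    stop("zero-slope calibration")
  conc <- (signal - calibration$intercept) / calibration$slope
  if (any(conc < 0)) {
    warning(sprintf("%d negative concentration(s) clipped to 0", sum(conc < 0)))
    conc[conc < 0] <- 0
  }
  conc
}
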
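#' Gas constant, J mol^-1 K^-1
#' @export
gas_constant <- 8.314

#' Fraction of unfolded protein in a two-state transition
#'
#' Van't Hoff two-state model with temperature-independent unfolding
#' enthalpy (Delta Cp = 0): the unfolding free energy is
#' `dG(T) = dHm * (1 - T/Tm)`, the equilibrium constant
#' `K = exp(-dG / (R T))`, and the unfolded fraction `fU = K / (1 + K)`.
#' At `T = Tm` exactly half the protein is unfolded; the transition
#' steepens with `dHm` (width ~ `R Tm^2 / dHm`).
#'
#' @param temp_K Absolute temperature(s), K.
#' @param Tm_K Mid-transition temperature, K.
#' @param dHm Van't Hoff unfolding enthalpy at `Tm`, J/mol.
#' @return Unfolded fraction in `[0, 1]`; vectorised over `temp_K`.
#' @export
fraction_unfolded <- function(temp_K, Tm_K, dHm) {
  stopifnot(all(temp_K > 0), Tm_K > 0)
  dG <- dHm * (1 - temp_K / Tm_K)
  # plogis(x) = 1/(1+exp(-x)) handles extreme arguments without overflow
  stats::plogis(-dG / (gas_constant * temp_K))
}

#' Two-state melting model parameters
#'
#' Bundles the six parameters of the two-state fluorescence melting
#' model: the mid-transition temperature and enthalpy plus the linear
#' native and denatured baselines. Thermal transitions of proDer p 3
#' zymogens are irreversible, so a fitted `Tm` is always reported as
#' *apparent* (`apparent = TRUE`).
#'
#' @param Tm_K Mid-transition temperature, K.
#' @param dHm Unfolding enthalpy at `Tm`, J/mol (> 0 for a transition).
#' @param yN,yU Native/denatured baseline intercepts (signal units at 0 K,
#'   i.e. the intercepts of the linear baselines `yN + p*T`, `yU + q*T`).
#' @param p,q Native/denatured baseline slopes, signal units per K.
#' @param se Optional named numeric vector of standard errors.
#' @param apparent Logical flag; irreversible transitions yield only an
#'   apparent `Tm`.
#' @return Object of class `"two_state_fit"`.
#' @export
two_state_fit <- function(Tm_K, dHm, yN, yU, p = 0, q = 0, se = NULL,
                          apparent = TRUE) {
  structure(list(Tm_K = Tm_K, dHm = dHm, yN = yN, yU = yU, p = p, q = q,
                 se = se, apparent = apparent),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("<two_state_fit> %sTm = %.2f K (%.2f C), dHm = %.1f kJ/mol\n",
              if (isTRUE(x$apparent)) "apparent " else "",
              x$Tm_K, x$Tm_K - 273.15, x$dHm / 1000))
  cat(sprintf("  baselines: native %.3g + %.3g*T, denatured %.3g + %.3g*T\n",
              x$yN, x$p, x$yU, x$q))
  if (!is.null(x$se) && "Tm_K" %in% names(x$se))
    cat(sprintf("  se(Tm) = %.3f K\n", x$se[["Tm_K"]]))
  if (!is.null(x$convergence))
    cat(sprintf("  converged: %s, residual sd %.3g\n",
                x$convergence, x$residual_sd))
  invisible(x)
}

#' Observed fluorescence signal of the two-state melting model
#'
#' `y(T) = (yN + p*T) * (1 - fU) + (yU + q*T) * fU` with `fU` from
#' [fraction_unfolded]: a linear native baseline, a linear denatured
#' baseline, and a sigmoidal hand-over between them centred at `Tm`.
#'
#' @param temp_K Temperature(s), K.
#' @param fit A [two_state_fit] (truth or fitted parameters).
#' @return Model signal; vectorised over `temp_K`.
#' @export
two_state_signal <- function(temp_K, fit) {
  stopifnot(inherits(fit, "two_state_fit"))
  fU <- fraction_unfolded(temp_K, fit$Tm_K, fit$dHm)
  (fit$yN + fit$p * temp_K) * (1 - fU) + (fit$yU + fit$q * temp_K) * fU
}

#' Melting curve container
#'
#' @param temperature_C Strictly increasing temperature grid, degrees C.
#' @param signal Fluorescence signal (arbitrary units).
#' @param scan_rate_C_min Scan rate metadata (default 0.5 C/min).
#' @param read_interval_s Read interval metadata (default 30 s).
#' @return Object of class `"melting_curve"`: data frame with columns
#'   `temperature_C`, `temperature_K`, `signal`.
#' @export
melting_curve <- function(temperature_C, signal, scan_rate_C_min = 0.5,
                          read_interval_s = 30) {
  stopifnot(length(temperature_C) == length(signal),
            length(temperature_C) >= 20)
  if (any(diff(temperature_C) <= 0))
    stop("temperatures must be strictly increasing")
  structure(data.frame(temperature_C = temperature_C,
                       temperature_K = temperature_C + 273.15,
                       signal = signal),
            scan_rate_C_min = scan_rate_C_min,
            read_interval_s = read_interval_s,
            class = c("melting_curve", "data.frame"))
}

#' Read a melting curve from CSV
#'
#' Expects columns `temperature_C` and `signal`.
#' @param path CSV file path.
#' @param ... Passed to [melting_curve].
#' @return A [melting_curve].
#' @export
read_melting_curve <- function(path, ...) {
  d <- utils::read.csv(path)
  stopifnot(all(c("temperature_C", "signal") %in% names(d)))
  melting_curve(d$temperature_C, d$signal, ...)
}

#' Initial parameter guess for a melting fit
#'
#' `Tm` is placed at the maximum absolute smoothed derivative of the
#' signal; baselines come from linear fits to the first and last 10% of
#' points; `dHm` defaults to 300 kJ/mol, a typical unfolding enthalpy
#' for a ~25 kDa globular protein. A curve with no discernible
#' transition (the baseline-corrected amplitude does not exceed the
#' baseline scatter) is rejected.
#'
#' @param curve A [melting_curve].
#' @param dHm_guess Starting enthalpy, J/mol.
#' @return A [two_state_fit] start value; attribute `edge_warning` is
#'   `TRUE` when the detected transition sits within the outer 5% of the
#'   scan range.
#' @export
init_guess_melting <- function(curve, dHm_guess = 3e5) {
  stopifnot(inherits(curve, "melting_curve"), nrow(curve) >= 20)
  TK <- curve$temperature_K; y <- curve$signal
  n <- length(TK)
  k <- max(3L, ceiling(0.1 * n))
  lo <- seq_len(k); hi <- seq(n - k + 1L, n)
  fitN <- stats::lm(y ~ TK, data = data.frame(TK = TK[lo], y = y[lo]))
  fitU <- stats::lm(y ~ TK, data = data.frame(TK = TK[hi], y = y[hi]))
  yN <- unname(stats::coef(fitN)[1]); p <- unname(stats::coef(fitN)[2])
  yU <- unname(stats::coef(fitU)[1]); q <- unname(stats::coef(fitU)[2])

  # transition must rise above the baseline scatter to be fittable
  gap_mid <- abs((yU + q * stats::median(TK)) - (yN + p * stats::median(TK)))
  scatter <- max(stats::sd(stats::resid(fitN)), stats::sd(stats::resid(fitU)), 1e-12)
  if (gap_mid < 5 * scatter)
    stop("no transition detected: baseline gap below baseline scatter")

  sm <- as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))
  interior <- which(!is.na(sm))
  dy <- diff(sm[interior]) / diff(TK[interior])
  i <- interior[which.max(abs(dy))]
  Tm0 <- (TK[i] + TK[i + 1]) / 2
  edge <- Tm0 < stats::quantile(TK, 0.05) || Tm0 > stats::quantile(TK, 0.95)
  if (edge) {
    warning("transition detected at the edge of the scan range")
    Tm0 <- min(max(Tm0, TK[2]), TK[n - 1])
  }
  out <- two_state_fit(Tm_K = Tm0, dHm = dHm_guess, yN = yN, yU = yU,
                       p = p, q = q)
  attr(out, "edge_warning") <- edge
  out
}

#' Fit the two-state melting model to a curve
#'
#' Levenberg-Marquardt least squares of all six parameters
#' (`Tm`, `dHm`, two baseline intercepts, two slopes) of
#' [two_state_signal] against the observed signal. The transitions this
#' model is applied to are irreversible, so the fitted `Tm` is an
#' apparent melting temperature.
#'
#' @param curve A [melting_curve].
#' @param init Optional [two_state_fit] start; defaults to
#'   [init_guess_melting].
#' @return A [two_state_fit] with standard errors (`$se`), convergence
#'   flag (`$convergence`), residual sd (`$residual_sd`), and
#'   `$Tm_C` for reporting. Warns when the fitted `Tm` leaves the
#'   scanned range.
#' @export
fit_melting <- function(curve, init = NULL) {
  stopifnot(inherits(curve, "melting_curve"))
  if (is.null(init)) init <- init_guess_melting(curve)
  d <- data.frame(TK = curve$temperature_K, y = curve$signal)
  start <- list(Tm = init$Tm_K, dHm = init$dHm, yN = init$yN, yU = init$yU,
                p = init$p, q = init$q)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ two_state_signal(TK, two_state_fit(Tm, dHm, yN, yU, p, q)),
                      data = d, start = start,
                      lower = c(Tm = min(d$TK) - 20, dHm = 1e3,
                                yN = -Inf, yU = -Inf, p = -Inf, q = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- init
    out$convergence <- FALSE
    out$residual_sd <- NA_real_
    warning("melting fit did not converge: ", conditionMessage(fit),
            "; returning the initial guess as best iterate")
    return(out)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 6))
  out <- two_state_fit(Tm_K = cf[["Tm"]], dHm = cf[["dHm"]], yN = cf[["yN"]],
                       yU = cf[["yU"]], p = cf[["p"]], q = cf[["q"]],
                       se = c(Tm_K = unname(se[1]), dHm = unname(se[2])),
                       apparent = TRUE)
  out$convergence <- TRUE
  out$residual_sd <- sqrt(mean(stats::resid(fit)^2))
  out$Tm_C <- out$Tm_K - 273.15
  if (out$Tm_K < min(d$TK) || out$Tm_K > max(d$TK)) {
    out$in_range <- FALSE
    warning("fitted Tm lies outside the scanned temperature range")
  } else out$in_range <- TRUE
  out
}
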
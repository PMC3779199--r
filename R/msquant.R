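#' Time-stamped centroided spectrum series
#'
#' Long-format container for a quenched-flow ESI-MS run: one row per
#' centroid, columns `scan_time_s`, `mz`, `intensity`. Scan times must
#' be non-decreasing row-wise and strictly increasing across scans;
#' intensities non-negative. The full scan-time grid (including scans
#' in which a given species has no centroid) is kept as an attribute so
#' extracted-ion traces are defined on every scan.
#'
#' @param scan_time_s,mz,intensity Equal-length vectors (s, Th, counts).
#' @param scan_times Optional full grid of scan times; defaults to the
#'   unique times present.
#' @return Object of class `"spectrum_series"` (a data frame).
#' @export
spectrum_series <- function(scan_time_s, mz, intensity, scan_times = NULL) {
  stopifnot(length(scan_time_s) == length(mz),
            length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (is.null(scan_times)) scan_times <- sort(unique(scan_time_s))
  if (any(diff(scan_times) <= 0)) stop("scan times must be strictly increasing")
  structure(data.frame(scan_time_s = scan_time_s, mz = mz,
                       intensity = intensity),
            scan_times = scan_times,
            class = c("spectrum_series", "data.frame"))
}

#' Read / write a spectrum series as long-format CSV
#'
#' Columns `scan_time_s`, `mz`, `intensity`.
#' @param path CSV file path.
#' @return A [spectrum_series] (for the reader); `path` invisibly (writer).
#' @export
read_spectrum_series <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("scan_time_s", "mz", "intensity") %in% names(d)))
  spectrum_series(d$scan_time_s, d$mz, d$intensity)
}

#' @rdname read_spectrum_series
#' @param series A [spectrum_series].
#' @export
write_spectrum_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Extracted-ion current (XIC) for one m/z target
#'
#' Per scan, sums the intensities of all centroids within
#' `[target - tol, target + tol]`; scans with no centroid in the window
#' contribute 0. This is the intensity-vs-time trace on which all
#' downstream quantification operates.
#'
#' @param series A [spectrum_series].
#' @param target Target m/z, Th.
#' @param tol Half-width of the matching window, Th (> 0); default 0.5,
#'   matching integer-rounded charge-state reports.
#' @return Data frame with `time_s` (every scan) and `intensity`.
#' @export
extract_xic <- function(series, target, tol = 0.5) {
  stopifnot(inherits(series, "spectrum_series"), tol > 0)
  times <- attr(series, "scan_times")
  sel <- series$mz >= target - tol & series$mz <= target + tol
  hit <- series[sel, , drop = FALSE]
  s <- vapply(split(hit$intensity, factor(hit$scan_time_s, levels = times)),
              sum, numeric(1))
  data.frame(time_s = times, intensity = unname(s))
}

#' Normalize an extracted-ion trace to the internal standard
#'
#' Pointwise ratio `I_t = I_o / I_std`: the raw intensity of one charge
#' state divided by the internal standard's intensity in the same scan.
#' Because every centroid in a scan shares that scan's ionization
#' efficiency, the ratio cancels spray fluctuation and slow drift —
#' the purpose of spiking a constant-concentration standard. Scans
#' where the standard's intensity is zero are marked missing (`NA`),
#' never zero.
#'
#' @param raw XIC data frame (`time_s`, `intensity`) of the analyte.
#' @param standard XIC data frame of the internal standard, on the same
#'   scan grid.
#' @return Data frame with `time_s` and dimensionless `I_t`.
#' @export
normalize_to_standard <- function(raw, standard) {
  if (!isTRUE(all.equal(raw$time_s, standard$time_s)))
    stop("analyte and standard traces must share the same scan grid")
  I_t <- ifelse(standard$intensity > 0, raw$intensity / standard$intensity,
                NA_real_)
  data.frame(time_s = raw$time_s, I_t = I_t)
}

#' Concentration time course from normalized intensities
#'
#' `C_t = C_0 * sum_I(t) / I_0`, where `sum_I(t)` sums the normalized
#' intensities of the species' charge states at time t and `I_0` is the
#' initial normalized intensity of the zymogen pool (for constructs
#' starting as mixtures of truncated forms, the sum over those forms'
#' initial intensities). Assumes equal ionization response across
#' species.
#'
#' @param sum_I Summed normalized intensity trace (vector, one value per
#'   scan; `NA` allowed for dropped scans).
#' @param time_s Scan times, s.
#' @param C_0 Initial zymogen-pool concentration, uM.
#' @param I_0 Initial normalized zymogen-pool intensity (> 0).
#' @return Data frame `time_s`, `conc_uM`.
#' @export
species_concentration <- function(sum_I, time_s, C_0, I_0) {
  if (!is.finite(I_0) || I_0 <= 0) stop("I_0 must be positive")
  data.frame(time_s = time_s, conc_uM = C_0 * sum_I / I_0)
}

#' Build species concentration time courses from a spectrum series
#'
#' Full quantification chain: extracted-ion currents for every declared
#' (species, charge) target, per-scan normalization to the internal
#' standard, per-species summation over charge states, and conversion
#' to concentrations against the initial zymogen-pool intensity.
#'
#' Scans in which the internal standard is absent are dropped from all
#' courses (reported via the `dropped_scans` attribute). Pairs of m/z
#' targets closer than `2 * tol` are flagged ambiguous on both species.
#'
#' @param series A [spectrum_series].
#' @param assignments List of [proteoform] objects with declared masses
#'   and charge states; exactly one must have role
#'   `"internal_standard"`, and at least one a zymogen role
#'   (`"zymogen"` / `"truncated_zymogen"`) to anchor `I_0`.
#' @param C_0 Initial total zymogen concentration, uM (default 16).
#' @param tol m/z matching half-window, Th (default 0.5).
#' @param i0_scans Number of leading scans used to anchor the initial
#'   zymogen-pool intensity `I_0`. With the default (20, one minute at
#'   3-s scans) `I_0` is the t = 0 extrapolation of a local quadratic
#'   fit to the pool intensity, which averages down the shot-to-shot
#'   noise a single scan would imprint on every concentration; with
#'   `i0_scans = 1` it is exactly the first scan's summed normalized
#'   intensity.
#' @return Object of class `"species_time_courses"`: data frame with
#'   `time_s` and one concentration column (uM) per non-standard
#'   species id, plus attributes `I_0`, `dropped_scans`, `roles`,
#'   `ambiguous` (character vector of flagged species ids).
#' @export
build_time_courses <- function(series, assignments, C_0 = 16, tol = 0.5,
                               i0_scans = 20L) {
  stopifnot(inherits(series, "spectrum_series"))
  if (nrow(series) == 0) {
    warning("empty spectrum series: returning empty courses")
    return(structure(data.frame(time_s = numeric(0)), I_0 = NA_real_,
                     dropped_scans = 0L, roles = character(0),
                     ambiguous = character(0),
                     class = c("species_time_courses", "data.frame")))
  }
  roles <- vapply(assignments, function(a) a$role, character(1))
  ids <- vapply(assignments, function(a) a$id, character(1))
  std_i <- which(roles == "internal_standard")
  if (length(std_i) != 1)
    stop("assignments must contain exactly one internal standard")
  # ambiguity screen over all declared targets
  targets <- do.call(rbind, lapply(assignments, function(a)
    data.frame(id = a$id, mz = unname(envelope_mz(a)))))
  amb <- character(0)
  if (nrow(targets) > 1) {
    dmat <- abs(outer(targets$mz, targets$mz, "-"))
    close <- which(dmat < 2 * tol & upper.tri(dmat), arr.ind = TRUE)
    if (nrow(close)) {
      amb <- unique(c(targets$id[close[, 1]], targets$id[close[, 2]]))
      warning("overlapping m/z targets within 2*tol for: ",
              paste(amb, collapse = ", "))
    }
  }
  std_xic <- extract_xic(series, envelope_mz(assignments[[std_i]])[1], tol)
  keep <- std_xic$intensity > 0
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("dropping %d scan(s) with no internal-standard signal",
                    n_drop))
  times <- std_xic$time_s[keep]
  sumI <- matrix(0, nrow = length(times), ncol = length(assignments),
                 dimnames = list(NULL, ids))
  for (j in seq_along(assignments)) {
    if (j == std_i) next
    for (mz_t in envelope_mz(assignments[[j]])) {
      xic <- extract_xic(series, mz_t, tol)
      nrm <- normalize_to_standard(xic, std_xic)
      sumI[, j] <- sumI[, j] + nrm$I_t[keep]
    }
  }
  zym <- which(roles %in% c("zymogen", "truncated_zymogen"))
  if (!length(zym)) stop("no zymogen-pool species among the assignments")
  pool <- rowSums(sumI[, zym, drop = FALSE])
  k <- min(max(as.integer(i0_scans), 1L), length(pool))
  if (k >= 4L) {
    tt <- times[seq_len(k)] - times[1]
    I_0 <- unname(stats::coef(
      stats::lm(pool[seq_len(k)] ~ tt + I(tt^2)))[1])
  } else {
    I_0 <- pool[1]
  }
  if (!is.finite(I_0) || I_0 <= 0)
    stop("initial zymogen-pool intensity is not positive; cannot anchor Eq.-style concentration scale")
  out <- data.frame(time_s = times)
  for (j in seq_along(assignments)) {
    if (j == std_i) next
    out[[ids[j]]] <- C_0 * sumI[, j] / I_0
  }
  structure(out, I_0 = I_0, dropped_scans = n_drop,
            roles = stats::setNames(roles[-std_i], ids[-std_i]),
            ambiguous = amb,
            class = c("species_time_courses", "data.frame"))
}

#' Total zymogen-pool course from reconstructed species courses
#'
#' @param courses A `"species_time_courses"` object.
#' @return Data frame `time_s`, `zymogen_uM` (sum over zymogen-role
#'   species).
#' @export
zymogen_pool_course <- function(courses) {
  roles <- attr(courses, "roles")
  zcols <- names(roles)[roles %in% c("zymogen", "truncated_zymogen")]
  if (!length(zcols)) stop("no zymogen-role species in the courses")
  data.frame(time_s = courses$time_s,
             zymogen_uM = rowSums(as.data.frame(courses)[, zcols, drop = FALSE]))
}

#' Estimate activation kinetics from reconstructed MS time courses
#'
#' Fits the Michaelis-Menten depletion model ([fit_mm_depletion]) to the
#' reconstructed zymogen-pool decay and reports `K_m` and `k_cat/K_m`
#' with approximate confidence intervals; wide intervals are reported as
#' ranges rather than point values.
#'
#' @param courses A `"species_time_courses"` object from
#'   [build_time_courses].
#' @param E1 Activator concentration, uM.
#' @param Z0 Initial zymogen concentration, uM.
#' @return As [fit_mm_depletion].
#' @export
estimate_activation_kinetics <- function(courses, E1, Z0 = 16) {
  zc <- zymogen_pool_course(courses)
  ok <- is.finite(zc$zymogen_uM)
  fit_mm_depletion(zc$time_s[ok], zc$zymogen_uM[ok], E1 = E1, Z0 = Z0)
}

#' Write species time courses to CSV
#'
#' @param courses A `"species_time_courses"` object.
#' @param path Output CSV path.
#' @export
write_time_courses <- function(courses, path) {
  utils::write.csv(as.data.frame(courses), path, row.names = FALSE)
  invisible(path)
}
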
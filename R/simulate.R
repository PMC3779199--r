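#' Simulate a fluorescence melting curve
#'
#' Evaluates the two-state forward model [two_state_signal] on a linear
#' temperature grid (default 20-70 degrees C read every 0.25 degrees,
#' i.e. a 0.5 C/min ramp read every 30 s: 201 points) and adds relative
#' Gaussian noise. Deterministic for a fixed seed.
#'
#' @param truth A [two_state_fit] holding the generating parameters
#'   (`Tm_K` in kelvin).
#' @param from_C,to_C,step_C Scan grid, degrees C.
#' @param noise_rel Relative Gaussian noise sd on the signal
#'   (default 0.005, i.e. 0.5%).
#' @param seed Integer seed.
#' @return A [melting_curve].
#' @export
simulate_melting_curve <- function(truth, from_C = 20, to_C = 70,
                                   step_C = 0.25, noise_rel = 0.005,
                                   seed = 1L) {
  stopifnot(inherits(truth, "two_state_fit"), noise_rel >= 0)
  set.seed(seed)
  tc <- seq(from_C, to_C, by = step_C)
  y <- two_state_signal(tc + 273.15, truth)
  if (noise_rel > 0) y <- y * (1 + stats::rnorm(length(y), 0, noise_rel))
  melting_curve(tc, y)
}

#' Simulate an activation progress curve
#'
#' Evaluates the lag progress model [progress_value] on a regular time
#' grid (default 30 min sampled every 5 s) and applies relative
#' Gaussian noise. Deterministic for a fixed seed.
#'
#' @param v_i,v_s,k_obs Generating parameters (uM/s, uM/s, 1/s).
#' @param duration_s,sampling_s Time grid, s.
#' @param noise_rel Relative Gaussian noise sd (default 0.01).
#' @param seed Integer seed.
#' @param ... Metadata passed to [progress_curve].
#' @return A [progress_curve].
#' @export
simulate_progress_curve <- function(v_i, v_s, k_obs, duration_s = 1800,
                                    sampling_s = 5, noise_rel = 0.01,
                                    seed = 1L, ...) {
  stopifnot(noise_rel >= 0)
  set.seed(seed)
  t <- seq(0, duration_s, by = sampling_s)
  P <- progress_value(t, v_i, v_s, k_obs)
  if (noise_rel > 0) P <- pmax(P * (1 + stats::rnorm(length(P), 0, noise_rel)), 0)
  progress_curve(t, P, ...)
}

#' Quenched-flow MS simulation scenario
#'
#' Bundles everything needed to emulate a continuous quenched-flow
#' electrospray run: the reaction kinetics (either a saturable
#' [mm_activation_params] single-zymogen depletion or a
#' [species_network] of truncated forms), the proteoforms observed and
#' their charge-state envelopes, the internal standard, and the
#' instrument model.
#'
#' The noise model has three parts, chosen to mirror what an internal
#' standard can and cannot correct: (i) a per-scan multiplicative
#' ionization fluctuation shared by every centroid in the scan
#' (`sigma_scan`, default 0.02 — the dominant electrospray instability,
#' cancelled exactly by normalization); (ii) small independent
#' per-centroid detector noise (`sigma_centroid`, default 0.003), which
#' normalization cannot remove; and (iii) Gaussian m/z jitter
#' (`mz_jitter_Th`, default 0.05 Th) so tolerance matching is
#' exercised. `drift` adds a slow linear ionization drift (total
#' fractional change over the run) on top, also shared with the
#' standard.
#'
#' @param kinetics A [mm_activation_params] or [species_network].
#' @param species Named list of [proteoform]s. For MM kinetics, must
#'   contain one proteoform each with roles `"zymogen"`, `"mature"`,
#'   `"propeptide"`; for a network, ids must match the network's species
#'   ids, plus `"mature"`/`"propeptide"` roles.
#' @param standard Internal-standard [proteoform] (default leucine
#'   enkephalin, YGGFL).
#' @param standard_uM Internal-standard concentration (default 1.8 uM).
#' @param Z0 Initial total zymogen concentration, uM (default 16; for MM
#'   kinetics taken from the params object).
#' @param envelopes Optional named list of per-species charge-envelope
#'   weight vectors (must sum to 1); default uniform over declared
#'   charges.
#' @param responses Optional named numeric vector of per-species
#'   ionization response factors (default 1 for all, the equal-response
#'   assumption of the quantification model).
#' @param scan_interval_s Scan period, s (default 3, i.e. 20 scans/min).
#' @param duration_s Run length, s (default 2400, i.e. 40 min).
#' @param sigma_scan,sigma_centroid,mz_jitter_Th,drift Noise model, see
#'   above.
#' @param dead_time_s Mixing dead time: reaction time = scan time +
#'   dead time (default 0).
#' @return Object of class `"qfms_scenario"`.
#' @export
qfms_scenario <- function(kinetics, species,
                          standard = proteoform("leu-enkephalin",
                                                sequence = "YGGFL",
                                                role = "internal_standard",
                                                charge_states = 1L),
                          standard_uM = 1.8, Z0 = 16,
                          envelopes = NULL, responses = NULL,
                          scan_interval_s = 3, duration_s = 2400,
                          sigma_scan = 0.02, sigma_centroid = 0.003,
                          mz_jitter_Th = 0.05, drift = 0,
                          dead_time_s = 0) {
  stopifnot(inherits(kinetics, "mm_activation_params") ||
              inherits(kinetics, "species_network"),
            sigma_scan >= 0, sigma_centroid >= 0, mz_jitter_Th >= 0,
            standard_uM > 0, scan_interval_s > 0, duration_s > 0)
  ids <- vapply(species, function(p) p$id, character(1))
  names(species) <- ids
  if (inherits(kinetics, "mm_activation_params")) Z0 <- kinetics$Z0
  roles <- vapply(species, function(p) p$role, character(1))
  if (inherits(kinetics, "mm_activation_params")) {
    need <- c("zymogen", "mature", "propeptide")
    if (!all(need %in% roles))
      stop("MM kinetics needs proteoforms with roles zymogen, mature, propeptide")
  } else {
    if (!all(kinetics$ids %in% ids))
      stop("network species ids missing from the proteoform list")
  }
  if (is.null(envelopes)) {
    envelopes <- lapply(species, function(p) {
      w <- rep(1 / length(p$charge_states), length(p$charge_states))
      stats::setNames(w, paste0(p$charge_states, "+"))
    })
  }
  for (id in ids) {
    w <- envelopes[[id]]
    if (is.null(w) || abs(sum(w) - 1) > 1e-9 || any(w < 0) ||
        length(w) != length(species[[id]]$charge_states))
      stop(sprintf("malformed envelope weights for species '%s'", id))
  }
  if (is.null(responses)) responses <- stats::setNames(rep(1, length(ids)), ids)
  stopifnot(all(responses > 0))
  structure(list(kinetics = kinetics, species = species, standard = standard,
                 standard_uM = standard_uM, Z0 = Z0, envelopes = envelopes,
                 responses = responses, scan_interval_s = scan_interval_s,
                 duration_s = duration_s, sigma_scan = sigma_scan,
                 sigma_centroid = sigma_centroid, mz_jitter_Th = mz_jitter_Th,
                 drift = drift, dead_time_s = dead_time_s),
            class = "qfms_scenario")
}

#' Default wild-type quenched-flow scenario
#'
#' Saturable Michaelis-Menten depletion of 16 uM zymogen by 0.16 uM
#' activator, observed through the reference proteoforms
#' ([reference_proteoforms]): zymogen 26354 Da (10-12+), mature
#' 24987 Da (9-12+), propeptide 1385 Da (1-2+), leucine-enkephalin
#' standard. `k_cat` defaults to 0.1 1/s so that, with `K_m` = 4.5 uM,
#' depletion completes within the 40-min run.
#'
#' @param K_m,k_cat,E1,Z0 Kinetic ground truth.
#' @param ... Passed to [qfms_scenario].
#' @return A `"qfms_scenario"`.
#' @export
qfms_scenario_wildtype <- function(K_m = 4.5, k_cat = 0.1, E1 = 0.16,
                                   Z0 = 16, ...) {
  ref <- reference_proteoforms()
  qfms_scenario(mm_activation_params(K_m, k_cat, E1 = E1, Z0 = Z0),
                species = ref[c("zymogen", "mature", "propeptide")],
                standard = ref$standard, ...)
}

# ground-truth concentration columns per species id, on the reaction clock
qfms_truth_courses <- function(scenario, t_reaction) {
  k <- scenario$kinetics
  ids <- names(scenario$species)
  roles <- vapply(scenario$species, function(p) p$role, character(1))
  truth <- data.frame(time_s = t_reaction)
  if (inherits(k, "mm_activation_params")) {
    dep <- mm_depletion(k, pmax(t_reaction, 0), method = "closed_form")
    truth[[ids[roles == "zymogen"]]] <- dep$zymogen_uM
    truth[[ids[roles == "mature"]]] <- dep$mature_uM
    truth[[ids[roles == "propeptide"]]] <- dep$propeptide_uM
  } else {
    net <- simulate_species_network(k, E1 = attr(scenario, "E1_network"),
                                    t_grid = t_reaction, Z0 = scenario$Z0)
    for (id in k$ids) truth[[id]] <- net[[id]]
    if ("mature" %in% roles)
      truth[[ids[roles == "mature"]]] <- net$mature_uM
    if ("propeptide" %in% roles)
      truth[[ids[roles == "propeptide"]]] <- net$propeptide_uM
  }
  truth
}

#' Simulate a quenched-flow ESI-MS spectrum series
#'
#' Integrates the scenario's kinetics, then per scan emits one centroid
#' per (species, charge state) at `mz_of(mass, z)` (+ jitter) with
#' intensity proportional to concentration x response x envelope
#' weight, modulated by the shared per-scan ionization factor, plus the
#' constant internal-standard centroid. Centroids with zero intensity
#' are not emitted (a centroided spectrum has no entry for an absent
#' species). Returns both the spectra and the exact concentration
#' courses used, so reconstruction can be validated against truth.
#'
#' @param scenario A [qfms_scenario].
#' @param seed Integer seed; the series is a pure function of
#'   (scenario, seed).
#' @param E1_network Activator concentration used when the scenario's
#'   kinetics is a [species_network] (ignored for MM kinetics).
#' @return List with `series` (a [spectrum_series]), `truth` (data
#'   frame of exact concentrations per species), and `scenario`.
#' @export
simulate_qfms_series <- function(scenario, seed = 1L, E1_network = 0.16) {
  stopifnot(inherits(scenario, "qfms_scenario"))
  set.seed(seed)
  attr(scenario, "E1_network") <- E1_network
  t_scan <- seq(0, scenario$duration_s, by = scenario$scan_interval_s)
  truth <- qfms_truth_courses(scenario, t_scan + scenario$dead_time_s)
  truth$time_s <- t_scan
  base <- 1000                                   # counts per uM at response 1
  nscan <- length(t_scan)
  g_drift <- 1 + scenario$drift * t_scan / max(scenario$duration_s, 1)
  g_scan <- g_drift * pmax(1 + stats::rnorm(nscan, 0, scenario$sigma_scan), 0)

  rows_t <- list(); rows_m <- list(); rows_i <- list(); r <- 0L
  emit <- function(conc_vec, mz0, weight, response) {
    inten <- conc_vec * response * weight * base * g_scan
    if (scenario$sigma_centroid > 0)
      inten <- inten * (1 + stats::rnorm(nscan, 0, scenario$sigma_centroid))
    inten <- pmax(inten, 0)
    mz <- rep(mz0, nscan)
    if (scenario$mz_jitter_Th > 0)
      mz <- mz + stats::rnorm(nscan, 0, scenario$mz_jitter_Th)
    keep <- inten > 0
    r <<- r + 1L
    rows_t[[r]] <<- t_scan[keep]; rows_m[[r]] <<- mz[keep]
    rows_i[[r]] <<- inten[keep]
  }
  for (id in names(scenario$species)) {
    p <- scenario$species[[id]]
    w <- scenario$envelopes[[id]]
    for (ci in seq_along(p$charge_states)) {
      emit(truth[[id]], mz_of(p$neutral_mass, p$charge_states[ci]),
           w[ci], scenario$responses[[id]])
    }
  }
  emit(rep(scenario$standard_uM, nscan),
       mz_of(scenario$standard$neutral_mass, scenario$standard$charge_states[1]),
       1, 1)
  st <- unlist(rows_t); o <- order(st)
  series <- spectrum_series(st[o], unlist(rows_m)[o], unlist(rows_i)[o],
                            scan_times = t_scan)
  list(series = series, truth = truth, scenario = scenario)
}
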
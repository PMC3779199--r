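# tiny hand-built series: two species + standard over three scans
tiny_series <- function() {
  spectrum_series(
    scan_time_s = c(0, 0, 0, 3, 3, 3, 6, 6),
    mz = c(2197.2, 2499.7, 556.6, 2197.3, 2499.6, 556.7, 2499.7, 556.6),
    intensity = c(100, 50, 10, 80, 70, 10, 120, 20))
}

test_that("XIC sums centroids inside the window and is 0 outside", {
  s <- tiny_series()
  x <- extract_xic(s, 2197.2, tol = 0.5)
  expect_equal(x$time_s, c(0, 3, 6))
  expect_equal(x$intensity, c(100, 80, 0))
  x2 <- extract_xic(s, 900, tol = 0.5)
  expect_equal(x2$intensity, c(0, 0, 0))
  # two centroids in one window are summed
  s2 <- spectrum_series(c(0, 0), c(1000.1, 1000.3), c(5, 7))
  expect_equal(extract_xic(s2, 1000.2, 0.5)$intensity, 12)
  expect_error(extract_xic(s, 1000, tol = 0), "tol > 0")
})

test_that("normalization is a pointwise ratio, NA where the standard is absent", {
  raw <- data.frame(time_s = c(0, 3, 6), intensity = c(10, 20, 30))
  std <- data.frame(time_s = c(0, 3, 6), intensity = c(10, 0, 15))
  n <- normalize_to_standard(raw, std)
  expect_equal(n$I_t, c(1, NA, 2))
  # trace equal to the standard gives the constant 1
  n1 <- normalize_to_standard(std, std)
  expect_equal(n1$I_t[c(1, 3)], c(1, 1))
  # doubling both leaves the ratio unchanged
  raw2 <- raw; raw2$intensity <- raw2$intensity * 2
  std2 <- std; std2$intensity <- std2$intensity * 2
  expect_equal(normalize_to_standard(raw2, std2)$I_t, n$I_t)
  expect_error(normalize_to_standard(raw, std[1:2, ]), "same scan grid")
})

test_that("species_concentration applies the C0 * sumI / I0 scale", {
  sc <- species_concentration(c(2, 1, 0), c(0, 3, 6), C_0 = 16, I_0 = 2)
  expect_equal(sc$conc_uM, c(16, 8, 0))
  expect_error(species_concentration(1, 0, 16, 0), "positive")
})

test_that("normalization cancels a global ionization drift", {
  sc <- qfms_scenario_wildtype(sigma_scan = 0, sigma_centroid = 0,
                               mz_jitter_Th = 0, drift = 0.2,
                               duration_s = 600)
  sim <- simulate_qfms_series(sc, seed = 4)
  tc <- build_time_courses(sim$series, unname(reference_proteoforms()),
                           i0_scans = 1)
  # drift multiplies analyte and standard alike: reconstruction is exact
  expect_equal(tc$proDerp3, sim$truth$proDerp3, tolerance = 1e-9)
  expect_equal(tc$Derp3, sim$truth$Derp3, tolerance = 1e-9)
})

test_that("noise-free simulation round-trips to machine precision", {
  sc <- qfms_scenario_wildtype(sigma_scan = 0, sigma_centroid = 0,
                               mz_jitter_Th = 0, duration_s = 600)
  sim <- simulate_qfms_series(sc, seed = 1)
  # pointwise first-scan anchor: round trip is exact to machine precision
  tc <- build_time_courses(sim$series, unname(reference_proteoforms()),
                           i0_scans = 1)
  for (id in c("proDerp3", "Derp3", "propeptide"))
    expect_equal(tc[[id]], sim$truth[[id]], tolerance = 1e-12)
  # default windowed anchor agrees up to its extrapolation error
  tcw <- build_time_courses(sim$series, unname(reference_proteoforms()))
  expect_equal(tcw$proDerp3, sim$truth$proDerp3, tolerance = 1e-5)
  f <- estimate_activation_kinetics(tc, E1 = 0.16, Z0 = 16)
  expect_equal(f$K_m, 4.5, tolerance = 1e-4)
  expect_equal(f$k_cat, 0.1, tolerance = 1e-4)
})

test_that("per-species XICs match generator bookkeeping with interleaved species", {
  sc <- qfms_scenario_wildtype(sigma_scan = 0, sigma_centroid = 0,
                               mz_jitter_Th = 0, duration_s = 300)
  sim <- simulate_qfms_series(sc, seed = 2)
  # one charge state of the zymogen: intensity = conc * weight * base
  x <- extract_xic(sim$series, mz_of(26354, 12), tol = 0.5)
  expect_equal(x$intensity, sim$truth$proDerp3 / 3 * 1000, tolerance = 1e-9)
  x2 <- extract_xic(sim$series, mz_of(24987, 10), tol = 0.5)
  expect_equal(x2$intensity, sim$truth$Derp3 / 4 * 1000, tolerance = 1e-9)
})

test_that("courses are invariant under global intensity rescaling", {
  sim <- simulate_qfms_series(qfms_scenario_wildtype(duration_s = 600),
                              seed = 8)
  tc1 <- build_time_courses(sim$series, unname(reference_proteoforms()))
  scaled <- spectrum_series(sim$series$scan_time_s, sim$series$mz,
                            sim$series$intensity * 37.5,
                            scan_times = attr(sim$series, "scan_times"))
  tc2 <- build_time_courses(scaled, unname(reference_proteoforms()))
  expect_equal(tc1$proDerp3, tc2$proDerp3, tolerance = 1e-12)
  expect_equal(tc1$Derp3, tc2$Derp3, tolerance = 1e-12)
})

test_that("charge-summation order does not matter given a common standard", {
  sim <- simulate_qfms_series(qfms_scenario_wildtype(duration_s = 300),
                              seed = 6)
  std <- extract_xic(sim$series, mz_of(average_mass("YGGFL"), 1))
  targets <- mz_of(26354, 10:12)
  xics <- lapply(targets, function(m) extract_xic(sim$series, m))
  norm_then_sum <- Reduce(`+`, lapply(xics, function(x)
    normalize_to_standard(x, std)$I_t))
  summed <- xics[[1]]; summed$intensity <- Reduce(`+`, lapply(xics, `[[`, "intensity"))
  sum_then_norm <- normalize_to_standard(summed, std)$I_t
  expect_equal(norm_then_sum, sum_then_norm, tolerance = 1e-12)
})

test_that("missing standard, empty series, and overlaps are handled", {
  ref <- unname(reference_proteoforms())
  s <- tiny_series()
  no_std <- ref[1:3]
  expect_error(build_time_courses(s, no_std), "internal standard")
  empty <- spectrum_series(numeric(0), numeric(0), numeric(0), scan_times = 0)
  expect_warning(tc <- build_time_courses(empty, ref), "empty")
  expect_equal(nrow(tc), 0)
  # two declared targets closer than 2*tol are flagged on both species
  clash <- list(
    proteoform("a", neutral_mass = 10000, role = "zymogen",
               charge_states = 5L),
    proteoform("b", neutral_mass = 10003, role = "mature",
               charge_states = 5L),
    proteoform("std", sequence = "YGGFL", role = "internal_standard",
               charge_states = 1L))
  s3 <- spectrum_series(c(0, 0, 0), c(2001, 2001.6, 556.6), c(10, 10, 5))
  expect_warning(tc3 <- build_time_courses(s3, clash, C_0 = 16),
                 "overlapping")
  expect_setequal(attr(tc3, "ambiguous"), c("a", "b"))
})

test_that("scans without internal-standard signal are dropped, not zeroed", {
  ref <- unname(reference_proteoforms())
  sc <- qfms_scenario_wildtype(sigma_scan = 0, sigma_centroid = 0,
                               mz_jitter_Th = 0, duration_s = 60)
  sim <- simulate_qfms_series(sc, seed = 3)
  drop_t <- attr(sim$series, "scan_times")[5]
  std_mz <- mz_of(average_mass("YGGFL"), 1)
  keep <- !(sim$series$scan_time_s == drop_t &
              abs(sim$series$mz - std_mz) < 0.5)
  pruned <- spectrum_series(sim$series$scan_time_s[keep],
                            sim$series$mz[keep],
                            sim$series$intensity[keep],
                            scan_times = attr(sim$series, "scan_times"))
  expect_message(tc <- build_time_courses(pruned, ref), "dropping 1 scan")
  expect_equal(attr(tc, "dropped_scans"), 1L)
  expect_false(drop_t %in% tc$time_s)
})

test_that("a non-processing scenario yields flat courses and an unidentifiable fit", {
  net <- species_network(c("SAQAT", "AQAT", "AT"), c(0.5, 0.25, 0.25),
                         k_process = c(0, 0, 0))
  species <- list(
    proteoform("SAQAT", neutral_mass = 25510, role = "truncated_zymogen",
               charge_states = 10:12),
    proteoform("AQAT", neutral_mass = 25420, role = "truncated_zymogen",
               charge_states = 10:12),
    proteoform("AT", neutral_mass = 25230, role = "truncated_zymogen",
               charge_states = 10:12),
    proteoform("mature", neutral_mass = 24987, role = "mature",
               charge_states = 9:12))
  sc <- qfms_scenario(net, species, duration_s = 600, sigma_scan = 0,
                      sigma_centroid = 0, mz_jitter_Th = 0)
  sim <- simulate_qfms_series(sc, seed = 5, E1_network = 0.16)
  tc <- build_time_courses(sim$series,
                           c(species, list(sc$standard)), C_0 = 16)
  expect_equal(tc$mature, rep(0, nrow(tc)))
  expect_equal(tc$SAQAT, rep(8, nrow(tc)), tolerance = 1e-9)
  expect_warning(f <- estimate_activation_kinetics(tc, E1 = 0.16, Z0 = 16),
                 "flat")
  expect_false(f$km_identifiable)
})

test_that("spectrum series CSV round trip preserves the run", {
  sim <- simulate_qfms_series(qfms_scenario_wildtype(duration_s = 60),
                              seed = 9)
  path <- tempfile(fileext = ".csv")
  write_spectrum_series(sim$series, path)
  back <- read_spectrum_series(path)
  expect_equal(nrow(back), nrow(sim$series))
  expect_equal(back$intensity, sim$series$intensity, tolerance = 1e-9)
})
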
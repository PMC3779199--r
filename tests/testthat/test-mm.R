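test_that("closed-form depletion matches the implicit-equation oracle", {
  pars <- mm_activation_params(K_m = 4.5, k_cat = 0.1, E1 = 0.16, Z0 = 16)
  tg <- c(0, 60, 600, 1200, 2400)
  z <- mm_depletion(pars, tg, method = "closed_form")$zymogen_uM
  expect_equal(z, oracle_mm_z(tg, 4.5, 0.1, 0.16, 16), tolerance = 1e-8)
  # frozen spot value from the root-finding oracle
  expect_equal(z[3], 8.992760073, tolerance = 1e-7)
})

test_that("numerical and closed-form integrated MM agree to 1e-6 relative", {
  pars <- mm_activation_params(K_m = 4.5, k_cat = 0.1, E1 = 0.16, Z0 = 16)
  tg <- seq(0, 2400, length.out = 2000)
  a <- mm_depletion(pars, tg, method = "closed_form")
  b <- mm_depletion(pars, tg, method = "ode")
  rel <- abs(a$zymogen_uM - b$zymogen_uM) / pmax(abs(a$zymogen_uM), 1e-9 * 16)
  expect_lt(max(rel), 1e-6)
  expect_equal(a$mature_uM + a$zymogen_uM, rep(16, 2000), tolerance = 1e-9)
  expect_equal(a$propeptide_uM, a$mature_uM)
})

test_that("depletion reduces to first order for K_m >> Z0 and zero order for K_m << Z0", {
  # first-order limit: rate k_cat*E1/K_m
  p1 <- mm_activation_params(K_m = 1e4, k_cat = 100, E1 = 0.16, Z0 = 16)
  tg <- seq(0, 2400, by = 60)
  z1 <- mm_depletion(p1, tg)$zymogen_uM
  expect_equal(z1, 16 * exp(-100 * 0.16 / 1e4 * tg), tolerance = 1e-2)
  # zero-order (saturated) early phase: rate k_cat*E1
  p2 <- mm_activation_params(K_m = 0.01, k_cat = 0.1, E1 = 0.16, Z0 = 16)
  tearly <- seq(0, 300, by = 30)
  z2 <- mm_depletion(p2, tearly)$zymogen_uM
  expect_equal(z2, 16 - 0.1 * 0.16 * tearly, tolerance = 1e-3)
})

test_that("closed form refuses sinks; ODE handles them with conservation", {
  pars <- mm_activation_params(4.5, 0.1, k_auto = 1e-4, k_deg = 5e-4)
  expect_error(mm_depletion(pars, 0:10, "closed_form"), "sinks")
  tg <- seq(0, 2400, by = 30)
  sol <- mm_depletion(pars, tg, method = "ode")
  total <- sol$zymogen_uM + sol$mature_uM + sol$autolyzed_uM + sol$degraded_uM
  expect_equal(total, rep(16, length(tg)), tolerance = 1e-6)
  expect_true(all(diff(sol$autolyzed_uM) > 0))
})

test_that("noise-free depletion fits recover the generating parameters", {
  pars <- mm_activation_params(4.5, 0.1, E1 = 0.16, Z0 = 16)
  tg <- seq(0, 2400, by = 3)
  z <- mm_depletion(pars, tg)$zymogen_uM
  f <- fit_mm_depletion(tg, z, E1 = 0.16, Z0 = 16)
  expect_true(f$km_identifiable)
  expect_equal(f$K_m, 4.5, tolerance = 1e-4)
  expect_equal(f$k_cat, 0.1, tolerance = 1e-4)
  expect_equal(f$kcat_over_Km, 0.1 / 4.5, tolerance = 1e-4)
})

test_that("noisy depletion recovers K_m within 25% and the ratio within 10%", {
  pars <- mm_activation_params(4.5, 0.1, E1 = 0.16, Z0 = 16)
  tg <- seq(0, 2400, by = 3)
  z0 <- mm_depletion(pars, tg)$zymogen_uM
  fits <- lapply(1:50, function(s) {
    set.seed(700 + s)
    z <- pmax(z0 * (1 + rnorm(length(z0), 0, 0.05)), 0)
    fit_mm_depletion(tg, z, E1 = 0.16, Z0 = 16)
  })
  km <- vapply(fits, function(f) f$K_m, numeric(1))
  ratio <- vapply(fits, function(f) f$kcat_over_Km, numeric(1))
  expect_lt(abs(stats::median(km) / 4.5 - 1), 0.25)
  expect_lt(abs(stats::median(ratio) / (0.1 / 4.5) - 1), 0.10)
})

test_that("a purely exponential course flags K_m as unidentifiable", {
  tg <- seq(0, 2400, by = 3)
  z <- 16 * exp(-0.0015 * tg)
  expect_warning(f <- fit_mm_depletion(tg, z, E1 = 0.16, Z0 = 16),
                 "not identifiable")
  expect_false(f$km_identifiable)
  expect_equal(f$kcat_over_Km, 0.0015 / 0.16, tolerance = 1e-3)
})

test_that("species network conserves protein and honours inert species", {
  net <- species_network(ids = c("intact", "trunc", "inert"),
                         fractions = c(0.5, 0.3, 0.2),
                         k_process = c(0.05, 0.02, 0),
                         k_auto = c(1e-4, 0, 0), k_deg = 2e-4)
  tg <- seq(0, 2400, by = 3)
  sol <- simulate_species_network(net, E1 = 0.16, tg, Z0 = 16)
  total <- sol$intact + sol$trunc + sol$inert + sol$mature_uM +
    sol$autolyzed_uM + sol$degraded_uM
  expect_equal(total, rep(16, length(tg)), tolerance = 1e-9)
  expect_equal(sol$inert, rep(0.2 * 16, length(tg)))
  expect_true(all(diff(sol$propeptide_uM) >= 0))
})

test_that("an all-inert network yields flat courses and no mature enzyme", {
  net <- species_network(c("a", "b"), c(0.6, 0.4), c(0, 0))
  sol <- simulate_species_network(net, E1 = 0.16, seq(0, 600, 3), Z0 = 16)
  expect_equal(unique(sol$mature_uM), 0)
  expect_equal(sol$a, rep(9.6, nrow(sol)))
  expect_equal(sol$b, rep(6.4, nrow(sol)))
})

test_that("a single-species network reduces to MM depletion in the first-order limit", {
  Km <- 1e4; kcat <- 100; E1 <- 0.16; Z0 <- 16
  tg <- seq(0, 2400, by = 30)
  net <- species_network("z", 1, k_process = kcat / Km)
  sol_net <- simulate_species_network(net, E1, tg, Z0)
  sol_mm <- mm_depletion(mm_activation_params(Km, kcat, E1, Z0), tg)
  expect_equal(sol_net$z, sol_mm$zymogen_uM, tolerance = 1e-3)
})

test_that("network fraction and rate validation rejects malformed input", {
  expect_error(species_network(c("a", "b"), c(0.7, 0.2), c(0, 0)), "sum")
  expect_error(species_network("a", 1, -0.1))
})
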
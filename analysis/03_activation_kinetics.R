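#!/usr/bin/env Rscript

# Activation kinetics in the coupled continuous assay: zymogen (12.5 nM)
# plus activating protease, with nascent mature enzyme hydrolysing a
# fluorogenic reporter. Progress curves follow the lag equation
# P(t) = v_s t + (v_i - v_s)(1 - exp(-k_obs t))/k_obs; k_obs is the
# pseudo-first-order maturation rate constant. The panel's measured
# k_obs values (wild type 0.0035, P2A 0.0029, P5A 0.0011 1/s) serve as
# simulation ground truths; the P8A and P-A mutants do not mature on
# this timescale at low activator and are represented by k_obs = 0.

suppressPackageStartupMessages(library(zymokin))
out_dir <- "results/activation_kinetics"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
SEED <- 1L
n_rep <- 50L

## -- k_obs recovery per construct ---------------------------------------
panel <- c("wild type" = 0.0035, "P2A" = 0.0029, "P5A" = 0.0011)
rows <- list()
for (i in seq_along(panel)) {
  ks <- vapply(seq_len(n_rep), function(r) {
    pc <- simulate_progress_curve(5e-4, 5e-3, panel[i],
                                  duration_s = 1800, sampling_s = 5,
                                  noise_rel = 0.01,
                                  seed = SEED * 10000L + i * 100L + r)
    suppressWarnings(fit_progress(pc))$k_obs
  }, numeric(1))
  rows[[i]] <- data.frame(construct = names(panel)[i],
                          k_obs_true = unname(panel[i]),
                          k_obs_fit_mean = signif(mean(ks), 4),
                          k_obs_fit_sd = signif(sd(ks), 3),
                          rel_bias_pct = round(100 * (mean(ks) / panel[i] - 1), 2))
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out_dir, "kobs_recovery.csv"), row.names = FALSE)
cat(sprintf("k_obs recovery (%d replicates, 30-min curves, 1%% noise):\n",
            n_rep))
print(tab, row.names = FALSE)

# one example fitted curve for inspection
pc <- simulate_progress_curve(5e-4, 5e-3, 0.0035, seed = SEED)
write.csv(data.frame(time_s = pc$time_s, product_uM = pc$product_uM),
          file.path(out_dir, "example_progress_curve.csv"), row.names = FALSE)

## -- k_obs vs activator concentration -----------------------------------
# in the sub-saturating regime k_obs grows linearly with activator; the
# slope is the apparent specificity constant of activation. Simulate a
# titration (0-1.5 nM activator) with a small basal intercept.
set.seed(SEED)
slope_true <- 2.4    # uM^-1 s^-1
int_true <- 1e-4     # 1/s basal
conc_uM <- c(0, 0.25, 0.5, 0.75, 1.0, 1.5) / 1000
k_obs_obs <- (int_true + slope_true * conc_uM) *
  (1 + rnorm(length(conc_uM), 0, 0.02))
lin <- fit_kobs_linear(conc_uM, k_obs_obs)
cat(sprintf("\nk_obs vs activator: slope %.3g +/- %.2g uM^-1 s^-1 (true %.3g),\n",
            lin$slope, lin$se_slope, slope_true))
cat(sprintf("  intercept %.3g +/- %.2g 1/s (true %.3g)\n",
            lin$intercept, lin$se_intercept, int_true))
write.csv(data.frame(activator_uM = conc_uM, k_obs = k_obs_obs),
          file.path(out_dir, "kobs_vs_activator.csv"), row.names = FALSE)
jsonlite::write_json(list(slope_uM_s = lin$slope, intercept_s = lin$intercept,
                          se_slope = lin$se_slope,
                          se_intercept = lin$se_intercept),
                     file.path(out_dir, "kobs_linear_fit.json"),
                     auto_unbox = TRUE, digits = NA)
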
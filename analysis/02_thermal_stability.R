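#!/usr/bin/env Rscript

# Two-state thermal-unfolding analysis of the zymogen panel: simulate
# fluorescence melting curves (20-70 C ramp at 0.5 C/min read every
# 30 s, 0.5% relative noise) at each construct's apparent Tm and verify
# that the six-parameter fit returns it. The proteolytically active
# constructs melt near 48-50 C; inactivating the catalytic serine
# (S196A) raises the apparent Tm by ~5 C, showing that self-proteolysis,
# not the propeptide prolines, limits apparent stability.

suppressPackageStartupMessages(library(zymokin))
out_dir <- "results/thermal_stability"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
SEED <- 1L

panel <- c("proDer p 3" = 49.5, "P2A" = 49.1, "P5A" = 49.4,
           "P8A" = 48.7, "P-A" = 48.1, "S196A" = 54.2, "P-A S196A" = 55.1)
dHm_true <- 3e5  # J/mol, typical for a ~25 kDa globular domain

rows <- list()
for (i in seq_along(panel)) {
  truth <- two_state_fit(Tm_K = panel[i] + 273.15, dHm = dHm_true,
                         yN = 100, yU = 30, p = -0.2, q = -0.05)
  fits <- lapply(1:10, function(r) {
    mc <- simulate_melting_curve(truth, noise_rel = 0.005,
                                 seed = SEED * 1000L + i * 50L + r)
    fit_melting(mc)
  })
  tms <- vapply(fits, function(f) f$Tm_C, numeric(1))
  rows[[i]] <- data.frame(
    construct = names(panel)[i], Tm_true_C = unname(panel[i]),
    Tm_fit_C = round(mean(tms), 2), Tm_fit_sd_C = round(sd(tms), 3),
    dHm_fit_kJ = round(mean(vapply(fits, function(f) f$dHm, 1)) / 1000, 1))
  # keep one example curve per construct for plotting/inspection
  mc <- simulate_melting_curve(truth, noise_rel = 0.005,
                               seed = SEED * 1000L + i * 50L + 1L)
  write.csv(data.frame(temperature_C = mc$temperature_C, signal = mc$signal),
            file.path(out_dir, paste0("curve_", gsub("[^A-Za-z0-9]+", "_",
                                                     names(panel)[i]), ".csv")),
            row.names = FALSE)
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out_dir, "tm_recovery.csv"), row.names = FALSE)
cat("Apparent Tm recovery (10 replicate fits per construct):\n")
print(tab, row.names = FALSE)
cat("\nAll fits are flagged 'apparent': the transitions are irreversible,\n",
    "so the two-state Tm is an operational midpoint, not an equilibrium\n",
    "melting temperature.\n", sep = "")
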
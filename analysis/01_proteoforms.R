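#!/usr/bin/env Rscript

# Proteoform bookkeeping for the proDer p 3 construct panel:
# masses and charge-state m/z of the reaction species, expansion of the
# per-construct N-terminal form catalogs with activatability classes,
# and proline-rich-motif scans of the propeptide variants.

suppressPackageStartupMessages(library(zymokin))
out_dir <- "results/proteoforms"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

## -- reference species and their ESI envelopes ---------------------------
ref <- reference_proteoforms()
cat("Reaction species:\n")
for (p in ref) print(p)

env <- do.call(rbind, lapply(ref, function(p)
  data.frame(species = p$id, role = p$role, mass_Da = p$neutral_mass,
             charge = p$charge_states,
             mz_Th = round(unname(envelope_mz(p)), 2))))
write.csv(env, file.path(out_dir, "charge_state_envelopes.csv"),
          row.names = FALSE)
cat("\nCharge-state envelope (m/z, Th):\n")
print(env, row.names = FALSE)

# mass balance of the one-step maturation: zymogen -> mature + propeptide
cat(sprintf("\nMass balance: 26354 - 24987 + %.2f (water) = %.1f Da (propeptide)\n",
            mass_water, 26354 - 24987 + mass_water))
cat(sprintf("Sequence mass of the EF-extended propeptide EFNPILPASPQAT: %.2f Da\n",
            average_mass("EFNPILPASPQAT")))

## -- construct catalogs and activatable fractions ------------------------
summaries <- list()
for (nm in zymogen_constructs()) {
  forms <- enumerate_truncations(zymogen_catalog(nm))
  s <- attr(forms, "summary")
  s$construct <- nm
  summaries[[nm]] <- s
  proteoforms_to_json(forms, file.path(out_dir, paste0(
    "forms_", gsub("[^A-Za-z0-9]+", "_", nm), ".json")))
}
all_forms <- do.call(rbind, summaries)
write.csv(all_forms, file.path(out_dir, "construct_forms.csv"),
          row.names = FALSE)

frac <- data.frame(
  construct = zymogen_constructs(),
  activatable_percent = vapply(zymogen_constructs(), function(nm)
    attr(enumerate_truncations(zymogen_catalog(nm)), "activatable_percent"),
    numeric(1)))
write.csv(frac, file.path(out_dir, "activatable_fractions.csv"),
          row.names = FALSE)
cat("\nActivatable fraction per construct (%):\n")
print(frac, row.names = FALSE)
cat("\nNote: the heavily truncated P-A preparation is still 94% activatable;\n",
    "only its ALAGE- internal fragment (6%) cannot mature. Unidentified\n",
    "forms in the deletion constructs are counted as 'unknown'.\n", sep = "")

## -- proline-rich motif in the propeptide variants -----------------------
props <- c("wild type" = "NPILPASPQAT", "P2A" = "NAILPASPQAT",
           "P5A" = "NPILAASPQAT", "P8A" = "NPILPASAQAT",
           "P-A" = "NAILAASAQAT")
cat("\nProline-rich motif scan of the 11-residue propeptide variants:\n")
motif_rows <- lapply(names(props), function(nm) {
  hits <- find_proline_rich_motif(props[[nm]], min_prolines = 2)
  if (length(hits)) {
    h <- hits[[which.max(vapply(hits, function(x) length(x$positions), 1L))]]
    data.frame(variant = nm, sequence = props[[nm]], motif = h$motif,
               prolines = paste(h$positions, collapse = ","))
  } else {
    data.frame(variant = nm, sequence = props[[nm]], motif = "-",
               prolines = "-")
  }
})
motifs <- do.call(rbind, motif_rows)
print(motifs, row.names = FALSE)
write.csv(motifs, file.path(out_dir, "propeptide_motifs.csv"),
          row.names = FALSE)
cat("\nThe wild-type propeptide carries the full PxxPxxP motif (prolines\n",
    "2, 5, 8); each single mutation degrades it to a PxxP pair and the\n",
    "all-alanine mutant removes it entirely.\n", sep = "")
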
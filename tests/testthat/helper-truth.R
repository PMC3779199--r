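# shared ground-truth objects for the simulation-recovery tests

melt_truth <- function(Tm_C = 54.2, dHm = 3e5)
  two_state_fit(Tm_K = Tm_C + 273.15, dHm = dHm,
                yN = 100, yU = 30, p = -0.2, q = -0.05)

# random peptide of length n from the 20 standard residues
random_peptide <- function(n)
  paste(sample(names(residue_masses), n, replace = TRUE), collapse = "")

# independent brute-force mass oracle: per-residue lookup in a loop
oracle_mass <- function(sequence) {
  total <- 18.01528
  for (ch in strsplit(sequence, "")[[1]]) total <- total + residue_masses[[ch]]
  total
}

# independent oracle for the integrated Michaelis-Menten relation:
# root-finding on Km*ln(Z0/Z) + (Z0 - Z) = kcat*E1*t
oracle_mm_z <- function(t, Km, kcat, E1, Z0) {
  vapply(t, function(ti) {
    if (ti == 0) return(Z0)
    f <- function(z) Km * log(Z0 / z) + (Z0 - z) - kcat * E1 * ti
    stats::uniroot(f, c(Z0 * 1e-12, Z0), tol = 1e-13)$root
  }, numeric(1))
}
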
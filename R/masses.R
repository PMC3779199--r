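#' Average residue masses of the 20 standard amino acids
#'
#' Monomer (residue) average masses in daltons, i.e. the mass each residue
#' contributes inside a peptide chain. A free peptide adds one water.
#' Electrospray adducts add one proton per charge.
#'
#' @format Named numeric vector (one-letter codes); see also
#'   [mass_water] and [mass_proton].
#' @export
residue_masses <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

#' @rdname residue_masses
#' @export
mass_water <- 18.01528

#' @rdname residue_masses
#' @export
mass_proton <- 1.00728

#' Average (chemical) mass of a peptide or protein
#'
#' Sums the average residue masses of a one-letter amino-acid sequence and
#' adds one water for the free termini. Average, not monoisotopic, masses
#' are used throughout: the neutral masses this package reports (for
#' example 26354 Da for the zymogen, 24987 Da for the mature protease,
#' 1385 Da for the released propeptide, 556 Da for leucine enkephalin)
#' are average-mass values as read off a deconvoluted ESI spectrum.
#'
#' @param sequence Character scalar, one-letter amino-acid codes
#'   (upper case). The empty string returns the mass of water.
#' @return Neutral average mass in Da.
#' @examples
#' average_mass("EFNPILPASPQAT")  # ~1384.55, the released propeptide
#' average_mass("YGGFL")          # ~555.63, leucine enkephalin
#' @export
average_mass <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  if (nchar(sequence) == 0L) return(mass_water)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% names(residue_masses))
  if (length(bad)) {
    stop(sprintf("unknown residue code '%s' at position %d", res[bad[1]], bad[1]))
  }
  sum(residue_masses[res]) + mass_water
}

#' Mass-to-charge ratio of a protonated ion
#'
#' m/z of the `[M + zH]^z+` ion in positive-mode electrospray:
#' `(M + z * m_H) / z` with the proton mass `m_H` = 1.00728 Da.
#' Values are returned at full precision; round only when reporting
#' (the integer m/z values quoted for protein charge states, e.g. 2197
#' for the 12+ zymogen ion, are rounded reports of this quantity).
#'
#' @param neutral_mass Neutral mass M in Da (> 0). Vectorised.
#' @param z Positive integer charge. Vectorised.
#' @return m/z in thomson (Th).
#' @examples
#' mz_of(26354, 12)  # 2197.17
#' mz_of(24987, 10)  # 2499.71
#' @export
mz_of <- function(neutral_mass, z) {
  stopifnot(is.numeric(neutral_mass), is.numeric(z))
  if (any(z < 1 | z != round(z))) stop("charge z must be a positive integer")
  if (any(neutral_mass <= 0)) stop("neutral_mass must be > 0")
  (neutral_mass + z * mass_proton) / z
}
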
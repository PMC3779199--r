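# N-terminal form catalogs of the expressed proDer p 3 constructs, as
# determined by Edman sequencing after purification at 4 degrees C. All
# constructs carry the N9Q mutation (no propeptide glycosylation) and the
# EF- extension left by the EcoRI cloning site; the deletion constructs
# additionally show EA-/EAEA- remnants of incomplete alpha-factor
# processing. Sequences are the N-terminal window only; the mature
# protease domain starts at IVGG.
.construct_forms <- list(
  "proDer p 3" = list(seq = "EFNPILPASPQATIVGGEKALAG", pct = 100),
  "P2A" = list(seq = "EFNAILPASPQATIVGGEKALAG", pct = 100),
  "P5A" = list(seq = "EFNPILAASPQATIVGGEKALAG", pct = 100),
  "P8A" = list(seq = "EFNPILPASAQATIVGGEKALAG", pct = 100),
  "P-A" = list(
    seq = c("EFNAILAASAQATIVGGEKALAG", "ILAASAQATIVGGEKALAG",
            "ASAQATIVGGEKALAG", "SAQATIVGGEKALAG", "AQATIVGGEKALAG",
            "ATIVGGEKALAG", "ALAGE"),
    pct = c(8, 5, 9, 42, 16, 14, 6)),
  "d1-2" = list(seq = c("EFILPASPQATIVGGEKALAG", "SPQATIVGGEKALAG", NA),
                pct = c(88, 3, 9),
                ref = "EFILPASPQATIVGGEKALAG"),
  "d1-5" = list(seq = c("EFASPQATIVGGEKALAG", "ATIVGGEKALAG", NA),
                pct = c(88, 8, 4),
                ref = "EFASPQATIVGGEKALAG"),
  "d1-8" = list(seq = c("EFQATIVGGEKALAG", "EAEFQATIVGGEKALAG", NA),
                pct = c(24, 74, 2),
                ref = "EFQATIVGGEKALAG"),
  "d1-11" = list(seq = c("EAEFIVGGEKALAG", "EAEAEFIVGGEKALAG"),
                 pct = c(94, 6),
                 ref = "EFIVGGEKALAG")
)

#' Catalogs of N-terminal zymogen forms per construct
#'
#' Returns the [construct_catalog] of N-terminal forms (sequence and
#' approximate abundance, %) observed for one recombinant proDer p 3
#' construct after purification at 4 degrees C: the reference zymogen
#' (`"proDer p 3"`), the single proline-to-alanine mutants (`"P2A"`,
#' `"P5A"`, `"P8A"`), the all-alanine mutant (`"P-A"`), and the
#' propeptide deletions (`"d1-2"`, `"d1-5"`, `"d1-8"`, `"d1-11"`,
#' lacking 2, 5, 8 or all 11 propeptide residues). Forms whose sequence
#' could not be identified are `NA` rows.
#'
#' The P-A construct, heavily truncated by non-specific proteolysis
#' during expression, is the motivating case: of its seven forms, the
#' six whose N-terminus precedes the mature-domain junction (94% in
#' total) are still activatable; the 6% ALAGE- internal fragment is not.
#'
#' @param construct Construct name; see `zymogen_constructs()` for the
#'   valid set.
#' @return A [construct_catalog].
#' @seealso [enumerate_truncations]
#' @export
zymogen_catalog <- function(construct) {
  if (!construct %in% names(.construct_forms))
    stop(sprintf("unknown construct '%s'; valid names: %s", construct,
                 paste(names(.construct_forms), collapse = ", ")))
  e <- .construct_forms[[construct]]
  construct_catalog(construct, e$seq, e$pct,
                    reference = if (!is.null(e$ref)) e$ref else e$seq[1])
}

#' @rdname zymogen_catalog
#' @export
zymogen_constructs <- function() names(.construct_forms)

#' Reference proteoforms of the wild-type activation reaction
#'
#' The four species tracked in the quenched-flow MS experiment:
#' zymogen (26354 Da, charges 10-12+), mature protease (24987 Da,
#' charges 9-12+), released propeptide (1385 Da, charges 1-2+) and the
#' leucine-enkephalin internal standard (YGGFL, 556 Da, 1+).
#'
#' @return Named list of [proteoform] objects
#'   (`zymogen`, `mature`, `propeptide`, `standard`).
#' @export
reference_proteoforms <- function() {
  list(
    zymogen = proteoform("proDerp3", "proDer p 3", neutral_mass = 26354,
                         role = "zymogen", charge_states = 10:12),
    mature = proteoform("Derp3", "proDer p 3", neutral_mass = 24987,
                        role = "mature", charge_states = 9:12),
    propeptide = proteoform("propeptide", "proDer p 3",
                            sequence = "EFNPILPASPQAT", role = "propeptide",
                            charge_states = 1:2),
    standard = proteoform("leu-enkephalin", sequence = "YGGFL",
                          role = "internal_standard", charge_states = 1L)
  )
}
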
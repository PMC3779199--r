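#' Construct a proteoform record
#'
#' A proteoform is one named protein or peptide species: a construct's
#' intact zymogen, an N-terminally truncated or extended zymogen form,
#' the mature protease, the released propeptide, an inactive internal
#' fragment, or the internal standard used for MS normalization.
#'
#' @param id Unique identifier string.
#' @param construct Construct name the form belongs to (e.g. "P-A proDer p 3").
#' @param sequence One-letter amino-acid sequence, or `NA` when only the
#'   mass is known (common for species read off a deconvoluted spectrum).
#' @param neutral_mass Neutral average mass in Da. Computed from
#'   `sequence` when omitted and the sequence is complete.
#' @param role One of `"zymogen"`, `"truncated_zymogen"`, `"mature"`,
#'   `"propeptide"`, `"internal_fragment"`, `"internal_standard"`,
#'   `"unknown"`.
#' @param charge_states Integer vector of observable positive charges
#'   (may be empty for species not tracked by MS).
#' @param fraction Abundance fraction within its construct, in `[0, 1]`.
#' @param sequence_partial Logical; `TRUE` when `sequence` is only the
#'   N-terminal portion of the molecule (as in an Edman-sequencing
#'   catalog), in which case no mass is computed from it and the
#'   sequence/mass consistency check is skipped with a warning.
#' @return An object of class `"proteoform"` (a named list).
#' @export
proteoform <- function(id, construct = NA_character_, sequence = NA_character_,
                       neutral_mass = NA_real_,
                       role = c("zymogen", "truncated_zymogen", "mature",
                                "propeptide", "internal_fragment",
                                "internal_standard", "unknown"),
                       charge_states = integer(0), fraction = NA_real_,
                       sequence_partial = FALSE) {
  role <- match.arg(role)
  has_seq <- !is.na(sequence) && nzchar(sequence)
  if (has_seq && !sequence_partial) {
    m <- average_mass(sequence)
    if (is.na(neutral_mass)) {
      neutral_mass <- m
    } else if (abs(neutral_mass - m) > 0.01) {
      stop(sprintf("neutral_mass %.2f Da disagrees with sequence mass %.2f Da for '%s'",
                   neutral_mass, m, id))
    }
  } else if (has_seq && sequence_partial && !is.na(neutral_mass)) {
    warning(sprintf("'%s': sequence is partial; mass/sequence consistency not checked", id))
  }
  if (length(charge_states)) {
    stopifnot(all(charge_states >= 1), all(charge_states == round(charge_states)))
  }
  structure(list(id = id, construct = construct,
                 sequence = if (has_seq) sequence else NA_character_,
                 neutral_mass = neutral_mass, role = role,
                 charge_states = as.integer(charge_states),
                 fraction = fraction, sequence_partial = sequence_partial),
            class = "proteoform")
}

#' @export
print.proteoform <- function(x, ...) {
  cat(sprintf("<proteoform> %s (%s)\n", x$id, x$role))
  if (!is.na(x$sequence))
    cat(sprintf("  sequence: %s%s\n", x$sequence,
                if (x$sequence_partial) " (N-terminal, partial)" else ""))
  if (!is.na(x$neutral_mass)) cat(sprintf("  mass: %.2f Da\n", x$neutral_mass))
  if (length(x$charge_states))
    cat("  charges:", paste0(x$charge_states, "+", collapse = " "), "\n")
  if (!is.na(x$fraction)) cat(sprintf("  fraction: %.2f\n", x$fraction))
  invisible(x)
}

#' Target m/z values of a proteoform's charge-state envelope
#'
#' @param x A [proteoform] with a known mass and declared charge states.
#' @return Named numeric vector of m/z (Th), names like `"12+"`.
#' @export
envelope_mz <- function(x) {
  stopifnot(inherits(x, "proteoform"), !is.na(x$neutral_mass),
            length(x$charge_states) > 0)
  stats::setNames(mz_of(x$neutral_mass, x$charge_states),
                  paste0(x$charge_states, "+"))
}

#' Cleave a zymogen into propeptide and mature protease
#'
#' Hydrolysis of one peptide bond: the N-terminal product is residues
#' `1..site_index`, the C-terminal product the remainder. Each product
#' gains the elements of water, so
#' `mass(N) + mass(C) = mass(whole) + mass_water` (to 0.01 Da) — the mass
#' balance by which a 26354 Da zymogen and a 24987 Da mature protease
#' imply a released propeptide of 26354 - 24987 + 18.02 = 1385 Da.
#'
#' @param zymogen A [proteoform] with a complete sequence.
#' @param site_index 1-based index of the last residue of the N-terminal
#'   product (the P1 residue of the scissile bond).
#' @return List with elements `propeptide` and `mature`, both proteoforms.
#' @export
cleave <- function(zymogen, site_index) {
  stopifnot(inherits(zymogen, "proteoform"))
  if (is.na(zymogen$sequence) || zymogen$sequence_partial)
    stop("cleave() needs a complete sequence")
  n <- nchar(zymogen$sequence)
  if (!(site_index > 0 && site_index < n))
    stop(sprintf("cleavage site %d outside sequence (1..%d)", site_index, n - 1))
  left <- substr(zymogen$sequence, 1L, site_index)
  right <- substr(zymogen$sequence, site_index + 1L, n)
  list(
    propeptide = proteoform(paste0(zymogen$id, "_propeptide"), zymogen$construct,
                            sequence = left, role = "propeptide"),
    mature = proteoform(paste0(zymogen$id, "_mature"), zymogen$construct,
                        sequence = right, role = "mature")
  )
}

#' N-terminal form catalog of one zymogen construct
#'
#' Records the N-terminal sequencing result for one expressed construct:
#' the set of co-purified N-terminal forms with their approximate
#' abundances. Sequences are the N-terminal portion only (the protein
#' continues beyond the region shown), so no masses are derived from
#' them. Rows whose sequence could not be identified carry `NA`.
#'
#' @param construct Construct name.
#' @param form_sequence Character vector of N-terminal sequences (`NA`
#'   allowed for unidentified forms).
#' @param percent Numeric vector of abundances (%), summing to 100 +/- 1.
#' @param reference Full-length reference N-terminal sequence of the
#'   intact form (used to validate that every listed form aligns to the
#'   construct).
#' @param mature_start Sequence marking the start of the mature protease
#'   domain (default `"IVGG"`, the canonical trypsin-family junction).
#' @return Object of class `"construct_catalog"`.
#' @export
construct_catalog <- function(construct, form_sequence, percent,
                              reference = form_sequence[1],
                              mature_start = "IVGG") {
  stopifnot(length(form_sequence) == length(percent), all(percent >= 0),
            all(percent <= 100))
  if (abs(sum(percent) - 100) > 1)
    stop(sprintf("form percentages sum to %.1f, not 100 +/- 1", sum(percent)))
  structure(list(construct = construct,
                 forms = data.frame(form_sequence = form_sequence,
                                    percent = percent,
                                    stringsAsFactors = FALSE),
                 reference = reference, mature_start = mature_start),
            class = "construct_catalog")
}

# A form aligns to the construct if some ungapped overlap with the
# reference N-terminal sequence matches exactly, the overlap is
# non-trivial, and the form runs to (or past) the end of the shown
# reference window: forms differ only at the N-terminus (truncation or
# cloning extension), never internally.
aligns_to_reference <- function(form, reference, min_overlap = 4L) {
  nf <- nchar(form); nr <- nchar(reference)
  fv <- strsplit(form, "")[[1]]; rv <- strsplit(reference, "")[[1]]
  for (s in seq(-(nf - 1L), nr - 1L)) {        # form pos 1 aligns to ref pos s+1
    if (s + nf < nr) next                       # must reach the ref C-terminus
    i1 <- max(1L, s + 1L); i2 <- min(nr, s + nf)
    len <- i2 - i1 + 1L
    if (len < min_overlap) next
    if (identical(rv[i1:i2], fv[(i1 - s):(i2 - s)])) return(TRUE)
  }
  FALSE
}

#' Enumerate the proteoforms of a construct catalog
#'
#' Expands a [construct_catalog] into one [proteoform] per listed
#' N-terminal form and classifies each as activatable or not. A form is
#' *activatable* when its N-terminus lies at or before the start of the
#' mature protease domain (its sequence still contains the intact
#' mature-domain junction), so the activating protease can still produce
#' mature enzyme from it; a form starting inside the mature domain is an
#' inactive internal fragment; an unidentified form is classified
#' `"unknown"`.
#'
#' @param catalog A [construct_catalog].
#' @return List of proteoforms, with attribute `activatable_percent`
#'   (sum of activatable form percentages) and `summary` (data frame of
#'   form, percent, class).
#' @examples
#' cat_pa <- zymogen_catalog("P-A")
#' forms <- enumerate_truncations(cat_pa)
#' attr(forms, "activatable_percent")  # 94
#' @export
enumerate_truncations <- function(catalog) {
  stopifnot(inherits(catalog, "construct_catalog"))
  forms <- catalog$forms
  out <- vector("list", nrow(forms))
  cls <- character(nrow(forms))
  for (i in seq_len(nrow(forms))) {
    fs <- forms$form_sequence[i]
    if (is.na(fs)) {
      cls[i] <- "unknown"
      role <- "unknown"
    } else {
      if (!aligns_to_reference(fs, catalog$reference))
        stop(sprintf("form '%s' does not align to the %s reference sequence",
                     fs, catalog$construct))
      if (grepl(catalog$mature_start, fs, fixed = TRUE)) {
        cls[i] <- "activatable"
        role <- if (identical(fs, catalog$reference)) "zymogen" else "truncated_zymogen"
      } else {
        cls[i] <- "non_activatable"
        role <- "internal_fragment"
      }
    }
    out[[i]] <- proteoform(
      id = sprintf("%s_form%02d", gsub("\\s+", "_", catalog$construct), i),
      construct = catalog$construct, sequence = fs, role = role,
      fraction = forms$percent[i] / 100, sequence_partial = TRUE)
  }
  structure(out,
            activatable_percent = sum(forms$percent[cls == "activatable"]),
            summary = data.frame(form_sequence = forms$form_sequence,
                                 percent = forms$percent, class = cls,
                                 stringsAsFactors = FALSE))
}

#' Find proline-rich PxxP-periodic motifs
#'
#' Scans a sequence for maximal runs of prolines spaced exactly three
#' residues apart (positions i, i+3, i+6, ...), the periodicity of a
#' polyproline-II helix with three residues per turn. The 11-residue
#' propeptide of the proDer p 3 zymogen carries such a motif (prolines
#' 2, 5 and 8: PxxPxxP); consecutive prolines ("PPP") do not match.
#'
#' @param sequence One-letter amino-acid string.
#' @param min_prolines Minimum prolines in a reported run (default 2,
#'   i.e. at least a PxxP).
#' @return List of hits; each hit is a list with `positions` (1-based
#'   proline positions), `motif` (e.g. `"PxxPxxP"`) and `span`
#'   (first and last position of the run). Empty list when none.
#' @export
find_proline_rich_motif <- function(sequence, min_prolines = 2L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(sequence, "")[[1]]
  p <- which(res == "P")
  hits <- list()
  for (start in p) {
    if ((start - 3L) %in% p) next       # not maximal: extendable to the left
    run <- start
    while ((run[length(run)] + 3L) %in% p) run <- c(run, run[length(run)] + 3L)
    if (length(run) >= min_prolines) {
      hits[[length(hits) + 1L]] <- list(
        positions = run,
        motif = paste0("P", strrep("xxP", length(run) - 1L)),
        span = c(run[1], run[length(run)]))
    }
  }
  hits
}

#' Export a set of proteoforms to JSON
#'
#' @param proteoforms List of [proteoform] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
proteoforms_to_json <- function(proteoforms, path) {
  recs <- lapply(proteoforms, function(p)
    list(id = p$id, construct = p$construct, sequence = p$sequence,
         mass = p$neutral_mass, role = p$role,
         charges = p$charge_states, fraction = p$fraction))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet()`.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}
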
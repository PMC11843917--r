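# In-silico tryptic digestion and theoretical-peptide counting.
#
# iBAQ divides a protein's summed peptide intensity by the number of
# theoretically observable tryptic peptides, so this count is the
# denominator of every absolute-quantification value downstream.

#' Monoisotopic residue masses (Da) for the 20 standard amino acids
#'
#' Residue (not free amino-acid) masses; one water (18.0105646863 Da) is
#' added per peptide when computing peptide mass.
#'
#' @keywords internal
MONO_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER <- 18.0105646863

#' Digestion parameters for theoretical-peptide counting
#'
#' Defaults mirror typical search-engine settings for bottom-up plant
#' proteomics: tryptic cleavage after K or R but not before P, a minimum
#' peptide length of 7 residues and a maximum peptide mass of 4600 Da.
#' Missed cleavages default to 0 for iBAQ-style counting; the search
#' itself typically allows up to 2, so the window is fully configurable.
#'
#' @param min_length Minimum peptide length in residues (default 7).
#' @param max_mass_da Maximum peptide monoisotopic mass in Da (default 4600).
#' @param missed_cleavages Number of internal cleavage sites a peptide may
#'   retain (default 0).
#' @param on_unknown What to do with non-standard residue letters:
#'   `"error"` (default) or `"average"` (assign the mean residue mass and
#'   warn).
#' @return A list of class `digest_params`.
#' @export
digest_params <- function(min_length = 7L, max_mass_da = 4600,
                          missed_cleavages = 0L,
                          on_unknown = c("error", "average")) {
  on_unknown <- match.arg(on_unknown)
  if (min_length < 1L) stop("`min_length` must be >= 1", call. = FALSE)
  if (max_mass_da <= 0) stop("`max_mass_da` must be positive", call. = FALSE)
  if (missed_cleavages < 0L) stop("`missed_cleavages` must be >= 0", call. = FALSE)
  structure(
    list(min_length = as.integer(min_length), max_mass_da = max_mass_da,
         missed_cleavages = as.integer(missed_cleavages),
         on_unknown = on_unknown),
    class = "digest_params"
  )
}

# Cleavage sites: positions i such that residue i is K or R and residue
# i+1 is not P. Returns the end index of every tryptic segment.
tryptic_segment_ends <- function(residues) {
  n <- length(residues)
  if (n == 0L) return(integer())
  is_kr <- residues %in% c("K", "R")
  next_p <- c(residues[-1] == "P", FALSE)
  cuts <- which(is_kr & !next_p)
  unique(c(cuts, n))
}

#' Count theoretically observable tryptic peptides
#'
#' Cleaves a protein sequence after K/R (not before P), assembles all
#' peptides with at most `missed_cleavages` retained internal sites, and
#' counts the distinct peptide sequences whose length is at least
#' `min_length` residues and whose monoisotopic mass (residue masses plus
#' one water) is at most `max_mass_da`.
#'
#' @param sequence A single protein sequence (character scalar).
#'   Case-insensitive; surrounding whitespace ignored.
#' @param params A [digest_params()] object.
#' @return Integer count of distinct observable peptides.
#' @examples
#' count_theoretical_peptides("AAAAAAAK")  # one peptide of length 8
#' @export
count_theoretical_peptides <- function(sequence, params = digest_params()) {
  stopifnot(inherits(params, "digest_params"))
  peps <- theoretical_peptides(sequence, params)
  length(unique(peps))
}

#' Enumerate theoretically observable tryptic peptides
#'
#' Same rules as [count_theoretical_peptides()] but returns the peptide
#' sequences themselves (with duplicates removed).
#'
#' @inheritParams count_theoretical_peptides
#' @return Character vector of distinct peptide sequences.
#' @export
theoretical_peptides <- function(sequence, params = digest_params()) {
  if (length(sequence) != 1L || !is.character(sequence) || is.na(sequence))
    stop("`sequence` must be a single character string", call. = FALSE)
  seq_clean <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(seq_clean)) stop("`sequence` is empty", call. = FALSE)
  residues <- strsplit(seq_clean, "", fixed = TRUE)[[1]]

  unknown <- setdiff(unique(residues), names(MONO_RESIDUE_MASS))
  masses <- MONO_RESIDUE_MASS
  if (length(unknown) > 0L) {
    if (params$on_unknown == "error") {
      stop("unknown residue character(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    warning("unknown residue character(s) ", paste(unknown, collapse = ", "),
            " assigned the average residue mass", call. = FALSE)
    avg <- mean(MONO_RESIDUE_MASS)
    masses <- c(masses, stats::setNames(rep(avg, length(unknown)), unknown))
  }

  ends <- tryptic_segment_ends(residues)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  n_seg <- length(ends)
  res_mass <- unname(masses[residues])
  cum <- c(0, cumsum(res_mass))

  out <- character()
  for (i in seq_len(n_seg)) {
    for (k in 0:params$missed_cleavages) {
      j <- i + k
      if (j > n_seg) break
      from <- starts[i]; to <- ends[j]
      len <- to - from + 1L
      if (len < params$min_length) next
      mass <- cum[to + 1L] - cum[from] + MASS_WATER
      if (mass > params$max_mass_da) next
      out <- c(out, substr(seq_clean, from, to))
    }
  }
  unique(out)
}

#' Protein molecular weight from sequence (kDa)
#'
#' Monoisotopic residue masses plus one water, reported in kDa. Used when
#' a fragment lead protein's molecular weight is replaced by that of its
#' resolved full-length counterpart.
#'
#' @param sequence Protein sequence (character scalar).
#' @return Molecular weight in kDa.
#' @export
sequence_mw_kda <- function(sequence) {
  seq_clean <- toupper(gsub("[[:space:]]", "", sequence))
  residues <- strsplit(seq_clean, "", fixed = TRUE)[[1]]
  unknown <- setdiff(unique(residues), names(MONO_RESIDUE_MASS))
  if (length(unknown) > 0L)
    stop("unknown residue character(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  (sum(MONO_RESIDUE_MASS[residues]) + MASS_WATER) / 1000
}
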
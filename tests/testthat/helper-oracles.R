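# Independent oracles and fixture builders used across the suite.

# Brute-force theoretical-peptide count: enumerate every contiguous run
# of tryptic segments with at most `mc` retained cleavage sites, filter
# by length and monoisotopic mass, count distinct sequences. Kept
# deliberately naive (regex site finding, per-peptide mass summation) so
# it is an independent check on the package implementation.
oracle_count_peptides <- function(seq, min_length = 7L, max_mass = 4600,
                                  mc = 0L) {
  seq <- toupper(seq)
  masses <- greenprot:::MONO_RESIDUE_MASS
  hits <- gregexpr("[KR](?!P)", seq, perl = TRUE)[[1]]
  sites <- if (hits[1] == -1L) integer() else as.integer(hits)
  ends <- sort(unique(c(sites, nchar(seq))))
  starts <- c(1L, head(ends, -1L) + 1L)
  peps <- character()
  for (i in seq_along(starts)) {
    for (j in i:min(i + mc, length(ends))) {
      p <- substr(seq, starts[i], ends[j])
      if (nchar(p) < min_length) next
      m <- sum(masses[strsplit(p, "")[[1]]]) + 18.0105646863
      if (m <= max_mass) peps <- c(peps, p)
    }
  }
  length(unique(peps))
}

random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(greenprot:::MONO_RESIDUE_MASS), len, replace = TRUE),
        collapse = "")
}

# Assemble a protein-group tibble directly from matrices, bypassing the
# generators, for hand-constructed fixtures.
make_pg <- function(accessions, names, samples,
                    intensity, ibaq = intensity, lfq = intensity,
                    msms = NULL, unique_peptides = NULL, coverage = NULL,
                    score = rep(100, length(accessions)),
                    mw_kda = rep(50, length(accessions)),
                    members = accessions,
                    is_contaminant = rep(FALSE, length(accessions)),
                    is_reverse = rep(FALSE, length(accessions))) {
  n <- length(accessions)
  zero <- matrix(0, n, length(samples))
  fill <- function(m, default) if (is.null(m)) default else m
  as_mat <- function(m) matrix(as.numeric(m), n, length(samples))
  ids <- tibble::tibble(
    group_id = seq_len(n), lead_accession = accessions,
    member_accessions = members, protein_name = names,
    gene_name = NA_character_, is_contaminant = is_contaminant,
    is_reverse = is_reverse, mw_kda = mw_kda, score = score
  )
  greenprot:::pg_table(ids, samples, list(
    intensity = as_mat(intensity), ibaq = as_mat(ibaq), lfq = as_mat(lfq),
    msms = as_mat(fill(msms, zero + 5)),
    unique_peptides = as_mat(fill(unique_peptides, zero + 5)),
    coverage = as_mat(fill(coverage, zero + 50))
  ))
}
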
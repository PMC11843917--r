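# Protein-level quantification: decoy/contaminant filtering, fragment
# iBAQ recalculation, riBAQ / TriBAQ, isoform combination and abundance
# thresholds.
#
# Fragment lead proteins carry a truncated database sequence, which
# inflates iBAQ (fewer theoretical peptides in the denominator than the
# real protein has). Their iBAQ is therefore recalculated as
# raw intensity / TP_max, where TP_max is the theoretical-peptide count
# of a resolved full-length counterpart: a same-name member of the group,
# a same-name lead elsewhere in the dataset, or a user-supplied surrogate
# (e.g. a BLAST hit). Recalculated entries are marked "*" in the working
# protein name and, for orphans, the counterpart's MW replaces the group
# MW downstream.

#' Remove contaminant and reverse (decoy) protein groups
#'
#' @param pg Protein-group tibble.
#' @return List with `kept` (filtered table) and `report` (tibble of
#'   removal counts by reason). Rows flagged as both contaminant and
#'   reverse are removed once and counted as contaminants.
#' @export
filter_decoys_contaminants <- function(pg) {
  con <- pg$is_contaminant
  rev <- pg$is_reverse & !con
  report <- tibble::tibble(
    reason = c("contaminants", "false_positives"),
    n_removed = c(sum(con), sum(rev))
  )
  kept <- pg[!(con | rev), , drop = FALSE]
  attr(kept, "samples") <- pg_samples(pg)
  list(kept = kept, report = report)
}

strip_fragment <- function(name) sub("\\s*\\(Fragment\\)\\s*$", "", name)

is_fragment_name <- function(name) {
  grepl("\\(Fragment\\)\\s*$", name) & !is.na(name)
}

#' Classify protein groups by fragment status
#'
#' Splits groups into three classes: `full` (no fragment annotation),
#' `fragment_with_same_name_full` (annotated `"(Fragment)"`, with a
#' full-length group of the same name in the dataset) and
#' `fragment_orphan` (fragment with no full-length namesake anywhere).
#' Fragment classes get `"*"` appended to the working name to mark the
#' later iBAQ recalculation.
#'
#' @param pg Protein-group tibble.
#' @return The table with added columns `fragment_class` and
#'   `working_name`.
#' @export
mark_fragment_groups <- function(pg) {
  frag <- is_fragment_name(pg$protein_name)
  base <- strip_fragment(pg$protein_name)
  full_names <- unique(pg$protein_name[!frag])
  cls <- dplyr::case_when(
    !frag ~ "full",
    base %in% full_names ~ "fragment_with_same_name_full",
    TRUE ~ "fragment_orphan"
  )
  out <- dplyr::mutate(pg,
    fragment_class = cls,
    working_name = ifelse(frag, paste0(base, "*"), pg$protein_name)
  )
  attr(out, "samples") <- pg_samples(pg)
  out
}

#' Recalculate iBAQ for a fragment protein group
#'
#' `iBAQ_rec = raw intensity / TP_max`, applied protein- and sample-wise;
#' missing intensities stay missing.
#'
#' @param intensity Per-sample raw intensities (numeric, `NA` allowed).
#' @param tp_max Theoretical-peptide count of the resolved full-length
#'   counterpart (>= 1).
#' @return Recalculated iBAQ values.
#' @export
recalc_fragment_ibaq <- function(intensity, tp_max) {
  if (length(tp_max) != 1L || is.na(tp_max) || tp_max < 1)
    stop("invalid resolution: `tp_max` must be a single value >= 1",
         call. = FALSE)
  intensity / tp_max
}

#' Resolve TP_max for a fragment lead protein
#'
#' Search order: (1) a full-length member of the same name inside the
#' group (`in_group`); (2) a full-length lead protein of the same name
#' elsewhere in the dataset (`in_dataset`); (3) a user-supplied surrogate
#' sequence, e.g. a BLAST hit (`surrogate`). TP_max and the replacement
#' MW are computed from the resolved sequence.
#'
#' @param accession Lead accession of the fragment group.
#' @param pg Protein-group tibble (after [mark_fragment_groups()]).
#' @param fasta Search-database sequences as returned by [read_fasta()]
#'   (`desc` holds the protein name).
#' @param surrogates Optional tibble keyed by the fragment `accession`
#'   with a full-length `sequence` and optionally `surrogate_accession`.
#' @param digest A [digest_params()].
#' @return One-row tibble: accession, tp_max, source, surrogate_accession,
#'   mw_used_kda.
#' @export
resolve_tp_max <- function(accession, pg, fasta, surrogates = NULL,
                           digest = digest_params()) {
  row <- pg[pg$lead_accession == accession, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("accession not found (or ambiguous) in table: ", accession,
         call. = FALSE)
  if (!"fragment_class" %in% names(row) ||
      row$fragment_class == "full")
    stop("group is not classified as a fragment: ", accession, call. = FALSE)
  base <- strip_fragment(row$protein_name)
  seq_of <- stats::setNames(fasta$sequence, fasta$accession)
  name_of <- stats::setNames(fasta$desc, fasta$accession)

  result <- function(seq, source, surrogate_accession = NA_character_) {
    tibble::tibble(
      accession = accession,
      tp_max = count_theoretical_peptides(seq, digest),
      source = source,
      surrogate_accession = surrogate_accession,
      mw_used_kda = sequence_mw_kda(seq)
    )
  }

  members <- setdiff(strsplit(row$member_accessions, ";", fixed = TRUE)[[1]],
                     accession)
  hit <- members[!is.na(name_of[members]) & name_of[members] == base]
  if (length(hit) > 0L) {
    tps <- vapply(seq_of[hit], count_theoretical_peptides, integer(1),
                  params = digest)
    best <- hit[which.max(tps)]
    return(result(seq_of[[best]], "in_group"))
  }

  others <- pg[pg$lead_accession != accession &
                 pg$fragment_class == "full" &
                 pg$protein_name == base, , drop = FALSE]
  others <- others[others$lead_accession %in% names(seq_of), , drop = FALSE]
  if (nrow(others) > 0L) {
    tps <- vapply(seq_of[others$lead_accession], count_theoretical_peptides,
                  integer(1), params = digest)
    best <- others$lead_accession[which.max(tps)]
    return(result(seq_of[[best]], "in_dataset"))
  }

  if (!is.null(surrogates) && accession %in% surrogates$accession) {
    srow <- surrogates[surrogates$accession == accession, , drop = FALSE][1, ]
    sacc <- if ("surrogate_accession" %in% names(srow))
      srow$surrogate_accession else NA_character_
    return(result(srow$sequence, "surrogate", sacc))
  }

  stop("unresolved fragment: no full-length counterpart or surrogate for ",
       accession, call. = FALSE)
}

#' Apply fragment iBAQ recalculation across a table
#'
#' Resolves every fragment-classified group with [resolve_tp_max()],
#' replaces its per-sample iBAQ by intensity / TP_max, and (for orphans)
#' replaces the group MW by the resolved counterpart's MW.
#'
#' @inheritParams resolve_tp_max
#' @return List with `pg` (updated table) and `resolutions` (one row per
#'   recalculated group).
#' @export
apply_fragment_recalc <- function(pg, fasta, surrogates = NULL,
                                  digest = digest_params()) {
  stopifnot("fragment_class" %in% names(pg))
  frag_acc <- pg$lead_accession[pg$fragment_class != "full"]
  res <- purrr::map_dfr(frag_acc, resolve_tp_max, pg = pg, fasta = fasta,
                        surrogates = surrogates, digest = digest)
  samples <- pg_samples(pg)
  out <- pg
  for (i in seq_along(frag_acc)) {
    r <- which(out$lead_accession == frag_acc[i])
    intens <- as.numeric(out[r, paste0("intensity.", samples)])
    out[r, paste0("ibaq.", samples)] <-
      as.list(recalc_fragment_ibaq(intens, res$tp_max[i]))
    if (out$fragment_class[r] == "fragment_orphan")
      out$mw_kda[r] <- res$mw_used_kda[i]
  }
  attr(out, "samples") <- samples
  list(pg = out, resolutions = res)
}

#' Relative iBAQ (riBAQ): per-sample molar fractions
#'
#' Divides each iBAQ value by the per-sample sum over non-missing
#' entries, so every sample column sums to 1. Missing values stay
#' missing.
#'
#' @param mat Numeric protein x sample matrix of iBAQ values.
#' @return Matrix of the same shape; attribute `kind = "ribaq"`.
#' @export
compute_ribaq <- function(mat) {
  totals <- colSums(mat, na.rm = TRUE)
  bad <- colSums(!is.na(mat)) == 0L
  if (any(bad))
    stop("sample(s) with no observed values: ",
         paste(colnames(mat)[bad], collapse = ", "), call. = FALSE)
  out <- sweep(mat, 2L, totals, "/")
  attr(out, "kind") <- "ribaq"
  out
}

#' TriBAQ: a protein's mean riBAQ share across SEC fractions
#'
#' `TriBAQ_i = sum_f riBAQ_if / F` with missing values counted as zero,
#' so TriBAQ stays on the riBAQ (molar-fraction) scale and sums to 1 over
#' proteins.
#'
#' @param ribaq riBAQ matrix (fraction columns).
#' @return Named numeric vector of per-protein totals.
#' @export
compute_tribaq <- function(ribaq) {
  if (ncol(ribaq) < 1L) stop("need at least one fraction column", call. = FALSE)
  m <- ribaq
  m[is.na(m)] <- 0
  rowSums(m) / ncol(m)
}

#' Merge isoforms: sum riBAQ over rows sharing a protein name
#'
#' Rows whose working name is identical (after trimming whitespace) are
#' summed per sample; fragment-marked names (trailing `"*"`) never merge
#' with unmarked ones. The merged row is named
#' `"<name> (<n isoforms>)"`. Per-sample totals are conserved exactly.
#'
#' @param ribaq riBAQ matrix with accession row names.
#' @param names Working protein name for each row (same order).
#' @return Merged matrix with a `merge_map` attribute (tibble:
#'   merged_name, members, n_isoforms).
#' @export
combine_isoforms <- function(ribaq, names) {
  stopifnot(length(names) == nrow(ribaq))
  key <- trimws(names)
  groups <- split(seq_len(nrow(ribaq)), key)
  groups <- groups[order(names(groups))]
  out <- matrix(NA_real_, length(groups), ncol(ribaq),
                dimnames = list(NULL, colnames(ribaq)))
  map <- tibble::tibble(merged_name = character(length(groups)),
                        members = character(length(groups)),
                        n_isoforms = integer(length(groups)))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    sub <- ribaq[idx, , drop = FALSE]
    all_na <- colSums(!is.na(sub)) == 0L
    s <- colSums(sub, na.rm = TRUE)
    s[all_na] <- NA_real_
    out[g, ] <- s
    map$merged_name[g] <- paste0(names(groups)[g], " (", length(idx), ")")
    map$members[g] <- paste(rownames(ribaq)[idx], collapse = ";")
    map$n_isoforms[g] <- length(idx)
  }
  rownames(out) <- map$merged_name
  attr(out, "kind") <- "ribaq"
  attr(out, "merge_map") <- map
  out
}

#' Abundance thresholds on riBAQ / TriBAQ
#'
#' Three modes: `global` keeps proteins whose TriBAQ exceeds 0.5%;
#' `fractional` keeps proteins exceeding 2% riBAQ in any single fraction;
#' `shortlist` (the screening criterion) keeps proteins with TriBAQ above
#' 0.5% or riBAQ above 1% in any fraction. Inequalities are strict by
#' default ("above" a threshold).
#'
#' @param ribaq riBAQ matrix.
#' @param mode One of `"global"`, `"fractional"`, `"shortlist"`.
#' @param tribaq Optional precomputed TriBAQ vector.
#' @param thresholds Named list overriding `global` (0.005),
#'   `fractional` (0.02), `shortlist_ribaq` (0.01).
#' @param strict Use strict inequalities (default TRUE).
#' @return Character vector of passing row names.
#' @export
abundance_filter <- function(ribaq,
                             mode = c("global", "fractional", "shortlist"),
                             tribaq = compute_tribaq(ribaq),
                             thresholds = list(), strict = TRUE) {
  mode <- match.arg(mode)
  th <- utils::modifyList(
    list(global = 0.005, fractional = 0.02, shortlist_ribaq = 0.01),
    thresholds)
  gt <- if (strict) `>` else `>=`
  max_ribaq <- apply(ribaq, 1L, function(x)
    if (all(is.na(x))) 0 else max(x, na.rm = TRUE))
  pass <- switch(mode,
    global = gt(tribaq, th$global),
    fractional = gt(max_ribaq, th$fractional),
    shortlist = gt(tribaq, th$global) | gt(max_ribaq, th$shortlist_ribaq)
  )
  rownames(ribaq)[pass]
}
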
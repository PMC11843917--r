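# Readers and writers for the formats the pipeline touches: MaxQuant-style
# protein-group tables (tab-separated) and FASTA sequence files.
#
# Internal representation of a protein-group table: one tibble row per
# group with identification columns plus per-sample quantitative columns
# named "<kind>.<sample>" for kinds intensity, ibaq, lfq, msms,
# unique_peptides, coverage. The sample ids are carried in the "samples"
# attribute. Intensity-like values of 0 are stored as NA: in MaxQuant
# output a zero intensity means "not quantified", not "measured as zero".

PG_KINDS <- c("intensity", "ibaq", "lfq", "msms", "unique_peptides", "coverage")
PG_INTENSITY_KINDS <- c("intensity", "ibaq", "lfq")

#' Column-name mapping for MaxQuant v2.2-style proteinGroups tables
#'
#' Maps the logical columns the pipeline needs onto the header names of a
#' MaxQuant `proteinGroups.txt`. Per-sample columns are located by prefix
#' (e.g. `"iBAQ "` followed by the sample id).
#'
#' @param ... Named overrides for any entry.
#' @return Named list of header names / prefixes.
#' @export
maxquant_dialect <- function(...) {
  d <- list(
    group_id = "id",
    members = "Majority protein IDs",
    protein_name = "Protein names",
    gene_name = "Gene names",
    reverse = "Reverse",
    contaminant = "Potential contaminant",
    mw_kda = "Mol. weight [kDa]",
    score = "Score",
    intensity = "Intensity ",
    ibaq = "iBAQ ",
    lfq = "LFQ intensity ",
    msms = "MS/MS count ",
    unique_peptides = "Unique peptides ",
    coverage = "Sequence coverage [%] "
  )
  utils::modifyList(d, list(...))
}

#' Sample ids of a protein-group table
#' @param pg A protein-group tibble from [read_protein_groups()] or
#'   [generate_protein_groups()].
#' @return Character vector of sample ids.
#' @export
pg_samples <- function(pg) attr(pg, "samples")

#' Extract a protein x sample matrix from a protein-group table
#'
#' @param pg Protein-group tibble.
#' @param what One of `"intensity"`, `"ibaq"`, `"lfq"`, `"msms"`,
#'   `"unique_peptides"`, `"coverage"`.
#' @param rownames_from Column used for row names (default
#'   `"lead_accession"`).
#' @return Numeric matrix, proteins in rows, samples in columns.
#' @export
pg_matrix <- function(pg, what = "ibaq", rownames_from = "lead_accession") {
  what <- match.arg(what, PG_KINDS)
  samples <- pg_samples(pg)
  cols <- paste0(what, ".", samples)
  missing_cols <- setdiff(cols, names(pg))
  if (length(missing_cols) > 0L)
    stop("protein-group table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  m <- as.matrix(pg[cols])
  dimnames(m) <- list(pg[[rownames_from]], samples)
  m
}

# Build the internal tibble from parts; sets the samples attribute and
# checks the ProteinGroup invariants.
pg_table <- function(ids, samples, matrices) {
  stopifnot(all(PG_KINDS %in% names(matrices)))
  tbl <- tibble::as_tibble(ids)
  for (kind in PG_KINDS) {
    m <- matrices[[kind]]
    stopifnot(ncol(m) == length(samples))
    colnames(m) <- paste0(kind, ".", samples)
    tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(m))
  }
  if (anyDuplicated(tbl$group_id))
    stop("duplicate group_id in protein-group table", call. = FALSE)
  lead_in_members <- mapply(
    function(lead, members) lead %in% strsplit(members, ";", fixed = TRUE)[[1]],
    tbl$lead_accession, tbl$member_accessions
  )
  if (!all(lead_in_members))
    stop("lead_accession not contained in member_accessions", call. = FALSE)
  attr(tbl, "samples") <- samples
  tbl
}

#' Read a MaxQuant-style protein-group table
#'
#' @param path Path to a tab-separated proteinGroups file.
#' @param dialect Column mapping, see [maxquant_dialect()].
#' @return Protein-group tibble (see package overview); sample ids in the
#'   `"samples"` attribute. Intensity-like zeros become `NA`.
#' @export
read_protein_groups <- function(path, dialect = maxquant_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, name_repair = "minimal")
  required <- c("group_id", "members", "protein_name", "mw_kda", "score")
  for (key in required) {
    if (!dialect[[key]] %in% names(raw))
      stop("required column missing: '", dialect[[key]], "'", call. = FALSE)
  }

  samples <- character()
  for (kind in PG_KINDS) {
    prefix <- dialect[[kind]]
    hit <- names(raw)[startsWith(names(raw), prefix)]
    found <- substring(hit, nchar(prefix) + 1L)
    if (kind == "intensity") {
      # "Intensity " prefix also matches nothing else in the default
      # dialect, but guard against e.g. "iBAQ peptides"-style columns
      samples <- found
      if (length(samples) == 0L)
        stop("no per-sample columns found for prefix '", prefix, "'",
             call. = FALSE)
    } else if (!setequal(found, samples)) {
      stop("per-sample columns for '", prefix,
           "' do not match the intensity samples", call. = FALSE)
    }
  }

  members <- raw[[dialect$members]]
  lead <- vapply(strsplit(members, ";", fixed = TRUE), `[`, character(1), 1L)
  plus_flag <- function(key) {
    if (!is.null(dialect[[key]]) && dialect[[key]] %in% names(raw)) {
      v <- raw[[dialect[[key]]]]
      !is.na(v) & v == "+"
    } else rep(FALSE, nrow(raw))
  }
  ids <- tibble::tibble(
    group_id = as.integer(raw[[dialect$group_id]]),
    lead_accession = lead,
    member_accessions = members,
    protein_name = raw[[dialect$protein_name]],
    gene_name = if (dialect$gene_name %in% names(raw))
      raw[[dialect$gene_name]] else NA_character_,
    is_contaminant = plus_flag("contaminant") | startsWith(lead, "CON__"),
    is_reverse = plus_flag("reverse") | startsWith(lead, "REV__"),
    mw_kda = as.numeric(raw[[dialect$mw_kda]]),
    score = as.numeric(raw[[dialect$score]])
  )

  matrices <- list()
  for (kind in PG_KINDS) {
    cols <- paste0(dialect[[kind]], samples)
    m <- vapply(raw[cols], as.numeric, numeric(nrow(raw)))
    m <- matrix(m, nrow = nrow(raw))
    if (kind %in% PG_INTENSITY_KINDS) m[!is.na(m) & m == 0] <- NA_real_
    matrices[[kind]] <- m
  }
  pg_table(ids, samples, matrices)
}

#' Write a protein-group table in the MaxQuant dialect
#'
#' Inverse of [read_protein_groups()]: missing intensity-like values are
#' written as 0 (the MaxQuant "not quantified" convention) and flags as
#' `"+"` marks.
#'
#' @param pg Protein-group tibble.
#' @param path Output path.
#' @param dialect Column mapping.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(pg, path, dialect = maxquant_dialect()) {
  samples <- pg_samples(pg)
  out <- tibble::tibble(.rows = nrow(pg))
  out[[dialect$group_id]] <- pg$group_id
  out[[dialect$members]] <- pg$member_accessions
  out[[dialect$protein_name]] <- pg$protein_name
  out[[dialect$gene_name]] <- pg$gene_name
  out[[dialect$reverse]] <- ifelse(pg$is_reverse, "+", "")
  out[[dialect$contaminant]] <- ifelse(pg$is_contaminant, "+", "")
  out[[dialect$mw_kda]] <- pg$mw_kda
  out[[dialect$score]] <- pg$score
  for (kind in PG_KINDS) {
    m <- pg_matrix(pg, kind)
    if (kind %in% PG_INTENSITY_KINDS) m[is.na(m)] <- 0
    colnames(m) <- paste0(dialect[[kind]], samples)
    for (cn in colnames(m)) out[[cn]] <- m[, cn]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a FASTA file of protein sequences
#'
#' @param path FASTA path.
#' @return Tibble with `accession` (first whitespace-delimited header
#'   token), `desc` (remainder of the header, `NA` if absent) and
#'   `sequence` (uppercased, wrapped lines joined).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path, call. = FALSE)
  headers <- names(set)
  accession <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), NA_character_)
  tibble::tibble(accession = accession, desc = desc,
                 sequence = unname(toupper(as.character(set))))
}

#' Write protein sequences to FASTA
#'
#' @param fasta Tibble with `accession`, optional `desc`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(fasta, path) {
  set <- Biostrings::AAStringSet(fasta$sequence)
  desc <- if ("desc" %in% names(fasta)) fasta$desc else NA_character_
  names(set) <- ifelse(is.na(desc), fasta$accession,
                       paste(fasta$accession, desc))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
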
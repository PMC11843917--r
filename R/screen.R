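# Candidate antioxidant screening.
#
# Proteins are first predicted as potential antioxidants from GO terms
# and annotation keywords, then taken through a three-step filter:
# (1) cross-reference against proteins identified in the crude
# fractions, (2) a 3-of-4 identification-confidence filter on the green
# juice triplicates, (3) an abundance filter on the fractionated juice
# (TriBAQ above 0.5% or riBAQ above 1% in any fraction).

#' Screening criteria
#'
#' Defaults are the GO terms and keywords used for in-silico antioxidant
#' prediction, and the confidence/abundance thresholds of the three-step
#' filter: a protein-level search-engine score of at least 40,
#' identification by MS/MS, at least 5% sequence coverage and at least
#' two unique peptides each in at least 2 of 3 juice replicates (3 of
#' the 4 criteria required), and the shortlist abundance rule.
#'
#' @param ... Named overrides for any entry.
#' @return List of class `screen_criteria`.
#' @export
screen_criteria <- function(...) {
  crit <- list(
    go_ids = c("GO:0034599", "GO:0009055", "GO:0042542", "GO:0006979"),
    keywords = c(
      "Heme binding", "oxidoreductase activity",
      "glutathione transferase activity", "electron transfer activity",
      "peroxidase activity", "lactoperoxidase activity",
      "metal ion binding", "chaperone activity", "iron", "oxidative",
      "superoxide", "transition", "proton", "ferri", "ferre"
    ),
    score_min = 40,
    replicate_min = 2L,
    msms_min = 1L,
    coverage_min_pct = 5,
    unique_peptides_min = 2L,
    criteria_required = 3L,
    tribaq_min = 0.005,
    ribaq_any_min = 0.01
  )
  crit <- utils::modifyList(crit, list(...))
  structure(crit, class = "screen_criteria")
}

parse_semi <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else
    strsplit(x, ";", fixed = TRUE)[[1]] |> trimws()
}

# TRUE if any of the accessions carries a listed GO id or a term that
# contains one of the criteria keywords (case-insensitive substring).
annotation_hit <- function(accessions, annotations, criteria) {
  rows <- annotations[annotations$accession %in% accessions, , drop = FALSE]
  if (nrow(rows) == 0L) return(FALSE)
  go <- unlist(lapply(rows$go_ids, parse_semi))
  if (length(intersect(go, criteria$go_ids)) > 0L) return(TRUE)
  terms <- tolower(unlist(lapply(rows$keywords, parse_semi)))
  if (length(terms) == 0L) return(FALSE)
  any(vapply(tolower(criteria$keywords), function(kw)
    any(grepl(kw, terms, fixed = TRUE)), logical(1)))
}

#' GO/keyword antioxidant prediction filter
#'
#' A protein passes if any of its lead accessions carries one of the
#' criteria GO ids, or any annotated term (GO term name, UniProt
#' keyword, free-text function) contains one of the criteria keywords as
#' a case-insensitive substring. Proteins without annotation fail.
#'
#' @param proteins Tibble with `protein` (name) and `accessions`
#'   (semicolon-joined lead accessions).
#' @param annotations Tibble with `accession`, `go_ids`
#'   (semicolon-joined), `keywords` (semicolon-joined term texts).
#' @param criteria A [screen_criteria()].
#' @return The subset of `proteins` that passes.
#' @export
go_keyword_filter <- function(proteins, annotations,
                              criteria = screen_criteria()) {
  pass <- vapply(proteins$accessions, function(a)
    annotation_hit(parse_semi(a), annotations, criteria), logical(1))
  proteins[pass, , drop = FALSE]
}

#' Cross-reference filter against crude-fraction identifications
#'
#' Retains proteins with at least one lead accession identified in the
#' crude-fraction analysis (the crude set is expected to be built with
#' the 2-of-3 replicate-presence rule).
#'
#' @param proteins Tibble with `protein` and `accessions`.
#' @param crude_identifications Character vector of crude accessions.
#' @return The retained subset.
#' @export
cross_reference_filter <- function(proteins, crude_identifications) {
  if (length(crude_identifications) == 0L) {
    warning("crude identification set is empty; all proteins removed",
            call. = FALSE)
    return(proteins[0, , drop = FALSE])
  }
  keep <- vapply(proteins$accessions, function(a)
    any(parse_semi(a) %in% crude_identifications), logical(1))
  proteins[keep, , drop = FALSE]
}

#' Identification-confidence filter (3 of 4 criteria)
#'
#' Per protein group, evaluates: (1) protein-level score at least
#' `score_min`; (2) MS/MS identification (`msms_count >= 1`) in at least
#' 2 of the 3 juice replicates; (3) sequence coverage at least 5% in at
#' least 2 of 3; (4) at least 2 unique peptides in at least 2 of 3. The
#' group passes when at least `criteria_required` (default 3) hold.
#'
#' @param pg Protein-group tibble covering the juice replicates.
#' @param juice_samples The 3 juice replicate sample ids.
#' @param criteria A [screen_criteria()].
#' @return Tibble: lead_accession, c_score, c_msms, c_coverage,
#'   c_unique, n_met, pass.
#' @export
confidence_filter <- function(pg, juice_samples,
                              criteria = screen_criteria()) {
  if (length(juice_samples) < 3L)
    stop("confidence filter requires 3 juice replicates", call. = FALSE)
  msms <- pg_matrix(pg, "msms")[, juice_samples, drop = FALSE]
  cov <- pg_matrix(pg, "coverage")[, juice_samples, drop = FALSE]
  uniq <- pg_matrix(pg, "unique_peptides")[, juice_samples, drop = FALSE]
  rep_rule <- function(m, threshold)
    rowSums(m >= threshold, na.rm = TRUE) >= criteria$replicate_min
  res <- tibble::tibble(
    lead_accession = pg$lead_accession,
    c_score = pg$score >= criteria$score_min,
    c_msms = rep_rule(msms, criteria$msms_min),
    c_coverage = rep_rule(cov, criteria$coverage_min_pct),
    c_unique = rep_rule(uniq, criteria$unique_peptides_min)
  )
  res$n_met <- rowSums(res[c("c_score", "c_msms", "c_coverage", "c_unique")])
  res$pass <- res$n_met >= criteria$criteria_required
  res
}

#' Run the full antioxidant screen
#'
#' Applies, in order: GO/keyword prediction, cross-reference against
#' crude identifications, the 3-of-4 confidence filter (a protein passes
#' if any of its lead accessions passes), and the shortlist abundance
#' rule (TriBAQ above 0.5% or riBAQ above 1% in any fraction). All four
#' flags are also reported per protein; the shortlist is the set with
#' all four true. Optional literature categories (direct antioxidant
#' "A", indirect "I", none "N") are attached from `category_map`.
#'
#' @param proteins Tibble with `protein` (merged name) and `accessions`.
#' @param ribaq Merged riBAQ matrix over SEC fractions, rows named by
#'   `protein`.
#' @param annotations Annotation tibble (see [go_keyword_filter()]).
#' @param crude_identifications Crude accession set.
#' @param juice_pg Protein-group tibble for the crude juice triplicates.
#' @param juice_samples The 3 juice replicate sample ids.
#' @param criteria A [screen_criteria()].
#' @param category_map Optional tibble `protein`, `category`.
#' @return List: `result` (per-protein flags, shortlisted, category) and
#'   `funnel` (stage, n_remaining).
#' @export
run_screen <- function(proteins, ribaq, annotations, crude_identifications,
                       juice_pg, juice_samples,
                       criteria = screen_criteria(), category_map = NULL) {
  go_pass <- go_keyword_filter(proteins, annotations, criteria)
  xref_pass <- cross_reference_filter(go_pass, crude_identifications)
  conf <- confidence_filter(juice_pg, juice_samples, criteria)
  conf_by_acc <- stats::setNames(conf$pass, conf$lead_accession)
  acc_pass <- function(a) {
    accs <- parse_semi(a)
    known <- accs[accs %in% names(conf_by_acc)]
    length(known) > 0L && any(conf_by_acc[known])
  }

  tribaq <- compute_tribaq(ribaq)
  short_names <- abundance_filter(ribaq, "shortlist", tribaq,
                                  thresholds = list(
                                    global = criteria$tribaq_min,
                                    shortlist_ribaq = criteria$ribaq_any_min))
  # merged rows carry an "(n)" isoform suffix; match on the bare name too
  bare <- sub(" \\([0-9]+\\)$", "", rownames(ribaq))

  result <- dplyr::mutate(proteins,
    pass_go = .data$protein %in% go_pass$protein,
    pass_crossref = .data$protein %in% xref_pass$protein,
    pass_confidence = vapply(.data$accessions, acc_pass, logical(1)),
    pass_abundance = .data$protein %in% short_names |
      .data$protein %in% bare[rownames(ribaq) %in% short_names],
    shortlisted = .data$pass_go & .data$pass_crossref &
      .data$pass_confidence & .data$pass_abundance
  )
  if (!is.null(category_map))
    result <- dplyr::left_join(result, category_map, by = "protein")

  conf_stage <- xref_pass[vapply(xref_pass$accessions, acc_pass, logical(1)), ]
  final <- result$protein[result$shortlisted]
  funnel <- tibble::tibble(
    stage = c("named_proteins", "go_keyword", "cross_reference",
              "confidence", "abundance_shortlist"),
    n_remaining = c(nrow(proteins), nrow(go_pass), nrow(xref_pass),
                    nrow(conf_stage), length(final))
  )
  list(result = result, funnel = funnel, confidence_detail = conf)
}
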
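# End-to-end orchestration: simulate inputs to disk, validate a
# configuration, and run the staged analysis (filter -> fragment
# recalculation -> riBAQ -> isoform merge -> GO screen -> three-step
# filter -> crude enrichment), emitting every intermediate table and a
# per-stage count summary (the "filtering funnel").

#' Write a complete synthetic input bundle to disk
#'
#' Generates a proteome, SEC- and crude-design protein-group tables,
#' annotations, SEC calibration inputs and assay plates, and writes them
#' as plain-text files (FASTA / tab-separated) together with a
#' ground-truth sidecar table.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_proteins Proteome size.
#' @param seed Integer seed controlling every generator.
#' @param sec_fractions SEC fraction indices.
#' @param ... Passed to [generate_proteome()].
#' @return Named list of written paths, invisibly.
#' @export
simulate_inputs <- function(out_dir, n_proteins = 200L, seed = 1L,
                            sec_fractions = 1:15, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prot <- generate_proteome(n_proteins, seed = seed, ...)
  sec <- generate_protein_groups(prot$truth, sec_design(sec_fractions),
                                 seed = seed + 1L)
  crude <- generate_protein_groups(prot$truth, crude_design(),
                                   seed = seed + 2L)
  cal <- generate_sec_inputs(seed = seed + 3L)
  plate <- generate_plate(true_ec50_ugml = 50, regime = "linear",
                          top_conc = 100, seed = seed + 4L)
  ann <- tibble::tibble(
    accession = prot$truth$proteins$accession,
    go_ids = "", keywords = ""
  )
  paths <- list(
    fasta = file.path(out_dir, "proteome.fasta"),
    sec_protein_groups = file.path(out_dir, "proteinGroups_sec.txt"),
    crude_protein_groups = file.path(out_dir, "proteinGroups_crude.txt"),
    annotations = file.path(out_dir, "annotations.tsv"),
    standards = file.path(out_dir, "sec_standards.tsv"),
    fractions = file.path(out_dir, "sec_fractions.tsv"),
    plate = file.path(out_dir, "plate_dpph.tsv"),
    truth = file.path(out_dir, "ground_truth.tsv")
  )
  write_fasta(prot$fasta, paths$fasta)
  write_protein_groups(sec, paths$sec_protein_groups)
  write_protein_groups(crude, paths$crude_protein_groups)
  readr::write_tsv(ann, paths$annotations, progress = FALSE)
  readr::write_tsv(cal$standards, paths$standards, progress = FALSE)
  readr::write_tsv(cal$fractions, paths$fractions, progress = FALSE)
  readr::write_tsv(plate, paths$plate, progress = FALSE)
  readr::write_tsv(
    dplyr::select(prot$truth$proteins, -"sequence"),
    paths$truth, progress = FALSE)
  invisible(paths)
}

#' Pipeline configuration
#'
#' Collects input paths, thresholds and the seed for a full run. See
#' [validate_config()] for the checks applied.
#'
#' @param sec_protein_groups,crude_protein_groups,fasta,annotations
#'   Input paths.
#' @param surrogates Optional FASTA of surrogate full-length sequences
#'   for orphan fragments (headers keyed by the fragment accession).
#' @param juice_samples The 3 crude juice replicate sample ids.
#' @param crude_groups Named list: fraction -> replicate sample ids.
#' @param criteria A [screen_criteria()].
#' @param digest A [digest_params()].
#' @param fdr,log2fc_min Differential-abundance thresholds.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sec_protein_groups, crude_protein_groups,
                            fasta, annotations, surrogates = NULL,
                            juice_samples = paste0("juice_", 1:3),
                            crude_groups = list(
                              grass = paste0("grass_", 1:3),
                              pulp = paste0("pulp_", 1:3),
                              juice = paste0("juice_", 1:3)),
                            criteria = screen_criteria(),
                            digest = digest_params(),
                            fdr = 0.05, log2fc_min = 1,
                            seed = 1L, out_dir = tempfile("greenprot_run_")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks that every referenced file exists, thresholds are positive and
#' the design names enough replicates; returns a report rather than
#' stopping.
#'
#' @param config A [pipeline_config()].
#' @return Tibble: level (`"error"`/`"warning"`), message. Zero rows
#'   mean a clean configuration.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  rep <- list()
  note <- function(level, msg) rep[[length(rep) + 1L]] <<-
    tibble::tibble(level = level, message = msg)
  for (key in c("sec_protein_groups", "crude_protein_groups", "fasta",
                "annotations")) {
    p <- config[[key]]
    if (is.null(p) || !file.exists(p))
      note("error", paste0("missing input file for `", key, "`: ",
                           if (is.null(p)) "<unset>" else p))
  }
  if (!is.null(config$surrogates) && !file.exists(config$surrogates))
    note("error", paste0("missing surrogate FASTA: ", config$surrogates))
  for (key in c("fdr", "log2fc_min")) {
    if (config[[key]] <= 0)
      note("error", paste0("threshold `", key, "` must be positive"))
  }
  if (length(config$juice_samples) < 3L)
    note("warning", "fewer than 3 juice replicates named; confidence filter needs 3")
  short <- names(config$crude_groups)[lengths(config$crude_groups) < 3L]
  if (length(short) > 0L)
    note("warning", paste0("fraction(s) with fewer than 3 replicates: ",
                           paste(short, collapse = ", ")))
  if (length(rep) == 0L)
    tibble::tibble(level = character(), message = character())
  else dplyr::bind_rows(rep)
}

#' Run the staged analysis end-to-end
#'
#' Executes: read inputs; remove contaminants/decoys; classify and
#' recalculate fragment iBAQ; riBAQ; isoform merge; TriBAQ; crude
#' replicate-presence sets; GO/keyword + three-step screen; LFQ
#' normalization, NMAR imputation and pairwise differential abundance.
#' Every intermediate table is written to `config$out_dir` and the
#' per-stage row counts are returned as the filtering funnel.
#' Deterministic given `config$seed`.
#'
#' @param config A validated [pipeline_config()].
#' @return List of result objects (see elements of the return value).
#' @export
run_pipeline <- function(config) {
  val <- validate_config(config)
  if (any(val$level == "error"))
    stop("configuration errors:\n",
         paste(val$message[val$level == "error"], collapse = "\n"),
         call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(x, name)
    readr::write_tsv(x, file.path(config$out_dir, paste0(name, ".tsv")),
                     progress = FALSE)

  fasta <- read_fasta(config$fasta)
  surrogates <- if (!is.null(config$surrogates))
    read_fasta(config$surrogates)
  sec_raw <- read_protein_groups(config$sec_protein_groups)
  crude_raw <- read_protein_groups(config$crude_protein_groups)

  sec_f <- filter_decoys_contaminants(sec_raw)
  crude_f <- filter_decoys_contaminants(crude_raw)
  emit(sec_f$report, "sec_removal_report")
  emit(crude_f$report, "crude_removal_report")

  sec_pg <- mark_fragment_groups(sec_f$kept)
  rec <- apply_fragment_recalc(sec_pg, fasta, surrogates, config$digest)
  emit(rec$resolutions, "fragment_resolutions")
  sec_pg <- rec$pg

  ribaq <- compute_ribaq(pg_matrix(sec_pg, "ibaq"))
  merged <- combine_isoforms(ribaq, sec_pg$working_name)
  tribaq <- compute_tribaq(merged)
  emit(tibble::tibble(protein = rownames(merged),
                      tribaq = tribaq,
                      tibble::as_tibble(merged)), "sec_ribaq_merged")

  crude_sets <- replicate_presence_filter(
    pg_matrix(crude_f$kept, "intensity"), config$crude_groups)
  emit(crude_sets$intersections, "crude_identification_overlap")
  crude_ids <- unique(unlist(crude_sets$sets))

  map <- attr(merged, "merge_map")
  proteins <- tibble::tibble(
    protein = map$merged_name,
    accessions = map$members
  )
  annotations <- readr::read_tsv(config$annotations,
                                 col_types = readr::cols(.default = "c"),
                                 progress = FALSE)
  screen <- run_screen(proteins, merged, annotations, crude_ids,
                       crude_f$kept, config$juice_samples, config$criteria)
  emit(screen$result, "screen_result")
  emit(screen$funnel, "screen_funnel")

  lfq <- pg_matrix(crude_f$kept, "lfq")
  norm <- normalize_log_lfq(lfq)
  imp <- impute_nmar(norm, seed = config$seed)
  pairs <- utils::combn(names(config$crude_groups), 2L, simplify = FALSE)
  differential <- purrr::map_dfr(pairs, function(pp) {
    tibble::tibble(comparison = paste(pp, collapse = " vs "),
                   pairwise_differential(imp$mat,
                                         config$crude_groups[[pp[1]]],
                                         config$crude_groups[[pp[2]]],
                                         mask = imp$mask,
                                         fdr = config$fdr,
                                         log2fc_min = config$log2fc_min))
  })
  emit(differential, "crude_differential")

  funnel <- tibble::tibble(
    stage = c("sec_groups_raw", "sec_groups_filtered",
              "sec_merged_names", "crude_groups_raw",
              "crude_groups_filtered", screen$funnel$stage),
    n = c(nrow(sec_raw), nrow(sec_f$kept), nrow(merged), nrow(crude_raw),
          nrow(crude_f$kept), screen$funnel$n_remaining)
  )
  emit(funnel, "pipeline_funnel")

  list(funnel = funnel, sec_pg = sec_pg, ribaq_merged = merged,
       tribaq = tribaq, crude_sets = crude_sets, screen = screen,
       differential = differential, removal = list(
         sec = sec_f$report, crude = crude_f$report),
       resolutions = rec$resolutions, out_dir = config$out_dir,
       seed = config$seed)
}
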
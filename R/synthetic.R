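# Synthetic-data generators.
#
# Every input the pipeline consumes can be generated here with recorded
# ground truth: a proteome FASTA with isoform families, fragment entries,
# contaminants and decoys; MaxQuant-style protein-group tables for crude
# triplicates or SEC fractions; microplate absorbance layouts for the
# DPPH and iron-chelation assays; and SEC standards/fraction volumes from
# a known calibration line. Downstream estimators can then be validated
# against the truth (noise-free limits invert them exactly).

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

AA20 <- names(MONO_RESIDUE_MASS)

# Vocabulary for plausible plant-protein annotations; combined with an
# index to keep base names unique.
PROTEIN_NOUNS <- c(
  "Ribulose bisphosphate carboxylase", "Chlorophyll a-b binding protein",
  "ATP synthase subunit", "Thioredoxin-dependent peroxiredoxin",
  "Superoxide dismutase", "Ferredoxin-NADP reductase",
  "L-ascorbate peroxidase", "Glutathione S-transferase", "Peroxidase",
  "Lactoylglutathione lyase", "Sedoheptulose-bisphosphatase",
  "Ribulose-phosphate epimerase", "Fructose-bisphosphate aldolase",
  "Glyceraldehyde-3-phosphate dehydrogenase", "Phosphoglycerate kinase",
  "Carbonic anhydrase", "Plastocyanin", "Ferredoxin", "Chitinase",
  "Beta-glucosidase", "Pectinesterase", "Malate dehydrogenase",
  "Elongation factor", "Heat shock protein", "Actin", "Tubulin",
  "Photosystem I reaction center subunit", "Photosystem II protein",
  "Cytochrome b6-f complex subunit", "Glutamine synthetase"
)

random_sequences <- function(n, min_len = 80L, max_len = 1200L) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(l) paste(sample(AA20, l, replace = TRUE),
                                 collapse = ""), character(1))
}

#' Generate a synthetic proteome with recorded ground truth
#'
#' Produces random protein sequences with realistic annotation structure:
#' isoform families (distinct accessions sharing a protein name),
#' fragment entries (truncated copies of a parent, annotated
#' `"(Fragment)"`), contaminant (`CON__`) and decoy (`REV__`) records.
#' True molar abundances and assembled-complex molecular weights are
#' recorded for downstream validation.
#'
#' @param n_proteins Number of target proteome entries (>= 10).
#' @param isoform_rate Fraction of entries that reuse an existing protein
#'   name, forming an isoform family (in `[0, 1)`).
#' @param fragment_rate Fraction of entries that are truncated fragments
#'   of another entry (in `[0, 1)`).
#' @param contaminant_count,decoy_count Extra `CON__`/`REV__` records.
#' @param n_enriched Number of entries with a nonzero true log2 fold
#'   change between green juice and grass in crude designs.
#' @param enriched_log2fc True log2 fold change for the enriched set.
#' @param seed Integer RNG seed.
#' @return List with `fasta` (tibble: accession, desc, sequence) and
#'   `truth` (list with `proteins` tibble, `enriched` tibble, `seed`).
#' @export
generate_proteome <- function(n_proteins, isoform_rate = 0.1,
                              fragment_rate = 0.1,
                              contaminant_count = 0L, decoy_count = 0L,
                              n_enriched = 0L, enriched_log2fc = 2,
                              seed = 1L) {
  if (n_proteins < 10L) stop("`n_proteins` must be >= 10", call. = FALSE)
  if (isoform_rate < 0 || isoform_rate >= 1 ||
      fragment_rate < 0 || fragment_rate >= 1)
    stop("rates must lie in [0, 1)", call. = FALSE)

  with_seed(seed, {
    n <- as.integer(n_proteins)
    n_frag <- as.integer(floor(fragment_rate * n))
    n_iso <- as.integer(floor(isoform_rate * n))
    n_base <- n - n_frag

    # unique base names for non-fragment entries; isoform members reuse one
    pool_n <- n_base - n_iso
    noun <- PROTEIN_NOUNS[((seq_len(pool_n) - 1L) %% length(PROTEIN_NOUNS)) + 1L]
    base_names <- paste(noun, seq_len(pool_n))
    name_of <- c(base_names,
                 if (n_iso > 0L) sample(base_names, n_iso, replace = TRUE))
    name_of <- sample(name_of)  # shuffle family positions

    accession <- sprintf("GP%05d", seq_len(n))
    sequence <- random_sequences(n_base)
    is_fragment <- c(rep(FALSE, n_base), rep(TRUE, n_frag))

    fragment_of <- rep(NA_character_, n)
    name <- c(name_of, rep(NA_character_, n_frag))
    if (n_frag > 0L) {
      parents <- sample(seq_len(n_base), n_frag, replace = TRUE)
      frag_seq <- vapply(parents, function(p) {
        full <- sequence[p]
        keep <- max(30L, floor(nchar(full) * stats::runif(1, 0.3, 0.7)))
        substr(full, 1L, keep)
      }, character(1))
      sequence <- c(sequence, frag_seq)
      fragment_of[(n_base + 1L):n] <- accession[parents]
      name[(n_base + 1L):n] <- paste0(name_of[parents], " (Fragment)")
    }

    mw <- vapply(sequence, sequence_mw_kda, numeric(1), USE.NAMES = FALSE)
    multimer <- sample(c(1, 1, 1, 2, 4, 8, 16), n, replace = TRUE)
    true_abundance <- stats::rlnorm(n, meanlog = log(100), sdlog = 1.5)

    enriched <- tibble::tibble(accession = character(), log2fc = numeric())
    if (n_enriched > 0L) {
      if (enriched_log2fc == 0) stop("`enriched_log2fc` must be nonzero",
                                     call. = FALSE)
      idx <- sample(which(!is_fragment), min(n_enriched, n_base))
      enriched <- tibble::tibble(accession = accession[idx],
                                 log2fc = enriched_log2fc)
    }

    proteins <- tibble::tibble(
      accession = accession, name = name,
      base_name = sub(" \\(Fragment\\)$", "", name),
      is_fragment = is_fragment, fragment_of = fragment_of,
      is_contaminant = FALSE, is_reverse = FALSE,
      sequence = sequence, mw_kda = mw,
      complex_mw_kda = mw * multimer,
      true_abundance = true_abundance
    )

    if (contaminant_count > 0L) {
      cseq <- random_sequences(contaminant_count)
      proteins <- dplyr::bind_rows(proteins, tibble::tibble(
        accession = sprintf("CON__K%04d", seq_len(contaminant_count)),
        name = paste("Keratin, type II cytoskeletal", seq_len(contaminant_count)),
        base_name = name, is_fragment = FALSE, fragment_of = NA_character_,
        is_contaminant = TRUE, is_reverse = FALSE, sequence = cseq,
        mw_kda = vapply(cseq, sequence_mw_kda, numeric(1), USE.NAMES = FALSE),
        complex_mw_kda = mw_kda, true_abundance =
          stats::rlnorm(contaminant_count, log(10), 1)
      ))
    }
    if (decoy_count > 0L) {
      src <- sample(seq_len(n), decoy_count, replace = TRUE)
      rseq <- vapply(strsplit(sequence[src], ""), function(x)
        paste(rev(x), collapse = ""), character(1))
      proteins <- dplyr::bind_rows(proteins, tibble::tibble(
        accession = paste0("REV__", accession[src]),
        name = paste("Reversed", name[src]),
        base_name = name, is_fragment = FALSE, fragment_of = NA_character_,
        is_contaminant = FALSE, is_reverse = TRUE, sequence = rseq,
        mw_kda = vapply(rseq, sequence_mw_kda, numeric(1), USE.NAMES = FALSE),
        complex_mw_kda = mw_kda,
        true_abundance = stats::rlnorm(decoy_count, log(5), 1)
      ))
    }
    if (anyDuplicated(proteins$accession))
      stop("internal error: duplicate accessions generated", call. = FALSE)

    fasta <- tibble::tibble(accession = proteins$accession,
                            desc = proteins$name,
                            sequence = proteins$sequence)
    list(fasta = fasta,
         truth = list(proteins = proteins, enriched = enriched, seed = seed))
  })
}

#' Sample design for a crude-fraction (grass/pulp/juice) experiment
#' @param fractions Fraction labels.
#' @param replicates Replicates per fraction.
#' @export
crude_design <- function(fractions = c("grass", "pulp", "juice"),
                         replicates = 3L) {
  if (length(fractions) == 0L) stop("design names no samples", call. = FALSE)
  tibble::tibble(
    sample = paste0(rep(fractions, each = replicates), "_",
                    rep(seq_len(replicates), length(fractions))),
    fraction = rep(fractions, each = replicates),
    replicate = rep(seq_len(replicates), length(fractions)),
    kind = "crude"
  )
}

#' Sample design for a SEC fractionation experiment
#'
#' Each fraction index is one sample. The elution position of a protein
#' complex is a linear function of log10 molecular weight over
#' `mw_range_kda`, emulating a calibrated size-exclusion column.
#'
#' @param fractions Integer fraction indices.
#' @param mw_range_kda MW (kDa) eluting at the first and last fraction.
#' @export
sec_design <- function(fractions = 1:15, mw_range_kda = c(600, 0.05)) {
  if (length(fractions) == 0L) stop("design names no samples", call. = FALSE)
  d <- tibble::tibble(
    sample = sprintf("F%02d", fractions),
    fraction = fractions,
    kind = "sec"
  )
  attr(d, "mw_range_kda") <- mw_range_kda
  d
}

#' Missing-value model for synthetic intensities
#'
#' Not-missing-at-random: the probability that a cell is missing
#' decreases with its (log10) intensity. `mode = "logistic"` uses
#' `plogis(-slope * (log10(I) - mid))`; `mode = "threshold"` deletes every
#' value below `limit`; `mode = "none"` keeps all values.
#'
#' @param mode One of `"none"`, `"logistic"`, `"threshold"`.
#' @param mid Log10-intensity of 50% missingness (logistic mode).
#' @param slope Steepness of the logistic curve (per log10 unit).
#' @param limit Intensity threshold (threshold mode).
#' @export
missing_model <- function(mode = c("none", "logistic", "threshold"),
                          mid = 1, slope = 2, limit = 0) {
  mode <- match.arg(mode)
  list(mode = mode, mid = mid, slope = slope, limit = limit)
}

miss_prob <- function(intensity, model) {
  switch(model$mode,
    none = rep(0, length(intensity)),
    logistic = stats::plogis(-model$slope * (log10(intensity) - model$mid)),
    threshold = as.numeric(intensity < model$limit)
  )
}

#' Generate a MaxQuant-style protein-group table from ground truth
#'
#' Per-sample raw intensities are log-normal around
#' `true_abundance x theoretical-peptide count`, so that iBAQ (intensity
#' divided by peptide count) recovers molar abundance. In SEC designs,
#' intensities follow a Gaussian elution profile over fraction index
#' centred at the position implied by the assembled-complex MW. In crude
#' designs, enriched-set proteins have their juice mean offset by the
#' true log2 fold change. MS/MS counts, unique peptides, sequence
#' coverage and the protein score increase monotonically with abundance.
#'
#' @param truth Ground truth from [generate_proteome()].
#' @param design A [crude_design()] or [sec_design()] tibble.
#' @param cv Replicate coefficient of variation of intensities (>= 0).
#' @param missingness A [missing_model()].
#' @param elution_sd SD of the SEC elution profile, in fraction indices.
#' @param digest A [digest_params()] used for the iBAQ denominator.
#' @param seed Integer RNG seed.
#' @return Protein-group tibble (same shape as [read_protein_groups()]
#'   output) with the per-protein expectations in attribute `"expected"`.
#' @export
generate_protein_groups <- function(truth, design, cv = 0.15,
                                    missingness = missing_model("none"),
                                    elution_sd = 1.5,
                                    digest = digest_params(),
                                    seed = 1L) {
  if (!all(c("sample", "kind") %in% names(design)) || nrow(design) == 0L)
    stop("design names no samples", call. = FALSE)
  if (cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  pr <- truth$proteins
  samples <- design$sample

  with_seed(seed, {
    tp <- vapply(pr$sequence, function(s)
      count_theoretical_peptides(s, digest), integer(1), USE.NAMES = FALSE)
    tp <- pmax(tp, 1L)

    n <- nrow(pr)
    expected <- matrix(pr$true_abundance * tp, n, length(samples),
                       dimnames = list(pr$accession, samples))

    if (design$kind[1] == "sec") {
      rng <- attr(design, "mw_range_kda")
      f <- design$fraction
      # linear map log10(MW) -> fraction index over the design's range
      ctr <- f[1] + (log10(pr$complex_mw_kda) - log10(rng[1])) *
        (f[length(f)] - f[1]) / (log10(rng[2]) - log10(rng[1]))
      prof <- outer(ctr, f, function(c, x) exp(-(x - c)^2 / (2 * elution_sd^2)))
      expected <- expected * prof
      attr(expected, "center_fraction") <- ctr
    } else if (nrow(truth$enriched) > 0L) {
      in_juice <- design$fraction == "juice"
      hit <- match(truth$enriched$accession, pr$accession)
      expected[hit, in_juice] <-
        expected[hit, in_juice] * 2^truth$enriched$log2fc
    }

    sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
    noise <- if (cv > 0)
      matrix(stats::rlnorm(n * length(samples), -sdlog^2 / 2, sdlog),
             n, length(samples))
    else matrix(1, n, length(samples))
    intensity <- expected * noise

    pmiss <- matrix(miss_prob(pmax(intensity, .Machine$double.xmin),
                              missingness), n, length(samples))
    drop <- matrix(stats::runif(n * length(samples)) < pmiss,
                   n, length(samples))
    intensity[drop | intensity == 0] <- NA_real_

    ibaq <- intensity / tp
    lfq <- intensity

    li <- log10(pmax(intensity, 1e-12))
    msms <- ifelse(is.na(intensity), 0, pmax(1, round(1.5 * li)))
    uniq <- ifelse(is.na(intensity), 0,
                   pmin(tp, pmax(1, round(tp * stats::plogis(li - 1)))))
    cover <- ifelse(is.na(intensity), 0,
                    pmin(100, round(100 * stats::plogis(li - 2), 1)))
    score <- pmin(323, 40 * log10(1 + rowMeans(intensity, na.rm = TRUE)))
    score[is.nan(score)] <- 0

    ids <- tibble::tibble(
      group_id = seq_len(n) - 1L,
      lead_accession = pr$accession,
      member_accessions = pr$accession,
      protein_name = pr$name,
      gene_name = NA_character_,
      is_contaminant = pr$is_contaminant,
      is_reverse = pr$is_reverse,
      mw_kda = pr$mw_kda,
      score = score
    )
    pg <- pg_table(ids, samples, list(
      intensity = intensity, ibaq = ibaq, lfq = lfq, msms = msms,
      unique_peptides = uniq, coverage = cover
    ))
    attr(pg, "expected") <- expected
    attr(pg, "tp") <- stats::setNames(tp, pr$accession)
    attr(pg, "design") <- design
    pg
  })
}

#' Generate a microplate dilution series with known EC50
#'
#' Builds a long-format plate table whose absorbances, when pushed
#' through the activity formula and the two-regime EC50 fit, recover
#' `true_ec50_ugml`. In the linear regime activity rises linearly through
#' 50% at the EC50; in the logarithmic regime activity is linear in
#' log-concentration (points above 80% activity occur, which is what
#' selects that fit downstream).
#'
#' @param true_ec50_ugml True EC50 in ug/mL.
#' @param regime `"linear"` or `"logarithmic"` generating curve.
#' @param top_conc Highest concentration in the series (ug/mL). Default
#'   places the top point at 75% activity (linear) or just above 80%
#'   (logarithmic), so each generating curve lands in its own fit
#'   branch.
#' @param dilution_factor Serial dilution factor (> 1).
#' @param n_points Number of dilution steps (>= 3).
#' @param noise_sd Absorbance noise SD (AU).
#' @param log_slope Slope of the logarithmic curve (% activity per ln
#'   unit).
#' @param a_negative Negative-control absorbance (AU).
#' @param a_blank Background (blank) absorbance (AU).
#' @param sample_id,plate_id Identifiers stamped on the wells.
#' @param seed Integer RNG seed.
#' @return Tibble (plate_id, well, role, sample_id, dilution_step,
#'   concentration_ugml, absorbance) with the truth in attributes
#'   `"true_ec50_ugml"` and `"regime"`.
#' @export
generate_plate <- function(true_ec50_ugml,
                           regime = c("linear", "logarithmic"),
                           top_conc = NULL,
                           dilution_factor = 1.25, n_points = 8L,
                           noise_sd = 0, log_slope = 30,
                           a_negative = 0.9, a_blank = 0.05,
                           sample_id = "S1", plate_id = "P1", seed = 1L) {
  regime <- match.arg(regime)
  if (is.null(top_conc))
    top_conc <- switch(regime,
      linear = 1.5 * true_ec50_ugml,
      logarithmic = true_ec50_ugml * exp(35 / log_slope))
  if (top_conc <= 0) stop("`top_conc` must be positive", call. = FALSE)
  if (dilution_factor <= 1) stop("`dilution_factor` must be > 1", call. = FALSE)
  if (n_points < 3L) stop("`n_points` must be >= 3", call. = FALSE)

  with_seed(seed, {
    step <- 0:(n_points - 1L)
    conc <- top_conc / dilution_factor^step
    act <- switch(regime,
      linear = 50 * conc / true_ec50_ugml,
      logarithmic = log_slope * log(conc) +
        (50 - log_slope * log(true_ec50_ugml))
    )
    a_sample <- a_blank + a_negative * (1 - act / 100)

    nz <- function(n) if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    rows <- list(
      tibble::tibble(role = "sample", sample_id = sample_id,
                     dilution_step = step, concentration_ugml = conc,
                     absorbance = a_sample + nz(n_points)),
      tibble::tibble(role = "sample_blank", sample_id = sample_id,
                     dilution_step = step, concentration_ugml = conc,
                     absorbance = a_blank + nz(n_points)),
      tibble::tibble(role = "negative_control", sample_id = NA_character_,
                     dilution_step = NA_integer_,
                     concentration_ugml = NA_real_,
                     absorbance = a_negative + nz(3L)),
      tibble::tibble(role = "positive_control", sample_id = "positive",
                     dilution_step = 0:2,
                     concentration_ugml = c(75, 37.5, 18.8) / 4,
                     absorbance = a_blank +
                       a_negative * (1 - pmin(95, 50 * (c(75, 37.5, 18.8) / 4) /
                                                (top_conc / 2)) / 100) + nz(3L)),
      tibble::tibble(role = "positive_blank", sample_id = "positive",
                     dilution_step = 0:2,
                     concentration_ugml = c(75, 37.5, 18.8) / 4,
                     absorbance = a_blank + nz(3L))
    )
    plate <- dplyr::bind_rows(rows)
    plate <- tibble::tibble(plate_id = plate_id,
                            well = sprintf("%s%02d", LETTERS[1 + (seq_len(nrow(plate)) - 1L) %/% 12],
                                           1L + (seq_len(nrow(plate)) - 1L) %% 12),
                            plate)
    attr(plate, "true_ec50_ugml") <- true_ec50_ugml
    attr(plate, "regime") <- regime
    plate
  })
}

#' Generate SEC calibration inputs from a known line
#'
#' Elution volumes of calibration standards are computed from an internal
#' true line in Kd-versus-log10(MW) space (plus optional jitter), and
#' fraction mean elution volumes are laid out on a fixed collection grid.
#' The true line is returned so calibration fits can be checked exactly.
#'
#' @param standards Tibble with `name` and `mw_kda` (>= 2 rows). Defaults
#'   to ovalbumin / conalbumin / aldolase.
#' @param v0_ml Void volume (mL). @param vc_ml Column volume (mL).
#' @param true_slope,true_intercept Kd = slope * log10(MW kDa) +
#'   intercept. The default intercept puts a 75 kDa standard at Kd 0.5.
#' @param jitter_sd SD of elution-volume jitter (mL).
#' @param n_fractions Number of collected fractions.
#' @param fraction_volume_ml Collected volume per fraction (mL).
#' @param collection_start_ml Elution volume at which fraction 1 starts.
#' @param seed Integer RNG seed.
#' @return List with `standards` (name, mw_kda, ve_ml), `fractions`
#'   (fraction, ve_mean_ml) and `truth` (slope, intercept, v0_ml, vc_ml).
#' @export
generate_sec_inputs <- function(standards = tibble::tibble(
                                  name = c("ovalbumin", "conalbumin", "aldolase"),
                                  mw_kda = c(44, 75, 158)),
                                v0_ml = 94.7, vc_ml = 320,
                                true_slope = -0.45,
                                true_intercept = 0.5 - true_slope * log10(75),
                                jitter_sd = 0, n_fractions = 62L,
                                fraction_volume_ml = 4,
                                collection_start_ml = 82,
                                seed = 1L) {
  if (nrow(standards) < 2L) stop("need at least 2 standards", call. = FALSE)
  if (any(standards$mw_kda <= 0)) stop("standard MW must be positive",
                                       call. = FALSE)
  if (v0_ml >= vc_ml) stop("`v0_ml` must be smaller than `vc_ml`",
                           call. = FALSE)
  with_seed(seed, {
    kd <- true_slope * log10(standards$mw_kda) + true_intercept
    ve <- v0_ml + kd * (vc_ml - v0_ml)
    if (jitter_sd > 0) ve <- ve + stats::rnorm(length(ve), 0, jitter_sd)
    fr <- tibble::tibble(
      fraction = seq_len(n_fractions),
      ve_mean_ml = collection_start_ml +
        (seq_len(n_fractions) - 0.5) * fraction_volume_ml
    )
    list(standards = tibble::tibble(standards, ve_ml = ve),
         fractions = fr,
         truth = list(slope = true_slope, intercept = true_intercept,
                      v0_ml = v0_ml, vc_ml = vc_ml))
  })
}
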
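# Crude-fraction analysis: mass/protein balance over grass, pulp and
# juice, replicate-presence filtering, LFQ normalization,
# not-missing-at-random imputation, pairwise differential abundance
# (Welch t + Benjamini-Hochberg) and group-level riBAQ statistics.

#' Crude protein from nitrogen content
#'
#' Crude protein (CP) is nitrogen multiplied by the standard
#' nitrogen-to-protein conversion factor 6.25.
#'
#' @param nitrogen_pct Nitrogen content (%, dry-matter basis).
#' @param factor Conversion factor (default 6.25).
#' @return Crude protein (%).
#' @export
crude_protein_pct <- function(nitrogen_pct, factor = 6.25) {
  if (any(nitrogen_pct < 0)) stop("nitrogen must be >= 0", call. = FALSE)
  nitrogen_pct * factor
}

#' Mass, dry-matter and crude-protein balance over wet fractionation
#'
#' From the fresh masses and mean compositions of grass (input), pulp
#' and juice (outputs), computes the absolute mass loss, the dry-matter
#' (DM) and crude-protein (CP) mass of every fraction, the distribution
#' of DM and CP relative to the grass input, and the closure losses
#' (input minus summed outputs, as % of input).
#'
#' @param measurements Tibble with columns `fraction` (must contain
#'   "grass", "pulp", "juice"), `mass_g`, `dm_pct` and either `cp_pct`
#'   (DM basis) or `nitrogen_pct` (converted via
#'   [crude_protein_pct()]).
#' @return List: `fractions` (per-fraction masses and distributions),
#'   `mass_loss_g`, `dm_loss_pct`, `cp_loss_pct`.
#' @export
mass_balance <- function(measurements) {
  need <- c("grass", "pulp", "juice")
  if (!all(need %in% measurements$fraction))
    stop("measurements must cover grass, pulp and juice", call. = FALSE)
  m <- measurements[match(need, measurements$fraction), , drop = FALSE]
  if (!"cp_pct" %in% names(m)) {
    if (!"nitrogen_pct" %in% names(m))
      stop("need `cp_pct` or `nitrogen_pct`", call. = FALSE)
    m$cp_pct <- crude_protein_pct(m$nitrogen_pct)
  }
  m$dm_mass_g <- m$mass_g * m$dm_pct / 100
  m$cp_mass_g <- m$dm_mass_g * m$cp_pct / 100
  grass <- m[m$fraction == "grass", ]
  m$dm_distribution_pct <- 100 * m$dm_mass_g / grass$dm_mass_g
  m$cp_distribution_pct <- 100 * m$cp_mass_g / grass$cp_mass_g
  outputs <- m[m$fraction != "grass", ]
  list(
    fractions = tibble::as_tibble(m),
    mass_loss_g = grass$mass_g - sum(outputs$mass_g),
    dm_loss_pct = 100 * (grass$dm_mass_g - sum(outputs$dm_mass_g)) /
      grass$dm_mass_g,
    cp_loss_pct = 100 * (grass$cp_mass_g - sum(outputs$cp_mass_g)) /
      grass$cp_mass_g
  )
}

#' Replicate-presence identification filter
#'
#' A protein counts as identified in a fraction when its intensity is
#' observed in at least `min_present` of that fraction's replicates.
#' Also reports the intersection counts used for Venn diagrams.
#'
#' @param intensity Protein x sample intensity matrix (`NA` = missing).
#' @param groups Named list: fraction -> replicate sample ids.
#' @param min_present Minimum replicates with an observation (default 2).
#' @return List: `sets` (fraction -> accession vector), `counts`
#'   (per-fraction sizes), `intersections` (tibble: combination, n).
#' @export
replicate_presence_filter <- function(intensity, groups, min_present = 2L) {
  sets <- lapply(groups, function(ids) {
    sub <- intensity[, ids, drop = FALSE]
    rownames(intensity)[rowSums(!is.na(sub)) >= min_present]
  })
  combos <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, simplify = FALSE)), recursive = FALSE)
  inter <- purrr::map_dfr(combos, function(cc) {
    tibble::tibble(combination = paste(cc, collapse = "&"),
                   n = length(Reduce(intersect, sets[cc])))
  })
  list(sets = sets,
       counts = tibble::tibble(fraction = names(sets),
                               n = lengths(sets)),
       intersections = inter)
}

#' Log2 transform and median-center LFQ intensities
#'
#' Transforms to log2 and subtracts each sample's median, putting every
#' sample on a common scale (per-sample median 0); rescaling any sample
#' by a constant therefore leaves the result unchanged. Missing values
#' are preserved.
#'
#' @param mat Protein x sample LFQ matrix (positive or `NA`).
#' @return Log2, median-centered matrix.
#' @export
normalize_log_lfq <- function(mat) {
  if (any(mat <= 0, na.rm = TRUE))
    stop("LFQ intensities must be positive (zeros should be missing)",
         call. = FALSE)
  lg <- log2(mat)
  med <- apply(lg, 2L, stats::median, na.rm = TRUE)
  sweep(lg, 2L, med, "-")
}

#' Not-missing-at-random imputation of log intensities
#'
#' Missing values in sample `s` are drawn from
#' `Normal(mu_s - mpf * sigma_s, (sdf * sigma_s)^2)` where `mu_s` and
#' `sigma_s` are the observed log2 mean and SD of that sample - a
#' left-shifted ("downshifted normal") distribution reflecting that
#' label-free missingness concentrates at low abundance. Defaults:
#' mean position factor 1.8, SD factor 0.3.
#'
#' @param log_mat Log2 intensity matrix with `NA` for missing.
#' @param mean_position_factor Downshift in observed-SD units.
#' @param sd_factor Imputation SD in observed-SD units.
#' @param seed Integer RNG seed.
#' @return List: `mat` (completed matrix; observed cells untouched) and
#'   `mask` (logical matrix of imputed cells).
#' @export
impute_nmar <- function(log_mat, mean_position_factor = 1.8,
                        sd_factor = 0.3, seed = 1L) {
  n_obs <- colSums(!is.na(log_mat))
  if (any(n_obs < 2L))
    stop("sample(s) with fewer than 2 observed values: ",
         paste(colnames(log_mat)[n_obs < 2L], collapse = ", "),
         call. = FALSE)
  mask <- is.na(log_mat)
  out <- log_mat
  with_seed(seed, {
    for (j in seq_len(ncol(log_mat))) {
      miss <- which(mask[, j])
      if (length(miss) == 0L) next
      mu <- mean(log_mat[, j], na.rm = TRUE)
      sg <- stats::sd(log_mat[, j], na.rm = TRUE)
      out[miss, j] <- stats::rnorm(length(miss),
                                   mu - mean_position_factor * sg,
                                   sd_factor * sg)
    }
  })
  list(mat = out, mask = mask)
}

#' Pairwise differential abundance between two crude fractions
#'
#' Per protein: `log2FC = mean(group A) - mean(group B)`, Welch
#' two-sample t-test, Benjamini-Hochberg adjustment across proteins. A
#' protein is called differential when the adjusted p-value is below
#' `fdr` (default 0.05) and `|log2FC|` exceeds `log2fc_min` (default 1,
#' i.e. fold change above 2). Proteins with zero variance in both groups
#' are flagged `degenerate` (p set to 1 when the means are equal, 0
#' otherwise) rather than propagating NaN.
#'
#' @param mat Completed log2 matrix.
#' @param group_a,group_b Sample id vectors (>= 2 each).
#' @param mask Optional imputation mask to count imputed cells.
#' @param fdr FDR threshold on adjusted p.
#' @param log2fc_min Absolute log2-fold-change threshold.
#' @return Tibble: protein, log2fc, p_value, adj_p_value, n_imputed_a,
#'   n_imputed_b, degenerate, differential.
#' @export
pairwise_differential <- function(mat, group_a, group_b, mask = NULL,
                                  fdr = 0.05, log2fc_min = 1) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  a <- mat[, group_a, drop = FALSE]
  b <- mat[, group_b, drop = FALSE]
  log2fc <- rowMeans(a) - rowMeans(b)
  va <- apply(a, 1L, stats::var)
  vb <- apply(b, 1L, stats::var)
  degenerate <- va == 0 & vb == 0
  p <- rep(NA_real_, nrow(mat))
  for (i in seq_len(nrow(mat))) {
    p[i] <- if (degenerate[i]) {
      if (log2fc[i] == 0) 1 else 0
    } else {
      stats::t.test(a[i, ], b[i, ], var.equal = FALSE)$p.value
    }
  }
  adj <- stats::p.adjust(p, method = "BH")
  count_imp <- function(g) {
    if (is.null(mask)) rep(NA_integer_, nrow(mat))
    else rowSums(mask[, g, drop = FALSE])
  }
  tibble::tibble(
    protein = rownames(mat),
    log2fc = log2fc, p_value = p, adj_p_value = adj,
    n_imputed_a = count_imp(group_a), n_imputed_b = count_imp(group_b),
    degenerate = degenerate,
    differential = adj < fdr & abs(log2fc) > log2fc_min
  )
}

#' Group-level riBAQ statistics across crude fractions
#'
#' Summed member riBAQ per protein family and replicate, then per
#' family: mean and SD per fraction, a Welch (unequal-variance) one-way
#' omnibus test and pairwise unequal-variance t contrasts with Holm
#' adjustment. A `cumulative` pseudo-family sums every member of every
#' family (the total candidate-set abundance).
#'
#' @param ribaq riBAQ matrix over crude samples.
#' @param families Named list: family -> member row names.
#' @param groups Named list: fraction -> replicate sample ids (each
#'   >= 2).
#' @param cumulative Add the all-members pseudo-family (default TRUE).
#' @return List: `summary` (family, fraction, mean, sd), `omnibus`
#'   (family, statistic, p_value), `pairwise` (family, contrast, p_adj).
#' @export
group_abundance_stats <- function(ribaq, families, groups,
                                  cumulative = TRUE) {
  if (any(lengths(groups) < 2L))
    stop("need >= 2 replicates in every fraction", call. = FALSE)
  if (cumulative)
    families <- c(families,
                  list(cumulative = unique(unlist(families))))
  samples <- unlist(groups, use.names = FALSE)
  fraction_of <- rep(names(groups), lengths(groups))

  fam_mat <- t(vapply(families, function(members) {
    sub <- ribaq[intersect(members, rownames(ribaq)), samples, drop = FALSE]
    sub[is.na(sub)] <- 0
    colSums(sub)
  }, numeric(length(samples))))

  summary <- purrr::map_dfr(names(families), function(f) {
    purrr::map_dfr(names(groups), function(g) {
      v <- fam_mat[f, fraction_of == g]
      tibble::tibble(family = f, fraction = g,
                     mean = mean(v), sd = stats::sd(v))
    })
  })
  omnibus <- purrr::map_dfr(names(families), function(f) {
    v <- fam_mat[f, ]
    ow <- tryCatch(
      stats::oneway.test(v ~ factor(fraction_of), var.equal = FALSE),
      error = function(e) list(statistic = NA_real_, p.value = NA_real_))
    tibble::tibble(family = f, statistic = unname(ow$statistic[1]),
                   p_value = ow$p.value)
  })
  pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
  pairwise <- purrr::map_dfr(names(families), function(f) {
    p_raw <- vapply(pairs, function(pp) {
      x <- fam_mat[f, fraction_of == pp[1]]
      y <- fam_mat[f, fraction_of == pp[2]]
      tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
               error = function(e) NA_real_)
    }, numeric(1))
    tibble::tibble(family = f,
                   contrast = vapply(pairs, paste, character(1),
                                     collapse = " vs "),
                   p_adj = stats::p.adjust(p_raw, method = "holm"))
  })
  list(summary = summary, omnibus = omnibus, pairwise = pairwise,
       family_matrix = fam_mat, fraction_of = fraction_of)
}

#' Row Z-score and hierarchical clustering for heatmap reporting
#'
#' Rows are Z-scored (constant rows become all zeros, with a warning),
#' clustered by Euclidean distance with average linkage, and cut at a
#' fixed distance.
#'
#' @param mat Numeric matrix (>= 2 rows).
#' @param distance_cutoff Tree cut height (default 3).
#' @return List: `z` (Z-scored matrix), `clusters` (named integer
#'   labels), `order` (leaf order), `hclust`.
#' @export
zscore_cluster <- function(mat, distance_cutoff = 3) {
  if (nrow(mat) < 2L) stop("need >= 2 rows", call. = FALSE)
  sds <- apply(mat, 1L, stats::sd)
  if (any(sds == 0))
    warning("constant row(s) Z-scored as zeros", call. = FALSE)
  z <- (mat - rowMeans(mat)) / ifelse(sds == 0, 1, sds)
  z[sds == 0, ] <- 0
  hc <- stats::hclust(stats::dist(z), method = "average")
  clusters <- stats::cutree(hc, h = distance_cutoff)
  list(z = z, clusters = clusters, order = hc$order, hclust = hc)
}
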
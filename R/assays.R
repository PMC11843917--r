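# Antioxidant activity from microplate absorbances: DPPH radical
# scavenging (517 nm) and ferrozine iron chelation (562 nm).
#
# Activity% = (1 - (A_sample - A_blank) / A_negative) * 100. EC50 is the
# concentration giving 50% activity, obtained from a linear fit of
# activity against concentration or - when any point lies above 80%
# activity, i.e. the series has left the locally linear part of the
# sigmoid - a logarithmic fit of activity against ln(concentration).

#' Percent activity from absorbances
#'
#' @param a_sample Sample absorbance (AU), vectorized.
#' @param a_blank Matched blank absorbance (AU).
#' @param a_negative Negative-control absorbance (AU), must be positive.
#' @return Activity in percent; may be negative (such points are flagged
#'   for exclusion downstream).
#' @export
activity_percent <- function(a_sample, a_blank, a_negative) {
  if (any(a_negative <= 0))
    stop("invalid control: negative-control absorbance must be positive",
         call. = FALSE)
  100 * (1 - (a_sample - a_blank) / a_negative)
}

#' Build an activity series from plate wells
#'
#' For each dilution step, activity is computed against the step's
#' matched sample blank (or a single averaged blank with
#' `blank = "average"`) and the mean of the negative-control wells;
#' replicate sample wells at a step are averaged. Points with negative
#' activity are excluded (recorded with a reason), matching the practice
#' of discarding points where background absorbance exceeds the signal.
#'
#' @param wells Long-format plate tibble (see [generate_plate()]).
#' @param sample_id Sample to extract.
#' @param assay Label stored on the series (e.g. `"DPPH"`, `"FeFz"`).
#' @param blank `"per_step"` (default) or `"average"`.
#' @return List of class `activity_series`: sample_id, assay, points
#'   (tibble concentration_ugml, activity_pct), excluded_points.
#' @export
build_series <- function(wells, sample_id, assay = "DPPH",
                         blank = c("per_step", "average")) {
  blank <- match.arg(blank)
  neg <- wells$absorbance[wells$role == "negative_control"]
  if (length(neg) == 0L)
    stop("invalid plate: no negative-control wells", call. = FALSE)
  a_neg <- mean(neg)
  sm <- wells[wells$role == "sample" & wells$sample_id == sample_id, ]
  bl <- wells[wells$role == "sample_blank" & wells$sample_id == sample_id, ]
  if (nrow(sm) == 0L)
    stop("no sample wells for '", sample_id, "'", call. = FALSE)
  avg_blank <- if (nrow(bl) > 0L) mean(bl$absorbance) else 0

  pts <- sm |>
    dplyr::group_by(.data$dilution_step, .data$concentration_ugml) |>
    dplyr::summarise(a_sample = mean(.data$absorbance), .groups = "drop")
  pts$a_blank <- vapply(pts$dilution_step, function(st) {
    if (blank == "per_step") {
      b <- bl$absorbance[bl$dilution_step == st]
      if (length(b) > 0L) mean(b) else avg_blank
    } else avg_blank
  }, numeric(1))
  pts$activity_pct <- activity_percent(pts$a_sample, pts$a_blank, a_neg)
  pts <- dplyr::arrange(pts, dplyr::desc(.data$concentration_ugml))

  neg_act <- pts$activity_pct < 0
  excluded <- tibble::tibble(
    concentration_ugml = pts$concentration_ugml[neg_act],
    activity_pct = pts$activity_pct[neg_act],
    reason = "negative activity"
  )
  structure(
    list(sample_id = sample_id, assay = assay,
         points = pts[!neg_act, c("concentration_ugml", "activity_pct")],
         excluded_points = excluded),
    class = "activity_series"
  )
}

#' Fit EC50 from an activity series
#'
#' If any usable point exceeds `log_threshold` (default 80%) activity,
#' `activity = a * ln(conc) + b` is fitted; otherwise
#' `activity = a * conc + b`. EC50 solves the fitted line at 50%
#' activity. The fit is declared unusable (`fit_kind = "none"`, EC50
#' missing, with a reason) when fewer than 2 usable points remain, the
#' slope is not positive, or the EC50 falls outside the observed
#' concentration window by more than a factor of 10.
#'
#' @param series An `activity_series` from [build_series()].
#' @param log_threshold Activity (%) above which the logarithmic branch
#'   is used.
#' @param window_factor Allowed extrapolation factor for the EC50 beyond
#'   the concentration range.
#' @return List of class `ec50_result`: sample_id, assay, fit_kind,
#'   slope, intercept, ec50_ugml, ec50_um (NA until [ec50_molar()]),
#'   n_points, reason.
#' @export
fit_ec50 <- function(series, log_threshold = 80, window_factor = 10) {
  stopifnot(inherits(series, "activity_series"))
  pts <- series$points
  out <- list(sample_id = series$sample_id, assay = series$assay,
              fit_kind = "none", slope = NA_real_, intercept = NA_real_,
              ec50_ugml = NA_real_, ec50_um = NA_real_,
              mw_kda_used = NA_real_, n_points = nrow(pts),
              reason = NA_character_)
  class(out) <- "ec50_result"
  if (nrow(pts) < 2L) {
    out$reason <- "fewer than 2 usable points"
    return(out)
  }
  use_log <- any(pts$activity_pct > log_threshold)
  x <- if (use_log) log(pts$concentration_ugml) else pts$concentration_ugml
  fit <- stats::lm(pts$activity_pct ~ x)
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  if (!is.finite(a) || a <= 0) {
    out$reason <- "non-positive slope"
    return(out)
  }
  ec50 <- if (use_log) exp((50 - b) / a) else (50 - b) / a
  lo <- min(pts$concentration_ugml) / window_factor
  hi <- max(pts$concentration_ugml) * window_factor
  if (!is.finite(ec50) || ec50 <= 0 || ec50 < lo || ec50 > hi) {
    out$reason <- "EC50 outside concentration window"
    return(out)
  }
  out$fit_kind <- if (use_log) "logarithmic" else "linear"
  out$slope <- a; out$intercept <- b; out$ec50_ugml <- ec50
  out
}

#' Convert a mass EC50 to molar units
#'
#' `ug/mL` divided by `kDa` is `umol/L` exactly, so
#' `EC50[uM] = EC50[ug/mL] / MW[kDa]`.
#'
#' @param ec50_ugml Mass EC50 (ug/mL).
#' @param mw_kda Estimated fraction molecular weight (kDa); `NA` for
#'   void fractions.
#' @return List: ec50_um (NA when MW is missing) and reason.
#' @export
ec50_molar <- function(ec50_ugml, mw_kda) {
  if (is.na(ec50_ugml))
    return(list(ec50_um = NA_real_, reason = "no mass EC50"))
  if (is.na(mw_kda))
    return(list(ec50_um = NA_real_,
                reason = "MW undefined (void fraction)"))
  if (mw_kda <= 0) stop("`mw_kda` must be positive", call. = FALSE)
  list(ec50_um = ec50_ugml / mw_kda, reason = NA_character_)
}

#' Assemble an EC50 results table across fractions
#'
#' Joins fitted mass EC50s with per-fraction MW estimates and performs
#' the molar conversion, carrying reason codes for undetermined values.
#'
#' @param results List of `ec50_result` objects.
#' @param mw_table Tibble from [estimate_mw()] with `fraction_id` values
#'   matching the results' `sample_id`s.
#' @return Tibble: sample_id, assay, mw_kda, status, fit_kind,
#'   ec50_ugml, ec50_um, reason.
#' @export
ec50_table <- function(results, mw_table = NULL) {
  rows <- purrr::map_dfr(results, function(r) {
    tibble::tibble(sample_id = r$sample_id, assay = r$assay,
                   fit_kind = r$fit_kind, ec50_ugml = r$ec50_ugml,
                   n_points = r$n_points, reason = r$reason)
  })
  if (!is.null(mw_table)) {
    mw <- tibble::tibble(sample_id = as.character(mw_table$fraction_id),
                         mw_kda = mw_table$mw_kda, status = mw_table$status)
    rows <- dplyr::left_join(dplyr::mutate(rows,
                                           sample_id = as.character(.data$sample_id)),
                             mw, by = "sample_id")
    conv <- purrr::map2(rows$ec50_ugml, rows$mw_kda, ec50_molar)
    rows$ec50_um <- vapply(conv, `[[`, numeric(1), "ec50_um")
    conv_reason <- vapply(conv, `[[`, character(1), "reason")
    rows$reason <- ifelse(is.na(rows$reason), conv_reason, rows$reason)
  } else {
    rows$mw_kda <- NA_real_
    rows$ec50_um <- NA_real_
  }
  rows
}
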
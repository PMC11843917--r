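# Size-exclusion chromatography calibration and per-fraction molecular
# weight estimation.
#
# The distribution coefficient Kd = (Ve - V0) / (Vc - V0) locates an
# analyte between the void volume V0 (Kd = 0) and the total column
# volume Vc (Kd = 1), and is linear in log10(MW) within the column's
# resolving range. Calibration standards define that line by ordinary
# least squares; fraction MW is the inverse mapping at the fraction's
# mean elution volume.

#' Distribution coefficient of an analyte on a SEC column
#'
#' @param ve_ml Elution volume (mL), vectorized.
#' @param v0_ml Void volume (mL).
#' @param vc_ml Total column volume (mL), must exceed `v0_ml`.
#' @return `Kd = (ve - v0) / (vc - v0)`.
#' @export
compute_kd <- function(ve_ml, v0_ml, vc_ml) {
  if (vc_ml <= v0_ml)
    stop("invalid geometry: `vc_ml` must exceed `v0_ml`", call. = FALSE)
  (ve_ml - v0_ml) / (vc_ml - v0_ml)
}

#' Fit the SEC calibration line
#'
#' Ordinary least squares of Kd on log10(MW) over the calibration
#' standards.
#'
#' @param standards Tibble with `mw_kda` and `ve_ml` (and optionally
#'   `name`); at least two standards with distinct MW.
#' @param v0_ml,vc_ml Column geometry (mL).
#' @return List of class `sec_calibration`: v0_ml, vc_ml, slope,
#'   intercept, standards (with fitted kd and residuals).
#' @export
fit_calibration <- function(standards, v0_ml, vc_ml) {
  if (nrow(standards) < 2L || length(unique(standards$mw_kda)) < 2L)
    stop("calibration requires >= 2 standards with distinct MW",
         call. = FALSE)
  kd <- compute_kd(standards$ve_ml, v0_ml, vc_ml)
  logmw <- log10(standards$mw_kda)
  fit <- stats::lm(kd ~ logmw)
  co <- stats::coef(fit)
  structure(
    list(v0_ml = v0_ml, vc_ml = vc_ml,
         slope = unname(co["logmw"]), intercept = unname(co["(Intercept)"]),
         kd_range = range(kd),
         standards = tibble::tibble(standards, kd = kd,
                                    residual = stats::resid(fit))),
    class = "sec_calibration"
  )
}

#' Estimate fraction molecular weight from elution volume
#'
#' Inverts the calibration line: `MW = 10^((Kd - intercept) / slope)`.
#' Fractions at or before the void volume (`ve <= v0`) have no defined
#' MW and are reported with status `"void"`; fractions whose Kd falls
#' outside the standards' range are reported with status
#' `"extrapolated"` (the estimate is kept but flagged, since such values
#' lie outside the column's resolving range).
#'
#' @param model A `sec_calibration` from [fit_calibration()].
#' @param ve_mean_ml Mean elution volume(s) of the fraction(s), mL.
#' @param fraction_id Optional fraction identifiers.
#' @return Tibble: fraction_id, ve_mean_ml, kd, mw_kda, status.
#' @export
estimate_mw <- function(model, ve_mean_ml,
                        fraction_id = seq_along(ve_mean_ml)) {
  stopifnot(inherits(model, "sec_calibration"))
  if (model$slope == 0)
    stop("degenerate model: calibration slope is zero", call. = FALSE)
  kd <- compute_kd(ve_mean_ml, model$v0_ml, model$vc_ml)
  mw <- 10^((kd - model$intercept) / model$slope)
  void <- ve_mean_ml <= model$v0_ml
  extrap <- !void & (kd < model$kd_range[1] | kd > model$kd_range[2])
  mw[void] <- NA_real_
  tibble::tibble(
    fraction_id = fraction_id,
    ve_mean_ml = ve_mean_ml,
    kd = kd,
    mw_kda = mw,
    status = dplyr::case_when(void ~ "void", extrap ~ "extrapolated",
                              TRUE ~ "ok")
  )
}
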
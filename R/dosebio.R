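#' Fractionation scheme
#'
#' Describes how the total physical dose is split into fractions. In the LQ
#' conversion, the per-voxel dose per fraction is taken as the voxel total
#' dose divided by the number of fractions (uniform fractionation).
#'
#' @param n_fractions number of fractions (>= 1).
#' @param dose_per_fraction prescription dose per fraction at the isocentre (Gy).
#' @return a `fractionation_scheme` with fields `n_fractions`,
#'   `dose_per_fraction`, `total_dose`.
#' @export
fractionation_scheme <- function(n_fractions, dose_per_fraction) {
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L) stop("n_fractions must be >= 1")
  if (!is.finite(dose_per_fraction) || dose_per_fraction <= 0)
    stop("dose_per_fraction must be positive")
  structure(list(n_fractions = n_fractions,
                 dose_per_fraction = dose_per_fraction,
                 total_dose = n_fractions * dose_per_fraction),
            class = "fractionation_scheme")
}

#' @method print fractionation_scheme
#' @export
print.fractionation_scheme <- function(x, ...) {
  cat(sprintf("<fractionation_scheme> %d x %.3g Gy = %.3g Gy\n",
              x$n_fractions, x$dose_per_fraction, x$total_dose))
  invisible(x)
}

#' Biologically effective dose of a total physical dose
#'
#' LQ-model conversion `BED = n d (1 + d / (alpha/beta))` with
#' `d = total_dose / n`, so `BED = D (1 + (D/n) / (alpha/beta))`.
#' Vectorized over `total_dose`.
#'
#' @param total_dose total physical dose in Gy (scalar or vector), >= 0.
#' @param scheme a [fractionation_scheme()]; only `n_fractions` is used.
#' @param alpha_beta tissue alpha/beta ratio in Gy (> 0); ~3 Gy for
#'   late-responding lung, ~10 Gy for tumour.
#' @return BED in Gy, same shape as `total_dose`; always >= `total_dose`.
#' @export
bed_total <- function(total_dose, scheme, alpha_beta) {
  if (!is.finite(alpha_beta) || alpha_beta <= 0) stop("alpha_beta must be > 0")
  if (any(total_dose < 0, na.rm = TRUE)) stop("total_dose must be non-negative")
  n <- scheme$n_fractions
  total_dose * (1 + (total_dose / n) / alpha_beta)
}

#' Voxelwise BED conversion of a dose grid
#'
#' Applies [bed_total()] element-wise, with per-voxel dose per fraction equal
#' to the voxel total dose over the number of fractions. Strictly monotone in
#' dose; returns a grid on the same lattice.
#'
#' @param dose a `volume_grid` of total physical dose (Gy), non-negative.
#' @inheritParams bed_total
#' @return a `volume_grid` of BED (Gy).
#' @export
bed_voxelwise <- function(dose, scheme, alpha_beta) {
  neg <- which(unclass(dose) < 0)
  if (length(neg))
    stop(sprintf("negative dose at voxel index %d (%.4g Gy)", neg[1], dose[neg[1]]))
  vg_like(bed_total(unclass(dose), scheme, alpha_beta), dose)
}

#' Physical dose whose BED equals a target
#'
#' Closed-form inverse of the LQ conversion: solves
#' `D (1 + (D/n)/ab) = bed_target` for D >= 0, giving
#' `D = (n ab / 2) (-1 + sqrt(1 + 4 bed_target / (n ab)))`.
#' Used to build iso-BED region masks (e.g. B70) from a physical dose grid.
#'
#' @param bed_target target BED in Gy (>= 0), vectorized.
#' @inheritParams bed_total
#' @return physical total dose in Gy; round-trips through [bed_total()] to
#'   1e-9 relative.
#' @export
physical_threshold_for_bed <- function(bed_target, scheme, alpha_beta) {
  if (!is.finite(alpha_beta) || alpha_beta <= 0) stop("alpha_beta must be > 0")
  if (any(bed_target < 0, na.rm = TRUE)) stop("bed_target must be non-negative")
  nab <- scheme$n_fractions * alpha_beta
  (nab / 2) * (-1 + sqrt(1 + 4 * bed_target / nab))
}

#' Cumulative dose-volume histogram of a masked grid
#'
#' `volume_percent[k]` is the percentage of mask voxels whose value is
#' greater than or equal to `thresholds[k]` (inclusive comparison, so the
#' volume at threshold 0 is exactly 100 for a non-negative grid).
#'
#' @param values a `volume_grid` (dose or BED, Gy).
#' @param mask logical array on the same lattice; must be non-empty.
#' @param thresholds ascending numeric thresholds (Gy).
#' @return a `dvh_curve`: list with `thresholds` and `volume_percent`.
#' @export
dvh <- function(values, mask, thresholds) {
  if (!any(mask)) stop("empty mask: DVH undefined")
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  stopifnot_same_lattice(values, mask)
  v <- unclass(values)[mask]
  nv <- length(v)
  vp <- vapply(thresholds, function(th) 100 * sum(v >= th) / nv, numeric(1))
  structure(list(thresholds = as.numeric(thresholds), volume_percent = vp),
            class = "dvh_curve")
}

#' @method print dvh_curve
#' @export
print.dvh_curve <- function(x, ...) {
  cat("<dvh_curve>\n")
  print(data.frame(threshold_Gy = x$thresholds, volume_percent = x$volume_percent))
  invisible(x)
}

#' Dosimetric scalar metrics of a plan
#'
#' V5 and V20 (percent of the nontarget lung receiving >= 5 / 20 Gy physical
#' dose), the mean lung dose, the V_BEDx grid for x = 10, 20, ..., 200
#' computed on the alpha/beta = 3 BED grid, and the tumour BED of the
#' prescription (alpha/beta = 10).
#'
#' @param dose physical dose `volume_grid` (Gy).
#' @param bed3 BED `volume_grid` (Gy) on the same lattice, lung alpha/beta
#'   convention (3 Gy).
#' @param lung_mask nontarget lung mask (bilateral lungs minus GTV).
#' @param scheme the [fractionation_scheme()].
#' @param prescription prescription total dose at the isocentre (Gy); defaults
#'   to `scheme$total_dose`.
#' @param tumour_alpha_beta alpha/beta for the tumour BED (default 10 Gy).
#' @return named list: `V5`, `V20`, `MLD`, `VBED10` ... `VBED200`,
#'   `tumour_BED`.
#' @export
dose_metrics <- function(dose, bed3, lung_mask, scheme,
                         prescription = scheme$total_dose,
                         tumour_alpha_beta = 10) {
  stopifnot_same_lattice(dose, bed3)
  stopifnot_same_lattice(dose, lung_mask)
  if (!any(lung_mask)) stop("empty lung mask")
  metrics_from_vectors(unclass(dose)[lung_mask], unclass(bed3)[lung_mask],
                       scheme, prescription, tumour_alpha_beta)
}

# shared scalar-metric core operating on lung-voxel dose/BED vectors
metrics_from_vectors <- function(dv, bv, scheme,
                                 prescription = scheme$total_dose,
                                 tumour_alpha_beta = 10) {
  nv <- length(dv)
  xs <- seq(10, 200, by = 10)
  vbed <- vapply(xs, function(x) 100 * sum(bv >= x) / nv, numeric(1))
  c(list(V5 = 100 * sum(dv >= 5) / nv,
         V20 = 100 * sum(dv >= 20) / nv,
         MLD = mean(dv)),
    as.list(setNames(vbed, paste0("VBED", xs))),
    list(tumour_BED = bed_total(prescription, scheme, tumour_alpha_beta)))
}

#' SRP incidence as a percentage
#'
#' @param cases number of events.
#' @param n cohort size.
#' @return `100 * cases / n`.
#' @export
incidence_percent <- function(cases, n) {
  if (n <= 0) stop("n must be positive")
  100 * cases / n
}
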
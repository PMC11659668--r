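#' Names of the seven discrete regions and three composites
#'
#' The pipeline analyses seven discrete regions of interest spanning three
#' dimensions — anatomical (GTV, PTV, PTV_GTV, Lungs), physical-dose (D5,
#' D20) and biological-dose (B70) — plus three composites defined as ordered
#' region lists: RA (anatomical), RAP (anatomical + physical) and RAPB
#' (anatomical + physical + BED).
#'
#' @return character vector of region names.
#' @export
discrete_regions <- function() c("GTV", "PTV", "PTV_GTV", "Lungs", "D5", "D20", "B70")

#' @rdname discrete_regions
#' @export
composite_regions <- function() {
  list(RA   = c("GTV", "PTV", "PTV_GTV", "Lungs"),
       RAP  = c("GTV", "PTV", "PTV_GTV", "Lungs", "D5", "D20"),
       RAPB = c("GTV", "PTV", "PTV_GTV", "Lungs", "D5", "D20", "B70"))
}

#' Build the anatomical regions
#'
#' PTV_GTV is the set difference PTV minus GTV (the margin shell of normal
#' tissue); Lungs is the bilateral lung minus the GTV.
#'
#' @param lungs_total bilateral lung mask (including the tumour voxels).
#' @param gtv gross tumour volume mask.
#' @param ptv planning target volume mask; must contain the GTV.
#' @return named list of logical masks: GTV, PTV, PTV_GTV, Lungs.
#' @export
build_anatomical <- function(lungs_total, gtv, ptv) {
  if (!identical(dim(lungs_total), dim(gtv)) || !identical(dim(gtv), dim(ptv)))
    stop("masks are not co-registered")
  if (!any(gtv)) stop("empty GTV mask")
  if (!any(ptv)) stop("empty PTV mask")
  if (!any(lungs_total)) stop("empty lung mask")
  if (any(gtv & !ptv)) stop("GTV is not contained in PTV")
  ptv_gtv <- ptv & !gtv
  if (!any(ptv_gtv)) stop("PTV equals GTV: margin shell PTV_GTV is empty")
  lungs <- lungs_total & !gtv
  if (!any(lungs)) stop("nontarget lung (Lungs minus GTV) is empty")
  list(GTV = gtv, PTV = ptv, PTV_GTV = ptv_gtv, Lungs = lungs)
}

#' Build the dose-defined lung subregions
#'
#' D5 and D20 are the nontarget lung receiving >= 5 and >= 20 Gy physical
#' dose; B70 is the nontarget lung with BED (alpha/beta = 3) >= 70 Gy. All
#' comparisons are inclusive. Empty regions are allowed but flagged (the
#' feature extractor treats them as unusable).
#'
#' @param dose physical dose `volume_grid` (Gy).
#' @param bed3 lung BED `volume_grid` (Gy, alpha/beta = 3).
#' @param lungs nontarget lung mask (Lungs from [build_anatomical()]).
#' @param bed_threshold iso-BED threshold for B70 (default 70 Gy).
#' @return named list of masks D5, D20, B70 with attribute `empty_regions`
#'   naming any empty ones.
#' @export
build_dose_regions <- function(dose, bed3, lungs, bed_threshold = 70) {
  stopifnot_same_lattice(dose, bed3)
  if (!identical(dim(dose), dim(lungs))) stop("masks are not co-registered")
  out <- list(D5  = lungs & (unclass(dose) >= 5),
              D20 = lungs & (unclass(dose) >= 20),
              B70 = lungs & (unclass(bed3) >= bed_threshold))
  empty <- names(out)[!vapply(out, any, logical(1))]
  if (length(empty))
    warning("empty dose region(s): ", paste(empty, collapse = ", "),
            " - flagged unusable for feature extraction")
  attr(out, "empty_regions") <- empty
  out
}

#' Assemble the full ten-region set for one patient
#'
#' Combines [build_anatomical()] and [build_dose_regions()] and attaches the
#' composite definitions. Asserts the nesting invariants D20 within D5 and
#' (for the fractionation range used here) B70 within D20.
#'
#' @inheritParams build_anatomical
#' @inheritParams build_dose_regions
#' @param check_nesting assert D20 subset of D5 (always true) and report.
#' @return a `region_set`: list with `masks` (7 discrete masks),
#'   `composites` (named lists of member region names), `empty_regions`.
#' @export
build_region_set <- function(lungs_total, gtv, ptv, dose, bed3,
                             bed_threshold = 70, check_nesting = TRUE) {
  anat <- build_anatomical(lungs_total, gtv, ptv)
  dreg <- build_dose_regions(dose, bed3, anat$Lungs, bed_threshold)
  masks <- c(anat, dreg[c("D5", "D20", "B70")])
  if (check_nesting) {
    if (any(masks$D20 & !masks$D5)) stop("nesting violated: D20 not within D5")
  }
  structure(list(masks = masks,
                 composites = composite_regions(),
                 empty_regions = attr(dreg, "empty_regions")),
            class = "region_set")
}

#' @method print region_set
#' @export
print.region_set <- function(x, ...) {
  cat("<region_set>\n")
  for (nm in names(x$masks))
    cat(sprintf("  %-8s %d voxels\n", nm, sum(x$masks[[nm]])))
  cat("  composites:", paste(names(x$composites), collapse = ", "), "\n")
  invisible(x)
}
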
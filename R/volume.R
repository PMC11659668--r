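#' @useDynLib bedrad, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rbinom runif plogis qlogis sd var median quantile
#'   glm binomial coef predict pchisq pnorm pt qnorm fft cor t.test setNames
#'   complete.cases wilcox.test
#' @importFrom utils head write.csv
NULL

#' Construct a 3D scalar volume on a regular lattice
#'
#' A `volume_grid` is a plain 3D array carrying physical voxel spacing (mm)
#' and an origin. It is used for CT intensity grids, physical dose grids (Gy)
#' and BED grids (Gy).
#'
#' @param data 3D numeric or logical array.
#' @param spacing voxel size in mm, length 1 or 3.
#' @param origin physical coordinate (mm) of the first voxel centre.
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) stop("spacing must be positive")
  structure(data, spacing = spacing, origin = rep_len(as.numeric(origin), 3L),
            class = "volume_grid")
}

#' @method print volume_grid
#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x)
  sp <- vg_spacing(x)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Voxel spacing of a volume
#' @param x a `volume_grid` (or array with a spacing attribute).
#' @return numeric length-3 spacing in mm.
#' @export
vg_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) stop("object has no spacing attribute")
  sp
}

#' @rdname vg_spacing
#' @export
vg_voxel_volume <- function(x) prod(vg_spacing(x))

# new volume on the same lattice as a template
vg_like <- function(data, template) {
  volume_grid(data, vg_spacing(template),
              attr(template, "origin") %||% c(0, 0, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_same_lattice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mismatched lattices: grids have different dimensions")
  spa <- attr(a, "spacing")
  spb <- attr(b, "spacing")
  if (!is.null(spa) && !is.null(spb) && max(abs(spa - spb)) > 1e-9)
    stop("mismatched lattices: grids have different spacing")
  invisible(TRUE)
}

#' Euclidean distance (mm) to the nearest voxel of a mask
#'
#' Exact separable Euclidean distance transform on the voxel lattice; distance
#' is zero inside the mask.
#'
#' @param mask logical 3D array (a region mask).
#' @param spacing voxel spacing in mm (taken from the mask if present).
#' @return 3D array of distances in mm.
#' @export
distance_to_mask <- function(mask, spacing = NULL) {
  if (is.null(spacing)) spacing <- attr(mask, "spacing")
  if (is.null(spacing)) stop("spacing must be supplied")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (!any(mask)) stop("mask is empty: distance transform undefined")
  d2 <- cpp_edt3d(as.logical(mask), dim(mask), spacing)
  sqrt(array(d2, dim(mask)))
}

#' Resample a volume to an isotropic lattice
#'
#' Intensity volumes are trilinearly interpolated; masks should use
#' `method = "nearest"`, which keeps them binary. The physical extent of the
#' grid is preserved to within one voxel.
#'
#' @param vol a `volume_grid`.
#' @param target_mm target isotropic spacing (mm), default 1.
#' @param method `"linear"` (intensities) or `"nearest"` (masks/labels).
#' @return a `volume_grid` with spacing `c(target_mm, target_mm, target_mm)`.
#' @export
resample_isotropic <- function(vol, target_mm = 1, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (!is.finite(target_mm) || target_mm <= 0) stop("target_mm must be positive")
  sp <- vg_spacing(vol)
  d <- dim(vol)
  if (max(abs(sp - target_mm)) < 1e-9) return(vol)  # identity resample
  extent <- d * sp
  nd <- pmax(1L, as.integer(round(extent / target_mm)))
  # output voxel centres expressed in input (1-based) index coordinates
  cx <- ((seq_len(nd[1]) - 0.5) * target_mm) / sp[1] + 0.5
  cy <- ((seq_len(nd[2]) - 0.5) * target_mm) / sp[2] + 0.5
  cz <- ((seq_len(nd[3]) - 0.5) * target_mm) / sp[3] + 0.5
  arr <- unclass(vol)
  storage_logical <- is.logical(arr)
  if (method == "nearest") {
    ix <- pmin(pmax(round(cx), 1L), d[1])
    iy <- pmin(pmax(round(cy), 1L), d[2])
    iz <- pmin(pmax(round(cz), 1L), d[3])
    out <- arr[ix, iy, iz, drop = FALSE]
  } else {
    arrn <- arr * 1.0
    clamp <- function(v, n) pmin(pmax(v, 1), n)
    x0 <- clamp(floor(cx), d[1]); x1 <- clamp(x0 + 1, d[1]); wx <- clamp(cx, d[1]) - x0
    y0 <- clamp(floor(cy), d[2]); y1 <- clamp(y0 + 1, d[2]); wy <- clamp(cy, d[2]) - y0
    z0 <- clamp(floor(cz), d[3]); z1 <- clamp(z0 + 1, d[3]); wz <- clamp(cz, d[3]) - z0
    wx <- pmin(pmax(wx, 0), 1); wy <- pmin(pmax(wy, 0), 1); wz <- pmin(pmax(wz, 0), 1)
    w3 <- function(a, b, c) outer(outer(a, b), c)
    out <- w3(1 - wx, 1 - wy, 1 - wz) * arrn[x0, y0, z0, drop = FALSE] +
           w3(wx,     1 - wy, 1 - wz) * arrn[x1, y0, z0, drop = FALSE] +
           w3(1 - wx, wy,     1 - wz) * arrn[x0, y1, z0, drop = FALSE] +
           w3(wx,     wy,     1 - wz) * arrn[x1, y1, z0, drop = FALSE] +
           w3(1 - wx, 1 - wy, wz)     * arrn[x0, y0, z1, drop = FALSE] +
           w3(wx,     1 - wy, wz)     * arrn[x1, y0, z1, drop = FALSE] +
           w3(1 - wx, wy,     wz)     * arrn[x0, y1, z1, drop = FALSE] +
           w3(wx,     wy,     wz)     * arrn[x1, y1, z1, drop = FALSE]
  }
  if (storage_logical && method == "nearest") out <- array(as.logical(out), nd)
  volume_grid(out, rep(target_mm, 3), attr(vol, "origin") %||% c(0, 0, 0))
}

#' Read a NIfTI volume as a `volume_grid`
#' @param path path to a .nii or .nii.gz file.
#' @return a `volume_grid`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D volume: ", path)
  volume_grid(arr, sp[seq_len(3)])
}

#' Write a `volume_grid` to NIfTI
#' @param vol a `volume_grid` (logical masks are written as 0/1 integers).
#' @param path output path (.nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- unclass(vol)
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  attributes(arr) <- list(dim = dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vg_spacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}
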
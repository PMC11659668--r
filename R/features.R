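#' Feature extraction configuration
#'
#' @param bin_width fixed intensity bin width (HU) used to discretize the
#'   region before texture matrices are built (default 25, a common
#'   radiomics choice).
#' @param min_voxels minimum region size for texture extraction; smaller
#'   regions yield a missing-feature sentinel (default 27, one 3x3x3
#'   neighbourhood).
#' @param classes feature classes to extract.
#' @return a `feature_config` list.
#' @export
feature_config <- function(bin_width = 25, min_voxels = 27,
                           classes = c("shape", "firstorder", "glcm",
                                       "glrlm", "glszm", "ngtdm")) {
  if (bin_width <= 0) stop("bin_width must be positive")
  structure(list(bin_width = bin_width, min_voxels = min_voxels,
                 classes = classes), class = "feature_config")
}

# names of every feature produced for the given classes, in extraction order
all_feature_names <- function(classes = feature_config()$classes) {
  nm <- list(
    shape = paste0("shape_", c("voxel_count", "volume_mm3", "surface_area_mm2",
                               "surface_volume_ratio", "sphericity",
                               "max_3d_diameter_mm", "major_axis_mm",
                               "minor_axis_mm", "least_axis_mm",
                               "elongation", "flatness")),
    firstorder = paste0("fo_", c("mean", "median", "min", "max", "range",
                                 "p10", "p90", "iqr", "variance", "skewness",
                                 "kurtosis", "energy", "total_energy", "rms",
                                 "mad", "rmad", "entropy", "uniformity")),
    glcm = paste0("glcm_", c("contrast", "dissimilarity", "homogeneity",
                             "idm", "correlation", "autocorrelation",
                             "cluster_shade", "cluster_prominence",
                             "joint_energy", "joint_entropy", "sum_average",
                             "sum_entropy", "difference_entropy",
                             "max_probability")),
    glrlm = paste0("glrlm_", c("sre", "lre", "gln", "rln", "rp", "lglre",
                               "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle")),
    glszm = paste0("glszm_", c("sae", "lae", "gln", "szn", "zp", "lglze",
                               "hglze", "salgle", "sahgle", "lalgle", "lahgle")),
    ngtdm = paste0("ngtdm_", c("coarseness", "contrast", "busyness",
                               "complexity", "strength")))
  unlist(nm[classes], use.names = FALSE)
}

# crop arrays to the bounding box of a mask (cuts texture kernel cost)
crop_to_mask <- function(mask, arrs) {
  idx <- which(mask, arr.ind = TRUE)
  rg <- apply(idx, 2, range)
  sl <- lapply(1:3, function(a) rg[1, a]:rg[2, a])
  c(list(mask = mask[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]),
    lapply(arrs, function(a) a[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]))
}

# fixed-bin-width discretization relative to the region minimum
discretize_region <- function(vals, bin_width) {
  pmax(1L, as.integer(floor((vals - min(vals)) / bin_width)) + 1L)
}

# ---- shape ------------------------------------------------------------------

# surface area from the gradient-magnitude integral of the Gaussian-smoothed
# indicator (sigma 0.8 voxels: lowest bias against analytic spheres)
surface_area_mm2 <- function(mask, spacing) {
  cpp_surface_area(as.logical(mask), dim(mask), spacing, 0.8)
}

# voxels of the mask with at least one 6-neighbour outside it
boundary_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  for (axis in 1:3) {
    n <- d[axis]
    for (o in c(-1L, 1L)) {
      sl <- lapply(d, seq_len)
      sl[[axis]] <- pmin(pmax(seq_len(n) + o, 1L), n)
      shifted <- mask[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
      # clamped border voxels count as boundary
      edge <- if (o == 1L) n else 1L
      slb <- lapply(d, seq_len)
      interior <- interior & shifted
      slb[[axis]] <- edge
      interior[slb[[1]], slb[[2]], slb[[3]]] <- FALSE
    }
  }
  mask & !interior
}

# near-uniform direction set for diameter estimation (Fibonacci sphere)
diameter_directions <- function(k = 49) {
  i <- seq_len(k) - 0.5
  phi <- acos(1 - 2 * i / k)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

shape_features <- function(mask, spacing) {
  nv <- sum(mask)
  voxvol <- prod(spacing)
  vol <- nv * voxvol
  area <- surface_area_mm2(mask, spacing)
  idx <- which(mask, arr.ind = TRUE)
  pts <- sweep(idx - 0.5, 2, spacing, `*`)
  # maximum 3D diameter approximated from extreme boundary voxels along 49
  # near-uniform directions
  bidx <- which(boundary_voxels(mask), arr.ind = TRUE)
  bp <- sweep(bidx - 0.5, 2, spacing, `*`)
  proj <- bp %*% t(diameter_directions())
  cand <- unique(c(apply(proj, 2, which.min), apply(proj, 2, which.max)))
  cp <- bp[cand, , drop = FALSE]
  maxdiam <- if (nrow(cp) > 1) sqrt(max(as.matrix(stats::dist(cp))^2)) else 0
  ev <- if (nv > 3) {
    e <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
    pmax(e, 0)
  } else c(0, 0, 0)
  axis_len <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  # surface discretization can push the estimate marginally past the
  # theoretical maximum of 1 for near-perfect spheres; cap at the bound
  sph <- if (area > 0) min((pi^(1 / 3) * (6 * vol)^(2 / 3)) / area, 1) else NA_real_
  c(shape_voxel_count = nv, shape_volume_mm3 = vol,
    shape_surface_area_mm2 = area,
    shape_surface_volume_ratio = if (vol > 0) area / vol else NA_real_,
    shape_sphericity = sph, shape_max_3d_diameter_mm = maxdiam,
    shape_major_axis_mm = axis_len[1], shape_minor_axis_mm = axis_len[2],
    shape_least_axis_mm = axis_len[3],
    shape_elongation = elong, shape_flatness = flat)
}

# ---- first order ------------------------------------------------------------

firstorder_features <- function(vals, voxvol, bin_width) {
  n <- length(vals)
  m <- mean(vals)
  s2 <- mean((vals - m)^2)
  s <- sqrt(s2)
  qs <- quantile(vals, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  inner <- vals[vals >= qs[1] & vals <= qs[4]]
  skew <- if (s > 0) mean((vals - m)^3) / s^3 else 0
  kurt <- if (s > 0) mean((vals - m)^4) / s2^2 else 0
  lev <- discretize_region(vals, bin_width)
  p <- tabulate(lev) / n
  p <- p[p > 0]
  c(fo_mean = m, fo_median = median(vals), fo_min = min(vals),
    fo_max = max(vals), fo_range = max(vals) - min(vals),
    fo_p10 = qs[1], fo_p90 = qs[4], fo_iqr = qs[3] - qs[2],
    fo_variance = s2, fo_skewness = skew, fo_kurtosis = kurt,
    fo_energy = sum(vals^2), fo_total_energy = sum(vals^2) * voxvol,
    fo_rms = sqrt(mean(vals^2)), fo_mad = mean(abs(vals - m)),
    fo_rmad = if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    fo_entropy = -sum(p * log2(p)), fo_uniformity = sum(p^2))
}

# ---- texture ----------------------------------------------------------------

glcm_features_one <- function(P) {
  nb <- nrow(P)
  lev <- seq_len(nb)
  I <- matrix(lev, nb, nb)
  J <- t(I)
  px <- rowSums(P)
  mux <- sum(lev * px)
  sx <- sqrt(sum((lev - mux)^2 * px))
  autoc <- sum(P * I * J)
  corr <- if (sx > 0) (autoc - mux^2) / sx^2 else 1
  pk <- rowsum(as.vector(P), as.vector(I + J))           # p_{x+y}
  kk <- as.numeric(rownames(pk))
  pd <- rowsum(as.vector(P), as.vector(abs(I - J)))      # p_{|x-y|}
  nz <- P[P > 0]
  pknz <- pk[pk > 0]
  pdnz <- pd[pd > 0]
  c(glcm_contrast = sum(P * (I - J)^2),
    glcm_dissimilarity = sum(P * abs(I - J)),
    glcm_homogeneity = sum(P / (1 + abs(I - J))),
    glcm_idm = sum(P / (1 + (I - J)^2)),
    glcm_correlation = corr,
    glcm_autocorrelation = autoc,
    glcm_cluster_shade = sum(P * (I + J - 2 * mux)^3),
    glcm_cluster_prominence = sum(P * (I + J - 2 * mux)^4),
    glcm_joint_energy = sum(P^2),
    glcm_joint_entropy = -sum(nz * log2(nz)),
    glcm_sum_average = sum(kk * pk),
    glcm_sum_entropy = -sum(pknz * log2(pknz)),
    glcm_difference_entropy = -sum(pdnz * log2(pdnz)),
    glcm_max_probability = max(P))
}

# features averaged over the 13 directions (symmetric co-occurrence)
glcm_features <- function(g, nb) {
  cube <- cpp_glcm(g, dim(g), nb)
  feats <- NULL
  used <- 0
  for (d in 1:13) {
    C <- cube[, , d, drop = TRUE]
    if (nb == 1) C <- matrix(C, 1, 1)
    tot <- sum(C)
    if (tot == 0) next
    f <- glcm_features_one(C / tot)
    feats <- if (is.null(feats)) f else feats + f
    used <- used + 1
  }
  if (used == 0) return(setNames(rep(NA_real_, 14), paste0("glcm_", c(
    "contrast", "dissimilarity", "homogeneity", "idm", "correlation",
    "autocorrelation", "cluster_shade", "cluster_prominence", "joint_energy",
    "joint_entropy", "sum_average", "sum_entropy", "difference_entropy",
    "max_probability"))))
  feats / used
}

glrlm_features <- function(g, nb, n_vox) {
  M <- cpp_glrlm(g, dim(g), nb)
  jmax <- max(which(colSums(M) > 0), 1)
  M <- M[, seq_len(jmax), drop = FALSE]
  i <- matrix(seq_len(nb), nb, jmax)
  j <- matrix(seq_len(jmax), nb, jmax, byrow = TRUE)
  Nr <- sum(M)
  Np <- 13 * n_vox  # voxels counted once per direction family
  c(glrlm_sre = sum(M / j^2) / Nr,
    glrlm_lre = sum(M * j^2) / Nr,
    glrlm_gln = sum(rowSums(M)^2) / Nr,
    glrlm_rln = sum(colSums(M)^2) / Nr,
    glrlm_rp = Nr / Np,
    glrlm_lglre = sum(M / i^2) / Nr,
    glrlm_hglre = sum(M * i^2) / Nr,
    glrlm_srlgle = sum(M / (i^2 * j^2)) / Nr,
    glrlm_srhgle = sum(M * i^2 / j^2) / Nr,
    glrlm_lrlgle = sum(M * j^2 / i^2) / Nr,
    glrlm_lrhgle = sum(M * i^2 * j^2) / Nr)
}

glszm_features <- function(g, nb, n_vox) {
  zones <- cpp_glszm_zones(g, dim(g))
  i <- zones[, 1]
  s <- zones[, 2]
  Nz <- nrow(zones)
  gl <- rowsum(rep(1, Nz), i)            # zones per grey level
  sz <- rowsum(rep(1, Nz), s)            # zones per size
  c(glszm_sae = sum(1 / s^2) / Nz,
    glszm_lae = sum(s^2) / Nz,
    glszm_gln = sum(gl^2) / Nz,
    glszm_szn = sum(sz^2) / Nz,
    glszm_zp = Nz / n_vox,
    glszm_lglze = sum(1 / i^2) / Nz,
    glszm_hglze = sum(i^2) / Nz,
    glszm_salgle = sum(1 / (i^2 * s^2)) / Nz,
    glszm_sahgle = sum(i^2 / s^2) / Nz,
    glszm_lalgle = sum(s^2 / i^2) / Nz,
    glszm_lahgle = sum(i^2 * s^2) / Nz)
}

ngtdm_features <- function(g, nb) {
  r <- cpp_ngtdm(g, dim(g), nb)
  s <- r$s
  n <- r$n
  N <- sum(n)
  p <- n / N
  nz <- which(p > 0)
  Ngp <- length(nz)
  lev <- seq_len(nb)
  denom_c <- sum(p * s)
  coarseness <- if (denom_c > 0) 1 / denom_c else 1e6
  contrast <- 0
  busyness <- 0
  complexity <- 0
  strength <- 0
  if (Ngp > 1) {
    pi_ <- p[nz]; si <- s[nz]; li <- lev[nz]
    D2 <- outer(li, li, function(a, b) (a - b)^2)
    contrast <- (sum(outer(pi_, pi_) * D2) / (Ngp * (Ngp - 1))) * (sum(si) / N)
    bd <- sum(abs(outer(li * pi_, li * pi_, `-`)))
    busyness <- if (bd > 0) sum(pi_ * si) / bd else 0
    PS <- outer(pi_ * si, pi_ * si, `+`)
    PP <- outer(pi_, pi_, `+`)
    complexity <- sum(abs(outer(li, li, `-`)) * PS / PP) / N
    strength <- if (sum(si) > 0) sum(PP * D2) / sum(si) else 0
  }
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

#' Extract radiomic features from one region of a CT volume
#'
#' Computes shape descriptors on the mask, first-order statistics on the
#' masked intensities and texture features (GLCM averaged over 13 3D
#' directions at distance 1, plus GLRLM, GLSZM and NGTDM) on intensities
#' discretized with a fixed bin width. Regions smaller than
#' `config$min_voxels` return an all-`NA` sentinel vector, which the
#' selection stage later imputes or drops.
#'
#' @param ct CT `volume_grid` or plain 3D array.
#' @param mask logical 3D region mask on the same lattice.
#' @param spacing voxel spacing (mm); taken from `ct` when absent.
#' @param config a [feature_config()].
#' @param classes feature classes to compute (default from config).
#' @return named numeric vector of features.
#' @export
extract_region_features <- function(ct, mask, spacing = NULL,
                                    config = feature_config(),
                                    classes = config$classes) {
  if (is.null(spacing)) spacing <- vg_spacing(ct)
  spacing <- rep_len(as.numeric(spacing), 3L)
  nv <- sum(mask)
  nms <- all_feature_names(classes)
  if (nv < config$min_voxels)
    return(setNames(rep(NA_real_, length(nms)), nms))
  out <- numeric(0)
  need_tex <- any(c("glcm", "glrlm", "glszm", "ngtdm") %in% classes)
  cr <- crop_to_mask(array(as.logical(mask), dim(mask)),
                     list(ct = unclass(ct) * 1.0))
  cmask <- cr$mask
  cct <- cr$ct
  vals <- cct[cmask]
  if ("shape" %in% classes) out <- c(out, shape_features(cmask, spacing))
  if ("firstorder" %in% classes)
    out <- c(out, firstorder_features(vals, prod(spacing), config$bin_width))
  if (need_tex) {
    g <- array(0L, dim(cmask))
    g[cmask] <- discretize_region(vals, config$bin_width)
    nb <- max(g)
    if ("glcm" %in% classes) out <- c(out, glcm_features(g, nb))
    if ("glrlm" %in% classes) out <- c(out, glrlm_features(g, nb, nv))
    if ("glszm" %in% classes) out <- c(out, glszm_features(g, nb, nv))
    if ("ngtdm" %in% classes) out <- c(out, ngtdm_features(g, nb))
  }
  out[nms]
}

#' Feature bookkeeping across regions
#'
#' The per-region feature count multiplied by the number of regions (seven
#' discrete plus three composite by default), the convention used when
#' quoting a cumulative feature count for the ten-region analysis.
#'
#' @param per_region features extracted per region.
#' @param n_regions number of regions (default 10).
#' @return total feature count.
#' @export
feature_bookkeeping <- function(per_region, n_regions = 10) per_region * n_regions

#' Build the cohort feature table
#'
#' Regenerates every patient of a synthetic cohort, builds its region set and
#' extracts features for the seven discrete regions. Composite regions (RA,
#' RAP, RAPB) are represented by concatenation of their member-region columns
#' (aliased, not duplicated in storage); the `composites` attribute maps each
#' composite to its member column names.
#'
#' @param cohort an `srp_cohort` from [generate_cohort()].
#' @param config a [feature_config()].
#' @param resample_mm optional isotropic resampling target before extraction
#'   (`NULL` keeps the native lattice, which for the phantom is already
#'   isotropic).
#' @return a `feature_table` data.frame: `patient_id`, `label`, then
#'   `<region>__<feature>` columns; attributes `composites`,
#'   `per_region_count`, `bookkeeping_total`.
#' @export
build_feature_table <- function(cohort, config = feature_config(),
                                resample_mm = NULL) {
  regions <- discrete_regions()
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pat <- phantom_patient(cohort, i)
    ct <- pat$ct; dose <- pat$dose; bed3 <- pat$bed3
    lungs <- pat$lungs; gtv <- pat$gtv; ptv <- pat$ptv
    if (!is.null(resample_mm)) {
      ct <- resample_isotropic(ct, resample_mm, "linear")
      dose <- resample_isotropic(dose, resample_mm, "linear")
      bed3 <- resample_isotropic(bed3, resample_mm, "linear")
      rs <- function(m) unclass(resample_isotropic(vg_like(m, pat$ct), resample_mm, "nearest"))
      lungs <- rs(lungs); gtv <- rs(gtv); ptv <- rs(ptv)
    }
    rs <- suppressWarnings(
      build_region_set(lungs, gtv, ptv, dose, bed3))
    feats <- lapply(regions, function(rn)
      extract_region_features(ct, rs$masks[[rn]], vg_spacing(ct), config))
    v <- unlist(feats)
    names(v) <- paste0(rep(regions, each = length(feats[[1]])),
                       "__", unlist(lapply(feats, names)))
    rows[[i]] <- v
  }
  mat <- do.call(rbind, rows)
  tab <- data.frame(patient_id = cohort$id, label = cohort$label,
                    mat, check.names = FALSE)
  per_region <- ncol(mat) / length(regions)
  comp <- lapply(composite_regions(), function(members)
    as.vector(outer(all_feature_names(config$classes),
                    members, function(f, r) paste0(r, "__", f))))
  structure(tab, composites = comp, per_region_count = per_region,
            bookkeeping_total = feature_bookkeeping(
              per_region, length(regions) + length(comp)),
            class = c("feature_table", "data.frame"))
}

feature_columns <- function(table) {
  setdiff(names(table), c("patient_id", "label", "split"))
}

#' Z-score normalization fitted on the training split
#'
#' Column means and sample standard deviations (n - 1) are computed on the
#' training rows only and applied to all rows. Missing values (undersized
#' regions) are imputed with the training-column median first. Columns with
#' zero training variance are dropped and recorded.
#'
#' @param table a feature table (data.frame with feature columns).
#' @param train logical/integer index of training rows.
#' @return list: `table` (normalized), `center`, `scale`, `dropped`,
#'   `medians` — apply to new data with [apply_normalization()].
#' @export
zscore_fit_transform <- function(table, train) {
  cols <- feature_columns(table)
  tr <- table[train, cols, drop = FALSE]
  if (nrow(tr) < 2) stop("need at least two training rows to fit a z-score")
  med <- vapply(tr, function(x) median(x, na.rm = TRUE), numeric(1))
  for (cn in cols) {
    x <- table[[cn]]
    x[is.na(x)] <- med[[cn]]
    table[[cn]] <- x
  }
  tr <- table[train, cols, drop = FALSE]
  ctr <- vapply(tr, mean, numeric(1))
  scl <- vapply(tr, sd, numeric(1))
  dropped <- cols[!is.finite(scl) | scl < 1e-12]
  keep <- setdiff(cols, dropped)
  for (cn in keep) table[[cn]] <- (table[[cn]] - ctr[[cn]]) / scl[[cn]]
  table <- table[, c(setdiff(names(table), cols), keep), drop = FALSE]
  list(table = table, center = ctr[keep], scale = scl[keep],
       dropped = dropped, medians = med)
}

#' Write a feature table to CSV with a JSON sidecar
#'
#' The CSV holds one row per patient (`patient_id`, `label`, optional
#' `split`, then feature columns); the sidecar records the normalization
#' parameters (if supplied) and the composite-region column map.
#'
#' @param table a feature table (normalized or raw).
#' @param path output CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param norm optional result of [zscore_fit_transform()].
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, norm = NULL) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  sidecar <- list(composites = attr(table, "composites"),
                  per_region_count = attr(table, "per_region_count"))
  if (!is.null(norm))
    sidecar$normalization <- list(center = as.list(norm$center),
                                  scale = as.list(norm$scale),
                                  dropped = norm$dropped)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Apply stored normalization parameters to new data
#' @param table feature table rows to transform.
#' @param norm result of [zscore_fit_transform()].
#' @return transformed table with the surviving feature columns.
#' @export
apply_normalization <- function(table, norm) {
  for (cn in names(norm$center)) {
    x <- table[[cn]]
    x[is.na(x)] <- norm$medians[[cn]]
    table[[cn]] <- (x - norm$center[[cn]]) / norm$scale[[cn]]
  }
  table[, c(setdiff(names(table), c(names(norm$center), norm$dropped)),
            names(norm$center)), drop = FALSE]
}
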
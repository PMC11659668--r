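#' Specification of a synthetic thoracic phantom
#'
#' Describes the geometry and texture of one synthetic patient: two lung
#' ellipsoids, a spherical tumour (GTV) inside one lung, CT noise, and a
#' correlated Gaussian-random-field lung texture. The PTV is produced by
#' anisotropic dilation of the GTV with SBRT-style margins (default 3 mm
#' lateral / posteroanterior, 5 mm craniocaudal).
#'
#' @param grid_shape voxels per axis (length 3).
#' @param spacing_mm voxel size in mm (length 1 or 3).
#' @param lung_ellipsoids list of two lists, each with `centre` and `radii`
#'   in mm (grid coordinates, origin at the first voxel corner).
#' @param tumour_centre_mm centre of the spherical GTV (mm).
#' @param tumour_radius_mm GTV radius (mm, > 0).
#' @param margins_mm PTV expansion margins per axis (mm), default c(3, 3, 5).
#' @param ct_noise_sd white CT noise standard deviation (HU).
#' @param texture_sd_hu amplitude (HU) of the correlated lung texture field.
#' @param texture_correlation_length_mm Gaussian-random-field correlation
#'   length (mm).
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing_mm = 2.5,
                         lung_ellipsoids = list(
                           list(centre = c(38, 80, 80), radii = c(30, 48, 62)),
                           list(centre = c(122, 80, 80), radii = c(30, 48, 62))),
                         tumour_centre_mm = c(38, 80, 80),
                         tumour_radius_mm = 15,
                         margins_mm = c(3, 3, 5),
                         ct_noise_sd = 20,
                         texture_sd_hu = 50,
                         texture_correlation_length_mm = 8) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("spacing must be positive")
  if (tumour_radius_mm <= 0) stop("tumour radius must be positive")
  if (any(vapply(lung_ellipsoids, function(e) any(e$radii <= 0), logical(1))))
    stop("lung radii must be positive")
  spec <- list(grid_shape = as.integer(rep_len(grid_shape, 3L)),
               spacing_mm = spacing_mm,
               lung_ellipsoids = lung_ellipsoids,
               tumour_centre_mm = as.numeric(tumour_centre_mm),
               tumour_radius_mm = as.numeric(tumour_radius_mm),
               margins_mm = rep_len(as.numeric(margins_mm), 3L),
               ct_noise_sd = ct_noise_sd,
               texture_sd_hu = texture_sd_hu,
               texture_correlation_length_mm = texture_correlation_length_mm)
  class(spec) <- "phantom_spec"
  # reject a tumour that cannot sit inside either lung (conservative
  # reduced-semi-axis check; exact voxel containment re-checked at build time)
  if (!any(vapply(lung_ellipsoids, function(e) {
    rr <- e$radii - spec$tumour_radius_mm
    all(rr > 0) && sum(((spec$tumour_centre_mm - e$centre) / rr)^2) <= 1
  }, logical(1))))
    stop("tumour sphere is not inside a lung ellipsoid: invalid phantom spec")
  spec
}

# stationary Gaussian random field with unit variance via FFT-filtered white
# noise; squared-exponential spectrum with correlation length ell (mm)
gaussian_random_field <- function(d, spacing, ell) {
  w <- array(rnorm(prod(d)), d)
  if (ell <= 0) return(w)
  kax <- function(n, s) {
    ii <- seq_len(n) - 1
    ii[ii > n / 2] <- ii[ii > n / 2] - n
    (2 * pi * ii / (n * s))^2
  }
  k2 <- outer(outer(kax(d[1], spacing[1]), kax(d[2], spacing[2]), "+"),
              kax(d[3], spacing[3]), "+")
  H <- exp(-0.5 * ell^2 * k2)
  f <- Re(fft(fft(w) * H, inverse = TRUE)) / prod(d)
  f / sd(f)
}

# deterministic geometry (no RNG): lungs/GTV/PTV masks of a phantom spec
phantom_geometry <- function(spec) {
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  xs <- (seq_len(d[1]) - 0.5) * sp[1]
  ys <- (seq_len(d[2]) - 0.5) * sp[2]
  zs <- (seq_len(d[3]) - 0.5) * sp[3]
  ell_mask <- function(centre, radii) {
    q <- outer(outer(((xs - centre[1]) / radii[1])^2,
                     ((ys - centre[2]) / radii[2])^2, "+"),
               ((zs - centre[3]) / radii[3])^2, "+")
    q <= 1
  }
  lungs <- Reduce(`|`, lapply(spec$lung_ellipsoids,
                              function(e) ell_mask(e$centre, e$radii)))
  ctr <- spec$tumour_centre_mm
  r <- spec$tumour_radius_mm
  gtv <- outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+"), (zs - ctr[3])^2, "+") <= r^2
  if (!any(gtv)) stop("GTV contains no voxels: tumour too small for the lattice")
  if (any(gtv & !lungs)) stop("tumour extends outside the lungs: invalid phantom spec")
  # anisotropic dilation: distance transform with axis spacing scaled by the
  # margins, thresholded at 1, gives an ellipsoidal structuring element;
  # computed on the GTV bounding box (plus margin) for speed
  idx <- which(gtv, arr.ind = TRUE)
  pad <- ceiling(spec$margins_mm / sp) + 2L
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  sub <- gtv[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d2 <- cpp_edt3d(as.logical(sub), dim(sub), sp / spec$margins_mm)
  ptv <- array(FALSE, d)
  ptv[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- d2 <= 1 + 1e-12
  list(lungs = lungs, gtv = gtv, ptv = ptv, spacing = sp)
}

#' Generate one synthetic thoracic phantom
#'
#' Builds the CT intensity volume and the lungs/GTV/PTV masks for a
#' [phantom_spec()]. The CT is soft tissue (~35 HU) outside the lungs,
#' lung parenchyma (~-800 HU) with an additive correlated texture field
#' inside, and tumour-like density (~20 HU) inside the GTV, plus white
#' noise everywhere. The PTV is the GTV dilated anisotropically by the
#' margins. Identical (spec, seed) pairs give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed.
#' @return list with `ct` (`volume_grid`), and logical masks `lungs`
#'   (bilateral lungs, tumour included), `gtv`, `ptv`.
#' @export
generate_phantom <- function(spec, seed) {
  set.seed(seed)
  geo <- phantom_geometry(spec)
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  field <- gaussian_random_field(d, sp, spec$texture_correlation_length_mm)
  ct <- array(35, d)
  ct[geo$lungs] <- -800 + spec$texture_sd_hu * field[geo$lungs]
  ct[geo$gtv] <- 20
  if (spec$ct_noise_sd > 0) ct <- ct + array(rnorm(prod(d), 0, spec$ct_noise_sd), d)
  list(ct = volume_grid(ct, sp),
       lungs = geo$lungs, gtv = geo$gtv, ptv = geo$ptv)
}

#' Generate an analytic SBRT-like dose grid
#'
#' The dose equals the prescription (the scheme's total dose) inside the
#' PTV and decays with the Euclidean distance to the PTV through an
#' exponential kernel `exp(-dist / falloff_mm)`, producing nested iso-dose
#' shells like a steep SBRT gradient.
#'
#' @param ct the phantom CT (`volume_grid`), used for the lattice.
#' @param ptv PTV mask; must be non-empty.
#' @param scheme a [fractionation_scheme()].
#' @param falloff_mm exponential falloff length (mm, > 0).
#' @return a dose `volume_grid` (Gy), maximum equal to the prescription.
#' @export
generate_dose <- function(ct, ptv, scheme, falloff_mm = 8) {
  if (!is.finite(falloff_mm) || falloff_mm <= 0) stop("falloff_mm must be positive")
  if (!any(ptv)) stop("empty PTV: cannot generate dose")
  dist <- distance_to_mask(ptv, vg_spacing(ct))
  vg_like(scheme$total_dose * exp(-dist / falloff_mm), ct)
}

#' Risk model for synthetic SRP labels
#'
#' Labels are drawn Bernoulli(p) with
#' `logit p = beta0 + beta_vbed70 * V_BED70 + beta_texture * z`, where
#' V_BED70 is in percent of the nontarget lung and z is the cohort-standardized
#' value of a named texture feature extracted inside the B70 region. `beta0`
#' is auto-calibrated by bisection so the mean event probability matches
#' `prevalence_target`.
#'
#' @param beta_vbed70 log-odds per percentage point of V_BED70; the default
#'   plants an odds ratio of 4.84 per unit.
#' @param beta_texture log-odds per SD of the texture covariate (default 0:
#'   the dosimetric signal is the sole risk factor).
#' @param texture_feature name of the B70 texture feature used as covariate.
#' @param prevalence_target mean event probability in (0, 1); default 0.146.
#' @return a `risk_model_spec`.
#' @export
risk_model_spec <- function(beta_vbed70 = log(4.84), beta_texture = 0,
                            texture_feature = "glcm_contrast",
                            prevalence_target = 0.146) {
  if (prevalence_target <= 0 || prevalence_target >= 1)
    stop("prevalence_target must be in (0, 1)")
  structure(list(beta_vbed70 = beta_vbed70, beta_texture = beta_texture,
                 texture_feature = texture_feature,
                 prevalence_target = prevalence_target),
            class = "risk_model_spec")
}

# bisection on the intercept so mean(plogis(b0 + eta)) hits the target
calibrate_intercept <- function(eta, target, tol = 0.005) {
  f <- function(b0) mean(plogis(b0 + eta))
  lo <- -40; hi <- 40
  if (f(lo) > target + tol || f(hi) < target - tol)
    stop("unattainable prevalence: event probabilities are saturated")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < 1e-9) break
  }
  b0 <- (lo + hi) / 2
  if (abs(f(b0) - target) > tol)
    stop("unattainable prevalence: bisection cannot reach the target")
  b0
}

#' Per-patient condition sampler for cohort generation
#'
#' Draws per-patient study conditions emulating the trial population:
#' fractionation schemes spanning 4-12 fractions of 6-12.5 Gy with tumour
#' BED10 near 100 Gy (10 x 6 Gy most common), tumour diameters ~16-44 mm,
#' tumour position uniform inside a lung, dose falloff 6-12 mm, lung texture
#' correlation length 4-12 mm, and baseline clinical covariates matching the
#' published marginals (age ~ N(73, 10) truncated to 39-94, 60% male, COPD
#' 33%, ECOG 0/1/2 at 18/51/31%). Clinical covariates carry no planted
#' effect.
#'
#' @param base a [phantom_spec()] providing the fixed anatomy (grid, lungs,
#'   noise/texture amplitudes).
#' @param schemes data.frame with columns `n`, `d` (fractions, Gy/fraction)
#'   and `prob`.
#' @param tumour_radius_range GTV radius range (mm) sampled uniformly;
#'   the default spans diameters of 16-44 mm.
#' @return a `phantom_sampler`: list with `base` and `draw(n)` returning a
#'   data.frame of per-patient parameters (uses the current RNG stream).
#' @export
phantom_sampler <- function(base = phantom_spec(),
                            schemes = data.frame(
                              n = c(10L, 8L, 5L, 4L),
                              d = c(6, 7.5, 10, 12),
                              prob = c(0.45, 0.20, 0.20, 0.15)),
                            tumour_radius_range = c(8, 22)) {
  draw <- function(np) {
    idx <- sample.int(nrow(schemes), np, replace = TRUE, prob = schemes$prob)
    radius <- runif(np, tumour_radius_range[1], tumour_radius_range[2])
    side <- sample.int(length(base$lung_ellipsoids), np, replace = TRUE)
    tc <- matrix(0, np, 3)
    for (i in seq_len(np)) {
      e <- base$lung_ellipsoids[[side[i]]]
      slack <- e$radii - radius[i] - 2
      if (any(slack <= 0)) slack <- pmax(e$radii - radius[i], 0.5)
      repeat {
        u <- runif(3, -1, 1)
        if (sum(u^2) <= 1) break
      }
      tc[i, ] <- e$centre + u * slack
    }
    age <- pmin(pmax(round(rnorm(np, 73, 10)), 39), 94)
    data.frame(n_fractions = schemes$n[idx],
               dose_per_fraction = schemes$d[idx],
               tumour_radius_mm = radius,
               tc_x = tc[, 1], tc_y = tc[, 2], tc_z = tc[, 3],
               falloff_mm = runif(np, 6, 12),
               corr_len_mm = runif(np, 4, 12),
               age = age,
               sex_male = rbinom(np, 1, 0.6),
               copd = rbinom(np, 1, 0.33),
               ecog = sample(0:2, np, replace = TRUE, prob = c(0.18, 0.51, 0.31)))
  }
  structure(list(base = base, draw = draw), class = "phantom_sampler")
}

# rebuild the phantom_spec of one cohort row
row_spec <- function(base, row) {
  spec <- base
  spec$tumour_centre_mm <- c(row$tc_x, row$tc_y, row$tc_z)
  spec$tumour_radius_mm <- row$tumour_radius_mm
  spec$texture_correlation_length_mm <- row$corr_len_mm
  class(spec) <- "phantom_spec"
  spec
}

#' Generate a synthetic SBRT cohort with SRP labels
#'
#' Samples per-patient phantoms and plans, computes the dosimetric metrics
#' of each plan, and draws SRP labels from the logistic risk model with a
#' bisection-calibrated intercept. The texture covariate (a named feature
#' inside the B70 region) is only extracted when `risk$beta_texture != 0`.
#' Volumes are not stored: each patient can be regenerated bit-identically
#' from the manifest via [phantom_patient()].
#'
#' @param n_patients cohort size (>= 2).
#' @param sampler a [phantom_sampler()].
#' @param risk a [risk_model_spec()].
#' @param seed integer seed controlling every random draw.
#' @param lung_alpha_beta alpha/beta (Gy) for the lung BED grid (default 3).
#' @return an `srp_cohort`: data.frame (one row per patient: id, seed,
#'   geometry/scheme parameters, clinical covariates, dosimetric metrics,
#'   `p_true`, `label`) with attributes `base_spec`, `risk`, `beta0`.
#' @export
generate_cohort <- function(n_patients, sampler = phantom_sampler(),
                            risk = risk_model_spec(), seed = 1,
                            lung_alpha_beta = 3) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_patients + 1L)
  params <- sampler$draw(n_patients)
  params$id <- sprintf("P%03d", seq_len(n_patients))
  params$seed <- seeds[seq_len(n_patients)]
  need_texture <- risk$beta_texture != 0

  met <- vector("list", n_patients)
  texture <- rep(NA_real_, n_patients)
  for (i in seq_len(n_patients)) {
    # a draw whose tumour sphere clips the lung boundary on the voxel
    # lattice is rejected and redrawn deterministically
    geo <- NULL
    for (attempt in 1:50) {
      spec_i <- row_spec(sampler$base, params[i, ])
      geo <- tryCatch(phantom_geometry(spec_i), error = function(e) NULL)
      if (!is.null(geo)) break
      set.seed(params$seed[i] + attempt)
      redraw <- sampler$draw(1)
      params[i, names(redraw)] <- redraw
    }
    if (is.null(geo)) stop("could not place a tumour inside the lungs for patient ", i)
    scheme <- fractionation_scheme(params$n_fractions[i], params$dose_per_fraction[i])
    vox <- prod(spec_i$spacing_mm) / 1000  # cm^3 per voxel
    if (need_texture) {
      # full phantom (CT needed for the texture covariate)
      ph <- generate_phantom(spec_i, params$seed[i])
      dose <- generate_dose(ph$ct, ph$ptv, scheme, params$falloff_mm[i])
      bed3 <- bed_voxelwise(dose, scheme, lung_alpha_beta)
      lungs_nt <- ph$lungs & !ph$gtv
      m <- dose_metrics(dose, bed3, lungs_nt, scheme)
      m$GTV_cc <- sum(ph$gtv) * vox
      m$PTV_cc <- sum(ph$ptv) * vox
      b70 <- lungs_nt & (unclass(bed3) >= 70)
      fv <- extract_region_features(ph$ct, b70, vg_spacing(ph$ct),
                                    classes = "glcm")
      texture[i] <- fv[[risk$texture_feature]]
    } else {
      # geometry-only fast path: the CT does not influence dose metrics or
      # labels, so only the lung-voxel dose/BED vectors are evaluated
      dist <- distance_to_mask(geo$ptv, spec_i$spacing_mm)
      lungs_nt <- geo$lungs & !geo$gtv
      dv <- scheme$total_dose * exp(-dist[lungs_nt] / params$falloff_mm[i])
      bv <- bed_total(dv, scheme, lung_alpha_beta)
      m <- metrics_from_vectors(dv, bv, scheme)
      m$GTV_cc <- sum(geo$gtv) * vox
      m$PTV_cc <- sum(geo$ptv) * vox
    }
    met[[i]] <- m
  }
  metrics <- do.call(rbind, lapply(met, function(m) as.data.frame(m)))
  out <- cbind(params, metrics)
  out$diameter_mm <- 2 * out$tumour_radius_mm
  out$total_dose <- out$n_fractions * out$dose_per_fraction

  eta <- risk$beta_vbed70 * out$VBED70
  if (need_texture) {
    z <- as.numeric(scale(texture))
    z[!is.finite(z)] <- 0
    out$texture_cov <- z
    eta <- eta + risk$beta_texture * z
  }
  beta0 <- calibrate_intercept(eta, risk$prevalence_target)
  out$p_true <- plogis(beta0 + eta)
  set.seed(seeds[n_patients + 1L])
  out$label <- rbinom(n_patients, 1, out$p_true)

  structure(out, base_spec = sampler$base, risk = risk, beta0 = beta0,
            lung_alpha_beta = lung_alpha_beta,
            class = c("srp_cohort", "data.frame"))
}

#' Regenerate the volumes of one cohort patient
#'
#' Rebuilds the CT, masks, dose and lung BED grids of patient `i` from the
#' manifest, bit-identically to the draw made inside [generate_cohort()].
#'
#' @param cohort an `srp_cohort`.
#' @param i patient row index.
#' @return list: `ct`, `lungs`, `gtv`, `ptv`, `dose`, `bed3`, `scheme`.
#' @export
phantom_patient <- function(cohort, i) {
  base <- attr(cohort, "base_spec")
  row <- cohort[i, ]
  spec_i <- row_spec(base, row)
  ph <- generate_phantom(spec_i, row$seed)
  scheme <- fractionation_scheme(row$n_fractions, row$dose_per_fraction)
  dose <- generate_dose(ph$ct, ph$ptv, scheme, row$falloff_mm)
  bed3 <- bed_voxelwise(dose, scheme, attr(cohort, "lung_alpha_beta") %||% 3)
  c(ph, list(dose = dose, bed3 = bed3, scheme = scheme))
}

#' Write a cohort to disk (NIfTI volumes, JSON manifest, clinical CSV)
#'
#' @param cohort an `srp_cohort`.
#' @param dir output directory (created if needed).
#' @param volumes also write per-patient ct/dose/mask NIfTI files.
#' @return path to the manifest `cohort.json`, invisibly.
#' @export
write_cohort <- function(cohort, dir, volumes = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(cohort)
  if (volumes) {
    for (i in seq_len(nrow(df))) {
      pat <- phantom_patient(cohort, i)
      pdir <- file.path(dir, df$id[i])
      dir.create(pdir, showWarnings = FALSE)
      write_volume(pat$ct, file.path(pdir, "ct.nii.gz"))
      write_volume(pat$dose, file.path(pdir, "dose.nii.gz"))
      for (nm in c("lungs", "gtv", "ptv"))
        write_volume(vg_like(pat[[nm]], pat$ct), file.path(pdir, paste0(nm, ".nii.gz")))
    }
    df$path <- file.path(dir, df$id)
  }
  manifest <- list(risk = unclass(attr(cohort, "risk")),
                   beta0 = attr(cohort, "beta0"),
                   patients = df)
  path <- file.path(dir, "cohort.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  clin <- df[, intersect(c("id", "age", "sex_male", "copd", "ecog", "n_fractions",
                           "dose_per_fraction", "total_dose", "diameter_mm",
                           "GTV_cc", "PTV_cc", "label"), names(df))]
  write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  invisible(path)
}
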
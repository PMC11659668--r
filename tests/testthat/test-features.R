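test_that("a digital ball is recognized as near-spherical", {
  dd <- c(31, 31, 31)
  xs <- (1:31 - 0.5) - 15.5
  ball <- outer(outer(xs^2, xs^2, "+"), xs^2, "+") <= 100
  fv <- extract_region_features(array(0, dd), ball, c(1, 1, 1), classes = "shape")
  expect_gte(fv[["shape_sphericity"]], 0.95)
  expect_lte(fv[["shape_sphericity"]], 1.0)
  expect_equal(fv[["shape_volume_mm3"]], sum(ball))
  expect_equal(fv[["shape_max_3d_diameter_mm"]], 20, tolerance = 0.06)
  expect_equal(fv[["shape_surface_area_mm2"]], 4 * pi * 100, tolerance = 0.03)
  # a sphere has no preferred axis
  expect_gt(fv[["shape_elongation"]], 0.95)
  expect_gt(fv[["shape_flatness"]], 0.95)
})

test_that("constant-intensity regions have zero heterogeneity", {
  m <- array(FALSE, c(8, 8, 8))
  m[2:6, 2:6, 2:6] <- TRUE
  ct <- array(100, c(8, 8, 8))
  fv <- extract_region_features(ct, m, c(1, 1, 1))
  expect_equal(fv[["fo_variance"]], 0)
  expect_equal(fv[["glcm_contrast"]], 0)
  expect_equal(fv[["fo_entropy"]], 0)
  expect_equal(fv[["glcm_max_probability"]], 1)
})

test_that("GLCM features match exhaustive co-occurrence enumeration", {
  # 4x4 single-slice toy image with fixed integer values, bin width 1
  g2 <- matrix(c(1, 2, 5, 2,
                 3, 5, 1, 1,
                 4, 1, 2, 3,
                 5, 3, 4, 4), 4, 4, byrow = TRUE)
  g <- array(0L, c(4, 4, 1))
  g[, , 1] <- as.integer(g2)
  mask <- g > 0
  ct <- (g - 1) * 1.0  # bin width 1 recovers exactly these levels
  cfg <- feature_config(bin_width = 1, min_voxels = 1)
  fv <- extract_region_features(ct, mask, c(1, 1, 1), config = cfg,
                                classes = "glcm")
  # oracle: average the per-direction contrast over the directions present
  dirs <- directions13()
  contrasts <- c()
  for (d in seq_len(13)) {
    M <- oracle_glcm_counts(g, dirs[d, ], 5)
    if (sum(M) == 0) next
    P <- M / sum(M)
    ii <- matrix(1:5, 5, 5)
    contrasts <- c(contrasts, sum(P * (ii - t(ii))^2))
  }
  expect_equal(fv[["glcm_contrast"]], mean(contrasts), tolerance = 1e-12)
})

test_that("GLCM and GLRLM counts match brute force on random toys", {
  set.seed(3)
  g <- array(sample(0:4, 5 * 5 * 5, replace = TRUE), c(5, 5, 5))
  nb <- 4
  cube <- bedrad:::cpp_glcm(as.integer(g), dim(g), nb)
  M <- bedrad:::cpp_glrlm(as.integer(g), dim(g), nb)
  dirs <- directions13()
  Msum <- matrix(0, nb, ncol(M))
  for (d in seq_len(13)) {
    expect_equal(cube[, , d], oracle_glcm_counts(g, dirs[d, ], nb))
    Msum <- Msum + oracle_glrlm_counts(g, dirs[d, ], nb, ncol(M))
  }
  expect_equal(unclass(M), Msum, ignore_attr = TRUE)
})

test_that("first-order and volume features are axis-permutation invariant", {
  set.seed(5)
  ct <- array(rnorm(16 * 12 * 10, -700, 60), c(16, 12, 10))
  m <- array(FALSE, c(16, 12, 10))
  m[3:14, 3:10, 3:8] <- TRUE
  a <- extract_region_features(ct, m, c(1, 1, 1), classes = c("shape", "firstorder"))
  b <- extract_region_features(aperm(ct, c(3, 1, 2)), aperm(m, c(3, 1, 2)),
                               c(1, 1, 1), classes = c("shape", "firstorder"))
  fo <- grep("^fo_", names(a), value = TRUE)
  expect_equal(a[fo], b[fo])
  expect_equal(a[["shape_volume_mm3"]], b[["shape_volume_mm3"]])
})

test_that("undersized regions produce the missing-feature sentinel", {
  m <- array(FALSE, c(6, 6, 6))
  m[1:2, 1, 1] <- TRUE  # 2 voxels < 27
  fv <- extract_region_features(array(0, c(6, 6, 6)), m, c(1, 1, 1))
  expect_true(all(is.na(fv)))
  expect_named(fv, all_feature_names())
})

test_that("feature extraction is reproducible bit-for-bit", {
  pl <- small_plan()
  rs <- suppressWarnings(build_region_set(pl$lungs, pl$gtv, pl$ptv, pl$dose, pl$bed3))
  a <- extract_region_features(pl$ct, rs$masks$B70, vg_spacing(pl$ct))
  b <- extract_region_features(pl$ct, rs$masks$B70, vg_spacing(pl$ct))
  expect_identical(a, b)
})

test_that("the feature table concatenates regions and keeps the bookkeeping", {
  co <- generate_cohort(6, sampler = small_sampler(), seed = 15)
  tab <- suppressWarnings(build_feature_table(co))
  nfeat <- attr(tab, "per_region_count")
  expect_equal(ncol(tab) - 2, 7 * nfeat)   # discrete columns only
  expect_equal(attr(tab, "bookkeeping_total"), feature_bookkeeping(nfeat, 10))
  comp <- attr(tab, "composites")
  expect_length(comp$RAPB, 7 * nfeat)
  expect_true(all(comp$RA %in% names(tab)))
  # published arithmetic convention: per-region count times ten regions
  expect_equal(feature_bookkeeping(1834, 10), 18340)
})

test_that("feature tables serialize to CSV with a JSON sidecar", {
  co <- generate_cohort(4, sampler = small_sampler(), seed = 16)
  tab <- suppressWarnings(build_feature_table(co))
  path <- file.path(tempdir(), "features.csv")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  norm <- zscore_fit_transform(tab, c(TRUE, TRUE, FALSE, FALSE))
  write_feature_table(tab, path, norm)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(back), 4)
  expect_equal(back$patient_id, co$id)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$per_region_count, attr(tab, "per_region_count"))
  expect_equal(unlist(side$normalization$center), norm$center)
})

test_that("z-score normalization follows the training-split sample-SD convention", {
  tab <- data.frame(patient_id = as.character(1:5), label = c(0, 1, 0, 1, 0),
                    a = c(1, 2, 3, 10, -4), b = c(5, 5, 5, 5, 5),
                    c = c(2, 4, 6, 8, 10))
  train <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  norm <- zscore_fit_transform(tab, train)
  # {1,2,3} with sample SD 1 normalizes to {-1, 0, 1}
  expect_equal(norm$table$a[train], c(-1, 0, 1))
  expect_equal(mean(norm$table$c[train]), 0, tolerance = 1e-9)
  expect_equal(sd(norm$table$c[train]), 1, tolerance = 1e-9)
  # constant training column dropped, validation transformed with train stats
  expect_true("b" %in% norm$dropped)
  expect_false("b" %in% names(norm$table))
  expect_equal(norm$table$a[4], (10 - 2) / 1)
  expect_error(zscore_fit_transform(tab, c(TRUE, rep(FALSE, 4))), "two training rows")
})

test_that("missing features are imputed with the training median", {
  tab <- data.frame(patient_id = as.character(1:4), label = c(0, 1, 0, 1),
                    a = c(1, NA, 3, NA))
  norm <- zscore_fit_transform(tab, c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(is.na(norm$table$a)))
  # training median of {1, 3} is 2; imputed then standardized
  expect_equal(norm$table$a[2], (2 - 2) / 1)
})
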
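test_that("phantom masks satisfy the geometric containment invariants", {
  ph <- generate_phantom(small_phantom_spec(), 3)
  expect_true(all(ph$gtv[ph$gtv] & ph$ptv[ph$gtv]))   # gtv subset of ptv
  expect_false(any(ph$gtv & !ph$lungs))               # gtv inside lungs
  expect_true(sum(ph$ptv) > sum(ph$gtv))              # margins add volume
  expect_true(is.logical(ph$lungs) && is.logical(ph$ptv))
})

test_that("identical spec and seed give bit-identical phantoms", {
  spec <- small_phantom_spec()
  a <- generate_phantom(spec, 99)
  b <- generate_phantom(spec, 99)
  expect_identical(a$ct, b$ct)
  expect_identical(a$ptv, b$ptv)
})

test_that("GTV voxel count approximates the analytic sphere volume at 1 mm", {
  spec <- phantom_spec(grid_shape = c(48, 48, 48), spacing_mm = 1,
                       lung_ellipsoids = list(
                         list(centre = c(24, 24, 24), radii = c(20, 20, 20))),
                       tumour_centre_mm = c(24, 24, 24), tumour_radius_mm = 10)
  ph <- generate_phantom(spec, 1)
  expect_lt(abs(sum(ph$gtv) - (4 / 3) * pi * 1000) / ((4 / 3) * pi * 1000), 0.05)
})

test_that("PTV expansion honours the anisotropic 3/5 mm margins", {
  spec <- phantom_spec(grid_shape = c(48, 48, 48), spacing_mm = 1,
                       lung_ellipsoids = list(
                         list(centre = c(24, 24, 24), radii = c(22, 22, 22))),
                       tumour_centre_mm = c(24, 24, 24), tumour_radius_mm = 8)
  ph <- generate_phantom(spec, 1)
  ext <- function(m, axis) {
    idx <- which(m, arr.ind = TRUE)[, axis]
    diff(range(idx)) + 1
  }
  # lateral margins add ~3 mm per side, craniocaudal ~5 mm per side
  expect_equal(ext(ph$ptv, 1) - ext(ph$gtv, 1), 6, tolerance = 1)
  expect_equal(ext(ph$ptv, 3) - ext(ph$gtv, 3), 10, tolerance = 1)
})

test_that("a tumour outside the lungs rejects the spec", {
  expect_error(phantom_spec(grid_shape = c(40, 40, 40), spacing_mm = 2.5,
                            lung_ellipsoids = list(
                              list(centre = c(30, 50, 50), radii = c(15, 20, 25))),
                            tumour_centre_mm = c(80, 50, 50),
                            tumour_radius_mm = 10),
               "not inside a lung")
})

test_that("the analytic dose kernel matches its closed form", {
  spec <- small_phantom_spec()
  ph <- generate_phantom(spec, 5)
  sch <- fractionation_scheme(5, 10)
  dose <- generate_dose(ph$ct, ph$ptv, sch, falloff_mm = 5)
  expect_equal(max(dose), sch$total_dose)
  expect_true(all(unclass(dose) >= 0))
  expect_true(all(unclass(dose)[ph$ptv] == sch$total_dose))
  # a voxel exactly 10 mm from the PTV sees prescription * exp(-2)
  dist <- distance_to_mask(ph$ptv, vg_spacing(ph$ct))
  at10 <- which(abs(dist - 10) < 1e-9)
  if (length(at10) == 0) {
    # force an exactly-10 mm voxel with a flat PTV face on a 1 mm lattice
    m <- array(FALSE, c(30, 30, 30))
    m[1:5, 1:30, 1:30] <- TRUE
    ct <- volume_grid(array(0, c(30, 30, 30)), 1)
    d2 <- generate_dose(ct, m, sch, falloff_mm = 5)
    expect_equal(d2[15, 15, 15], sch$total_dose * exp(-2), tolerance = 1e-9)
  } else {
    expect_equal(unclass(dose)[at10][1], sch$total_dose * exp(-2), tolerance = 1e-9)
  }
  # widening the falloff cannot decrease lung V20
  dose2 <- generate_dose(ph$ct, ph$ptv, sch, falloff_mm = 10)
  lungs_nt <- ph$lungs & !ph$gtv
  v20 <- function(d) 100 * sum(unclass(d)[lungs_nt] >= 20) / sum(lungs_nt)
  expect_gte(v20(dose2), v20(dose))
  expect_error(generate_dose(ph$ct, array(FALSE, dim(ph$ct)), sch, 5), "empty PTV")
})

test_that("cohort labels are reproducible and prevalence is calibrated", {
  risk0 <- risk_model_spec(beta_vbed70 = 0, beta_texture = 0,
                           prevalence_target = 0.146)
  co <- generate_cohort(120, sampler = small_sampler(), risk = risk0, seed = 21)
  # pure Bernoulli cohort: empirical prevalence within 3 SE of the target
  se <- sqrt(0.146 * 0.854 / 120)
  expect_lt(abs(mean(co$label) - 0.146), 3 * se)
  # mean event probability matches the target to the bisection tolerance
  expect_lt(abs(mean(co$p_true) - 0.146), 0.005 + 1e-9)
  co2 <- generate_cohort(120, sampler = small_sampler(), risk = risk0, seed = 21)
  expect_identical(co$label, co2$label)
  expect_identical(co$VBED70, co2$VBED70)
})

test_that("a planted V_BED70 effect separates the label groups", {
  co <- generate_cohort(200, sampler = small_sampler(), seed = 31)
  expect_gt(mean(co$VBED70[co$label == 1]), mean(co$VBED70[co$label == 0]))
  wt <- wilcox.test(co$VBED70[co$label == 1], co$VBED70[co$label == 0],
                    alternative = "greater")
  expect_lt(wt$p.value, 0.05)
})

test_that("patients can be regenerated bit-identically from the manifest", {
  co <- generate_cohort(5, sampler = small_sampler(), seed = 8)
  a <- phantom_patient(co, 2)
  b <- phantom_patient(co, 2)
  expect_identical(a$ct, b$ct)
  expect_identical(a$dose, b$dose)
  expect_equal(max(a$dose), a$scheme$total_dose)
})

test_that("cohorts round-trip through NIfTI and the JSON manifest", {
  co <- generate_cohort(2, sampler = small_sampler(), seed = 4)
  dir <- file.path(tempdir(), "bedrad-cohort")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  manifest <- write_cohort(co, dir)
  expect_true(file.exists(manifest))
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  pat <- phantom_patient(co, 1)
  ct2 <- read_volume(file.path(dir, co$id[1], "ct.nii.gz"))
  expect_equal(unclass(ct2), unclass(pat$ct), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(vg_spacing(ct2), vg_spacing(pat$ct), tolerance = 1e-6)
  lungs2 <- read_volume(file.path(dir, co$id[1], "lungs.nii.gz"))
  expect_equal(unclass(lungs2) > 0.5, unclass(pat$lungs),
               ignore_attr = TRUE)
})
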
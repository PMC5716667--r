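# Iterative constrained alignment: local rotational search with
# FFT-accelerated masked, normalized cross-correlation over shifts, and
# the reference-free ab initio driver that composes the whole protocol
# (sphere seeding, half-set processing, C3 centering, symmetrized
# refinement, CC filtering and duplicate removal).

#' Alignment configuration
#'
#' Schedules are parallel vectors, one entry per pass of the ab initio
#' protocol. With the defaults: pass 1 is the full-circle in-plane
#' emergence round against the bootstrap reference; pass 2 a local
#' in-plane refinement against the growing average; pass 3 the
#' C3-symmetrized refinement after the motif is centered; pass 4 the
#' final fine pass with a small out-of-plane cone search. In-plane
#' ranges >= 180 mean a full 360-degree scan.
#'
#' @param boxsize box edge, voxels.
#' @param inplane_step,inplane_range degrees per pass.
#' @param cone_step,cone_range out-of-plane cone grid per pass, degrees
#'   (0 disables the cone search in that pass).
#' @param iterations iterations per pass.
#' @param binning_schedule per-pass search binning factor.
#' @param shift_limit per-pass translation window, voxels
#'   (< boxsize / 4).
#' @param radial_lo,radial_hi per-pass bounds on the shift component
#'   along the particle's outward normal, voxels. The coat lies on a
#'   sphere, so radial excursions are tightly bounded while lateral
#'   search stays free; this prevents the search from sliding onto the
#'   membrane.
#' @param symmetry rotational symmetry order applied during refinement.
#' @param cc_keep_fraction fraction kept by [cc_filter()] after the
#'   emergence round.
#' @param duplicate_min_dist overlap-removal distance, Angstrom.
#' @param mask_radius,mask_height,mask_zoffset soft cylindrical
#'   alignment mask (reference frame), voxels. The cylinder is centered
#'   on the motif, raised by `mask_zoffset` so its soft lower edge does
#'   not graze the membrane; it covers one coat motif and excludes the
#'   membrane and neighboring triads.
#' @param seed_spacing spacing for [sphere_seed_points()]-style even
#'   seeding, nm (kept for completeness; the driver seeds at coat
#'   density peaks).
#' @param seed integer seed.
#' @return list of class `alignment_config`.
#' @export
alignment_config <- function(boxsize = 32,
                             inplane_step = c(30, 5, 5, 3, 1.5),
                             inplane_range = c(360, 20, 20, 6, 9),
                             cone_step = c(0, 0, 0, 4, 0),
                             cone_range = c(0, 0, 0, 8, 0),
                             iterations = c(1, 2, 2, 1, 2),
                             binning_schedule = c(1, 1, 1, 1, 1),
                             shift_limit = c(3, 2, 4, 3, 2),
                             radial_lo = c(-2.5, -2, -3, -2, -1.5),
                             radial_hi = c(2.5, 2, 3, 2, 1.5),
                             symmetry = 3,
                             cc_keep_fraction = 0.7,
                             duplicate_min_dist = 177,
                             mask_radius = 8,
                             mask_height = 7,
                             mask_zoffset = 0,
                             seed_spacing = 10,
                             seed = 1) {
  ln <- lengths(list(inplane_step, inplane_range, cone_step, cone_range,
                     iterations, binning_schedule, shift_limit,
                     radial_lo, radial_hi))
  if (length(unique(ln)) != 1)
    stopf("schedule vectors must have equal length")
  if (any(shift_limit >= boxsize / 4))
    stopf("shift_limit must be < boxsize / 4")
  structure(as.list(environment())[c("boxsize", "inplane_step",
    "inplane_range", "cone_step", "cone_range", "iterations",
    "binning_schedule", "shift_limit", "radial_lo", "radial_hi",
    "symmetry", "cc_keep_fraction", "duplicate_min_dist", "mask_radius",
    "mask_height", "mask_zoffset", "seed_spacing", "seed")],
    class = "alignment_config")
}

#' Local rotation grid around the identity
#'
#' In-plane offsets crossed with a cone of out-of-plane tilts; always
#' includes the identity.
#'
#' @param inplane_range,inplane_step degrees (range >= 180 scans the
#'   full circle).
#' @param cone_range,cone_step degrees.
#' @return list of 3x3 rotation matrices.
#' @export
rotation_grid <- function(inplane_range, inplane_step, cone_range = 0,
                          cone_step = 0) {
  grid <- rotation_grid_split(inplane_range, inplane_step, cone_range,
                              cone_step)
  out <- list()
  for (tl in grid$tilts) for (g in grid$gammas)
    out <- c(out, list(tl %*% Rz(g)))
  out
}

## The same grid kept factored as out-of-plane tilts x in-plane angles,
## which lets the (axially symmetric) mask be rotated once per tilt.
rotation_grid_split <- function(inplane_range, inplane_step, cone_range = 0,
                                cone_step = 0) {
  gammas <- if (inplane_range >= 180) {
    seq(0, 360 - inplane_step, by = inplane_step)
  } else if (inplane_range <= 0) 0 else {
    seq(-inplane_range, inplane_range, by = inplane_step)
  }
  tilts <- list(diag(3))
  if (cone_range > 0 && cone_step > 0) {
    for (th in seq(cone_step, cone_range, by = cone_step)) {
      naz <- max(6L, round(360 * sin(deg2rad(th)) / cone_step))
      for (az in seq(0, 360 - 360 / naz, by = 360 / naz))
        tilts <- c(tilts, list(
          rotation_about_axis(c(cos(deg2rad(az)), sin(deg2rad(az)), 0), th)))
    }
  }
  list(tilts = tilts, gammas = gammas)
}

## Per-particle FFT precomputations for masked normalized CC. Shifts
## where the local masked variance falls below a fraction of the box's
## global variance are flagged: a near-empty window under the mask would
## otherwise produce arbitrarily inflated correlation values.
particle_cc_prep <- function(box, mask_arr, n_m, sd_floor_frac = 0.1) {
  FP <- stats::fft(box)
  n <- length(box)
  FM <- attr(mask_arr, "fft") %||% stats::fft(mask_arr)
  S1 <- Re(stats::fft(Conj(FM) * FP, inverse = TRUE)) / n
  S2 <- Re(stats::fft(Conj(FM) * stats::fft(box^2), inverse = TRUE)) / n
  Vloc <- pmax(S2 - S1^2 / n_m, 0)
  floor_sd <- sd_floor_frac * stats::sd(box) * sqrt(n_m)
  list(FP = FP, sdloc = sqrt(Vloc), floor = floor_sd)
}

## Shift index set: offsets -L..L on each axis of an n^3 FFT output.
shift_window <- function(n, L) {
  idx <- c(1:(L + 1), (n - L + 1):n)
  offs <- c(0:L, -(L:1))
  list(idx = idx, offs = offs)
}

## Masked NCC of a (rotated, centered) reference against a prepared
## particle, maximized over shifts within the window. Returns the best
## subvoxel shift (delta, voxels) and the correlation there.
best_shift_cc <- function(refc, ref_norm, prep, win, allowed = NULL) {
  n <- length(refc)
  num <- Re(stats::fft(Conj(stats::fft(refc)) * prep$FP, inverse = TRUE)) / n
  d3 <- dim(refc)
  cc <- num / (ref_norm * pmax(prep$sdloc, prep$floor))
  cc[prep$sdloc < prep$floor] <- 0
  sub <- cc[win$idx, win$idx, win$idx]
  if (!is.null(allowed)) sub[!allowed] <- -Inf
  pk <- arrayInd(which.max(sub), dim(sub))
  peak_cc <- sub[pk]
  ## parabolic interpolation on the full wrapped cc array
  pk_full <- c(win$idx[pk[1]], win$idx[pk[2]], win$idx[pk[3]])
  off <- parabolic_offset_3d(cc, pk_full, d3)
  delta <- c(win$offs[pk[1]], win$offs[pk[2]], win$offs[pk[3]]) + off
  list(delta = delta, cc = clamp(peak_cc, -1, 1))
}

#' One alignment pass over a subtomogram stack
#'
#' For every particle, scans rotations on the configured local grid
#' around its current orientation; for each rotation the translation is
#' found at the maximum of the masked, normalized cross-correlation
#' (computed by FFT over all shifts, subvoxel peak by 3-point parabolic
#' interpolation). Updates angles, positions and `cc_score`, and
#' returns the new average built from the updated parameters.
#'
#' The mask is defined in the reference frame (e.g. a cylindrical band
#' that covers the coat layer and excludes the membrane) and is rotated
#' together with the reference for each candidate orientation. Masks
#' must be axially symmetric about z, so that their rotation depends
#' only on the out-of-plane part of the candidate (one mask resampling
#' per cone tilt, not per in-plane angle).
#'
#' @param stack `subtomo_stack`.
#' @param table `particle_table` covering the stack.
#' @param reference `volume3d` reference (same box size).
#' @param mask `volume3d` soft mask in the reference frame, values in
#'   [0, 1], axially symmetric about z.
#' @param inplane_range,inplane_step,cone_range,cone_step search grid,
#'   degrees.
#' @param shift_limit shift search window, voxels.
#' @param iterations number of iterations; after each, the reference is
#'   rebuilt from the updated table unless `update_reference = FALSE`.
#' @param symmetry symmetry order applied to rebuilt references.
#' @param update_reference rebuild the reference between iterations.
#' @param reference_fraction rebuild references from only the
#'   best-correlating fraction of particles (all particles stay in the
#'   table; this only controls who contributes to the reference).
#' @param flatten_reference subtract the azimuthal (about z) mean of the
#'   reference before correlating, so that the search is driven only by
#'   azimuthally asymmetric density. This suppresses the degenerate
#'   attractor in which particles align to the rotationally symmetric
#'   membrane/lumen signal instead of the coat motif, and is essential
#'   for reference-free convergence on membrane-bound lattices.
#' @param binning search at this binning factor (boxes, reference and
#'   mask are block-binned internally; positions are reported at the
#'   input scale). The returned average is always built at full scale.
#' @return list of class `average_result`: `average`, `table`,
#'   `mean_cc` (per iteration), `reference` (last used).
#' @export
align_iterate <- function(stack, table, reference, mask,
                          inplane_range = 360, inplane_step = 10,
                          cone_range = 0, cone_step = 0,
                          shift_limit = 6, iterations = 1,
                          symmetry = 1, update_reference = TRUE,
                          reference_fraction = 1,
                          flatten_reference = FALSE,
                          binning = 1, radial_limits = c(-Inf, Inf)) {
  if (length(stack$boxes) == 0) stopf("stack is empty")
  refa <- as_vol_array(reference)
  if (!all(dim(refa) == rep(stack$boxsize, 3)))
    stopf("reference and stack box sizes differ")
  if (max(abs(refa)) == 0) stopf("reference is all zero")
  b <- as.integer(binning)
  boxes <- if (b > 1) lapply(stack$boxes, bin_array, factor = b)
           else stack$boxes
  nb <- stack$boxsize %/% b
  mask_arr <- if (b > 1) bin_array(as_vol_array(mask), b)
              else as_vol_array(mask)
  grid <- rotation_grid_split(inplane_range, inplane_step, cone_range,
                              cone_step)
  win <- shift_window(nb, max(1L, round(shift_limit / b)))
  ## window offsets (binned voxels) for the radial shift constraint
  W <- rbind(rep(win$offs, times = length(win$offs)^2),
             rep(rep(win$offs, each = length(win$offs)), length(win$offs)),
             rep(win$offs, each = length(win$offs)^2))
  constrain <- any(is.finite(radial_limits))
  tab <- stack_rows(stack, table)
  mean_cc <- numeric(0)
  ref_cur <- if (b > 1) bin_array(refa, b) else refa
  for (it in seq_len(iterations)) {
    ref_eff <- if (flatten_reference) subtract_azimuthal_mean(ref_cur)
               else ref_cur
    for (i in seq_along(boxes)) {
      R_cur <- euler_to_matrix(c(tab$phi[i], tab$psi[i], tab$theta[i]))
      best <- list(cc = -Inf)
      for (tl in grid$tilts) {
        R_tilt <- R_cur %*% tl
        ## rotate the reference-frame mask with the out-of-plane part
        m_R <- clamp(resample_volume(mask_arr, rotation = t(R_tilt)), 0, 1)
        n_m <- sum(m_R)
        if (n_m < 8) next
        prep <- particle_cc_prep(boxes[[i]], m_R, n_m)
        allowed <- NULL
        if (constrain) {
          rad <- colSums(W * R_tilt[, 3]) * b
          allowed <- array(rad >= radial_limits[1] & rad <= radial_limits[2],
                           rep(length(win$offs), 3))
        }
        cc_by_g <- rep(NA_real_, length(grid$gammas))
        for (gi in seq_along(grid$gammas)) {
          g <- grid$gammas[gi]
          R_cand <- R_tilt %*% Rz(g)
          M <- resample_volume(ref_eff, rotation = t(R_cand))
          mu <- sum(m_R * M) / n_m
          refc <- m_R * (M - mu)
          ref_norm <- sqrt(sum(refc * (M - mu)))
          if (ref_norm < 1e-12) next
          res <- best_shift_cc(refc, ref_norm, prep, win, allowed)
          cc_by_g[gi] <- res$cc
          if (res$cc > best$cc)
            best <- c(res, list(R_tilt = R_tilt, gi = gi, ccg = NULL))
        }
        if (is.finite(best$cc) && !is.null(best$R_tilt) &&
            identical(best$R_tilt, R_tilt))
          best$ccg <- cc_by_g
      }
      if (!is.finite(best$cc)) { tab$cc_score[i] <- 0; next }
      ## sub-step in-plane angle by 3-point parabolic interpolation of
      ## the per-gamma peak correlations
      g_best <- grid$gammas[best$gi]
      dg <- 0
      ng <- length(grid$gammas)
      if (ng >= 3 && !is.null(best$ccg)) {
        full <- inplane_range >= 180
        gi <- best$gi
        im <- if (gi > 1) gi - 1 else if (full) ng else NA
        ip <- if (gi < ng) gi + 1 else if (full) 1L else NA
        if (!is.na(im) && !is.na(ip) &&
            is.finite(best$ccg[im]) && is.finite(best$ccg[ip])) {
          y0 <- best$ccg[im]; y1 <- best$ccg[gi]; y2 <- best$ccg[ip]
          den <- y0 - 2 * y1 + y2
          if (abs(den) > 1e-12)
            dg <- clamp(0.5 * (y0 - y2) / den, -1, 1) * inplane_step
        }
      }
      best$R <- best$R_tilt %*% Rz(g_best + dg)
      e <- matrix_to_euler(best$R)
      tab$phi[i] <- e[1]; tab$psi[i] <- e[2]; tab$theta[i] <- e[3]
      pos <- stack$center[i, ] + best$delta * b
      tab$x[i] <- pos[1]; tab$y[i] <- pos[2]; tab$z[i] <- pos[3]
      tab$cc_score[i] <- best$cc
    }
    mean_cc <- c(mean_cc, mean(tab$cc_score))
    if (update_reference || it == iterations) {
      rows <- seq_len(nrow(tab))
      if (reference_fraction < 1) {
        k <- max(2L, ceiling(reference_fraction * nrow(tab)))
        rows <- order(-tab$cc_score, tab$particle_id)[seq_len(k)]
      }
      avg <- initial_reference(
        structure(list(boxes = stack$boxes[rows],
                       center = stack$center[rows, , drop = FALSE],
                       particle_id = stack$particle_id[rows],
                       boxsize = stack$boxsize,
                       voxel_size = stack$voxel_size),
                  class = "subtomo_stack"),
        tab[rows, , drop = FALSE])
      if (symmetry > 1) avg <- symmetrize(avg, symmetry)
      if (update_reference)
        ref_cur <- if (b > 1) bin_array(as_vol_array(avg), b)
                   else as_vol_array(avg)
    }
  }
  structure(list(average = avg, table = particle_table(as.data.frame(tab)),
                 mean_cc = mean_cc,
                 reference = vol_like(ref_cur, reference)),
            class = "average_result")
}

#' In-plane rotational + translational registration of two references
#'
#' Finds the in-plane rotation (about z) and shift that best map
#' `moving` onto `fixed`, by scanning rotations and taking the FFT
#' cross-correlation peak for each. Used to bring the two independently
#' converged half-set references into a common orientation.
#'
#' @param fixed,moving `volume3d` of equal dimensions.
#' @param step scan step, degrees.
#' @param refine_step optional fine scan step around the coarse optimum.
#' @return list `phi` (degrees), `shift` (voxels), `cc`.
#' @export
align_references <- function(fixed, moving, step = 5, refine_step = 1) {
  a <- as_vol_array(fixed); a0 <- a - mean(a)
  FA <- Conj(stats::fft(a0)); na <- sqrt(sum(a0^2)); n <- length(a0)
  d <- dim(a)
  try_phi <- function(phi) {
    m <- as_vol_array(rotate_volume(moving, c(phi, 0, 0)))
    m0 <- m - mean(m)
    X <- Re(stats::fft(FA * stats::fft(m0), inverse = TRUE)) / n
    X <- X / (na * sqrt(sum(m0^2)))
    pk <- arrayInd(which.max(X), d)
    u <- as.numeric(((pk - 1 + d / 2) %% d) - d / 2) +
      parabolic_offset_3d(X, pk, d)
    list(phi = phi, shift = -u, cc = max(X))
  }
  coarse <- lapply(seq(0, 360 - step, by = step), try_phi)
  best <- coarse[[which.max(vapply(coarse, `[[`, 0, "cc"))]]
  if (!is.null(refine_step) && refine_step < step) {
    fine <- lapply(seq(best$phi - step, best$phi + step, by = refine_step),
                   try_phi)
    best <- fine[[which.max(vapply(fine, `[[`, 0, "cc"))]]
  }
  best
}

## Compose a reference re-orientation (rotate by Q about center, then
## shift by s) into the particle parameters aligned against it.
apply_reference_transform <- function(table, Q, s = c(0, 0, 0)) {
  for (i in seq_len(nrow(table))) {
    R <- euler_to_matrix(c(table$phi[i], table$psi[i], table$theta[i]))
    Rn <- R %*% t(Q)
    e <- matrix_to_euler(Rn)
    table$phi[i] <- e[1]; table$psi[i] <- e[2]; table$theta[i] <- e[3]
    pos <- c(table$x[i], table$y[i], table$z[i]) - as.numeric(Rn %*% s)
    table$x[i] <- pos[1]; table$y[i] <- pos[2]; table$z[i] <- pos[3]
  }
  table
}

## Subtract the azimuthal mean (about the central z-axis) from a 3D
## array: per z-slice, the mean over each integer radius bin is removed.
subtract_azimuthal_mean <- function(a) {
  d <- dim(a)
  ctr <- (d - 1) / 2
  r <- sqrt(outer(((seq_len(d[1]) - 1) - ctr[1])^2,
                  ((seq_len(d[2]) - 1) - ctr[2])^2, "+"))
  rb <- as.numeric(round(r))
  out <- a
  for (k in seq_len(d[3])) {
    sl <- as.numeric(a[, , k])
    out[, , k] <- sl - stats::ave(sl, rb)
  }
  out
}

#' Azimuthally asymmetric power profile and motif z-centering
#'
#' The membrane and lumen of a vesicle are invariant under rotation
#' about the particle's local z-axis, while the coat motif carries all
#' of the azimuthal structure. `motif_z_center` therefore locates the
#' motif along z as the intensity-weighted centroid of the azimuthally
#' asymmetric power per slice, which is robust to the strong (but
#' smooth) membrane density in the same box.
#'
#' @param vol `volume3d` reference containing a coat motif on a
#'   membrane.
#' @param max_radius restrict to this cylinder radius (voxels; default
#'   0.45 box).
#' @param z_range restrict to this 0-based z interval (e.g. the band
#'   above the membrane when the geometry bounds the motif's height).
#' @return z-coordinate (0-based voxels, subvoxel) of the motif.
#' @export
motif_z_center <- function(vol, max_radius = NULL, z_range = NULL) {
  a <- as_vol_array(vol)
  d <- dim(a)
  ctr <- (d - 1) / 2
  rmax <- max_radius %||% (0.45 * d[1])
  r <- sqrt(outer(((seq_len(d[1]) - 1) - ctr[1])^2,
                  ((seq_len(d[2]) - 1) - ctr[2])^2, "+"))
  rb <- pmin(round(r), ceiling(rmax))
  inside <- r <= rmax
  w <- numeric(d[3])
  for (k in seq_len(d[3])) {
    sl <- a[, , k]
    azmean <- stats::ave(as.numeric(sl), as.numeric(rb))
    res <- (as.numeric(sl) - azmean)[inside]
    w[k] <- sum(res^2)
  }
  if (!is.null(z_range)) {
    z0 <- seq_len(d[3]) - 1
    w[z0 < z_range[1] | z0 > z_range[2]] <- 0
  }
  w <- pmax(w - stats::median(w), 0)
  if (sum(w) <= 0) return(ctr[3])
  sum(w * (seq_len(d[3]) - 1)) / sum(w)
}

## Reset the out-of-plane orientation of each particle to the outward
## normal of its vesicle sphere at the current (refined) position,
## keeping the in-plane angle. Legitimate whenever the annotation sphere
## is trusted, as it is for sphere-seeded coat particles.
reseed_normals <- function(table, vesicles) {
  vs <- vesicles[match(table$vesicle_id, vesicles$vesicle_id), ]
  for (i in seq_len(nrow(table))) {
    v <- c(table$x[i] - vs$cx[i], table$y[i] - vs$cy[i], table$z[i] - vs$cz[i])
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) next
    ang <- normal_to_euler(v / nv, phi = table$phi[i])
    ## keep the same local z-direction but re-derive psi/theta; phi kept
    table$psi[i] <- ang[2]; table$theta[i] <- ang[3]
  }
  table
}


#' Soft cylindrical mask for resolution measurement
#'
#' The membrane-excluding mask applied to the half-maps before Fourier
#' shell correlation. It is slightly tighter than the alignment mask
#' and raised off the membrane so that its soft lower edge does not
#' graze the differently curved membranes of the two half-sets.
#'
#' @param config `alignment_config` (for the box size and radius).
#' @param voxel_size Angstrom per voxel.
#' @return `volume3d` mask.
#' @export
resolution_mask <- function(config, voxel_size) {
  ctr <- (config$boxsize - 1) / 2
  make_mask(mask_spec("cylinder", radius = config$mask_radius,
                      height = 6, center = c(ctr, ctr, ctr + 0.75),
                      edge_width = 2),
            rep(config$boxsize, 3), voxel_size)
}

#' Seed particles at coat-density maxima on annotated vesicle spheres
#'
#' Template-free positional seeding: directions on a dense Fibonacci
#' lattice are sampled through a low-pass-filtered copy of the tomogram
#' over a shell of radii just outside the annotated membrane sphere,
#' and local density maxima are kept greedily with a minimum angular
#' separation. On a coated vesicle the coat triads are the maxima of
#' the smoothed coat shell, so the seeds land near triad centers
#' without any reference structure. Orientations are initialised as the
#' outward surface normal with a random in-plane angle, as for
#' [sphere_seed_points()].
#'
#' @param tomogram `volume3d`.
#' @param vesicles `vesicle_table`.
#' @param smooth_res low-pass resolution used for peak detection,
#'   Angstrom (coarse enough to merge one triad into a single blob).
#' @param shell_range radii sampled, voxels outside the membrane radius.
#' @param min_sep minimum peak separation, Angstrom.
#' @param keep_frac keep peaks with density above this fraction of the
#'   per-vesicle maximum.
#' @param dir_spacing direction sampling spacing, nm.
#' @param rng_seed seed for the random in-plane angles.
#' @return `particle_table` of seeds ordered by descending peak density
#'   within each vesicle.
#' @export
seed_coat_peaks <- function(tomogram, vesicles, smooth_res = 140,
                            shell_range = c(1.5, 7), min_sep = 142,
                            keep_frac = 0.35, dir_spacing = 5,
                            rng_seed = 1) {
  voxel <- attr(tomogram, "voxel_size")
  sm <- as_vol_array(lowpass_filter(tomogram, smooth_res))
  out <- list()
  for (i in seq_len(nrow(vesicles))) {
    ctr <- c(vesicles$cx[i], vesicles$cy[i], vesicles$cz[i])
    r_mem <- vesicles$diameter_nm[i] * 10 / 2 / voxel
    ndir <- max(32L, round(4 * pi * (vesicles$diameter_nm[i] / 2 / dir_spacing)^2 * 4))
    dirs <- fibonacci_sphere(ndir)
    rs <- seq(r_mem + shell_range[1], r_mem + shell_range[2], by = 0.5)
    vals <- matrix(0, ndir, length(rs))
    for (j in seq_along(rs)) {
      p <- sweep(dirs * rs[j], 2, ctr, "+")
      vals[, j] <- trilinear_sample(sm, p[, 1], p[, 2], p[, 3], c(ndir, 1, 1))
    }
    v <- apply(vals, 1, max)
    rbest <- rs[apply(vals, 1, which.max)]
    min_ang <- min_sep / voxel / (r_mem + mean(shell_range))
    ord <- order(-v)
    acc <- integer(0)
    for (k in ord) {
      if (v[k] < keep_frac * max(v)) break
      if (length(acc) == 0 ||
          all(acos(clamp(dirs[acc, , drop = FALSE] %*% dirs[k, ], -1, 1)) > min_ang))
        acc <- c(acc, k)
    }
    if (length(acc) == 0) next
    pos <- sweep(dirs[acc, , drop = FALSE] * rbest[acc], 2, ctr, "+")
    phis <- with_seed(rng_seed + 17L * i, stats::runif(length(acc), 0, 360))
    ang <- t(vapply(seq_along(acc), function(k)
      normal_to_euler(dirs[acc[k], ], phi = phis[k]), numeric(3)))
    out[[length(out) + 1]] <- data.frame(
      vesicle_id = vesicles$vesicle_id[i],
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      phi = ang[, 1], psi = ang[, 2], theta = ang[, 3],
      peak_density = v[acc])
  }
  df <- do.call(rbind, out)
  if (is.null(df) || nrow(df) == 0) stopf("no coat density peaks found")
  df$particle_id <- seq_len(nrow(df))
  particle_table(df)
}

#' Reference-free ab initio subtomogram averaging of coated vesicles
#'
#' The full protocol, per independent half-set of vesicles:
#' \enumerate{
#'   \item seed particles on the annotated vesicle spheres (surface
#'     normals out-of-plane, random in-plane angles), positioned at the
#'     maxima of the smoothed coat shell ([seed_coat_peaks()]);
#'   \item bootstrap a starting reference from the single strongest
#'     seed (no external template) and run one full-circle in-plane
#'     alignment of all particles against it, correlating only the
#'     azimuthally asymmetric density so the membrane cannot drive the
#'     alignment;
#'   \item prune by cross-correlation, re-derive surface normals at the
#'     refined positions and refine locally against the growing
#'     average;
#'   \item bring the emergent three-fold feature to the box center
#'     (x, y by flattened self-rotation correlation, z by the
#'     azimuthally asymmetric power centroid) and refine with C3
#'     symmetry applied;
#'   \item remove overlapping particles and run the final fine pass
#'     with a small out-of-plane cone search.
#' }
#' The two half-set references are then registered in-plane and half 2
#' is re-refined against the common orientation, so the final half
#' maps are directly comparable by Fourier shell correlation.
#'
#' @param tomogram `volume3d`.
#' @param vesicles `vesicle_table`.
#' @param config `alignment_config`.
#' @param verbose print per-stage progress.
#' @return list with `halves` (two `average_result`s), `table` (merged
#'   refined `particle_table`), `split`, `config`, `centering` (per-half
#'   centering diagnostics) and `mean_cc_log`.
#' @export
run_ab_initio <- function(tomogram, vesicles, config = alignment_config(),
                          seed_min_sep = NULL, verbose = FALSE,
                          trace = FALSE) {
  voxel <- attr(tomogram, "voxel_size")
  t_start <- proc.time()[3]
  say <- function(...) if (verbose)
    message(sprintf("[%5.0fs] ", proc.time()[3] - t_start), sprintf(...))
  bs <- config$boxsize
  ctr <- (bs - 1) / 2
  mask <- make_mask(mask_spec("cylinder", radius = config$mask_radius,
                              height = config$mask_height,
                              center = c(ctr, ctr,
                                         ctr + config$mask_zoffset),
                              edge_width = 2),
                    rep(bs, 3), voxel)
  seeds <- seed_coat_peaks(tomogram, vesicles, rng_seed = config$seed,
                           min_sep = seed_min_sep %||%
                             (config$duplicate_min_dist * 0.8))
  split <- halfset_split(vesicles, config$seed)
  seeds <- apply_halfset(seeds, split)
  say("seeded %d coat-peak particles on %d vesicles", nrow(seeds),
      nrow(vesicles))
  pass_args <- function(p) list(inplane_range = config$inplane_range[p],
                                inplane_step = config$inplane_step[p],
                                cone_range = config$cone_range[p],
                                cone_step = config$cone_step[p],
                                binning = config$binning_schedule[p],
                                shift_limit = config$shift_limit[p],
                                radial_limits = c(config$radial_lo[p],
                                                  config$radial_hi[p]))
  flatC3_center <- function(avg) {
    f <- subtract_azimuthal_mean(as_vol_array(avg))
    cs <- center_symmetry_axis(vol_like(f, avg), config$symmetry,
                               min_cc = 0.1)
    out <- avg
    if (cs$ok && sqrt(sum(cs$transform$translation^2)) < bs / 6)
      out <- shift_volume(avg, cs$transform$translation)
    zc <- motif_z_center(out, max_radius = config$mask_radius + 1,
                         z_range = ctr + c(-2, 6))
    list(volume = shift_volume(out, c(0, 0, ctr - zc)),
         cc = cs$cc, ok = cs$ok,
         shift = c(cs$transform$translation[1:2], ctr - zc))
  }
  halves <- list(); centering <- list(); cc_log <- list()
  stage_trace <- list()
  snap <- function(h, label, tab)
    if (trace) stage_trace[[paste0("h", h, "_", label)]] <<- tab
  for (h in 1:2) {
    tab_h <- particle_table(as.data.frame(seeds[seeds$halfset == h, ]))
    ## order by peak density so row 1 is the strongest seed
    tab_h <- particle_table(as.data.frame(
      tab_h[order(-tab_h$peak_density), ]))
    stack <- extract_subtomograms(tomogram, tab_h, bs)
    tab_h <- stack$table
    ## pass 1: one full-circle emergence round against the single
    ## strongest seed particle (reference-free bootstrap)
    boot <- subset_stack(stack, stack$particle_id[1])
    ref <- initial_reference(boot, tab_h[1, , drop = FALSE])
    res <- do.call(align_iterate,
                   c(list(stack, tab_h, ref, mask,
                          iterations = config$iterations[1],
                          flatten_reference = TRUE,
                          update_reference = FALSE),
                     pass_args(1)))
    mean_cc <- res$mean_cc
    say("half %d emergence: mean cc %.3f", h, utils::tail(res$mean_cc, 1))
    snap(h, "emergence", res$table)
    ## re-derive normals at the refined positions and re-extract; all
    ## particles stay alive, but references are built from the
    ## best-correlating half so junk seeds cannot pollute them
    tab_h <- particle_table(as.data.frame(reseed_normals(res$table,
                                                         vesicles)))
    stack <- extract_subtomograms(tomogram, tab_h, bs)
    tab_h <- stack$table
    ## pass 2: local refinement against the growing (subset) average
    ref0 <- {
      k <- max(2L, ceiling(0.5 * nrow(tab_h)))
      rows <- order(-tab_h$cc_score, tab_h$particle_id)[seq_len(k)]
      initial_reference(subset_stack(stack, stack$particle_id[rows]),
                        tab_h[rows, , drop = FALSE])
    }
    res <- do.call(align_iterate,
                   c(list(stack, tab_h, ref0,
                          mask, iterations = config$iterations[2],
                          reference_fraction = 0.5,
                          flatten_reference = TRUE),
                     pass_args(2)))
    tab_h <- res$table
    mean_cc <- c(mean_cc, res$mean_cc)
    snap(h, "refineA", tab_h)
    ## center the emergent three-fold feature, refine with symmetry.
    ## The centering shift is composed into the particle parameters
    ## analytically (positions move by R s), so the subsequent search
    ## only has to polish, never to rediscover the jump.
    cent <- flatC3_center(res$average)
    centering[[h]] <- cent[c("cc", "ok", "shift")]
    say("half %d centering: C3 cc %.3f shift (%.2f, %.2f, %.2f)", h,
        cent$cc, cent$shift[1], cent$shift[2], cent$shift[3])
    tab_h <- particle_table(as.data.frame(
      apply_reference_transform(tab_h, diag(3), cent$shift)))
    tab_h <- particle_table(as.data.frame(reseed_normals(tab_h, vesicles)))
    stack <- extract_subtomograms(tomogram, tab_h, bs)
    tab_h <- stack$table
    ref <- symmetrize(cent$volume, config$symmetry)
    res <- do.call(align_iterate,
                   c(list(stack, tab_h, ref, mask,
                          iterations = config$iterations[3],
                          symmetry = config$symmetry,
                          reference_fraction = 0.5,
                          flatten_reference = TRUE),
                     pass_args(3)))
    tab_h <- res$table
    mean_cc <- c(mean_cc, res$mean_cc)
    snap(h, "refineB", tab_h)
    ## rescore against the full (unflattened) reference: the on-axis
    ## hub and membrane discriminate true lattice sites from the
    ## interstitial ghosts that a lobe-only comparison cannot reject
    rs <- align_iterate(stack, tab_h, res$average, mask,
                        inplane_range = 0, inplane_step = 1,
                        shift_limit = 1, iterations = 1,
                        update_reference = FALSE,
                        flatten_reference = FALSE,
                        radial_limits = c(-0.5, 0.5))
    tab_h$cc_score <- rs$table$cc_score[match(tab_h$particle_id,
                                              rs$table$particle_id)]
    ## overlap removal at the refined positions (best particle wins a
    ## site), then the low-CC tail is removed as in the standard
    ## protocol, then the fine passes
    tab_h <- remove_duplicates(tab_h, config$duplicate_min_dist, voxel)
    snap(h, "dedup", tab_h)
    tab_h <- drop_low_cc(tab_h, config$cc_keep_fraction)
    snap(h, "ccdrop", tab_h)
    tab_h <- particle_table(as.data.frame(reseed_normals(tab_h, vesicles)))
    stack <- extract_subtomograms(tomogram, tab_h, bs)
    tab_h <- stack$table
    say("half %d has %d particles after overlap removal", h, nrow(tab_h))
    np <- length(config$inplane_step)
    ref <- res$average
    for (p in seq_len(np)[-(1:3)]) {
      res <- do.call(align_iterate,
                     c(list(stack, tab_h, ref, mask,
                            iterations = config$iterations[p],
                            symmetry = config$symmetry,
                            flatten_reference = p < np),
                       pass_args(p)))
      tab_h <- res$table
      ref <- res$average
      mean_cc <- c(mean_cc, res$mean_cc)
      say("half %d pass %d: mean cc %.3f", h, p, utils::tail(res$mean_cc, 1))
      if (p < np) {
        tab_h <- particle_table(as.data.frame(reseed_normals(tab_h,
                                                             vesicles)))
        stack <- extract_subtomograms(tomogram, tab_h, bs)
        tab_h <- stack$table
      }
    }
    ## final junk rejection: the last pass scores against the full
    ## (unflattened) reference, where converged lattice sites separate
    ## cleanly from leftovers
    tab_h <- final_cc_drop(res$table)
    if (nrow(tab_h) < nrow(res$table)) {
      stack <- extract_subtomograms(tomogram, tab_h, bs)
      res$table <- stack$table
      res$average <- {
        a <- initial_reference(stack, stack$table)
        symmetrize(a, config$symmetry)
      }
      say("half %d final drop to %d particles", h, nrow(res$table))
    }
    halves[[h]] <- res
    cc_log[[h]] <- mean_cc
  }
  ## register half 2 onto half 1 and re-run the final pass
  reg <- align_references(halves[[1]]$average, halves[[2]]$average,
                          step = 3, refine_step = 0.5)
  say("half registration: phi %.2f, shift (%.2f, %.2f, %.2f), cc %.3f",
      reg$phi, reg$shift[1], reg$shift[2], reg$shift[3], reg$cc)
  tab2 <- apply_reference_transform(halves[[2]]$table, Rz(reg$phi), reg$shift)
  stack2 <- extract_subtomograms(tomogram,
                                 particle_table(as.data.frame(tab2)),
                                 config$boxsize)
  np <- length(config$inplane_step)
  res2 <- do.call(align_iterate,
                  c(list(stack2, stack2$table, halves[[1]]$average, mask,
                         iterations = 1, symmetry = config$symmetry,
                         flatten_reference = FALSE),
                    pass_args(np)))
  tab2f <- final_cc_drop(res2$table)
  if (nrow(tab2f) < nrow(res2$table)) {
    stack2 <- extract_subtomograms(tomogram, tab2f, config$boxsize)
    res2$table <- stack2$table
    res2$average <- symmetrize(initial_reference(stack2, stack2$table),
                               config$symmetry)
  }
  halves[[2]] <- res2
  merged <- particle_table(rbind(as.data.frame(halves[[1]]$table),
                                 as.data.frame(halves[[2]]$table)))
  out <- list(halves = halves, table = merged, split = split,
              config = config, centering = centering,
              mean_cc_log = cc_log)
  if (trace) out$stage_trace <- stage_trace
  out
}



## Remove the low-CC tail: a 1D 2-means split on the scores separates
## converged particles from seeds that found nothing (the two
## populations are well separated on clean data); if the two cluster
## centers are too close to call, fall back to the plain keep-fraction
## filter.
drop_low_cc <- function(table, keep_fraction) {
  cc <- table$cc_score
  if (length(unique(round(cc, 6))) < 3) return(table)
  km <- stats::kmeans(cc, centers = 2, nstart = 5)
  hi <- which.max(km$centers)
  ## drop the low cluster only when it is clearly separated; recall is
  ## favoured because a stray unconverged particle merely dilutes the
  ## average, while a dropped genuine site is lost for good
  if (min(km$centers) >= 0.75 * max(km$centers))
    return(table)
  out <- table[km$cluster == hi, , drop = FALSE]
  rownames(out) <- NULL
  particle_table(as.data.frame(out))
}


## Final low-score rejection against the unflattened reference: keep
## particles above 90% of the top-half median score.
final_cc_drop <- function(table) {
  cc <- table$cc_score
  if (all(is.na(cc)) || nrow(table) < 4) return(table)
  top_med <- stats::median(cc[cc >= stats::median(cc, na.rm = TRUE)],
                           na.rm = TRUE)
  out <- table[!is.na(cc) & cc >= 0.9 * top_med, , drop = FALSE]
  rownames(out) <- NULL
  particle_table(as.data.frame(out))
}

subset_stack <- function(stack, particle_ids) {
  idx <- match(particle_ids, stack$particle_id)
  if (any(is.na(idx))) stopf("particle ids missing from stack")
  structure(list(boxes = stack$boxes[idx],
                 center = stack$center[idx, , drop = FALSE],
                 particle_id = stack$particle_id[idx],
                 boxsize = stack$boxsize, voxel_size = stack$voxel_size,
                 table = if (!is.null(stack$table))
                   particle_table(as.data.frame(stack$table[idx, ]))),
            class = "subtomo_stack")
}
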
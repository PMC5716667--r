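# Bilayer leaflet peak-peak distance: radial straightening of curved
# membrane averages, density profiling with subsample peak
# interpolation, bootstrap statistics, 2D box averaging for planar
# cisternal membranes, and vesicle diameter measurement.

#' Straighten a spherical membrane by radial orthographic resampling
#'
#' Resamples the volume on a spherical-coordinate grid around
#' `curvature_center`, so that rays from the center become parallel
#' columns: a spherical shell of radius r maps to a flat slab at column
#' height r. Angular spacing equals one voxel of arc at the middle of
#' `radial_range`; elevation is restricted to a cone around the +z axis
#' to avoid polar distortion unless `cone_halfangle` covers the full
#' sphere.
#'
#' @param avg `volume3d` (e.g. a vesicle-centered average).
#' @param curvature_center 0-based voxel coordinates of the sphere
#'   center (`NULL` = box center; `Inf` flags an already-flat volume,
#'   returned unchanged).
#' @param radial_range `(r_min, r_max)` in voxels.
#' @param cone_halfangle half-angle of the resampled direction cone
#'   about +z, degrees.
#' @param axis direction of the cone axis (default +z).
#' @return `volume3d` with x = azimuth arc, y = elevation arc,
#'   z = radius (one voxel steps from `r_min`).
#' @export
straighten_radial <- function(avg, curvature_center = NULL,
                              radial_range, cone_halfangle = 55,
                              axis = c(0, 0, 1)) {
  a <- as_vol_array(avg)
  d <- dim(a)
  if (length(curvature_center) == 1 && !is.null(curvature_center) &&
      is.infinite(curvature_center[1]))
    return(avg)
  ctr <- curvature_center %||% ((d - 1) / 2)
  if (any(ctr < 0) || any(ctr > d - 1))
    stopf("curvature center outside the box")
  if (radial_range[1] < 0 || radial_range[2] <= radial_range[1])
    stopf("invalid radial_range")
  axis <- axis / sqrt(sum(axis^2))
  r_mid <- mean(radial_range)
  dang <- 1 / r_mid                       # one voxel of arc at r_mid
  amax <- deg2rad(cone_halfangle)
  na <- 2 * floor(amax / dang) + 1
  angs <- (seq_len(na) - (na + 1) / 2) * dang
  rs <- seq(radial_range[1], radial_range[2], by = 1)
  ## local frame: axis plus two orthogonal tangents
  b1 <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- b1 - sum(b1 * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  ## direction for (alpha, beta): rotate axis by alpha about e2 then
  ## beta about e1 (small-angle orthographic grid)
  out <- array(0, c(na, na, length(rs)))
  ca <- cos(angs); sa <- sin(angs)
  dirs <- array(0, c(na, na, 3))
  for (i in seq_len(na)) for (j in seq_len(na)) {
    v <- ca[i] * axis + sa[i] * e1
    v <- cos(angs[j]) * v + sin(angs[j]) * e2
    dirs[i, j, ] <- v / sqrt(sum(v^2))
  }
  dx <- as.numeric(dirs[, , 1]); dy <- as.numeric(dirs[, , 2])
  dz <- as.numeric(dirs[, , 3])
  for (k in seq_along(rs)) {
    out[, , k] <- trilinear_sample(a, ctr[1] + rs[k] * dx,
                                   ctr[2] + rs[k] * dy,
                                   ctr[3] + rs[k] * dz, c(na, na))
  }
  volume3d(out, voxel_size = attr(avg, "voxel_size"),
           origin = c(0, 0, radial_range[1] * attr(avg, "voxel_size")))
}

## 3-point parabolic peak refinement of a 1D profile at index i.
parabolic_peak_1d <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(list(pos = i, val = y[i]))
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  off <- if (abs(den) > 1e-12) clamp(0.5 * (y[i - 1] - y[i + 1]) / den, -1, 1)
         else 0
  list(pos = i + off, val = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * off)
}

#' Density profile and leaflet peak separation of a straightened membrane
#'
#' The laterally averaged density per column height is profiled and the
#' two highest local maxima are located with 3-point parabolic
#' subsample interpolation; their separation is reported in Angstrom.
#'
#' @param straightened `volume3d` from [straighten_radial()] (z =
#'   radius) or any volume whose z-axis is perpendicular to a flat
#'   membrane.
#' @param lateral_window optional `(lo, hi)` 0-based voxel bounds of
#'   the lateral window averaged (both axes); default central half.
#' @param min_prominence reject maxima below `min_prominence` times the
#'   profile's peak-to-baseline range.
#' @return list of class `membrane_profile`: `offsets` (Angstrom,
#'   relative to the first sample), `density`, `peak_positions`
#'   (Angstrom), `peak_separation` (Angstrom), `ok`.
#' @export
profile_and_peaks <- function(straightened, lateral_window = NULL,
                              min_prominence = 0.2) {
  a <- as_vol_array(straightened)
  d <- dim(a)
  voxel <- attr(straightened, "voxel_size")
  win <- lateral_window %||% c(floor(d[1] / 4), ceiling(3 * d[1] / 4) - 1)
  if (win[1] < 0 || win[2] > d[1] - 1 || win[1] >= win[2])
    stopf("lateral window outside the volume")
  sub <- a[win[1]:win[2] + 1, , , drop = FALSE]
  sub <- sub[, pmin(win[1]:win[2] + 1, d[2]), , drop = FALSE]
  prof <- apply(sub, 3, mean)
  offsets <- (seq_along(prof) - 1) * voxel
  base <- min(prof)
  rng <- max(prof) - base
  ## local maxima
  n <- length(prof)
  is_max <- which(prof > c(-Inf, prof[-n]) & prof >= c(prof[-1], -Inf))
  is_max <- is_max[prof[is_max] - base > min_prominence * rng]
  out <- list(offsets = offsets, density = prof,
              peak_positions = NULL, peak_separation = NA_real_,
              ok = FALSE)
  if (length(is_max) >= 2 && rng > 0) {
    top <- is_max[order(-prof[is_max])][1:2]
    pks <- vapply(sort(top), function(i)
      parabolic_peak_1d(prof, i)$pos, numeric(1))
    out$peak_positions <- (pks - 1) * voxel
    out$peak_separation <- abs(diff(out$peak_positions))
    out$ok <- TRUE
  }
  structure(out, class = "membrane_profile")
}

#' @export
print.membrane_profile <- function(x, ...) {
  if (x$ok)
    cat(sprintf("membrane_profile: leaflet peaks at %.1f / %.1f A, separation %.2f A\n",
                x$peak_positions[1], x$peak_positions[2],
                x$peak_separation))
  else cat("membrane_profile: measurement failed (fewer than two peaks)\n")
  invisible(x)
}

## Shared measurement path: average a set of aligned subtomograms (by
## index), filter, straighten and profile. The straightening operator
## and filters are linear, so per-subtomogram profiles are precomputed
## once and every (re)average of the set is a weighted mean of profiles;
## only the peak measurement is non-linear and is redone per replicate.
precompute_profiles <- function(subtomos, curvature_center, radial_range,
                                lowpass = 25, bfactor = -2000,
                                cone_halfangle = 55) {
  lapply(subtomos, function(v) {
    f <- bfactor_sharpen(lowpass_filter(v, lowpass), bfactor)
    st <- straighten_radial(f, curvature_center, radial_range,
                            cone_halfangle = cone_halfangle)
    d <- dim(st)
    win <- c(floor(d[1] / 4), ceiling(3 * d[1] / 4) - 1)
    sub <- as_vol_array(st)[win[1]:win[2] + 1, win[1]:win[2] + 1, ,
                            drop = FALSE]
    apply(sub, 3, mean)
  })
}

measure_profile_vector <- function(prof, voxel, min_prominence = 0.2) {
  mp <- profile_and_peaks(volume3d(array(rep(prof, each = 4),
                                         c(2, 2, length(prof))),
                                   voxel_size = voxel),
                          lateral_window = c(0, 1),
                          min_prominence = min_prominence)
  mp
}

#' Bootstrap the leaflet separation of a subtomogram set
#'
#' Repeats the full measurement (re-average a with-replacement resample
#' of the set, low-pass filter and sharpen, straighten radially,
#' profile, measure the peak-peak distance) `n_reps` times and reports
#' the mean and standard deviation over successful replicates. The
#' filtering, straightening and averaging steps are linear, so the
#' per-subtomogram straightened profiles are computed once and each
#' replicate profile is their resampled mean; the non-linear peak
#' measurement is recomputed per replicate.
#'
#' @param subtomos list of vesicle-centered `volume3d` subtomograms
#'   sharing the curvature center.
#' @param curvature_center 0-based voxel center (`NULL` = box center).
#' @param radial_range `(r_min, r_max)` voxels for straightening.
#' @param n_reps bootstrap replicates (default 750).
#' @param seed integer seed (bit-reproducible given it).
#' @param lowpass,bfactor pre-measurement filters (Angstrom,
#'   Angstrom^2).
#' @param max_fail_frac flag the result unreliable beyond this failed
#'   replicate fraction.
#' @return list of class `bootstrap_result`: `n_reps`,
#'   `mean_separation`, `sd_separation`, `separations`, `n_failed`,
#'   `reliable`, `seed`, plus the point estimate `separation` of the
#'   full set.
#' @export
bootstrap_thickness <- function(subtomos, curvature_center = NULL,
                                radial_range, n_reps = 750, seed = 1,
                                lowpass = 25, bfactor = -2000,
                                max_fail_frac = 0.2) {
  n <- length(subtomos)
  if (n < 5) stopf("need at least 5 subtomograms")
  if (n_reps < 2) stopf("n_reps must be >= 2")
  voxel <- attr(subtomos[[1]], "voxel_size")
  profs <- precompute_profiles(subtomos, curvature_center, radial_range,
                               lowpass, bfactor)
  P <- do.call(rbind, profs)       # n x n_r
  full <- measure_profile_vector(colMeans(P), voxel)
  seps <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      mp <- measure_profile_vector(colMeans(P[idx, , drop = FALSE]), voxel)
      if (mp$ok) mp$peak_separation else NA_real_
    }, numeric(1))
  })
  ok <- is.finite(seps)
  structure(list(n_reps = n_reps,
                 mean_separation = mean(seps[ok]),
                 sd_separation = stats::sd(seps[ok]),
                 separations = seps,
                 n_failed = sum(!ok),
                 reliable = mean(!ok) <= max_fail_frac,
                 separation = full$peak_separation,
                 seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: separation %.2f A (bootstrap %.2f +/- %.2f A, %d reps, %d failed%s)\n",
              x$separation, x$mean_separation, x$sd_separation, x$n_reps,
              x$n_failed, if (x$reliable) "" else "; UNRELIABLE"))
  invisible(x)
}

#' Extract aligned 2D boxes along a membrane polyline
#'
#' Samples `box`-sized 2D patches at fixed arc-length steps along a
#' polyline traced on a planar membrane in a tomographic slice, each
#' rotated so the local membrane tangent is horizontal (bilayer
#' vertical profile along the box y-axis). Boxes crossing the image
#' edge are dropped with a message.
#'
#' @param slice 2D `volume3d`.
#' @param polyline n x 2 matrix of 0-based voxel coordinates along the
#'   membrane (>= 2 points).
#' @param box box edge, pixels (default 20).
#' @param step arc-length sampling step, pixels (default `box / 2`).
#' @return list of class `box_stack_2d`: `boxes` (list of box x box
#'   matrices), `centers`, `tangents`, `voxel_size`.
#' @export
bilayer_boxes_2d <- function(slice, polyline, box = 20, step = NULL) {
  if (nrow(polyline) < 2) stopf("polyline needs at least 2 points")
  a <- as_vol_array(slice)
  d <- dim(a)
  step <- step %||% (box / 2)
  ## resample polyline at fixed arc length
  seg <- diff(polyline)
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  total <- cum[length(cum)]
  ss <- seq(0, total, by = step)
  pts <- t(vapply(ss, function(s) {
    i <- max(which(cum <= s + 1e-9)); i <- min(i, nrow(polyline) - 1)
    f <- (s - cum[i]) / max(lens[i], 1e-9)
    polyline[i, ] + f * (polyline[i + 1, ] - polyline[i, ])
  }, numeric(2)))
  tans <- t(vapply(ss, function(s) {
    i <- max(which(cum <= s + 1e-9)); i <- min(i, nrow(polyline) - 1)
    seg[i, ] / max(lens[i], 1e-9)
  }, numeric(2)))
  half <- (box - 1) / 2
  boxes <- list(); centers <- list(); tangents <- list()
  dropped <- 0
  grid <- expand.grid(u = seq_len(box) - 1 - half,
                      v = seq_len(box) - 1 - half)
  for (i in seq_len(nrow(pts))) {
    tv <- tans[i, ]; nv <- c(-tv[2], tv[1])
    sx <- pts[i, 1] + grid$u * tv[1] + grid$v * nv[1]
    sy <- pts[i, 2] + grid$u * tv[2] + grid$v * nv[2]
    if (any(sx < 0 | sx > d[1] - 2 | sy < 0 | sy > d[2] - 2)) {
      dropped <- dropped + 1
      next
    }
    ## duplicate the slice along z so the trilinear sampler has a valid
    ## 3D neighbourhood
    a3 <- array(c(a, a), c(d, 2))
    vals <- trilinear_sample(a3, sx, sy, rep(0, length(sx)), c(box, box))
    boxes[[length(boxes) + 1]] <- matrix(vals, box, box)
    centers[[length(centers) + 1]] <- pts[i, ]
    tangents[[length(tangents) + 1]] <- tv
  }
  if (dropped > 0)
    message(sprintf("bilayer_boxes_2d: dropped %d boxes at the image edge",
                    dropped))
  structure(list(boxes = boxes,
                 centers = do.call(rbind, centers),
                 tangents = do.call(rbind, tangents),
                 voxel_size = attr(slice, "voxel_size")),
            class = "box_stack_2d")
}

#' Align and average 2D bilayer boxes and measure the peak separation
#'
#' Boxes are aligned translationally (vertical only) by 1D correlation
#' of their lateral-mean profiles against the running average, then
#' averaged; the vertical profile of the average is measured as in
#' [profile_and_peaks()].
#'
#' @param stack `box_stack_2d` (>= 10 boxes).
#' @param max_shift maximum vertical shift, pixels.
#' @param min_corr flag alignment divergence below this mean
#'   correlation.
#' @return list with `average` (matrix), `profile`
#'   (`membrane_profile`), `shifts`, `mean_corr`, `ok`.
#' @export
average_2d_and_measure <- function(stack, max_shift = 4, min_corr = 0.2) {
  nb <- length(stack$boxes)
  if (nb < 10) stopf("need at least 10 boxes")
  box <- nrow(stack$boxes[[1]])
  profs <- vapply(stack$boxes, function(b) colMeans(b), numeric(box))
  ref <- rowMeans(profs)
  shifts <- numeric(nb); corrs <- numeric(nb)
  for (pass in 1:2) {
    for (i in seq_len(nb)) {
      best <- c(0, -Inf)
      for (s in -max_shift:max_shift) {
        idx <- seq_len(box) + s
        ok <- idx >= 1 & idx <= box
        cc <- suppressWarnings(stats::cor(profs[idx[ok], i], ref[which(ok)]))
        if (is.finite(cc) && cc > best[2]) best <- c(s, cc)
      }
      shifts[i] <- best[1]; corrs[i] <- best[2]
    }
    ## rebuild reference from aligned profiles
    al <- vapply(seq_len(nb), function(i) {
      p <- rep(NA_real_, box)
      idx <- seq_len(box) + shifts[i]
      ok <- idx >= 1 & idx <= box
      p[which(ok)] <- profs[idx[ok], i]
      p
    }, numeric(box))
    ref <- rowMeans(al, na.rm = TRUE)
  }
  avg <- matrix(0, box, box); wt <- matrix(0, box, box)
  for (i in seq_len(nb)) {
    idx <- seq_len(box) + shifts[i]
    ok <- idx >= 1 & idx <= box
    avg[, which(ok)] <- avg[, which(ok)] + stack$boxes[[i]][, idx[ok]]
    wt[, which(ok)] <- wt[, which(ok)] + 1
  }
  avg <- avg / pmax(wt, 1)
  vcol <- array(rep(colMeans(avg), each = 4), c(2, 2, box))
  mp <- profile_and_peaks(volume3d(vcol, voxel_size = stack$voxel_size),
                          lateral_window = c(0, 1))
  ok <- mean(corrs) >= min_corr
  list(average = avg, profile = mp, shifts = shifts,
       mean_corr = mean(corrs), ok = ok && mp$ok)
}

#' Measure a vesicle's membrane-to-membrane diameter
#'
#' Builds the radial density profile about the center, finds the outer
#' membrane (leaflet) peak with parabolic subsample interpolation and
#' reports `2 * r_peak` in nm. A coat above the membrane does not bias
#' the measurement because only the annulus around the expected
#' membrane radius competes for the peak.
#'
#' @param tomogram `volume3d` containing the vesicle.
#' @param center vesicle center, 0-based voxels.
#' @param r_range optional radial search range, voxels.
#' @param min_peak fail when the peak is below `min_peak` times the
#'   profile maximum.
#' @return list: `diameter_nm`, `r_peak_vox`, `profile`, `ok`.
#' @export
measure_vesicle_diameter <- function(tomogram, center, r_range = NULL,
                                     min_peak = 0.2) {
  a <- as_vol_array(tomogram)
  d <- dim(a)
  voxel <- attr(tomogram, "voxel_size")
  rmax_box <- min(c(center, d - 1 - center))
  if (rmax_box < 3) stopf("center too close to the volume edge")
  gx <- (seq_len(d[1]) - 1) - center[1]
  gy <- (seq_len(d[2]) - 1) - center[2]
  gz <- (seq_len(d[3]) - 1) - center[3]
  r <- sqrt(outer(outer(gx^2, gy^2, "+"), gz^2, "+"))
  rb <- round(r)
  sel <- rb <= rmax_box
  prof <- as.numeric(tapply(a[sel], rb[sel], mean))
  rr <- as.numeric(names(tapply(a[sel], rb[sel], mean)))
  if (!is.null(r_range)) {
    keep <- rr >= r_range[1] & rr <= r_range[2]
    prof <- prof[keep]; rr <- rr[keep]
  }
  n <- length(prof)
  if (n < 5) return(list(diameter_nm = NA_real_, ok = FALSE))
  loc <- which(prof > c(-Inf, prof[-n]) & prof >= c(prof[-1], -Inf))
  loc <- loc[prof[loc] > min_peak * max(prof)]
  loc <- loc[rr[loc] > 2]
  if (length(loc) == 0) return(list(diameter_nm = NA_real_,
                                    profile = data.frame(r = rr, density = prof),
                                    ok = FALSE))
  ## the outermost substantial peak is the outer leaflet
  i <- max(loc)
  pk <- parabolic_peak_1d(prof, i)
  r_peak <- rr[1] + (pk$pos - 1) * (rr[2] - rr[1])
  list(diameter_nm = 2 * r_peak * voxel / 10,
       r_peak_vox = r_peak,
       profile = data.frame(r = rr, density = prof),
       ok = TRUE)
}
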
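# Volume3D container and the spectral/real-space primitives built on it.

#' Create a 3D density volume
#'
#' The currency of the pipeline: a real-valued 3D grid with a voxel size
#' in Angstrom. Axes follow the MRC layout (x fastest, right-handed);
#' voxel indices are 0-based with positions at voxel centers.
#'
#' @param data numeric 3D array (or 2D matrix for slab images).
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @param origin physical origin in Angstrom, length 3.
#' @return object of class `volume3d` (an array with attributes).
#' @export
volume3d <- function(data, voxel_size = 1, origin = c(0, 0, 0)) {
  if (!is.array(data) || !(length(dim(data)) %in% c(2L, 3L)))
    stopf("data must be a 2D or 3D array")
  if (any(dim(data) < 2L)) stopf("grid dimensions must be >= 2 per axis")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stopf("voxel_size must be a single positive number")
  if (any(!is.finite(data))) stopf("volume values must be finite")
  structure(data, voxel_size = as.numeric(voxel_size),
            origin = as.numeric(origin), class = c("volume3d", "array"))
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("volume3d: %s voxels, %.4g A/voxel, range [%.4g, %.4g]\n",
              paste(d, collapse = " x "), attr(x, "voxel_size"),
              min(x), max(x)))
  invisible(x)
}

#' Voxel size of a volume
#' @param vol `volume3d`.
#' @return voxel size in Angstrom.
#' @export
voxel_size <- function(vol) attr(vol, "voxel_size")

## Rebuild a volume3d around new data, keeping metadata.
vol_like <- function(data, vol, voxel_size = attr(vol, "voxel_size")) {
  volume3d(data, voxel_size = voxel_size,
           origin = attr(vol, "origin") %||% c(0, 0, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_vol_array <- function(vol) {
  a <- unclass(vol)
  attr(a, "voxel_size") <- NULL
  attr(a, "origin") <- NULL
  a
}

## FFT sample frequencies for axis length n and spacing d (1/Angstrom),
## in the unshifted FFT layout.
fft_freqs <- function(n, d = 1) {
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
  k / (n * d)
}

## |s| over the full FFT grid of a volume, 1/Angstrom.
freq_grid <- function(dims, voxel) {
  fx <- fft_freqs(dims[1], voxel)
  fy <- fft_freqs(dims[2], voxel)
  fz <- if (length(dims) == 3L) fft_freqs(dims[3], voxel) else 0
  s2 <- outer(outer(fx^2, fy^2, "+"), fz^2, "+")
  if (length(dims) == 2L) dim(s2) <- dims
  sqrt(s2)
}

apply_fourier_filter <- function(vol, weight) {
  a <- as_vol_array(vol)
  out <- Re(stats::fft(stats::fft(a) * weight, inverse = TRUE)) / length(a)
  vol_like(out, vol)
}

## Block-mean binning of a plain 3D array (no metadata handling).
bin_array <- function(a, factor) {
  d <- dim(a)
  keep <- (d %/% factor) * factor
  if (any(keep != d))
    a <- a[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]), drop = FALSE]
  nd <- keep %/% factor
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  out <- apply(a, c(2, 4, 6), mean)
  out
}

#' Bin a volume by block averaging
#'
#' Each output voxel is the mean of a `factor^3` block; the voxel size is
#' multiplied by `factor`. Dimensions not divisible by `factor` are
#' cropped to the largest divisible box (with a message).
#'
#' @param vol `volume3d`.
#' @param factor integer >= 1.
#' @return binned `volume3d`.
#' @export
bin_volume <- function(vol, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stopf("factor must be an integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(vol)
  a <- as_vol_array(vol)
  d <- dim(a)
  keep <- (d %/% factor) * factor
  if (any(keep != d)) {
    message(sprintf("bin_volume: cropping %s to %s for factor %d",
                    paste(d, collapse = "x"), paste(keep, collapse = "x"),
                    factor))
    a <- a[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]), drop = FALSE]
  }
  volume3d(bin_array(a, factor),
           voxel_size = attr(vol, "voxel_size") * factor,
           origin = attr(vol, "origin") %||% c(0, 0, 0))
}

#' Low-pass filter a volume to a target resolution
#'
#' Fourier amplitudes beyond `1/resolution` are attenuated by a
#' raised-cosine edge of `edge_shells` Fourier shells; the zero frequency
#' is preserved exactly.
#'
#' @param vol `volume3d`.
#' @param resolution cutoff resolution in Angstrom
#'   (must be >= 2 * voxel size, the Nyquist limit).
#' @param edge_shells width of the cosine edge in Fourier shells.
#' @return filtered `volume3d`.
#' @export
lowpass_filter <- function(vol, resolution, edge_shells = 3) {
  voxel <- attr(vol, "voxel_size")
  if (resolution < 2 * voxel)
    stopf("resolution %.3g A is finer than Nyquist (%.3g A)", resolution,
          2 * voxel)
  dims <- dim(vol)
  s <- freq_grid(dims, voxel)
  fc <- 1 / resolution
  w <- edge_shells / (max(dims) * voxel)
  wt <- ifelse(s <= fc, 1,
        ifelse(s >= fc + w, 0, 0.5 * (1 + cos(pi * (s - fc) / w))))
  apply_fourier_filter(vol, wt)
}

#' Apply a B-factor to a volume
#'
#' Multiplies Fourier amplitudes by `exp(-B s^2 / 4)` with `s` the
#' spatial frequency in 1/Angstrom. Negative B sharpens.
#'
#' @param vol `volume3d`.
#' @param B B-factor in Angstrom^2 (e.g. -2000 for strong sharpening of
#'   low-resolution subtomogram averages).
#' @return `volume3d`.
#' @export
bfactor_sharpen <- function(vol, B) {
  if (B == 0) return(vol)
  s <- freq_grid(dim(vol), attr(vol, "voxel_size"))
  apply_fourier_filter(vol, exp(-B * s^2 / 4))
}

#' Mask geometry specification
#'
#' @param shape one of `"cylinder"`, `"sphere"`, `"wedge"`, `"sector"`.
#' @param ... geometry parameters: `center` (voxels, default box center);
#'   `radius` for sphere/cylinder; `height` for cylinder (voxels, default
#'   full box, axis z); `halfangle` (degrees) for wedge;
#'   `r_in`, `r_out`, `n_sectors`, `sector` for sector masks.
#' @param edge_width width of the cosine-soft edge in voxels (ramp is
#'   centered on the nominal boundary, so the mask value at the boundary
#'   is 0.5).
#' @return object of class `mask_spec`.
#' @export
mask_spec <- function(shape, ..., edge_width = 0) {
  shape <- match.arg(shape, c("cylinder", "sphere", "wedge", "sector"))
  structure(list(shape = shape, pars = list(...),
                 edge_width = as.numeric(edge_width)),
            class = "mask_spec")
}

## Cosine ramp on signed distance outside the boundary (d<0 inside).
soft_step <- function(d, ew) {
  if (ew <= 0) return(as.numeric(d < 0))
  ifelse(d <= -ew / 2, 1,
  ifelse(d >= ew / 2, 0, 0.5 * (1 + cos(pi * (d / ew + 0.5)))))
}

coord_grids <- function(dims, center) {
  x <- (seq_len(dims[1]) - 1) - center[1]
  y <- (seq_len(dims[2]) - 1) - center[2]
  z <- if (length(dims) == 3L) (seq_len(dims[3]) - 1) - center[3] else 0
  list(x = x, y = y, z = z)
}

#' Build a soft-edged mask volume
#'
#' Real-space masks (sphere, cylinder along z, annular sector) take
#' values 1 inside, 0 outside with a cosine ramp of `edge_width` voxels
#' across the boundary. The `wedge` shape is a Fourier-layout missing
#' wedge mask (0 inside the unsampled wedge about the z* axis in the
#' x*-z* plane, 1 elsewhere) used for tilt-limited simulations.
#'
#' @param spec `mask_spec`.
#' @param dims output dimensions (length 2 or 3).
#' @param voxel_size voxel size recorded in the output, Angstrom.
#' @return `volume3d` with values in [0, 1].
#' @export
make_mask <- function(spec, dims, voxel_size = 1) {
  if (!inherits(spec, "mask_spec")) stopf("spec must be a mask_spec")
  p <- spec$pars
  ew <- spec$edge_width
  center <- p$center %||% ((dims - 1) / 2)
  g <- coord_grids(dims, center)
  out <- switch(spec$shape,
    sphere = {
      if (is.null(p$radius) || p$radius <= 0) stopf("sphere mask needs radius > 0")
      r <- sqrt(outer(outer(g$x^2, g$y^2, "+"), g$z^2, "+"))
      soft_step(r - p$radius, ew)
    },
    cylinder = {
      if (is.null(p$radius) || p$radius <= 0) stopf("cylinder mask needs radius > 0")
      rxy <- sqrt(outer(g$x^2, g$y^2, "+"))
      m <- soft_step(outer(rxy, rep(1, max(1, length(g$z)))) - p$radius, ew)
      dim(m) <- dims
      if (!is.null(p$height) && length(dims) == 3L) {
        mz <- soft_step(abs(g$z) - p$height / 2, ew)
        m <- m * rep(mz, each = dims[1] * dims[2])
      }
      m
    },
    wedge = {
      if (is.null(p$halfangle) || p$halfangle <= 0)
        stopf("wedge mask needs halfangle > 0")
      fx <- fft_freqs(dims[1]); fz <- fft_freqs(dims[3])
      ## angle of (kx, kz) from the kz axis, per (kx, kz) pair
      axz <- atan2(abs(outer(abs(fx), rep(1, dims[3]))),
                   abs(outer(rep(1, dims[1]), abs(fz))))
      inwedge <- rad2deg(axz) < p$halfangle
      ## kz = 0 plane is always sampled
      inwedge[, abs(fz) < 1e-12] <- FALSE
      m <- array(1, dims)
      for (k in seq_len(dims[3]))
        m[, , k] <- m[, , k] * rep(1 - as.numeric(inwedge[, k]), dims[2])
      m
    },
    sector = {
      if (length(dims) != 2L) stopf("sector masks are 2D")
      r_in <- p$r_in %||% 0; r_out <- p$r_out
      ns <- p$n_sectors %||% 8L; k <- p$sector
      if (is.null(r_out) || r_out <= r_in) stopf("sector mask needs r_out > r_in")
      if (is.null(k) || k < 1 || k > ns) stopf("sector index out of range")
      r <- sqrt(outer(g$x^2, g$y^2, "+"))
      theta <- posmod(rad2deg(atan2(outer(rep(1, dims[1]), g$y),
                                    outer(g$x, rep(1, dims[2])))), 360)
      wsec <- 360 / ns
      insec <- theta >= (k - 1) * wsec & theta < k * wsec
      band <- soft_step(r - r_out, ew) * soft_step(r_in - r, ew)
      band * insec
    })
  dim(out) <- dims
  volume3d(clamp(out, 0, 1), voxel_size = voxel_size)
}

#' Resample a volume under a rigid transform (trilinear)
#'
#' Inverse-mapping sampler: the output at voxel `y` is the input sampled
#' at `rotation %*% (y - center) + center + offset` (0-based voxel
#' coordinates, trilinear interpolation, zero outside the grid). All
#' rotation/shift operations in the package are built on this primitive.
#'
#' @param vol `volume3d` or 3D array.
#' @param rotation 3x3 matrix applied in the inverse mapping.
#' @param offset length-3 shift (voxels) added in the inverse mapping.
#' @param center rotation center, 0-based voxels; default box center.
#' @param out_dims output dimensions; default same as input.
#' @return array (plain) of `out_dims`.
#' @export
resample_volume <- function(vol, rotation = diag(3), offset = c(0, 0, 0),
                            center = NULL, out_dims = NULL) {
  a <- if (inherits(vol, "volume3d")) as_vol_array(vol) else vol
  d <- dim(a)
  od <- out_dims %||% d
  ctr <- center %||% ((od - 1) / 2)
  ctr_in <- center %||% ((d - 1) / 2)
  ## output voxel coordinates relative to output center
  gx <- (seq_len(od[1]) - 1) - ctr[1]
  gy <- (seq_len(od[2]) - 1) - ctr[2]
  gz <- (seq_len(od[3]) - 1) - ctr[3]
  n <- prod(od)
  X <- rep(gx, times = od[2] * od[3])
  Y <- rep(rep(gy, each = od[1]), times = od[3])
  Z <- rep(gz, each = od[1] * od[2])
  P <- rotation %*% rbind(X, Y, Z)
  sx <- P[1, ] + ctr_in[1] + offset[1]
  sy <- P[2, ] + ctr_in[2] + offset[2]
  sz <- P[3, ] + ctr_in[3] + offset[3]
  trilinear_sample(a, sx, sy, sz, od)
}

## Vectorized trilinear interpolation at 0-based coordinates; 0 outside.
trilinear_sample <- function(a, sx, sy, sz, out_dims) {
  d <- dim(a)
  x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
  fx <- sx - x0; fy <- sy - y0; fz <- sz - z0
  ok <- x0 >= 0 & y0 >= 0 & z0 >= 0 &
        x0 <= d[1] - 2 & y0 <= d[2] - 2 & z0 <= d[3] - 2
  out <- numeric(length(sx))
  if (any(ok)) {
    x0k <- x0[ok]; y0k <- y0[ok]; z0k <- z0[ok]
    fxk <- fx[ok]; fyk <- fy[ok]; fzk <- fz[ok]
    base <- 1 + x0k + d[1] * (y0k + d[2] * z0k)
    dx <- 1L; dy <- d[1]; dz <- d[1] * d[2]
    c000 <- a[base];            c100 <- a[base + dx]
    c010 <- a[base + dy];       c110 <- a[base + dx + dy]
    c001 <- a[base + dz];       c101 <- a[base + dx + dz]
    c011 <- a[base + dy + dz];  c111 <- a[base + dx + dy + dz]
    c00 <- c000 * (1 - fxk) + c100 * fxk
    c10 <- c010 * (1 - fxk) + c110 * fxk
    c01 <- c001 * (1 - fxk) + c101 * fxk
    c11 <- c011 * (1 - fxk) + c111 * fxk
    c0 <- c00 * (1 - fyk) + c10 * fyk
    c1 <- c01 * (1 - fyk) + c11 * fyk
    out[ok] <- c0 * (1 - fzk) + c1 * fzk
  }
  array(out, out_dims)
}

#' Rotate a volume about its center
#'
#' Applies the rotation `R` to the density: the output at `x` equals the
#' input at `t(R) (x - c) + c`. Equivalent to rotating the object by `R`.
#'
#' @param vol `volume3d`.
#' @param rotation 3x3 rotation matrix or Euler triplet (degrees).
#' @return `volume3d`.
#' @export
rotate_volume <- function(vol, rotation) {
  if (is.numeric(rotation) && length(rotation) == 3L)
    rotation <- euler_to_matrix(rotation)
  check_rotation(rotation)
  out <- resample_volume(vol, rotation = t(rotation))
  vol_like(out, vol)
}

#' Shift a volume by a (possibly subvoxel) offset
#'
#' The density moves by `+shift` voxels (trilinear interpolation).
#'
#' @param vol `volume3d`.
#' @param shift length-3 shift in voxels.
#' @return `volume3d`.
#' @export
shift_volume <- function(vol, shift) {
  out <- resample_volume(vol, offset = -as.numeric(shift))
  vol_like(out, vol)
}
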
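# Gold-standard resolution estimation: Fourier shell correlation with
# mask correction by phase randomization, threshold crossing, and final
# map postprocessing (CTF-sum reweighting, low-pass, B-factor).

shell_index <- function(dims, voxel) {
  s <- freq_grid(dims, voxel)
  ds <- 1 / (max(dims) * voxel)
  idx <- pmin(as.integer(round(s / ds)), floor(max(dims) / 2))
  list(idx = idx, ds = ds, nshell = floor(max(dims) / 2) + 1L)
}

#' Fourier shell correlation between two volumes
#'
#' Per-shell normalized cross-spectral correlation. With a mask, both
#' volumes are multiplied by it first.
#'
#' @param vol1,vol2 `volume3d` of equal dimensions and voxel size.
#' @param mask optional `volume3d` mask.
#' @param variant label stored in the result (`"unmasked"`, `"masked"`,
#'   `"phase_randomized"`, `"corrected"`).
#' @return data.frame of class `fsc_curve` with columns `shell_freq`
#'   (1/Angstrom), `fsc`, `n_voxels`, and attributes `voxel_size`,
#'   `variant`.
#' @export
fsc <- function(vol1, vol2, mask = NULL, variant = "unmasked") {
  if (!all(dim(vol1) == dim(vol2)))
    stopf("volumes have different dimensions")
  voxel <- attr(vol1, "voxel_size")
  if (abs(voxel - attr(vol2, "voxel_size")) > 1e-6)
    stopf("volumes have different voxel sizes")
  a <- as_vol_array(vol1); b <- as_vol_array(vol2)
  if (!is.null(mask)) {
    m <- as_vol_array(mask)
    a <- a * m; b <- b * m
    if (variant == "unmasked") variant <- "masked"
  }
  FA <- stats::fft(a); FB <- stats::fft(b)
  sh <- shell_index(dim(a), voxel)
  num <- tapply(Re(FA * Conj(FB)), sh$idx, sum)
  na <- tapply(abs(FA)^2, sh$idx, sum)
  nb <- tapply(abs(FB)^2, sh$idx, sum)
  nv <- tapply(rep(1L, length(sh$idx)), sh$idx, sum)
  k <- as.integer(names(num))
  keep <- k <= floor(max(dim(a)) / 2) / 1  # up to Nyquist shell
  den <- sqrt(na * nb)
  val <- ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(shell_freq = k[keep] * sh$ds, fsc = as.numeric(val[keep]),
                    n_voxels = as.integer(nv[keep]))
  out <- out[order(out$shell_freq), ]
  rownames(out) <- NULL
  structure(out, voxel_size = voxel, variant = variant,
            class = c("fsc_curve", "data.frame"))
}

## Hermitian-symmetric random phase field for a real volume's FFT.
random_phase_field <- function(dims, seed) {
  ph <- with_seed(seed, array(stats::runif(prod(dims), 0, 2 * pi), dims))
  rev_idx <- function(n) c(1L, n:2L)
  phr <- ph[rev_idx(dims[1]), rev_idx(dims[2]), rev_idx(dims[3])]
  ph - phr   # antisymmetric: ph(-k) = -ph(k)
}

#' Randomize Fourier phases beyond a resolution shell
#'
#' Amplitudes are preserved; phases beyond `1/resolution` are replaced
#' by (Hermitian-symmetric) uniform random phases, so the volume stays
#' real. Used to measure mask-induced correlation in the FSC.
#'
#' @param vol `volume3d`.
#' @param resolution start of randomization, Angstrom.
#' @param seed integer seed.
#' @return `volume3d`.
#' @export
phase_randomize <- function(vol, resolution, seed) {
  a <- as_vol_array(vol)
  s <- freq_grid(dim(a), attr(vol, "voxel_size"))
  ph <- random_phase_field(dim(a), seed)
  w <- exp(1i * ph * (s > 1 / resolution))
  out <- Re(stats::fft(stats::fft(a) * w, inverse = TRUE)) / length(a)
  vol_like(out, vol)
}

#' Mask-corrected phase-randomized FSC
#'
#' The gold-standard procedure: the masked FSC of two half-maps is
#' corrected for mask-induced correlation by re-computing it after
#' randomizing the phases of both halves beyond `rand_start`, and
#' applying `(FSC_masked - FSC_rand) / (1 - FSC_rand)` beyond
#' `rand_start` plus a buffer of `buffer_shells` shells. Shells where
#' `FSC_rand` is within 1e-6 of 1 are flagged undefined (`NA`).
#'
#' @param half1,half2 independent half-maps (`volume3d`).
#' @param mask `volume3d` soft mask.
#' @param rand_start randomization start, Angstrom (coarser than the
#'   expected resolution).
#' @param seed integer seed; the two halves are randomized with
#'   independent derived seeds.
#' @param buffer_shells shells beyond `rand_start` left uncorrected.
#' @return `fsc_curve` (variant `"corrected"`) with extra columns
#'   `fsc_masked`, `fsc_rand`, `fsc_unmasked`.
#' @export
phase_randomized_fsc <- function(half1, half2, mask, rand_start, seed = 1,
                                 buffer_shells = 2) {
  f_un <- fsc(half1, half2)
  f_m <- fsc(half1, half2, mask, variant = "masked")
  r1 <- phase_randomize(half1, rand_start, seed * 2L + 11L)
  r2 <- phase_randomize(half2, rand_start, seed * 2L + 12L)
  f_r <- fsc(r1, r2, mask, variant = "phase_randomized")
  ds <- f_m$shell_freq[2] - f_m$shell_freq[1]
  start_k <- 1 / rand_start / ds + buffer_shells
  corrected <- f_m$fsc
  beyond <- seq_along(f_m$fsc) - 1 >= start_k
  denom <- 1 - f_r$fsc
  undef <- beyond & (abs(denom) < 1e-6 | !is.finite(denom))
  corr_region <- beyond & !undef
  corrected[corr_region] <- (f_m$fsc[corr_region] - f_r$fsc[corr_region]) /
    denom[corr_region]
  corrected[undef] <- NA_real_
  out <- f_m
  out$fsc <- corrected
  out$fsc_masked <- f_m$fsc
  out$fsc_rand <- f_r$fsc
  out$fsc_unmasked <- f_un$fsc
  attr(out, "variant") <- "corrected"
  attr(out, "rand_start") <- rand_start
  out
}

#' Resolution at an FSC threshold
#'
#' The first crossing of the curve below `threshold`, linearly
#' interpolated in spatial frequency between shells; returns the
#' Nyquist resolution (`2 * voxel`) if the curve never crosses.
#'
#' @param curve `fsc_curve`.
#' @param threshold FSC threshold (default 0.143; 0.5 is also common).
#' @return resolution in Angstrom.
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  if (!inherits(curve, "fsc_curve") || nrow(curve) == 0)
    stopf("curve must be a non-empty fsc_curve")
  voxel <- attr(curve, "voxel_size")
  f <- curve$fsc; s <- curve$shell_freq
  ok <- is.finite(f)
  f <- f[ok]; s <- s[ok]
  below <- which(f < threshold & s > 0)
  if (length(below) == 0) return(2 * voxel)
  i <- below[1]
  if (i == 1) return(1 / s[1])
  frac <- (f[i - 1] - threshold) / (f[i - 1] - f[i])
  s_cross <- s[i - 1] + frac * (s[i] - s[i - 1])
  1 / s_cross
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("fsc_curve (%s): %d shells to %.3g 1/A; resolution %.2f A (FSC 0.143), %.2f A (FSC 0.5)\n",
              attr(x, "variant"), nrow(x), max(x$shell_freq),
              resolution_at(x), resolution_at(x, 0.5)))
  invisible(x)
}

#' Postprocess a final map
#'
#' Fixed order: division by the radial CTF-sum weight (floored at
#' `wiener_floor`) when provided, then low-pass filtration to
#' `lowpass_res`, then B-factor sharpening.
#'
#' @param vol `volume3d`.
#' @param lowpass_res low-pass resolution, Angstrom (>= 2 voxel).
#' @param bfactor B-factor, Angstrom^2 (default -2000).
#' @param ctf_weight optional radial weight: data.frame or list with
#'   `freq` (1/Angstrom) and `weight`, interpolated per Fourier shell.
#' @param wiener_floor positive floor for the weight division.
#' @return `volume3d`.
#' @export
postprocess <- function(vol, lowpass_res, bfactor = -2000,
                        ctf_weight = NULL, wiener_floor = 1e-3) {
  out <- vol
  if (!is.null(ctf_weight)) {
    if (wiener_floor <= 0 && any(ctf_weight$weight == 0))
      stopf("ctf_weight contains zeros and wiener_floor is 0")
    s <- freq_grid(dim(vol), attr(vol, "voxel_size"))
    w <- stats::approx(ctf_weight$freq, ctf_weight$weight, xout = as.numeric(s),
                       rule = 2)$y
    w <- pmax(w, wiener_floor)
    out <- apply_fourier_filter(out, array(1 / w, dim(vol)))
  }
  out <- lowpass_filter(out, lowpass_res)
  bfactor_sharpen(out, bfactor)
}
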
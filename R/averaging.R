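# Subtomogram extraction, averaging bookkeeping and particle-set
# housekeeping (CC filtering, duplicate removal, half-set splitting).

#' Extract subtomograms from a tomogram
#'
#' One box per particle, centered on the particle position rounded to
#' the nearest voxel; the residual subvoxel offset stays in the table
#' (positions are not modified). Particles whose box would cross the
#' tomogram boundary are dropped with a message.
#'
#' @param tomogram `volume3d`.
#' @param table `particle_table`.
#' @param boxsize box edge length, voxels.
#' @return list of class `subtomo_stack` with elements `boxes` (list of
#'   arrays), `center` (n x 3 matrix of extraction centers, 0-based
#'   voxels), `particle_id`, `boxsize`, `voxel_size`, and `table` (the
#'   surviving rows).
#' @export
extract_subtomograms <- function(tomogram, table, boxsize) {
  validate_particle_table(table)
  d <- dim(tomogram)
  a <- as_vol_array(tomogram)
  half_lo <- floor((boxsize - 1) / 2)
  half_hi <- boxsize - 1 - half_lo
  if (nrow(table) == 0) {
    warnf("empty particle table: returning empty stack")
    return(structure(list(boxes = list(), center = matrix(0, 0, 3),
                          particle_id = table$particle_id, boxsize = boxsize,
                          voxel_size = attr(tomogram, "voxel_size"),
                          table = table), class = "subtomo_stack"))
  }
  q <- round(cbind(table$x, table$y, table$z))
  ok <- q[, 1] - half_lo >= 0 & q[, 1] + half_hi <= d[1] - 1 &
        q[, 2] - half_lo >= 0 & q[, 2] + half_hi <= d[2] - 1 &
        q[, 3] - half_lo >= 0 & q[, 3] + half_hi <= d[3] - 1
  if (any(!ok))
    message(sprintf("extract_subtomograms: dropped %d of %d particles at the tomogram edge",
                    sum(!ok), nrow(table)))
  keep <- which(ok)
  boxes <- lapply(keep, function(i)
    a[(q[i, 1] - half_lo):(q[i, 1] + half_hi) + 1,
      (q[i, 2] - half_lo):(q[i, 2] + half_hi) + 1,
      (q[i, 3] - half_lo):(q[i, 3] + half_hi) + 1])
  tab <- table[keep, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(boxes = boxes, center = q[keep, , drop = FALSE],
                 particle_id = tab$particle_id, boxsize = boxsize,
                 voxel_size = attr(tomogram, "voxel_size"),
                 table = particle_table(as.data.frame(tab))),
            class = "subtomo_stack")
}

## Rows of `table` matched to stack order; errors if a particle is absent.
stack_rows <- function(stack, table) {
  idx <- match(stack$particle_id, table$particle_id)
  if (any(is.na(idx))) stopf("table does not cover all particles in the stack")
  table[idx, , drop = FALSE]
}

## Contribution of one particle in the reference frame: the box resampled
## with its orientation and residual offset (position - extraction center).
reference_contribution <- function(box, rotation, delta) {
  resample_volume(box, rotation = rotation, offset = as.numeric(delta))
}

#' Average a stack under its table parameters (no alignment)
#'
#' Rotates/shifts every subtomogram into the reference frame according
#' to its current table entry and averages. With the sphere-seeded
#' random in-plane angles this produces the rotationally smeared smooth
#' starting reference of the first alignment round.
#'
#' @param stack `subtomo_stack`.
#' @param table `particle_table` covering the stack.
#' @return `volume3d` average.
#' @export
initial_reference <- function(stack, table) {
  if (length(stack$boxes) == 0) stopf("stack is empty")
  tab <- stack_rows(stack, table)
  acc <- array(0, rep(stack$boxsize, 3))
  for (i in seq_along(stack$boxes)) {
    R <- euler_to_matrix(c(tab$phi[i], tab$psi[i], tab$theta[i]))
    delta <- c(tab$x[i], tab$y[i], tab$z[i]) - stack$center[i, ]
    acc <- acc + reference_contribution(stack$boxes[[i]], R, delta)
  }
  volume3d(acc / length(stack$boxes), voxel_size = stack$voxel_size)
}

#' Symmetrize a volume about the z-axis
#'
#' Returns the mean of the `order` copies rotated by multiples of
#' `360/order` degrees, which is invariant (up to interpolation error)
#' under the symmetry rotation.
#'
#' @param vol `volume3d`.
#' @param order symmetry order (>= 1).
#' @return symmetrized `volume3d`.
#' @export
symmetrize <- function(vol, order) {
  if (order < 1 || order != round(order)) stopf("order must be a positive integer")
  if (order == 1) return(vol)
  acc <- as_vol_array(vol)
  for (k in seq_len(order - 1))
    acc <- acc + as_vol_array(rotate_volume(vol, c(360 * k / order, 0, 0)))
  vol_like(acc / order, vol)
}

#' Center the symmetry axis of a volume
#'
#' Finds the lateral (x, y) shift that maximizes the correlation between
#' the volume and its `360/order`-degree rotated copy, and applies it, so
#' the symmetry axis passes through the box center. Uses the closed-form
#' relation between the self-rotation cross-correlation peak `u` and the
#' axis displacement `s0`: `u = (R - I) s0` in the xy-plane.
#'
#' @param vol `volume3d` containing a dominant `order`-fold motif.
#' @param order symmetry order.
#' @param min_cc correlation below which the search is flagged failed.
#' @return list with `volume` (centered), `transform` (the applied
#'   shift as a `rigid_transform`), `cc` (peak self-rotation
#'   correlation) and `ok`.
#' @export
center_symmetry_axis <- function(vol, order = 3, min_cc = 0.5) {
  a <- as_vol_array(vol)
  w <- as_vol_array(rotate_volume(vol, c(360 / order, 0, 0)))
  a0 <- a - mean(a); w0 <- w - mean(w)
  n <- length(a0)
  X <- Re(stats::fft(Conj(stats::fft(a0)) * stats::fft(w0), inverse = TRUE)) / n
  X <- X / sqrt(sum(a0^2) * sum(w0^2))
  d <- dim(a)
  pk <- arrayInd(which.max(X), d)
  cc <- X[pk]
  if (!is.finite(cc) || cc < min_cc)
    return(list(volume = vol, transform = rigid_transform(), cc = cc, ok = FALSE))
  u <- ((pk - 1 + d / 2) %% d) - d / 2          # wrapped shift, voxels
  u <- u + parabolic_offset_3d(X, pk, d)
  ## if the axis is displaced by s0 from the center, the self-rotation
  ## ccf peaks at u = (R - I) s0; the centering shift is -s0
  Rm <- euler_to_matrix(c(360 / order, 0, 0)) - diag(3)
  s <- c(-solve(Rm[1:2, 1:2], u[1:2]), 0)
  list(volume = shift_volume(vol, s),
       transform = rigid_transform(diag(3), s, unit = "voxel"),
       cc = cc, ok = TRUE)
}

## 3-point parabolic sub-sample offset of a peak at index pk (wrapped).
parabolic_offset_3d <- function(X, pk, d) {
  off <- numeric(3)
  for (ax in 1:3) {
    im <- pk; ip <- pk
    im[ax] <- ((pk[ax] - 2) %% d[ax]) + 1
    ip[ax] <- (pk[ax] %% d[ax]) + 1
    y0 <- X[rbind(im)]; y1 <- X[rbind(pk)]; y2 <- X[rbind(ip)]
    den <- y0 - 2 * y1 + y2
    off[ax] <- if (abs(den) > 1e-12) clamp(0.5 * (y0 - y2) / den, -1, 1) else 0
  }
  off
}

#' Keep the best-correlating fraction of particles
#'
#' Keeps the top `keep_fraction` of rows by `cc_score` within each
#' half-set (or globally when half-sets are unassigned), with a
#' deterministic tie-break by `particle_id`.
#'
#' @param table `particle_table` with populated `cc_score`.
#' @param keep_fraction fraction in (0, 1].
#' @return filtered `particle_table`.
#' @export
cc_filter <- function(table, keep_fraction) {
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1)
    stopf("keep_fraction must be in (0, 1]")
  validate_particle_table(table)
  if (keep_fraction == 1 || nrow(table) == 0) return(table)
  if (all(is.na(table$cc_score))) stopf("cc_score is not populated")
  groups <- if (all(is.na(table$halfset))) rep(1L, nrow(table)) else table$halfset
  keep <- unlist(lapply(split(seq_len(nrow(table)), groups), function(idx) {
    sub <- table[idx, ]
    ord <- order(-sub$cc_score, sub$particle_id)
    k <- max(1L, floor(keep_fraction * length(idx) + 1e-9))
    idx[ord[seq_len(k)]]
  }))
  out <- table[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  particle_table(as.data.frame(out))
}

#' Remove overlapping particles by a distance threshold
#'
#' Greedy best-first: particles are visited in order of descending
#' `cc_score` (ties broken by `particle_id`) and kept only if no
#' already-kept particle of the same vesicle lies within `min_dist`.
#' Idempotent. The default threshold of 177 Angstrom (17.7 nm) is the
#' standard overlap cutoff for triads on 13.68 Angstrom voxel data
#' (13 pixels).
#'
#' @param table `particle_table`.
#' @param min_dist minimum center-to-center distance, Angstrom.
#' @param voxel_size Angstrom per voxel of the position coordinates.
#' @return filtered `particle_table`.
#' @export
remove_duplicates <- function(table, min_dist = 177, voxel_size) {
  validate_particle_table(table)
  if (nrow(table) < 2) return(table)
  cc <- ifelse(is.na(table$cc_score), -Inf, table$cc_score)
  ord <- order(-cc, table$particle_id)
  pos <- cbind(table$x, table$y, table$z) * voxel_size
  keep <- logical(nrow(table))
  for (vid in unique(table$vesicle_id)) {
    rows <- ord[table$vesicle_id[ord] == vid]
    kept <- integer(0)
    for (i in rows) {
      if (length(kept) == 0 ||
          min(sqrt(colSums((t(pos[kept, , drop = FALSE]) - pos[i, ])^2))) >= min_dist) {
        keep[i] <- TRUE
        kept <- c(kept, i)
      }
    }
  }
  out <- table[sort(which(keep)), , drop = FALSE]
  rownames(out) <- NULL
  particle_table(as.data.frame(out))
}

#' Split vesicles into two independent half-sets
#'
#' The split is at vesicle granularity so that no vesicle (and hence no
#' particle) contributes to both halves; half sizes differ by at most
#' one vesicle.
#'
#' @param vesicles `vesicle_table` (or vector of vesicle ids).
#' @param seed integer seed for the shuffle.
#' @return named integer vector mapping vesicle_id to half-set 1 or 2.
#' @export
halfset_split <- function(vesicles, seed) {
  ids <- if (is.data.frame(vesicles)) vesicles$vesicle_id else vesicles
  if (length(ids) < 2) stopf("need at least 2 vesicles to split")
  perm <- with_seed(seed, sample(length(ids)))
  half <- integer(length(ids))
  half[perm] <- rep(c(1L, 2L), length.out = length(ids))
  stats::setNames(half, as.character(ids))
}

#' Assign half-set labels to a particle table by vesicle
#' @param table `particle_table`.
#' @param split named vector from [halfset_split()].
#' @return `particle_table` with `halfset` filled in.
#' @export
apply_halfset <- function(table, split) {
  table$halfset <- unname(split[as.character(table$vesicle_id)])
  if (any(is.na(table$halfset))) stopf("split does not cover all vesicles")
  particle_table(as.data.frame(table))
}

#' Per-group averages from refined parameters
#'
#' Builds one average per label of a grouping column (`region_group` or
#' `stage`) from the already-refined table parameters, without any
#' re-alignment. Labels requested but absent from the table are skipped
#' with a warning.
#'
#' @param stack `subtomo_stack`.
#' @param table refined `particle_table`.
#' @param group grouping column name.
#' @param levels optional label set to report (default: labels present).
#' @return named list of `volume3d` averages with an `n` attribute.
#' @export
group_average <- function(stack, table, group = c("region_group", "stage"),
                          levels = NULL) {
  group <- match.arg(group)
  tab <- stack_rows(stack, table)
  labels <- levels %||% unique(tab[[group]])
  out <- list()
  for (lab in labels) {
    rows <- which(tab[[group]] == lab)
    if (length(rows) == 0) {
      warnf("group_average: no particles with %s = '%s', skipped", group, lab)
      next
    }
    sub <- structure(list(boxes = stack$boxes[rows],
                          center = stack$center[rows, , drop = FALSE],
                          particle_id = stack$particle_id[rows],
                          boxsize = stack$boxsize,
                          voxel_size = stack$voxel_size),
                     class = "subtomo_stack")
    avg <- initial_reference(sub, tab[rows, , drop = FALSE])
    attr(avg, "n") <- length(rows)
    out[[as.character(lab)]] <- avg
  }
  out
}
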
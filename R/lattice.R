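# Lattice maps, linkage pattern derivation, automated pattern search
# with C3 branch enumeration, and linkage subvolume averaging.

#' Build a per-vesicle lattice map from refined triads
#'
#' The neighbor graph has an (undirected) edge for every pair of triads
#' of the same vesicle whose center-to-center distance is within
#' `neighbor_cutoff`.
#'
#' @param table refined `particle_table` (positions in voxels).
#' @param voxel_size Angstrom per voxel.
#' @param neighbor_cutoff Angstrom.
#' @return list of class `lattice_map`: `table`, `edges` (data.frame
#'   `a, b, dist` with particle_id references, a < b), `neighbor_cutoff`.
#' @export
build_lattice_map <- function(table, voxel_size, neighbor_cutoff = 300) {
  validate_particle_table(table)
  edges <- list()
  for (vid in unique(table$vesicle_id)) {
    sub <- table[table$vesicle_id == vid, ]
    if (nrow(sub) < 2) next
    pos <- cbind(sub$x, sub$y, sub$z) * voxel_size
    dm <- as.matrix(stats::dist(pos))
    idx <- which(dm > 0 & dm <= neighbor_cutoff & upper.tri(dm),
                 arr.ind = TRUE)
    if (nrow(idx))
      edges[[length(edges) + 1]] <- data.frame(
        a = sub$particle_id[idx[, 1]], b = sub$particle_id[idx[, 2]],
        dist = dm[idx])
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(a = integer(0), b = integer(0), dist = numeric(0))
  structure(list(table = table, edges = edges,
                 neighbor_cutoff = neighbor_cutoff,
                 voxel_size = voxel_size),
            class = "lattice_map")
}

#' @export
print.lattice_map <- function(x, ...) {
  cat(sprintf("lattice_map: %d triads on %d vesicles, %d edges (cutoff %.0f A)\n",
              nrow(x$table), length(unique(x$table$vesicle_id)),
              nrow(x$edges), x$neighbor_cutoff))
  invisible(x)
}

## Pose (rigid transform, Angstrom) of a particle row.
particle_pose <- function(row, voxel_size) {
  rigid_transform(euler_to_matrix(c(row$phi, row$psi, row$theta)),
                  c(row$x, row$y, row$z) * voxel_size, unit = "angstrom")
}

## In-plane C3 symmetry operators (local frame).
c3_ops <- function(order = 3) lapply(0:(order - 1), function(k) Rz(k * 360 / order))

## All C3 x C3 branch images of a relative transform: replacing
## R_a -> R_a Z_i and R_b -> R_b Z_j maps (R, t) to (Z_i' R Z_j, Z_i' t).
branch_transforms <- function(rel, order = 3) {
  ops <- c3_ops(order)
  out <- list()
  for (zi in ops) for (zj in ops) {
    out[[length(out) + 1]] <- rigid_transform(
      t(zi) %*% rel$rotation %*% zj,
      as.numeric(t(zi) %*% rel$translation), unit = rel$unit)
  }
  out
}

## Residuals of a relative transform against a template, minimized over
## the C3 x C3 branches.
best_branch_residual <- function(rel, pattern, order = 3) {
  best <- list(rot = Inf, trans = Inf, score = Inf)
  for (br in branch_transforms(rel, order)) {
    rr <- rotation_angle(pattern$rotation, br$rotation)
    tr <- sqrt(sum((br$translation - pattern$translation)^2))
    score <- rr / max(pattern$rot_tol, 1e-9) +
             tr / max(pattern$trans_tol, 1e-9)
    if (score < best$score) best <- list(rot = rr, trans = tr, score = score)
  }
  best
}

## Quaternion from rotation matrix (w, x, y, z) and back.
mat_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Derive a linkage pattern template from exemplar pairs
#'
#' Exemplars are manually picked pairs of triad poses representing one
#' linkage. Each exemplar's relative transform is first canonicalized
#' into the C3 branch closest to the first exemplar, then the rotations
#' are averaged via a sign-aligned quaternion mean and the translations
#' component-wise. The exemplar scatter (maximum residual against the
#' mean) is reported and used as the suggested matching tolerance.
#'
#' @param exemplars list of pairs: each element a list with `a` and `b`,
#'   both `rigid_transform` poses in the same global frame (Angstrom).
#' @param name pattern name.
#' @param order symmetry order for canonicalization.
#' @param max_rot_scatter reject exemplar sets with rotation scatter
#'   beyond this (degrees).
#' @return `linkage_pattern` with attributes `rot_scatter`,
#'   `trans_scatter` (the observed exemplar scatter).
#' @export
derive_pattern <- function(exemplars, name, order = 3,
                           max_rot_scatter = 30) {
  if (length(exemplars) < 3) stopf("need at least 3 exemplar pairs")
  rels <- lapply(exemplars, function(e) relative_transform(e$a, e$b))
  ## canonicalize each into the branch nearest the first exemplar
  ref <- rels[[1]]
  canon <- lapply(rels, function(rel) {
    best <- NULL; bs <- Inf
    for (br in branch_transforms(rel, order)) {
      sc <- rotation_angle(ref$rotation, br$rotation) +
        sqrt(sum((br$translation - ref$translation)^2)) / 10
      if (sc < bs) { bs <- sc; best <- br }
    }
    best
  })
  qs <- t(vapply(canon, function(tr) mat_to_quat(tr$rotation), numeric(4)))
  for (i in seq_len(nrow(qs)))
    if (sum(qs[i, ] * qs[1, ]) < 0) qs[i, ] <- -qs[i, ]
  qbar <- colMeans(qs)
  Rbar <- quat_to_mat(qbar)
  tbar <- colMeans(do.call(rbind, lapply(canon, `[[`, "translation")))
  rot_scatter <- max(vapply(canon, function(tr)
    rotation_angle(Rbar, tr$rotation), numeric(1)))
  trans_scatter <- max(vapply(canon, function(tr)
    sqrt(sum((tr$translation - tbar)^2)), numeric(1)))
  tnorm <- sqrt(sum(tbar^2))
  if (rot_scatter > max_rot_scatter || trans_scatter > tnorm / 2)
    stopf("inconsistent exemplars: rotation scatter %.1f deg, translation scatter %.1f A (template norm %.1f A)",
          rot_scatter, trans_scatter, tnorm)
  out <- linkage_pattern(name, Rbar, tbar,
                         rot_tol = max(5, 2 * rot_scatter),
                         trans_tol = max(10, 2 * trans_scatter))
  attr(out, "rot_scatter") <- rot_scatter
  attr(out, "trans_scatter") <- trans_scatter
  out
}

#' Search a lattice map for occurrences of a linkage pattern
#'
#' For every neighbor-graph edge, the relative transform of the pair is
#' compared to the pattern template under all C3 x C3 symmetry branch
#' combinations of the two triads and in both pair orderings; a match
#' is reported for the branch with the smallest combined residual when
#' the rotation residual is within `rot_tol` and the translation
#' residual within `trans_tol`. Each unordered pair is reported at most
#' once per pattern.
#'
#' @param lattice `lattice_map`.
#' @param pattern `linkage_pattern`.
#' @param order symmetry order.
#' @return data.frame of matches: `vesicle_id, particle_a, particle_b,
#'   pattern, rot_residual, trans_residual`.
#' @export
search_linkages <- function(lattice, pattern, order = 3) {
  tab <- lattice$table
  out <- list()
  for (e in seq_len(nrow(lattice$edges))) {
    ia <- match(lattice$edges$a[e], tab$particle_id)
    ib <- match(lattice$edges$b[e], tab$particle_id)
    pa <- particle_pose(tab[ia, ], lattice$voxel_size)
    pb <- particle_pose(tab[ib, ], lattice$voxel_size)
    r1 <- best_branch_residual(relative_transform(pa, pb), pattern, order)
    r2 <- best_branch_residual(relative_transform(pb, pa), pattern, order)
    r <- if (r1$score <= r2$score) r1 else r2
    if (r$rot <= pattern$rot_tol && r$trans <= pattern$trans_tol)
      out[[length(out) + 1]] <- data.frame(
        vesicle_id = tab$vesicle_id[ia],
        particle_a = min(tab$particle_id[ia], tab$particle_id[ib]),
        particle_b = max(tab$particle_id[ia], tab$particle_id[ib]),
        pattern = pattern$name,
        rot_residual = r$rot, trans_residual = r$trans)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(vesicle_id = integer(0), particle_a = integer(0),
                  particle_b = integer(0), pattern = character(0),
                  rot_residual = numeric(0), trans_residual = numeric(0))
}

#' Average linkage subvolumes by in-plane iterative rotational alignment
#'
#' Subvolumes are extracted at the linkage midpoints with the
#' orientation of triad A. Following the half-set protocol for linkage
#' structures, the in-plane angle is randomized, the first half-set is
#' aligned by iterative in-plane-only rotational alignment
#' (regenerating the linkage structure), and the resulting reference is
#' low-pass filtered to `lowpass_start` (55 Angstrom by default) and
#' used as the starting reference for the second half-set.
#'
#' @param tomogram `volume3d`.
#' @param matches data.frame from [search_linkages()].
#' @param table refined `particle_table` (for poses and half-sets).
#' @param boxsize box edge, voxels.
#' @param mask optional alignment mask (`volume3d`); default soft
#'   sphere.
#' @param inplane_step,iterations in-plane search grid and iteration
#'   count.
#' @param lowpass_start low-pass applied to the half-1 reference before
#'   aligning half 2, Angstrom.
#' @param rng_seed seed for the in-plane randomization.
#' @return list with `halves` (two `average_result`s), `average`
#'   (combined mean), `n` per half.
#' @export
linkage_average <- function(tomogram, matches, table, boxsize = 32,
                            mask = NULL, inplane_step = 10,
                            iterations = 3, lowpass_start = 55,
                            rng_seed = 1) {
  validate_particle_table(table)
  if (nrow(matches) == 0) stopf("no matches to average")
  voxel <- attr(tomogram, "voxel_size")
  rows_a <- match(matches$particle_a, table$particle_id)
  rows_b <- match(matches$particle_b, table$particle_id)
  mid <- (cbind(table$x[rows_a], table$y[rows_a], table$z[rows_a]) +
          cbind(table$x[rows_b], table$y[rows_b], table$z[rows_b])) / 2
  phis <- with_seed(rng_seed, stats::runif(nrow(matches), 0, 360))
  ltab <- data.frame(particle_id = seq_len(nrow(matches)),
                     vesicle_id = matches$vesicle_id,
                     x = mid[, 1], y = mid[, 2], z = mid[, 3],
                     phi = phis,
                     psi = table$psi[rows_a], theta = table$theta[rows_a],
                     halfset = table$halfset[rows_a])
  if (all(is.na(ltab$halfset)))
    ltab$halfset <- rep(c(1L, 2L), length.out = nrow(ltab))
  per_half <- table(ltab$halfset)
  if (length(per_half) < 2 || any(per_half < 10))
    stopf("need at least 10 matches per half-set (have %s)",
          paste(per_half, collapse = "/"))
  if (is.null(mask))
    mask <- make_mask(mask_spec("sphere", radius = boxsize * 0.45,
                                edge_width = 3), rep(boxsize, 3), voxel)
  halves <- list()
  for (h in 1:2) {
    tab_h <- particle_table(ltab[ltab$halfset == h, ])
    stack <- extract_subtomograms(tomogram, tab_h, boxsize)
    tab_h <- stack$table
    ref <- if (h == 1) initial_reference(stack, tab_h)
           else lowpass_filter(halves[[1]]$average, lowpass_start)
    halves[[h]] <- align_iterate(stack, tab_h, ref, mask,
                                 inplane_range = 360,
                                 inplane_step = inplane_step,
                                 cone_range = 0, cone_step = 0,
                                 shift_limit = 2, iterations = iterations)
  }
  comb <- vol_like((as_vol_array(halves[[1]]$average) +
                    as_vol_array(halves[[2]]$average)) / 2,
                   halves[[1]]$average)
  list(halves = halves, average = comb,
       n = vapply(halves, function(x) nrow(x$table), integer(1)))
}

#' Plot a lattice map as triangle glyphs
#'
#' Projects each triad of one vesicle onto the plane perpendicular to
#' the view axis and draws a triangle at its position and in-plane
#' orientation, colored by `cc_score` (green high, red low).
#'
#' @param lattice `lattice_map`.
#' @param vesicle_id vesicle to draw.
#' @param view_axis projection axis (default z).
#' @param size triangle size in Angstrom.
#' @export
plot_lattice_map <- function(lattice, vesicle_id, view_axis = c(0, 0, 1),
                             size = 60) {
  tab <- lattice$table[lattice$table$vesicle_id == vesicle_id, ]
  if (nrow(tab) == 0) stopf("no triads for vesicle %s", vesicle_id)
  v <- view_axis / sqrt(sum(view_axis^2))
  b1 <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- b1 - sum(b1 * v) * v; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2], v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  pos <- cbind(tab$x, tab$y, tab$z) * lattice$voxel_size
  px <- pos %*% e1; py <- pos %*% e2
  cc <- tab$cc_score
  cc <- if (all(is.na(cc))) rep(0.5, length(px))
        else (cc - min(cc, na.rm = TRUE)) /
          max(1e-9, diff(range(cc, na.rm = TRUE)))
  cols <- grDevices::rgb(1 - cc, cc, 0.2)
  graphics::plot(px, py, type = "n", asp = 1, xlab = "x (A)", ylab = "y (A)",
                 main = sprintf("vesicle %s lattice map", vesicle_id))
  for (i in seq_along(px)) {
    R <- euler_to_matrix(c(tab$phi[i], tab$psi[i], tab$theta[i]))
    for (k in 0:2) {
      a <- deg2rad(120 * k)
      corner <- R %*% c(size * cos(a), size * sin(a), 0)
      cx <- sum(corner * e1); cy <- sum(corner * e2)
      if (k == 0) { xs <- px[i] + cx; ys <- py[i] + cy }
      else { xs <- c(xs, px[i] + cx); ys <- c(ys, py[i] + cy) }
    }
    graphics::polygon(xs, ys, col = cols[i], border = "grey30")
  }
  invisible(NULL)
}
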
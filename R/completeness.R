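# Sector-based coat-completeness statistic, its ranked distribution and
# the coated-lifetime-fraction estimate.

#' Average tomographic slices around a vesicle center
#'
#' The mean of `n_slices` XY planes centered on the vesicle's z
#' coordinate, the slab in which coat completeness is judged.
#'
#' @param tomogram `volume3d`.
#' @param center vesicle center, 0-based voxels.
#' @param n_slices number of planes (default 13).
#' @return 2D `volume3d` image.
#' @export
central_slab <- function(tomogram, center, n_slices = 13) {
  a <- as_vol_array(tomogram)
  d <- dim(a)
  z0 <- round(center[3]) - (n_slices - 1) %/% 2
  zs <- z0 + seq_len(n_slices) - 1
  if (any(zs < 0) || any(zs > d[3] - 1))
    stopf("slab [%d, %d] out of volume bounds", min(zs), max(zs))
  sl <- a[, , zs + 1, drop = FALSE]
  img <- apply(sl, c(1, 2), mean)
  volume3d(img, voxel_size = attr(tomogram, "voxel_size"))
}

#' Sector-based coat completeness of one vesicle
#'
#' Overlays the central slab with `n_sectors` equal angular sectors of
#' the coat band (an annulus outside the membrane radius); a sector
#' counts as occupied when its mean intensity exceeds the criterion
#' (by default, the background mean plus 2 background SD, with the
#' background taken from an annulus beyond the coat band). The angular
#' completeness is `occupied / n_sectors * 360` degrees. The sectors
#' are anchored to the +x axis of the slab.
#'
#' @param image 2D `volume3d` from [central_slab()].
#' @param center vesicle center in the slab, 0-based voxels (x, y).
#' @param membrane_radius membrane radius, voxels.
#' @param coat_band numeric `(r_in, r_out)` of the coat annulus,
#'   voxels; must lie outside `membrane_radius`.
#' @param n_sectors number of sectors (default 8).
#' @param criterion occupancy threshold; `NULL` (default) uses
#'   background mean + 2 SD.
#' @param background_band annulus for the background estimate, voxels
#'   (default just beyond the coat band).
#' @return list of class `completeness_record`: `occupied_sectors`,
#'   `angular_completeness` (degrees), `coated`, `sector_means`,
#'   `criterion`.
#' @export
sector_completeness <- function(image, center, membrane_radius, coat_band,
                                n_sectors = 8, criterion = NULL,
                                background_band = NULL) {
  if (n_sectors < 2) stopf("n_sectors must be >= 2")
  if (coat_band[1] < membrane_radius)
    stopf("coat_band must lie outside the membrane radius")
  a <- as_vol_array(image)
  d <- dim(a)
  if (coat_band[2] > min(d) / 2)
    stopf("coat band extends outside the image")
  gx <- (seq_len(d[1]) - 1) - center[1]
  gy <- (seq_len(d[2]) - 1) - center[2]
  r <- sqrt(outer(gx^2, gy^2, "+"))
  theta <- posmod(rad2deg(atan2(outer(rep(1, d[1]), gy),
                                outer(gx, rep(1, d[2])))), 360)
  if (is.null(background_band))
    background_band <- c(coat_band[2] + 1,
                         min(coat_band[2] + 6, min(d) / 2 - 1))
  bg <- a[r >= background_band[1] & r <= background_band[2]]
  if (length(bg) < 8) stopf("background annulus outside image")
  if (is.null(criterion)) criterion <- mean(bg) + 2 * stats::sd(bg)
  inband <- r >= coat_band[1] & r <= coat_band[2]
  wsec <- 360 / n_sectors
  sector_means <- vapply(seq_len(n_sectors), function(k) {
    sel <- inband & theta >= (k - 1) * wsec & theta < k * wsec
    if (!any(sel)) return(NA_real_)
    mean(a[sel])
  }, numeric(1))
  occupied <- sum(sector_means > criterion, na.rm = TRUE)
  structure(list(occupied_sectors = occupied,
                 angular_completeness = occupied / n_sectors * 360,
                 coated = occupied > 0,
                 sector_means = sector_means,
                 criterion = criterion),
            class = "completeness_record")
}

#' Rank completeness records for the uncoating profile
#'
#' Sorts records by descending angular completeness (stable on ties by
#' vesicle id), the ordering used to display the population-wide
#' uncoating profile.
#'
#' @param records data.frame with columns `vesicle_id`,
#'   `angular_completeness` (or a list of `completeness_record` plus
#'   ids).
#' @param plot draw the ranked bar profile.
#' @return the sorted data.frame.
#' @export
ranked_completeness <- function(records, plot = FALSE) {
  if (!is.data.frame(records))
    stopf("records must be a data.frame with vesicle_id and angular_completeness")
  ord <- order(-records$angular_completeness, records$vesicle_id)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (plot && nrow(out) > 0) {
    graphics::barplot(out$angular_completeness,
                      names.arg = out$vesicle_id,
                      ylab = "angular completeness (deg)",
                      xlab = "vesicle (ranked)", ylim = c(0, 360),
                      col = "steelblue", border = NA, las = 2)
    graphics::abline(h = 360, lty = 2, col = "grey50")
  }
  out
}

#' Coated fraction of the vesicle lifetime
#'
#' Under steady-state sampling of a vesicle population, the fraction of
#' vesicles that still carry a coat estimates the coated fraction of
#' the total vesicle lifetime; a coated:uncoated ratio of about 1:2
#' puts uncoating at roughly one third of the lifetime.
#'
#' @param n_coated,n_uncoated vesicle counts.
#' @return fraction in [0, 1].
#' @export
lifetime_fraction <- function(n_coated, n_uncoated) {
  if (n_coated < 0 || n_uncoated < 0) stopf("counts must be non-negative")
  if (n_coated + n_uncoated == 0) stopf("at least one vesicle required")
  n_coated / (n_coated + n_uncoated)
}
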
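# Particle and vesicle annotation tables: validation, TSV round-trip and
# a RELION-style STAR export for interoperability.

PARTICLE_COLUMNS <- c("particle_id", "vesicle_id", "x", "y", "z",
                      "phi", "psi", "theta", "cc_score", "halfset",
                      "region_group", "stage")

VESICLE_COLUMNS <- c("vesicle_id", "cx", "cy", "cz", "diameter_nm",
                     "luminal_density", "cisterna_index", "coated")

REGION_GROUPS <- c("cis", "medial_trans", "trans_tgn", "unassigned")
STAGES <- c("early_bud", "late_bud", "vesicle")
LUMINAL_CLASSES <- c("light", "dark", "translucent")

#' Construct a particle table
#'
#' One row per subtomogram: position (voxels), ZXZ Euler angles
#' (degrees), cross-correlation score, vesicle membership, half-set and
#' morphological labels.
#'
#' @param df data.frame; missing optional columns are filled with
#'   defaults (`cc_score` NA, `halfset` NA, `region_group` "unassigned",
#'   `stage` "vesicle").
#' @return validated data.frame of class `particle_table`.
#' @export
particle_table <- function(df) {
  if (!is.data.frame(df)) stopf("df must be a data.frame")
  if (nrow(df) > 0 && is.null(df$particle_id))
    df$particle_id <- seq_len(nrow(df))
  defaults <- list(cc_score = NA_real_, halfset = NA_integer_,
                   region_group = "unassigned", stage = "vesicle")
  for (col in names(defaults))
    if (is.null(df[[col]])) df[[col]] <- rep(defaults[[col]], nrow(df))
  if (nrow(df) == 0) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(PARTICLE_COLUMNS)),
                                 PARTICLE_COLUMNS))
    df$region_group <- character(0); df$stage <- character(0)
  }
  missing <- setdiff(PARTICLE_COLUMNS, names(df))
  if (length(missing))
    stopf("particle table is missing mandatory columns: %s",
          paste(missing, collapse = ", "))
  df <- df[, c(PARTICLE_COLUMNS, setdiff(names(df), PARTICLE_COLUMNS))]
  validate_particle_table(df)
  class(df) <- c("particle_table", "data.frame")
  df
}

validate_particle_table <- function(df) {
  if (anyDuplicated(df$particle_id))
    stopf("duplicate particle_id values in particle table")
  if (nrow(df) > 0) {
    for (col in c("x", "y", "z", "phi", "psi", "theta"))
      if (any(!is.finite(df[[col]]))) stopf("non-finite values in column %s", col)
    cc <- df$cc_score[!is.na(df$cc_score)]
    if (length(cc) && any(cc < -1 - 1e-9 | cc > 1 + 1e-9))
      stopf("cc_score outside [-1, 1]")
    hs <- df$halfset[!is.na(df$halfset)]
    if (length(hs) && !all(hs %in% c(1, 2)))
      stopf("halfset must be 1 or 2")
    ## half-set membership must be constant within a vesicle
    byv <- tapply(df$halfset, df$vesicle_id,
                  function(h) length(unique(h[!is.na(h)])))
    if (any(unlist(byv) > 1, na.rm = TRUE))
      stopf("halfset assignment differs within a vesicle")
    bad <- setdiff(unique(df$region_group), REGION_GROUPS)
    if (length(bad)) stopf("unknown region_group: %s", paste(bad, collapse = ", "))
    bad <- setdiff(unique(df$stage), STAGES)
    if (length(bad)) stopf("unknown stage: %s", paste(bad, collapse = ", "))
  }
  invisible(df)
}

#' Construct a vesicle annotation table
#'
#' @param df data.frame with columns `vesicle_id, cx, cy, cz` (voxels),
#'   `diameter_nm` (membrane-to-membrane), and optionally
#'   `luminal_density`, `cisterna_index`, `coated`.
#' @return validated data.frame of class `vesicle_table`.
#' @export
vesicle_table <- function(df) {
  if (!is.data.frame(df)) stopf("df must be a data.frame")
  if (is.null(df$luminal_density)) df$luminal_density <- rep("dark", nrow(df))
  if (is.null(df$cisterna_index)) df$cisterna_index <- rep(NA_integer_, nrow(df))
  if (is.null(df$coated)) df$coated <- rep(TRUE, nrow(df))
  missing <- setdiff(VESICLE_COLUMNS, names(df))
  if (length(missing))
    stopf("vesicle table is missing mandatory columns: %s",
          paste(missing, collapse = ", "))
  if (nrow(df) > 0) {
    if (anyDuplicated(df$vesicle_id)) stopf("duplicate vesicle_id values")
    if (any(df$diameter_nm <= 0)) stopf("diameter_nm must be > 0")
    ci <- df$cisterna_index[!is.na(df$cisterna_index)]
    if (length(ci) && any(ci == 0))
      stopf("cisterna_index 0 is not allowed (numbering skips 0)")
    bad <- setdiff(unique(df$luminal_density), LUMINAL_CLASSES)
    if (length(bad)) stopf("unknown luminal_density: %s", paste(bad, collapse = ", "))
  }
  df <- df[, c(VESICLE_COLUMNS, setdiff(names(df), VESICLE_COLUMNS))]
  class(df) <- c("vesicle_table", "data.frame")
  df
}

#' Read / write particle tables as TSV
#'
#' The native table format is tab-separated text with a fixed header
#' (`particle_id vesicle_id x y z phi psi theta cc_score halfset
#' region_group stage`); unknown extra columns are preserved.
#'
#' @param path file path.
#' @return `particle_table`.
#' @export
read_particles <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(PARTICLE_COLUMNS, names(df))
  if (length(missing))
    stopf("particle TSV is missing mandatory columns: %s",
          paste(missing, collapse = ", "))
  particle_table(df)
}

#' @rdname read_particles
#' @param table `particle_table`.
#' @export
write_particles <- function(table, path) {
  validate_particle_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write vesicle annotation tables as TSV
#' @param path file path.
#' @return `vesicle_table`.
#' @export
read_vesicles <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  vesicle_table(df)
}

#' @rdname read_vesicles
#' @param table `vesicle_table`.
#' @export
write_vesicles <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a particle table as a RELION-3.0-style STAR file
#'
#' Positions are written in voxels (`rlnCoordinateX/Y/Z`) and the ZXZ
#' Euler triplet is mapped onto `rlnAngleRot/Tilt/Psi`. Intended for
#' visual inspection in community tools, not as the native format.
#'
#' @param table `particle_table`.
#' @param path output path.
#' @export
write_star <- function(table, path) {
  validate_particle_table(table)
  cols <- c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
            "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi",
            "rlnMicrographName", "rlnAutopickFigureOfMerit",
            "rlnRandomSubset")
  lines <- c("", "data_particles", "", "loop_",
             sprintf("_%s #%d", cols, seq_along(cols)))
  if (nrow(table) > 0) {
    rows <- sprintf("%.4f %.4f %.4f %.4f %.4f %.4f vesicle_%s %.6f %d",
                    table$x, table$y, table$z,
                    table$phi, table$theta, table$psi,
                    as.character(table$vesicle_id),
                    ifelse(is.na(table$cc_score), 0, table$cc_score),
                    ifelse(is.na(table$halfset), 1L, as.integer(table$halfset)))
    lines <- c(lines, rows)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Expand a particle table over a point-group symmetry
#'
#' Each particle of a C`order` particle contains `order` asymmetric
#' units; expansion replicates every row `order` times with the in-plane
#' angle advanced by `360/order` degrees, so the table enumerates
#' asymmetric units (e.g. a 3579-particle C3 data set expands to 10737
#' rows).
#'
#' @param table `particle_table`.
#' @param order symmetry order (default 3).
#' @return expanded `particle_table` with suffixed particle ids.
#' @export
symmetry_expand <- function(table, order = 3L) {
  validate_particle_table(table)
  order <- as.integer(order)
  if (order < 1) stopf("order must be >= 1")
  if (order == 1L || nrow(table) == 0) return(table)
  out <- table[rep(seq_len(nrow(table)), each = order), , drop = FALSE]
  k <- rep(seq_len(order) - 1L, times = nrow(table))
  out$phi <- posmod(out$phi + k * 360 / order, 360)
  out$particle_id <- paste0(out$particle_id, "_su", k + 1L)
  rownames(out) <- NULL
  particle_table(as.data.frame(out))
}
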
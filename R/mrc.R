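# MRC2014 volume reading and writing (mode 2 float output; modes 0, 1, 2
# accepted on read). Layout: 1024-byte header, x-fastest data order,
# little-endian. Only the subset of the header the pipeline needs is
# interpreted; the origin word is respected on read and set from the
# volume's origin attribute on write.

#' Read an MRC2014 volume
#'
#' @param path path to an MRC file.
#' @return `volume3d` with the voxel size taken from `cella / mx`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  if (length(hdr_raw) < 1024) stopf("malformed MRC header: file shorter than 1024 bytes")
  int_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)], "integer",
                                size = 4, endian = "little")
  flt_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)], "numeric",
                                size = 4, endian = "little")
  magic <- rawToChar(hdr_raw[209:212])
  if (!identical(substr(magic, 1, 3), "MAP"))
    stopf("malformed MRC header: MAP magic missing (field 'map')")
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  mode <- int_at(4)
  if (any(c(nx, ny, nz) < 1) || any(c(nx, ny, nz) > 1e5))
    stopf("malformed MRC header: implausible dimensions (field 'nx/ny/nz')")
  mx <- int_at(8); my <- int_at(9); mz <- int_at(10)
  cella <- c(flt_at(11), flt_at(12), flt_at(13))
  mapcrs <- c(int_at(17), int_at(18), int_at(19))
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stopf("unsupported axis order (field 'mapc/mapr/maps' = %s)",
          paste(mapcrs, collapse = ","))
  nsymbt <- int_at(24)
  origin <- c(flt_at(50), flt_at(51), flt_at(52))
  n <- as.numeric(nx) * ny * nz
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE,
                             endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    stopf("unsupported MRC mode %d (field 'mode')", mode))
  if (length(data) < n) stopf("malformed MRC file: truncated data section")
  voxel <- if (mx > 0 && cella[1] > 0) cella[1] / mx else 1
  volume3d(array(data, c(nx, ny, nz)), voxel_size = voxel, origin = origin)
}

#' Write a volume as MRC2014 (mode 2)
#'
#' @param vol `volume3d`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "volume3d")) stopf("vol must be a volume3d")
  a <- as_vol_array(vol)
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  d <- dim(a)
  voxel <- attr(vol, "voxel_size")
  origin <- attr(vol, "origin") %||% c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2)                      # mode 2: float32
  wi(c(0, 0, 0))             # nstart
  wi(d)                      # mx my mz
  wf(d * voxel)              # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1, 2, 3))             # mapc mapr maps
  wf(c(min(a), max(a), mean(a)))
  wi(1)                      # ispg: volume
  wi(0)                      # nsymbt
  wi(rep(0, 25))             # extra (words 26-50 per MRC2014 numbering)
  ## note: MRC2014 puts origin at words 50-52 -> bytes 197-208
  seek(con, 196)
  wf(origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(a))
  wi(0)                      # nlabl
  writeBin(raw(1024 - 224), con)
  writeBin(as.numeric(a), con, size = 4, endian = "little")
  invisible(path)
}
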
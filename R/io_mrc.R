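#' Read and write MRC volumes
#'
#' Minimal MRC2014 reader/writer for the volume container used throughout the
#' package. Modes 0 (int8), 1 (int16) and 2 (float32) are supported; files are
#' little-endian. Cell dimensions are stored in nanometres, so the voxel size
#' round-trips to well below 1e-3 nm.
#'
#' @param path file path.
#' @return `read_mrc()` returns a [vox_volume].
#' @export
read_mrc <- function(path) {
  info <- file.info(path)
  if (is.na(info$size) || info$size < 1024)
    stop("MRC format error: file shorter than the 1024-byte header (", path, ")")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  xlen <- hdr_num[11]; ylen <- hdr_num[12]; zlen <- hdr_num[13]
  map_tag <- rawToChar(readBin({seek(con, 208); con}, "raw", 4))
  if (!(mode %in% c(0, 1, 2)))
    stop("MRC format error at byte offset 12: unsupported mode ", mode)
  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 1e5))
    stop("MRC format error at byte offset 0: implausible dimensions ",
         paste(c(nx, ny, nz), collapse = "x"))
  if (!identical(substr(map_tag, 1, 3), "MAP"))
    warning("MRC header lacks the 'MAP ' tag; attempting to read anyway")
  vs <- c(if (mx > 0) xlen / mx else NA,
          if (my > 0) ylen / my else NA,
          if (mz > 0) zlen / mz else NA)
  vs[!is.finite(vs) | vs <= 0] <- NA
  if (all(is.na(vs))) {
    voxel_size <- 1
  } else if (max(vs, na.rm = TRUE) - min(vs, na.rm = TRUE) > 1e-6) {
    warning("anisotropic voxel size in MRC header; using the x spacing")
    voxel_size <- vs[1]
  } else voxel_size <- mean(vs, na.rm = TRUE)
  origin <- hdr_num[50:52]
  n <- as.numeric(nx) * ny * nz
  bytes_per <- c(`0` = 1, `1` = 2, `2` = 4)[as.character(mode)]
  if (info$size < 1024 + hdr_int[24] + n * bytes_per)
    stop("MRC format error: truncated data section (expected ",
         1024 + hdr_int[24] + n * bytes_per, " bytes, file has ", info$size, ")")
  seek(con, 1024 + hdr_int[24]) # skip extended header
  data <- if (mode == 2) {
    readBin(con, "numeric", n = n, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n = n, size = bytes_per, signed = TRUE, endian = "little")
  }
  vox_volume(array(data, dim = c(nx, ny, nz)), voxel_size = voxel_size,
             origin = origin, validate = FALSE)
}

#' @rdname read_mrc
#' @param volume a [vox_volume].
#' @param mode MRC data mode: 0 (int8), 1 (int16) or 2 (float32).
#' @export
write_mrc <- function(volume, path, mode = 2) {
  stopifnot(inherits(volume, "vox_volume"), mode %in% c(0, 1, 2))
  d <- dim(volume$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(mode)
  wi(c(0, 0, 0))                      # nxstart
  wi(d)                               # mx my mz
  wf(d * volume$voxel_size)           # cell lengths (nm)
  wf(c(90, 90, 90))                   # cell angles
  wi(c(1, 2, 3))                      # axis order
  rng <- range(volume$data)
  wf(c(rng[1], rng[2], mean(volume$data)))
  wi(c(0, 0))                         # ispg, nsymbt
  wi(rep(0, 25))                      # extra
  wf(volume$origin)                   # origin x y z
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian machine stamp
  wf(sd(volume$data))
  wi(0)                               # nlabl
  writeBin(raw(800), con)
  if (mode == 2) {
    writeBin(as.numeric(volume$data), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(volume$data)), con, size = c(`0` = 1, `1` = 2)[as.character(mode)],
             endian = "little")
  }
  invisible(path)
}
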
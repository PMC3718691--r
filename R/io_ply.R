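#' Read and write PLY surface models
#'
#' Triangulated surfaces are exchanged in the PLY format, either ascii or
#' binary little-endian (float32 vertex coordinates, int32 face indices).
#'
#' @param path file path.
#' @return `read_ply()` returns a [surface_model].
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "ply")) stop("PLY format error: missing 'ply' magic line")
  fmt <- NULL; nv <- NULL; nf <- NULL
  vprops <- character()
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("PLY format error: header not terminated")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (tok[2] == "vertex") nv <- as.integer(tok[3])
      if (tok[2] == "face") nf <- as.integer(tok[3])
    }
    if (tok[1] == "property" && in_vertex && tok[2] != "list")
      vprops <- c(vprops, tok[3])
    if (tok[1] == "end_header") break
  }
  if (is.null(fmt) || is.null(nv) || is.null(nf))
    stop("PLY format error: incomplete header")
  if (fmt == "ascii") {
    txt <- readLines(con)
    vl <- txt[seq_len(nv)]
    V <- matrix(scan(text = vl, quiet = TRUE), nrow = nv, byrow = TRUE)
    fl <- txt[nv + seq_len(nf)]
    Fm <- matrix(scan(text = fl, quiet = TRUE), nrow = nf, byrow = TRUE)
    if (any(Fm[, 1] != 3)) stop("PLY format error: only triangular faces supported")
    faces <- Fm[, 2:4, drop = FALSE] + 1L
  } else if (fmt == "binary_little_endian") {
    np <- length(vprops)
    vdat <- readBin(con, "numeric", n = nv * np, size = 4, endian = "little")
    V <- matrix(vdat, ncol = np, byrow = TRUE)
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", n = 1, size = 1, signed = FALSE)
      if (length(cnt) == 0 || cnt != 3)
        stop("PLY format error: only triangular faces supported")
      faces[i, ] <- readBin(con, "integer", n = 3, size = 4, endian = "little") + 1L
    }
  } else stop("PLY format error: unsupported format ", fmt)
  ix <- match(c("x", "y", "z"), if (length(vprops)) vprops else c("x", "y", "z"))
  surface_model(V[, ix, drop = FALSE], faces)
}

#' @rdname read_ply
#' @param surface a [surface_model].
#' @param format `"ascii"` or `"binary_little_endian"`.
#' @export
write_ply <- function(surface, path, format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  V <- surface$vertices
  Fc <- surface$faces
  hdr <- c("ply", paste("format", format, "1.0"),
           "comment isodensity surface model",
           paste("element vertex", nrow(V)),
           "property float x", "property float y", "property float z",
           paste("element face", nrow(Fc)),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (format == "ascii") {
    writeLines(apply(V, 1, function(r) paste(format(r, digits = 9), collapse = " ")), con)
    writeLines(apply(Fc, 1, function(r) paste(c(3, r - 1L), collapse = " ")), con)
  } else {
    writeBin(as.numeric(t(V)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(Fc))) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(Fc[i, ] - 1L), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}
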
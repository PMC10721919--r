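#' Read a triangle mesh from PLY or OBJ
#'
#' Supports ASCII and binary little-endian PLY (vertex properties of a single
#' float type; extra per-vertex properties are ignored) and Wavefront OBJ with
#' triangular faces. Vertex order is preserved. PLY face indices are 0-based on
#' file, OBJ 1-based; both become 1-based in the returned mesh.
#'
#' @param path file path.
#' @param format `"ply"`, `"obj"` or `NULL` to infer from the extension.
#' @return A [tri_mesh()]. Mesh statistics are printed on load via
#'   [print.tri_mesh()] when `quiet = FALSE`.
#' @param quiet suppress the mesh-statistics log line.
#' @export
read_mesh <- function(path, format = NULL, quiet = TRUE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  format <- tolower(format %||% tools::file_ext(path))
  mesh <- switch(format,
    ply = read_ply(path),
    obj = read_obj(path),
    stop("unsupported mesh format: ", format)
  )
  if (!quiet) print(mesh)
  validate_mesh(mesh)
  mesh
}

#' Write a triangle mesh to PLY or OBJ
#'
#' Coordinates are written with 17 significant digits so an ASCII round-trip
#' reproduces double-precision vertices bit-for-bit.
#'
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @param format `"ply"`, `"obj"` or `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  validate_mesh(mesh)
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
    ply = write_ply(mesh, path),
    obj = write_obj(mesh, path),
    stop("unsupported mesh format: ", format)
  )
  invisible(path)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(raw, offset, type, n = 1L) {
  size <- ply_type_size[[type]]
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32"))
  readBin(raw[(offset + 1):(offset + size * n)], what = what, n = n,
          size = size, signed = if (size >= 4) TRUE else signed,
          endian = "little")
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = file.info(path)$size)
  # locate the header on the raw bytes (the body may contain nul bytes)
  hdr_end <- grepRaw("end_header\r?\n", raw)
  if (length(hdr_end) == 0L) stop("PLY format error: missing end_header")
  hdr_match <- grepRaw("end_header\r?\n", raw, value = TRUE)
  hdr_len <- hdr_end[1L] + length(hdr_match) - 1L
  header <- strsplit(rawToChar(raw[seq_len(hdr_len)]), "\r?\n")[[1]]
  header <- trimws(header)
  if (!identical(header[1], "ply")) stop("PLY format error: missing magic")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1) stop("PLY format error: missing format line")
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("PLY format error: unsupported format ", fmt)
  }

  # parse element/property declarations
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(list = TRUE, count_type = tok[3], type = tok[4], name = tok[5])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(list = FALSE, type = tok[2], name = tok[3])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  ve <- elements[["vertex"]]
  if (is.null(ve) || ve$count == 0L) stop("empty-input error: PLY has no vertices")
  fe <- elements[["face"]]

  vprop_names <- vapply(ve$props, `[[`, "", "name")
  xyz <- match(c("x", "y", "z"), vprop_names)
  if (anyNA(xyz)) stop("PLY format error: vertex element lacks x/y/z")

  if (fmt == "ascii") {
    body <- strsplit(substr(rawToChar(raw), hdr_len + 1L, nchar(rawToChar(raw))), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    if (length(body) < ve$count + (if (is.null(fe)) 0L else fe$count)) {
      stop("PLY format error: truncated body")
    }
    vlines <- body[seq_len(ve$count)]
    vals <- scan(text = vlines, quiet = TRUE)
    vmat <- matrix(vals, nrow = ve$count, byrow = TRUE)
    vertices <- vmat[, xyz, drop = FALSE]
    triangles <- NULL
    if (!is.null(fe) && fe$count > 0L) {
      flines <- body[ve$count + seq_len(fe$count)]
      faces <- lapply(strsplit(trimws(flines), "\\s+"), as.numeric)
      ks <- vapply(faces, `[[`, 0, 1L)
      if (any(ks != 3)) stop("PLY format error: non-triangular face")
      triangles <- t(vapply(faces, function(f) f[2:4], numeric(3))) + 1
    }
  } else {
    # binary little-endian; require homogeneous scalar vertex properties
    vtypes <- vapply(ve$props, `[[`, "", "type")
    if (any(vapply(ve$props, `[[`, TRUE, "list"))) {
      stop("PLY format error: list property in vertex element")
    }
    if (length(unique(vtypes)) != 1L) {
      stop("PLY format error: mixed vertex property types unsupported in binary")
    }
    size <- ply_type_size[[vtypes[1]]]
    np <- length(vtypes)
    off <- hdr_len
    vals <- ply_read_scalar(raw, off, vtypes[1], n = ve$count * np)
    vmat <- matrix(vals, nrow = ve$count, byrow = TRUE)
    vertices <- vmat[, xyz, drop = FALSE]
    off <- off + size * np * ve$count
    triangles <- NULL
    if (!is.null(fe) && fe$count > 0L) {
      lp <- fe$props[[1]]
      if (!lp$list) stop("PLY format error: face element lacks list property")
      csz <- ply_type_size[[lp$count_type]]
      isz <- ply_type_size[[lp$type]]
      triangles <- matrix(0L, fe$count, 3L)
      for (i in seq_len(fe$count)) {
        k <- ply_read_scalar(raw, off, lp$count_type)
        off <- off + csz
        if (k != 3L) stop("PLY format error: non-triangular face")
        triangles[i, ] <- ply_read_scalar(raw, off, lp$type, n = 3L) + 1L
        off <- off + 3L * isz
      }
    }
  }
  tryCatch(tri_mesh(vertices, triangles),
           error = function(e) stop("PLY format error: ", conditionMessage(e)))
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$triangles
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nrow(v)),
           "property double x", "property double y", "property double z",
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  if (nrow(f) > 0L) {
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L) stop("empty-input error: OBJ has no vertices")
  vertices <- matrix(scan(text = sub("^v\\s+", "", vlines), quiet = TRUE),
                     ncol = 3L, byrow = TRUE)
  triangles <- NULL
  if (length(flines) > 0L) {
    toks <- strsplit(sub("^f\\s+", "", flines), "\\s+")
    if (any(lengths(toks) != 3L)) stop("OBJ format error: non-triangular face")
    idx <- vapply(toks, function(t) as.integer(sub("/.*$", "", t)), integer(3))
    triangles <- t(idx)
  }
  tryCatch(tri_mesh(vertices, triangles),
           error = function(e) stop("OBJ format error: ", conditionMessage(e)))
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$triangles
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  if (nrow(f) > 0L) {
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}
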
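## Mesh file I/O: OFF, PLY (ascii + binary little-endian), STL (ascii +
## binary), OBJ (v/f records).  Units are assumed mm; no unit metadata is
## read or written.  ASCII writers use 17 significant digits so doubles
## round-trip exactly; binary PLY stores doubles (bit-exact), binary STL is
## constrained to float32 by the format.

detect_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(tolower(format),
                                         c("off", "ply", "stl", "obj")))
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("off", "ply", "stl", "obj"))
    stop(sprintf("cannot auto-detect mesh format from '%s'; pass `format`", path))
  ext
}

#' Read a triangle mesh from OFF/PLY/STL/OBJ
#'
#' @param path file path.
#' @param format one of `"off"`, `"ply"`, `"stl"`, `"obj"`; auto-detected
#'   from the extension when `NULL`.
#' @param validate run [validate_mesh()] on the result (default `TRUE`).
#' @param name mesh label; defaults to the file name.
#' @return a [triangle_mesh()].  Vertex order is preserved from the file;
#'   STL triangle-soup vertices are merged within 1e-9 mm.
#' @export
read_mesh <- function(path, format = NULL, validate = TRUE, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  format <- detect_format(path, format)
  if (is.null(name)) name <- basename(path)
  vf <- switch(format,
               off = read_off(path),
               obj = read_obj(path),
               ply = read_ply(path),
               stl = read_stl(path))
  triangle_mesh(vf$vertices, vf$faces, name = name, validate = validate)
}

#' Write a triangle mesh to OFF/PLY/STL/OBJ
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param format as in [read_mesh()]; auto-detected from the extension.
#' @param binary for PLY/STL, write the binary little-endian dialect
#'   (default `TRUE`); ignored for OFF/OBJ.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = TRUE) {
  if (!inherits(mesh, "triangle_mesh")) stop("`mesh` must be a triangle_mesh")
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L)
    stop("refusing to write an empty mesh")
  format <- detect_format(path, format)
  ok <- tryCatch({
    switch(format,
           off = write_off(mesh, path),
           obj = write_obj(mesh, path),
           ply = write_ply(mesh, path, binary = binary),
           stl = write_stl(mesh, path, binary = binary))
    TRUE
  }, error = function(e) stop(sprintf("cannot write '%s': %s", path,
                                      conditionMessage(e))))
  invisible(path)
}

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

## ---- OFF ----

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L || toupper(lines[1L]) != "OFF")
    stop("not an OFF file (missing OFF header)")
  counts <- scan(text = lines[2L], quiet = TRUE)
  nv <- counts[1L]; nf <- counts[2L]
  body <- lines[-(1:2)]
  if (length(body) < nv + nf) stop("truncated OFF file")
  vtx <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE),
                ncol = 3L, byrow = TRUE)
  frows <- lapply(body[nv + seq_len(nf)], function(l) scan(text = l, quiet = TRUE))
  if (any(vapply(frows, function(r) r[1L] != 3, logical(1L))))
    stop("OFF file contains non-triangular faces")
  faces <- do.call(rbind, lapply(frows, function(r) r[2:4] + 1L))
  list(vertices = vtx, faces = faces)
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1L, function(r) paste(fmt17(r), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1L,
                   function(r) paste(c(3L, r), collapse = " ")), con)
}

## ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L || length(fl) == 0L) stop("OBJ file has no v/f records")
  vtx <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE),
                ncol = 3L, byrow = TRUE)
  parse_f <- function(l) {
    toks <- strsplit(trimws(sub("^f ", "", l)), "[[:space:]]+")[[1L]]
    idx <- as.integer(sub("/.*$", "", toks))
    if (length(idx) != 3L) stop("OBJ file contains non-triangular faces")
    idx
  }
  faces <- do.call(rbind, lapply(fl, parse_f))
  list(vertices = vtx, faces = faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1L,
                   function(r) paste(c("v", fmt17(r)), collapse = " ")), con)
  writeLines(apply(mesh$faces, 1L,
                   function(r) paste(c("f", r), collapse = " ")), con)
}

## ---- PLY ----

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_hline <- function() {
    chars <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("unexpected end of PLY header")
      if (ch == "\n") break
      chars <- c(chars, ch)
    }
    sub("\r$", "", paste(chars, collapse = ""))
  }
  if (read_hline() != "ply") stop("not a PLY file")
  fmt <- NULL; nv <- NULL; nf <- NULL
  vprops <- character(0)
  cur <- NULL
  repeat {
    l <- read_hline()
    if (l == "end_header") break
    toks <- strsplit(trimws(l), "[[:space:]]+")[[1L]]
    if (toks[1L] == "format") fmt <- toks[2L]
    else if (toks[1L] == "element") {
      cur <- toks[2L]
      if (cur == "vertex") nv <- as.integer(toks[3L])
      if (cur == "face") nf <- as.integer(toks[3L])
    } else if (toks[1L] == "property" && identical(cur, "vertex")) {
      if (toks[2L] == "list") stop("list property on vertices is unsupported")
      vprops <- c(vprops, structure(toks[2L], names = toks[3L]))
    }
  }
  if (is.null(fmt) || is.null(nv) || is.null(nf)) stop("malformed PLY header")
  if (!all(c("x", "y", "z") %in% names(vprops)))
    stop("PLY vertex element lacks x/y/z")
  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    vdat <- matrix(scan(text = rest[seq_len(nv)], quiet = TRUE),
                   nrow = nv, byrow = TRUE)
    colnames(vdat) <- names(vprops)
    vtx <- vdat[, c("x", "y", "z"), drop = FALSE]
    frows <- lapply(rest[nv + seq_len(nf)],
                    function(l) scan(text = l, quiet = TRUE))
    if (any(vapply(frows, function(r) r[1L] != 3, logical(1L))))
      stop("PLY file contains non-triangular faces")
    faces <- do.call(rbind, lapply(frows, function(r) r[2:4] + 1L))
  } else if (fmt == "binary_little_endian") {
    readv <- function(type, n) {
      switch(type,
             float = , float32 = readBin(con, "double", n, size = 4L,
                                         endian = "little"),
             double = , float64 = readBin(con, "double", n, size = 8L,
                                          endian = "little"),
             char = , int8 = readBin(con, "integer", n, size = 1L,
                                     signed = TRUE, endian = "little"),
             uchar = , uint8 = readBin(con, "integer", n, size = 1L,
                                       signed = FALSE, endian = "little"),
             short = , int16 = readBin(con, "integer", n, size = 2L,
                                       signed = TRUE, endian = "little"),
             ushort = , uint16 = readBin(con, "integer", n, size = 2L,
                                         signed = FALSE, endian = "little"),
             int = , int32 = , uint = , uint32 =
               readBin(con, "integer", n, size = 4L, endian = "little"),
             stop(sprintf("unsupported PLY property type '%s'", type)))
    }
    vdat <- matrix(0, nrow = nv, ncol = length(vprops),
                   dimnames = list(NULL, names(vprops)))
    ## vertex records are interleaved: read row by row
    for (i in seq_len(nv))
      for (j in seq_along(vprops))
        vdat[i, j] <- readv(vprops[j], 1L)
    vtx <- vdat[, c("x", "y", "z"), drop = FALSE]
    faces <- matrix(0L, nrow = nf, ncol = 3L)
    for (i in seq_len(nf)) {
      cnt <- readv("uchar", 1L)
      if (cnt != 3L) stop("PLY file contains non-triangular faces")
      faces[i, ] <- readv("int", 3L) + 1L
    }
  } else stop(sprintf("unsupported PLY format '%s'", fmt))
  list(vertices = unname(vtx), faces = faces)
}

write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
              "comment written by canalssd",
              sprintf("element vertex %d", nv),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(header, collapse = "\n"), "\n"), con,
              eos = NULL, useBytes = TRUE)
    writeBin(as.vector(t(mesh$vertices)), con, size = 8L, endian = "little")
    f0 <- mesh$faces - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(apply(mesh$vertices, 1L,
                     function(r) paste(fmt17(r), collapse = " ")), con)
    writeLines(apply(mesh$faces - 1L, 1L,
                     function(r) paste(c(3L, r), collapse = " ")), con)
  }
}

## ---- STL ----

## STL stores a triangle soup: merge vertices within `tol` mm on read.
soup_to_mesh <- function(tri_vertices, tol = 1e-9) {
  key <- paste(round(tri_vertices[, 1L] / tol),
               round(tri_vertices[, 2L] / tol),
               round(tri_vertices[, 3L] / tol))
  idx <- match(key, key)                 # first occurrence index
  keep <- !duplicated(key)
  remap <- cumsum(keep)
  vmap <- remap[idx]
  vertices <- tri_vertices[keep, , drop = FALSE]
  faces <- matrix(vmap, ncol = 3L, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

read_stl <- function(path) {
  ## sniff: ascii STL starts with "solid" AND parses as text; binary headers
  ## may also start with "solid", so fall back to binary on parse failure
  head_raw <- readBin(path, "raw", n = 5L)
  looks_ascii <- identical(rawToChar(head_raw), "solid")
  if (looks_ascii) {
    out <- tryCatch(read_stl_ascii(path), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- lines[startsWith(lines, "vertex")]
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("malformed ascii STL")
  coords <- matrix(scan(text = sub("^vertex", "", vl), quiet = TRUE),
                   ncol = 3L, byrow = TRUE)
  soup_to_mesh(coords)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (nf <= 0L) stop("binary STL with no facets")
  coords <- matrix(0, nrow = 3L * nf, ncol = 3L)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "double", 12L, size = 4L, endian = "little")
    coords[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], ncol = 3L,
                                               byrow = TRUE)
    invisible(readBin(con, "raw", n = 2L))  # attribute byte count
  }
  soup_to_mesh(coords)
}

write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  n <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "canalssd binary STL"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      rec <- c(n[i, ], t(v[f[i, ], , drop = FALSE]))
      writeBin(as.vector(rec), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$name), con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %s", paste(fmt17(n[i, ]), collapse = " ")), con)
      writeLines("    outer loop", con)
      for (k in 1:3)
        writeLines(sprintf("      vertex %s",
                           paste(fmt17(v[f[i, k], ]), collapse = " ")), con)
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines(sprintf("endsolid %s", mesh$name), con)
  }
}
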
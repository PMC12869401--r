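# FreeSurfer binary formats. Everything is big-endian. Surface files carry the
# 3-byte magic 0xFFFFFE, curv ("morph data") files the new-format magic
# 0xFFFFFF, annot files are plain int32 streams. Readers validate magics and
# lengths and report the byte offset of the failure.

.read_int3 <- function(con) {
  b <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  if (length(b) < 3L) stop("truncated file: could not read 3-byte magic at offset 0")
  b[1] * 65536L + b[2] * 256L + b[3]
}

.write_int3 <- function(con, value) {
  writeBin(as.raw(c(value %/% 65536L, (value %/% 256L) %% 256L, value %% 256L)), con)
}

#' Read a FreeSurfer binary surface file
#'
#' Parses the triangle-surface layout: 3-byte magic 0xFFFFFE, a creator
#' comment terminated by two newlines, vertex and face counts (int32,
#' big-endian), then float32 vertex coordinates and int32 0-based face
#' indices (converted to 1-based on read).
#'
#' @param path file path.
#' @param hemisphere label to attach to the returned mesh.
#' @param expectedVertices optional vertex count to validate against.
#' @return a [SurfaceMesh].
#' @export
readFreeSurferGeometry <- function(path, hemisphere = "left", expectedVertices = NULL) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- .read_int3(con)
  if (magic != 0xFFFFFE)
    stop(sprintf("not a FreeSurfer triangle surface: bad magic 0x%06X at offset 0", magic))
  # creator string: terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    ch <- readBin(con, "raw", n = 1L)
    if (!length(ch)) stop("truncated file: unterminated creator string at offset 3")
    if (ch == as.raw(10) && prev == as.raw(10)) break
    prev <- ch
  }
  counts <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
  if (length(counts) < 2L) stop("truncated file: missing vertex/face counts")
  nv <- counts[1]; nf <- counts[2]
  if (nv < 0 || nf < 0) stop("corrupt counts in surface header")
  if (!is.null(expectedVertices) && nv != expectedVertices)
    stop(sprintf("vertex count mismatch: file has %d, expected %d", nv, expectedVertices))
  v <- readBin(con, "numeric", n = 3L * nv, size = 4L, endian = "big")
  if (length(v) < 3L * nv) stop("truncated file: vertex block short")
  f <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(f) < 3L * nf) stop("truncated file: face block short")
  .newMesh(matrix(v, ncol = 3L, byrow = TRUE),
           matrix(f, ncol = 3L, byrow = TRUE) + 1L, hemisphere)
}

#' Write a FreeSurfer binary surface file
#' @param mesh a [SurfaceMesh].
#' @param path output path.
#' @param comment creator comment written into the header.
#' @export
writeFreeSurferGeometry <- function(mesh, path, comment = "created by geromorph") {
  con <- file(path, "wb"); on.exit(close(con))
  .write_int3(con, 0xFFFFFE)
  writeBin(charToRaw(comment), con)
  writeBin(as.raw(c(10, 10)), con)
  writeBin(as.integer(c(nrow(mesh@vertices), nrow(mesh@faces))), con,
           size = 4L, endian = "big")
  writeBin(as.numeric(t(mesh@vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh@faces) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read a FreeSurfer curv (morph data) file
#'
#' New-format curv files: 3-byte magic 0xFFFFFF, int32 vertex count, int32
#' face count, int32 values-per-vertex (must be 1), then float32 values.
#'
#' @param path file path.
#' @param expectedVertices optional vertex count to validate against.
#' @return numeric vector of per-vertex values.
#' @export
readFreeSurferMorph <- function(path, expectedVertices = NULL) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- .read_int3(con)
  if (magic != 0xFFFFFF)
    stop(sprintf("not a new-format curv file: bad magic 0x%06X at offset 0", magic))
  hdr <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
  if (length(hdr) < 3L) stop("truncated file: curv header short at offset 3")
  nv <- hdr[1]; vpv <- hdr[3]
  if (vpv != 1L) stop(sprintf("unsupported values-per-vertex %d at offset 11", vpv))
  if (!is.null(expectedVertices) && nv != expectedVertices)
    stop(sprintf("vertex count mismatch: file has %d values, expected %d", nv, expectedVertices))
  x <- readBin(con, "numeric", n = nv, size = 4L, endian = "big")
  if (length(x) < nv) stop("truncated file: value block short at offset 15")
  x
}

#' Write a FreeSurfer curv (morph data) file
#' @param values numeric per-vertex vector.
#' @param path output path.
#' @param nFaces face count recorded in the header (informational).
#' @export
writeFreeSurferMorph <- function(values, path, nFaces = 0L) {
  con <- file(path, "wb"); on.exit(close(con))
  .write_int3(con, 0xFFFFFF)
  writeBin(as.integer(c(length(values), nFaces, 1L)), con, size = 4L, endian = "big")
  writeBin(as.numeric(values), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read a FreeSurfer annot (parcellation) file
#'
#' Parses the vertex/label pair block and, when present, the version-2
#' colortable, returning integer region codes per vertex plus a lookup table
#' mapping codes to region names.
#'
#' @param path file path.
#' @return list with `labels` (integer codes per vertex) and `table`
#'   (data.frame of name + code), the latter NULL when no colortable exists.
#' @export
readFreeSurferAnnot <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (!length(n) || n < 0) stop("corrupt annot file: bad vertex count at offset 0")
  pairs <- readBin(con, "integer", n = 2L * n, size = 4L, endian = "big")
  if (length(pairs) < 2L * n) stop("truncated annot file: pair block short at offset 4")
  m <- matrix(pairs, ncol = 2L, byrow = TRUE)
  labels <- m[order(m[, 1]), 2]
  tab <- NULL
  tag <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(tag) && tag == 1L) {
    version <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    if (version != -2L) stop(sprintf("unsupported annot colortable version %d", version))
    maxstruc <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    flen <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    readBin(con, "raw", n = flen)  # original colortable filename, unused
    nentries <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    nm <- character(nentries); code <- integer(nentries)
    for (i in seq_len(nentries)) {
      readBin(con, "integer", n = 1L, size = 4L, endian = "big")  # structure id
      slen <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
      raw <- readBin(con, "raw", n = slen)
      nm[i] <- rawToChar(raw[raw != as.raw(0)])
      rgba <- readBin(con, "integer", n = 4L, size = 4L, endian = "big")
      code[i] <- rgba[1] + rgba[2] * 256L + rgba[3] * 65536L
    }
    tab <- data.frame(name = nm, code = code, stringsAsFactors = FALSE)
  }
  list(labels = labels, table = tab)
}

#' Write a FreeSurfer annot (parcellation) file
#' @param labels integer region codes, one per vertex.
#' @param path output path.
#' @param regionNames optional character vector naming each unique code (in
#'   the order of `sort(unique(labels))`); written as a version-2 colortable.
#' @export
writeFreeSurferAnnot <- function(labels, path, regionNames = NULL) {
  con <- file(path, "wb"); on.exit(close(con))
  n <- length(labels)
  writeBin(as.integer(n), con, size = 4L, endian = "big")
  pairs <- rbind(seq_len(n) - 1L, as.integer(labels))
  writeBin(as.integer(pairs), con, size = 4L, endian = "big")
  if (!is.null(regionNames)) {
    codes <- sort(unique(as.integer(labels)))
    stopifnot(length(regionNames) == length(codes))
    writeBin(1L, con, size = 4L, endian = "big")          # tag: colortable
    writeBin(-2L, con, size = 4L, endian = "big")         # version
    writeBin(length(codes), con, size = 4L, endian = "big")
    fname <- charToRaw("geromorph.ctab")
    writeBin(length(fname), con, size = 4L, endian = "big")
    writeBin(fname, con)
    writeBin(length(codes), con, size = 4L, endian = "big")
    for (i in seq_along(codes)) {
      writeBin(i - 1L, con, size = 4L, endian = "big")
      nm <- charToRaw(regionNames[i])
      writeBin(length(nm) + 1L, con, size = 4L, endian = "big")
      writeBin(c(nm, as.raw(0)), con)
      code <- codes[i]
      writeBin(as.integer(c(code %% 256L, (code %/% 256L) %% 256L,
                            (code %/% 65536L) %% 256L, 0L)), con,
               size = 4L, endian = "big")
    }
  }
  invisible(path)
}

#' Write / read a named-array exchange container
#'
#' A minimal container of named numeric arrays (vertices, faces, features,
#' medial_wall, ...) used to cache hierarchies and receptive-field maps
#' between runs, serialised with R's native format.
#'
#' @param arrays named list of arrays/vectors.
#' @param path file path.
#' @export
writeArrayContainer <- function(arrays, path) {
  stopifnot(is.list(arrays), !is.null(names(arrays)), all(nzchar(names(arrays))))
  saveRDS(arrays, path)
  invisible(path)
}

#' @rdname writeArrayContainer
#' @export
readArrayContainer <- function(path) readRDS(path)
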
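#' @importFrom Matrix sparseMatrix Diagonal bdiag rowSums colSums t crossprod
NULL

#' Number of vertices of a mesh
#' @param x a SurfaceMesh
#' @export
nVertices <- function(x) nrow(x@vertices)

#' Vertex coordinates of a mesh
#' @param x a SurfaceMesh
#' @return numeric matrix n x 3
#' @export
meshVertices <- function(x) x@vertices

#' Face index matrix of a mesh
#' @param x a SurfaceMesh
#' @return integer matrix m x 3 (1-based)
#' @export
meshFaces <- function(x) x@faces

#' Hemisphere label of a mesh
#' @param x a SurfaceMesh
#' @export
hemisphere <- function(x) x@hemisphere

#' Per-vertex hemisphere id (1 = left, 2 = right)
#' @param x a SurfaceMesh
#' @export
hemiId <- function(x) x@hemiId

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh (%s): %d vertices, %d faces\n",
              object@hemisphere, nrow(object@vertices), nrow(object@faces)))
})

.newMesh <- function(vertices, faces, hemisphere, hemiId = NULL) {
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  dimnames(vertices) <- NULL
  if (is.null(hemiId))
    hemiId <- rep(if (hemisphere == "right") 2L else 1L, nrow(vertices))
  new("SurfaceMesh", vertices = vertices, faces = faces,
      hemisphere = hemisphere, hemiId = as.integer(hemiId))
}

# Canonical regular icosahedron: 12 vertices from the three golden rectangles,
# normalised to the unit sphere, with a fixed face list. Vertex order is fixed
# so subdivision is reproducible bit-for-bit.
.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(vertices = v, faces = f)
}

# One midpoint-subdivision step. Parents keep their indices; edge midpoints are
# appended in lexicographic edge order (min index, then max index), giving the
# deterministic parents-first ordering that makes level k a prefix of level k+1.
.subdivide <- function(vertices, faces) {
  n <- nrow(vertices)
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  key <- (lo - 1) * n + hi
  ord <- order(lo, hi)
  ukey <- key[ord][!duplicated(key[ord])]
  mid_of <- match(key, ukey) + n          # midpoint index for each face-edge slot
  ulo <- ((ukey - 1) %/% n) + 1; uhi <- ((ukey - 1) %% n) + 1
  mids <- (vertices[ulo, , drop = FALSE] + vertices[uhi, , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  nf <- nrow(faces)
  mab <- mid_of[seq_len(nf)]
  mbc <- mid_of[nf + seq_len(nf)]
  mca <- mid_of[2 * nf + seq_len(nf)]
  newf <- rbind(
    cbind(faces[, 1], mab, mca),
    cbind(faces[, 2], mbc, mab),
    cbind(faces[, 3], mca, mbc),
    cbind(mab, mbc, mca)
  )
  list(vertices = rbind(vertices, mids), faces = newf)
}

#' Build a unit icosphere by midpoint subdivision
#'
#' Starts from a regular icosahedron and applies `level` midpoint
#' subdivisions, re-normalising every new vertex onto the unit sphere. The
#' vertex ordering is deterministic and parents-first: the first
#' \eqn{10 \cdot 4^k + 2} vertices of level \eqn{k+1} are exactly the level-k
#' vertices, which downstream cross-resolution matching relies on.
#'
#' @param level non-negative integer number of subdivisions.
#' @param hemisphere label to attach ("left" or "right").
#' @return a [SurfaceMesh] with \eqn{10 \cdot 4^{level} + 2} vertices.
#' @examples
#' m <- buildIcosphere(2)
#' nVertices(m)  # 162
#' @export
buildIcosphere <- function(level, hemisphere = "left") {
  if (length(level) != 1L || is.na(level) || level < 0 || level != round(level))
    stop("'level' must be a single non-negative integer")
  ico <- .icosahedron()
  v <- ico$vertices; f <- ico$faces
  for (i in seq_len(level)) {
    s <- .subdivide(v, f)
    v <- s$vertices; f <- s$faces
  }
  .newMesh(v, f, hemisphere)
}

#' Concatenate two hemisphere meshes into one joint mesh
#'
#' Right-hemisphere vertex indices are offset by the number of left vertices;
#' no edges are added between hemispheres, so the joint graph has exactly two
#' connected components. For spatial separation the left block is translated
#' to x - `separation` and the right block to x + `separation`; the model
#' never reads absolute coordinates, so this is cosmetic (and recorded in the
#' returned mesh's coordinates only).
#'
#' @param left,right [SurfaceMesh] objects for the two hemispheres.
#' @param separation half-distance between hemisphere centres along x.
#' @return a joint [SurfaceMesh].
#' @export
concatenateHemispheres <- function(left, right, separation = 2) {
  nl <- nVertices(left)
  vl <- left@vertices; vr <- right@vertices
  vl[, 1] <- vl[, 1] - separation
  vr[, 1] <- vr[, 1] + separation
  .newMesh(
    rbind(vl, vr),
    rbind(left@faces, right@faces + nl),
    "joint",
    c(rep(1L, nl), rep(2L, nVertices(right)))
  )
}

#' 1-hop adjacency of a mesh as neighbour lists
#'
#' Symmetric, deduplicated neighbour sets derived from face edges; self-loops
#' are not stored. Each element is a sorted integer vector.
#'
#' @param mesh a [SurfaceMesh]
#' @return list of length `nVertices(mesh)` of integer vectors.
#' @export
meshAdjacency <- function(mesh) {
  n <- nVertices(mesh)
  f <- mesh@faces
  src <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  dst <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  keep <- !duplicated((src - 1) * n + dst)
  src <- src[keep]; dst <- dst[keep]
  ord <- order(src, dst)
  out <- split(dst[ord], factor(src[ord], levels = seq_len(n)))
  names(out) <- NULL
  out
}

#' Sparse symmetric adjacency matrix of a mesh
#' @param mesh a [SurfaceMesh]
#' @return a sparse n x n 0/1 matrix (dgCMatrix), no diagonal.
#' @export
adjacencyMatrix <- function(mesh) {
  n <- nVertices(mesh)
  f <- mesh@faces
  src <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  dst <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  Matrix::sparseMatrix(i = src, j = dst, x = 1, dims = c(n, n), use.last.ij = TRUE)
}

#' Vertices within graph distance k
#'
#' Breadth-first search from `v` over the 1-hop adjacency, returning all
#' vertices at distance 1..k. `v` itself is excluded. Because mesh edges never
#' cross hemispheres, neither does the neighbourhood.
#'
#' @param mesh a [SurfaceMesh] (or an adjacency list from [meshAdjacency]).
#' @param v vertex index.
#' @param k positive integer hop count.
#' @return sorted integer vector of vertex indices.
#' @export
khopNeighbors <- function(mesh, v, k) {
  adj <- if (is.list(mesh)) mesh else meshAdjacency(mesh)
  n <- length(adj)
  if (length(v) != 1L || is.na(v) || v < 1L || v > n)
    stop("'v' must be a valid vertex index")
  if (k < 1L) stop("'k' must be >= 1")
  seen <- logical(n); seen[v] <- TRUE
  frontier <- v; acc <- integer(0)
  for (step in seq_len(k)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    if (!length(nxt)) break
    seen[nxt] <- TRUE
    acc <- c(acc, nxt)
    frontier <- nxt
  }
  sort(acc)
}

#' Connected components of a mesh graph
#' @param mesh a [SurfaceMesh] or adjacency list.
#' @return integer vector of component labels (1-based), one per vertex.
#' @export
graphComponents <- function(mesh) {
  adj <- if (is.list(mesh)) mesh else meshAdjacency(mesh)
  n <- length(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s; comp[s] <- cur
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}
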
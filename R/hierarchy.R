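setMethod("show", "AtlasHierarchy", function(object) {
  n <- vapply(object@meshes, nVertices, integer(1))
  cat(sprintf("AtlasHierarchy: %d levels (ico%s), joint vertex counts %s\n",
              length(n), paste(object@levels, collapse = "/"),
              paste(n, collapse = "/")))
  cat(sprintf("  medial wall: %s vertices per level\n",
              paste(vapply(object@medialWall, sum, integer(1)), collapse = "/")))
})

#' Number of levels in a hierarchy
#' @param x an [AtlasHierarchy]
#' @export
nLevels <- function(x) length(x@meshes)

#' Joint mesh at one hierarchy level
#' @param x an [AtlasHierarchy]
#' @param i level index (1 = coarsest) or "finest"/"coarsest".
#' @export
levelMesh <- function(x, i) {
  if (identical(i, "finest")) i <- nLevels(x)
  if (identical(i, "coarsest")) i <- 1L
  x@meshes[[i]]
}

#' Medial-wall mask at one hierarchy level
#' @inheritParams levelMesh
#' @return logical vector, TRUE at medial-wall vertices.
#' @export
medialWall <- function(x, i = nLevels(x)) {
  if (identical(i, "finest")) i <- nLevels(x)
  x@medialWall[[i]]
}

#' Vertex counts per hierarchy level
#' @param x an [AtlasHierarchy]
#' @export
vertexCounts <- function(x) vapply(x@meshes, nVertices, integer(1))

#' Geodesic-cap medial wall mask for a joint icosphere mesh
#'
#' The wall is the set of vertices within angular radius `radius` of each
#' hemisphere's medial pole — the pole that faces the other hemisphere
#' (+x for the left-hemisphere unit sphere, -x for the right). Real atlas
#' annotations can be substituted wherever a mask is accepted.
#'
#' @param mesh a joint [SurfaceMesh] built from unit icospheres.
#' @param radius angular radius in radians.
#' @param separation hemisphere translation used when the joint mesh was built.
#' @return logical vertex mask.
#' @export
medialWallMask <- function(mesh, radius = 0.25, separation = 2) {
  v <- mesh@vertices
  hid <- mesh@hemiId
  # undo the cosmetic translation to recover unit-sphere coordinates
  v[, 1] <- v[, 1] + ifelse(hid == 1L, separation, -separation)
  pole_x <- ifelse(hid == 1L, 1, -1)
  cosang <- pmin(1, pmax(-1, v[, 1] * pole_x))  # dot product with (±1, 0, 0)
  acos(cosang) <= radius
}

#' Build a nested two-hemisphere icosphere hierarchy
#'
#' Constructs joint meshes at each requested subdivision level (both
#' hemispheres concatenated, right block offset along +x) and the medial-wall
#' mask per level. The joint vertex count at level n is
#' \eqn{2 (10 \cdot 4^n + 2)}; the reference configuration
#' `levels = c(4, 5, 6)` gives 5124, 20484 and 81924.
#'
#' @param levels increasing integer subdivision levels, coarsest first.
#' @param wallRadius angular radius (radians) of the medial-wall cap.
#' @param separation hemisphere translation along x.
#' @return an [AtlasHierarchy].
#' @examples
#' h <- buildAtlasHierarchy(0:2)
#' vertexCounts(h)  # 24, 84, 324
#' @export
buildAtlasHierarchy <- function(levels = c(4L, 5L, 6L), wallRadius = 0.25,
                                separation = 2) {
  levels <- as.integer(levels)
  if (any(diff(levels) <= 0L)) stop("'levels' must be strictly increasing")
  if (any(levels < 0L)) stop("'levels' must be non-negative")
  # subdivide once per hemisphere shape and snapshot at requested levels;
  # both hemispheres share the same unit-sphere geometry
  ico <- .icosahedron()
  v <- ico$vertices; f <- ico$faces
  snapshots <- vector("list", length(levels))
  cur <- 0L
  for (k in seq_along(levels)) {
    while (cur < levels[k]) {
      s <- .subdivide(v, f)
      v <- s$vertices; f <- s$faces
      cur <- cur + 1L
    }
    snapshots[[k]] <- list(vertices = v, faces = f)
  }
  meshes <- lapply(snapshots, function(s) {
    lh <- .newMesh(s$vertices, s$faces, "left")
    rh <- .newMesh(s$vertices, s$faces, "right")
    concatenateHemispheres(lh, rh, separation = separation)
  })
  wall <- lapply(meshes, medialWallMask, radius = wallRadius,
                 separation = separation)
  new("AtlasHierarchy", meshes = meshes, levels = levels, medialWall = wall)
}
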
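setMethod("show", "ReceptiveFieldMap", function(object) {
  cat(sprintf("ReceptiveFieldMap %d -> %d vertices; field sizes %d-%d; %d fine vertices uncovered\n",
              object@nCoarse, object@nFine,
              min(lengths(object@fields)), max(lengths(object@fields)),
              sum(lengths(object@inverse) == 0L)))
})

#' Receptive fields of a map
#' @param rf a [ReceptiveFieldMap]
#' @export
receptiveFields <- function(rf) rf@fields

#' Inverse receptive fields of a map
#' @param rf a [ReceptiveFieldMap]
#' @export
inverseFields <- function(rf) rf@inverse

#' Matched fine vertex per coarse vertex
#' @param rf a [ReceptiveFieldMap]
#' @export
matchedVertex <- function(rf) rf@match

# chunked within-hemisphere nearest neighbour; ties broken by lowest fine index
.nearestVertex <- function(coarseXYZ, fineXYZ, chunk = 512L) {
  nc <- nrow(coarseXYZ)
  out <- integer(nc)
  fsq <- rowSums(fineXYZ^2)
  for (s in seq(1L, nc, by = chunk)) {
    idx <- s:min(s + chunk - 1L, nc)
    # squared distance = |c|^2 - 2 c.f + |f|^2 ; |c|^2 constant per row
    g <- -2 * coarseXYZ[idx, , drop = FALSE] %*% t(fineXYZ)
    g <- sweep(g, 2L, fsq, "+")
    out[idx] <- max.col(-g, ties.method = "first")
  }
  out
}

#' Build receptive fields between two atlas resolutions
#'
#' For each coarse vertex, finds the nearest fine vertex by Euclidean
#' distance within the same hemisphere (ties to the lowest index), then
#' takes the receptive field as that vertex plus its 1-hop neighbours in the
#' fine mesh. The inverse map is populated by exact set duality:
#' u is in R^-1 of a fine vertex iff that fine vertex is in R(u).
#'
#' @param coarse,fine [SurfaceMesh] objects from the same hierarchy (coarse
#'   has fewer or equal vertices).
#' @param coarseLevel,fineLevel optional level indices recorded in the map.
#' @return a [ReceptiveFieldMap].
#' @export
buildReceptiveFields <- function(coarse, fine, coarseLevel = 1L, fineLevel = 2L) {
  nc <- nVertices(coarse); nf <- nVertices(fine)
  if (nc == 0L || nf == 0L) stop("empty mesh")
  match <- integer(nc)
  for (h in unique(coarse@hemiId)) {
    ci <- which(coarse@hemiId == h)
    fi <- which(fine@hemiId == h)
    if (!length(fi)) stop("fine mesh lacks hemisphere present in coarse mesh")
    nn <- .nearestVertex(coarse@vertices[ci, , drop = FALSE],
                         fine@vertices[fi, , drop = FALSE])
    match[ci] <- fi[nn]
  }
  adjF <- meshAdjacency(fine)
  fields <- lapply(match, function(m) sort(c(m, adjF[[m]])))
  inv <- vector("list", nf)
  flat <- unlist(fields, use.names = FALSE)
  owner <- rep.int(seq_len(nc), lengths(fields))
  ord <- order(flat, owner)
  inv_split <- split(owner[ord], factor(flat[ord], levels = seq_len(nf)))
  names(inv_split) <- NULL
  new("ReceptiveFieldMap", coarseLevel = as.integer(coarseLevel),
      fineLevel = as.integer(fineLevel), match = match, fields = fields,
      inverse = inv_split, nCoarse = nc, nFine = nf)
}

#' Sparse averaging operator for downsampling
#'
#' Row v of the returned (nCoarse x nFine) matrix holds 1/|R(v)| on the
#' members of R(v), so `P %*% X` averages fine features within each
#' receptive field.
#'
#' @param rf a [ReceptiveFieldMap]
#' @return sparse dgCMatrix.
#' @export
poolDownMatrix <- function(rf) {
  sizes <- lengths(rf@fields)
  i <- rep.int(seq_len(rf@nCoarse), sizes)
  j <- unlist(rf@fields, use.names = FALSE)
  Matrix::sparseMatrix(i = i, j = j, x = rep.int(1 / sizes, sizes),
                       dims = c(rf@nCoarse, rf@nFine))
}

#' Sparse averaging operator for upsampling
#'
#' Row u of the returned (nFine x nCoarse) matrix averages over the inverse
#' receptive field R^-1(u). Fine vertices with an empty inverse field (never
#' the case on nested icospheres) are imputed deterministically: in
#' increasing-index waves, an uncovered vertex takes the mean of its
#' already-covered 1-hop fine neighbours, iterated until all vertices are
#' covered. The number of imputed vertices is attached as attribute
#' `nImputed`.
#'
#' @param rf a [ReceptiveFieldMap]
#' @param fineMesh the fine [SurfaceMesh]; required only when imputation is
#'   needed.
#' @return sparse dgCMatrix with attribute `nImputed`.
#' @export
poolUpMatrix <- function(rf, fineMesh = NULL) {
  sizes <- lengths(rf@inverse)
  covered <- sizes > 0L
  i <- rep.int(which(covered), sizes[covered])
  j <- unlist(rf@inverse[covered], use.names = FALSE)
  P <- Matrix::sparseMatrix(i = i, j = j,
                            x = rep.int(1 / sizes[covered], sizes[covered]),
                            dims = c(rf@nFine, rf@nCoarse))
  nImputed <- sum(!covered)
  if (nImputed > 0L) {
    if (is.null(fineMesh))
      stop("fine mesh required to impute fine vertices with empty inverse fields")
    adj <- meshAdjacency(fineMesh)
    todo <- which(!covered)
    while (length(todo)) {
      progressed <- FALSE
      next_todo <- integer(0)
      for (u in todo) {  # increasing-index wave; rows built from covered rows only
        nb <- adj[[u]]
        nb <- nb[covered[nb]]
        if (!length(nb)) { next_todo <- c(next_todo, u); next }
        P[u, ] <- Matrix::colSums(P[nb, , drop = FALSE]) / length(nb)
        progressed <- TRUE
      }
      covered[setdiff(todo, next_todo)] <- TRUE
      if (!progressed) stop("imputation cannot cover isolated fine vertices")
      todo <- next_todo
    }
  }
  attr(P, "nImputed") <- nImputed
  P
}

#' Downsample per-vertex features by receptive-field averaging
#' @param features fine matrix (nFine x F) or vector.
#' @param rf a [ReceptiveFieldMap]
#' @return coarse matrix (nCoarse x F).
#' @export
poolDown <- function(features, rf) {
  features <- as.matrix(features)
  if (nrow(features) != rf@nFine)
    stop(sprintf("feature rows (%d) must equal fine vertex count (%d)",
                 nrow(features), rf@nFine))
  as.matrix(poolDownMatrix(rf) %*% features)
}

#' Upsample per-vertex features by inverse-receptive-field averaging
#' @param features coarse matrix (nCoarse x F) or vector.
#' @param rf a [ReceptiveFieldMap]
#' @param fineMesh fine mesh, needed only if imputation is required.
#' @return fine matrix (nFine x F).
#' @export
poolUp <- function(features, rf, fineMesh = NULL) {
  features <- as.matrix(features)
  if (nrow(features) != rf@nCoarse)
    stop(sprintf("feature rows (%d) must equal coarse vertex count (%d)",
                 nrow(features), rf@nCoarse))
  as.matrix(poolUpMatrix(rf, fineMesh) %*% features)
}

#' Receptive-field maps for every consecutive level pair of a hierarchy
#' @param hierarchy an [AtlasHierarchy]
#' @return list of [ReceptiveFieldMap], element i mapping level i -> i+1.
#' @export
hierarchyReceptiveFields <- function(hierarchy) {
  L <- nLevels(hierarchy)
  lapply(seq_len(L - 1L), function(i)
    buildReceptiveFields(levelMesh(hierarchy, i), levelMesh(hierarchy, i + 1L),
                         coarseLevel = i, fineLevel = i + 1L))
}
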
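# Post-processing of raw local brain age maps: medial-wall removal, then
# iterative neighbourhood smoothing on the remaining vertices, then
# semi-global bias correction of the age gaps.

#' Construct an LbaMaps object
#'
#' @param values matrix (working vertices x scans) of predicted ages, years.
#' @param vertexIndex row indices in the full mesh (default: rows are the
#'   full mesh).
#' @param nFull full finest-level vertex count.
#' @param stage processing stage.
#' @param scanIds scan identifiers (default: column names or 1..n).
#' @return an [LbaMaps].
#' @export
LbaMaps <- function(values, vertexIndex = seq_len(nrow(values)),
                    nFull = nrow(values), stage = "raw", scanIds = NULL) {
  values <- as.matrix(values)
  if (is.null(scanIds))
    scanIds <- if (!is.null(colnames(values))) colnames(values)
               else as.character(seq_len(ncol(values)))
  new("LbaMaps", values = values, vertexIndex = as.integer(vertexIndex),
      nFull = as.integer(nFull), stage = stage, scanIds = as.character(scanIds))
}

#' Predicted-age values of an LbaMaps object
#' @param maps an [LbaMaps]
#' @return matrix (working vertices x scans), years.
#' @export
lbaValues <- function(maps) maps@values

#' Processing stage of an LbaMaps object
#' @param maps an [LbaMaps]
#' @export
lbaStage <- function(maps) maps@stage

#' Row indices of the working vertices in the full mesh
#' @param maps an [LbaMaps]
#' @export
vertexIndex <- function(maps) maps@vertexIndex

#' Local brain-age gaps (predicted minus chronological age)
#' @param maps an [LbaMaps]
#' @param ca chronological ages, one per scan.
#' @return matrix (working vertices x scans), years.
#' @export
lbagValues <- function(maps, ca) sweep(maps@values, 2L, ca)

#' Global brain-age gap per scan
#'
#' The vertex-averaged gap over the working vertex set — the scan-level
#' summary used for cohort comparisons and cognition regressions.
#'
#' @inheritParams lbagValues
#' @return numeric vector, years.
#' @export
gbag <- function(maps, ca) colMeans(maps@values) - ca

setMethod("show", "LbaMaps", function(object) {
  cat(sprintf("LbaMaps [%s]: %d vertices (of %d) x %d scans\n",
              object@stage, nrow(object@values), object@nFull,
              ncol(object@values)))
})

#' Remove the medial wall from age maps
#'
#' Restricts the maps to non-wall vertices (keeping the index mapping back to
#' the full mesh). Performed before smoothing; the wall is not part of the
#' cortex and would distort neighbourhood averages.
#'
#' @param maps an [LbaMaps] at the full vertex count.
#' @param mask logical wall mask (TRUE = wall), length = full vertex count,
#'   or an [AtlasHierarchy] whose finest-level mask is used.
#' @return an [LbaMaps] restricted to non-wall vertices.
#' @export
removeMedialWall <- function(maps, mask) {
  if (is(mask, "AtlasHierarchy")) mask <- medialWall(mask)
  if (length(mask) != nrow(maps@values))
    stop(sprintf("mask length (%d) must match map rows (%d)",
                 length(mask), nrow(maps@values)))
  keep <- which(!mask)
  new("LbaMaps", values = maps@values[keep, , drop = FALSE],
      vertexIndex = maps@vertexIndex[keep], nFull = maps@nFull,
      stage = maps@stage, scanIds = maps@scanIds)
}

#' Scatter working-vertex maps back onto the full mesh
#' @param maps an [LbaMaps]
#' @param fill value placed at excluded (wall) vertices.
#' @return matrix (full vertices x scans).
#' @export
scatterToFullMesh <- function(maps, fill = NA_real_) {
  out <- matrix(fill, maps@nFull, ncol(maps@values))
  out[maps@vertexIndex, ] <- maps@values
  colnames(out) <- maps@scanIds
  out
}

#' Sparse neighbourhood-averaging operator
#'
#' Row v averages v together with its neighbours up to `hops` steps away
#' within the working vertex set (wall vertices, if already removed, do not
#' contribute). Applying the operator once performs one synchronous
#' (Jacobi-style) smoothing iteration.
#'
#' @param mesh the finest-level [SurfaceMesh].
#' @param workingIndex integer indices of the working vertices in the mesh.
#' @param hops neighbourhood radius in graph steps.
#' @return sparse row-stochastic matrix over the working vertices.
#' @export
smoothingOperator <- function(mesh, workingIndex = seq_len(nVertices(mesh)),
                              hops = 2L) {
  A <- adjacencyMatrix(mesh)[workingIndex, workingIndex, drop = FALSE]
  n <- nrow(A)
  S <- A + Matrix::Diagonal(n)
  reach <- S
  for (h in seq_len(hops - 1L)) reach <- reach %*% S
  reach <- 1 * (reach != 0)
  Matrix::Diagonal(x = 1 / Matrix::rowSums(reach)) %*% reach
}

#' Smooth age maps by iterated neighbourhood averaging
#'
#' Each iteration replaces every vertex value by the unweighted mean of
#' itself and its neighbours up to `hops` steps away, all vertices updated
#' synchronously from the previous iterate. The defaults (2 hops, 4
#' iterations) remove spatial prediction artifacts while retaining cortical
#' variability.
#'
#' @param maps an [LbaMaps] (typically after [removeMedialWall]).
#' @param mesh the finest-level [SurfaceMesh] of the bound hierarchy, or an
#'   [AtlasHierarchy].
#' @param hops neighbourhood radius in graph steps.
#' @param iterations number of averaging passes.
#' @return an [LbaMaps] with stage "smoothed".
#' @export
smoothLba <- function(maps, mesh, hops = 2L, iterations = 4L) {
  if (is(mesh, "AtlasHierarchy")) mesh <- levelMesh(mesh, "finest")
  S <- smoothingOperator(mesh, maps@vertexIndex, hops = hops)
  v <- maps@values
  for (i in seq_len(iterations)) v <- as.matrix(S %*% v)
  new("LbaMaps", values = v, vertexIndex = maps@vertexIndex,
      nFull = maps@nFull, stage = "smoothed", scanIds = maps@scanIds)
}

#' Fit the semi-global bias model
#'
#' At each vertex, ordinary least squares of the local brain-age gap
#' (predicted minus chronological age) on chronological age across scans
#' gives a slope and intercept; these are averaged across vertices to a
#' single semi-global slope/intercept pair.
#'
#' @param maps an [LbaMaps] for the fitting cohort.
#' @param ca chronological ages, one per scan.
#' @param label cohort label recorded with the model.
#' @return a [BiasModel].
#' @export
fitBias <- function(maps, ca, label = "CN") {
  n <- length(ca)
  if (ncol(maps@values) != n) stop("one age per scan required")
  if (n < 3L) stop("need at least 3 scans to fit the bias model")
  cac <- ca - mean(ca)
  ss <- sum(cac^2)
  if (ss == 0) stop("zero variance in chronological age; bias fit undefined")
  G <- lbagValues(maps, ca)
  slopes <- as.numeric(G %*% cac) / ss
  intercepts <- rowMeans(G) - slopes * mean(ca)
  new("BiasModel", slopes = slopes, intercepts = intercepts,
      mMu = mean(slopes), bMu = mean(intercepts), fittedOn = label)
}

#' Semi-global slope / intercept of a bias model
#' @param model a [BiasModel]
#' @export
biasSlope <- function(model) model@mMu

#' @rdname biasSlope
#' @export
biasIntercept <- function(model) model@bMu

setMethod("show", "BiasModel", function(object) {
  cat(sprintf("BiasModel (fitted on %s, %d vertices): m_mu = %.4f, b_mu = %.3f y\n",
              object@fittedOn, length(object@slopes), object@mMu, object@bMu))
})

#' Apply semi-global bias correction
#'
#' Subtracts the semi-global adjustment term (mMu * CA + bMu) from every
#' vertex of each scan. Coefficients fitted on a reference (e.g. cognitively
#' normal) cohort are reused unchanged for a disease cohort so that
#' disease-specific bias is not removed.
#'
#' @param maps an [LbaMaps].
#' @param ca chronological ages, one per scan.
#' @param model a fitted [BiasModel].
#' @return an [LbaMaps] with stage "bias_corrected".
#' @export
applyBias <- function(maps, ca, model) {
  if (length(model@slopes) == 0L && length(model@mMu) == 0L)
    stop("bias model is not fitted")
  if (length(ca) != ncol(maps@values)) stop("one age per scan required")
  adj <- model@mMu * ca + model@bMu
  new("LbaMaps", values = sweep(maps@values, 2L, adj),
      vertexIndex = maps@vertexIndex, nFull = maps@nFull,
      stage = "bias_corrected", scanIds = maps@scanIds)
}

#' Serialise a bias model to JSON
#' @param model a [BiasModel]
#' @param path output path.
#' @export
writeBiasModel <- function(model, path) {
  jsonlite::write_json(
    list(slopes = model@slopes, intercepts = model@intercepts,
         m_mu = model@mMu, b_mu = model@bMu, fitted_on = model@fittedOn),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a bias model from JSON
#' @param path file written by [writeBiasModel].
#' @return a [BiasModel]
#' @export
readBiasModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("BiasModel", slopes = as.numeric(x$slopes),
      intercepts = as.numeric(x$intercepts),
      mMu = as.numeric(x$m_mu), bMu = as.numeric(x$b_mu),
      fittedOn = as.character(x$fitted_on))
}
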
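#' @importFrom SummarizedExperiment SummarizedExperiment assays assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

setValidity("SurfaceCohort", function(object) {
  nfine <- nVertices(levelMesh(object@hierarchy, "finest"))
  if (nrow(object) != nfine)
    return(sprintf("assay rows (%d) must equal finest-level vertex count (%d)",
                   nrow(object), nfine))
  cd <- colData(object)
  if (!"ca" %in% colnames(cd)) return("colData must contain 'ca' (chronological age)")
  if (ncol(object) > 0L && any(cd$ca <= 0)) return("chronological ages must be positive")
  TRUE
})

#' Construct a SurfaceCohort
#'
#' @param featureList named list of vertices x scans matrices, one per
#'   morphometric feature, all with identical dimensions.
#' @param hierarchy the [AtlasHierarchy] the scans are registered to.
#' @param colData a data.frame/DataFrame of scan metadata containing at least
#'   `ca` (chronological age, years).
#' @param rowData optional per-vertex annotation.
#' @return a [SurfaceCohort].
#' @export
SurfaceCohort <- function(featureList, hierarchy, colData, rowData = NULL) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = featureList, colData = S4Vectors::DataFrame(colData))
  if (!is.null(rowData)) SummarizedExperiment::rowData(se) <- S4Vectors::DataFrame(rowData)
  new("SurfaceCohort", se, hierarchy = hierarchy)
}

#' Hierarchy bound to a cohort
#' @param x a [SurfaceCohort]
#' @export
cohortHierarchy <- function(x) x@hierarchy

#' Chronological ages of a cohort (years)
#' @param x a [SurfaceCohort]
#' @export
chronoAge <- function(x) colData(x)$ca

#' Per-scan feature matrix
#'
#' @param x a [SurfaceCohort]
#' @param scan column index or name.
#' @return vertices x features numeric matrix, feature columns in assay order.
#' @export
featureMatrix <- function(x, scan) {
  m <- vapply(assayNames(x), function(a) assay(x, a)[, scan],
              numeric(nrow(x)))
  colnames(m) <- assayNames(x)
  m
}

#' Stack a set of scans into a sample-major feature matrix
#'
#' Rows are ordered scan-by-scan (all vertices of scan 1, then scan 2, ...);
#' this is the layout the batched network operators act on.
#'
#' @param x a [SurfaceCohort]
#' @param scans column indices (default all).
#' @return (nScans * nVertices) x nFeatures matrix.
#' @keywords internal
.stackFeatures <- function(x, scans = seq_len(ncol(x))) {
  mats <- lapply(assayNames(x), function(a) assay(x, a)[, scans, drop = FALSE])
  nv <- nrow(x)
  out <- matrix(0, nrow = nv * length(scans), ncol = length(mats))
  for (f in seq_along(mats)) out[, f] <- as.numeric(mats[[f]])
  colnames(out) <- assayNames(x)
  out
}

setMethod("show", "SurfaceCohort", function(object) {
  methods::callNextMethod()
  cat(sprintf("hierarchy: joint vertex counts %s\n",
              paste(vertexCounts(object@hierarchy), collapse = "/")))
})
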
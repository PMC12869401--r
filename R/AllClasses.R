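#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom Rcpp evalCpp
#' @useDynLib geromorph, .registration = TRUE
NULL

#' SurfaceMesh: a triangulated surface
#'
#' Container for a triangle mesh. Atlas meshes live on the unit sphere (one
#' sphere per hemisphere); a joint mesh holds both hemispheres as two
#' disconnected blocks of vertices, the right block translated along x so the
#' spheres do not overlap. Graph structure never crosses hemispheres.
#'
#' @slot vertices numeric matrix (n x 3) of vertex coordinates.
#' @slot faces integer matrix (m x 3) of 1-based vertex indices.
#' @slot hemisphere one of "left", "right", "joint".
#' @slot hemiId integer vector of length n: 1 for left-hemisphere vertices,
#'   2 for right. For single-hemisphere meshes it is constant.
#' @export
setClass("SurfaceMesh",
  representation(
    vertices = "matrix",
    faces = "matrix",
    hemisphere = "character",
    hemiId = "integer"
  )
)

setValidity("SurfaceMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must be an n x 3 matrix")
  if (nrow(f) > 0L && ncol(f) != 3L) return("faces must be an m x 3 matrix (triangles)")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v)) return("face indices out of range")
    hid <- object@hemiId
    if (any(hid[f[, 1L]] != hid[f[, 2L]]) || any(hid[f[, 1L]] != hid[f[, 3L]]))
      return("faces must not cross hemispheres")
  }
  if (length(object@hemiId) != nrow(v)) return("hemiId must have one entry per vertex")
  if (!object@hemisphere %in% c("left", "right", "joint"))
    return("hemisphere must be 'left', 'right' or 'joint'")
  TRUE
})

#' AtlasHierarchy: nested joint meshes at ordered resolutions
#'
#' Holds joint (two-hemisphere) meshes ordered coarsest to finest, the atlas
#' subdivision level of each, and a per-level medial-wall mask. Within one
#' hemisphere the vertex orderings are nested: level-k vertices are a prefix
#' of level-(k+1) vertices with identical unit-sphere coordinates.
#'
#' @slot meshes list of joint [SurfaceMesh] objects, coarsest first.
#' @slot levels integer subdivision levels matching `meshes`.
#' @slot medialWall list of logical vertex masks (TRUE = medial wall).
#' @export
setClass("AtlasHierarchy",
  representation(
    meshes = "list",
    levels = "integer",
    medialWall = "list"
  )
)

setValidity("AtlasHierarchy", function(object) {
  n <- vapply(object@meshes, function(m) nrow(m@vertices), integer(1))
  if (length(n) < 2L) return("need at least two levels")
  if (any(diff(n) <= 0L)) return("levels must strictly increase in vertex count")
  if (length(object@levels) != length(n)) return("levels vector length mismatch")
  wl <- lengths(object@medialWall)
  if (any(wl != n)) return("medial-wall mask lengths must match vertex counts")
  TRUE
})

#' ReceptiveFieldMap: cross-resolution pooling structure
#'
#' For a pair of consecutive atlas resolutions, stores for each coarse vertex
#' its matched fine vertex (nearest neighbour within the same hemisphere),
#' the receptive field R(v) = matched vertex plus the matched vertex's 1-hop
#' fine neighbours, and the exact set-dual inverse fields R^-1(u) used for
#' upsampling.
#'
#' @slot coarseLevel,fineLevel hierarchy level indices (1-based, coarse first).
#' @slot match integer: matched fine vertex per coarse vertex.
#' @slot fields list of integer vectors: R(v) per coarse vertex.
#' @slot inverse list of integer vectors: R^-1(u) per fine vertex.
#' @slot nCoarse,nFine vertex counts.
#' @export
setClass("ReceptiveFieldMap",
  representation(
    coarseLevel = "integer",
    fineLevel = "integer",
    match = "integer",
    fields = "list",
    inverse = "list",
    nCoarse = "integer",
    nFine = "integer"
  )
)

setValidity("ReceptiveFieldMap", function(object) {
  if (length(object@match) != object@nCoarse) return("match length != nCoarse")
  if (length(object@fields) != object@nCoarse) return("fields length != nCoarse")
  if (length(object@inverse) != object@nFine) return("inverse length != nFine")
  if (any(lengths(object@fields) < 2L)) return("every receptive field must have >= 2 members")
  TRUE
})

#' SurfaceCohort: per-vertex morphometry for a set of scans
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose rows are the vertices of the finest atlas mesh and whose columns are
#' scans. Each assay is one morphometric feature (vertices x scans); the
#' canonical five are `thickness`, `sulc`, `curv`, `area`, `gwr`. Subject
#' metadata (chronological age `ca` in years, `sex`, `education`, `cohort`,
#' cognitive scores) lives in `colData`; per-vertex annotation (hemisphere,
#' medial wall, region label) in `rowData`; the bound [AtlasHierarchy] in the
#' `hierarchy` slot.
#'
#' @slot hierarchy the bound [AtlasHierarchy].
#' @export
setClass("SurfaceCohort",
  contains = "SummarizedExperiment",
  representation(hierarchy = "AtlasHierarchy")
)

#' GraphUNet: a trained (or initialised) graph U-Net age model
#'
#' Parameters, batch-normalisation running statistics, the feature
#' standardisation constants learned from the training set, the training-loss
#' history, and the atlas hierarchy plus receptive-field maps the model is
#' bound to.
#'
#' @slot config model configuration list (see [unetConfig]).
#' @slot params named list of weight matrices / vectors.
#' @slot bnStats named list of running mean/variance per batch-norm layer.
#' @slot featureStats list with `mean` and `sd` per input feature column.
#' @slot lossHistory mean training loss per epoch (years).
#' @slot hierarchy the bound [AtlasHierarchy].
#' @slot rfMaps list of [ReceptiveFieldMap] for consecutive level pairs.
#' @export
setClass("GraphUNet",
  representation(
    config = "list",
    params = "list",
    bnStats = "list",
    featureStats = "list",
    lossHistory = "numeric",
    hierarchy = "AtlasHierarchy",
    rfMaps = "list"
  )
)

#' LbaMaps: per-vertex predicted age for a set of scans
#'
#' Values are years, one column per scan, rows restricted to a working vertex
#' set (`vertexIndex` maps rows back to the full finest-level mesh). The
#' `stage` records how far along the post-processing chain the maps are:
#' `raw`, `smoothed`, or `bias_corrected`.
#'
#' @slot values numeric matrix (working vertices x scans) of predicted ages.
#' @slot vertexIndex integer indices of rows in the full mesh.
#' @slot nFull full finest-level vertex count.
#' @slot stage one of "raw", "smoothed", "bias_corrected".
#' @slot scanIds character scan identifiers (column names).
#' @export
setClass("LbaMaps",
  representation(
    values = "matrix",
    vertexIndex = "integer",
    nFull = "integer",
    stage = "character",
    scanIds = "character"
  )
)

setValidity("LbaMaps", function(object) {
  if (nrow(object@values) != length(object@vertexIndex))
    return("vertexIndex must have one entry per row of values")
  if (!object@stage %in% c("raw", "smoothed", "bias_corrected"))
    return("stage must be raw, smoothed or bias_corrected")
  if (length(object@scanIds) != ncol(object@values))
    return("scanIds must have one entry per scan")
  TRUE
})

#' BiasModel: semi-global brain-age-gap bias correction coefficients
#'
#' Per-vertex OLS slope and intercept of the local brain-age gap on
#' chronological age, and their vertex-wise averages, which define the
#' semi-global adjustment term applied to every vertex of a scan.
#'
#' @slot slopes per-vertex slope (years per year).
#' @slot intercepts per-vertex intercept (years).
#' @slot mMu averaged slope.
#' @slot bMu averaged intercept.
#' @slot fittedOn label of the cohort the model was fitted on.
#' @export
setClass("BiasModel",
  representation(
    slopes = "numeric",
    intercepts = "numeric",
    mMu = "numeric",
    bMu = "numeric",
    fittedOn = "character"
  )
)

setValidity("BiasModel", function(object) {
  if (length(object@slopes) != length(object@intercepts))
    return("slopes and intercepts must have equal length")
  if (length(object@slopes) > 0) {
    if (abs(object@mMu - mean(object@slopes)) > 1e-10)
      return("mMu must equal the mean of the per-vertex slopes")
    if (abs(object@bMu - mean(object@intercepts)) > 1e-10)
      return("bMu must equal the mean of the per-vertex intercepts")
  }
  TRUE
})

#' SaliencyMap: integrated-gradients attributions
#'
#' Per-vertex, per-feature attribution of the model's mean predicted age,
#' computed against a zero (z-score 0) or fixed cohort-batch baseline.
#'
#' @slot attributions numeric matrix (vertices x features).
#' @slot baseline "zero" or "cohort_batch".
#' @slot steps number of path-integral steps N.
#' @slot scanId scan identifier or "group_mean".
#' @export
setClass("SaliencyMap",
  representation(
    attributions = "matrix",
    baseline = "character",
    steps = "integer",
    scanId = "character"
  )
)
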
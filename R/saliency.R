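# Integrated-gradients attribution. The scalar target f differentiated with
# respect to the (standardised) input features is the mean predicted age over
# non-medial-wall vertices — the natural cohort-comparable reduction of the
# vertex-wise output. Gradients are taken with batch normalisation in
# inference mode, so they are exact gradients of the deterministic predictor.

# gradient of f(x) = mean_{non-wall} prediction wrt the standardised input
.inputGradient <- function(model, X, ops) {
  L <- nLevels(model@hierarchy)
  wall <- medialWall(model@hierarchy)
  w <- as.numeric(!wall) / sum(!wall)
  fw <- .forwardUNet(model@params, model@bnStats, X, ops, L, "eval",
                     model@config$bnMomentum, model@config$bnEps)
  dY <- matrix(w, ncol = 1L)
  bw <- .backwardUNet(dY, model@params, fw$caches, ops, L, "eval")
  list(grad = bw$dX, f = sum(w * as.numeric(fw$Y)))
}

#' Mean predicted age of one feature matrix
#'
#' The scalar the attribution method explains: the model's predicted age
#' averaged over non-medial-wall vertices. `x` is a raw (unstandardised)
#' vertices x features matrix.
#'
#' @param model a trained [GraphUNet].
#' @param x feature matrix (finest-level vertices x features), raw scale.
#' @return scalar, years.
#' @export
predictMeanAge <- function(model, x) {
  X <- sweep(sweep(as.matrix(x), 2L, model@featureStats$mean), 2L,
             model@featureStats$sd, "/")
  ops <- .batchOps(model@hierarchy, model@rfMaps, 1L)
  L <- nLevels(model@hierarchy)
  fw <- .forwardUNet(model@params, model@bnStats, X, ops, L, "eval",
                     model@config$bnMomentum, model@config$bnEps)
  wall <- medialWall(model@hierarchy)
  mean(as.numeric(fw$Y)[!wall])
}

#' Integrated-gradients attribution for one scan
#'
#' Attribution of entry (v, f) is
#' \eqn{(x - \bar x)_{vf} \cdot \frac{1}{N}\sum_{k=1}^{N} \partial f /
#' \partial x_{vf}} evaluated at \eqn{\bar x + (k/N)(x - \bar x)} — a
#' right-endpoint Riemann sum along the straight path from baseline to input,
#' where f is the mean predicted age over non-wall vertices. Inputs and
#' baseline live in the model's standardised feature space, so the all-zero
#' baseline is "every feature at the training-set mean" (z-score 0).
#'
#' @param model a trained [GraphUNet].
#' @param x raw feature matrix (vertices x features) for the scan.
#' @param baseline `"zero"` for the z-score-0 baseline, or a raw feature
#'   matrix of the same shape (e.g. a fixed cohort-batch average).
#' @param steps number of path steps N.
#' @param scanId identifier stored in the result.
#' @return a [SaliencyMap].
#' @export
integratedGradients <- function(model, x, baseline = "zero", steps = 50L,
                                scanId = "scan") {
  fs <- model@featureStats
  X <- sweep(sweep(as.matrix(x), 2L, fs$mean), 2L, fs$sd, "/")
  if (identical(baseline, "zero")) {
    B0 <- matrix(0, nrow(X), ncol(X))
    bkind <- "zero"
  } else {
    baseline <- as.matrix(baseline)
    if (!all(dim(baseline) == dim(X)))
      stop("baseline shape must match the feature matrix")
    B0 <- sweep(sweep(baseline, 2L, fs$mean), 2L, fs$sd, "/")
    bkind <- "cohort_batch"
  }
  D <- X - B0
  ops <- .batchOps(model@hierarchy, model@rfMaps, 1L)
  gsum <- matrix(0, nrow(X), ncol(X))
  for (k in seq_len(steps)) {
    gk <- .inputGradient(model, B0 + (k / steps) * D, ops)
    gsum <- gsum + gk$grad
  }
  attr <- D * gsum / steps
  colnames(attr) <- colnames(x)
  new("SaliencyMap", attributions = attr, baseline = bkind,
      steps = as.integer(steps), scanId = scanId)
}

#' Attribution matrix of a saliency map
#' @param x a [SaliencyMap]
#' @export
attributions <- function(x) x@attributions

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf("SaliencyMap (%s baseline, N = %d, %s): %d vertices x %d features\n",
              object@baseline, object@steps, object@scanId,
              nrow(object@attributions), ncol(object@attributions)))
})

#' Group-level integrated-gradients map
#'
#' Per-scan attribution maps averaged element-wise across a cohort. With
#' `baseline = "zero"` every scan is attributed against the z-score-0
#' baseline (the protocol for a normative cohort). With a reference cohort
#' supplied, one random batch of reference scans is drawn once (fixed seed),
#' averaged into a single baseline feature matrix, and reused for every
#' target scan (the protocol for a disease cohort attributed against
#' normals).
#'
#' @param model a trained [GraphUNet].
#' @param cohort the target [SurfaceCohort].
#' @param baseline `"zero"` or `"cohort"`.
#' @param refCohort reference [SurfaceCohort] (required for `"cohort"`).
#' @param refBatchSize reference scans averaged into the baseline (capped at
#'   the reference cohort size; default the training batch size).
#' @param seed seed for the reference-batch draw.
#' @param steps path steps per scan.
#' @return a [SaliencyMap] with scanId "group_mean".
#' @export
groupSaliency <- function(model, cohort, baseline = c("zero", "cohort"),
                          refCohort = NULL, refBatchSize = NULL, seed = 1L,
                          steps = 50L) {
  baseline <- match.arg(baseline)
  n <- ncol(cohort)
  if (n == 0L) stop("empty cohort")
  if (baseline == "zero") {
    B <- "zero"
  } else {
    if (is.null(refCohort) || ncol(refCohort) == 0L)
      stop("a non-empty reference cohort is required for the cohort baseline")
    if (is.null(refBatchSize)) refBatchSize <- model@config$batchSize
    refBatchSize <- min(refBatchSize, ncol(refCohort))
    set.seed(seed)
    pick <- sample.int(ncol(refCohort), refBatchSize)
    B <- matrix(0, nrow(refCohort), length(assayNames(refCohort)))
    for (s in pick) B <- B + featureMatrix(refCohort, s)
    B <- B / refBatchSize
  }
  acc <- NULL
  for (s in seq_len(n)) {
    m <- integratedGradients(model, featureMatrix(cohort, s), baseline = B,
                             steps = steps, scanId = as.character(s))
    acc <- if (is.null(acc)) m@attributions else acc + m@attributions
  }
  new("SaliencyMap", attributions = acc / n,
      baseline = if (identical(B, "zero")) "zero" else "cohort_batch",
      steps = as.integer(steps), scanId = "group_mean")
}
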
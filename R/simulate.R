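# Synthetic cortical cohorts with known ground truth. Each scan's per-vertex
# features are a smooth baseline spatial field plus an age-dependent term
# (per-feature spatial slope field times the vertex's "local age" centred on
# the cohort mid-age) plus Gaussian noise. Local age equals chronological
# age everywhere except on designated lesioned regions of an
# accelerated-aging subgroup, where a fixed offset in years is added — so
# the recoverable ground truth is exactly the quantity the pipeline
# estimates.

#' Simulation configuration
#'
#' @param levels atlas subdivision levels of the hierarchy (coarsest first).
#' @param nSubjects number of scans (one scan per subject).
#' @param caRange uniform chronological-age range in years.
#' @param features feature (assay) names.
#' @param ageSlope named per-year slope per feature; features with slope 0
#'   carry no age signal. The slope is modulated vertex-wise by a smooth
#'   field in [0.5, 1.5].
#' @param noiseSd Gaussian feature noise SD.
#' @param baselineSd SD of the smooth baseline spatial field.
#' @param lesionFraction fraction of subjects in the accelerated-aging
#'   subgroup (cohort label "ACC"; the rest are "CN").
#' @param lesionYears added years of local aging on lesioned regions.
#' @param lesionRegions region labels (of the deterministic geodesic
#'   parcellation) that carry the lesion.
#' @param nRegionsPerHemi regions per hemisphere in the built-in parcellation.
#' @param sexOffsetYears global extra aging years for males (0 = no sex
#'   effect).
#' @param wallRadius medial-wall cap radius (radians).
#' @param seed RNG seed; the whole cohort is deterministic given the config.
#' @return a named list.
#' @export
simConfig <- function(levels = 0:2, nSubjects = 400L, caRange = c(45, 90),
                      features = c("thickness", "sulc", "curv", "area", "gwr"),
                      ageSlope = c(thickness = 1, sulc = 0, curv = 0,
                                   area = 1, gwr = 0),
                      noiseSd = 0.1, baselineSd = 1,
                      lesionFraction = 0.25, lesionYears = 10,
                      lesionRegions = 3L, nRegionsPerHemi = 8L,
                      sexOffsetYears = 0, wallRadius = 0.25, seed = 0L) {
  stopifnot(length(caRange) == 2L, caRange[1] > 0, caRange[2] > caRange[1],
            lesionFraction >= 0, lesionFraction <= 1,
            is.finite(noiseSd), noiseSd >= 0, all(is.finite(ageSlope)))
  if (!all(names(ageSlope) %in% features))
    stop("ageSlope names must be feature names")
  list(levels = as.integer(levels), nSubjects = as.integer(nSubjects),
       caRange = caRange, features = features, ageSlope = ageSlope,
       noiseSd = noiseSd, baselineSd = baselineSd,
       lesionFraction = lesionFraction, lesionYears = lesionYears,
       lesionRegions = as.integer(lesionRegions),
       nRegionsPerHemi = as.integer(nRegionsPerHemi),
       sexOffsetYears = sexOffsetYears, wallRadius = wallRadius,
       seed = as.integer(seed))
}

# smooth unit-SD spatial field: white noise diffused over the mesh
.smoothField <- function(S, n = nrow(S)) {
  z <- stats::rnorm(n)
  for (i in 1:4) z <- as.numeric(S %*% z)
  z / stats::sd(z)
}

#' Simulate a synthetic cortical cohort
#'
#' Draws chronological ages uniformly over the configured range, builds
#' per-vertex features as baseline field + slope field x (local age - mid
#' age) + noise, assigns sexes, education and an accelerated-aging subgroup,
#' and emits cognitive scores as linear functions of the ground-truth global
#' gap plus noise ("memory", higher = better; "tmtb", higher = worse with a
#' ceiling at 300). The ground-truth local age of a vertex is chronological
#' age plus the lesion offset on lesioned regions of lesioned subjects (plus
#' the sex offset for males when configured).
#'
#' @param config a [simConfig] list.
#' @return a [SurfaceCohort]; `rowData` holds the wall mask and region
#'   labels, and `metadata(cohort)$groundTruth` holds the true gap matrix,
#'   lesioned regions, and the config.
#' @export
simulateCohort <- function(config = simConfig()) {
  hierarchy <- buildAtlasHierarchy(config$levels, wallRadius = config$wallRadius)
  mesh <- levelMesh(hierarchy, "finest")
  V <- nVertices(mesh)
  wall <- medialWall(hierarchy)
  parc <- geodesicParcellation(mesh, wall, nPerHemi = config$nRegionsPerHemi)
  n <- config$nSubjects
  F <- length(config$features)

  set.seed(config$seed)
  ca <- stats::runif(n, config$caRange[1], config$caRange[2])
  caMid <- mean(config$caRange)
  sex <- ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "M", "F")
  education <- sample(8:20, n, replace = TRUE)
  lesioned <- stats::rbinom(n, 1L, config$lesionFraction) == 1L
  cohortLab <- ifelse(lesioned, "ACC", "CN")

  S <- smoothingOperator(mesh, hops = 2L)
  baseline <- matrix(0, V, F)
  slopeField <- matrix(0, V, F)
  for (f in seq_len(F)) {
    baseline[, f] <- config$baselineSd * .smoothField(S)
    sl <- config$ageSlope[config$features[f]]
    if (is.na(sl)) sl <- 0
    # smooth modulation in [0.5, 1.5] around the configured per-year slope
    mod <- 1 + 0.5 * tanh(.smoothField(S))
    slopeField[, f] <- sl * mod
  }

  lesionMask <- parc %in% config$lesionRegions
  gap <- matrix(0, V, n)                       # ground-truth local gap (years)
  if (config$sexOffsetYears != 0)
    gap <- gap + outer(rep(1, V), ifelse(sex == "M", config$sexOffsetYears, 0))
  if (any(lesioned) && any(lesionMask))
    gap[lesionMask, lesioned] <- gap[lesionMask, lesioned] + config$lesionYears

  featureList <- lapply(seq_len(F), function(f) {
    localAge <- outer(rep(1, V), ca) + gap      # V x n
    m <- baseline[, f] + slopeField[, f] * (localAge - caMid) +
      matrix(stats::rnorm(V * n, sd = config$noiseSd), V, n)
    colnames(m) <- sprintf("scan%03d", seq_len(n))
    m
  })
  names(featureList) <- config$features

  gGap <- colMeans(gap[!wall, , drop = FALSE])
  memory <- -1 * gGap + stats::rnorm(n, sd = 1)
  tmtb <- pmin(300, 120 + 12 * gGap + stats::rnorm(n, sd = 40))

  cd <- S4Vectors::DataFrame(
    subjectId = sprintf("sub%03d", seq_len(n)),
    scanId = sprintf("scan%03d", seq_len(n)),
    ca = ca, sex = sex, education = education, cohort = cohortLab,
    memory = memory, tmtb = tmtb,
    row.names = sprintf("scan%03d", seq_len(n)))
  cohort <- SurfaceCohort(featureList, hierarchy, cd,
                          rowData = S4Vectors::DataFrame(
                            wall = wall, region = as.integer(parc),
                            hemi = mesh@hemiId))
  S4Vectors::metadata(cohort)$groundTruth <- list(
    gap = gap, lesionRegions = config$lesionRegions,
    lesionMask = lesionMask, slopeField = slopeField, config = config)
  cohort
}

#' Export a simulated cohort to FreeSurfer-format files
#'
#' Writes one directory per scan containing the finest-level joint surface
#' and one curv (morph data) file per feature, plus a cohort metadata table
#' and a label-per-vertex parcellation file.
#'
#' @param cohort a [SurfaceCohort].
#' @param dir output directory.
#' @export
exportCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mesh <- levelMesh(cohortHierarchy(cohort), "finest")
  for (s in seq_len(ncol(cohort))) {
    sd <- file.path(dir, colnames(cohort)[s])
    dir.create(sd, showWarnings = FALSE)
    writeFreeSurferGeometry(mesh, file.path(sd, "joint.surf"))
    for (a in assayNames(cohort))
      writeFreeSurferMorph(assay(cohort, a)[, s], file.path(sd, paste0(a, ".curv")),
                           nFaces = nrow(mesh@faces))
  }
  utils::write.csv(as.data.frame(colData(cohort)),
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  writeLines(as.character(rowData(cohort)$region),
             file.path(dir, "parcellation.txt"))
  invisible(dir)
}

#' Epoch count for a fixed optimiser-step budget
#'
#' Desk-scale cohorts are orders of magnitude smaller than production ones,
#' so a fixed epoch count would mean almost no optimiser steps. This keeps
#' the optimisation effort constant instead: the epoch count is chosen so
#' that `epochs * ceiling(nTrain/batchSize)` reaches the step budget. The
#' default budget (1500 steps) is ample once the output bias starts at the
#' training-mean age (see the methods vignette).
#'
#' @param nTrain training scans.
#' @param batchSize batch size.
#' @param refSteps optimiser-step budget.
#' @export
scaledEpochs <- function(nTrain, batchSize = 128L, refSteps = 1500L) {
  as.integer(ceiling(refSteps / ceiling(nTrain / batchSize)))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulate, split the non-lesioned ("CN") subjects into train/test, train
#' the graph U-Net on the training split, predict the held-out CN and the
#' accelerated ("ACC") subgroup, remove the medial wall, smooth, fit the
#' semi-global bias model on the held-out CN maps and apply it to both
#' groups, then compute regional means and group statistics. Every
#' intermediate is returned.
#'
#' @param config a [simConfig].
#' @param modelConfig a [unetConfig]; defaults to the reference widths/batch
#'   with the epoch count scaled to the reference optimiser-step budget.
#' @param trainFraction fraction of CN subjects used for training.
#' @param verbose print training progress.
#' @return list: cohort, model, indices, raw/smoothed/corrected maps, bias
#'   model, regional matrices, test tables, MAEs.
#' @export
endToEndFixture <- function(config = simConfig(), modelConfig = NULL,
                            trainFraction = 0.8, verbose = FALSE) {
  cohort <- simulateCohort(config)
  cn <- which(colData(cohort)$cohort == "CN")
  acc <- which(colData(cohort)$cohort == "ACC")
  set.seed(config$seed + 1L)
  nTrain <- max(1L, floor(trainFraction * length(cn)))
  trainIdx <- sort(sample(cn, nTrain))
  testIdx <- setdiff(cn, trainIdx)
  if (is.null(modelConfig)) {
    L <- length(config$levels)
    widths <- c(length(assayNames(cohort)), 8L, rep(16L, max(0L, L - 2L)))[seq_len(L)]
    modelConfig <- unetConfig(featureWidths = widths,
                              epochs = scaledEpochs(nTrain),
                              seed = config$seed)
  }
  model <- trainGraphUNet(cohort[, trainIdx], modelConfig, verbose = verbose)
  hierarchy <- cohortHierarchy(cohort)
  ca <- chronoAge(cohort)

  predTest <- predictLba(model, cohort[, testIdx])
  maeModel <- evaluateMae(predTest, ca[testIdx])
  maeConstant <- mean(abs(ca[testIdx] - stats::median(ca[trainIdx])))

  wallFix <- function(p) smoothLba(removeMedialWall(p, hierarchy), hierarchy)
  smTest <- wallFix(predTest)
  bias <- fitBias(smTest, ca[testIdx], label = "CN")
  corTest <- applyBias(smTest, ca[testIdx], bias)
  parc <- as.integer(rowData(cohort)$region)
  regTest <- regionalMeans(corTest, parc)
  caTests <- regionVsCaTests(regTest, ca[testIdx])

  predAcc <- smAcc <- corAcc <- regAcc <- diffTests <- NULL
  if (length(acc)) {
    predAcc <- predictLba(model, cohort[, acc])
    smAcc <- wallFix(predAcc)
    corAcc <- applyBias(smAcc, ca[acc], bias)   # CN-fitted coefficients reused
    regAcc <- regionalMeans(corAcc, parc)
    diffTests <- cohortDifferenceTests(regAcc, regTest)
  }

  list(cohort = cohort, model = model, trainIdx = trainIdx, testIdx = testIdx,
       accIdx = acc, rawTest = predTest, rawAcc = predAcc,
       smoothedTest = smTest, smoothedAcc = smAcc, bias = bias,
       correctedTest = corTest, correctedAcc = corAcc,
       regionalTest = regTest, regionalAcc = regAcc,
       diffTests = diffTests, caTests = caTests,
       maeModel = maeModel, maeConstant = maeConstant)
}
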
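test_that("gcnLayer matches the dense normalised-adjacency oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    A01 <- matrix(0, n, n)
    for (e in seq_len(sample(3:12, 1))) {
      ij <- sample(n, 2)
      A01[ij[1], ij[2]] <- 1; A01[ij[2], ij[1]] <- 1
    }
    X <- matrix(rnorm(n * 3), n, 3)
    W <- matrix(rnorm(3 * 2), 3, 2)
    b <- rnorm(2)
    As <- methods::as(A01, "CsparseMatrix")
    expect_equal(gcnLayer(X, As, W, b), ref_gcn(X, A01, W, b),
                 tolerance = 1e-10)
  }
})

test_that("gcnLayer with identity weights on an isolated vertex is input plus bias", {
  A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(1, 1))
  expect_equal(gcnLayer(matrix(2.5), A, matrix(1), b = 5), matrix(7.5))
})

test_that("gcnLayer respects graph automorphisms", {
  # two connected vertices with equal inputs produce equal outputs
  A <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(2, 2), symmetric = TRUE)
  A <- methods::as(A, "generalMatrix")
  X <- matrix(c(1.2, 1.2, -0.7, -0.7), 2, 2)
  out <- gcnLayer(X, A, matrix(rnorm(4), 2, 2), b = c(1, 2))
  expect_equal(out[1, ], out[2, ])
  expect_error(gcnLayer(X, A, matrix(0, 3, 2)), "must match")
})

test_that("U-Net forward matches a straight-line dense reference implementation", {
  h <- tiny_hierarchy(0:2)
  rf <- hierarchyReceptiveFields(h)
  L <- 3
  set.seed(0)
  specs <- geromorph:::.layerSpecs(L, c(4L, 6L, 8L))
  init <- geromorph:::.initParams(specs, outBias = 50)
  params <- init$params
  # non-trivial running stats so inference-mode BN is actually exercised
  bn <- lapply(init$bn, function(s)
    list(mean = rnorm(length(s$mean), 0, 0.3),
         var = runif(length(s$var), 0.5, 2)))
  V <- nVertices(levelMesh(h, "finest"))
  X <- matrix(rnorm(V * 4), V, 4)
  ops <- geromorph:::.batchOps(h, rf, 1L)
  got <- as.numeric(geromorph:::.forwardUNet(params, bn, X, ops, L, "eval",
                                             0.1, 1e-5)$Y)
  want <- ref_unet_eval(params, bn, X, h, rf)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("swapping identical hemispheres permutes the output identically", {
  h <- tiny_hierarchy(0:1)
  rf <- hierarchyReceptiveFields(h)
  set.seed(1)
  specs <- geromorph:::.layerSpecs(2L, c(3L, 5L))
  init <- geromorph:::.initParams(specs, outBias = 60)
  bn <- init$bn
  V <- nVertices(levelMesh(h, "finest"))
  half <- V / 2
  X <- matrix(rnorm(V * 3), V, 3)
  ops <- geromorph:::.batchOps(h, rf, 1L)
  fwd <- function(Xin) as.numeric(
    geromorph:::.forwardUNet(init$params, bn, Xin, ops, 2L, "eval", 0.1, 1e-5)$Y)
  swap <- c(half + 1:half, 1:half)
  expect_equal(fwd(X[swap, ]), fwd(X)[swap], tolerance = 1e-12)
})

test_that("perturbations never leak across hemispheres and obey locality", {
  h <- tiny_hierarchy(2:4)
  rf <- hierarchyReceptiveFields(h)
  set.seed(2)
  specs <- geromorph:::.layerSpecs(3L, c(2L, 4L, 4L))
  init <- geromorph:::.initParams(specs, outBias = 60)
  V <- nVertices(levelMesh(h, "finest"))
  X <- matrix(rnorm(V * 2), V, 2)
  ops <- geromorph:::.batchOps(h, rf, 1L)
  fwd <- function(Xin) as.numeric(
    geromorph:::.forwardUNet(init$params, init$bn, Xin, ops, 3L, "eval",
                             0.1, 1e-5)$Y)
  y0 <- fwd(X)
  X2 <- X; X2[1, ] <- X2[1, ] + 10   # vertex 1 is in the left hemisphere
  y1 <- fwd(X2)
  right <- hemiId(levelMesh(h, "finest")) == 2
  expect_identical(y1[right], y0[right])
  # quantitative locality: 6 gcn layers + 4 pooling transitions reach far
  # less than 30 fine-mesh hops; antipodal vertices are unaffected
  adj <- meshAdjacency(levelMesh(h, "finest"))
  d <- rep(NA_integer_, V); d[1] <- 0L; frontier <- 1L
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier])); nxt <- nxt[is.na(d[nxt])]
    d[nxt] <- d[frontier[1]] + 1L  # all frontier vertices share a distance
    frontier <- nxt
  }
  far <- which(!is.na(d) & d > 30)
  expect_gt(length(far), 0)
  expect_identical(y1[far], y0[far])
})

test_that("all-zero weights with zero bias give an all-zero age map", {
  h <- tiny_hierarchy(0:1)
  rf <- hierarchyReceptiveFields(h)
  set.seed(3)
  specs <- geromorph:::.layerSpecs(2L, c(2L, 3L))
  init <- geromorph:::.initParams(specs, outBias = 0)
  params <- lapply(init$params, function(p) p * 0)
  # gamma of batch norm must stay 1 for the layer to be well-defined; the
  # final gcn has zero weights so the output is exactly zero regardless
  for (nm in names(params)) if (grepl("gamma", nm)) params[[nm]] <- params[[nm]] + 1
  V <- nVertices(levelMesh(h, "finest"))
  X <- matrix(rnorm(V * 2), V, 2)
  ops <- geromorph:::.batchOps(h, rf, 1L)
  y <- as.numeric(geromorph:::.forwardUNet(params, init$bn, X, ops, 2L,
                                           "eval", 0.1, 1e-5)$Y)
  expect_equal(y, rep(0, V))
})

test_that("training is deterministic, decreases the loss, and memorises one scan", {
  cfg <- simConfig(levels = 0:1, nSubjects = 12L, seed = 9L, lesionFraction = 0)
  co <- simulateCohort(cfg)
  mc <- unetConfig(featureWidths = c(5L, 8L), epochs = 6L, batchSize = 4L,
                   seed = 7L)
  m1 <- trainGraphUNet(co, mc)
  m2 <- trainGraphUNet(co, mc)
  expect_identical(lossHistory(m1), lossHistory(m2))
  expect_identical(m1@params, m2@params)
  expect_lt(min(lossHistory(m1)), lossHistory(m1)[1])
  # single-sample cohort: loss falls below its initial value within the run
  mc1 <- unetConfig(featureWidths = c(5L, 8L), epochs = 50L, batchSize = 1L,
                    seed = 7L)
  ms <- trainGraphUNet(co[, 1], mc1)
  expect_lt(utils::tail(lossHistory(ms), 1), lossHistory(ms)[1])
  expect_error(trainGraphUNet(co[, integer(0)], mc), "empty cohort")
})

test_that("prediction is deterministic and evaluateMae matches hand computation", {
  fit <- trained_tiny_model()
  p1 <- predictLba(fit$model, fit$cohort)
  p2 <- predictLba(fit$model, fit$cohort, batchSize = 7L)
  expect_equal(lbaValues(p1), lbaValues(p2), tolerance = 1e-12)
  expect_identical(lbaStage(p1), "raw")

  ca <- c(60, 70)
  perfect <- LbaMaps(cbind(rep(60, 10), rep(70, 10)))
  expect_equal(evaluateMae(perfect, ca), 0)
  shifted <- LbaMaps(cbind(rep(63, 10), rep(73, 10)))
  expect_equal(evaluateMae(shifted, ca), 3)
  # per-scan MAEs 2 and 4 average to 3
  two <- LbaMaps(cbind(rep(62, 10), rep(74, 10)))
  expect_equal(evaluateMae(two, ca), 3)
  # constant predictor: mean |c - CA|
  const <- LbaMaps(matrix(65, 10, 2))
  expect_equal(evaluateMae(const, ca), mean(abs(65 - ca)))
  expect_error(evaluateMae(const, c(60, 70, 80)), "one age per scan")
})

test_that("a trained model recovers a strong linear age signal", {
  fit <- trained_tiny_model()
  ca <- chronoAge(fit$cohort)
  maps <- predictLba(fit$model, fit$cohort)
  mae <- evaluateMae(maps, ca)
  constMae <- mean(abs(ca - median(ca)))
  expect_lt(mae, 0.5 * constMae)
})
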
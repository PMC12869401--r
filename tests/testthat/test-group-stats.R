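test_that("geodesic parcellation is deterministic, contiguous and covers non-wall vertices", {
  h <- tiny_hierarchy(0:2)
  mesh <- levelMesh(h, "finest")
  wall <- medialWall(h)
  p1 <- geodesicParcellation(mesh, wall, nPerHemi = 8)
  p2 <- geodesicParcellation(mesh, wall, nPerHemi = 8)
  expect_identical(p1, p2)
  expect_true(all(p1[wall] == 0))
  expect_true(all(p1[!wall] > 0))
  expect_equal(sort(unique(p1[!wall])), 1:16)
  expect_length(attr(p1, "regionNames"), 16)
  # no region crosses hemispheres
  for (r in 1:16)
    expect_length(unique(hemiId(mesh)[p1 == r]), 1)
})

test_that("regional means average within regions and exclude the wall", {
  V <- 10L
  parc <- c(0L, rep(1L, 2), rep(2L, 2), rep(3L, 5))
  vals <- matrix(c(99, 1, 1, 2, 4, 5, 5, 5, 5, 5), V, 1)
  maps <- LbaMaps(vals)
  reg <- regionalMeans(maps, parc)
  expect_equal(as.numeric(reg), c(1, 3, 5))
  # constant map: every region equals the constant
  regc <- regionalMeans(LbaMaps(matrix(7, V, 2)), parc)
  expect_true(all(regc == 7))
  # loop oracle on a simulated parcellation
  h <- tiny_hierarchy(0:1)
  mesh <- levelMesh(h, "finest")
  p <- geodesicParcellation(mesh, medialWall(h), nPerHemi = 4)
  maps2 <- random_lba_maps(nVertices(mesh), 3, seed = 31)
  m2 <- removeMedialWall(maps2, medialWall(h))
  reg2 <- regionalMeans(m2, p)
  lab <- p[vertexIndex(m2)]
  for (r in rownames(reg2))
    expect_equal(reg2[r, ], colMeans(lbaValues(m2)[lab == as.integer(r), ,
                                                   drop = FALSE]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  # an empty region is dropped with a warning
  p3 <- parc; p3[p3 == 2] <- 1L; p3[1] <- 2L  # region 2 only on the wall row
  maps3 <- removeMedialWall(LbaMaps(vals), c(TRUE, rep(FALSE, 9)))
  expect_warning(regionalMeans(maps3, p3), "no working vertices")
})

test_that("t statistics match the textbook pooled-variance formula and t.test", {
  lba <- c(70, 72, 74); ca <- c(60, 62, 64)
  got <- regionVsCaTests(rbind(r1 = lba), ca)
  # hand computation: means 72 and 62, pooled s2 = 4, se = sqrt(4 * 2/3)
  tHand <- 10 / sqrt(4 * (1 / 3 + 1 / 3))
  expect_equal(got$t, tHand, tolerance = 1e-12)
  expect_equal(got$meanLbag, 10)
  # identical vectors: t = 0, p = 1
  same <- regionVsCaTests(rbind(r1 = ca), ca)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # cross-check against the independent library implementation
  set.seed(33)
  for (rep in 1:5) {
    a <- rnorm(8, 70, 4); b <- rnorm(8, 68, 4)
    ours <- geromorph:::.tTest(a, b, welch = FALSE)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(unname(ours["t"]), unname(ref$statistic), tolerance = 1e-12)
    expect_equal(unname(ours["p"]), ref$p.value, tolerance = 1e-12)
    oursW <- geromorph:::.tTest(a, b, welch = TRUE)
    refW <- stats::t.test(a, b)
    expect_equal(unname(oursW["t"]), unname(refW$statistic), tolerance = 1e-12)
    expect_equal(unname(oursW["df"]), unname(refW$parameter), tolerance = 1e-9)
    expect_equal(unname(oursW["p"]), refW$p.value, tolerance = 1e-12)
  }
  # invariance to adding a constant to both vectors
  g1 <- regionVsCaTests(rbind(r1 = lba), ca)
  g2 <- regionVsCaTests(rbind(r1 = lba + 5), ca + 5)
  expect_equal(g1$t, g2$t, tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment follows the step-up procedure", {
  # by hand: sorted p (0.01, 0.02, 0.03, 0.04) with m = 4 gives
  # p_(i) * 4/i = (0.04, 0.04, 0.04, 0.04); the running minimum from the
  # top keeps them all at 0.04
  reg <- rbind(a = c(10, 11), b = c(10, 12), c = c(10, 13), d = c(10, 14))
  out <- regionVsCaTests(reg, c(1, 2))
  expect_equal(out$pAdj, stats::p.adjust(out$p, "BH"))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_true(all(out$pAdj >= out$p))
  expect_true(all(out$pAdj <= 1))
  # monotone in the raw p-values
  set.seed(34)
  p <- runif(20)
  adj <- stats::p.adjust(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("cohort difference tests report A-minus-B means with BH correction", {
  set.seed(35)
  A <- matrix(rnorm(5 * 12, 72, 3), 5, 12, dimnames = list(paste0("r", 1:5)))
  expect_error(cohortDifferenceTests(A, A[1:3, ]), "region sets")
  # identical cohorts: zero differences, p = 1
  same <- cohortDifferenceTests(A, A)
  expect_equal(same$diff, rep(0, 5))
  expect_equal(same$p, rep(1, 5))
  # a constant shift appears exactly in the difference column
  sh <- cohortDifferenceTests(A + 2, A)
  expect_equal(sh$diff, rep(2, 5), tolerance = 1e-12)
  # dual-route: random cohorts against t.test
  B <- matrix(rnorm(5 * 10, 70, 3), 5, 10, dimnames = list(paste0("r", 1:5)))
  out <- cohortDifferenceTests(A, B)
  for (i in 1:5) {
    ref <- stats::t.test(A[i, ], B[i, ], var.equal = TRUE)
    expect_equal(out$t[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(out$p[i], ref$p.value, tolerance = 1e-12)
  }
})

test_that("sex bootstrap bins by integer age and is reproducible", {
  # identical maps for both sexes: degenerate distribution at 0
  sex <- rep(c("M", "F"), each = 10)
  ca <- rep(51:60, 2)
  g <- c(1:10, 1:10) * 0.1
  bs <- sexBootstrap(g, sex, ca, reps = 50, seed = 4)
  expect_equal(bs$global, rep(0, 50))
  expect_equal(bs$ci, c(0, 0))
  # one overlapping year, one subject per sex: point mass at the difference
  bs2 <- sexBootstrap(c(5, 3), c("M", "F"), c(70.2, 70.9), reps = 20, seed = 1)
  expect_equal(bs2$global, rep(2, 20))
  expect_identical(bs2$years, 70)
  # reproducibility is bitwise
  set.seed(36)
  g3 <- rnorm(40); sex3 <- rep(c("M", "F"), 20); ca3 <- runif(40, 60, 70)
  b1 <- sexBootstrap(g3, sex3, ca3, reps = 100, seed = 11)
  b2 <- sexBootstrap(g3, sex3, ca3, reps = 100, seed = 11)
  expect_identical(b1$global, b2$global)
  expect_error(sexBootstrap(c(1, 2), c("M", "F"), c(50.1, 80.5)),
               "overlapping")
})

test_that("a known male offset is recovered inside the bootstrap interval", {
  set.seed(37)
  n <- 200
  sex <- rep(c("M", "F"), n / 2)
  ca <- runif(n, 55, 75)
  g <- rnorm(n, 0, 1) + ifelse(sex == "M", 1, 0)
  bs <- sexBootstrap(g, sex, ca, reps = 500, seed = 8)
  expect_gt(bs$ci[2], 1); expect_lt(bs$ci[1], 1)   # interval covers the truth
  expect_equal(mean(bs$global), 1, tolerance = 0.3)
  # regional distributions carry the same structure: a male-only regional
  # offset appears in that region's male-minus-female differences
  reg <- rbind(r1 = g, r2 = g + 0.5 * (sex == "M"))
  bsr <- sexBootstrap(g, sex, ca, regional = reg, reps = 100, seed = 8)
  expect_equal(dim(bsr$regional), c(2L, 100L))
  expect_equal(mean(bsr$regional["r2", ] - bsr$regional["r1", ]), 0.5,
               tolerance = 1e-12)
})

test_that("cognition regression standardises, orients and excludes ceilings", {
  set.seed(38)
  n <- 120
  ca <- runif(n, 55, 85)
  sex <- rep(c("M", "F"), n / 2)
  edu <- sample(10:20, n, replace = TRUE)
  score <- rnorm(n, 50, 10)
  z <- (score - mean(score)) / sd(score)
  bag <- 2 * z                      # exact linear relation, no noise
  out <- suppressWarnings(   # the noise-free relation is a perfect fit
    cognitionRegression(bag, score, ca, sex, edu, testName = "adas11"))
  expect_equal(out$beta, 2, tolerance = 1e-8)
  expect_lt(out$p, 1e-12)
  # orientation flip: higher-is-better scores are negated before scaling
  outFlip <- suppressWarnings(
    cognitionRegression(bag, score, ca, sex, edu,
                        testName = "memory", higherIsWorse = FALSE))
  expect_equal(outFlip$beta, -2, tolerance = 1e-8)
  # TMT-B ceiling at 300 excluded
  score2 <- score; score2[1:10] <- 300
  out2 <- suppressWarnings(
    cognitionRegression(bag, score2, ca, sex, edu, testName = "tmtb"))
  expect_equal(out2$n, n - 10)
  # constant sex: collinearity error naming the column
  expect_error(cognitionRegression(bag, score, ca, rep("M", n), edu),
               "collinear.*sex")
  # cross-check the coefficient against a hand-built lm
  bag3 <- 1.5 * z + 0.1 * ca + rnorm(n, 0, 0.5)
  out3 <- cognitionRegression(bag3, score, ca, sex, edu, testName = "cdrsb")
  ref <- stats::lm(bag3 ~ z + ca + factor(sex) + edu)
  expect_equal(out3$beta, unname(coef(ref)["z"]), tolerance = 1e-10)
})

test_that("null cognition regressions are calibrated", {
  set.seed(39)
  reps <- 100
  pvals <- vapply(seq_len(reps), function(r) {
    n <- 500
    ca <- runif(n, 55, 85)
    sex <- sample(c("M", "F"), n, replace = TRUE)
    edu <- sample(8:20, n, replace = TRUE)
    bag <- rnorm(n)
    score <- rnorm(n)             # independent of bag
    cognitionRegression(bag, score, ca, sex, edu)$p
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("a battery of tests shares one BH family", {
  set.seed(40)
  n <- 80
  ca <- runif(n, 55, 85); sex <- rep(c("M", "F"), n / 2)
  edu <- sample(8:20, n, replace = TRUE)
  bag <- rnorm(n)
  scores <- list(adas11 = bag * 2 + rnorm(n, 0, 0.1), mmse = rnorm(n),
                 tmtb = rnorm(n, 150, 40))
  out <- cognitionBattery(bag, scores, ca, sex, edu,
                          higherIsWorse = c(mmse = FALSE))
  expect_equal(nrow(out), 3)
  expect_equal(out$pAdj, stats::p.adjust(out$p, "BH"))
})
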
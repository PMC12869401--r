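# Region-level group statistics: parcellation, regional means, independent
# t-tests with Benjamini-Hochberg correction, the chronological-age-binned
# sex bootstrap, and cognition regressions. t statistics are computed from
# the closed-form pooled-variance (or Welch) formulas; tests cross-check
# them against stats::t.test.

#' Deterministic geodesic-patch parcellation
#'
#' Splits each hemisphere's non-wall vertices into `nPerHemi` contiguous
#' patches: seed vertices are chosen by farthest-point sampling on graph
#' distance (starting from the lowest-index non-wall vertex; ties to the
#' lowest index), then every vertex joins its nearest seed (ties to the
#' lowest seed index). Wall vertices get label 0.
#'
#' @param mesh a joint [SurfaceMesh].
#' @param wall logical medial-wall mask (label 0 in the output).
#' @param nPerHemi regions per hemisphere.
#' @return integer vector of region labels (1..2*nPerHemi; 0 = wall), with
#'   region names in attribute `regionNames`.
#' @export
geodesicParcellation <- function(mesh, wall = rep(FALSE, nVertices(mesh)),
                                 nPerHemi = 8L) {
  adj <- meshAdjacency(mesh)
  n <- nVertices(mesh)
  labels <- integer(n)
  nextLabel <- 0L
  nms <- character(0)
  bfsDist <- function(sources, allowed) {
    d <- rep(NA_integer_, n)
    d[sources] <- 0L
    frontier <- sources
    step <- 0L
    while (length(frontier)) {
      step <- step + 1L
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[allowed[nxt] & is.na(d[nxt])]
      d[nxt] <- step
      frontier <- nxt
    }
    d
  }
  for (h in sort(unique(mesh@hemiId))) {
    allowed <- mesh@hemiId == h & !wall
    cand <- which(allowed)
    if (!length(cand)) next
    k <- min(nPerHemi, length(cand))
    seeds <- cand[1L]
    dmin <- bfsDist(seeds, allowed)
    while (length(seeds) < k) {
      far <- cand[which.max(dmin[cand])]  # which.max takes the first (lowest index) tie
      seeds <- c(seeds, far)
      dmin <- pmin(dmin, bfsDist(far, allowed), na.rm = TRUE)
    }
    # multi-source BFS, seed priority = seed order for ties
    lab <- integer(n)
    d <- rep(NA_integer_, n)
    for (si in seq_along(seeds)) { d[seeds[si]] <- 0L; lab[seeds[si]] <- si }
    frontier <- seeds
    while (length(frontier)) {
      frontier <- frontier[order(lab[frontier])]
      cand2 <- integer(0)
      for (v in frontier) {
        nb <- adj[[v]]
        nb <- nb[allowed[nb] & is.na(d[nb])]
        if (length(nb)) { d[nb] <- d[v] + 1L; lab[nb] <- lab[v]; cand2 <- c(cand2, nb) }
      }
      frontier <- cand2
    }
    labels[allowed] <- lab[allowed] + nextLabel
    nms <- c(nms, sprintf("%s_patch_%02d", if (h == 1L) "lh" else "rh", seq_len(k)))
    nextLabel <- nextLabel + k
  }
  attr(labels, "regionNames") <- nms
  labels
}

#' Read a label-per-vertex parcellation from a text file
#' @param path text file with one integer region label per line (0 = wall).
#' @return integer label vector.
#' @export
readParcellationText <- function(path) as.integer(readLines(path))

#' Region-averaged map values
#'
#' Unweighted mean of vertex values within each region, wall (label 0)
#' excluded. Regions with no working vertices are dropped with a warning.
#'
#' @param maps an [LbaMaps] (typically bias-corrected).
#' @param parcellation integer label per full-mesh vertex (0 = wall), e.g.
#'   from [geodesicParcellation].
#' @return matrix (regions x scans) with region labels as row names.
#' @export
regionalMeans <- function(maps, parcellation) {
  if (length(parcellation) != maps@nFull)
    stop("parcellation must label every vertex of the full mesh")
  lab <- parcellation[maps@vertexIndex]
  keep <- lab > 0L
  labs <- sort(unique(lab[keep]))
  missing <- setdiff(setdiff(sort(unique(parcellation)), 0L), labs)
  if (length(missing))
    warning(sprintf("dropping %d region(s) with no working vertices: %s",
                    length(missing), paste(missing, collapse = ", ")))
  out <- matrix(NA_real_, length(labs), ncol(maps@values),
                dimnames = list(as.character(labs), maps@scanIds))
  for (i in seq_along(labs)) {
    rows <- which(lab == labs[i])
    out[i, ] <- colMeans(maps@values[rows, , drop = FALSE])
  }
  out
}

# closed-form independent two-sample t-test (pooled variance or Welch)
.tTest <- function(x, y, welch = FALSE) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  d <- mean(x) - mean(y)
  if (welch) {
    se2 <- vx / nx + vy / ny
    if (se2 == 0) return(c(t = NA_real_, df = NA_real_, p = NA_real_, diff = d))
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    tt <- d / sqrt(se2)
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    df <- nx + ny - 2
    if (sp2 == 0) {
      if (d == 0) return(c(t = 0, df = df, p = 1, diff = 0))
      return(c(t = NA_real_, df = df, p = NA_real_, diff = d))
    }
    tt <- d / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  c(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df), diff = d)
}

#' Test regional predicted ages against chronological ages
#'
#' Per region, an independent two-tailed t-test (equal-variance by default)
#' between the vector of regional predicted ages and the vector of
#' chronological ages, with Benjamini-Hochberg adjustment across regions.
#' Regions whose adjusted p is >= `alpha` are flagged insignificant.
#'
#' @param regional matrix (regions x scans) from [regionalMeans].
#' @param ca chronological ages, one per scan.
#' @param welch use the Welch (unequal-variance) test.
#' @param alpha significance threshold on the adjusted p.
#' @return data.frame: region, meanLbag, t, df, p, pAdj, significant.
#' @export
regionVsCaTests <- function(regional, ca, welch = FALSE, alpha = 0.05) {
  if (ncol(regional) < 2L) stop("need at least 2 scans")
  res <- t(apply(regional, 1L, function(r) .tTest(r, ca, welch = welch)))
  out <- data.frame(region = rownames(regional),
                    meanLbag = rowMeans(regional) - mean(ca),
                    t = res[, "t"], df = res[, "df"], p = res[, "p"])
  out$pAdj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$pAdj) & out$pAdj < alpha
  rownames(out) <- NULL
  out
}

#' Compare regional predicted ages between two cohorts
#'
#' Per region, an independent two-tailed t-test of cohort A versus cohort B
#' regional values plus the difference of means (A - B), with
#' Benjamini-Hochberg adjustment across regions.
#'
#' @param regionalA,regionalB matrices (regions x scans) over the same
#'   region set.
#' @inheritParams regionVsCaTests
#' @return data.frame: region, diff (A - B, years), t, df, p, pAdj,
#'   significant.
#' @export
cohortDifferenceTests <- function(regionalA, regionalB, welch = FALSE,
                                  alpha = 0.05) {
  if (!identical(rownames(regionalA), rownames(regionalB)))
    stop("region sets differ between cohorts")
  if (ncol(regionalA) == 0L || ncol(regionalB) == 0L) stop("empty cohort")
  res <- t(vapply(seq_len(nrow(regionalA)), function(i)
    .tTest(regionalA[i, ], regionalB[i, ], welch = welch), numeric(4)))
  out <- data.frame(region = rownames(regionalA), diff = res[, "diff"],
                    t = res[, "t"], df = res[, "df"], p = res[, "p"])
  out$pAdj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$pAdj) & out$pAdj < alpha
  rownames(out) <- NULL
  out
}

#' Chronological-age-binned sex bootstrap of brain-age gaps
#'
#' For each bootstrap replicate: for every integer year of chronological age
#' present in both sexes, one male and one female are drawn uniformly at
#' random and the male-minus-female gap difference recorded; the replicate
#' value is the mean difference across years. Returns the replicate
#' distribution (globally and, when regional gaps are supplied, per region)
#' with percentile intervals.
#'
#' @param gbagValues numeric global gap per scan (years).
#' @param sex character/factor per scan with levels containing "M" and "F".
#' @param ca chronological ages per scan (years; binned by `floor`).
#' @param regional optional matrix (regions x scans) of regional gaps.
#' @param reps bootstrap replicates.
#' @param seed RNG seed (replicate draws are reproducible bit-for-bit).
#' @param level confidence level of the percentile interval.
#' @return list with `global` (replicate vector), `ci` (percentile bounds),
#'   `regional` (regions x reps matrix or NULL), `regionalCi`, `years` used.
#' @export
sexBootstrap <- function(gbagValues, sex, ca, regional = NULL, reps = 500L,
                         seed = 1L, level = 0.95) {
  sex <- as.character(sex)
  yr <- floor(ca)
  yearsM <- unique(yr[sex == "M"])
  yearsF <- unique(yr[sex == "F"])
  years <- sort(intersect(yearsM, yearsF))
  if (!length(years)) stop("no overlapping integer years of age between sexes")
  idxM <- lapply(years, function(y) which(sex == "M" & yr == y))
  idxF <- lapply(years, function(y) which(sex == "F" & yr == y))
  set.seed(seed)
  global <- numeric(reps)
  reg <- if (!is.null(regional)) matrix(0, nrow(regional), reps,
                                        dimnames = list(rownames(regional), NULL))
  for (r in seq_len(reps)) {
    mi <- vapply(idxM, function(v) v[sample.int(length(v), 1L)], integer(1))
    fi <- vapply(idxF, function(v) v[sample.int(length(v), 1L)], integer(1))
    global[r] <- mean(gbagValues[mi] - gbagValues[fi])
    if (!is.null(regional))
      reg[, r] <- rowMeans(regional[, mi, drop = FALSE] -
                             regional[, fi, drop = FALSE])
  }
  a <- (1 - level) / 2
  out <- list(global = global,
              ci = stats::quantile(global, c(a, 1 - a), names = FALSE),
              years = years)
  if (!is.null(regional)) {
    out$regional <- reg
    out$regionalCi <- t(apply(reg, 1L, stats::quantile, probs = c(a, 1 - a)))
  }
  out
}

#' Regress brain-age gaps on a cognitive score
#'
#' Ordinary least squares of the gap on the standardised score, controlling
#' for chronological age, sex and education years. Trail Making Test B
#' scores equal to 300 are excluded (ceiling). The score is z-standardised
#' on the included scans and sign-flipped when `higherIsWorse = FALSE`, so
#' that higher always means worse performance and coefficients are
#' comparable across tests.
#'
#' @param bag numeric gap per scan (years).
#' @param score numeric cognitive score per scan (NAs dropped).
#' @param ca,sex,education covariates per scan.
#' @param testName name of the cognitive test; when it matches "tmt" and
#'   `excludeCeiling` is TRUE, scores equal to 300 are excluded.
#' @param higherIsWorse orientation of the raw score.
#' @param excludeCeiling apply the TMT-B 300 exclusion.
#' @return one-row data.frame: test, beta (years per SD of score), se, t, p,
#'   n; the standardisation constants and sign flip are attached as
#'   attribute `transform`.
#' @export
cognitionRegression <- function(bag, score, ca, sex, education,
                                testName = "score", higherIsWorse = TRUE,
                                excludeCeiling = grepl("tmt", tolower(testName))) {
  keep <- !is.na(score) & !is.na(bag)
  if (excludeCeiling) keep <- keep & score != 300
  n <- sum(keep)
  if (n < 5L) stop("fewer than 5 complete cases after exclusions")
  sc <- score[keep]
  sgn <- if (higherIsWorse) 1 else -1
  mu <- mean(sc); sdev <- stats::sd(sc)
  if (sdev == 0) stop("score has zero variance after exclusions")
  z <- sgn * (sc - mu) / sdev
  sexNum <- as.integer(factor(as.character(sex[keep]))) - 1L
  df <- data.frame(bag = bag[keep], z = z, ca = ca[keep], sex = sexNum,
                   edu = education[keep])
  X <- stats::model.matrix(~ z + ca + sex + edu, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("collinear design: column(s) %s", paste(bad, collapse = ", ")))
  }
  fit <- stats::lm(bag ~ z + ca + sex + edu, data = df)
  co <- summary(fit)$coefficients["z", ]
  out <- data.frame(test = testName, beta = co[["Estimate"]],
                    se = co[["Std. Error"]], t = co[["t value"]],
                    p = co[["Pr(>|t|)"]], n = n)
  attr(out, "transform") <- list(mean = mu, sd = sdev, signFlip = sgn == -1)
  out
}

#' Run cognition regressions for a battery of tests with BH correction
#'
#' One [cognitionRegression] per test, Benjamini-Hochberg adjustment across
#' the battery (one family per cohort).
#'
#' @param bag numeric gap per scan.
#' @param scores data.frame/list of score vectors, one per test.
#' @param ca,sex,education covariates per scan.
#' @param higherIsWorse named logical per test (default TRUE).
#' @return data.frame with one row per test including pAdj.
#' @export
cognitionBattery <- function(bag, scores, ca, sex, education,
                             higherIsWorse = NULL) {
  tests <- names(scores)
  rows <- lapply(tests, function(tn) {
    hw <- if (!is.null(higherIsWorse) && tn %in% names(higherIsWorse))
      higherIsWorse[[tn]] else TRUE
    cognitionRegression(bag, scores[[tn]], ca, sex, education,
                        testName = tn, higherIsWorse = hw)
  })
  out <- do.call(rbind, rows)
  out$pAdj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
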
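# Graph U-Net for vertex-level age prediction.
#
# The network runs on L nested atlas resolutions (hierarchy level 1 =
# coarsest .. L = finest). Encoder (finest -> coarsest): graph convolution,
# batch normalisation, ReLU at each level, receptive-field average pooling
# between levels. Decoder (coarsest -> finest): inverse-field average
# unpooling, concatenation with the encoder skip tensor of the same level,
# then graph convolution + BN + ReLU. The output block is a single graph
# convolution to one feature per vertex (no BN, no ReLU) — the local brain
# age. Loss is the vertex-wise mean absolute error against chronological age
# broadcast to every vertex; optimisation is Adam.
#
# Batches are processed as sample-major stacked matrices ((B*V) x F); the
# per-level graph and pooling operators are expanded to block diagonals once
# per batch size and cached. Batch-norm statistics are therefore taken over
# all vertices of all graphs in a batch, and all gradients (including the
# gradient with respect to the input, needed for integrated gradients) are
# computed by an explicit reverse pass over the same block sequence.

#' Symmetrically normalised adjacency with self-loops
#'
#' \eqn{\hat A = \tilde D^{-1/2} (A + I) \tilde D^{-1/2}} where degrees
#' include the self-loop — the propagation operator of the spectral graph
#' convolution used throughout the network.
#'
#' @param graph a [SurfaceMesh] or a sparse 0/1 adjacency matrix without
#'   self-loops.
#' @return sparse symmetric matrix.
#' @export
normalizedAdjacency <- function(graph) {
  A <- if (is(graph, "SurfaceMesh")) adjacencyMatrix(graph) else graph
  A <- A + Matrix::Diagonal(nrow(A))
  dis <- 1 / sqrt(Matrix::rowSums(A))
  Matrix::Diagonal(x = dis) %*% A %*% Matrix::Diagonal(x = dis)
}

#' One graph convolution layer
#'
#' Computes \eqn{\hat A X W + b}: self-loops added, adjacency symmetrically
#' normalised by inverse-sqrt degree, neighbour features aggregated, then a
#' learned linear map plus bias. The output at a vertex depends only on its
#' closed 1-hop neighbourhood.
#'
#' @param x per-vertex feature matrix (V x Fin).
#' @param graph a [SurfaceMesh], sparse adjacency, or pre-normalised operator
#'   (pass `normalized = TRUE` for the latter).
#' @param W weight matrix (Fin x Fout).
#' @param b bias vector (length Fout).
#' @param normalized set TRUE when `graph` is already a normalised operator.
#' @return matrix V x Fout.
#' @export
gcnLayer <- function(x, graph, W, b = rep(0, ncol(W)), normalized = FALSE) {
  x <- as.matrix(x)
  if (nrow(W) != ncol(x))
    stop(sprintf("weight rows (%d) must match feature columns (%d)", nrow(W), ncol(x)))
  Ahat <- if (normalized) graph else normalizedAdjacency(graph)
  out <- as.matrix(Ahat %*% x %*% W)
  sweep(out, 2L, b, "+")
}

#' Graph U-Net configuration
#'
#' @param featureWidths integer vector, one width per hierarchy level ordered
#'   finest-first: input features F0, then the encoder output widths. The
#'   reference configuration is `c(5, 8, 16)`.
#' @param epochs training epochs.
#' @param batchSize scans per optimisation step.
#' @param learningRate Adam learning rate.
#' @param seed integer seed controlling initialisation and batch shuffling.
#' @param maskWallLoss if TRUE, medial-wall vertices are excluded from the
#'   training loss (by default they are included; the wall is removed only
#'   after training).
#' @param bnMomentum,bnEps batch-normalisation running-average momentum and
#'   variance floor.
#' @return a named list.
#' @export
unetConfig <- function(featureWidths = c(5L, 8L, 16L), epochs = 50L,
                       batchSize = 128L, learningRate = 0.01, seed = 1L,
                       maskWallLoss = FALSE, bnMomentum = 0.1, bnEps = 1e-5) {
  stopifnot(length(featureWidths) >= 2L, all(featureWidths >= 1L),
            epochs >= 1L, batchSize >= 1L, learningRate > 0)
  list(featureWidths = as.integer(featureWidths), epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), learningRate = learningRate,
       seed = as.integer(seed), maskWallLoss = isTRUE(maskWallLoss),
       bnMomentum = bnMomentum, bnEps = bnEps)
}

# ---- layer bookkeeping ------------------------------------------------------
# Hierarchy levels are numbered 1 (coarsest) .. L (finest); featureWidths w
# is ordered finest-first with w[1] = F0. Encoder block at level l maps
# w[L-l+1] -> w[L-l+2]; the bottleneck at level 1 maps w[L] -> w[L]; the
# decoder block at level l mirrors its encoder partner.

.layerSpecs <- function(L, w) {
  stopifnot(length(w) == L)
  specs <- list()
  for (l in L:2) {
    j <- L - l + 1L
    specs[[paste0("enc", l)]] <- list(fin = w[j], fout = w[j + 1L], level = l, bn = TRUE)
  }
  specs[["bot"]] <- list(fin = w[L], fout = w[L], level = 1L, bn = TRUE)
  for (l in 2:L) {
    skipW <- w[L - l + 2L]
    belowW <- if (l == 2L) w[L] else w[L - l + 3L]
    specs[[paste0("dec", l)]] <- list(fin = belowW + skipW, fout = skipW,
                                      level = l, bn = TRUE, upWidth = belowW)
  }
  specs[["out"]] <- list(fin = w[2L], fout = 1L, level = L, bn = FALSE)
  specs
}

.glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

# outBias: initial value of the output-layer bias. For an age regressor this
# is set to the training-set mean age so the optimiser starts from a sensible
# constant predictor instead of 0 years.
.initParams <- function(specs, outBias = 0) {
  params <- list()
  bn <- list()
  for (id in names(specs)) {
    s <- specs[[id]]
    params[[paste0(id, ".W")]] <- .glorot(s$fin, s$fout)
    params[[paste0(id, ".b")]] <- numeric(s$fout)
    if (isTRUE(s$bn)) {
      params[[paste0(id, ".gamma")]] <- rep(1, s$fout)
      params[[paste0(id, ".beta")]] <- numeric(s$fout)
      bn[[id]] <- list(mean = numeric(s$fout), var = rep(1, s$fout))
    }
  }
  params[["out.b"]] <- rep(outBias, specs[["out"]]$fout)
  list(params = params, bn = bn)
}

# fast column-wise ops (compiled kernels) and dense extraction without the
# dgeMatrix -> matrix copy through as()
.colAdd <- function(x, v) .gmColAdd(x, rep_len(as.numeric(v), ncol(x)))
.colMul <- function(x, v) .gmScaleShift(x, rep_len(as.numeric(v), ncol(x)),
                                        numeric(ncol(x)))
.dense <- function(m) {
  if (methods::is(m, "dgeMatrix")) { x <- m@x; dim(x) <- m@Dim; x } else as.matrix(m)
}

# Block-diagonal batch operators for batch size B (cached per B by callers).
.batchOps <- function(hierarchy, rfMaps, B) {
  L <- nLevels(hierarchy)
  A <- lapply(seq_len(L), function(l) {
    Ah <- normalizedAdjacency(levelMesh(hierarchy, l))
    if (B == 1L) Ah else Matrix::bdiag(rep(list(Ah), B))
  })
  Pd <- vector("list", L - 1L); Pu <- vector("list", L - 1L); Put <- vector("list", L - 1L); Pdt <- vector("list", L - 1L)
  for (i in seq_len(L - 1L)) {
    pd <- poolDownMatrix(rfMaps[[i]])
    pu <- poolUpMatrix(rfMaps[[i]], fineMesh = levelMesh(hierarchy, i + 1L))
    if (B > 1L) {
      pd <- Matrix::bdiag(rep(list(pd), B))
      pu <- Matrix::bdiag(rep(list(pu), B))
    }
    Pd[[i]] <- pd; Pu[[i]] <- pu
    Pdt[[i]] <- Matrix::t(pd); Put[[i]] <- Matrix::t(pu)
  }
  list(A = A, Pd = Pd, Pu = Pu, Pdt = Pdt, Put = Put, B = B)
}

# ---- forward / backward -----------------------------------------------------

.bnForward <- function(x, gamma, beta, stats, mode, momentum, eps) {
  if (mode == "train") {
    r <- .gmBnTrainForward(x, gamma, beta, eps)
    newStats <- list(mean = (1 - momentum) * stats$mean + momentum * r$mu,
                     var = (1 - momentum) * stats$var + momentum * r$var)
    list(y = r$y, cache = list(xhat = r$xhat, sd = r$sd), stats = newStats)
  } else {
    scale <- gamma / sqrt(stats$var + eps)
    y <- .gmScaleShift(x, scale, beta - stats$mean * scale)
    list(y = y, cache = list(scale = scale), stats = stats)
  }
}

.bnBackward <- function(dy, gamma, cache, mode) {
  if (mode == "train") {
    r <- .gmBnTrainBackward(dy, gamma, cache$xhat, cache$sd)
    list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
  } else {
    list(dx = .colMul(dy, cache$scale), dgamma = NULL, dbeta = NULL)
  }
}

# GCN + (optional BN) + (optional ReLU) block
.blockForward <- function(H, A, params, bnStats, id, hasBn, hasRelu, mode,
                          momentum, eps) {
  AH <- .dense(A %*% H)
  Z <- .colAdd(AH %*% params[[paste0(id, ".W")]], params[[paste0(id, ".b")]])
  cache <- list(AH = AH)
  stats <- bnStats[[id]]
  if (hasBn) {
    bnres <- .bnForward(Z, params[[paste0(id, ".gamma")]],
                        params[[paste0(id, ".beta")]], stats, mode, momentum, eps)
    Z2 <- bnres$y
    cache$bn <- bnres$cache
    stats <- bnres$stats
  } else Z2 <- Z
  if (hasRelu) {
    r <- .gmReluForward(Z2)
    out <- r$out
    cache$relu <- r$mask
  } else out <- Z2
  list(out = out, cache = cache, stats = stats)
}

.blockBackward <- function(dout, A, params, id, cache, hasBn, hasRelu, mode, grads) {
  if (hasRelu) dout <- dout * cache$relu
  if (hasBn) {
    bb <- .bnBackward(dout, params[[paste0(id, ".gamma")]], cache$bn, mode)
    dout <- bb$dx
    if (mode == "train") {
      grads[[paste0(id, ".gamma")]] <- bb$dgamma
      grads[[paste0(id, ".beta")]] <- bb$dbeta
    }
  }
  W <- params[[paste0(id, ".W")]]
  if (mode == "train") {
    grads[[paste0(id, ".W")]] <- base::crossprod(cache$AH, dout)
    grads[[paste0(id, ".b")]] <- base::colSums(dout)
  }
  # A is symmetric, so the adjoint of H -> A H is A itself
  dH <- .dense(A %*% base::tcrossprod(dout, W))
  list(dH = dH, grads = grads)
}

.forwardUNet <- function(params, bnStats, X, ops, L, mode, momentum, eps) {
  caches <- list()
  skips <- vector("list", L)
  H <- X
  for (l in L:2) {
    id <- paste0("enc", l)
    r <- .blockForward(H, ops$A[[l]], params, bnStats, id, TRUE, TRUE, mode, momentum, eps)
    bnStats[[id]] <- r$stats
    caches[[id]] <- r$cache
    skips[[l]] <- r$out
    H <- .dense(ops$Pd[[l - 1L]] %*% r$out)
  }
  r <- .blockForward(H, ops$A[[1L]], params, bnStats, "bot", TRUE, TRUE, mode, momentum, eps)
  bnStats[["bot"]] <- r$stats
  caches[["bot"]] <- r$cache
  H <- r$out
  for (l in 2:L) {
    id <- paste0("dec", l)
    U <- .dense(ops$Pu[[l - 1L]] %*% H)
    C <- cbind(U, skips[[l]])
    r <- .blockForward(C, ops$A[[l]], params, bnStats, id, TRUE, TRUE, mode, momentum, eps)
    bnStats[[id]] <- r$stats
    caches[[id]] <- r$cache
    caches[[paste0(id, ".upWidth")]] <- ncol(U)
    H <- r$out
  }
  r <- .blockForward(H, ops$A[[L]], params, bnStats, "out", FALSE, FALSE, mode, momentum, eps)
  caches[["out"]] <- r$cache
  list(Y = r$out, caches = caches, bnStats = bnStats)
}

.backwardUNet <- function(dY, params, caches, ops, L, mode) {
  grads <- list()
  bb <- .blockBackward(dY, ops$A[[L]], params, "out", caches[["out"]],
                       FALSE, FALSE, mode, grads)
  grads <- bb$grads
  G <- bb$dH
  dSkip <- vector("list", L)
  for (l in L:2) {
    id <- paste0("dec", l)
    bb <- .blockBackward(G, ops$A[[l]], params, id, caches[[id]],
                         TRUE, TRUE, mode, grads)
    grads <- bb$grads
    uw <- caches[[paste0(id, ".upWidth")]]
    dU <- bb$dH[, seq_len(uw), drop = FALSE]
    dSkip[[l]] <- bb$dH[, uw + seq_len(ncol(bb$dH) - uw), drop = FALSE]
    G <- .dense(ops$Put[[l - 1L]] %*% dU)
  }
  bb <- .blockBackward(G, ops$A[[1L]], params, "bot", caches[["bot"]],
                       TRUE, TRUE, mode, grads)
  grads <- bb$grads
  G <- bb$dH
  for (l in 2:L) {
    id <- paste0("enc", l)
    dS <- .dense(ops$Pdt[[l - 1L]] %*% G) + dSkip[[l]]
    bb <- .blockBackward(dS, ops$A[[l]], params, id, caches[[id]],
                         TRUE, TRUE, mode, grads)
    grads <- bb$grads
    G <- bb$dH
  }
  list(grads = grads, dX = G)
}

.adamStep <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# ---- training / prediction --------------------------------------------------

#' Train a graph U-Net on a cohort
#'
#' Standardises each input feature to z-scores using training-set global
#' mean/SD (stored with the model), then minimises the mean absolute error
#' between per-vertex predicted age and chronological age broadcast to every
#' vertex, with Adam over shuffled mini-batches. Medial-wall vertices are
#' included in the loss by default (the wall is removed only after training);
#' set `maskWallLoss = TRUE` in the config to exclude them.
#'
#' @param cohort a [SurfaceCohort] of training scans.
#' @param config a configuration from [unetConfig]; `featureWidths[1]` must
#'   equal the number of assays.
#' @param rfMaps optional precomputed list of receptive-field maps (built
#'   from the cohort hierarchy when omitted).
#' @param verbose print the loss every few epochs.
#' @return a trained [GraphUNet] (loss history in years via
#'   [lossHistory]).
#' @export
trainGraphUNet <- function(cohort, config = unetConfig(), rfMaps = NULL,
                           verbose = FALSE) {
  if (ncol(cohort) == 0L) stop("empty cohort")
  hierarchy <- cohortHierarchy(cohort)
  L <- nLevels(hierarchy)
  if (length(config$featureWidths) != L)
    stop("featureWidths must have one entry per hierarchy level")
  if (config$featureWidths[1L] != length(assayNames(cohort)))
    stop(sprintf("featureWidths[1] (%d) must equal the number of feature assays (%d)",
                 config$featureWidths[1L], length(assayNames(cohort))))
  if (is.null(rfMaps)) rfMaps <- hierarchyReceptiveFields(hierarchy)
  n <- ncol(cohort)
  V <- nrow(cohort)
  ca <- chronoAge(cohort)

  Xall <- .stackFeatures(cohort)                      # (n*V) x F, sample-major
  fmean <- colMeans(Xall)
  fsd <- apply(Xall, 2L, stats::sd)
  fsd[fsd == 0] <- 1
  Xall <- sweep(sweep(Xall, 2L, fmean), 2L, fsd, "/")

  specs <- .layerSpecs(L, config$featureWidths)
  set.seed(config$seed)
  init <- .initParams(specs, outBias = mean(ca))
  params <- init$params
  bnStats <- init$bn
  adam <- list(m = list(), v = list(), t = 0L)
  opsCache <- list()
  wallW <- if (config$maskWallLoss) as.numeric(!medialWall(hierarchy)) else rep(1, V)

  lossHist <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batchSize)
    epochLoss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batchSize - 1L, n)]
      B <- length(idx)
      key <- as.character(B)
      if (is.null(opsCache[[key]]))
        opsCache[[key]] <- .batchOps(hierarchy, rfMaps, B)
      ops <- opsCache[[key]]
      rows <- rep((idx - 1L) * V, each = V) + seq_len(V)
      X <- Xall[rows, , drop = FALSE]
      y <- rep(ca[idx], each = V)
      w <- rep(wallW, times = B)
      fw <- .forwardUNet(params, bnStats, X, ops, L, "train",
                         config$bnMomentum, config$bnEps)
      bnStats <- fw$bnStats
      resid <- as.numeric(fw$Y) - y
      sw <- sum(w)
      loss <- sum(w * abs(resid)) / sw
      dY <- matrix(w * sign(resid) / sw, ncol = 1L)
      bw <- .backwardUNet(dY, params, fw$caches, ops, L, "train")
      upd <- .adamStep(params, bw$grads, adam, config$learningRate)
      params <- upd$params
      adam <- upd$state
      epochLoss <- epochLoss + loss * B
    }
    lossHist[epoch] <- epochLoss / n
    if (verbose && (epoch %% max(1L, config$epochs %/% 10L) == 0L))
      message(sprintf("epoch %d/%d: loss %.3f y", epoch, config$epochs, lossHist[epoch]))
  }
  new("GraphUNet", config = config, params = params, bnStats = bnStats,
      featureStats = list(mean = fmean, sd = fsd), lossHistory = lossHist,
      hierarchy = hierarchy, rfMaps = rfMaps)
}

#' Training-loss history of a model (years per epoch)
#' @param model a [GraphUNet]
#' @export
lossHistory <- function(model) model@lossHistory

setMethod("show", "GraphUNet", function(object) {
  cat(sprintf("GraphUNet: %d levels, widths %s; %d epochs trained, final loss %.3f y\n",
              nLevels(object@hierarchy),
              paste(object@config$featureWidths, collapse = "/"),
              length(object@lossHistory),
              if (length(object@lossHistory)) utils::tail(object@lossHistory, 1) else NA_real_))
})

#' Predict local brain age maps
#'
#' Deterministic inference: features are standardised with the stored
#' training statistics and batch normalisation uses the stored running
#' statistics.
#'
#' @param model a trained [GraphUNet].
#' @param cohort a [SurfaceCohort] bound to the same hierarchy geometry.
#' @param batchSize scans per forward pass.
#' @return an [LbaMaps] with stage "raw" at the full finest-level vertex set.
#' @export
predictLba <- function(model, cohort, batchSize = 32L) {
  hierarchy <- model@hierarchy
  L <- nLevels(hierarchy)
  V <- nVertices(levelMesh(hierarchy, "finest"))
  if (nrow(cohort) != V) stop("cohort is not bound to the model's hierarchy")
  n <- ncol(cohort)
  out <- matrix(NA_real_, V, n)
  opsCache <- list()
  for (s in seq(1L, n, by = batchSize)) {
    idx <- s:min(s + batchSize - 1L, n)
    B <- length(idx)
    key <- as.character(B)
    if (is.null(opsCache[[key]]))
      opsCache[[key]] <- .batchOps(hierarchy, model@rfMaps, B)
    X <- .stackFeatures(cohort, idx)
    X <- sweep(sweep(X, 2L, model@featureStats$mean), 2L, model@featureStats$sd, "/")
    fw <- .forwardUNet(model@params, model@bnStats, X, opsCache[[key]], L,
                       "eval", model@config$bnMomentum, model@config$bnEps)
    out[, idx] <- matrix(as.numeric(fw$Y), V, B)
  }
  ids <- colnames(cohort)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  new("LbaMaps", values = out, vertexIndex = seq_len(V), nFull = V,
      stage = "raw", scanIds = ids)
}

#' Mean absolute error of predicted age maps
#'
#' Mean over scans of the per-scan mean over (non-excluded) vertices of
#' |predicted age - chronological age|, computed before bias correction.
#'
#' @param maps an [LbaMaps].
#' @param ca chronological ages (years), one per scan.
#' @return MAE in years.
#' @export
evaluateMae <- function(maps, ca) {
  if (length(ca) != ncol(maps@values)) stop("one age per scan required")
  mean(colMeans(abs(sweep(maps@values, 2L, ca))))
}
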
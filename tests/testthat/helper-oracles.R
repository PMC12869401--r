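# Shared fixtures and independent oracles. Everything here is deliberately
# written as straight-line/dense/loop code, structured differently from the
# package implementation it checks.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

tiny_hierarchy <- function(levels = 0:1) {
  cached(paste0("hier_", paste(levels, collapse = "_")),
         buildAtlasHierarchy(levels))
}

# dense normalised adjacency straight from faces (loop construction)
dense_norm_adj <- function(mesh) {
  n <- nVertices(mesh)
  A <- matrix(0, n, n)
  f <- meshFaces(mesh)
  for (r in seq_len(nrow(f))) {
    tri <- f[r, ]
    for (pair in list(c(1, 2), c(2, 3), c(3, 1))) {
      A[tri[pair[1]], tri[pair[2]]] <- 1
      A[tri[pair[2]], tri[pair[1]]] <- 1
    }
  }
  diag(A) <- 1
  d <- rowSums(A)
  diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
}

# dense GCN oracle for an arbitrary 0/1 adjacency matrix (no self-loops)
ref_gcn <- function(X, A01, W, b) {
  At <- A01 + diag(nrow(A01))
  d <- rowSums(At)
  Ah <- diag(1 / sqrt(d)) %*% At %*% diag(1 / sqrt(d))
  Ah %*% X %*% W + outer(rep(1, nrow(X)), b)
}

# loop oracle for receptive-field pooling
ref_pool_down <- function(X, rf) {
  fields <- receptiveFields(rf)
  out <- matrix(0, length(fields), ncol(X))
  for (v in seq_along(fields))
    out[v, ] <- colMeans(X[fields[[v]], , drop = FALSE])
  out
}

ref_pool_up <- function(X, rf) {
  inv <- inverseFields(rf)
  out <- matrix(NA_real_, length(inv), ncol(X))
  for (u in seq_along(inv))
    if (length(inv[[u]]))
      out[u, ] <- colMeans(X[inv[[u]], , drop = FALSE])
  out
}

# straight-line dense reference of the whole U-Net in inference mode,
# one sample at a time (no batching, no sparse algebra)
ref_unet_eval <- function(params, bnStats, X, hier, rfMaps, eps = 1e-5) {
  L <- length(hier@meshes)
  Ah <- lapply(seq_len(L), function(l) dense_norm_adj(levelMesh(hier, l)))
  bn_eval <- function(Z, id) {
    g <- params[[paste0(id, ".gamma")]]
    be <- params[[paste0(id, ".beta")]]
    st <- bnStats[[id]]
    for (j in seq_len(ncol(Z)))
      Z[, j] <- g[j] * (Z[, j] - st$mean[j]) / sqrt(st$var[j] + eps) + be[j]
    Z
  }
  block <- function(H, id, l, bnRelu = TRUE) {
    Z <- Ah[[l]] %*% H %*% params[[paste0(id, ".W")]]
    Z <- Z + outer(rep(1, nrow(Z)), params[[paste0(id, ".b")]])
    if (bnRelu) {
      Z <- bn_eval(Z, id)
      Z[Z < 0] <- 0
    }
    Z
  }
  skips <- vector("list", L)
  H <- X
  for (l in L:2) {
    H <- block(H, paste0("enc", l), l)
    skips[[l]] <- H
    H <- ref_pool_down(H, rfMaps[[l - 1]])
  }
  H <- block(H, "bot", 1)
  for (l in 2:L) {
    U <- ref_pool_up(H, rfMaps[[l - 1]])
    H <- block(cbind(U, skips[[l]]), paste0("dec", l), l)
  }
  as.numeric(block(H, "out", L, bnRelu = FALSE))
}

# small trained model on a lesion-free synthetic cohort, reused by several
# test files
trained_tiny_model <- function() {
  cached("trained_tiny", {
    cfg <- simConfig(levels = 0:1, nSubjects = 40L, seed = 3L,
                     lesionFraction = 0)
    co <- simulateCohort(cfg)
    mc <- unetConfig(featureWidths = c(5L, 8L), epochs = 40L,
                     batchSize = 16L, seed = 2L)
    list(cohort = co, model = trainGraphUNet(co, mc))
  })
}

random_lba_maps <- function(V, n, seed = 1, mean = 70, sd = 5) {
  set.seed(seed)
  LbaMaps(matrix(rnorm(V * n, mean, sd), V, n))
}

# Model whose network is affine on the whole line segment used by the path
# integral: large positive batch-norm shifts keep every ReLU active, so
# gradients are constant and integrated gradients have a closed form.
affine_model <- function() {
  cached("affine_model", {
    h <- tiny_hierarchy(0:1)
    rf <- hierarchyReceptiveFields(h)
    set.seed(21)
    specs <- geromorph:::.layerSpecs(2L, c(3L, 4L))
    init <- geromorph:::.initParams(specs, outBias = 60)
    params <- init$params
    for (nm in names(params)) {
      if (grepl("\\.W$", nm)) params[[nm]] <- params[[nm]] * 0.2
      if (grepl("beta", nm)) params[[nm]] <- params[[nm]] + 30  # ReLU always on
    }
    new("GraphUNet", config = unetConfig(featureWidths = c(3L, 4L), seed = 1L),
        params = params, bnStats = init$bn,
        featureStats = list(mean = c(a = 0, b = 0, c = 0),
                            sd = c(a = 1, b = 1, c = 1)),
        lossHistory = numeric(0), hierarchy = h, rfMaps = rf)
  })
}
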
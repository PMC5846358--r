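# small helper: a hand-built model around given codebook weights
manual_model <- function(W, rows, cols, norm = NULL) {
  structure(list(som_rows = rows, som_cols = cols, weights = W,
                 grid = expand.grid(row = seq_len(rows), col = seq_len(cols)),
                 epochs = 0, alpha0 = 0, alphaT = 0, sigma0 = 1, sigmaT = 1,
                 seed = 0, normalization = norm, qe_history = numeric(0)),
            class = "som_model")
}

test_that("min-max normalization scales, inverts and reuses training stats", {
  fm <- data.frame(subject_id = "s", phase = "before", segment = 1:3,
                   speed = c(0, 5, 10), acceleration = c(1, 2, 4),
                   locomotory_rate = c(0, 5, 11), stop_number = c(0, 1, 2),
                   stop_time = c(0, 2.5, 5), turning_rate = c(0, 1, 3),
                   meander = c(0, 0.5, 2))
  norm <- normalize_features(fm)
  expect_equal(unname(norm$data[, "speed"]), c(0, 0.5, 1))
  back <- denormalize_features(norm$stats, norm$data)
  expect_equal(unname(back),
               unname(as.matrix(fm[, feature_names()])), tolerance = 1e-9)

  # held-out vector is scaled with training stats, not its own range
  held <- fm[1, ]; held$speed <- 20
  hn <- apply_normalization(norm$stats, held)
  expect_equal(unname(hn[, "speed"]), 2)   # beyond [0,1]: training min/max used

  fm$speed <- 3
  expect_error(normalize_features(fm), "speed")
})

test_that("the sequential update rule follows the Kohonen equation", {
  # single node, h = 1, alpha = 0.5, w = 0, x = 1 -> w becomes 0.5
  W <- matrix(0, 1, 7)
  W1 <- daphtrack:::som_update_step(W, rep(1, 7), data.frame(row = 1, col = 1),
                                    alpha = 0.5, sigma = 1)
  expect_equal(as.vector(W1), rep(0.5, 7))

  # neighborhood scales the pull: node at lattice distance 1, sigma = 1
  W <- matrix(0, 2, 1)
  W[2, 1] <- 10   # winner for x = 8 is node 2
  grid <- data.frame(row = 1:2, col = 1)
  W1 <- daphtrack:::som_update_step(W, 8, grid, alpha = 1, sigma = 1)
  expect_equal(W1[2, 1], 8)                       # winner jumps to x
  expect_equal(W1[1, 1], exp(-0.5) * 8)           # neighbor pulled by h
})

test_that("training has the contractive fixed point and zero-rate identity", {
  v <- c(0.2, 0.4, 0.6, 0.8, 0.1, 0.3, 0.5)
  X <- matrix(rep(v, each = 30), nrow = 30)
  m <- train_som(X, som_rows = 2, som_cols = 2, epochs = 10, seed = 1)
  expect_lt(max(abs(sweep(m$weights, 2, v))), 1e-3)

  # alpha = 0 leaves the (seeded, data-sampled) initialization untouched
  set.seed(123)
  Xr <- matrix(runif(50 * 7), 50, 7)
  m0 <- train_som(Xr, som_rows = 3, som_cols = 3, epochs = 3,
                  alpha0 = 0, alphaT = 0, seed = 77)
  set.seed(77)
  init <- Xr[sample.int(50, 9), ]
  expect_equal(unname(m0$weights), unname(init), tolerance = 1e-12)

  expect_error(train_som(Xr[0, , drop = FALSE]), "empty")
  Xb <- Xr; Xb[3, 2] <- NA
  expect_error(train_som(Xb), "non-finite")
})

test_that("training is bit-for-bit deterministic for a fixed seed", {
  set.seed(99)
  X <- matrix(runif(80 * 7), 80, 7)
  m1 <- train_som(X, som_rows = 4, som_cols = 4, epochs = 3, seed = 5)
  m2 <- train_som(X, som_rows = 4, som_cols = 4, epochs = 3, seed = 5)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_som(X, som_rows = 4, som_cols = 4, epochs = 3, seed = 6)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("with a vanishing neighborhood training reduces to online k-means", {
  set.seed(31)
  X <- matrix(runif(40 * 3), 40, 3)
  R <- 2; C <- 2; epochs <- 2; a0 <- 0.3; aT <- 0.05; seed <- 8
  m <- train_som(X, som_rows = R, som_cols = C, epochs = epochs,
                 alpha0 = a0, alphaT = aT, sigma0 = 1e-9, sigmaT = 1e-9,
                 seed = seed)
  # independent online k-means replay: winner-only updates, same schedule
  set.seed(seed)
  W <- X[sample.int(nrow(X), R * C), ]
  total <- epochs * nrow(X); tp <- 0
  for (ep in seq_len(epochs)) {
    for (i in sample.int(nrow(X))) {
      alpha <- a0 + (aT - a0) * tp / (total - 1)
      win <- which.min(colSums((t(W) - X[i, ])^2))
      W[win, ] <- W[win, ] + alpha * (X[i, ] - W[win, ])
      tp <- tp + 1
    }
  }
  expect_equal(unname(m$weights), unname(W), tolerance = 1e-12)
})

test_that("BMU lookup matches an exhaustive scan and breaks ties low", {
  set.seed(17)
  W <- matrix(runif(64 * 7), 64, 7)
  m <- manual_model(W, 8, 8)
  expect_equal(bmu(m, W[7, ]), 7L)

  # two equidistant nodes -> lowest index
  W2 <- matrix(0, 10, 2)
  W2[3, ] <- c(1, 0); W2[9, ] <- c(-1, 0)
  W2[setdiff(1:10, c(3, 9)), ] <- 50
  expect_equal(bmu(manual_model(W2, 5, 2), c(0, 0)), 3L)

  for (rep in 1:20) {
    x <- runif(7)
    scan <- which.min(apply(W, 1, function(w) sum((w - x)^2)))
    expect_equal(bmu(m, x), scan)
  }
  # matrix interface agrees with the vector one
  Q <- matrix(runif(5 * 7), 5, 7)
  expect_equal(bmu(m, Q), vapply(1:5, function(i) bmu(m, Q[i, ]), integer(1)))
  expect_error(bmu(m, runif(3)), "length")
})

test_that("Ward clustering of the codebook recovers planted structure", {
  m64 <- manual_model(matrix(runif(64 * 7), 64, 7), 8, 8)
  cl_all <- ward_cluster(m64, k = 64)
  expect_equal(sort(unique(cl_all$node_to_cluster)), 1:64)
  cl_one <- ward_cluster(m64, k = 1)
  expect_true(all(cl_one$node_to_cluster == 1))
  expect_error(ward_cluster(m64, k = 65), "between 1")

  # 12 vectors in 3 well-separated blobs
  set.seed(2)
  blobs <- rbind(matrix(rnorm(4 * 7, 0, 0.05), 4, 7),
                 matrix(rnorm(4 * 7, 5, 0.05), 4, 7),
                 matrix(rnorm(4 * 7, 10, 0.05), 4, 7))
  cl <- ward_cluster(manual_model(blobs, 4, 3), k = 3)
  truth <- rep(1:3, each = 4)
  expect_equal(length(unique(paste(cl$node_to_cluster, truth))), 3L)
})

test_that("pattern naming follows the profile-ranking rule and ignores indexing", {
  # six archetype-like profiles, already on the denormalized scale
  prof <- rbind(
    line    = c(8, 4, 8, 0, 0, 0.4, 0.05),
    loop    = c(6, 4, 6, 0, 0, 3.0, 0.4),
    cross   = c(4.5, 12, 5, 1, 0.3, 3.0, 0.6),
    shaking = c(2.5, 3, 2.6, 1, 0.3, 7.5, 3),
    swirl   = c(1.5, 1.8, 1.6, 1, 0.6, 2.9, 2),
    stay    = c(0.1, 0.2, 0, 1, 5, 0.2, 2.6))
  colnames(prof) <- feature_names()
  mins <- apply(prof, 2, min); maxs <- apply(prof, 2, max)
  norm <- structure(list(min = mins, max = maxs), class = "feature_norm")
  Wn <- apply_normalization(norm, prof)

  for (perm in list(1:6, c(3, 1, 6, 2, 5, 4), 6:1)) {
    m <- manual_model(Wn[perm, , drop = FALSE], 3, 2, norm = norm)
    cl <- structure(list(hclust = NULL, k = 6, node_to_cluster = 1:6,
                         cluster_names = NULL), class = "som_clusters")
    named <- name_patterns(m, cl)
    got <- named$cluster_names
    want <- c("P1", "P2", "P3", "P4", "P5", "P6")[perm]
    expect_equal(got, want)
  }

  cl5 <- structure(list(hclust = NULL, k = 5, node_to_cluster = 1:5,
                        cluster_names = NULL), class = "som_clusters")
  expect_error(name_patterns(manual_model(Wn[1:5, ], 5, 1, norm), cl5),
               "exactly 6")
})

test_that("classification routes vectors through BMU to cluster names", {
  set.seed(4)
  arch <- generate_archetype_set(40, seed = 21)
  fm <- build_feature_matrix(arch$segments)
  norm <- normalize_features(fm)
  m <- train_som(norm$data, som_rows = 6, som_cols = 6, epochs = 5, seed = 9,
                 normalization = norm$stats)
  cl <- name_patterns(m, ward_cluster(m, 6))

  # training rows re-classified equal their BMU clusters
  labs <- classify_segments(m, cl, fm)
  nodes <- bmu(m, norm$data)
  expect_equal(labs, cl$cluster_names[cl$node_to_cluster[nodes]])

  # a vector equal to a node weight lands in that node's cluster
  w5 <- denormalize_features(m$normalization, m$weights[5, , drop = FALSE])
  fv <- as.data.frame(w5); names(fv) <- feature_names()
  expect_equal(classify_segments(m, cl, fv),
               cl$cluster_names[cl$node_to_cluster[5]])

  expect_error(classify_segments(m, cl, fm[, 1:5]), "lacks parameters")
})

test_that("component planes expose the denormalized codebook", {
  arch <- generate_archetype_set(20, seed = 51)
  fm <- build_feature_matrix(arch$segments)
  norm <- normalize_features(fm)
  m <- train_som(norm$data, som_rows = 5, som_cols = 5, epochs = 3, seed = 2,
                 normalization = norm$stats)
  planes <- component_planes(m)
  expect_named(planes, feature_names())
  Wd <- denormalize_features(norm$stats, m$weights)
  for (p in feature_names())
    expect_equal(as.vector(planes[[p]]), unname(Wd[, which(feature_names() == p)]))
  # plane values stay within the training data range per parameter
  for (p in feature_names()) {
    expect_gte(min(planes[[p]]), norm$stats$min[[p]] - 1e-9)
    expect_lte(max(planes[[p]]), norm$stats$max[[p]] + 1e-9)
  }
})

test_that("model serialization round-trips and dendrograms export as Newick", {
  arch <- generate_archetype_set(20, seed = 77)
  fm <- build_feature_matrix(arch$segments)
  norm <- normalize_features(fm)
  m <- train_som(norm$data, som_rows = 4, som_cols = 4, epochs = 3, seed = 3,
                 normalization = norm$stats)
  cl <- ward_cluster(m, 6)
  path <- withr::local_tempfile(fileext = ".yml")
  write_som(m, path, clusters = cl)
  back <- read_som(path)
  expect_equal(back$model$weights, m$weights, tolerance = 1e-9)
  expect_equal(back$model$normalization$min, m$normalization$min, tolerance = 1e-9)
  expect_equal(back$clusters$node_to_cluster, unname(cl$node_to_cluster))
  expect_equal(bmu(back$model, norm$data[3, ]), bmu(m, norm$data[3, ]))

  nwk <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram(cl, nwk)
  tree <- ape::read.tree(nwk)
  expect_equal(ape::Ntip(tree), 16L)
})

test_that("well-separated classes occupy contiguous lattice territories", {
  set.seed(6)
  blobs <- rbind(matrix(rnorm(60 * 7, 0, 0.03), 60, 7),
                 matrix(rnorm(60 * 7, 0.5, 0.03), 60, 7),
                 matrix(rnorm(60 * 7, 1, 0.03), 60, 7))
  lab <- rep(1:3, each = 60)
  m <- train_som(blobs, som_rows = 6, som_cols = 6, epochs = 8, seed = 13)
  nodes <- bmu(m, blobs)
  pos <- cbind(m$grid$row[nodes], m$grid$col[nodes])
  dmat <- as.matrix(stats::dist(pos))
  same <- outer(lab, lab, "==") & upper.tri(dmat)
  diff_ <- outer(lab, lab, "!=") & upper.tri(dmat)
  expect_lt(mean(dmat[same]), mean(dmat[diff_]))
})
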
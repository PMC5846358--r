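#' Min-max normalization of a feature matrix
#'
#' Scales each of the seven movement parameters to [0, 1] over the supplied
#' matrix and returns the per-parameter (min, max) so that later query
#' vectors are normalized with the *training* statistics, and so the
#' transform can be inverted exactly.
#'
#' @param features Feature matrix data frame from [build_feature_matrix()],
#'   or any data frame containing the columns in [feature_names()].
#' @return List with `data` (numeric matrix, rows = segments, columns = the
#'   7 parameters, values in [0,1]) and `stats` (class `"feature_norm"`,
#'   with `min` and `max` per parameter).
#' @export
normalize_features <- function(features) {
  X <- as.matrix(features[, feature_names(), drop = FALSE])
  if (anyNA(X) || any(!is.finite(X))) stop("feature matrix has missing or non-finite values")
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  flat <- maxs - mins <= 0
  if (any(flat))
    stop("constant parameter cannot be normalized: ",
         paste(feature_names()[flat], collapse = ", "))
  stats <- structure(list(min = mins, max = maxs), class = "feature_norm")
  list(data = apply_normalization(stats, features), stats = stats)
}

#' Apply stored normalization statistics
#'
#' @param stats A `"feature_norm"` object from [normalize_features()].
#' @param features Data frame (or matrix/vector in parameter order) to scale.
#' @return Numeric matrix on the training scale.
#' @export
apply_normalization <- function(stats, features) {
  stopifnot(inherits(stats, "feature_norm"))
  if (is.data.frame(features)) {
    X <- as.matrix(features[, feature_names(), drop = FALSE])
  } else if (is.null(dim(features))) {
    X <- matrix(features, nrow = 1, dimnames = list(NULL, feature_names()))
  } else X <- features
  sweep(sweep(X, 2, stats$min), 2, stats$max - stats$min, "/")
}

#' Invert min-max normalization
#'
#' @param stats A `"feature_norm"`.
#' @param X Normalized matrix (or vector).
#' @return Matrix on the original parameter scale.
#' @export
denormalize_features <- function(stats, X) {
  stopifnot(inherits(stats, "feature_norm"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  sweep(sweep(X, 2, stats$max - stats$min, "*"), 2, stats$min, "+")
}

#' Train a sequential self-organizing map
#'
#' Classical online Kohonen training on a rectangular lattice. Each
#' presented vector x is compared to every node j by squared Euclidean
#' distance d_j = sum_i (x_i - w_ij)^2; the best-matching unit (BMU) is the
#' argmin (ties broken by lowest node index), and every node is moved toward
#' x by
#'   w_ij <- w_ij + alpha(t) * h_cj(t) * (x_i - w_ij),
#' with a Gaussian neighborhood h_cj(t) = exp(-lattice_dist(c,j)^2 /
#' (2 sigma(t)^2)) around the winner c. The learning rate alpha and radius
#' sigma decay linearly over the total number of presentations
#' (epochs x nrow(data)); presentation order is a fresh seeded permutation
#' each epoch; weights are initialized from distinct data rows. Training is
#' fully deterministic for a fixed seed.
#'
#' @param data Normalized numeric matrix (rows = segments, columns =
#'   parameters), e.g. `normalize_features(fm)$data`.
#' @param som_rows,som_cols Lattice dimensions; default 8 x 8.
#' @param epochs Passes over the data (default 10).
#' @param alpha0,alphaT Initial/final learning rate (default 0.5 -> 0.01).
#' @param sigma0,sigmaT Initial/final neighborhood radius in lattice units
#'   (default max(rows, cols)/2 -> 0.5, so training ends with essentially
#'   winner-only updates and few non-specialized bridge nodes).
#' @param seed Integer seed controlling initialization and presentation
#'   order.
#' @param normalization Optional `"feature_norm"` to embed in the model so
#'   that later queries can be normalized consistently.
#' @return An object of class `"som_model"`: list with `weights` (R*C x P
#'   codebook matrix, nodes in row-major order), `grid` (node lattice
#'   coordinates), training settings, `seed`, `normalization` and
#'   `qe_history` (mean quantization error after each epoch).
#' @export
train_som <- function(data, som_rows = 8, som_cols = 8, epochs = 10,
                      alpha0 = 0.5, alphaT = 0.01,
                      sigma0 = max(som_rows, som_cols) / 2, sigmaT = 0.5,
                      seed = 1, normalization = NULL) {
  X <- as.matrix(data)
  if (nrow(X) == 0L) stop("empty training data")
  if (anyNA(X) || any(!is.finite(X))) stop("training data has non-finite values")
  if (epochs < 1) stop("epochs must be >= 1")
  n_nodes <- som_rows * som_cols
  if (nrow(X) < n_nodes)
    stop("need at least as many training rows as lattice nodes")
  P <- ncol(X)
  set.seed(seed)
  grid <- expand.grid(row = seq_len(som_rows), col = seq_len(som_cols))
  W <- X[sample.int(nrow(X), n_nodes), , drop = FALSE]
  total <- epochs * nrow(X)
  qe_history <- numeric(epochs)
  t_pres <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nrow(X))
    for (i in ord) {
      frac <- if (total > 1L) t_pres / (total - 1L) else 0
      alpha <- alpha0 + (alphaT - alpha0) * frac
      sigma <- sigma0 + (sigmaT - sigma0) * frac
      W <- som_update_step(W, X[i, ], grid, alpha, sigma)
      t_pres <- t_pres + 1L
    }
    qe_history[ep] <- mean_quantization_error(W, X)
  }
  colnames(W) <- colnames(X)
  structure(list(
    som_rows = som_rows, som_cols = som_cols,
    weights = W, grid = grid,
    epochs = epochs, alpha0 = alpha0, alphaT = alphaT,
    sigma0 = sigma0, sigmaT = sigmaT, seed = seed,
    normalization = normalization,
    qe_history = qe_history
  ), class = "som_model")
}

# one sequential presentation: find the winner by squared Euclidean
# distance (first index wins ties) and pull every node toward x with a
# Gaussian lattice-neighborhood factor around the winner
som_update_step <- function(W, x, grid, alpha, sigma) {
  diffs <- sweep(W, 2, x)
  win <- which.min(rowSums(diffs * diffs))
  ld2 <- (grid$row - grid$row[win])^2 + (grid$col - grid$col[win])^2
  h <- exp(-ld2 / (2 * sigma^2))
  W - (alpha * h) * diffs
}

# mean Euclidean distance of each row of X to its nearest codebook vector
mean_quantization_error <- function(W, X) {
  D2 <- outer(rowSums(X^2), rowSums(W^2), "+") - 2 * X %*% t(W)
  mean(sqrt(pmax(apply(D2, 1, min), 0)))
}

#' Mean quantization error of a trained map
#'
#' @param model A `"som_model"`.
#' @param data Normalized matrix of query vectors.
#' @return Mean Euclidean distance of each row to its BMU.
#' @export
quantization_error <- function(model, data) {
  mean_quantization_error(model$weights, as.matrix(data))
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<SOM %d x %d, %d parameters, %d epochs, seed %d, QE %.4f>\n",
              x$som_rows, x$som_cols, ncol(x$weights), x$epochs, x$seed,
              x$qe_history[length(x$qe_history)]))
  invisible(x)
}

#' Best-matching unit
#'
#' Returns the index of the codebook node minimizing the squared Euclidean
#' distance to `x`; ties resolve to the lowest node index.
#'
#' @param model A `"som_model"`.
#' @param x Normalized vector of length P, or a matrix of such rows.
#' @return Integer node index (vector if `x` is a matrix).
#' @export
bmu <- function(model, x) {
  W <- model$weights
  if (is.null(dim(x))) {
    if (length(x) != ncol(W)) stop("query length does not match codebook")
    diffs <- sweep(W, 2, x)
    return(which.min(rowSums(diffs * diffs)))
  }
  X <- as.matrix(x)
  if (ncol(X) != ncol(W)) stop("query width does not match codebook")
  D2 <- outer(rowSums(X^2), rowSums(W^2), "+") - 2 * X %*% t(W)
  max.col(-D2, ties.method = "first")
}

#' Ward clustering of the SOM codebook
#'
#' Agglomerative hierarchical clustering (Ward criterion, Euclidean
#' distances; `stats::hclust(method = "ward.D2")`) of the trained codebook
#' vectors, cut into `k` clusters. The merge tree is retained for
#' dendrogram export.
#'
#' @param model A `"som_model"`.
#' @param k Number of clusters (default 6, the canonical movement-pattern
#'   count).
#' @return Object of class `"som_clusters"`: list with `hclust`, `k`,
#'   `node_to_cluster` (integer per node) and `cluster_names` (`NULL` until
#'   [name_patterns()] is applied).
#' @export
ward_cluster <- function(model, k = 6) {
  n_nodes <- nrow(model$weights)
  if (k < 1 || k > n_nodes) stop("k must lie between 1 and the node count")
  hc <- stats::hclust(stats::dist(model$weights), method = "ward.D2")
  structure(list(
    hclust = hc, k = k,
    node_to_cluster = stats::cutree(hc, k = k),
    cluster_names = NULL
  ), class = "som_clusters")
}

#' @export
print.som_clusters <- function(x, ...) {
  cat(sprintf("<Ward clustering of SOM codebook: k = %d>\n", x$k))
  if (!is.null(x$cluster_names)) {
    nm <- x$cluster_names
    cat("  ", paste(sprintf("%d=%s(%s)", seq_along(nm), nm,
                            pattern_archetypes()[nm]), collapse = " "), "\n")
  }
  invisible(x)
}

#' Canonical archetype label of each movement pattern
#'
#' @return Named character vector mapping pattern codes P1..P6 to the
#'   archetype names line, loop, cross, shaking, swirl, stay.
#' @export
pattern_archetypes <- function() {
  c(P1 = "line", P2 = "loop", P3 = "cross",
    P4 = "shaking", P5 = "swirl", P6 = "stay")
}

#' Per-cluster mean parameter profile
#'
#' Denormalized mean codebook vector of each cluster; the basis for pattern
#' naming and for interpreting what each cluster "does".
#'
#' @param model A `"som_model"` carrying normalization statistics.
#' @param clusters A `"som_clusters"`.
#' @return Matrix, one row per cluster, columns = the 7 parameters.
#' @export
cluster_profiles <- function(model, clusters) {
  W <- model$weights
  if (!is.null(model$normalization))
    W <- denormalize_features(model$normalization, W)
  colnames(W) <- colnames(model$weights)
  prof <- t(vapply(seq_len(clusters$k), function(cl)
    colMeans(W[clusters$node_to_cluster == cl, , drop = FALSE]),
    numeric(ncol(W))))
  rownames(prof) <- paste0("cluster", seq_len(clusters$k))
  prof
}

#' Name the six movement patterns from cluster profiles
#'
#' Deterministic replacement for naming clusters by visual inspection, based
#' on the denormalized mean parameter profile of each cluster:
#' P1 (line) is the cluster with the highest speed; P6 (stay) the highest
#' stop time among the rest; P3 (cross) the highest acceleration among the
#' rest; the remaining three are ordered by decreasing speed as P2 (loop),
#' P4 (shaking), P5 (swirl). Exact ties abort with an error prompting manual
#' assignment.
#'
#' @param model A `"som_model"` with normalization statistics.
#' @param clusters A `"som_clusters"` with `k = 6`.
#' @return The `"som_clusters"` with `cluster_names` filled in (pattern code
#'   per cluster index).
#' @export
name_patterns <- function(model, clusters) {
  if (clusters$k != 6L) stop("pattern naming requires exactly 6 clusters")
  prof <- cluster_profiles(model, clusters)
  pick_max <- function(values, pool, what) {
    v <- values[pool]
    top <- pool[which(v == max(v))]
    if (length(top) > 1L)
      stop("tie on ", what, " between clusters ",
           paste(top, collapse = ", "), "; assign patterns manually")
    top
  }
  pool <- seq_len(6L)
  p1 <- pick_max(prof[, "speed"], pool, "speed");               pool <- setdiff(pool, p1)
  p6 <- pick_max(prof[, "stop_time"], pool, "stop time");       pool <- setdiff(pool, p6)
  p3 <- pick_max(prof[, "acceleration"], pool, "acceleration"); pool <- setdiff(pool, p3)
  sp <- prof[pool, "speed"]
  if (anyDuplicated(sp)) stop("tie on speed among remaining clusters; assign patterns manually")
  rest <- pool[order(sp, decreasing = TRUE)]
  names_by_cluster <- character(6L)
  names_by_cluster[c(p1, p6, p3, rest)] <- c("P1", "P6", "P3", "P2", "P4", "P5")
  clusters$cluster_names <- names_by_cluster
  clusters
}

#' Classify segments into movement patterns
#'
#' Normalizes each feature row with the model's stored training statistics,
#' finds its BMU and returns the BMU's cluster pattern name.
#'
#' @param model A `"som_model"` with normalization statistics.
#' @param clusters A named `"som_clusters"` (after [name_patterns()]), or an
#'   unnamed one (cluster indices are then returned as `"cluster<i>"`).
#' @param features Feature matrix data frame containing the training
#'   parameters.
#' @return Character vector of pattern labels, one per row.
#' @export
classify_segments <- function(model, clusters, features) {
  if (is.null(model$normalization))
    stop("model carries no normalization statistics")
  missing_cols <- setdiff(feature_names(), names(features))
  if (length(missing_cols))
    stop("feature matrix lacks parameters: ", paste(missing_cols, collapse = ", "))
  Xn <- apply_normalization(model$normalization, features)
  nodes <- bmu(model, Xn)
  cl <- clusters$node_to_cluster[nodes]
  if (is.null(clusters$cluster_names)) paste0("cluster", cl)
  else clusters$cluster_names[cl]
}

#' Component planes of a trained map
#'
#' One R x C lattice of denormalized weights per parameter, the standard
#' SOM visualization of how each input parameter distributes over the map.
#'
#' @param model A `"som_model"`.
#' @return Named list of `som_rows` x `som_cols` matrices.
#' @export
component_planes <- function(model) {
  W <- model$weights
  if (!is.null(model$normalization)) {
    W <- denormalize_features(model$normalization, W)
    colnames(W) <- colnames(model$weights)
  }
  planes <- lapply(colnames(W), function(p)
    matrix(W[, p], nrow = model$som_rows, ncol = model$som_cols))
  names(planes) <- colnames(W)
  planes
}

#' Export the Ward merge tree as Newick text
#'
#' @param clusters A `"som_clusters"`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(clusters, path) {
  ape::write.tree(ape::as.phylo(clusters$hclust), file = path)
  invisible(path)
}

#' Serialize / restore a trained SOM
#'
#' Single-file portable YAML container with a versioned header holding the
#' lattice dimensions, codebook, schedules, seed, normalization statistics
#' and (optionally) the cluster map and pattern names.
#'
#' @param model A `"som_model"`.
#' @param path Destination file.
#' @param clusters Optional `"som_clusters"` to store alongside.
#' @return `write_som` returns `path` invisibly; `read_som` returns a list
#'   with elements `model` and `clusters` (`NULL` if none stored).
#' @export
write_som <- function(model, path, clusters = NULL) {
  obj <- list(
    format = "daphtrack-som", version = 1L,
    som_rows = model$som_rows, som_cols = model$som_cols,
    parameters = colnames(model$weights),
    weights = as.vector(model$weights),  # column-major
    epochs = model$epochs, alpha0 = model$alpha0, alphaT = model$alphaT,
    sigma0 = model$sigma0, sigmaT = model$sigmaT, seed = model$seed,
    qe_history = model$qe_history,
    normalization = if (!is.null(model$normalization))
      list(min = as.vector(model$normalization$min),
           max = as.vector(model$normalization$max))
  )
  if (!is.null(clusters)) {
    obj$clusters <- list(k = clusters$k,
                         node_to_cluster = as.vector(clusters$node_to_cluster),
                         cluster_names = clusters$cluster_names)
  }
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_som
#' @export
read_som <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$format, "daphtrack-som"))
    stop("not a daphtrack SOM model file")
  if (obj$version != 1L) stop("unsupported model file version: ", obj$version)
  n_nodes <- obj$som_rows * obj$som_cols
  W <- matrix(obj$weights, nrow = n_nodes,
              dimnames = list(NULL, obj$parameters))
  norm <- NULL
  if (!is.null(obj$normalization)) {
    norm <- structure(list(
      min = stats::setNames(as.numeric(obj$normalization$min), obj$parameters),
      max = stats::setNames(as.numeric(obj$normalization$max), obj$parameters)
    ), class = "feature_norm")
  }
  model <- structure(list(
    som_rows = obj$som_rows, som_cols = obj$som_cols,
    weights = W,
    grid = expand.grid(row = seq_len(obj$som_rows), col = seq_len(obj$som_cols)),
    epochs = obj$epochs, alpha0 = obj$alpha0, alphaT = obj$alphaT,
    sigma0 = obj$sigma0, sigmaT = obj$sigmaT, seed = obj$seed,
    normalization = norm, qe_history = as.numeric(obj$qe_history)
  ), class = "som_model")
  clusters <- NULL
  if (!is.null(obj$clusters)) {
    clusters <- structure(list(
      hclust = NULL, k = obj$clusters$k,
      node_to_cluster = as.integer(obj$clusters$node_to_cluster),
      cluster_names = obj$clusters$cluster_names
    ), class = "som_clusters")
  }
  list(model = model, clusters = clusters)
}
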
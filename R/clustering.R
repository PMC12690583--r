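# Chemical-space partitioning: complexity-stratified sampling of a compound
# pool, variance-targeted PCA of fingerprint bit matrices, and seeded k-means.
# The fitted model (projection basis + centroids) assigns any compound with a
# matching-length fingerprint a cluster id.

#' Complexity-stratified compound sampling
#'
#' Groups a pool of compounds into `n_classes` substructure-complexity classes
#' (equal-frequency bins of fingerprint on-bit counts) and draws a sample
#' whose per-class sizes are proportional to class populations
#' (largest-remainder rounding), so the complexity histogram of the sample
#' matches the pool.
#'
#' @param pool Data frame with `compound_id` and `complexity_bits`.
#' @param n_sample Total number of compounds to draw (`<= nrow(pool)`).
#' @param n_classes Number of complexity classes.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Character vector of sampled compound ids.
#' @export
stratified_sample <- function(pool, n_sample, n_classes = 100, seed = 1) {
  dt <- as_interaction_dt(pool, c("compound_id", "complexity_bits"))
  if (n_sample > nrow(dt)) stop("n_sample exceeds pool size")
  if (n_sample == nrow(dt)) return(sort(dt$compound_id))
  data.table::setorder(dt, complexity_bits, compound_id)
  # equal-frequency binning guarantees non-empty classes even when the
  # on-bit counts are heavily tied; few distinct values get one class each
  vals <- sort(unique(dt$complexity_bits))
  if (length(vals) <= n_classes) {
    cls <- match(dt$complexity_bits, vals)
  } else {
    qs <- unique(quantile(dt$complexity_bits,
                          probs = seq(0, 1, length.out = n_classes + 1),
                          type = 1))
    cls <- findInterval(dt$complexity_bits, qs, rightmost.closed = TRUE,
                        all.inside = TRUE)
  }
  sizes <- tabulate(cls, nbins = max(cls))
  idx <- which(sizes > 0)
  raw <- n_sample * sizes[idx] / nrow(dt)
  alloc <- floor(raw)
  rem <- n_sample - sum(alloc)
  # largest-remainder apportionment, capped at class size
  frac_order <- order(raw - alloc, decreasing = TRUE)
  i <- 1
  while (rem > 0) {
    j <- frac_order[(i - 1) %% length(idx) + 1]
    if (alloc[j] < sizes[idx[j]]) { alloc[j] <- alloc[j] + 1; rem <- rem - 1 }
    i <- i + 1
  }
  with_seed(derive_seed(seed, "stratified_sample"), {
    out <- lapply(seq_along(idx), function(j) {
      ids <- dt$compound_id[cls == idx[j]]
      ids[sample.int(length(ids), alloc[j])]
    })
  })
  sort(unlist(out))
}

#' Fit a variance-targeted linear projection of fingerprints
#'
#' Centers the bit matrix and keeps the smallest number of principal
#' components whose cumulative explained variance reaches `variance_target`.
#'
#' @param fingerprints Numeric (0/1) matrix, compounds in rows.
#' @param variance_target Fraction of total variance to retain, in (0, 1].
#' @return List with `rotation` (basis, columns = components), `center`,
#'   `explained_variance_fraction`, `d` (number of components).
#' @export
fit_projection <- function(fingerprints, variance_target = 0.95) {
  x <- as.matrix(fingerprints)
  if (nrow(x) < 2) stop("need at least two rows to fit a projection")
  if (!(variance_target > 0 && variance_target <= 1))
    stop("variance_target must be in (0, 1]")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  tot <- sum(v)
  if (tot <= .Machine$double.eps)
    stop("degenerate input: all fingerprint columns are constant")
  # drop numerically-zero components so variance_target = 1 yields the rank
  pos <- v / tot > 1e-12
  v <- v[pos]
  cum <- cumsum(v) / tot
  d <- which(cum >= variance_target - 1e-12)[1]
  list(rotation = pc$rotation[, seq_len(d), drop = FALSE],
       center = pc$center,
       explained_variance_fraction = cum[d],
       d = d)
}

#' Project fingerprints with a fitted basis
#'
#' @param fingerprints Matrix (or single vector) of fingerprints.
#' @param projection Result of [fit_projection()].
#' @return Projected coordinate matrix (rows = compounds).
#' @export
project_fingerprints <- function(fingerprints, projection) {
  x <- if (is.null(dim(fingerprints))) matrix(fingerprints, nrow = 1)
       else as.matrix(fingerprints)
  if (ncol(x) != length(projection$center))
    stop("fingerprint length does not match the projection basis")
  sweep(x, 2, projection$center) %*% projection$rotation
}

# Squared Euclidean distances between row sets; the shared expansion keeps
# tied distances bitwise identical across points and centroids.
pairwise_sqdist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- pairwise_sqdist(x, x[centers[1], , drop = FALSE])[, 1]
  for (i in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1] <- sample.int(n, 1, prob = p)
    d2 <- pmin(d2, pairwise_sqdist(x, x[centers[i + 1], , drop = FALSE])[, 1])
  }
  x[centers, , drop = FALSE]
}

#' Seeded Lloyd k-means with k-means++ initialization
#'
#' Empty clusters arising during iteration are re-seeded at the point
#' farthest from its assigned centroid. The within-cluster sum of squares is
#' non-increasing across iterations (re-seeding replaces an empty, zero-mass
#' centroid and cannot raise the objective).
#'
#' @param projected Numeric matrix of projected coordinates.
#' @param K Number of clusters (`<= nrow(projected)`).
#' @param seed Integer seed.
#' @param max_iter Iteration cap.
#' @return List with `centroids` (K x d), `assignment`, `objective_history`,
#'   `iterations`, `K`, `seed`.
#' @export
fit_kmeans <- function(projected, K, seed = 1, max_iter = 100) {
  x <- as.matrix(projected)
  if (K > nrow(x)) stop("K exceeds the number of rows")
  with_seed(derive_seed(seed, "kmeans"), {
    cen <- kmeanspp_init(x, K)
    hist <- numeric(0)
    assign_prev <- NULL
    for (it in seq_len(max_iter)) {
      d2 <- pairwise_sqdist(x, cen)
      a <- max.col(-d2, ties.method = "first")
      for (k in which(tabulate(a, K) == 0L)) {
        far <- which.max(d2[cbind(seq_len(nrow(x)), a)])
        cen[k, ] <- x[far, ]
        a[far] <- k
        d2 <- pairwise_sqdist(x, cen)
      }
      hist <- c(hist, sum(d2[cbind(seq_len(nrow(x)), a)]))
      if (!is.null(assign_prev) && all(a == assign_prev)) break
      assign_prev <- a
      for (k in seq_len(K)) cen[k, ] <- colMeans(x[a == k, , drop = FALSE])
    }
  })
  list(centroids = cen, assignment = a, objective_history = hist,
       iterations = length(hist), K = K, seed = seed)
}

#' Fit a full cluster model from fingerprints
#'
#' Convenience wrapper: PCA projection at `variance_target`, then k-means on
#' the projected coordinates.
#'
#' @param fingerprints 0/1 matrix with compound ids as row names.
#' @param K Number of clusters.
#' @param variance_target Passed to [fit_projection()].
#' @param seed Integer seed.
#' @param max_iter Passed to [fit_kmeans()].
#' @return Object of class `cdpn_cluster_model` with the projection, the
#'   centroids, `K`, `seed`, and (if row names were given) the training
#'   assignment as a named vector.
#' @export
fit_cluster_model <- function(fingerprints, K, variance_target = 0.95,
                              seed = 1, max_iter = 100) {
  proj <- fit_projection(fingerprints, variance_target)
  z <- project_fingerprints(fingerprints, proj)
  km <- fit_kmeans(z, K, seed = seed, max_iter = max_iter)
  assignment <- km$assignment
  if (!is.null(rownames(fingerprints))) names(assignment) <- rownames(fingerprints)
  structure(list(projection = proj$rotation, center = proj$center,
                 explained_variance_fraction = proj$explained_variance_fraction,
                 centroids = km$centroids, K = K, seed = seed,
                 assignment = assignment),
            class = "cdpn_cluster_model")
}

#' @export
print.cdpn_cluster_model <- function(x, ...) {
  cat(sprintf("cdpn cluster model: K = %d, d = %d, explained variance = %.3f\n",
              x$K, ncol(x$projection), x$explained_variance_fraction))
  invisible(x)
}

#' Assign compounds to clusters
#'
#' Projects fingerprints with the model basis and returns the id of the
#' nearest centroid (squared Euclidean distance); ties break to the lowest
#' cluster id.
#'
#' @param fingerprints Fingerprint matrix or single fingerprint vector whose
#'   length matches the model basis.
#' @param model A `cdpn_cluster_model`.
#' @return Integer vector of cluster ids in `1..K`.
#' @export
assign_cluster <- function(fingerprints, model) {
  stopifnot(inherits(model, "cdpn_cluster_model"))
  z <- project_fingerprints(
    fingerprints,
    list(rotation = model$projection, center = model$center))
  d2 <- pairwise_sqdist(z, model$centroids)
  apply(d2, 1, which.min)
}

#' Serialize / restore a cluster model as JSON text
#'
#' @param model A `cdpn_cluster_model`.
#' @param path File path.
#' @return `read_cluster_model` returns the restored model.
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "cdpn_cluster_model"))
  obj <- list(format = "cdpn_cluster_model", version = 1L,
              projection = model$projection, center = model$center,
              explained_variance_fraction = model$explained_variance_fraction,
              centroids = model$centroids, K = model$K, seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cdpn_cluster_model"))
    stop("not a serialized cdpn cluster model")
  structure(list(projection = as.matrix(obj$projection),
                 center = as.numeric(obj$center),
                 explained_variance_fraction = obj$explained_variance_fraction,
                 centroids = as.matrix(obj$centroids),
                 K = as.integer(obj$K), seed = as.integer(obj$seed),
                 assignment = NULL),
            class = "cdpn_cluster_model")
}
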
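#' K-means clustering of curve features
#'
#' Lloyd's algorithm with k-means++ seeding, run to convergence from each of
#' `restarts` seeded initializations; the run with minimal within-cluster sum
#' of squared Euclidean distances (SSE) is kept and its labels are
#' canonicalized with [canonicalize_labels()]. With a fixed `seed` the result
#' is bit-reproducible.
#'
#' @param features Numeric n x p matrix (rows = patients); for spinal curves
#'   p = 34 (see [curve_features()]).
#' @param k Number of clusters, 2 <= k <= n.
#' @param restarts Number of independent k-means++ initializations
#'   (default 100).
#' @param seed Integer seed, or NULL to use the current RNG stream.
#' @param max_iter Cap on Lloyd iterations per restart.
#' @param tol Convergence threshold on the SSE improvement.
#' @return Object of class `curve_kmeans`: list with `k`, `labels`
#'   (1..k, named by rownames of `features`), `centers` (k x p, each the
#'   mean of its members), `sizes`, `sse`, `sse_trace` (per-iteration SSE of
#'   the winning restart) and `mean_silhouette`.
#' @export
kmeans_cluster <- function(features, k, restarts = 100L, seed = NULL,
                           max_iter = 200L, tol = 1e-10) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  if (!all(is.finite(features))) stop("features must be finite")
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k = ", k, " exceeds the number of points n = ", n)
  if (all(features == rep(features[1L, ], each = n)))
    stop("degenerate input: all points identical; clustering with k >= 2 is undefined")
  res <- .with_seed(seed,
    .kmeans_pp_lloyd(features, k, as.integer(restarts), as.integer(max_iter),
                     tol))
  model <- structure(
    list(k = k,
         labels = setNames(res$labels, rownames(features)),
         centers = res$centers,
         sizes = tabulate(res$labels, nbins = k),
         sse = res$sse,
         sse_trace = res$sse_trace,
         mean_silhouette = NA_real_),
    class = "curve_kmeans")
  model <- canonicalize_labels(model)
  model$mean_silhouette <- mean_silhouette(features, model$labels)
  model
}

#' Canonicalize cluster labels
#'
#' Renumbers clusters 1..k by descending cluster size; ties are broken by
#' lexicographic comparison of the cluster centers. The relabelling is a pure
#' permutation, so applying it twice equals applying it once. This makes
#' cluster indices deterministic across runs (K-means numbering is otherwise
#' arbitrary).
#'
#' @param model A `curve_kmeans` model.
#' @return The model with permuted labels, centers and sizes.
#' @export
canonicalize_labels <- function(model) {
  stopifnot(inherits(model, "curve_kmeans"))
  ord <- do.call(order, c(list(-model$sizes),
                          lapply(seq_len(ncol(model$centers)),
                                 function(j) model$centers[, j])))
  perm <- integer(model$k)
  perm[ord] <- seq_len(model$k)   # old label -> new label
  model$labels[] <- perm[model$labels]
  model$centers <- model$centers[ord, , drop = FALSE]
  model$sizes <- model$sizes[ord]
  model
}

#' @export
print.curve_kmeans <- function(x, ...) {
  cat(sprintf("<curve_kmeans> k = %d, sizes = %s, SSE = %.4g, mean silhouette = %.3f\n",
              x$k, paste(x$sizes, collapse = "/"), x$sse, x$mean_silhouette))
  invisible(x)
}

#' Mean silhouette width
#'
#' For each point, `s = (b - a) / max(a, b)` where `a` is the mean Euclidean
#' distance to the other members of its own cluster and `b` is the smallest
#' mean distance to the members of any other cluster. Points in singleton
#' clusters contribute `s = 0` (standard convention), as do points with
#' `a = b = 0`. Returns the mean over all points, a value in \[-1, 1\].
#'
#' @param features Numeric n x p matrix.
#' @param labels Integer cluster labels of length n; at least two distinct,
#'   each nonempty.
#' @return Mean silhouette width (scalar).
#' @export
mean_silhouette <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  n <- nrow(features)
  stopifnot(length(labels) == n)
  cl <- sort(unique(labels))
  if (length(cl) < 2L) stop("silhouette requires at least two clusters")
  D <- as.matrix(dist(features))
  sizes <- as.vector(table(factor(labels, levels = cl)))
  # sum of distances from each point to the members of each cluster
  S <- t(rowsum(D, group = factor(labels, levels = cl)))  # n x k
  own <- match(labels, cl)
  a <- S[cbind(seq_len(n), own)] / pmax(sizes[own] - 1L, 1L)
  Mean <- sweep(S, 2L, sizes, "/")
  Mean[cbind(seq_len(n), own)] <- Inf
  b <- apply(Mean, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[own] == 1L] <- 0          # singleton clusters
  s[!is.finite(s)] <- 0             # coincident points: a = b = 0
  mean(s)
}

#' Select the number of clusters by silhouette
#'
#' Fits [kmeans_cluster()] for every k in `k_range` and returns the k with
#' the largest mean silhouette width; ties are broken toward the smaller k.
#'
#' @inheritParams kmeans_cluster
#' @param k_range Candidate k values, a subset of \[2, n - 1\].
#' @return List with `k` (selected), `model` (the winning `curve_kmeans`),
#'   and `silhouettes` (named vector, one entry per k examined).
#' @export
select_k <- function(features, k_range = 2:6, restarts = 100L, seed = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("empty k_range")
  if (any(k_range < 2L) || any(k_range > n - 1L))
    stop("k_range must lie within [2, n - 1]")
  models <- lapply(k_range, function(k)
    kmeans_cluster(features, k, restarts = restarts, seed = seed))
  sil <- vapply(models, function(m) m$mean_silhouette, numeric(1L))
  names(sil) <- k_range
  best <- which.max(sil)  # first maximum: ties go to the smaller k
  list(k = k_range[best], model = models[[best]], silhouettes = sil)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to relabelling), about 0 for independent
#' ones.
#'
#' @param a,b Two label vectors of equal length.
#' @return The adjusted Rand index (scalar).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
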
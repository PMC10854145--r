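# ---- base clusterers -------------------------------------------------------

# k-means++ seeding followed by Lloyd iterations; x has observations in rows
kmeanspp <- function(x, k, nstart = 10) {
  n <- nrow(x)
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1, ] <- x[sample.int(n, 1), ]
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    if (k > 1) for (i in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[i, ] <- x[sample.int(n, 1, prob = prob), ]
      di <- rowSums((x - matrix(centers[i, ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, di)
    }
    fit <- suppressWarnings(stats::kmeans(x, centers = centers,
                                          iter.max = 100))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best$cluster
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample columns of a score matrix on
#' Euclidean distance; deterministic.
#'
#' @param x sets-by-samples matrix (e.g. IWHMB).
#' @param k number of clusters, `2 <= k <= ncol(x)`.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return object of class `cluster_result` (see [cluster_result()]).
#' @export
hierarchical_cluster <- function(x, k, linkage = "average") {
  if (k < 2 || k > ncol(x)) stop("k out of range", call. = FALSE)
  hc <- stats::hclust(stats::dist(t(x)), method = linkage)
  labels <- stats::cutree(hc, k = k)
  cluster_result(labels, k = k, matrix = x, method = "hclust")
}

#' k-means clustering of samples
#'
#' k-means with k-means++ initialization and 10 restarts, seed-controlled.
#'
#' @param x sets-by-samples matrix.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @return object of class `cluster_result`.
#' @export
kmeans_cluster <- function(x, k, seed = 1) {
  if (k < 2 || k > ncol(x)) stop("k out of range", call. = FALSE)
  set.seed(seed)
  labels <- stats::setNames(kmeanspp(t(x), k), colnames(x))
  cluster_result(labels, k = k, matrix = x, method = "kmeans")
}

#' Assemble a clustering result
#'
#' @param labels integer labels (1..k) named by sample.
#' @param k number of clusters.
#' @param matrix the clustered score matrix (used to derive the dominant
#'   gene set per cluster — the set with the highest mean score).
#' @param method method tag.
#' @param consensus optional samples-by-samples consensus matrix.
#' @param consensus_counts optional co-sampling count matrix.
#' @return object of class `cluster_result`.
#' @export
cluster_result <- function(labels, k, matrix = NULL, method = NA_character_,
                           consensus = NULL, consensus_counts = NULL) {
  labels <- stats::setNames(as.integer(labels), names(labels))
  dominant <- NULL
  if (!is.null(matrix) && !is.null(rownames(matrix))) {
    dominant <- vapply(seq_len(k), function(c) {
      cols <- names(labels)[labels == c]
      if (length(cols) == 0) return(NA_character_)
      rownames(matrix)[which.max(rowMeans(matrix[, cols, drop = FALSE]))]
    }, character(1))
  }
  structure(list(labels = labels, k = k, method = method,
                 dominant_set = dominant, consensus = consensus,
                 consensus_counts = consensus_counts),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("clustering (%s): k = %d, sizes: %s\n", x$method, x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  if (!is.null(x$dominant_set))
    cat("  dominant sets:", paste(x$dominant_set, collapse = ", "), "\n")
  invisible(x)
}

#' Subsampling consensus clustering
#'
#' For each k, repeatedly subsamples a fraction `p_item` of the samples,
#' clusters the subsample with the base algorithm, and records for every
#' sample pair how often they co-cluster among the subsamples that contain
#' both. The consensus matrix (co-clustered / co-sampled) is then cut with
#' average-linkage hierarchical clustering of `1 - consensus` to produce
#' final labels. Sample pairs that were never co-sampled carry `NA` in the
#' consensus matrix and are treated as dissimilarity 1 when cutting.
#'
#' @param x sets-by-samples matrix.
#' @param max_k largest k to evaluate; capped at `ncol(x) - 1`.
#' @param reps number of subsampling repetitions (>= 2).
#' @param p_item fraction of samples drawn per repetition, in (0, 1].
#' @param alg base clustering algorithm: `"km"` (k-means++) or `"hc"`
#'   (average-linkage hierarchical).
#' @param seed RNG seed controlling subsampling and k-means restarts.
#' @return named list (`k2`, `k3`, ...) of `cluster_result` objects, each
#'   with its consensus matrix; attribute `delta_area` reports the
#'   change in area under the consensus CDF per k (a k-selection
#'   diagnostic, never auto-applied).
#' @export
consensus_cluster <- function(x, max_k, reps = 50, p_item = 0.8,
                              alg = c("km", "hc"), seed = 1) {
  alg <- match.arg(alg)
  if (max_k < 2) stop("max_k must be >= 2", call. = FALSE)
  if (reps < 2) stop("reps must be >= 2", call. = FALSE)
  if (p_item <= 0 || p_item > 1) stop("p_item must be in (0, 1]", call. = FALSE)
  n <- ncol(x)
  ks <- 2:min(max_k, n - 1)
  m_sub <- ceiling(p_item * n)
  set.seed(seed)
  # fix the subsample memberships once so every k sees the same draws
  draws <- lapply(seq_len(reps), function(r) sort(sample.int(n, m_sub)))
  results <- list()
  areas <- numeric(0)
  for (k in ks) {
    co_clust <- matrix(0, n, n)
    co_samp <- matrix(0, n, n)
    for (r in seq_len(reps)) {
      idx <- draws[[r]]
      sub <- x[, idx, drop = FALSE]
      lab <- if (alg == "km") kmeanspp(t(sub), k)
             else stats::cutree(stats::hclust(stats::dist(t(sub)),
                                              method = "average"), k)
      same <- outer(lab, lab, "==") * 1
      co_clust[idx, idx] <- co_clust[idx, idx] + same
      co_samp[idx, idx] <- co_samp[idx, idx] + 1
    }
    cons <- co_clust / co_samp          # NaN where never co-sampled
    cons[!is.finite(cons)] <- NA
    diag(cons) <- 1
    dimnames(cons) <- list(colnames(x), colnames(x))
    dis <- 1 - cons
    dis[is.na(dis)] <- 1
    hc <- stats::hclust(stats::as.dist(dis), method = "average")
    labels <- stats::setNames(stats::cutree(hc, k = k), colnames(x))
    results[[paste0("k", k)]] <- cluster_result(
      labels, k = k, matrix = x, method = paste0("consensus-", alg),
      consensus = cons, consensus_counts = co_samp)
    vals <- cons[upper.tri(cons)]
    vals <- vals[!is.na(vals)]
    # area under the empirical CDF of consensus values
    areas <- c(areas, mean(stats::ecdf(vals)(seq(0, 1, by = 0.01))) )
  }
  delta <- c(areas[1], diff(areas) / pmax(areas[-length(areas)], .Machine$double.eps))
  names(delta) <- paste0("k", ks)
  attr(results, "delta_area") <- delta
  results
}
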
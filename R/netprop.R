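#' Integrate undirected PPI edges with directed TF-target edges
#'
#' Produces one directed graph in which every undirected protein-protein
#' edge contributes transitions both ways and every TF-target edge
#' contributes a one-way transition; the result feeds [rwr()].
#'
#' @param ppi undirected `igraph` network.
#' @param tf optional directed `igraph` network of TF-target edges.
#' @return a directed `igraph` graph.
#' @export
integrate_networks <- function(ppi, tf = NULL) {
  el <- igraph::as_edgelist(ppi)
  edges <- rbind(data.frame(from = el[, 1], to = el[, 2],
                            stringsAsFactors = FALSE),
                 data.frame(from = el[, 2], to = el[, 1],
                            stringsAsFactors = FALSE))
  if (!is.null(tf)) {
    if (!igraph::is_directed(tf))
      stop("tf network must be directed", call. = FALSE)
    elt <- igraph::as_edgelist(tf)
    edges <- rbind(edges, data.frame(from = elt[, 1], to = elt[, 2],
                                     stringsAsFactors = FALSE))
  }
  network_from_edges(edges, directed = TRUE, provenance = "integrated")
}

#' Random walk with restart over an interaction network
#'
#' Iterates `p <- (1 - restart) * t(W) %*% p + restart * p0` where `W` is
#' the column-normalized transition matrix of the network (a directed edge
#' contributes a one-way transition; undirected input is expanded to both
#' directions) and `p0` puts the seed weights (uniform by default) on the
#' in-network seed genes. Dangling nodes (no out-edges) teleport to `p0`.
#' Iteration stops when the L1 residual drops below `tol`.
#'
#' @param net `igraph` network (directed or undirected).
#' @param seeds character vector of seed genes, or a named numeric vector
#'   of positive seed weights.
#' @param restart restart probability in (0, 1].
#' @param tol L1 convergence tolerance.
#' @param max_iter maximum iterations; non-convergence is an error that
#'   reports the residual.
#' @return object of class `rwr_scores`: list with `scores` (named
#'   visiting probabilities summing to 1), `seeds`, `restart`,
#'   `iterations`, `residual`.
#' @export
rwr <- function(net, seeds, restart = 0.7, tol = 1e-10, max_iter = 1000) {
  if (restart <= 0 || restart > 1)
    stop("restart must be in (0, 1]", call. = FALSE)
  nodes <- igraph::V(net)$name
  if (is.null(names(seeds))) {
    seeds <- stats::setNames(rep(1, length(seeds)), seeds)
  }
  if (any(seeds <= 0)) stop("seed weights must be positive", call. = FALSE)
  dropped <- setdiff(names(seeds), nodes)
  if (length(dropped) == length(seeds))
    stop("no seed gene is present in the network", call. = FALSE)
  if (length(dropped) > 0)
    warning("seeds absent from network dropped: ",
            paste(utils::head(dropped, 10), collapse = ", "))
  seeds <- seeds[names(seeds) %in% nodes]
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[names(seeds)] <- seeds / sum(seeds)

  a <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  out_deg <- rowSums(a)
  dangling <- out_deg == 0
  # transition probability from i to j = a[i, j] / out_deg[i]
  inv <- ifelse(dangling, 0, 1 / out_deg)
  wt <- t(a * inv)                  # wt[j, i] = P(i -> j); wt = t(W)
  p <- p0
  residual <- Inf
  iters <- 0
  for (it in seq_len(max_iter)) {
    iters <- it
    dang_mass <- sum(p[dangling])
    p_new <- (1 - restart) * (as.vector(wt %*% p) + dang_mass * p0) +
      restart * p0
    residual <- sum(abs(p_new - p))
    p <- stats::setNames(p_new, nodes)
    if (residual < tol) break
  }
  if (residual >= tol)
    stop(sprintf("random walk did not converge in %d iterations (L1 residual %.3g)",
                 max_iter, residual), call. = FALSE)
  structure(list(scores = p / sum(p), seeds = seeds, restart = restart,
                 iterations = iters, residual = residual),
            class = "rwr_scores")
}

#' @export
print.rwr_scores <- function(x, ...) {
  cat(sprintf("random walk with restart: %d nodes, %d seeds, restart %.2f, %d iterations\n",
              length(x$scores), length(x$seeds), x$restart, x$iterations))
  invisible(x)
}

#' Top-k nodes of a random-walk ranking
#'
#' Returns the k highest-scoring genes in descending score order; score
#' ties are broken lexicographically by gene symbol so the cut is
#' reproducible. Seeds can be excluded before ranking.
#'
#' @param scores `rwr_scores` object.
#' @param k list length; if `k` exceeds the number of nodes the full
#'   ranking is returned with a warning.
#' @param exclude_seeds drop seed genes before ranking.
#' @return character vector of gene symbols.
#' @export
top_k <- function(scores, k = 500, exclude_seeds = FALSE) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  s <- scores$scores
  if (exclude_seeds) s <- s[!(names(s) %in% names(scores$seeds))]
  ord <- order(-s, names(s))
  ranked <- names(s)[ord]
  if (k > length(ranked)) {
    warning("k exceeds number of ranked nodes; returning full ranking")
    k <- length(ranked)
  }
  ranked[seq_len(k)]
}

#' Bridge hub genes: intersection of two prioritized lists
#'
#' Intersects two top-k rankings (e.g. walks seeded from a progression
#' module and from its related immune genes) and orders the shared genes
#' by the worse (maximum) of their two ranks.
#'
#' @param list_a,list_b character vectors in ranking order.
#' @return object of class `bhg_set`: list with `genes` (ordered
#'   intersection), `rank_a`, `rank_b`.
#' @export
bhg_intersect <- function(list_a, list_b) {
  common <- intersect(list_a, list_b)
  if (length(common) == 0)
    warning("the two prioritized lists share no genes")
  ra <- match(common, list_a)
  rb <- match(common, list_b)
  ord <- order(pmax(ra, rb), common)
  structure(list(genes = common[ord],
                 rank_a = stats::setNames(ra[ord], common[ord]),
                 rank_b = stats::setNames(rb[ord], common[ord])),
            class = "bhg_set")
}

#' @export
print.bhg_set <- function(x, ...) {
  cat(sprintf("bridge hub genes: %d shared genes\n", length(x$genes)))
  if (length(x$genes) > 0)
    cat("  top:", paste(utils::head(x$genes, 10), collapse = ", "), "\n")
  invisible(x)
}

#' Upper-tail hypergeometric enrichment test
#'
#' Tests whether a hit list overlaps an annotation set more than expected
#' when drawing from a finite universe: `P(X >= overlap)` under the
#' hypergeometric distribution.
#'
#' @param hits character vector of hit genes (must lie in `universe`).
#' @param annotation character vector of annotated genes (subset of
#'   `universe`).
#' @param universe the background gene universe.
#' @return list with `p_value`, `overlap`, `expected`, `fold_enrichment`.
#' @export
enrich_hypergeom <- function(hits, annotation, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  hits <- unique(intersect(hits, universe))
  annotation <- unique(intersect(annotation, universe))
  q <- length(intersect(hits, annotation))
  m <- length(annotation)
  n <- length(universe) - m
  k <- length(hits)
  p <- stats::phyper(q - 1, m, n, k, lower.tail = FALSE)
  expected <- k * m / length(universe)
  list(p_value = p, overlap = q, expected = expected,
       fold_enrichment = if (expected > 0) q / expected else NA_real_)
}

#' Upper-tailed 2x2 chi-square enrichment test
#'
#' Pearson chi-square statistic of the 2x2 table (no continuity
#' correction) with the p-value from the upper tail of the chi-square
#' distribution with 1 degree of freedom.
#'
#' @param hits_in,hits_out,bg_in,bg_out the four table counts: hits inside
#'   / outside the annotation, background inside / outside.
#' @return list with `statistic` and `p_value`.
#' @export
enrich_chisq_upper <- function(hits_in, hits_out, bg_in, bg_out) {
  tab <- c(hits_in, hits_out, bg_in, bg_out)
  if (any(tab < 0)) stop("counts must be nonnegative", call. = FALSE)
  n <- sum(tab)
  r1 <- hits_in + hits_out
  r2 <- bg_in + bg_out
  c1 <- hits_in + bg_in
  c2 <- hits_out + bg_out
  if (any(c(r1, r2, c1, c2) == 0))
    stop("a margin of the 2x2 table is zero", call. = FALSE)
  stat <- n * (hits_in * bg_out - hits_out * bg_in)^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Community detection on an interaction network
#'
#' Pluggable community assignment: the default greedy modularity
#' maximization is deterministic; Louvain is seed-controlled; the
#' `components` method simply labels connected components. Every node gets
#' exactly one community id.
#'
#' @param net `igraph` network (directed input is symmetrized).
#' @param method `"fast_greedy"`, `"louvain"` or `"components"`.
#' @param seed RNG seed (used by Louvain).
#' @return object of class `community_assignment`: list with `membership`
#'   (named integer vector) and `method`.
#' @export
detect_communities <- function(net, method = c("fast_greedy", "louvain",
                                               "components"), seed = 1) {
  method <- match.arg(method)
  if (igraph::vcount(net) == 0) stop("empty network", call. = FALSE)
  if (igraph::is_directed(net))
    net <- igraph::as_undirected(net, mode = "collapse")
  membership <- switch(method,
    fast_greedy = igraph::membership(igraph::cluster_fast_greedy(net)),
    louvain = { set.seed(seed); igraph::membership(igraph::cluster_louvain(net)) },
    components = igraph::components(net)$membership)
  structure(list(membership = stats::setNames(as.integer(membership),
                                              igraph::V(net)$name),
                 method = method),
            class = "community_assignment")
}

#' @export
print.community_assignment <- function(x, ...) {
  cat(sprintf("community assignment (%s): %d nodes in %d communities\n",
              x$method, length(x$membership), max(x$membership)))
  invisible(x)
}
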
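#' Merge interaction networks into one global network
#'
#' Takes the union of nodes and edges over several edge sources (e.g.
#' STRING-, BioGRID- and KEGG-derived edge lists) and concatenates their
#' provenance tags. All sources must share the undirected/directed flag.
#'
#' @param ... `igraph` networks, or a single list of them.
#' @return an `igraph` graph.
#' @export
build_global_network <- function(...) {
  sources <- list(...)
  if (length(sources) == 1 && is.list(sources[[1]]) &&
      !igraph::is_igraph(sources[[1]]))
    sources <- sources[[1]]
  if (length(sources) < 1) stop("need at least one edge source", call. = FALSE)
  directed <- vapply(sources, igraph::is_directed, logical(1))
  if (length(unique(directed)) > 1)
    stop("cannot mix directed and undirected sources; integrate instead",
         call. = FALSE)
  edges <- do.call(rbind, lapply(sources, function(g) {
    el <- igraph::as_edgelist(g)
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
  }))
  if (nrow(edges) == 0) stop("empty network", call. = FALSE)
  prov <- vapply(sources, function(g)
    as.character(igraph::graph_attr(g, "provenance") %||% NA_character_),
    character(1))
  network_from_edges(edges, directed = directed[[1]],
                     provenance = paste(stats::na.omit(prov), collapse = "+"))
}

#' Filter a global network down to a cohort-specific network
#'
#' Retains an edge only when both endpoint genes are present in the cohort
#' expression matrix and their expression profiles are correlated:
#' `|Pearson r| > r_min` with two-sided `p < p_max` (p from the exact t
#' transform of r with n-2 degrees of freedom). Edges touching a gene with
#' zero expression variance are dropped (their correlation is undefined).
#'
#' @param net global `igraph` network.
#' @param expr genes-by-samples expression matrix with at least 3 samples.
#' @param r_min absolute-correlation threshold (strict inequality).
#' @param p_max p-value threshold (strict inequality).
#' @return the filtered `igraph` network (node set restricted to the
#'   endpoints of surviving edges).
#' @export
cohort_specific_network <- function(net, expr, r_min = 0.4, p_max = 0.05) {
  assert_matrix(expr, "expr")
  n <- ncol(expr)
  if (n < 3) stop("need at least 3 samples to test edge correlations",
                  call. = FALSE)
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0) return(net)
  present <- el[, 1] %in% rownames(expr) & el[, 2] %in% rownames(expr)
  el <- el[present, , drop = FALSE]
  if (nrow(el) == 0)
    return(network_from_edges(
      data.frame(from = character(), to = character()),
      directed = igraph::is_directed(net),
      provenance = igraph::graph_attr(net, "provenance")))
  r <- row_pearson(expr[el[, 1], , drop = FALSE], expr[el[, 2], , drop = FALSE])
  p <- cor_pvalue(r, n)
  keep <- !is.na(r) & abs(r) > r_min & !is.na(p) & p < p_max
  network_from_edges(
    data.frame(from = el[keep, 1], to = el[keep, 2],
               stringsAsFactors = FALSE),
    directed = igraph::is_directed(net),
    provenance = igraph::graph_attr(net, "provenance"))
}

#' Induced subnetwork on a gene set
#'
#' @param net an `igraph` network.
#' @param genes character vector of gene symbols.
#' @return the induced subgraph on `genes` intersected with the network's
#'   node set; may be empty or disconnected.
#' @export
geneset_subnetwork <- function(net, genes) {
  keep <- intersect(genes, igraph::V(net)$name)
  igraph::induced_subgraph(net, keep)
}

# principal-eigenvector scores of an undirected graph, computed per
# connected component by power iteration on A + I (the shift makes the
# Perron eigenvalue strictly dominant on bipartite components), then
# rescaled so the maximum over the whole graph is 1
eigenvector_scores <- function(g, tol = 1e-10, max_iter = 1000) {
  nv <- igraph::vcount(g)
  scores <- stats::setNames(numeric(nv), igraph::V(g)$name)
  if (nv == 0) return(scores)
  comp <- igraph::components(g)
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    if (length(members) == 1) next                       # isolated node -> 0
    sub <- igraph::induced_subgraph(g, members)
    a <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
    x <- rep(1 / sqrt(nrow(a)), nrow(a))
    for (it in seq_len(max_iter)) {
      x_new <- as.vector(a %*% x) + x                    # (A + I) x
      x_new <- x_new / sqrt(sum(x_new^2))
      if (max(abs(x_new - x)) < tol) { x <- x_new; break }
      x <- x_new
    }
    scores[igraph::V(sub)$name] <- x
  }
  mx <- max(scores)
  if (mx > 0) scores <- scores / mx
  scores
}

#' Raw node centralities of a gene-set subnetwork
#'
#' Computes, for every node of an undirected subnetwork: degree (number of
#' neighbors), betweenness centrality (sum over unordered source-target
#' pairs, endpoints excluded, of the fraction of shortest paths through the
#' node) and eigenvector centrality (principal-eigenvector score of the
#' adjacency matrix, computed per connected component and rescaled to a
#' maximum of 1 over the subnetwork). Isolated nodes score (0, 0, 0).
#'
#' @param sub an undirected `igraph` subnetwork (directed input is
#'   symmetrized first).
#' @param set_name gene set label stored in the output.
#' @return data frame with columns `set`, `gene`, `degree`, `betweenness`,
#'   `eigenvector`.
#' @export
centralities <- function(sub, set_name = NA_character_) {
  if (igraph::is_directed(sub))
    sub <- igraph::as_undirected(sub, mode = "collapse")
  nodes <- igraph::V(sub)$name
  if (length(nodes) == 0)
    return(data.frame(set = character(), gene = character(),
                      degree = numeric(), betweenness = numeric(),
                      eigenvector = numeric(), stringsAsFactors = FALSE))
  data.frame(
    set = set_name,
    gene = nodes,
    degree = as.numeric(igraph::degree(sub)),
    betweenness = as.numeric(igraph::betweenness(sub, directed = FALSE,
                                                 normalized = FALSE)),
    eigenvector = as.numeric(eigenvector_scores(sub)),
    stringsAsFactors = FALSE,
    row.names = NULL)
}

#' Normalize centrality features within each gene-set subnetwork
#'
#' Each feature is shifted by its within-set minimum and divided by its
#' within-set standard deviation (n-1 denominator):
#' `x_n = (x - min x) / sd(x)`. A feature that is constant over the
#' subnetwork (sd = 0, including single-node subnetworks) normalizes to 0
#' for every node, and the minimum normalized value is always exactly 0.
#'
#' @param table data frame from [centralities()] (possibly several sets
#'   stacked).
#' @return the table with added columns `degree_n`, `betweenness_n`,
#'   `eigenvector_n`.
#' @export
normalize_centralities <- function(table) {
  norm1 <- function(x) {
    s <- sd_n1(x)
    if (s == 0) return(rep(0, length(x)))
    (x - min(x)) / s
  }
  out <- lapply(split(table, factor(table$set, levels = unique(table$set))),
                function(d) {
    d$degree_n <- norm1(d$degree)
    d$betweenness_n <- norm1(d$betweenness)
    d$eigenvector_n <- norm1(d$eigenvector)
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Centrality table for every set of a collection
#'
#' Extracts the induced subnetwork of each gene set, computes raw node
#' centralities and normalizes them within the set.
#'
#' @param net the (cohort-specific) `igraph` network.
#' @param sets a `gene_sets` collection.
#' @return normalized centrality table (class `data.frame`), one row per
#'   (set, in-network set gene).
#' @export
geneset_centralities <- function(net, sets) {
  tabs <- lapply(names(sets), function(nm)
    centralities(geneset_subnetwork(net, sets[[nm]]), set_name = nm))
  tab <- do.call(rbind, tabs)
  if (is.null(tab) || nrow(tab) == 0)
    return(data.frame(set = character(), gene = character(),
                      degree = numeric(), betweenness = numeric(),
                      eigenvector = numeric(), degree_n = numeric(),
                      betweenness_n = numeric(), eigenvector_n = numeric(),
                      stringsAsFactors = FALSE))
  normalize_centralities(tab)
}
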
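#' Weighted gene-set mutation burden (WHMB)
#'
#' Scores each (gene set, sample) pair as the mean network-centrality
#' weight of the sample's mutated genes inside the set:
#' \deqn{WHMB(s, j) = \frac{1}{M_{size}(s)} \sum_{g \in s \cap mut(j)} w(g)}
#' where `M_size(s)` is the number of genes in set `s` and the weight of a
#' mutated gene is the sum of its three normalized centralities
#' (degree + betweenness + eigenvector) in the set's subnetwork when the
#' gene is in the cohort-specific network, and 1 when it is not. With
#' `use_counts = TRUE` each weight is multiplied by the gene's mutation
#' count.
#'
#' @param profiles a `mutation_profiles` object.
#' @param sets a `gene_sets` collection.
#' @param table normalized centrality table from [geneset_centralities()],
#'   computed on `net`.
#' @param net the cohort-specific `igraph` network the centralities were
#'   computed on; membership in this network decides which weight branch a
#'   gene takes.
#' @param use_counts logical; weight each gene by its mutation count.
#' @param samples optional character vector of expected sample identifiers;
#'   samples absent from `profiles` get an all-zero column with a warning.
#' @return sets-by-samples numeric matrix with attributes `kind = "WHMB"`
#'   and `m_size` (named integer vector of set sizes).
#' @export
compute_whmb <- function(profiles, sets, table, net, use_counts = FALSE,
                         samples = NULL) {
  if (length(sets) == 0) stop("empty gene set collection", call. = FALSE)
  net_nodes <- igraph::V(net)$name
  # per-set named weight vectors for in-network genes
  wtab <- lapply(split(table, factor(table$set, levels = names(sets))),
                 function(d)
    stats::setNames(d$degree_n + d$betweenness_n + d$eigenvector_n, d$gene))
  if (is.null(samples)) samples <- names(profiles)
  missing <- setdiff(samples, names(profiles))
  if (length(missing) > 0)
    warning("samples absent from mutation profiles scored as all-zero: ",
            paste(missing, collapse = ", "))
  m <- matrix(0, nrow = length(sets), ncol = length(samples),
              dimnames = list(names(sets), samples))
  for (j in samples) {
    prof <- profiles[[j]]
    if (is.null(prof) || length(prof) == 0) next
    mut <- names(prof)
    for (s in names(sets)) {
      hit <- intersect(sets[[s]], mut)
      if (length(hit) == 0) next
      w <- ifelse(hit %in% net_nodes,
                  unname(wtab[[s]][hit]),
                  1)
      w[is.na(w)] <- 1   # in network but outside this set's subnetwork table
      if (use_counts) w <- w * prof[hit]
      m[s, j] <- sum(w) / length(sets[[s]])
    }
  }
  structure(m, kind = "WHMB",
            m_size = stats::setNames(lengths(sets), names(sets)))
}

#' Individualized WHMB (per-sample z-score)
#'
#' Standardizes the WHMB matrix within each sample column across gene sets:
#' `IWHMB = (WHMB - mean) / sd` (n-1 denominator). This removes any
#' per-sample scale — in particular the global tumor mutational burden —
#' so scores are comparable across patients; a positive IWHMB is read as
#' the pathway's mutation status being activated in that patient. A sample
#' whose WHMB column is constant gets an all-zero column with a warning.
#'
#' @param whmb sets-by-samples matrix from [compute_whmb()].
#' @return matrix of the same shape with attribute `kind = "IWHMB"` and
#'   attributes `whmb_mean`, `whmb_sd` (per-sample).
#' @export
compute_iwhmb <- function(whmb) {
  if (nrow(whmb) < 2)
    stop("need at least 2 gene sets to standardize within samples",
         call. = FALSE)
  mu <- colMeans(whmb)
  sd_ <- apply(whmb, 2, sd_n1)
  degenerate <- sd_ == 0
  if (any(degenerate))
    warning("constant WHMB column(s) set to zero: ",
            paste(colnames(whmb)[degenerate], collapse = ", "))
  z <- sweep(whmb, 2, mu, "-")
  z <- sweep(z, 2, ifelse(degenerate, 1, sd_), "/")
  z[, degenerate] <- 0
  structure(z, kind = "IWHMB", m_size = attr(whmb, "m_size"),
            whmb_mean = mu, whmb_sd = sd_)
}

#' Dichotomize samples on one gene set's IWHMB
#'
#' @param iwhmb IWHMB matrix.
#' @param set_name row to dichotomize on.
#' @return named character vector over samples: `"high"` if IWHMB > 0,
#'   else `"low"` (a score of exactly 0 is low).
#' @export
dichotomize <- function(iwhmb, set_name) {
  if (!set_name %in% rownames(iwhmb))
    stop(sprintf("unknown gene set '%s'", set_name), call. = FALSE)
  stats::setNames(ifelse(iwhmb[set_name, ] > 0, "high", "low"),
                  colnames(iwhmb))
}

#' Tumor mutational burden
#'
#' Total number of retained (non-silent) mutations per sample, divided by
#' the size of the sequenced coding region in megabases.
#'
#' @param profiles a `mutation_profiles` object.
#' @param region_mb coding region size in Mb (default 38, the approximate
#'   human exome footprint).
#' @return named numeric vector over samples.
#' @export
tmb <- function(profiles, region_mb = 38) {
  if (region_mb <= 0) stop("region_mb must be positive", call. = FALSE)
  vapply(profiles, function(p) sum(p) / region_mb, numeric(1))
}

#' Copy-number burden
#'
#' Per-sample sum of absolute gene-level copy-number calls.
#'
#' @param cnv integer genes-by-samples matrix of calls.
#' @return named numeric vector over samples.
#' @export
cnb <- function(cnv) {
  colSums(abs(cnv))
}

#' Jaccard similarity coefficient
#'
#' `|A intersect B| / (|A| + |B| - |A intersect B|)`; two empty sets give 0
#' by convention.
#'
#' @param a,b vectors treated as sets.
#' @return similarity in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  inter <- length(intersect(a, b))
  denom <- length(a) + length(b) - inter
  if (denom == 0) return(0)
  inter / denom
}

#' Fit the network-weighted pathway mutation burden model
#'
#' The package's main entry point. Builds the cohort-specific interaction
#' network (when an expression matrix is supplied), computes per-gene-set
#' normalized centralities, the weighted burden matrix (WHMB) and its
#' per-sample standardization (IWHMB), and returns everything as one
#' fitted object.
#'
#' @param profiles a `mutation_profiles` object (e.g. from [read_maf()]).
#' @param sets a `gene_sets` collection (e.g. from [read_gmt()]).
#' @param network global interaction `igraph` network.
#' @param expr optional genes-by-samples expression matrix; when given, the
#'   network is first filtered to edges with `|Pearson r| > r_min` and
#'   `p < p_max` across the cohort.
#' @param r_min,p_max cohort-specific edge-filter thresholds.
#' @param use_counts logical; weight genes by mutation count in WHMB.
#' @param samples optional expected sample identifiers.
#' @return object of class `iwhmb_fit` with components `whmb`, `iwhmb`,
#'   `centralities`, `network` (cohort-specific), `global_network`, `call`.
#' @examples
#' cohort <- toy_fixture()
#' fit <- iwhmb(cohort$profiles, cohort$sets, cohort$network)
#' fit$iwhmb
#' @export
iwhmb <- function(profiles, sets, network, expr = NULL,
                  r_min = 0.4, p_max = 0.05, use_counts = FALSE,
                  samples = NULL) {
  net <- if (!is.null(expr)) {
    cohort_specific_network(network, expr, r_min = r_min, p_max = p_max)
  } else network
  tab <- geneset_centralities(net, sets)
  whmb <- compute_whmb(profiles, sets, tab, net, use_counts = use_counts,
                       samples = samples)
  iw <- compute_iwhmb(whmb)
  structure(list(whmb = whmb, iwhmb = iw, centralities = tab,
                 network = net, global_network = network,
                 call = match.call()),
            class = "iwhmb_fit")
}

#' @export
print.iwhmb_fit <- function(x, ...) {
  cat("Network-weighted pathway mutation burden fit\n")
  cat(sprintf("  gene sets: %d   samples: %d\n", nrow(x$iwhmb), ncol(x$iwhmb)))
  cat(sprintf("  cohort network: %d nodes, %d edges\n",
              igraph::vcount(x$network), igraph::ecount(x$network)))
  cat(sprintf("  IWHMB range: [%.3f, %.3f]\n",
              min(x$iwhmb), max(x$iwhmb)))
  invisible(x)
}

#' @export
summary.iwhmb_fit <- function(object, ...) {
  act <- rowMeans(object$iwhmb > 0)
  top <- sort(act, decreasing = TRUE)
  cat("Network-weighted pathway mutation burden fit\n")
  cat(sprintf("  %d gene sets x %d samples\n",
              nrow(object$iwhmb), ncol(object$iwhmb)))
  cat("  fraction of samples with activated status (IWHMB > 0), top sets:\n")
  show <- utils::head(top, 10)
  for (nm in names(show)) cat(sprintf("    %-40s %.2f\n", nm, show[[nm]]))
  invisible(list(activation_fraction = act))
}

#' @export
plot.iwhmb_fit <- function(x, ...) {
  m <- x$iwhmb
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  xlab = "sample", ylab = "gene set", axes = FALSE,
                  main = "IWHMB", ...)
  graphics::axis(1)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m),
                 las = 2, cex.axis = 0.5)
  invisible(x)
}
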
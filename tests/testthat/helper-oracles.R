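# Independent brute-force oracles used to check the package's network and
# scoring code. Everything here works directly on adjacency matrices and
# plain loops; none of it calls the code paths under test.

# shortest-path distance matrix via adjacency powers (walk counting)
brute_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  pw <- diag(n)
  for (k in seq_len(n)) {
    pw <- pw %*% a
    newly <- pw > 0 & !is.finite(d)
    d[newly] <- k
  }
  d
}

# number of shortest paths between every pair: count walks of the shortest
# length (a walk of minimal length is necessarily a path)
brute_path_counts <- function(a) {
  n <- nrow(a)
  d <- brute_distances(a)
  pows <- vector("list", n)
  pows[[1]] <- a
  for (k in seq_len(n - 1) + 1) pows[[k]] <- pows[[k - 1]] %*% a
  cnt <- matrix(0, n, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(d[s, t])) next
    cnt[s, t] <- pows[[d[s, t]]][s, t]
  }
  cnt
}

# betweenness as the literal sum over unordered pairs (s, t), endpoints
# excluded, of the fraction of shortest s-t paths through i; a shortest
# path passes through i iff d(s,i) + d(i,t) = d(s,t), and the number of
# such paths is count(s,i) * count(i,t)
brute_betweenness <- function(a) {
  n <- nrow(a)
  d <- brute_distances(a)
  cnt <- brute_path_counts(a)
  b <- numeric(n)
  for (i in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
      if (s == i || t == i || s == t) next
      if (!is.finite(d[s, t]) || cnt[s, t] == 0) next
      if (d[s, i] + d[i, t] == d[s, t])
        b[i] <- b[i] + cnt[s, i] * cnt[i, t] / cnt[s, t]
    }
  }
  b
}

brute_degree <- function(a) rowSums(a)

# dense per-component principal eigenvector, rescaled to global max 1
brute_eigenvector <- function(a) {
  n <- nrow(a)
  d <- brute_distances(a)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1
    comp[is.finite(d[i, ])] <- cid
  }
  scores <- numeric(n)
  for (c in seq_len(cid)) {
    idx <- which(comp == c)
    if (length(idx) < 2) next
    sub <- a[idx, idx, drop = FALSE]
    ev <- eigen(sub, symmetric = TRUE)
    v <- ev$vectors[, 1]
    if (sum(v) < 0) v <- -v
    v <- abs(v)                       # Perron vector is nonnegative
    scores[idx] <- v / sqrt(sum(v^2))
  }
  if (max(scores) > 0) scores <- scores / max(scores)
  scores
}

# literal triple-loop weighted burden (mirrors the score definition, not
# the vectorized implementation)
brute_whmb <- function(profiles, sets, table, net_nodes, use_counts = FALSE) {
  out <- matrix(0, length(sets), length(profiles),
                dimnames = list(names(sets), names(profiles)))
  for (s in names(sets)) {
    for (j in names(profiles)) {
      ws <- numeric(0)
      for (g in sets[[s]]) {
        counts <- profiles[[j]]
        if (!(g %in% names(counts))) next
        w <- if (g %in% net_nodes) {
          row <- table[table$set == s & table$gene == g, ]
          if (nrow(row) == 1)
            row$degree_n + row$betweenness_n + row$eigenvector_n
          else 1
        } else 1
        if (use_counts) w <- w * counts[[g]]
        ws <- c(ws, w)
      }
      out[s, j] <- sum(ws) / length(sets[[s]])
    }
  }
  out
}

# closed-form stationary solution of the restart walk on a dense graph
brute_rwr <- function(a, seeds_idx, restart, directed = FALSE) {
  n <- nrow(a)
  out_deg <- rowSums(a)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) if (out_deg[i] > 0) w[i, ] <- a[i, ] / out_deg[i]
  p0 <- numeric(n)
  p0[seeds_idx] <- 1 / length(seeds_idx)
  # dangling rows teleport to p0
  for (i in which(out_deg == 0)) w[i, ] <- p0
  solve(diag(n) - (1 - restart) * t(w), restart * p0)
}

# adjacency of a uniform random undirected graph on n nodes
random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- stats::rbinom(length(up), 1, p)
  a + t(a)
}

adjacency_to_graph <- function(a, names_ = NULL) {
  if (is.null(names_)) names_ <- paste0("n", seq_len(nrow(a)))
  dimnames(a) <- list(names_, names_)
  idx <- which(a > 0 & upper.tri(a), arr.ind = TRUE)
  g <- network_from_edges(
    data.frame(from = names_[idx[, 1]], to = names_[idx[, 2]],
               stringsAsFactors = FALSE),
    directed = FALSE, provenance = "test")
  isolated <- setdiff(names_, igraph::V(g)$name)
  if (length(isolated) > 0)
    g <- igraph::add_vertices(g, length(isolated), name = isolated)
  g
}

is_connected_adj <- function(a) all(is.finite(brute_distances(a)))

# adjusted Rand index between two labelings (contingency-table formula)
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c / choose(n, 2)
  mx <- (b + c) / 2
  if (mx == expected) return(0)
  (a - expected) / (mx - expected)
}
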
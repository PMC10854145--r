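test_that("two-node walk matches the closed-form stationary solution", {
  net <- network_from_edges(data.frame(from = "A", to = "B"))
  # seed on A with restart r: p_A = 1/(2 - r), p_B = (1 - r)/(2 - r)
  for (r in c(0.3, 0.5, 0.7)) {
    res <- rwr(net, "A", restart = r)
    expect_equal(unname(res$scores["A"]), 1 / (2 - r), tolerance = 1e-9)
    expect_equal(unname(res$scores["B"]), (1 - r) / (2 - r), tolerance = 1e-9)
  }
  # restart = 1 returns the seed vector itself
  res1 <- rwr(net, "A", restart = 1)
  expect_equal(unname(res1$scores), c(1, 0))
})

test_that("walk scores agree with the linear-system oracle on random graphs", {
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    a <- random_adjacency(n, stats::runif(1, 0.1, 0.5))
    # keep at least one edge so the graph object has all nodes via names
    if (sum(a) == 0) a[1, 2] <- a[2, 1] <- 1
    g <- adjacency_to_graph(a)
    missing_nodes <- setdiff(paste0("n", 1:n), igraph::V(g)$name)
    if (length(missing_nodes) > 0)
      g <- igraph::add_vertices(g, length(missing_nodes),
                                name = missing_nodes)
    seeds_idx <- sort(sample.int(n, sample(1:3, 1)))
    restart <- stats::runif(1, 0.2, 0.9)
    res <- rwr(g, paste0("n", seeds_idx), restart = restart)
    oracle <- brute_rwr(a, seeds_idx, restart)
    expect_equal(unname(res$scores[paste0("n", 1:n)]), oracle,
                 tolerance = 1e-7)
    expect_equal(sum(res$scores), 1, tolerance = 1e-12)
  }
})

test_that("walk scores are equivariant under node relabeling", {
  set.seed(14)
  a <- random_adjacency(12, 0.3)
  g <- adjacency_to_graph(a)
  res <- rwr(g, c("n1", "n5"), restart = 0.6)
  perm <- sample(12)
  relabel <- stats::setNames(paste0("m", seq_len(12)), paste0("n", perm))
  b <- a[perm, perm]
  g2 <- adjacency_to_graph(b, paste0("m", 1:12))
  seeds2 <- unname(relabel[c("n1", "n5")])
  res2 <- rwr(g2, seeds2, restart = 0.6)
  expect_equal(unname(res2$scores[unname(relabel[paste0("n", 1:12)])]),
               unname(res$scores[paste0("n", 1:12)]), tolerance = 1e-9)
})

test_that("directed integration expands PPI edges both ways, TF edges one way", {
  ppi <- network_from_edges(data.frame(from = "A", to = "B"))
  tf <- network_from_edges(data.frame(from = "B", to = "C"), directed = TRUE)
  g <- integrate_networks(ppi, tf)
  expect_true(igraph::is_directed(g))
  el <- apply(igraph::as_edgelist(g), 1, paste, collapse = ">")
  expect_setequal(el, c("A>B", "B>A", "B>C"))
  expect_error(integrate_networks(ppi, ppi), "must be directed")
  # on the directed chain, probability can reach C only through the TF edge
  res <- rwr(g, "A", restart = 0.5)
  expect_gt(res$scores[["C"]], 0)
})

test_that("the walk validates seeds and restart", {
  net <- network_from_edges(data.frame(from = "A", to = "B"))
  expect_error(rwr(net, "Z"), "no seed gene")
  expect_warning(res <- rwr(net, c("A", "Z")), "dropped")
  expect_error(rwr(net, "A", restart = 0), "restart")
  expect_error(rwr(net, stats::setNames(c(1, -1), c("A", "B"))), "positive")
  # named seed weights shift mass toward the heavier seed
  w <- rwr(net, stats::setNames(c(3, 1), c("A", "B")), restart = 0.9)
  expect_gt(w$scores[["A"]], w$scores[["B"]])
})

test_that("top-k ranking is score-descending with lexicographic tie-break", {
  scores <- structure(list(
    scores = c(b = 0.3, a = 0.3, d = 0.25, c = 0.15),
    seeds = c(d = 1)), class = "rwr_scores")
  expect_equal(top_k(scores, 3), c("a", "b", "d"))
  expect_equal(top_k(scores, 2, exclude_seeds = TRUE), c("a", "b"))
  expect_warning(full <- top_k(scores, 10), "exceeds")
  expect_length(full, 4)
  expect_error(top_k(scores, 0), "k must be")
})

test_that("bridge hub intersection orders genes by their worse rank", {
  la <- c("x", "y", "z", "w")
  lb <- c("z", "q", "x")
  res <- bhg_intersect(la, lb)
  # x: ranks (1, 3) -> max 3; z: ranks (3, 1) -> max 3; tie broken by name
  expect_equal(res$genes, c("x", "z"))
  expect_equal(unname(res$rank_a), c(1L, 3L))
  expect_equal(unname(res$rank_b), c(3L, 1L))
  expect_warning(empty <- bhg_intersect("a", "b"), "no genes")
  expect_length(empty$genes, 0)
})

test_that("hypergeometric enrichment reproduces the textbook worked example", {
  # universe of 210 genes, 40 annotated, 15 hits, 5 overlapping:
  # P(X >= 5) with X ~ Hypergeom(m = 40, n = 170, k = 15)
  universe <- paste0("u", 1:210)
  annotation <- universe[1:40]
  hits <- c(universe[1:5], universe[100:109])
  res <- enrich_hypergeom(hits, annotation, universe)
  expect_equal(res$overlap, 5)
  expect_equal(res$p_value,
               stats::phyper(4, 40, 170, 15, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$expected, 15 * 40 / 210, tolerance = 1e-12)
  expect_equal(res$fold_enrichment, 5 / (15 * 40 / 210), tolerance = 1e-12)
  # the full annotation as hits is maximally enriched (p near the minimum)
  expect_lt(enrich_hypergeom(annotation, annotation, universe)$p_value,
            1e-20)
  expect_error(enrich_hypergeom("a", "a", character(0)), "empty universe")
})

test_that("chi-square enrichment matches the hand formula and stats oracle", {
  # table (20, 5 / 5, 20): statistic n(ad - bc)^2 / margins = 18
  res <- enrich_chisq_upper(20, 5, 5, 20)
  expect_equal(res$statistic, 50 * (20 * 20 - 5 * 5)^2 / 25^4)
  expect_equal(res$statistic, 18, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pchisq(18, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # agreement with stats::chisq.test without continuity correction
  oracle <- stats::chisq.test(matrix(c(20, 5, 5, 20), 2), correct = FALSE)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-12)
  # doubling all counts doubles the statistic (chi-square scales with n)
  expect_equal(enrich_chisq_upper(40, 10, 10, 40)$statistic, 36,
               tolerance = 1e-12)
  expect_error(enrich_chisq_upper(0, 0, 1, 1), "margin")
  expect_error(enrich_chisq_upper(-1, 1, 1, 1), "nonnegative")
})

test_that("community detection labels every node exactly once", {
  # two triangles joined by one edge: both methods find the two triangles
  edges <- data.frame(from = c("a", "b", "c", "x", "y", "z", "c"),
                      to = c("b", "c", "a", "y", "z", "x", "x"))
  net <- network_from_edges(edges)
  for (m in c("fast_greedy", "louvain")) {
    res <- detect_communities(net, method = m)
    expect_length(res$membership, 6)
    mem <- res$membership
    expect_equal(length(unique(mem[c("a", "b", "c")])), 1)
    expect_equal(length(unique(mem[c("x", "y", "z")])), 1)
    expect_false(mem[["a"]] == mem[["x"]])
  }
  # components method on a disconnected graph
  net2 <- network_from_edges(data.frame(from = c("a", "x"), to = c("b", "y")))
  res2 <- detect_communities(net2, method = "components")
  expect_equal(max(res2$membership), 2)
  expect_error(detect_communities(igraph::make_empty_graph(0)), "empty")
})
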
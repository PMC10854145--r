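make_iwhmb_like <- function(n_sets = 5, n_samples = 60, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_sets * n_samples), n_sets, n_samples,
              dimnames = list(paste0("SET", seq_len(n_sets)),
                              paste0("s", seq_len(n_samples))))
  scale(m)  # column-standardized like a real IWHMB matrix
}

test_that("row z-scoring standardizes, flags constants, and is idempotent", {
  set.seed(2)
  expr <- rbind(a = stats::rnorm(10, 5, 2), b = rep(3, 10),
                c = stats::runif(10))
  colnames(expr) <- paste0("s", 1:10)
  z <- zscore_rows(expr)
  expect_equal(unname(rowMeans(z)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, stats::sd)), c(1, 0, 1), tolerance = 1e-12)
  expect_equal(attr(z, "constant_rows"), "b")
  expect_equal(unclass(zscore_rows(z)), unclass(z), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(zscore_rows(expr[, 1, drop = FALSE]), "at least 2")
})

test_that("a noiseless linear response yields near-perfect fit statistics", {
  iw <- make_iwhmb_like(n_sets = 4, n_samples = 80, seed = 3)
  expr <- rbind(hit = 0.9 * iw["SET1", ] - 0.6 * iw["SET3", ],
                noise = stats::rnorm(80))
  colnames(expr) <- colnames(iw)
  fits <- fit_svr_per_gene(iw, zscore_rows(expr))
  st <- fits$stats
  expect_gt(st$r[st$gene == "hit"], 0.99)
  expect_lt(st$p[st$gene == "hit"], 1e-10)
  expect_lt(abs(st$r[st$gene == "noise"]), 0.3)
  # recovered coefficients carry the planted signs on the driving sets
  expect_gt(fits$coef["hit", "SET1"], 0.3)
  expect_lt(fits$coef["hit", "SET3"], -0.2)
  expect_lt(max(abs(fits$coef["hit", c("SET2", "SET4")])), 0.15)
})

test_that("in-sample statistic (cv_folds = 0) uses the full-data fitted values", {
  iw <- make_iwhmb_like(n_sets = 3, n_samples = 40, seed = 4)
  expr <- rbind(g = iw["SET2", ] + stats::rnorm(40, 0, 0.1))
  colnames(expr) <- colnames(iw)
  fits <- fit_svr_per_gene(iw, zscore_rows(expr), cv_folds = 0)
  expect_gt(fits$stats$r[1], 0.95)
  # in-sample r is never below the cross-validated r for the same signal
  cv <- fit_svr_per_gene(iw, zscore_rows(expr), cv_folds = 4)
  expect_gte(fits$stats$r[1], cv$stats$r[1] - 0.02)
})

test_that("per-gene fits validate their inputs", {
  iw <- make_iwhmb_like(n_sets = 3, n_samples = 20, seed = 5)
  expr <- matrix(stats::rnorm(40), 2, 20,
                 dimnames = list(c("a", "b"), paste0("x", 1:20)))
  expect_error(fit_svr_per_gene(iw, expr), "sample mismatch")
  colnames(expr) <- colnames(iw)
  expect_error(fit_svr_per_gene(iw, expr, set_subset = "NOPE"),
               "unknown gene set")
  # constant IWHMB rows are excluded from the default set selection
  iw2 <- rbind(iw, FLAT = 0)
  fits <- fit_svr_per_gene(iw2, expr)
  expect_false("FLAT" %in% fits$sets)
})

test_that("IRG calling applies strict thresholds and the validation rule", {
  stats_d <- data.frame(
    gene = c("pass", "low_r", "edge_r", "high_p", "conserved", "fails_valid"),
    r = c(0.5, 0.1, 0.2, 0.6, 0.4, 0.4),
    p = c(0.001, 0.001, 0.001, 0.2, 0.001, 0.001))
  stats_v <- data.frame(
    gene = stats_d$gene,
    r = c(NA, NA, NA, NA, 0.3, 0.05),
    p = rep(0.01, 6))
  fd <- structure(list(stats = stats_d), class = "svr_fits")
  fv <- structure(list(stats = stats_v), class = "svr_fits")

  no_valid <- call_irgs(fd)
  expect_equal(no_valid$status[no_valid$gene == "pass"], "discovery")
  expect_equal(no_valid$status[no_valid$gene == "low_r"], "rejected")
  # thresholds are strict: r == 0.2 exactly does not pass
  expect_equal(no_valid$status[no_valid$gene == "edge_r"], "rejected")
  expect_equal(no_valid$status[no_valid$gene == "high_p"], "rejected")

  with_valid <- call_irgs(fd, fv)
  expect_equal(with_valid$status[with_valid$gene == "conserved"], "conserved")
  # discovery gene below the validation bar stays discovery, not conserved
  expect_equal(with_valid$status[with_valid$gene == "fails_valid"],
               "discovery")
  expect_equal(with_valid$status[with_valid$gene == "pass"], "discovery")
  # loosening r_disc admits more genes (monotone)
  loose <- call_irgs(fd, r_disc = 0.05)
  expect_gte(sum(loose$status != "rejected"),
             sum(no_valid$status != "rejected"))
})

test_that("the permutation control is calibrated near zero", {
  iw <- make_iwhmb_like(n_sets = 6, n_samples = 100, seed = 7)
  set.seed(8)
  expr <- matrix(stats::rnorm(40 * 100), 40, 100,
                 dimnames = list(paste0("g", 1:40), colnames(iw)))
  # make every row a true signal, then let the control destroy it
  for (i in 1:40) expr[i, ] <- iw["SET1", ] + stats::rnorm(100, 0, 0.2)
  ctrl <- random_control(iw, zscore_rows(expr), n_genes = 30, seed = 2)
  expect_lt(abs(ctrl$mean_r), 0.1)
  expect_gt(ctrl$mean_p, 0.3)
  expect_error(random_control(iw, expr, n_genes = 1000), "exceeds")
})

test_that("perturbation links use a strict absolute-coefficient cutoff", {
  coefs <- matrix(c(0.2, -0.3, 0.15, 0.1,
                    0.0, 0.151, -0.149, 0.5), 2, 4, byrow = TRUE,
                  dimnames = list(c("g1", "g2"), paste0("S", 1:4)))
  fits <- structure(list(coef = coefs), class = "svr_fits")
  links <- perturbation_links(fits)
  expect_setequal(paste(links$gene, links$set),
                  c("g1 S1", "g1 S2", "g2 S2", "g2 S4"))
  # |coef| == 0.15 exactly is NOT a link
  expect_false(any(links$gene == "g1" & links$set == "S3"))
  spg <- attr(links, "sets_per_gene")
  expect_equal(as.integer(spg[c("g1", "g2")]), c(2L, 2L))
  # raising the cutoff shrinks the link set
  expect_lte(nrow(perturbation_links(fits, coef_min = 0.4)), nrow(links))
})

test_that("co-expression networks respect sign and threshold rules", {
  set.seed(9)
  base <- stats::rnorm(30)
  expr <- rbind(a = base, b = base + stats::rnorm(30, 0, 0.1),
                c = -base + stats::rnorm(30, 0, 0.1),
                d = stats::rnorm(30))
  colnames(expr) <- paste0("s", 1:30)
  pos <- coexpression_network(expr, rownames(expr))
  expect_true(igraph::are_adjacent(pos, "a", "b"))
  expect_false("c" %in% igraph::V(pos)$name &&
                 igraph::are_adjacent(pos, "a", "c"))
  both <- coexpression_network(expr, rownames(expr), positive_only = FALSE)
  expect_true(igraph::are_adjacent(both, "a", "c"))
  expect_warning(coexpression_network(expr, c("a", "zz")), "zz")
  expect_error(coexpression_network(expr[, 1:2], rownames(expr)),
               "3 samples")
})

test_that("module eigengene equals the first right singular vector", {
  set.seed(10)
  n <- 50
  latent <- stats::rnorm(n)
  expr <- t(vapply(1:8, function(i) 2 * latent + stats::rnorm(n, 0, 0.3),
                   numeric(n)))
  rownames(expr) <- paste0("m", 1:8)
  colnames(expr) <- paste0("s", 1:n)
  eg <- module_eigengene(expr, rownames(expr))
  expect_s3_class(eg, "module_eigengene")
  # score is unit-norm and tracks the latent factor almost perfectly
  expect_equal(sum(eg$score^2), 1, tolerance = 1e-12)
  expect_gt(abs(stats::cor(eg$score, latent)), 0.98)
  # sign convention: positively correlated with mean module expression
  expect_gte(stats::cor(eg$score, colMeans(expr)), 0)
  # oracle: first right singular vector of the row-standardized matrix
  sv <- svd(t(scale(t(expr))))
  v1 <- sv$v[, 1] * sign(stats::cor(sv$v[, 1], colMeans(expr)))
  expect_equal(unname(eg$score), v1, tolerance = 1e-9)
  expect_equal(eg$explained_variance, sv$d[1]^2 / sum(sv$d^2),
               tolerance = 1e-12)
  # a tight module explains most of its variance
  expect_gt(eg$explained_variance, 0.8)
  expect_error(module_eigengene(expr, "m1"), "fewer than 2")
})
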
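#' Row-wise z-score of an expression matrix
#'
#' Standardizes every gene row to mean 0 and sd 1 (n-1 denominator).
#' Constant rows become all-zero and are flagged in the `constant_rows`
#' attribute. The operation is idempotent on already-standardized rows.
#'
#' @param expr genes-by-samples matrix with >= 2 samples.
#' @return matrix of the same shape with attribute `constant_rows`.
#' @export
zscore_rows <- function(expr) {
  if (ncol(expr) < 2) stop("need at least 2 samples", call. = FALSE)
  mu <- rowMeans(expr)
  s <- apply(expr, 1, sd_n1)
  flat <- s == 0
  z <- (expr - mu) / ifelse(flat, 1, s)
  z[flat, ] <- 0
  structure(z, constant_rows = rownames(expr)[flat])
}

# Spearman correlation with a two-sided p-value from the t approximation
# (exact permutation distribution via cor.test for small n on request)
spearman_test <- function(x, y, exact = FALSE) {
  if (exact && length(x) < 30) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    return(c(r = unname(ct$estimate), p = ct$p.value))
  }
  r <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  if (is.na(r)) return(c(r = NA_real_, p = NA_real_))
  c(r = r, p = cor_pvalue(r, length(x)))
}

#' Per-gene linear-kernel SVR of expression on IWHMB
#'
#' Fits, for every gene, an epsilon-insensitive support-vector regression
#' (linear kernel) of the gene's z-scored expression on the selected IWHMB
#' rows across samples, and records the primal coefficient per gene set,
#' the fitted values, and the Spearman correlation between predicted and
#' observed expression with its p-value. By default the correlation is
#' estimated by k-fold cross-validation (deterministic interleaved folds):
#' each sample's prediction comes from a model that never saw it, so the
#' statistic is calibrated under the null hypothesis of no relation. With
#' `cv_folds = 0` the statistic is computed in-sample on the full-data
#' fitted values instead; note that the in-sample statistic is inflated by
#' overfitting when the number of gene sets is an appreciable fraction of
#' the sample count. Coefficients always come from the full-data fit.
#' Genes whose predicted or observed values are constant get `NA`
#' statistics.
#'
#' @param iwhmb sets-by-samples IWHMB matrix (independent variables).
#' @param expr_z genes-by-samples z-scored expression (dependent variables);
#'   sample columns must match `iwhmb` exactly.
#' @param set_subset optional character vector of sets to use; by default
#'   all sets whose IWHMB varies across samples (sd >= 1e-8) are used.
#' @param epsilon epsilon of the insensitive tube.
#' @param cost regularization constant C.
#' @param cv_folds folds for the cross-validated fit statistic (default 3);
#'   0 switches to the in-sample statistic.
#' @param tolerance optimizer termination tolerance passed to
#'   [e1071::svm()] (looser than its default; coefficient changes are
#'   below 1e-2, well under every calling threshold).
#' @return object of class `svr_fits`: list with `stats` (data frame
#'   `gene`, `r`, `p`), `coef` (genes-by-sets coefficient matrix),
#'   `predicted` (genes-by-samples matrix of the values the statistic was
#'   computed on), `sets` (sets used).
#' @export
fit_svr_per_gene <- function(iwhmb, expr_z, set_subset = NULL,
                             epsilon = 0.1, cost = 1, cv_folds = 3,
                             tolerance = 0.01) {
  if (!identical(colnames(iwhmb), colnames(expr_z))) {
    extra <- union(setdiff(colnames(iwhmb), colnames(expr_z)),
                   setdiff(colnames(expr_z), colnames(iwhmb)))
    stop("sample mismatch between IWHMB and expression: ",
         paste(utils::head(extra, 10), collapse = ", "), call. = FALSE)
  }
  if (is.null(set_subset)) {
    keep_sd <- apply(iwhmb, 1, sd_n1) >= 1e-8
    set_subset <- rownames(iwhmb)[keep_sd]
  } else {
    bad <- setdiff(set_subset, rownames(iwhmb))
    if (length(bad) > 0)
      stop("unknown gene set(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  X <- t(iwhmb[set_subset, , drop = FALSE])   # samples x sets
  n <- nrow(X)
  n_genes <- nrow(expr_z)
  coefs <- matrix(0, n_genes, length(set_subset),
                  dimnames = list(rownames(expr_z), set_subset))
  pred_m <- matrix(NA_real_, n_genes, ncol(expr_z),
                   dimnames = dimnames(expr_z))
  r <- p <- rep(NA_real_, n_genes)
  fold <- if (cv_folds > 0) rep_len(seq_len(cv_folds), n) else NULL
  svr1 <- function(X, y) e1071::svm(X, y, type = "eps-regression",
                                    kernel = "linear", epsilon = epsilon,
                                    cost = cost, scale = FALSE,
                                    tolerance = tolerance)
  for (i in seq_len(n_genes)) {
    y <- expr_z[i, ]
    fit <- svr1(X, y)
    # primal weights of the linear kernel: w = t(alpha) %*% SV
    coefs[i, ] <- as.vector(t(fit$coefs) %*% fit$SV)
    pred <- if (cv_folds > 0) {
      out <- numeric(n)
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        m <- svr1(X[tr, , drop = FALSE], y[tr])
        out[!tr] <- stats::predict(m, X[!tr, , drop = FALSE])
      }
      out
    } else {
      stats::fitted(fit)
    }
    pred_m[i, ] <- pred
    st <- spearman_test(pred, y)
    r[i] <- st[["r"]]
    p[i] <- st[["p"]]
  }
  structure(list(
    stats = data.frame(gene = rownames(expr_z), r = r, p = p,
                       stringsAsFactors = FALSE, row.names = NULL),
    coef = coefs, predicted = pred_m, sets = set_subset,
    epsilon = epsilon, cost = cost, cv_folds = cv_folds),
    class = "svr_fits")
}

#' @export
print.svr_fits <- function(x, ...) {
  cat(sprintf("per-gene linear SVR fits: %d genes on %d gene sets\n",
              nrow(x$stats), length(x$sets)))
  cat(sprintf("  fit r: median %.3f, max %.3f\n",
              stats::median(x$stats$r, na.rm = TRUE),
              max(x$stats$r, na.rm = TRUE)))
  invisible(x)
}

#' Call IWHMB-related genes (IRGs) from SVR fit statistics
#'
#' A gene passes discovery when its fit correlation exceeds `r_disc` and
#' its p-value is below `p_disc` (both strict). A discovery gene is
#' `conserved` when a validation fit is available and its correlation
#' exceeds `r_valid`; a discovery gene without validation data keeps status
#' `discovery`; all other genes are `rejected`.
#'
#' @param fits_discovery `svr_fits` from the discovery cohort.
#' @param fits_validation optional `svr_fits` from a validation cohort.
#' @param r_disc,p_disc discovery thresholds.
#' @param r_valid validation correlation threshold.
#' @return data frame with columns `gene`, `r_discovery`, `p_discovery`,
#'   `r_validation`, `p_validation`, `status`.
#' @export
call_irgs <- function(fits_discovery, fits_validation = NULL,
                      r_disc = 0.2, p_disc = 0.05, r_valid = 0.1) {
  d <- fits_discovery$stats
  out <- data.frame(gene = d$gene, r_discovery = d$r, p_discovery = d$p,
                    r_validation = NA_real_, p_validation = NA_real_,
                    stringsAsFactors = FALSE)
  pass_disc <- !is.na(d$r) & d$r > r_disc & !is.na(d$p) & d$p < p_disc
  status <- ifelse(pass_disc, "discovery", "rejected")
  if (!is.null(fits_validation)) {
    v <- fits_validation$stats
    idx <- match(out$gene, v$gene)
    out$r_validation <- v$r[idx]
    out$p_validation <- v$p[idx]
    pass_valid <- !is.na(out$r_validation) & out$r_validation > r_valid
    status[pass_disc & pass_valid] <- "conserved"
  }
  out$status <- status
  out
}

#' Permutation null for the per-gene SVR fit statistic
#'
#' Refits the SVR on a subset of genes whose expression columns are
#' independently permuted across samples, destroying any relation to IWHMB
#' while preserving each gene's marginal distribution. Returns the mean
#' fit correlation and mean p-value over genes and repetitions — the
#' random-model control against which observed fits are judged.
#'
#' @param iwhmb sets-by-samples IWHMB matrix.
#' @param expr_z genes-by-samples z-scored expression.
#' @param n_genes number of gene rows to draw per repetition.
#' @param n_reps repetitions.
#' @param seed RNG seed.
#' @param ... passed to [fit_svr_per_gene()].
#' @return list with `mean_r`, `mean_p`, and the pooled per-gene `stats`.
#' @export
random_control <- function(iwhmb, expr_z, n_genes = 200, n_reps = 1,
                           seed = 1, ...) {
  if (n_genes > nrow(expr_z))
    stop("n_genes exceeds available genes", call. = FALSE)
  set.seed(seed)
  all_stats <- list()
  for (rep in seq_len(n_reps)) {
    rows <- sample.int(nrow(expr_z), n_genes)
    perm <- t(apply(expr_z[rows, , drop = FALSE], 1,
                    function(x) x[sample.int(length(x))]))
    colnames(perm) <- colnames(expr_z)
    rownames(perm) <- rownames(expr_z)[rows]
    fits <- fit_svr_per_gene(iwhmb, perm, ...)
    all_stats[[rep]] <- fits$stats
  }
  pooled <- do.call(rbind, all_stats)
  list(mean_r = mean(pooled$r, na.rm = TRUE),
       mean_p = mean(pooled$p, na.rm = TRUE),
       stats = pooled)
}

#' Gene-set-to-gene perturbation links from SVR coefficients
#'
#' A (gene set, gene) pair is a perturbation link when the absolute SVR
#' regression coefficient strictly exceeds `coef_min`, reading the set's
#' mutation burden as perturbing that gene's expression.
#'
#' @param fits `svr_fits` object.
#' @param coef_min absolute-coefficient threshold (strict).
#' @return data frame `set`, `gene`, `coefficient`; attribute
#'   `sets_per_gene` counts perturbing sets per linked gene.
#' @export
perturbation_links <- function(fits, coef_min = 0.15) {
  idx <- which(abs(fits$coef) > coef_min, arr.ind = TRUE)
  out <- data.frame(set = colnames(fits$coef)[idx[, 2]],
                    gene = rownames(fits$coef)[idx[, 1]],
                    coefficient = fits$coef[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$set), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, sets_per_gene = table(out$gene))
}

#' Co-expression network over a gene list
#'
#' Connects two genes when their expression Pearson correlation exceeds
#' `r_min` with `p < p_max`. By default only positively correlated pairs
#' are kept (the dominant regulatory mode in tumors); with
#' `positive_only = FALSE` the threshold applies to `|r|`. Nodes are the
#' input genes with at least one retained pair.
#'
#' @param expr genes-by-samples matrix with >= 3 samples.
#' @param genes genes to consider (must be rows of `expr`; absent genes are
#'   dropped with a warning).
#' @param r_min,p_max thresholds (strict).
#' @param positive_only keep only positive correlations.
#' @return an undirected `igraph` network.
#' @export
coexpression_network <- function(expr, genes, r_min = 0.4, p_max = 0.05,
                                 positive_only = TRUE) {
  if (ncol(expr) < 3) stop("need at least 3 samples", call. = FALSE)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0)
    warning("genes absent from expression dropped: ",
            paste(utils::head(missing, 10), collapse = ", "))
  genes <- intersect(genes, rownames(expr))
  sub <- expr[genes, , drop = FALSE]
  cm <- suppressWarnings(stats::cor(t(sub)))
  n <- ncol(expr)
  pm <- matrix(cor_pvalue(as.vector(cm), n), nrow(cm), ncol(cm))
  pass <- if (positive_only) cm > r_min else abs(cm) > r_min
  pass <- pass & pm < p_max
  pass[is.na(pass)] <- FALSE
  pass[lower.tri(pass, diag = TRUE)] <- FALSE
  idx <- which(pass, arr.ind = TRUE)
  network_from_edges(
    data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
               stringsAsFactors = FALSE),
    directed = FALSE, provenance = "coexpression")
}

#' Module eigengene: first principal component of a gene module
#'
#' Row-standardizes the module's expression submatrix and extracts the
#' first right singular vector as the per-sample module score. The score
#' has unit norm and its sign is fixed so that it correlates positively
#' with the mean module expression.
#'
#' @param expr genes-by-samples matrix.
#' @param module_genes genes of the module; at least 2 must be present in
#'   `expr`.
#' @return object of class `module_eigengene`: list with `score` (named
#'   per-sample vector), `explained_variance`, `genes`, `sign_flipped`.
#' @export
module_eigengene <- function(expr, module_genes) {
  found <- intersect(module_genes, rownames(expr))
  if (length(found) < 2)
    stop("fewer than 2 module genes found in expression; missing: ",
         paste(utils::head(setdiff(module_genes, rownames(expr)), 10),
               collapse = ", "), call. = FALSE)
  z <- zscore_rows(expr[found, , drop = FALSE])
  sv <- svd(z)
  score <- sv$v[, 1]
  flipped <- FALSE
  mean_expr <- colMeans(expr[found, , drop = FALSE])
  cc <- suppressWarnings(stats::cor(score, mean_expr))
  if (!is.na(cc) && cc < 0) {
    score <- -score
    flipped <- TRUE
  }
  structure(list(score = stats::setNames(score, colnames(expr)),
                 explained_variance = sv$d[1]^2 / sum(sv$d^2),
                 genes = found, sign_flipped = flipped),
            class = "module_eigengene")
}

#' @export
print.module_eigengene <- function(x, ...) {
  cat(sprintf("module eigengene over %d genes: %.1f%% variance explained\n",
              length(x$genes), 100 * x$explained_variance))
  invisible(x)
}
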
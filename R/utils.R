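# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# two-sided p-value for a Pearson/Spearman correlation via the exact t
# transform with n - 2 degrees of freedom
cor_pvalue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- is.finite(r) & n > 2
  rr <- pmin(pmax(r[ok], -1), 1)
  tt <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[ok][abs(rr) == 1] <- 0
  p
}

# rowwise Pearson correlation between matched rows of two matrices
row_pearson <- function(x, y) {
  stopifnot(ncol(x) == ncol(y), nrow(x) == nrow(y))
  n <- ncol(x)
  cx <- x - rowMeans(x)
  cy <- y - rowMeans(y)
  sx <- sqrt(rowSums(cx^2))
  sy <- sqrt(rowSums(cy^2))
  r <- rowSums(cx * cy) / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  r
}

assert_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", what), call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("'%s' must have row and column names", what), call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(sprintf("duplicate row identifiers in '%s'", what), call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(sprintf("duplicate column identifiers in '%s'", what), call. = FALSE)
  invisible(x)
}

# sample standard deviation (n - 1 denominator), 0 for length-1 input
sd_n1 <- function(x) {
  if (length(x) < 2) return(0)
  stats::sd(x)
}

# stable hash of an R object, used for provenance stamping of outputs
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = "\n"), f)
  unname(tools::md5sum(f))
}
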
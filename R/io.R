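#' Default variant classifications treated as silent
#'
#' Somatic variant classes that do not alter the protein product and are
#' excluded from pathway mutation burden scoring. Intergenic and purely
#' regulatory-flank classes are included because burden scoring consumes
#' gene-level non-silent mutation status only.
#'
#' @export
SILENT_CLASSES <- c("Silent", "Intron", "3'UTR", "5'UTR",
                    "3'Flank", "5'Flank", "IGR", "RNA")

#' Read somatic mutation calls from a MAF-like table
#'
#' Parses a tab-separated mutation annotation file and collapses it to one
#' mutation profile per tumor sample: the set of non-silently mutated gene
#' symbols with per-gene mutation counts. Gene symbols are matched by exact
#' string; no alias resolution is attempted.
#'
#' @param path path to a tab-separated file with at least the columns
#'   `Hugo_Symbol`, `Tumor_Sample_Barcode` and `Variant_Classification`.
#' @param keep_classes optional character vector; when given, only rows whose
#'   `Variant_Classification` is in this set are retained and
#'   `silent_classes` is ignored.
#' @param silent_classes variant classes dropped as silent; defaults to
#'   [SILENT_CLASSES].
#' @return an object of class `mutation_profiles`: a named list (one element
#'   per sample) of named integer vectors giving per-gene mutation counts.
#' @export
read_maf <- function(path, keep_classes = NULL, silent_classes = SILENT_CLASSES) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "#")
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0)
    stop("MAF file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) {
    warning("MAF file contains no mutation rows")
    return(mutation_profiles(list()))
  }
  keep <- if (!is.null(keep_classes)) {
    df$Variant_Classification %in% keep_classes
  } else {
    !(df$Variant_Classification %in% silent_classes)
  }
  df <- df[keep, , drop = FALSE]
  profiles <- lapply(split(df$Hugo_Symbol, df$Tumor_Sample_Barcode), function(g) {
    counts <- table(g)
    stats::setNames(as.integer(counts), names(counts))
  })
  mutation_profiles(profiles)
}

#' Construct a mutation-profile collection
#'
#' @param profiles named list; each element is either a character vector of
#'   mutated gene symbols or a named integer vector of per-gene counts.
#' @return object of class `mutation_profiles`.
#' @export
mutation_profiles <- function(profiles) {
  if (length(profiles) > 0 && is.null(names(profiles)))
    stop("profiles must be a named list (names are sample identifiers)",
         call. = FALSE)
  out <- lapply(profiles, function(p) {
    if (is.character(p)) p <- stats::setNames(rep(1L, length(p)), p)
    if (length(p) > 0) {
      if (is.null(names(p)) || any(!nzchar(names(p))))
        stop("gene symbols must be nonempty strings", call. = FALSE)
      if (any(p < 1)) stop("mutation counts must be >= 1", call. = FALSE)
    }
    stats::setNames(as.integer(p), names(p))
  })
  structure(out, class = "mutation_profiles")
}

#' @export
print.mutation_profiles <- function(x, ...) {
  cat(sprintf("mutation profiles: %d samples, median %s mutated genes/sample\n",
              length(x),
              if (length(x)) stats::median(lengths(x)) else "NA"))
  invisible(x)
}

#' Serialize mutation profiles to a minimal MAF-like table
#'
#' Writes one `Missense_Mutation` row per mutation event (counts expand to
#' repeated rows), so that re-reading with [read_maf()] reproduces the
#' profiles exactly.
#'
#' @param profiles a `mutation_profiles` object.
#' @param path output path.
#' @export
write_maf <- function(profiles, path) {
  rows <- lapply(sort(names(profiles)), function(s) {
    p <- profiles[[s]]
    if (length(p) == 0) return(NULL)
    p <- p[sort(names(p))]   # canonical order: reserialization is stable
    data.frame(Hugo_Symbol = rep(names(p), times = p),
               Tumor_Sample_Barcode = s,
               Variant_Classification = "Missense_Mutation",
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(Hugo_Symbol = character(), Tumor_Sample_Barcode = character(),
                     Variant_Classification = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene set collection in GMT format
#'
#' Each line holds a set name, a description and one or more gene symbols,
#' tab-separated (the MSigDB interchange dialect). Within-set duplicate
#' genes are dropped with a warning.
#'
#' @param path path to the GMT file.
#' @param source optional source tag stored on the collection.
#' @return object of class `gene_sets`: a named list of character vectors.
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", i),
           call. = FALSE)
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate genes in set '%s' dropped", fields[[1]]))
      genes <- unique(genes)
    }
    sets[[fields[[1]]]] <- genes
  }
  gene_sets(sets, source = source)
}

#' Construct a gene set collection
#'
#' @param sets named list of character vectors of gene symbols.
#' @param source optional source tag.
#' @return object of class `gene_sets`.
#' @export
gene_sets <- function(sets, source = NA_character_) {
  if (length(sets) > 0 && is.null(names(sets)))
    stop("sets must be a named list", call. = FALSE)
  for (nm in names(sets)) {
    if (length(sets[[nm]]) < 1)
      stop(sprintf("gene set '%s' is empty", nm), call. = FALSE)
    if (anyDuplicated(sets[[nm]]))
      stop(sprintf("gene set '%s' contains duplicate genes", nm), call. = FALSE)
  }
  structure(lapply(sets, as.character), class = "gene_sets", source = source)
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene set collection: %d sets, sizes %s-%s\n", length(x),
              if (length(x)) min(lengths(x)) else "NA",
              if (length(x)) max(lengths(x)) else "NA"))
  invisible(x)
}

#' Write a gene set collection in GMT format
#' @param sets a `gene_sets` object.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction network from a 2-3 column edge list
#'
#' Columns are tab-separated gene symbols (an optional third column carries
#' an edge weight or provenance tag). Self-loops are dropped and duplicate
#' edges merged; the network is undirected unless `directed = TRUE`.
#'
#' @param path path to the edge list.
#' @param directed logical; read edges as directed (e.g. TF-target links).
#' @param provenance provenance tag attached to the network.
#' @return an `igraph` graph whose vertex names are gene symbols.
#' @export
read_edge_list <- function(path, directed = FALSE, provenance = basename(path)) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (ncol(df) < 2) stop("edge list needs at least 2 columns", call. = FALSE)
  edges <- data.frame(from = as.character(df[[1]]), to = as.character(df[[2]]),
                      stringsAsFactors = FALSE)
  if (ncol(df) >= 3) edges$weight <- suppressWarnings(as.numeric(df[[3]]))
  network_from_edges(edges, directed = directed, provenance = provenance)
}

#' Build an interaction network from an in-memory edge table
#'
#' @param edges data frame with columns `from` and `to` (and optionally
#'   `weight`).
#' @param directed logical.
#' @param provenance provenance tag.
#' @return an `igraph` graph.
#' @export
network_from_edges <- function(edges, directed = FALSE, provenance = NA_character_) {
  if (any(is.na(edges$from)) || any(is.na(edges$to)) ||
      any(!nzchar(edges$from)) || any(!nzchar(edges$to)))
    stop("edge list contains an empty node name", call. = FALSE)
  edges <- edges[edges$from != edges$to, , drop = FALSE]   # self-loops
  if (!directed) {
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    edges$from <- a
    edges$to <- b
  }
  edges <- edges[!duplicated(edges[c("from", "to")]), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = directed)
  g <- igraph::set_graph_attr(g, "provenance", provenance)
  g
}

#' Write a network as a tab-separated edge list
#' @param net an `igraph` graph.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' First column holds gene identifiers, header row the sample identifiers.
#' Values are expected on a log scale (e.g. log(TPM+1)); the reader only
#' enforces numeric, finite entries and unique identifiers.
#'
#' @param path path to the TSV file.
#' @return numeric matrix (genes in rows, samples in columns).
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (ncol(df) < 2) stop("matrix has no samples", call. = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample identifiers", call. = FALSE)
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                 genes[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
  }
  rownames(m) <- genes
  m
}

#' Write a matrix as TSV (lossless to full double precision)
#' @param m matrix with row and column names.
#' @param path output path.
#' @param id_col name of the first (identifier) column in the header.
#' @param header optional character vector of `#`-prefixed provenance lines
#'   written before the table.
#' @export
write_matrix <- function(m, path, id_col = "gene", header = NULL) {
  assert_matrix(m, "matrix")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(row)
    paste(format(row, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read a gene-level copy-number call matrix
#'
#' Same layout as [read_expression()] but entries must be integers
#' (GISTIC-style calls, by default in \{-1, 0, 1\} but any integer range is
#' accepted).
#'
#' @param path path to the TSV file.
#' @return integer matrix (genes in rows, samples in columns).
#' @export
read_cnv <- function(path) {
  m <- read_expression(path)
  if (any(m != round(m)))
    stop("copy-number matrix must contain integers only", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}
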
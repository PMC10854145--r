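# provenance header stamped into every pipeline output (no timestamps, so
# reruns with an identical configuration are byte-identical)
provenance_header <- function(config) {
  c(sprintf("iwhmb %s", as.character(utils::packageVersion("iwhmb"))),
    sprintf("config_hash %s", config_hash(config)),
    sprintf("seed %s", format(config$seed %||% NA)))
}

write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param maf,gmt,edges,expr input paths (required by [run_all()]).
#' @param tf_edges optional directed TF-target edge list path.
#' @param seed RNG seed used by every stochastic stage.
#' @param k number of subtype clusters.
#' @param subtype_method `"consensus"`, `"hclust"` or `"kmeans"`.
#' @param reps,p_item consensus-clustering subsampling parameters.
#' @param r_min,p_max cohort network / co-expression edge thresholds.
#' @param epsilon,cost SVR hyperparameters.
#' @param r_disc,p_disc,r_valid IRG calling thresholds.
#' @param coef_min perturbation-link coefficient threshold.
#' @param restart RWR restart probability.
#' @param top_k prioritized list length.
#' @param use_counts weight genes by mutation count in WHMB.
#' @return a named list; unknown keys passed by callers are rejected by
#'   [run_all()].
#' @export
pipeline_config <- function(maf = NULL, gmt = NULL, edges = NULL,
                            expr = NULL, tf_edges = NULL, seed = 1,
                            k = 4, subtype_method = "consensus", reps = 50,
                            p_item = 0.8, r_min = 0.4, p_max = 0.05,
                            epsilon = 0.1, cost = 1, r_disc = 0.2,
                            p_disc = 0.05, r_valid = 0.1, coef_min = 0.15,
                            restart = 0.7, top_k = 500,
                            use_counts = FALSE) {
  as.list(environment())
}

stop_missing_input <- function(path, what) {
  if (is.null(path))
    stop(structure(class = c("iwhmb_input_error", "error", "condition"),
                   list(message = sprintf("no %s input configured", what),
                        call = NULL)))
  if (!file.exists(path))
    stop(structure(class = c("iwhmb_input_error", "error", "condition"),
                   list(message = sprintf("%s input not found: %s",
                                          what, path),
                        call = NULL)))
  path
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "iwhmb_input_error")) stop(e)
    stop(structure(class = c("iwhmb_stage_error", "error", "condition"),
                   list(message = sprintf("stage '%s' failed: %s", name,
                                          conditionMessage(e)),
                        call = NULL)))
  })
}

#' Run the whole pipeline on one cohort
#'
#' Executes scoring, subtyping, SVR-based gene calling, co-expression
#' network and community assembly, module eigengene scoring and
#' random-walk bridge-gene prioritization, writing every intermediate as a
#' provenance-stamped TSV under `out_dir`. All randomness derives from
#' `config$seed`, so reruns with an identical configuration are
#' byte-identical. By default the two largest co-expression communities
#' seed the two random walks; real analyses would pass curated progression
#' and immune gene lists via `seeds_a` / `seeds_b`.
#'
#' @param config list from [pipeline_config()] (unknown keys are
#'   rejected), with input paths `maf`, `gmt`, `edges`, `expr` and
#'   optionally `tf_edges`.
#' @param out_dir output directory.
#' @param seeds_a,seeds_b optional seed gene vectors for the two random
#'   walks.
#' @return named vector of output paths, invisibly.
#' @export
run_all <- function(config, out_dir, seeds_a = NULL, seeds_b = NULL) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  config <- utils::modifyList(pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(config)
  paths <- character(0)
  emit <- function(name) {
    p <- file.path(out_dir, name)
    paths[[name]] <<- p
    p
  }

  ## inputs
  profiles <- run_stage("read", read_maf(stop_missing_input(config$maf, "MAF")))
  sets <- run_stage("read", read_gmt(stop_missing_input(config$gmt, "GMT")))
  net <- run_stage("read",
                   read_edge_list(stop_missing_input(config$edges, "edge list")))
  expr <- run_stage("read",
                    read_expression(stop_missing_input(config$expr, "expression")))
  tf <- if (!is.null(config$tf_edges))
    run_stage("read", read_edge_list(config$tf_edges, directed = TRUE))
  else NULL

  ## score
  fit <- run_stage("score",
    iwhmb(profiles, sets, net, expr = expr, r_min = config$r_min,
          p_max = config$p_max, use_counts = config$use_counts))
  write_matrix(fit$whmb, emit("whmb.tsv"), id_col = "set", header = hdr)
  write_matrix(fit$iwhmb, emit("iwhmb.tsv"), id_col = "set", header = hdr)

  ## subtype
  subtype <- run_stage("subtype", {
    switch(config$subtype_method,
      consensus = consensus_cluster(fit$iwhmb, max_k = config$k,
                                    reps = config$reps,
                                    p_item = config$p_item,
                                    seed = config$seed)[[paste0("k", config$k)]],
      hclust = hierarchical_cluster(fit$iwhmb, k = config$k),
      kmeans = kmeans_cluster(fit$iwhmb, k = config$k, seed = config$seed),
      stop("unknown subtype method: ", config$subtype_method))
  })
  write_tsv(data.frame(sample = names(subtype$labels),
                       cluster = subtype$labels,
                       dominant_set = subtype$dominant_set[subtype$labels]),
            emit("subtype_labels.tsv"), header = hdr)

  ## irg
  expr_z <- zscore_rows(expr)
  fits <- run_stage("irg",
    fit_svr_per_gene(fit$iwhmb, expr_z, epsilon = config$epsilon,
                     cost = config$cost))
  irgs <- call_irgs(fits, r_disc = config$r_disc, p_disc = config$p_disc)
  write_tsv(irgs, emit("irgs.tsv"), header = hdr)
  links <- perturbation_links(fits, coef_min = config$coef_min)
  write_tsv(links, emit("links.tsv"), header = hdr)

  ## co-expression network + communities over discovery genes
  called <- irgs$gene[irgs$status != "rejected"]
  bhg_out <- NULL
  if (length(called) >= 2) {
    coex <- run_stage("coexpression",
      coexpression_network(expr, called, r_min = config$r_min,
                           p_max = config$p_max))
    write_edge_list(coex, emit("coexpression_edges.tsv"))
    if (igraph::vcount(coex) > 0) {
      comm <- run_stage("communities", detect_communities(coex))
      write_tsv(data.frame(gene = names(comm$membership),
                           community = comm$membership),
                emit("communities.tsv"), header = hdr)
      comm_sizes <- sort(table(comm$membership), decreasing = TRUE)
      main_genes <- names(comm$membership)[comm$membership ==
                                             as.integer(names(comm_sizes)[1])]
      if (length(main_genes) >= 2) {
        eig <- run_stage("eigengene", module_eigengene(expr, main_genes))
        write_tsv(data.frame(sample = names(eig$score), score = eig$score),
                  emit("eigengene.tsv"), header = hdr)
      }
      ## bridge genes: random walks seeded from the two largest communities
      if (is.null(seeds_a)) seeds_a <- main_genes
      if (is.null(seeds_b) && length(comm_sizes) >= 2)
        seeds_b <- names(comm$membership)[comm$membership ==
                                            as.integer(names(comm_sizes)[2])]
      if (!is.null(seeds_a) && !is.null(seeds_b)) {
        walk_net <- integrate_networks(net, tf)
        bhg_out <- run_stage("bhg", {
          ra <- rwr(walk_net, seeds_a, restart = config$restart)
          rb <- rwr(walk_net, seeds_b, restart = config$restart)
          bhg_intersect(top_k(ra, k = config$top_k),
                        top_k(rb, k = config$top_k))
        })
        write_tsv(data.frame(gene = bhg_out$genes,
                             rank_a = bhg_out$rank_a,
                             rank_b = bhg_out$rank_b),
                  emit("bhg.tsv"), header = hdr)
      }
    }
  }
  invisible(paths)
}
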
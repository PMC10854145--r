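#' Configuration for a synthetic mutation-expression cohort
#'
#' Bundles every knob of the generator with defaults chosen to emulate a
#' desk-scale tumor cohort: a scale-free interaction network over 2000
#' genes, 50 gene sets, 300 samples split into 4 pathway-mutation
#' subtypes whose enriched sets carry an 8-fold mutation-rate multiplier,
#' a lognormal per-sample global mutation rate (the TMB confound the
#' per-sample standardization must remove), 200 planted genes whose
#' expression responds linearly to IWHMB, and planted bridge genes wired
#' to both a progression module and an immune gene list.
#'
#' @param n_samples number of tumor samples.
#' @param n_genes size of the gene universe.
#' @param n_sets number of gene sets.
#' @param set_size_range inclusive range of set sizes.
#' @param pa_power preferential-attachment power of the scale-free network.
#' @param pa_m edges added per node during attachment.
#' @param n_subtypes number of planted subtypes.
#' @param sets_per_subtype enriched sets per subtype (disjoint across
#'   subtypes).
#' @param enrich_multiplier mutation-rate multiplier inside a subtype's
#'   enriched sets; 1 plants no subtype signal.
#' @param background_rate median per-gene background mutation probability.
#' @param tmb_sdlog lognormal sd of the per-sample global rate.
#' @param count_extra_prob probability that a mutated gene carries a second
#'   mutation event (exercises count mode).
#' @param n_planted_irgs number of genes with planted IWHMB-driven
#'   expression.
#' @param coef_range absolute-coefficient range of planted responses.
#' @param sets_per_irg_max planted responses draw 1..this many sets.
#' @param expr_noise_sd Gaussian noise sd added to planted expression.
#' @param n_planted_bridges number of planted bridge genes.
#' @param bridge_degree edges wired from each bridge to each side.
#' @param group_size size of the progression module and of the immune gene
#'   list the bridges connect.
#' @param n_tf_edges number of random directed TF-target edges.
#' @param seed RNG seed (mandatory; the whole cohort is a pure function of
#'   the configuration).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 300, n_genes = 2000, n_sets = 50,
                             set_size_range = c(15, 40), pa_power = 1,
                             pa_m = 2, n_subtypes = 4, sets_per_subtype = 6,
                             enrich_multiplier = 8, background_rate = 0.05,
                             tmb_sdlog = 0.8, count_extra_prob = 0.05,
                             n_planted_irgs = 200, coef_range = c(0.3, 0.9),
                             sets_per_irg_max = 3, expr_noise_sd = 0.5,
                             n_planted_bridges = 15, bridge_degree = 4,
                             group_size = 40, n_tf_edges = 200, seed = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_samples > 0, n_genes > 0, n_sets > 1,
              set_size_range[1] >= 1, set_size_range[2] <= n_genes,
              n_subtypes >= 1, enrich_multiplier > 0,
              background_rate > 0, background_rate < 1,
              n_planted_irgs <= n_genes, expr_noise_sd >= 0,
              length(seed) == 1)
    if (n_subtypes * sets_per_subtype > n_sets)
      stop("not enough sets for the requested subtype enrichment",
           call. = FALSE)
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic cohort with planted structure
#'
#' Builds, in order: (i) a scale-free interaction network over the gene
#' universe, with planted bridge genes wired to both a progression module
#' and an immune gene list, plus random directed TF-target edges; (ii)
#' gene sets sampled from the universe; (iii) somatic mutation profiles
#' with a lognormal per-sample global rate and an elevated rate inside
#' each subtype's enriched sets; (iv) the WHMB/IWHMB matrices, computed by
#' the package's own scoring pipeline on the generated network; (v) an
#' expression matrix in which planted genes respond linearly to the IWHMB
#' of their driver sets plus Gaussian noise while the remaining genes are
#' pure noise; and (vi) a random copy-number call matrix. The result is a
#' pure function of the configuration (identical seeds give identical
#' cohorts).
#'
#' @param config a [synthetic_config()] object.
#' @return object of class `synthetic_cohort`: list with `profiles`,
#'   `sets`, `network`, `tf_network`, `expr`, `cnv`, `whmb`, `iwhmb`,
#'   `truth` (subtype labels, enriched sets, planted coefficients, bridge
#'   genes, module gene lists, per-sample global rates) and `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  cfg <- config
  set.seed(cfg$seed)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))

  ## (i) scale-free network + planted bridges + TF edges
  g <- igraph::sample_pa(cfg$n_genes, power = cfg$pa_power, m = cfg$pa_m,
                         directed = FALSE)
  igraph::V(g)$name <- genes
  non_hub <- genes
  progression <- sample(non_hub, cfg$group_size)
  immune <- sample(setdiff(non_hub, progression), cfg$group_size)
  bridges <- sample(setdiff(non_hub, c(progression, immune)),
                    cfg$n_planted_bridges)
  bridge_edges <- do.call(rbind, lapply(bridges, function(b) {
    data.frame(from = b,
               to = c(sample(progression, cfg$bridge_degree),
                      sample(immune, cfg$bridge_degree)),
               stringsAsFactors = FALSE)
  }))
  el <- igraph::as_edgelist(g)
  net <- network_from_edges(
    rbind(data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
          bridge_edges),
    directed = FALSE, provenance = "synthetic")
  tf <- network_from_edges(
    data.frame(from = sample(genes, cfg$n_tf_edges, replace = TRUE),
               to = sample(genes, cfg$n_tf_edges, replace = TRUE),
               stringsAsFactors = FALSE),
    directed = TRUE, provenance = "synthetic-tf")

  ## (ii) gene sets, grown by random walks on the network so that each
  ## set's induced subnetwork is connected and carries centrality signal
  ## (pathway members interact; a uniform draw would give edgeless
  ## subnetworks at this network density)
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  adj <- lapply(adj, function(v) v$name)
  names(adj) <- igraph::V(net)$name
  sizes <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]),
                  cfg$n_sets, replace = TRUE)
  set_list <- lapply(sizes, function(target) {
    members <- sample(genes, 1)
    frontier <- members
    while (length(members) < target) {
      nb <- setdiff(unique(unlist(adj[frontier])), members)
      if (length(nb) == 0) {            # stuck component: restart elsewhere
        frontier <- sample(setdiff(genes, members), 1)
        members <- c(members, frontier)
        next
      }
      take <- sample(nb, min(length(nb), target - length(members)))
      members <- c(members, take)
      frontier <- take
    }
    sample(members)                      # shuffle member order
  })
  names(set_list) <- sprintf("SET_%02d", seq_len(cfg$n_sets))
  sets <- gene_sets(set_list, source = "synthetic")

  ## (iii) mutation profiles with subtype enrichment and TMB confound
  subtype <- stats::setNames(
    sample(rep_len(seq_len(cfg$n_subtypes), cfg$n_samples)), samples)
  enriched_sets <- split(names(set_list)[seq_len(cfg$n_subtypes *
                                                   cfg$sets_per_subtype)],
                         rep(seq_len(cfg$n_subtypes),
                             each = cfg$sets_per_subtype))
  enriched_genes <- lapply(enriched_sets, function(s)
    unique(unlist(set_list[s])))
  global_rate <- stats::setNames(
    stats::rlnorm(cfg$n_samples, meanlog = log(cfg$background_rate),
                  sdlog = cfg$tmb_sdlog), samples)
  profiles <- lapply(samples, function(j) {
    rate <- rep(min(global_rate[[j]], 0.5), cfg$n_genes)
    idx <- match(enriched_genes[[subtype[[j]]]], genes)
    rate[idx] <- pmin(rate[idx] * cfg$enrich_multiplier, 0.9)
    hit <- stats::rbinom(cfg$n_genes, 1, rate) == 1
    mut <- genes[hit]
    counts <- 1L + stats::rbinom(length(mut), 1, cfg$count_extra_prob)
    stats::setNames(as.integer(counts), mut)
  })
  names(profiles) <- samples
  profiles <- mutation_profiles(profiles)

  ## (iv) scoring by the pipeline itself
  ctab <- geneset_centralities(net, sets)
  whmb <- compute_whmb(profiles, sets, ctab, net)
  iw <- suppressWarnings(compute_iwhmb(whmb))

  ## (v) expression: planted linear responses to IWHMB
  irgs <- sample(genes, cfg$n_planted_irgs)
  expr <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples), cfg$n_genes,
                 cfg$n_samples, dimnames = list(genes, samples))
  coef_rows <- list()
  for (gname in irgs) {
    k <- sample.int(cfg$sets_per_irg_max, 1)
    drv <- sample(names(set_list), k)
    beta <- stats::runif(k, cfg$coef_range[1], cfg$coef_range[2]) *
      sample(c(-1, 1), k, replace = TRUE)
    signal <- as.vector(crossprod(iw[drv, , drop = FALSE], beta))
    expr[gname, ] <- signal + stats::rnorm(cfg$n_samples, 0,
                                           cfg$expr_noise_sd)
    coef_rows[[gname]] <- data.frame(gene = gname, set = drv, beta = beta,
                                     stringsAsFactors = FALSE)
  }
  planted_coef <- do.call(rbind, c(coef_rows, list(make.row.names = FALSE)))

  ## (vi) copy-number calls
  cnv <- matrix(sample(c(-1L, 0L, 1L), cfg$n_genes * cfg$n_samples,
                       replace = TRUE, prob = c(0.1, 0.8, 0.1)),
                cfg$n_genes, cfg$n_samples,
                dimnames = list(genes, samples))

  structure(list(
    profiles = profiles, sets = sets, network = net, tf_network = tf,
    expr = expr, cnv = cnv, whmb = whmb, iwhmb = iw,
    truth = list(subtype = subtype, enriched_sets = enriched_sets,
                 planted_irgs = irgs, planted_coef = planted_coef,
                 bridges = bridges, progression_module = progression,
                 immune_genes = immune, global_rate = global_rate),
    config = cfg), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d samples, %d genes, %d sets, %d subtypes (seed %s)\n",
              x$config$n_samples, x$config$n_genes, x$config$n_sets,
              x$config$n_subtypes, format(x$config$seed)))
  invisible(x)
}

#' Hand-checkable toy cohort
#'
#' A fixed 5-node path network A-B-C-D-E, two 4-gene sets and three
#' samples with hand-written mutations, small enough that the weighted
#' burden scores can be recomputed by hand.
#'
#' @return a `synthetic_cohort`-like list with `profiles`, `sets`,
#'   `network`, `expr`.
#' @export
toy_fixture <- function() {
  net <- network_from_edges(
    data.frame(from = c("A", "B", "C", "D"),
               to = c("B", "C", "D", "E"), stringsAsFactors = FALSE),
    directed = FALSE, provenance = "toy")
  sets <- gene_sets(list(S1 = c("A", "B", "C", "D"),
                         S2 = c("C", "D", "E", "F")), source = "toy")
  profiles <- mutation_profiles(list(
    P1 = c("A", "F"),
    P2 = c("B", "C"),
    P3 = c("E")))
  expr <- matrix(c(1, 2, 3,
                   2, 4, 6,
                   3, 2, 1,
                   0.5, 0.1, 0.9,
                   1.5, 1.0, 0.5,
                   2.0, 2.2, 2.4), nrow = 6, byrow = TRUE,
                 dimnames = list(c("A", "B", "C", "D", "E", "F"),
                                 c("P1", "P2", "P3")))
  list(profiles = profiles, sets = sets, network = net, expr = expr)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `mutations.maf`, `sets.gmt`, `edges.tsv`, `tf_edges.tsv`,
#' `expr.tsv`, `cnv.tsv` and `truth.json` under `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(maf = file.path(dir, "mutations.maf"),
             gmt = file.path(dir, "sets.gmt"),
             edges = file.path(dir, "edges.tsv"),
             tf = file.path(dir, "tf_edges.tsv"),
             expr = file.path(dir, "expr.tsv"),
             cnv = file.path(dir, "cnv.tsv"),
             truth = file.path(dir, "truth.json"))
  write_maf(cohort$profiles, paths[["maf"]])
  write_gmt(cohort$sets, paths[["gmt"]])
  write_edge_list(cohort$network, paths[["edges"]])
  write_edge_list(cohort$tf_network, paths[["tf"]])
  write_matrix(cohort$expr, paths[["expr"]])
  write_matrix(cohort$cnv, paths[["cnv"]])
  truth <- cohort$truth
  truth$subtype <- as.list(truth$subtype)
  truth$global_rate <- as.list(truth$global_rate)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
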
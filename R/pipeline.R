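#' Run the full prioritization pipeline from a configuration
#'
#' One-shot orchestration of every stage: read inputs, filter drugs, infer
#' pathway activities (ssGSEA on mRNA; hypergeometric microRNA pathways and
#' their activities when microRNA inputs are supplied), build and merge the
#' pathway-level drug similarity networks, run the random walk from the seed
#' set, optionally attach permutation significance, and evaluate seed
#' recovery by LOOCV/ROC. Any stage's output may be supplied precomputed:
#' giving `inputs$network` skips the construction stages entirely.
#'
#' The configuration is a YAML file or an equivalent nested list with blocks
#' `inputs` (paths: `mrna`, `mirna`, `gene_sets`, `mirna_targets`,
#' `drug_activity`, `network`, `seeds`), `params` (see the parameter
#' defaults in [filter_drugs()], [pathway_activity()], [select_edges()],
#' [rwr()], [permutation_significance()]; plus `n_perm = 0` to skip the
#' permutation test, `remove_redundant`/`overlap_thresh` for pathway
#' de-redundancy, `mirna_alpha` for microRNA pathway assignment and
#' `rng_seed`) and `out_dir`.
#'
#' Written artifacts: `ranked.tsv` (the prioritization table), `network.tsv`
#' (edge list), `roc.tsv` (LOOCV ROC curve), pathway-activity matrices, and
#' `manifest.yaml` recording inputs, parameters, executed stages and MD5
#' hashes of every output.
#'
#' @param config YAML file path or nested list.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @param quiet suppress stage progress messages.
#' @return (invisibly) a list: `ranked` tibble, `network`, `evaluation`
#'   (`loocv_eval` or `NULL`), `manifest`, and output `paths`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  inputs <- config$inputs %||% list()
  prm <- pipeline_params(config$params %||% list())
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) {
    stop_dsn("no output directory configured", "dsn_bad_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  say <- function(stage, fmt, ...) {
    if (!quiet) {
      message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                      stage, sprintf(fmt, ...)))
    }
  }

  have_network <- !is.null(inputs$network)
  required <- c("seeds", if (!have_network)
    c("mrna", "gene_sets", "drug_activity"))
  missing_inputs <- setdiff(required, names(inputs))
  if (length(missing_inputs) > 0L) {
    stop_dsn(
      sprintf("missing required input(s): %s",
              paste(missing_inputs, collapse = ", ")),
      "dsn_bad_config"
    )
  }
  declared <- unlist(inputs, use.names = TRUE)
  absent <- declared[!file.exists(declared)]
  if (length(absent) > 0L) {
    stop_dsn(
      sprintf("input file(s) not found: %s", paste(absent, collapse = ", ")),
      "dsn_bad_config"
    )
  }

  stages <- character(0)
  paths <- c(manifest = file.path(out_dir, "manifest.yaml"))

  if (have_network) {
    say("network", "loading precomputed network from %s", inputs$network)
    network <- read_edge_list(inputs$network)
    stages <- c(stages, "load-network")
  } else {
    say("drug-screen", "reading drug activity from %s", inputs$drug_activity)
    acts <- read_drug_activity(inputs$drug_activity)
    acts <- filter_drugs(acts, min_obs = prm$min_obs, prob = prm$quartile_prob,
                         quantile_type = prm$quantile_type)
    say("drug-screen", "%d drugs retained", nrow(acts))
    stages <- c(stages, "filter-drugs")

    gene_sets <- read_gmt(inputs$gene_sets)
    if (isTRUE(prm$remove_redundant)) {
      gene_sets <- remove_redundant_pathways(gene_sets, prm$overlap_thresh)
      say("pathways", "%d non-redundant pathways", length(gene_sets))
    }
    mrna <- read_expression_matrix(inputs$mrna)
    act_mrna <- pathway_activity(mrna, gene_sets, tau = prm$tau)
    paths["mrna_pathway_activity"] <- file.path(out_dir, "mrna_pathway_activity.tsv")
    write_matrix_tsv(act_mrna, paths[["mrna_pathway_activity"]],
                     id_column = "pathway")
    say("pathway-activity", "%d mRNA pathways x %d samples",
        nrow(act_mrna), ncol(act_mrna))
    stages <- c(stages, "pathway-activity")

    nets <- list(build_level_network(act_mrna, acts, prm))
    say("build-network", "mRNA-level network: %d edges",
        nrow(network_edges(nets[[1]])))
    stages <- c(stages, "build-network-mrna")

    if (!is.null(inputs$mirna) && !is.null(inputs$mirna_targets)) {
      mirna <- read_expression_matrix(inputs$mirna)
      targets <- read_mirna_targets(inputs$mirna_targets)
      universe <- intersect(
        rownames(mrna),
        unique(c(unlist(gene_sets, use.names = FALSE),
                 unlist(targets, use.names = FALSE)))
      )
      mirna_sets <- build_mirna_pathways(targets, gene_sets,
                                         universe = universe,
                                         alpha = prm$mirna_alpha)
      if (length(mirna_sets) > 0L) {
        act_mirna <- pathway_activity(mirna, mirna_sets, tau = prm$tau)
        paths["mirna_pathway_activity"] <-
          file.path(out_dir, "mirna_pathway_activity.tsv")
        write_matrix_tsv(act_mirna, paths[["mirna_pathway_activity"]],
                         id_column = "pathway")
        nets <- c(nets, list(build_level_network(act_mirna, acts, prm)))
        say("build-network", "microRNA-level network: %d edges (%d pathways)",
            nrow(network_edges(nets[[2]])), nrow(act_mirna))
        stages <- c(stages, "build-network-mirna")
      } else {
        say("build-network", "no microRNA pathway retained; microRNA level skipped")
      }
    }
    network <- do.call(merge_networks, nets)
    stages <- c(stages, "merge-networks")
  }
  paths["network"] <- file.path(out_dir, "network.tsv")
  write_edge_list(network, paths[["network"]])
  say("network", "integrated network: %d nodes, %d edges",
      length(network_nodes(network)), nrow(network_edges(network)))

  seeds <- read_seed_list(inputs$seeds, network)
  say("prioritize", "%d seed drugs (restart set '%s')", length(seeds),
      attr(seeds, "label"))

  if (prm$n_perm > 0) {
    ranked <- permutation_significance(
      network, seeds, alpha = prm$alpha, tol = prm$tol,
      p0_mode = prm$p0_mode, n_perm = prm$n_perm,
      estimator = prm$p_estimator, null_model = prm$null_model,
      seed = prm$rng_seed
    )
    stages <- c(stages, "prioritize", "significance")
  } else {
    fit <- rwr(network, seeds, alpha = prm$alpha, tol = prm$tol,
               p0_mode = prm$p0_mode)
    ranked <- dplyr::mutate(fit$scores, p_value = NA_real_, fdr = NA_real_)
    ranked <- dplyr::relocate(ranked, "drug_id", "prior_score", "p_value",
                              "fdr", "rank", "is_seed")
    stages <- c(stages, "prioritize")
  }
  paths["ranked"] <- file.path(out_dir, "ranked.tsv")
  utils::write.table(ranked, paths[["ranked"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  evaluation <- NULL
  if (length(seeds) >= 2L) {
    evaluation <- loocv_evaluate(network, seeds, alpha = prm$alpha,
                                 tol = prm$tol, p0_mode = prm$p0_mode,
                                 negatives = prm$negatives)
    paths["roc"] <- file.path(out_dir, "roc.tsv")
    utils::write.table(evaluation$roc$curve, paths[["roc"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    say("evaluate", "LOOCV AUROC = %.4f", evaluation$auroc)
    stages <- c(stages, "evaluate")
  }

  outputs <- paths[names(paths) != "manifest"]
  manifest <- list(
    label = config$label %||% attr(seeds, "label"),
    inputs = as.list(inputs),
    params = prm,
    stages = stages,
    outputs = lapply(as.list(outputs), function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  )
  yaml::write_yaml(manifest, paths[["manifest"]])

  invisible(list(ranked = ranked, network = network, evaluation = evaluation,
                 manifest = manifest, paths = paths))
}

# one pathway level (mRNA or microRNA): correlations -> edge rule
build_level_network <- function(activity, acts, prm) {
  pd <- pathway_drug_correlation(activity, acts, min_pairs = prm$min_pairs)
  dd <- drug_drug_similarity(pd, min_pairs = prm$min_pairs)
  select_edges(dd, r_min = prm$r_min, fdr_max = prm$fdr_max,
               top_frac = prm$top_frac, rule = prm$edge_rule)
}

pipeline_params <- function(p) {
  defaults <- list(
    tau = 0.25, min_obs = 4, quartile_prob = 0.75, quantile_type = 7,
    min_pairs = 3, r_min = 0.7, fdr_max = 0.05, top_frac = 0.0005,
    edge_rule = "union", alpha = 0.7, tol = 1e-10, p0_mode = "unit",
    n_perm = 0, p_estimator = "literal", null_model = "rewire",
    negatives = "pooled", remove_redundant = FALSE, overlap_thresh = 0.8,
    mirna_alpha = 0.05, rng_seed = 1
  )
  unknown <- setdiff(names(p), names(defaults))
  if (length(unknown) > 0L) {
    stop_dsn(
      sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")),
      "dsn_bad_config"
    )
  }
  utils::modifyList(defaults, p)
}
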
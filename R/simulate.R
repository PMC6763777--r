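#' Configuration for the synthetic cell-line panel generator
#'
#' Describes a small NCI-60-like screening panel with planted structure:
#' cell lines grouped by tissue of origin, latent pathway activities shared
#' within tissues, gene (and microRNA) expression that co-varies with the
#' latent activity of the pathway it belongs to, and drug activity vectors
#' coupled to module-specific pathway signatures so that drugs fall into
#' known functional modules. Every downstream stage — ssGSEA, the
#' correlation-of-correlations network, the random walk, LOOCV — can then
#' be validated against exact ground truth.
#'
#' Defaults mirror the panel the method targets (60 cell lines from nine
#' tissues) with planted-module conditions used in the recovery analyses:
#' 4 modules of 5 drugs plus 20 uncoupled drugs, coupling strength
#' `beta = 2` against drug noise `noise_sd = 0.5`.
#'
#' @param n_samples number of cell lines (default 60).
#' @param n_tissues number of tissues of origin (default 9).
#' @param n_genes number of measured genes (default 600).
#' @param n_mirnas number of measured microRNAs (default 60).
#' @param n_pathways number of pathways (default 30).
#' @param pathway_size member genes per pathway (default 15; pathways get
#'   disjoint gene blocks, the remainder are background genes).
#' @param n_drugs total number of drugs (default 40).
#' @param n_drug_modules number of planted drug modules (default 4).
#' @param module_size drugs per module (default 5; remaining drugs are
#'   uncoupled noise).
#' @param signature_size pathways per module signature (default 3, disjoint
#'   across modules).
#' @param beta pathway-drug coupling strength (default 2; 0 removes all
#'   module structure).
#' @param noise_sd standard deviation of drug activity noise (default 0.5).
#' @param rng_seed integer seed; the whole panel is a deterministic function
#'   of the configuration.
#' @return a validated list of class `synthetic_panel_config`.
#' @export
synthetic_panel_config <- function(n_samples = 60, n_tissues = 9,
                                   n_genes = 600, n_mirnas = 60,
                                   n_pathways = 30, pathway_size = 15,
                                   n_drugs = 40, n_drug_modules = 4,
                                   module_size = 5, signature_size = 3,
                                   beta = 2, noise_sd = 0.5, rng_seed = 1) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_tissues = as.integer(n_tissues),
    n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
    n_pathways = as.integer(n_pathways), pathway_size = as.integer(pathway_size),
    n_drugs = as.integer(n_drugs), n_drug_modules = as.integer(n_drug_modules),
    module_size = as.integer(module_size),
    signature_size = as.integer(signature_size),
    beta = as.numeric(beta), noise_sd = as.numeric(noise_sd),
    rng_seed = as.integer(rng_seed)
  )
  assert_scalar_number(cfg$beta, "beta", lower = 0)
  assert_scalar_number(cfg$noise_sd, "noise_sd", lower = .Machine$double.xmin)
  if (cfg$n_tissues > cfg$n_samples) {
    stop_dsn("n_tissues cannot exceed n_samples", "dsn_bad_config")
  }
  if (cfg$n_drug_modules * cfg$module_size > cfg$n_drugs) {
    stop_dsn("module drugs (n_drug_modules * module_size) exceed n_drugs",
             "dsn_bad_config")
  }
  if (cfg$n_drug_modules * cfg$signature_size > cfg$n_pathways) {
    stop_dsn("module signatures need n_drug_modules * signature_size <= n_pathways",
             "dsn_bad_config")
  }
  if (cfg$n_pathways * cfg$pathway_size > cfg$n_genes) {
    stop_dsn("pathway gene blocks need n_pathways * pathway_size <= n_genes",
             "dsn_bad_config")
  }
  structure(cfg, class = "synthetic_panel_config")
}

#' Generate a synthetic screening panel with planted drug modules
#'
#' Latent-factor construction (all randomness from `rng_seed`):
#' \itemize{
#'   \item each pathway's latent activity is a per-tissue baseline
#'     `N(0, 1)` plus per-sample noise `N(0, 0.5)`;
#'   \item member genes of a pathway equal its latent activity plus
#'     `N(0, 0.5)` measurement noise, so ssGSEA ranks them high exactly when
#'     the pathway is active; background genes are `N(0, 1)` noise;
#'   \item two microRNAs per pathway track the pathway's latent activity and
#'     target a 60 percent subset of its genes (plus a few background genes);
#'     remaining microRNAs are noise with random targets;
#'   \item module drugs get activity `beta * sum(signature pathway
#'     activities) + N(0, noise_sd)`; uncoupled drugs are `N(0, 1)` noise.
#' }
#'
#' @param config a [synthetic_panel_config()].
#' @return a list: `mrna`, `mirna` (matrices features x samples),
#'   `gene_sets` ([gene_set_collection()]), `mirna_targets` (named list),
#'   `drug_activity` (matrix drugs x samples), `truth` (list with
#'   `module_of` tibble, `signature_pathways`, `seed_module`), `tissue_of`
#'   (named tissue assignment), and the `config`.
#' @export
generate_panel <- function(config = synthetic_panel_config()) {
  stopifnot(inherits(config, "synthetic_panel_config"))
  cfg <- config
  withr::with_seed(cfg$rng_seed, {
    samples <- sprintf("CL%02d", seq_len(cfg$n_samples))
    tissue_of <- stats::setNames(
      sort(rep_len(sprintf("T%02d", seq_len(cfg$n_tissues)), cfg$n_samples)),
      samples
    )
    pathways <- sprintf("PWY%02d", seq_len(cfg$n_pathways))
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    mirnas <- sprintf("mir%03d", seq_len(cfg$n_mirnas))
    drugs <- sprintf("D%03d", seq_len(cfg$n_drugs))

    # latent pathway activity: tissue baseline + sample noise
    act <- matrix(NA_real_, cfg$n_pathways, cfg$n_samples,
                  dimnames = list(pathways, samples))
    for (p in seq_len(cfg$n_pathways)) {
      base <- stats::rnorm(cfg$n_tissues)
      names(base) <- sprintf("T%02d", seq_len(cfg$n_tissues))
      act[p, ] <- base[tissue_of] + stats::rnorm(cfg$n_samples, sd = 0.5)
    }

    # disjoint member-gene blocks; leftover genes are background noise
    sets <- list()
    mrna <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples), cfg$n_genes,
                   dimnames = list(genes, samples))
    for (p in seq_len(cfg$n_pathways)) {
      block <- genes[((p - 1) * cfg$pathway_size + 1):(p * cfg$pathway_size)]
      sets[[pathways[p]]] <- block
      mrna[block, ] <- matrix(rep(act[p, ], each = cfg$pathway_size),
                              cfg$pathway_size) +
        matrix(stats::rnorm(cfg$pathway_size * cfg$n_samples, sd = 0.5),
               cfg$pathway_size)
    }
    gene_sets <- gene_set_collection(sets)
    background <- setdiff(genes, unlist(sets, use.names = FALSE))

    # microRNAs: 2 per pathway track its activity and target its genes
    mirna <- matrix(stats::rnorm(cfg$n_mirnas * cfg$n_samples), cfg$n_mirnas,
                    dimnames = list(mirnas, samples))
    mirna_targets <- list()
    linked <- utils::head(mirnas, min(cfg$n_mirnas, 2L * cfg$n_pathways))
    for (i in seq_along(mirnas)) {
      m <- mirnas[i]
      if (m %in% linked) {
        p <- ((i - 1L) %/% 2L) %% cfg$n_pathways + 1L
        block <- sets[[pathways[p]]]
        tg <- sample(block, max(2L, round(0.6 * length(block))))
        if (length(background) >= 3L) tg <- c(tg, sample(background, 3L))
        mirna[m, ] <- act[p, ] + stats::rnorm(cfg$n_samples, sd = 0.5)
      } else {
        tg <- sample(genes, 10L)
      }
      mirna_targets[[m]] <- tg
    }

    # drug modules: disjoint pathway signatures, coupled activity vectors
    n_module_drugs <- cfg$n_drug_modules * cfg$module_size
    module_of <- tibble(
      drug_id = drugs,
      module = c(rep(seq_len(cfg$n_drug_modules), each = cfg$module_size),
                 rep(NA_integer_, cfg$n_drugs - n_module_drugs))
    )
    signature_pathways <- lapply(seq_len(cfg$n_drug_modules), function(m) {
      pathways[((m - 1) * cfg$signature_size + 1):(m * cfg$signature_size)]
    })
    names(signature_pathways) <- paste0("module", seq_len(cfg$n_drug_modules))
    drug_activity <- matrix(stats::rnorm(cfg$n_drugs * cfg$n_samples),
                            cfg$n_drugs, dimnames = list(drugs, samples))
    for (d in seq_len(n_module_drugs)) {
      m <- module_of$module[d]
      sig <- signature_pathways[[m]]
      signal <- colSums(act[sig, , drop = FALSE])
      drug_activity[d, ] <- cfg$beta * signal +
        stats::rnorm(cfg$n_samples, sd = cfg$noise_sd)
    }

    list(
      mrna = mrna, mirna = mirna, gene_sets = gene_sets,
      mirna_targets = mirna_targets, drug_activity = drug_activity,
      truth = list(module_of = module_of,
                   signature_pathways = signature_pathways,
                   seed_module = 1L),
      tissue_of = tissue_of,
      config = cfg
    )
  })
}

#' Write a synthetic panel to standard-format files
#'
#' Emits the panel as the on-disk artifacts the pipeline consumes: TSV
#' matrices, a GMT of pathway gene sets, a two-column microRNA-target TSV
#' and a ground-truth module table.
#'
#' @param panel result of [generate_panel()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mrna = file.path(dir, "mrna.tsv"),
    mirna = file.path(dir, "mirna.tsv"),
    drug_activity = file.path(dir, "drug_activity.tsv"),
    gene_sets = file.path(dir, "pathways.gmt"),
    mirna_targets = file.path(dir, "mirna_targets.tsv"),
    modules = file.path(dir, "drug_modules.tsv")
  )
  write_matrix_tsv(panel$mrna, paths[["mrna"]], id_column = "gene_id")
  write_matrix_tsv(panel$mirna, paths[["mirna"]], id_column = "mirna_id")
  write_matrix_tsv(panel$drug_activity, paths[["drug_activity"]],
                   id_column = "drug_id")
  write_gmt(panel$gene_sets, paths[["gene_sets"]])
  tg <- tibble(
    mirna_id = rep(names(panel$mirna_targets),
                   lengths(panel$mirna_targets)),
    gene_id = unlist(panel$mirna_targets, use.names = FALSE)
  )
  utils::write.table(tg, paths[["mirna_targets"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$truth$module_of, paths[["modules"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a two-column microRNA-target interaction table
#'
#' TSV with microRNA IDs in the first column and target gene IDs in the
#' second; a header row is detected when the first line repeats no pair.
#'
#' @param path file path.
#' @param header `NULL` (auto: treat the first row as a header when its
#'   fields are the literal column names `mirna_id`/`gene_id`, or `TRUE`/
#'   `FALSE`).
#' @return named list: microRNA ID -> character vector of target genes.
#' @export
read_mirna_targets <- function(path, header = NULL) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) {
    stop_dsn(sprintf("'%s' is empty", path), "dsn_format_error")
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop_dsn("every row needs a microRNA ID and a target gene ID",
             "dsn_format_error")
  }
  if (is.null(header)) {
    header <- identical(tolower(fields[[1L]][1:2]), c("mirna_id", "gene_id"))
  }
  if (header) fields <- fields[-1L]
  m <- vapply(fields, `[[`, character(1), 1L)
  g <- vapply(fields, `[[`, character(1), 2L)
  out <- split(g, factor(m, levels = unique(m)))
  lapply(out, unique)
}
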
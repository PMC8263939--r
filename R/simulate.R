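#' @title Synthetic multi-dataset studies with planted ground truth
#' @description Generates multi-dataset expression studies (three sample
#'   groups per dataset, planted differentially expressed genes with
#'   group-monotone trends, planted decorrelated outlier samples,
#'   probe-level duplication with many-to-many mappings, intensity-dependent
#'   absent calls) and STRING-style weighted PPI edge lists with a planted
#'   dense module around a designated core gene set.  Every generator is a
#'   pure function of its configuration, including the seed; ground truth
#'   is returned separately and is never embedded in the matrices.
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param n_genes Number of genes.
#' @param group_sizes Named vector of samples per group per dataset,
#'   e.g. `c(normal = 10, primary = 10, metastatic = 10)` (each >= 3).
#' @param n_datasets_test,n_datasets_validation Dataset counts.
#' @param de_fraction Fraction of genes planted as DEGs per comparison
#'   class.
#' @param effect_size Log2-fold-change magnitude of planted effects (> 0).
#' @param noise_sd Log2-intensity noise SD.
#' @param monotone_fraction Fraction of MvsN-planted genes that get a
#'   monotone normal < primary < metastatic trend (primary at half effect).
#' @param n_outliers Planted outlier samples per dataset.
#' @param outlier_strength Decorrelation mixing weight in \[0, 1\].
#' @param probe_multiplicity Named probabilities of probes per gene, e.g.
#'   `c("1" = 0.6, "2" = 0.3, "3" = 0.1)`.
#' @param multi_gene_probe_rate Fraction of probes additionally mapped to a
#'   second gene (the many-to-many case).
#' @param absent_rate Overall fraction of absent detection calls, enriched
#'   in low-intensity cells.
#' @param ppi_n_nodes,ppi_core_size,ppi_module_size Planted-PPI geometry.
#' @param ppi_module_weights,ppi_background_weights Weight ranges
#'   (length-2, within (0, 1\]).
#' @param ppi_background_p Background (Erdos-Renyi) edge probability.
#' @param seed Master RNG seed; per-dataset streams are derived from it by
#'   fixed offsets so adding datasets never perturbs earlier ones.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       group_sizes = c(normal = 10, primary = 10,
                                       metastatic = 10),
                       n_datasets_test = 3, n_datasets_validation = 2,
                       de_fraction = 0.05, effect_size = 1.0,
                       noise_sd = 0.5, monotone_fraction = 0.5,
                       n_outliers = 1, outlier_strength = 1.0,
                       probe_multiplicity = c("1" = 0.6, "2" = 0.3,
                                              "3" = 0.1),
                       multi_gene_probe_rate = 0.02,
                       absent_rate = 0.1,
                       ppi_n_nodes = 60, ppi_core_size = 4,
                       ppi_module_size = 10,
                       ppi_module_weights = c(0.7, 0.95),
                       ppi_background_p = 0.05,
                       ppi_background_weights = c(0.15, 0.6),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 1, n_datasets_test >= 1, n_datasets_validation >= 0,
            de_fraction >= 0, de_fraction <= 1, effect_size > 0,
            noise_sd > 0, monotone_fraction >= 0, monotone_fraction <= 1,
            outlier_strength >= 0, outlier_strength <= 1,
            absent_rate >= 0, absent_rate <= 1,
            ppi_core_size >= 1, ppi_module_size <= ppi_n_nodes,
            ppi_core_size <= ppi_module_size,
            abs(sum(probe_multiplicity) - 1) < 1e-8)
  if (any(group_sizes < 3))
    stop_io("each group needs >= 3 samples (variance estimates undefined)")
  if (is.null(names(group_sizes)))
    names(group_sizes) <- GROUP_LEVELS
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-dataset expression study
#'
#' Each dataset carries the three groups with the configured sizes.  A
#' per-class set of planted DEG genes (disjoint across classes) shifts the
#' relevant group means by exactly +/- `effect_size` consistently across all
#' datasets; a configurable subset of the MvsN genes gets a monotone
#' normal < primary < metastatic trend.  Planted outlier samples are convex
#' mixtures of the sample's clean profile with an independent random
#' profile at `outlier_strength`.  The probe-level view duplicates gene
#' rows per the probe-multiplicity distribution with independent noise, and
#' absent calls are assigned at `absent_rate`, enriched in low-intensity
#' cells.
#'
#' @param config A [sim_config()].
#' @return list with elements:
#'   `datasets` (per dataset: gene-level `expr`, probe-level `probe_expr`,
#'   `calls` on probes, `role` = test/validation), `sheet` (combined sample
#'   sheet), `probe_map`, and `truth`
#'   (planted_degs per class, planted_outliers, gene_means per group).
#' @export
simulate_expression_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))

  ## gene-level truth: one stream, independent of dataset count
  set.seed(cfg$seed)
  base_mu <- log2(1 + stats::rlnorm(cfg$n_genes, meanlog = 6, sdlog = 1.2))
  names(base_mu) <- genes
  n_de <- round(cfg$de_fraction * cfg$n_genes)
  classes <- c("MvsN", "PvsN", "MvsP")
  if (3 * n_de > cfg$n_genes)
    stop_io("de_fraction too large for disjoint per-class planting")
  pool <- sample(genes, 3 * n_de)
  planted <- split(pool, rep(classes, each = n_de))[classes]
  dirs <- lapply(classes, function(cl)
    sample(c(1, -1), n_de, replace = TRUE))
  names(dirs) <- classes
  monotone <- if (n_de) sample(seq_len(n_de),
                               round(cfg$monotone_fraction * n_de)) else integer()

  ## per-group true means (log2), identical across datasets
  mu <- cbind(normal = base_mu, primary = base_mu, metastatic = base_mu)
  es <- cfg$effect_size
  if (n_de) {
    g <- planted$MvsN; d <- dirs$MvsN
    mu[g, "metastatic"] <- mu[g, "metastatic"] + d * es
    mu[g[monotone], "primary"] <- base_mu[g[monotone]] +
      d[monotone] * es / 2
    g <- planted$PvsN; d <- dirs$PvsN
    mu[g, "primary"] <- mu[g, "primary"] + d * es
    g <- planted$MvsP; d <- dirs$MvsP
    mu[g, "metastatic"] <- mu[g, "metastatic"] + d * es
  }

  ## probe map: one stream
  set.seed(cfg$seed + 1L)
  k <- sample(as.integer(names(cfg$probe_multiplicity)), cfg$n_genes,
              replace = TRUE, prob = cfg$probe_multiplicity)
  probe_gene <- rep(genes, k)
  probes <- sprintf("%s_at%d", probe_gene,
                    unlist(lapply(k, seq_len), use.names = FALSE))
  probe_map <- data.frame(probe_id = probes, gene_symbol = probe_gene,
                          stringsAsFactors = FALSE)
  extra <- which(stats::runif(length(probes)) < cfg$multi_gene_probe_rate)
  if (length(extra)) {
    second <- sample(genes, length(extra), replace = TRUE)
    ok <- second != probe_map$gene_symbol[extra]
    probe_map <- rbind(probe_map,
                       data.frame(probe_id = probes[extra][ok],
                                  gene_symbol = second[ok],
                                  stringsAsFactors = FALSE))
  }

  n_total <- cfg$n_datasets_test + cfg$n_datasets_validation
  datasets <- vector("list", n_total)
  sheets <- list()
  outlier_ids <- character()
  mu_span <- stats::sd(base_mu)

  for (ds in seq_len(n_total)) {
    set.seed(cfg$seed + 1000L * ds)        # fixed per-dataset stream
    ds_id <- sprintf("D%02d", ds)
    role <- if (ds <= cfg$n_datasets_test) "test" else "validation"
    grp <- rep(names(cfg$group_sizes), cfg$group_sizes)
    smp <- sprintf("%s_%s_%02d", ds_id, substr(grp, 1, 1),
                   unlist(lapply(cfg$group_sizes, seq_len),
                          use.names = FALSE))
    expr <- mu[, grp, drop = FALSE] +
      matrix(stats::rnorm(cfg$n_genes * length(grp), 0, cfg$noise_sd),
             nrow = cfg$n_genes)
    dimnames(expr) <- list(genes, smp)

    ## planted outliers: convex mixture with an independent profile
    n_out <- min(cfg$n_outliers, length(smp))
    outs <- sample(smp, n_out)
    for (s in outs) {
      indep <- mean(base_mu) + stats::rnorm(cfg$n_genes, 0, mu_span) +
        stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
      expr[, s] <- (1 - cfg$outlier_strength) * expr[, s] +
        cfg$outlier_strength * indep
    }
    outlier_ids <- c(outlier_ids, outs)

    ## probe-level duplication with independent probe noise
    probe_rows <- match(rep(genes, k), genes)
    probe_expr <- expr[probe_rows, , drop = FALSE] +
      matrix(stats::rnorm(length(probes) * length(smp), 0, cfg$noise_sd / 2),
             nrow = length(probes))
    rownames(probe_expr) <- probes

    ## absent calls enriched in low-intensity cells:
    ## P(absent | rank r of intensity) = 2 * absent_rate * (1 - r), mean
    ## absent_rate by construction
    rk <- (rank(probe_expr, ties.method = "first") - 0.5) /
      length(probe_expr)
    p_abs <- pmin(1, 2 * cfg$absent_rate * (1 - rk))
    calls <- matrix(ifelse(stats::runif(length(probe_expr)) < p_abs,
                           "A", "P"),
                    nrow = nrow(probe_expr), dimnames = dimnames(probe_expr))

    datasets[[ds]] <- list(id = ds_id, role = role, expr = expr,
                           probe_expr = probe_expr, calls = calls)
    sheets[[ds]] <- data.frame(sample_id = smp, dataset_id = ds_id,
                               group = grp, stringsAsFactors = FALSE)
  }
  names(datasets) <- vapply(datasets, `[[`, "", "id")
  sheet <- do.call(rbind, sheets)
  rownames(sheet) <- NULL

  planted_degs <- lapply(classes, function(cl) {
    if (!n_de) return(data.frame(gene = character(), direction = character(),
                                 stringsAsFactors = FALSE))
    data.frame(gene = planted[[cl]],
               direction = ifelse(dirs[[cl]] > 0, "Up", "Down"),
               stringsAsFactors = FALSE)
  })
  names(planted_degs) <- classes

  list(datasets = datasets, sheet = sheet, probe_map = probe_map,
       truth = list(planted_degs = planted_degs,
                    planted_outliers = unique(outlier_ids),
                    gene_means = mu))
}

#' Simulate a STRING-style weighted PPI edge list with a planted module
#'
#' The planted module is a dense, high-weight, guaranteed-connected
#' subgraph containing all core nodes plus the planted proximal nodes; the
#' background layer is an Erdos-Renyi graph at `ppi_background_p` with
#' lower weights.  With background probability 0 every edge lies inside the
#' module.
#'
#' @param config A [sim_config()].
#' @param node_names Optional character vector of length `ppi_n_nodes`; the
#'   first `ppi_module_size` are the module (of which the first
#'   `ppi_core_size` are the cores).  Defaults to `N001...`.
#' @return list(edges = data.frame(node1, node2, weight),
#'   truth = list(core_nodes, planted_proximal_nodes, module_nodes,
#'   background_nodes)).
#' @export
simulate_ppi <- function(config, node_names = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$ppi_n_nodes
  m <- cfg$ppi_module_size
  if (m > n) stop_io("module size exceeds node count")
  if (is.null(node_names)) node_names <- sprintf("N%03d", seq_len(n))
  stopifnot(length(node_names) == n, !anyDuplicated(node_names))
  set.seed(cfg$seed + 77L)
  module <- node_names[seq_len(m)]
  core <- module[seq_len(cfg$ppi_core_size)]
  proximal <- setdiff(module, core)

  runif_range <- function(k, rng) stats::runif(k, rng[1L], rng[2L])
  edges <- list()
  ## module: spanning path for guaranteed connectivity + dense random fill
  if (m >= 2L) {
    edges$path <- data.frame(node1 = module[-m], node2 = module[-1L],
                             stringsAsFactors = FALSE)
    pairs <- t(utils::combn(module, 2L))
    pick <- stats::runif(nrow(pairs)) < 0.75
    edges$dense <- data.frame(node1 = pairs[pick, 1L],
                              node2 = pairs[pick, 2L],
                              stringsAsFactors = FALSE)
  }
  mod_edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(node1 = character(), node2 = character(),
               stringsAsFactors = FALSE)
  mod_edges$weight <- runif_range(nrow(mod_edges), cfg$ppi_module_weights)

  ## background layer: every pair not fully inside the module
  bg_edges <- NULL
  if (cfg$ppi_background_p > 0 && n >= 2L) {
    all_pairs <- t(utils::combn(node_names, 2L))
    inside <- all_pairs[, 1L] %in% module & all_pairs[, 2L] %in% module
    cand <- all_pairs[!inside, , drop = FALSE]
    pick <- stats::runif(nrow(cand)) < cfg$ppi_background_p
    if (any(pick)) {
      bg_edges <- data.frame(node1 = cand[pick, 1L], node2 = cand[pick, 2L],
                             weight = runif_range(sum(pick),
                                                  cfg$ppi_background_weights),
                             stringsAsFactors = FALSE)
    }
  }
  out <- rbind(mod_edges, bg_edges)
  lo <- pmin(out$node1, out$node2); hi <- pmax(out$node1, out$node2)
  out$node1 <- lo; out$node2 <- hi
  out <- out[!duplicated(paste(lo, hi)), , drop = FALSE]
  out <- out[order(out$node1, out$node2), , drop = FALSE]
  rownames(out) <- NULL
  list(edges = out,
       truth = list(core_nodes = core, planted_proximal_nodes = proximal,
                    module_nodes = module,
                    background_nodes = setdiff(node_names, module)))
}

#' Write a simulated study to disk
#'
#' Emits per-dataset expression, probe-level and call TSVs, the combined
#' sample sheet, the probe map, and the ground truth as separate files
#' (pipeline stages must never read the truth files).
#'
#' @param study Output of [simulate_expression_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ds in study$datasets) {
    write_expression_tsv(ds$expr, file.path(dir, paste0(ds$id, "_genes.tsv")))
    write_expression_tsv(ds$probe_expr,
                         file.path(dir, paste0(ds$id, "_probes.tsv")))
    write_calls_tsv(ds$calls, file.path(dir, paste0(ds$id, "_calls.tsv")))
  }
  write_sample_sheet(study$sheet, file.path(dir, "samples.tsv"))
  write_probe_map(study$probe_map, file.path(dir, "probe_map.tsv"))
  truth_dir <- file.path(dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  for (cl in names(study$truth$planted_degs))
    utils::write.table(study$truth$planted_degs[[cl]],
                       file.path(truth_dir, paste0("planted_", cl, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(study$truth$planted_outliers,
             file.path(truth_dir, "planted_outliers.txt"))
  invisible(dir)
}
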
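#' @title Pipeline orchestration
#' @description Runs the full chain -- simulate/ingest, preprocessing,
#'   outlier QC, differential expression, meta-integration and core-network
#'   extraction -- from one structured configuration, writing every
#'   intermediate artifact plus a run manifest with content hashes so a
#'   re-run with the same config and inputs is reproducible hash-for-hash.
#' @name pipeline_cli
NULL

default_thresholds <- function() {
  list(max_absent = 2, absent_mode = "all_groups",
       outlier_threshold = -2, outlier_convention = "correlation",
       outlier_iterations = 1,
       lfc_cut = 0.5, alpha = 0.05,
       report_cut = 0.2, presence_cut = 0.2,
       sp_mode = "complete")
}

#' Validate a pipeline configuration
#'
#' Accepts either a configuration list or a path to a YAML file.  Returns a
#' data.frame of violations (field, problem); an empty frame means the
#' configuration is valid.
#'
#' @param config List or YAML path.
#' @return data.frame (field, problem).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_io("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_io("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  v <- list()
  bad <- function(field, problem) v[[length(v) + 1L]] <<-
    data.frame(field = field, problem = problem, stringsAsFactors = FALSE)
  th <- utils::modifyList(default_thresholds(),
                          if (is.null(config$thresholds)) list()
                          else config$thresholds)
  chk_range <- function(name, lo, hi) {
    x <- th[[name]]
    if (!is.numeric(x) || length(x) != 1L || x < lo || x > hi)
      bad(name, sprintf("must be a number in [%s, %s]", lo, hi))
  }
  chk_range("alpha", 0, 1)
  chk_range("lfc_cut", 0, Inf)
  chk_range("report_cut", 0, Inf)
  chk_range("presence_cut", 0, Inf)
  chk_range("max_absent", 0, Inf)
  if (!th$absent_mode %in% c("all_groups", "any_group"))
    bad("absent_mode", "must be all_groups or any_group")
  if (!th$outlier_convention %in% c("correlation", "distance"))
    bad("outlier_convention", "must be correlation or distance")
  if (!th$sp_mode %in% c("complete", "edges_only"))
    bad("sp_mode", "must be complete or edges_only")
  if (is.null(config$simulation)) {
    dss <- config$datasets
    if (is.null(dss) || !length(dss)) {
      bad("datasets", "no datasets and no simulation block")
    } else {
      roles <- vapply(dss, function(d)
        if (is.null(d$role)) "" else d$role, "")
      if (!any(roles == "test"))
        bad("datasets", "at least one dataset must have role 'test'")
      for (d in dss) {
        for (p in intersect(names(d),
                            c("expr_path", "probe_path", "calls_path"))) {
          if (!file.exists(d[[p]]))
            bad(p, paste("missing path:", d[[p]]))
        }
      }
    }
    if (!is.null(config$ppi_path) && !file.exists(config$ppi_path))
      bad("ppi_path", paste("missing path:", config$ppi_path))
  }
  if (!is.null(config$core_genes_path) &&
      !file.exists(config$core_genes_path))
    bad("core_genes_path", paste("missing path:", config$core_genes_path))
  if (length(v)) do.call(rbind, v)
  else data.frame(field = character(), problem = character(),
                  stringsAsFactors = FALSE)
}

preprocess_dataset <- function(ds, sheet, th) {
  reports <- list()
  if (!is.null(ds$probe_expr)) {
    fa <- filter_absent(ds$probe_expr, ds$calls, sheet,
                        max_absent = th$max_absent, mode = th$absent_mode)
    reports$absent <- fa$report
    qn <- quantile_normalize(fa$expr)
    lv <- filter_low_variance(qn)
    reports$low_variance <- lv$report
    cp <- collapse_probes(lv$expr, ds$probe_map)
    reports$collapse <- cp$report
    expr <- cp$expr
  } else {
    pp <- prepare_precomputed(ds$expr, already_log2 = isTRUE(ds$already_log2))
    reports$precomputed <- pp$report
    expr <- quantile_normalize(pp$expr)
  }
  list(expr = expr, reports = reports)
}

comparisons_for <- function(groups_present) {
  specs <- list(MvsN = c("metastatic", "normal"),
                PvsN = c("primary", "normal"),
                MvsP = c("metastatic", "primary"))
  Filter(function(s) all(s %in% groups_present), specs)
}

#' Run the full pipeline
#'
#' Stages run in fixed order: ingest/simulate, preprocess, outlier QC,
#' per-dataset differential expression, meta-integration (test datasets
#' drive the per-class intersections and core-gene selection, validation
#' datasets drive the final-DEG filter and the direction table), and
#' core-network extraction.  All intermediate artifacts are written under
#' `config$outdir` and hashed into the returned manifest.
#'
#' @param config Configuration list (or YAML path).  Recognized fields:
#'   `outdir` (required), `seed`, `simulation` (a list of [sim_config()]
#'   arguments; mutually exclusive with `datasets`/`ppi_path`),
#'   `datasets` (list of entries with `id`, `role`, `expr_path` or
#'   `probe_path` + `calls_path`, `already_log2`), `sheet_path`,
#'   `probe_map_path`, `ppi_path`, `ppi_score_scale`, `core_genes_path` or
#'   `core_genes`, and `thresholds` (overrides of the documented defaults).
#' @return A `pipeline_result` list: de_results, class_intersections,
#'   final_degs, core_genes, scores, core_network, descriptives,
#'   outlier_reports, manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    viol <- validate_config(config)
    config <- yaml::read_yaml(config)
  } else viol <- validate_config(config)
  if (nrow(viol))
    stop_io("invalid config: ",
            paste(viol$field, viol$problem, sep = ": ", collapse = "; "))
  if (is.null(config$outdir)) stop_io("config$outdir is required")
  th <- utils::modifyList(default_thresholds(),
                          if (is.null(config$thresholds)) list()
                          else config$thresholds)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  log_warn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  stage <- "ingest"
  result <- withCallingHandlers(warning = log_warn, tryCatch({
    ## ---- ingest or simulate -------------------------------------------
    if (!is.null(config$simulation)) {
      cfg <- do.call(sim_config, config$simulation)
      study <- simulate_expression_study(cfg)
      sheet <- study$sheet
      datasets <- lapply(study$datasets, function(d)
        list(id = d$id, role = d$role, probe_expr = d$probe_expr,
             calls = d$calls, probe_map = study$probe_map))
      ## PPI nodes drawn from the simulated gene universe: cores from the
      ## planted MvsP genes, proximal module members from the other
      ## planted classes, background from unplanted genes
      truth <- study$truth
      pick <- function(x, n) x[seq_len(min(n, length(x)))]
      cores <- pick(sort(truth$planted_degs$MvsP$gene), cfg$ppi_core_size)
      prox <- pick(sort(c(truth$planted_degs$MvsN$gene,
                          truth$planted_degs$PvsN$gene)),
                   cfg$ppi_module_size - length(cores))
      planted_all <- unlist(lapply(truth$planted_degs, `[[`, "gene"),
                            use.names = FALSE)
      bg <- pick(sort(setdiff(rownames(study$datasets[[1]]$expr),
                              planted_all)),
                 cfg$ppi_n_nodes - length(cores) - length(prox))
      ppi <- simulate_ppi(cfg, node_names = c(cores, prox, bg))
      edges <- ppi$edges
      write_string_edgelist(edges, file.path(outdir, "ppi_edges.tsv"))
    } else {
      sheet <- read_sample_sheet(config$sheet_path)
      probe_map <- if (!is.null(config$probe_map_path))
        read_probe_map(config$probe_map_path) else NULL
      datasets <- lapply(config$datasets, function(d) {
        entry <- list(id = d$id, role = d$role,
                      already_log2 = isTRUE(d$already_log2))
        if (!is.null(d$probe_path)) {
          entry$probe_expr <- read_expression_tsv(d$probe_path)
          entry$calls <- if (!is.null(d$calls_path))
            read_calls_tsv(d$calls_path) else NULL
          entry$probe_map <- probe_map
        } else entry$expr <- read_expression_tsv(d$expr_path)
        entry
      })
      names(datasets) <- vapply(datasets, `[[`, "", "id")
      edges <- read_string_edgelist(
        config$ppi_path,
        if (is.null(config$ppi_score_scale)) "milli"
        else config$ppi_score_scale)
    }

    ## ---- preprocess + outlier QC + DE ---------------------------------
    stage <- "preprocess"
    de_results <- list()
    outlier_reports <- list()
    roles <- character()
    for (d in datasets) {
      ds_sheet <- sheet[sheet$dataset_id == d$id, , drop = FALSE]
      pp <- preprocess_dataset(d, ds_sheet, th)
      expr <- pp$expr
      stage <- "outlier_qc"
      oq <- remove_outliers(expr, ds_sheet,
                            threshold = th$outlier_threshold,
                            convention = th$outlier_convention,
                            max_iterations = th$outlier_iterations)
      outlier_reports[[d$id]] <- oq$reports
      expr <- oq$expr; ds_sheet <- oq$sheet
      write_expression_tsv(expr,
                           file.path(outdir, paste0(d$id, "_clean.tsv")))
      stage <- "diffexpr"
      grp_present <- names(which(table(ds_sheet$group) >= 2))
      for (cmp in names(comparisons_for(grp_present))) {
        spec <- comparisons_for(grp_present)[[cmp]]
        key <- paste(d$id, cmp, sep = ".")
        de <- moderated_t_test(expr, ds_sheet, spec[1L], spec[2L],
                               label = key)
        de_results[[key]] <- de
        roles[key] <- d$role
        utils::write.table(as.data.frame(de),
                           file.path(outdir, paste0("de_", key, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }

    ## ---- meta-integration ---------------------------------------------
    stage <- "meta_integration"
    classes <- c("MvsN", "PvsN", "MvsP")
    test_keys <- names(de_results)[roles == "test"]
    val_keys <- names(de_results)[roles == "validation"]
    class_of <- function(keys, cl) keys[grepl(paste0("\\.", cl, "$"), keys)]
    intersections <- lapply(classes, function(cl) {
      keys <- class_of(test_keys, cl)
      if (!length(keys))
        return(data.frame(gene = character(), direction = character(),
                          stringsAsFactors = FALSE))
      intersect_class(lapply(de_results[keys], select_degs,
                             lfc_cut = th$lfc_cut, alpha = th$alpha))
    })
    names(intersections) <- classes
    validation_by_class <- lapply(classes, function(cl)
      de_results[class_of(val_keys, cl)])
    names(validation_by_class) <- classes
    final_degs <- final_deg_set(intersections, validation_by_class,
                                presence_cut = th$presence_cut)
    user_core <- if (!is.null(config$core_genes)) config$core_genes
      else if (!is.null(config$core_genes_path))
        read_gene_set(config$core_genes_path) else NULL
    core_genes <- select_core_genes(intersections, final_degs, user_core)
    for (cl in classes)
      write_gene_set(intersections[[cl]]$gene,
                     file.path(outdir, paste0("common_", cl, ".txt")))
    write_gene_set(final_degs$gene, file.path(outdir, "final_degs.txt"))
    write_gene_set(core_genes, file.path(outdir, "core_genes.txt"))
    dt <- direction_table(de_results, sort(unique(final_degs$gene)),
                          report_cut = th$report_cut)
    dt_df <- data.frame(gene = rownames(dt), dt,
                        concordance = apply(dt, 1L, classify_concordance),
                        check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(dt_df, file.path(outdir, "direction_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## ---- core network --------------------------------------------------
    stage <- "core_network"
    g <- build_graph(edges)
    gc <- giant_component(g)
    core_in_graph <- intersect(core_genes, igraph::V(gc)$name)
    scores <- NULL; core_net <- NULL; desc <- NULL
    if (length(core_in_graph) &&
        length(core_in_graph) < igraph::vcount(gc)) {
      tom <- tom_similarity(gc)
      dmat <- tom_distance(tom)
      sp <- all_shortest_paths_matrix(dmat, mode = th$sp_mode, graph = gc)
      scores <- dj_scores(sp, core_in_graph)
      core_net <- extract_core_network(gc, scores)
      desc <- network_descriptives(core_net)
      write_score_table(scores, file.path(outdir, "dj_scores.tsv"))
      write_graph_file(core_net, file.path(outdir, "core_network.tsv"),
                       "tsv")
      write_graph_file(core_net, file.path(outdir, "core_network.graphml"),
                       "graphml")
    } else {
      warning("no usable core genes in the giant component; ",
              "network scoring skipped", call. = FALSE)
    }

    list(de_results = de_results, class_intersections = intersections,
         final_degs = final_degs, core_genes = core_genes,
         direction_table = dt_df, scores = scores,
         core_network = core_net, descriptives = desc,
         outlier_reports = outlier_reports)
  }, error = function(e) {
    writeLines(paste0("FAILED at stage ", stage, ": ",
                      conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }))

  ## ---- manifest -------------------------------------------------------
  files <- setdiff(list.files(outdir, recursive = TRUE, full.names = TRUE),
                   file.path(outdir, "manifest.tsv"))
  manifest <- data.frame(
    file = sub(paste0("^", outdir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  result$manifest <- manifest
  result$warnings <- warnings_log
  result$config <- config
  class(result) <- "pipeline_result"
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  analyses:          ", length(x$de_results), "\n")
  for (cl in names(x$class_intersections))
    cat(sprintf("  common %s:       %4d genes\n", cl,
                nrow(x$class_intersections[[cl]])))
  cat("  final DEGs:        ", length(unique(x$final_degs$gene)), "\n")
  cat("  core genes:        ", length(x$core_genes), "\n")
  if (!is.null(x$core_network))
    cat("  core network:      ", igraph::vcount(x$core_network), "nodes /",
        igraph::ecount(x$core_network), "edges\n")
  invisible(x)
}
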
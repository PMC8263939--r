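#' @title On-disk formats
#' @description Readers and writers for every artifact the pipeline touches:
#'   expression matrices, sample sheets, detection-call matrices, probe-gene
#'   maps, STRING-style edge lists, gene sets, node score tables and graphs.
#'   All files are tab-separated UTF-8 with no quoting; readers validate
#'   strictly and reject rather than coerce malformed input.
#' @name io
NULL

stop_io <- function(...) stop(..., call. = FALSE)

#' Read an expression matrix from TSV
#'
#' The file must have a header row of sample IDs and a first column of
#' feature (probe or gene) IDs.  Values are log2-scale intensities or
#' expression levels; the literal string `NA` encodes a missing value.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with feature IDs as rownames and sample IDs as
#'   colnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop_io("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop_io("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  if (anyDuplicated(samples))
    stop_io("duplicate sample ID: ", samples[duplicated(samples)][1L])
  body <- fields[-1L]
  ncol_expected <- length(header)
  bad <- which(vapply(body, length, 1L) != ncol_expected)
  if (length(bad))
    stop_io("ragged row ", bad[1L] + 1L, ": expected ", ncol_expected,
            " fields")
  feats <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(feats))
    stop_io("duplicate feature ID: ", feats[duplicated(feats)][1L])
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples),
                 dimnames = list(feats, samples))
  for (i in seq_along(body)) {
    raw <- body[[i]][-1L]
    v <- suppressWarnings(as.numeric(raw))
    miss <- is.na(v) & raw != "NA"
    if (any(miss))
      stop_io("non-numeric value '", raw[which(miss)[1L]], "' at row ",
              i + 1L, ", column ", which(miss)[1L] + 1L)
    vals[i, ] <- v
  }
  vals
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]: full-precision (`%.17g`) values so the
#' round trip is exact.
#'
#' @param expr Numeric matrix with row and column names.
#' @param path Output path.
#' @export
write_expression_tsv <- function(expr, path) {
  validate_expression(expr)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(expr)), collapse = "\t"), con)
  body <- apply(expr, 1L, function(r)
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = "\t"))
  writeLines(paste(rownames(expr), body, sep = "\t"), con)
  invisible(path)
}

validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop_io("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop_io("expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    stop_io("duplicate feature ID: ",
            rownames(expr)[duplicated(rownames(expr))][1L])
  if (anyDuplicated(colnames(expr)))
    stop_io("duplicate sample ID: ",
            colnames(expr)[duplicated(colnames(expr))][1L])
  invisible(expr)
}

GROUP_LEVELS <- c("normal", "primary", "metastatic")

#' Read or validate a sample sheet
#'
#' A sample sheet assigns every sample to a dataset and to one of the three
#' groups `normal`, `primary`, `metastatic`.
#'
#' @param path Path to a TSV with columns `sample_id`, `dataset_id`, `group`.
#' @return A data.frame with those three character columns.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet A data.frame to validate in place.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "dataset_id", "group")
  if (!all(need %in% names(sheet)))
    stop_io("sample sheet needs columns: ", paste(need, collapse = ", "))
  sheet <- as.data.frame(sheet)[need]
  if (anyDuplicated(sheet$sample_id))
    stop_io("duplicate sample ID in sheet: ",
            sheet$sample_id[duplicated(sheet$sample_id)][1L])
  bad <- setdiff(unique(sheet$group), GROUP_LEVELS)
  if (length(bad))
    stop_io("invalid group label(s): ", paste(bad, collapse = ", "),
            " (must be one of ", paste(GROUP_LEVELS, collapse = "/"), ")")
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a detection-call (present/absent) matrix
#'
#' Same layout as an expression TSV but entries are `P` or `A` (marginal
#' calls, if present as `M`, are mapped to `P`).
#'
#' @param path Path to the TSV.
#' @return Character matrix of `"P"`/`"A"` with dimnames.
#' @export
read_calls_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          row.names = 1L, colClasses = "character",
                          check.names = FALSE)
  m <- as.matrix(df)
  m[m == "M"] <- "P"
  bad <- setdiff(unique(as.vector(m)), c("P", "A"))
  if (length(bad))
    stop_io("invalid detection call(s): ", paste(bad, collapse = ", "))
  m
}

#' @rdname read_calls_tsv
#' @param calls Character matrix of calls.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     col.names = NA, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column TSV `(probe_id, gene_symbol)`.  Probes may map to several
#' genes and genes to several probes; identifiers are case-sensitive and
#' never translated.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `probe_id`, `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  need <- c("probe_id", "gene_symbol")
  if (!all(need %in% names(df)))
    stop_io("probe map needs columns: ", paste(need, collapse = ", "))
  unique(df[need])
}

#' @rdname read_probe_map
#' @param map data.frame with `probe_id`, `gene_symbol`.
#' @export
write_probe_map <- function(map, path) {
  utils::write.table(map[c("probe_id", "gene_symbol")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a STRING-style weighted edge list
#'
#' Expects three whitespace- or tab-delimited columns: `node1`, `node2`,
#' `combined_score`.  Scores are either integers on the 0--1000 STRING scale
#' (`score_scale = "milli"`, the STRING download format) or reals in
#' \[0, 1\] (`score_scale = "unit"`).  Self-loops are dropped with a warning
#' and duplicated unordered pairs are collapsed keeping the maximum score.
#'
#' @param path Path to the edge-list file (a header line is auto-detected).
#' @param score_scale `"milli"` or `"unit"`.
#' @return data.frame `(node1, node2, weight)` with weights in \[0, 1\].
#' @export
read_string_edgelist <- function(path, score_scale = c("milli", "unit")) {
  score_scale <- match.arg(score_scale)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(node1 = character(), node2 = character(),
                      weight = numeric()))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- vapply(parts, length, 1L)
  if (any(nf != 3L))
    stop_io("edge list row ", which(nf != 3L)[1L], " does not have 3 fields")
  first_score <- suppressWarnings(as.numeric(parts[[1L]][3L]))
  if (is.na(first_score)) parts <- parts[-1L]  # header line
  if (!length(parts)) {
    return(data.frame(node1 = character(), node2 = character(),
                      weight = numeric()))
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(s)) stop_io("non-numeric score at edge row ", which(is.na(s))[1L])
  if (score_scale == "milli") {
    if (any(s < 0 | s > 1000))
      stop_io("score outside 0-1000 at edge row ",
              which(s < 0 | s > 1000)[1L])
    w <- s / 1000
  } else {
    if (any(s < 0 | s > 1))
      stop_io("score outside [0,1] at edge row ", which(s < 0 | s > 1)[1L])
    w <- s
  }
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    a <- a[!loops]; b <- b[!loops]; w <- w[!loops]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  w <- vapply(split(w, key), max, 0)              # max-collapse duplicates
  pair <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  out <- data.frame(node1 = pair[, 1L], node2 = pair[, 2L],
                    weight = unname(w), stringsAsFactors = FALSE)
  out[order(out$node1, out$node2), , drop = FALSE]
}

#' @rdname read_string_edgelist
#' @param edges data.frame `(node1, node2, weight)`, weights in \[0, 1\].
#' @export
write_string_edgelist <- function(edges, path) {
  df <- data.frame(node1 = edges$node1, node2 = edges$node2,
                   combined_score = as.integer(round(edges$weight * 1000)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write plain-text gene sets (one symbol per line)
#' @param path File path.
#' @return Character vector of symbols.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path, encoding = "UTF-8")
  unique(trimws(x[nzchar(trimws(x))]))
}

#' @rdname read_gene_set
#' @param genes Character vector.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path, useBytes = TRUE)
  invisible(path)
}

#' Write a weighted graph with node scores
#'
#' Exports an [igraph][igraph::graph] object to an edge-list TSV or GraphML.
#' Both are lossless for nodes, edges, edge weights and the node attributes
#' `is_core` and `Dj` when present (GraphML keeps them natively; the TSV
#' format writes a companion `<path>.nodes.tsv` score table).
#'
#' @param graph An igraph object with a `weight` edge attribute.
#' @param path Output file path.
#' @param format `"tsv"` or `"graphml"`.
#' @export
write_graph_file <- function(graph, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    df <- data.frame(node1 = el$from, node2 = el$to,
                     weight = if (nrow(el)) el$weight else numeric())
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    nt <- node_score_table(graph)
    utils::write.table(nt, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @rdname write_graph_file
#' @export
read_graphml <- function(path) igraph::read_graph(path, format = "graphml")

node_score_table <- function(graph) {
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name
  data.frame(
    node = if (is.null(nm)) as.character(seq_len(n)) else nm,
    Dj = if ("Dj" %in% igraph::vertex_attr_names(graph))
      igraph::V(graph)$Dj else rep(NA_real_, n),
    is_core = if ("is_core" %in% igraph::vertex_attr_names(graph))
      igraph::V(graph)$is_core else rep(NA, n),
    stringsAsFactors = FALSE
  )
}

#' Write a per-node Dj score table
#' @param scores A `core_scores` data.frame (see [dj_scores()]).
#' @param path Output TSV path.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
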
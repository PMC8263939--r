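#' @title Expression preprocessing cascade
#' @description The per-dataset filtering and normalization cascade applied
#'   before differential expression: absent-call filter, quantile
#'   normalization, median-SD variance filter, highest-IQR probe collapse.
#'   The cascade order is fixed; each stage returns a `filter_report` so the
#'   feature bookkeeping is auditable.
#' @name preprocess
NULL

filter_report <- function(stage, features_in, removed_ids, extra = list()) {
  structure(c(list(stage = stage,
                   features_in = features_in,
                   features_removed = length(removed_ids),
                   removed_ids = removed_ids), extra),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s: %d -> %d features (%d removed)\n",
              x$stage, x$features_in, x$features_in - x$features_removed,
              x$features_removed))
  invisible(x)
}

#' Remove features called absent across groups
#'
#' A feature is dropped when its number of absent (`"A"`) detection calls
#' exceeds `max_absent` in every sample group (`mode = "all_groups"`, the
#' default) or in at least one group (`mode = "any_group"`).  The default
#' follows the usual reading of "more than two absent values in each group":
#' only features unreliable everywhere are discarded.
#'
#' @param expr Expression matrix (features x samples).
#' @param calls Detection-call matrix paired with `expr` (same dimnames),
#'   or `NULL`, in which case the stage is skipped with a warning.
#' @param sheet Sample sheet covering the columns of `expr`.
#' @param max_absent Per-group absent-call tolerance (default 2).
#' @param mode `"all_groups"` or `"any_group"`.
#' @return list(expr = filtered matrix, report = filter_report).
#' @export
filter_absent <- function(expr, calls, sheet, max_absent = 2,
                          mode = c("all_groups", "any_group")) {
  mode <- match.arg(mode)
  validate_expression(expr)
  if (is.null(calls)) {
    warning("no detection-call matrix supplied; absent filter skipped",
            call. = FALSE)
    return(list(expr = expr,
                report = filter_report("filter_absent", nrow(expr),
                                       character(), list(skipped = TRUE))))
  }
  if (!identical(dimnames(calls), dimnames(expr)))
    stop_io("detection-call matrix does not match the expression matrix")
  sheet <- validate_sample_sheet(sheet)
  grp <- sheet$group[match(colnames(expr), sheet$sample_id)]
  if (anyNA(grp))
    stop_io("sample missing from sheet: ",
            colnames(expr)[which(is.na(grp))[1L]])
  absent_by_group <- vapply(split(seq_along(grp), grp), function(idx)
    rowSums(calls[, idx, drop = FALSE] == "A"), numeric(nrow(expr)))
  if (is.null(dim(absent_by_group)))
    absent_by_group <- matrix(absent_by_group, nrow = nrow(expr))
  over <- absent_by_group > max_absent
  drop <- if (mode == "all_groups") apply(over, 1L, all) else apply(over, 1L, any)
  removed <- rownames(expr)[drop]
  list(expr = expr[!drop, , drop = FALSE],
       report = filter_report("filter_absent", nrow(expr), removed,
                              list(max_absent = max_absent, mode = mode)))
}

#' Quantile normalization
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' target is the across-sample mean of the column order statistics, and each
#' column's values are replaced by the target value at their rank.  Ties
#' within a column receive the mean of their tied target quantiles, so the
#' map is rank-preserving and idempotent.
#'
#' @param expr Expression matrix with no missing values.
#' @return Normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(expr) {
  validate_expression(expr)
  if (anyNA(expr)) stop_io("quantile normalization requires complete data")
  target <- rowMeans(apply(expr, 2L, sort, method = "radix"))
  out <- expr
  for (j in seq_len(ncol(expr))) {
    o <- order(expr[, j], method = "radix")
    # tied values are contiguous after sorting; each tied block gets the
    # mean of its block of target order statistics
    out[o, j] <- stats::ave(target, expr[o, j], FUN = mean)
  }
  out
}

#' Remove low-variance features
#'
#' Computes the (unbiased) per-feature standard deviation across all samples
#' and removes every feature whose SD is less than or equal to the median
#' SD; features must be strictly above the cutoff to survive.
#'
#' @param expr Expression matrix with at least two samples.
#' @return list(expr, report); the report records the cutoff.
#' @export
filter_low_variance <- function(expr) {
  validate_expression(expr)
  if (ncol(expr) < 2L) stop_io("variance filter needs >= 2 samples")
  sds <- apply(expr, 1L, stats::sd)
  cutoff <- stats::median(sds)
  keep <- sds > cutoff
  if (!any(keep))
    warning("all features share the median SD; none retained", call. = FALSE)
  removed <- rownames(expr)[!keep]
  list(expr = expr[keep, , drop = FALSE],
       report = filter_report("filter_low_variance", nrow(expr), removed,
                              list(sd_cutoff = cutoff)))
}

#' Collapse probes to genes by highest IQR
#'
#' For each gene symbol, among the probes mapping to it the probe with the
#' largest interquartile range across samples is kept as the gene's row
#' (a probe mapping to several genes competes for each of them).  Ties are
#' broken by the lexicographically smallest probe ID.  Probes absent from
#' the map are dropped with a warning.
#'
#' @param expr Probe-level expression matrix.
#' @param map data.frame `(probe_id, gene_symbol)`.
#' @return list(expr = gene-level matrix with unique gene rownames, report).
#' @export
collapse_probes <- function(expr, map) {
  validate_expression(expr)
  map <- unique(map[c("probe_id", "gene_symbol")])
  known <- rownames(expr) %in% map$probe_id
  if (!all(known))
    warning(sum(!known), " probe(s) missing from the map were dropped",
            call. = FALSE)
  iqr <- apply(expr, 1L, stats::IQR)
  map <- map[map$probe_id %in% rownames(expr), , drop = FALSE]
  map$iqr <- iqr[map$probe_id]
  ord <- order(map$gene_symbol, -map$iqr, map$probe_id, method = "radix")
  map <- map[ord, , drop = FALSE]
  winners <- map[!duplicated(map$gene_symbol), , drop = FALSE]
  out <- expr[winners$probe_id, , drop = FALSE]
  rownames(out) <- winners$gene_symbol
  removed <- setdiff(rownames(expr), winners$probe_id)
  list(expr = out,
       report = filter_report("collapse_probes", nrow(expr), removed,
                              list(n_genes = nrow(out))))
}

#' Prepare a pre-normalized (e.g. FPKM) matrix
#'
#' Drops genes with zero expression in every sample and, unless the data are
#' already on the log2 scale, applies `log2(x + offset)` (default offset 1,
#' which keeps zeros at zero).
#'
#' @param expr Expression matrix; non-negative when `already_log2 = FALSE`.
#' @param already_log2 Is the matrix already log2-transformed?
#' @param offset Pseudo-count added before the log (linear scale only).
#' @return list(expr, report).
#' @export
prepare_precomputed <- function(expr, already_log2 = FALSE, offset = 1) {
  validate_expression(expr)
  all_zero <- rowSums(expr != 0, na.rm = TRUE) == 0L
  removed <- rownames(expr)[all_zero]
  out <- expr[!all_zero, , drop = FALSE]
  if (!already_log2) {
    if (any(out < 0, na.rm = TRUE))
      stop_io("negative values in a linear-scale matrix")
    out <- log2(out + offset)
  }
  list(expr = out,
       report = filter_report("prepare_precomputed", nrow(expr), removed,
                              list(already_log2 = already_log2)))
}
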
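#' @title Outlier-sample detection (Number-SD)
#' @description Sample-level quality control based on inter-sample Pearson
#'   correlation.  Each sample's mean correlation (or 1 - r distance) with
#'   its group mates is standardized across the group; samples whose
#'   "Number-SD" score falls below -2 sit apart from their cluster and are
#'   removed.  PCA coordinates and correlation-distance dendrograms are
#'   provided for reporting only and never drive automated decisions.
#' @name outlier_qc
NULL

#' Inter-sample correlation-distance matrix
#'
#' `D[i, j] = 1 - cor(sample_i, sample_j)` (Pearson), zero diagonal.
#'
#' @param expr Expression matrix with >= 3 samples and >= 2 features.
#' @return Symmetric numeric matrix of distances in \[0, 2\].
#' @export
correlation_distance_matrix <- function(expr) {
  validate_expression(expr)
  if (ncol(expr) < 3L) stop_io("need >= 3 samples")
  if (nrow(expr) < 2L) stop_io("need >= 2 features")
  sds <- apply(expr, 2L, stats::sd)
  if (any(sds == 0))
    stop_io("zero-variance sample: ", colnames(expr)[which(sds == 0)[1L]])
  d <- 1 - stats::cor(expr)
  diag(d) <- 0
  d
}

#' Number-SD outlier scores
#'
#' For each sample, the mean of its off-diagonal inter-sample statistic is
#' standardized across samples: `score_s = (m_s - mean(m)) / sd(m)` with the
#' unbiased SD.  Under the default `convention = "correlation"` the
#' statistic is mean pairwise Pearson correlation, so decorrelated samples
#' score negative (matching the "< -2" flagging rule); under
#' `"distance"` it is the mean `1 - r` distance and signs flip.
#'
#' @param expr Expression matrix (>= 3 samples).
#' @param convention `"correlation"` (default) or `"distance"`.
#' @return An `outlier_report`: data.frame (sample, mean_stat, number_sd)
#'   with attributes `convention`.
#' @export
number_sd_scores <- function(expr, convention = c("correlation", "distance")) {
  convention <- match.arg(convention)
  d <- correlation_distance_matrix(expr)
  stat <- if (convention == "correlation") 1 - d else d
  diag(stat) <- NA
  m <- rowMeans(stat, na.rm = TRUE)
  s <- stats::sd(m)
  if (is.na(s) || s == 0) {
    warning("all samples have identical mean statistic; scores set to 0",
            call. = FALSE)
    score <- rep(0, length(m))
  } else {
    score <- (m - mean(m)) / s
  }
  structure(data.frame(sample = colnames(expr), mean_stat = unname(m),
                       number_sd = unname(score), stringsAsFactors = FALSE),
            convention = convention, class = c("outlier_report", "data.frame"))
}

#' Flag outlier samples from Number-SD scores
#'
#' Strict inequality: a sample is flagged iff its score is below the
#' threshold (default -2, the correlation-convention rule; a score of
#' exactly -2 is kept).
#'
#' @param report An `outlier_report` from [number_sd_scores()].
#' @param threshold Flagging threshold (default -2).
#' @return Character vector of flagged sample IDs.
#' @export
detect_outliers <- function(report, threshold = -2) {
  report$sample[report$number_sd < threshold]
}

#' Remove outlier samples group by group
#'
#' Computes Number-SD within each (dataset, group) stratum separately
#' (`per_group = TRUE`, the default) or over all samples pooled, removes
#' flagged samples, and optionally iterates until no sample is flagged.
#' Groups that would shrink below 3 samples stop iterating with a warning.
#'
#' @param expr Expression matrix.
#' @param sheet Sample sheet covering the columns of `expr`.
#' @param threshold Number-SD flagging threshold (default -2).
#' @param convention Passed to [number_sd_scores()].
#' @param per_group Stratify by group within dataset? Default `TRUE`.
#' @param max_iterations Maximum removal rounds (default 1: single pass).
#' @return list(expr, sheet, reports) where `reports` is a list of
#'   per-iteration data.frames (sample, group, dataset, mean_stat,
#'   number_sd, flagged).
#' @export
remove_outliers <- function(expr, sheet, threshold = -2,
                            convention = c("correlation", "distance"),
                            per_group = TRUE, max_iterations = 1L) {
  convention <- match.arg(convention)
  sheet <- validate_sample_sheet(sheet)
  reports <- list()
  for (iter in seq_len(max_iterations)) {
    sub <- sheet[match(colnames(expr), sheet$sample_id), , drop = FALSE]
    strata <- if (per_group) split(sub$sample_id,
                                   paste(sub$dataset_id, sub$group, sep = "/"))
              else list(all = sub$sample_id)
    flagged <- character()
    iter_report <- list()
    for (str_name in names(strata)) {
      ids <- strata[[str_name]]
      if (length(ids) < 3L) {
        warning("stratum ", str_name, " has fewer than 3 samples; skipped",
                call. = FALSE)
        next
      }
      rep_s <- number_sd_scores(expr[, ids, drop = FALSE], convention)
      fl <- detect_outliers(rep_s, threshold)
      keep_n <- length(ids) - length(fl)
      if (keep_n < 3L && length(fl)) {
        warning("stratum ", str_name,
                " would shrink below 3 samples; removals suppressed",
                call. = FALSE)
        fl <- character()
      }
      rep_s$stratum <- str_name
      rep_s$flagged <- rep_s$sample %in% fl
      rep_s$iteration <- iter
      iter_report[[str_name]] <- rep_s
      flagged <- c(flagged, fl)
    }
    reports[[iter]] <- do.call(rbind, iter_report)
    if (!length(flagged)) break
    expr <- expr[, setdiff(colnames(expr), flagged), drop = FALSE]
    sheet <- sheet[!sheet$sample_id %in% flagged, , drop = FALSE]
  }
  list(expr = expr, sheet = sheet, reports = reports)
}

#' Two-component PCA embedding of samples
#'
#' Mean-centered principal components of the samples (features as
#' variables), for QC plots.  Reporting only -- never used for automated
#' flagging.
#'
#' @param expr Expression matrix (>= 3 samples).
#' @return list(coords = samples x 2 matrix, explained = variance fractions
#'   for all components).
#' @export
pca_embedding <- function(expr) {
  validate_expression(expr)
  if (ncol(expr) < 3L) stop_io("need >= 3 samples")
  p <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  k <- min(2L, ncol(p$x))
  coords <- p$x[, seq_len(k), drop = FALSE]
  list(coords = coords, explained = expl)
}
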
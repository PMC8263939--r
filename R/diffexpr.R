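#' @title Moderated two-group differential expression
#' @description Empirical-Bayes moderated t-tests for two-group comparisons
#'   on log2-scale expression, with Benjamini-Hochberg adjustment and the
#'   effect-size / significance DEG call.  The gene-wise residual variances
#'   are shrunk toward a common prior estimated by moment matching on the
#'   log sample variances (scaled-F model), which stabilizes inference for
#'   small groups.
#' @name diffexpr
NULL

#' Estimate the variance prior (d0, s0^2) by moment matching
#'
#' Fits the scaled-F model for gene-wise sample variances: given variances
#' `s2` on `df` residual degrees of freedom, `log(s2)` has mean
#' `log(s0^2) + digamma(df/2) - log(df/2)` and excess variance
#' `trigamma(d0/2)` beyond `trigamma(df/2)`.  The prior df `d0` is obtained
#' by inverting the (monotone) trigamma via bisection; when the observed
#' spread does not exceed the sampling spread, `d0 = Inf` (complete
#' shrinkage to `s0^2`).
#'
#' @param s2 Gene-wise sample variances (positive; zeros dropped).
#' @param df Residual degrees of freedom (scalar).
#' @return list(d0, s02).
#' @keywords internal
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(d0 = Inf, s02 = stats::median(s2[ok])))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- stats::var(z)
  excess <- ev - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 1e-10) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    # solve trigamma(d0/2) = excess; trigamma is strictly decreasing
    inv_trigamma <- function(y) {
      lo <- 1e-8; hi <- 1e8
      while (trigamma(lo) < y) lo <- lo / 2
      while (trigamma(hi) > y) hi <- hi * 2
      for (i in 1:200) {
        mid <- sqrt(lo * hi)
        if (trigamma(mid) > y) lo <- mid else hi <- mid
        if (hi / lo < 1 + 1e-12) break
      }
      sqrt(lo * hi)
    }
    d0 <- 2 * inv_trigamma(excess)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated two-sample t-test per gene
#'
#' For every gene, the log2 fold change is the numerator-group mean minus
#' the denominator-group mean; the pooled residual variance `s_g^2` on
#' `n1 + n2 - 2` df is shrunk to
#' `s_tilde^2 = (d0 s0^2 + df s_g^2) / (d0 + df)` and the moderated
#' statistic `t = logFC / (s_tilde * sqrt(1/n1 + 1/n2))` is referred to a
#' Student t with `d0 + df` degrees of freedom (a normal reference when
#' `d0 = Inf`).  Setting `d0 = 0` recovers the ordinary pooled t-test.
#'
#' @param expr Expression matrix (genes x samples, log2 scale).
#' @param sheet Sample sheet covering the columns of `expr`.
#' @param numerator,denominator Group labels compared
#'   (`logFC = mean(numerator) - mean(denominator)`).
#' @param label Comparison label, e.g. `"MvsN"`; stored on the result.
#' @param d0 Optional prior df override: `0` disables moderation, `Inf`
#'   forces complete shrinkage, `NULL` (default) estimates it.
#' @return A `de_result` data.frame: gene, logFC, t, df_total, p, adj_p.
#' @export
moderated_t_test <- function(expr, sheet, numerator, denominator,
                             label = paste0(numerator, "_vs_", denominator),
                             d0 = NULL) {
  validate_expression(expr)
  sheet <- validate_sample_sheet(sheet)
  grp <- sheet$group[match(colnames(expr), sheet$sample_id)]
  i1 <- which(grp == numerator)
  i2 <- which(grp == denominator)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L)
    stop_io("each group needs >= 2 samples (", numerator, ": ", n1, ", ",
            denominator, ": ", n2, ")")
  sub <- expr[, c(i1, i2), drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  if (!all(complete))
    warning(sum(!complete), " gene(s) with missing values dropped from ",
            label, call. = FALSE)
  sub <- sub[complete, , drop = FALSE]
  x1 <- sub[, seq_len(n1), drop = FALSE]
  x2 <- sub[, n1 + seq_len(n2), drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  lfc <- m1 - m2
  df_resid <- n1 + n2 - 2
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s2 <- ss / df_resid
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, df_resid)
    d0 <- prior$d0; s02 <- prior$s02
  } else if (is.infinite(d0)) {
    s02 <- exp(mean(log(s2[s2 > 0])))
  } else {
    s02 <- if (d0 > 0) fit_variance_prior(s2, df_resid)$s02 else 0
  }
  s2_tilde <- if (is.infinite(d0)) rep(s02, length(s2))
              else (d0 * s02 + df_resid * s2) / (d0 + df_resid)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, Inf * sign(lfc)))
  if (any(se == 0))
    warning(sum(se == 0), " gene(s) with zero residual variance", call. = FALSE)
  df_total <- d0 + df_resid
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat))
       else 2 * stats::pt(-abs(tstat), df = df_total)
  p[is.infinite(tstat)] <- 0
  p[se == 0 & lfc == 0] <- 1
  res <- data.frame(gene = rownames(sub), logFC = unname(lfc),
                    t = unname(tstat), df_total = df_total, p = unname(p),
                    stringsAsFactors = FALSE)
  res$adj_p <- bh_adjust(res$p)
  structure(res, label = label, d0 = d0, s02 = s02,
            class = c("de_result", "data.frame"))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' FDR-controlling step-up adjustment of raw p-values (delegates to
#' `stats::p.adjust(method = "BH")` after validation).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_io("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Strict thresholds on both criteria: `|logFC| > lfc_cut` and
#' `adj_p < alpha`.  Direction is the sign of logFC.
#'
#' @param result A `de_result` from [moderated_t_test()].
#' @param lfc_cut Absolute log2-fold-change cutoff (default 0.5).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return data.frame (gene, direction) with direction in `Up`/`Down`.
#' @export
select_degs <- function(result, lfc_cut = 0.5, alpha = 0.05) {
  sel <- abs(result$logFC) > lfc_cut & result$adj_p < alpha
  data.frame(gene = result$gene[sel],
             direction = ifelse(result$logFC[sel] > 0, "Up", "Down"),
             stringsAsFactors = FALSE)
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %s: %d genes, d0 = %.3g\n",
              attr(x, "label"), nrow(x), attr(x, "d0")))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}
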
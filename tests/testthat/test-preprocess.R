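make_calls <- function(expr, absent = character()) {
  calls <- matrix("P", nrow(expr), ncol(expr), dimnames = dimnames(expr))
  calls
}

test_that("absent filter applies the per-group rule under both modes", {
  sizes <- c(normal = 5, primary = 5, metastatic = 5)
  grp <- rep(names(sizes), sizes)
  smp <- sprintf("S%02d", seq_along(grp))
  expr <- matrix(5, nrow = 3, ncol = 15,
                 dimnames = list(c("fClean", "fAllAbsent", "fOneGroupOk"),
                                 smp))
  sheet <- data.frame(sample_id = smp, dataset_id = "D01", group = grp)
  calls <- make_calls(expr)
  # fAllAbsent: 3 absents in each of the 3 groups (> 2 everywhere)
  for (g in names(sizes))
    calls["fAllAbsent", which(grp == g)[1:3]] <- "A"
  # fOneGroupOk: 3 absents in two groups, only 2 in the third
  calls["fOneGroupOk", which(grp == "normal")[1:3]] <- "A"
  calls["fOneGroupOk", which(grp == "primary")[1:3]] <- "A"
  calls["fOneGroupOk", which(grp == "metastatic")[1:2]] <- "A"

  res_all <- filter_absent(expr, calls, sheet, mode = "all_groups")
  expect_setequal(res_all$report$removed_ids, "fAllAbsent")
  expect_true("fOneGroupOk" %in% rownames(res_all$expr))  # retained
  expect_true("fClean" %in% rownames(res_all$expr))

  res_any <- filter_absent(expr, calls, sheet, mode = "any_group")
  expect_setequal(res_any$report$removed_ids,
                  c("fAllAbsent", "fOneGroupOk"))

  # missing call matrix: stage skipped with a warning, matrix untouched
  expect_warning(sk <- filter_absent(expr, NULL, sheet), "skipped")
  expect_identical(sk$expr, expr)
})

test_that("quantile normalization matches the order-statistic definition", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  # identical columns are a fixed point
  m2 <- matrix(rep(c(3, 1, 2), 4), nrow = 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(quantile_normalize(m2), m2)

  # all column means equal, ranks preserved, idempotent
  set.seed(42)
  r <- matrix(rnorm(200), 20, dimnames = list(sprintf("g%02d", 1:20),
                                              sprintf("s%02d", 1:10)))
  qr <- quantile_normalize(r)
  expect_lt(diff(range(colMeans(qr))), 1e-12)
  for (j in 1:10) expect_equal(rank(qr[, j]), rank(r[, j]))
  expect_equal(quantile_normalize(qr), qr, tolerance = 1e-12)

  # ties within a column get the mean of the tied target quantiles
  mt <- matrix(c(1, 1, 5, 2, 4, 6), nrow = 3,
               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  qt <- quantile_normalize(mt)
  target <- rowMeans(apply(mt, 2, sort))
  expect_equal(unname(qt[1:2, 1]), rep(mean(target[1:2]), 2))

  mna <- m; mna[1, 1] <- NA
  expect_error(quantile_normalize(mna), "complete")

  # agrees with the reference implementation on tie-free matrices
  skip_if_not_installed("limma")
  expect_equal(quantile_normalize(r),
               limma::normalizeQuantiles(r, ties = TRUE),
               tolerance = 1e-10)
})

test_that("variance filter removes SD <= median and records the cutoff", {
  # 4 features engineered to SDs 1, 2, 3, 4
  base <- c(-1, 0, 1) / sd(c(-1, 0, 1))
  m <- rbind(f1 = base, f2 = 2 * base, f3 = 3 * base, f4 = 4 * base)
  colnames(m) <- c("s1", "s2", "s3")
  res <- filter_low_variance(m)
  expect_setequal(rownames(res$expr), c("f3", "f4"))   # median SD = 2.5
  expect_equal(res$report$sd_cutoff, 2.5)

  # degenerate: all SDs equal -> all removed, warning
  mc <- rbind(a = base, b = base + 5, c = base - 2)
  colnames(mc) <- c("s1", "s2", "s3")
  expect_warning(rc <- filter_low_variance(mc), "none retained")
  expect_equal(nrow(rc$expr), 0)

  # at most ceiling(n/2) features survive
  set.seed(5)
  r <- matrix(rnorm(9 * 6), 9, dimnames = list(paste0("g", 1:9),
                                               paste0("s", 1:6)))
  expect_lte(nrow(filter_low_variance(r)$expr), ceiling(9 / 2))
})

test_that("probe collapse keeps the highest-IQR probe per gene", {
  m <- rbind(p_low  = c(1, 2, 3, 4),       # IQR 1.5
             p_high = c(0, 2, 4, 6),       # IQR 3
             p_only = c(5, 5, 6, 6))
  colnames(m) <- paste0("s", 1:4)
  map <- data.frame(probe_id = c("p_low", "p_high", "p_only"),
                    gene_symbol = c("GENE1", "GENE1", "GENE2"))
  res <- collapse_probes(m, map)
  expect_setequal(rownames(res$expr), c("GENE1", "GENE2"))
  expect_equal(unname(res$expr["GENE1", ]), unname(m["p_high", ]))
  expect_equal(unname(res$expr["GENE2", ]), unname(m["p_only", ]))

  # identical IQR: lexicographically smaller probe ID wins
  m2 <- rbind(pB = c(1, 2, 3, 4), pA = c(11, 12, 13, 14))
  colnames(m2) <- paste0("s", 1:4)
  map2 <- data.frame(probe_id = c("pB", "pA"), gene_symbol = "G")
  r2 <- collapse_probes(m2, map2)
  expect_equal(unname(r2$expr["G", ]), unname(m2["pA", ]))

  # a probe mapping to two genes competes for both
  map3 <- data.frame(probe_id = c("p_low", "p_high", "p_high"),
                     gene_symbol = c("GENE1", "GENE1", "GENE3"))
  r3 <- collapse_probes(m[1:2, ], map3)
  expect_setequal(rownames(r3$expr), c("GENE1", "GENE3"))
  expect_equal(unname(r3$expr["GENE3", ]), unname(m["p_high", ]))

  # unmapped probes dropped with a warning; output genes unique
  expect_warning(r4 <- collapse_probes(m, map[1:2, ]), "missing from the map")
  expect_false(anyDuplicated(rownames(r4$expr)) > 0)
})

test_that("precomputed matrices drop all-zero genes and log2-transform", {
  m <- rbind(zero = c(0, 0, 0), seven = c(7, 7, 7), one = c(0, 1, 3))
  colnames(m) <- paste0("s", 1:3)
  res <- prepare_precomputed(m, already_log2 = FALSE)
  expect_false("zero" %in% rownames(res$expr))
  expect_equal(unname(res$expr["seven", ]), rep(3, 3))   # log2(8)
  expect_equal(res$expr["one", 1], 0)                    # log2(0 + 1)

  # pass-through when already log2; negatives rejected on linear scale
  m2 <- rbind(g = c(-1, 2, 3)); colnames(m2) <- paste0("s", 1:3)
  expect_error(prepare_precomputed(m2, already_log2 = FALSE), "negative")
  expect_equal(prepare_precomputed(m2, already_log2 = TRUE)$expr, m2)
})

test_that("the cascade keeps an auditable feature count trail", {
  set.seed(9)
  study <- simulate_expression_study(sim_config(n_genes = 300, seed = 9L,
                                                n_datasets_test = 1,
                                                n_datasets_validation = 0))
  d <- study$datasets[[1]]
  sheet <- study$sheet
  fa <- filter_absent(d$probe_expr, d$calls, sheet)
  expect_equal(fa$report$features_in - fa$report$features_removed,
               nrow(fa$expr))
  lv <- filter_low_variance(quantile_normalize(fa$expr))
  expect_equal(lv$report$features_in, nrow(fa$expr))
  cp <- collapse_probes(lv$expr, study$probe_map)
  expect_equal(cp$report$features_in, nrow(lv$expr))
  expect_false(anyDuplicated(rownames(cp$expr)) > 0)
})
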
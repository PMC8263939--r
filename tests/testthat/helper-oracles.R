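# Independent brute-force oracles and small random-instance generators.
# These deliberately avoid the package's own code paths.

# random simple weighted graph as a symmetric adjacency matrix in [0,1]
random_adjacency <- function(n, p_edge = 0.4, wmin = 0.05, wmax = 1) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) a[i, j] <- a[j, i] <- runif(1, wmin, wmax)
  }
  dimnames(a) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  a
}

adjacency_to_edges <- function(a) {
  idx <- which(a > 0 & upper.tri(a), arr.ind = TRUE)
  data.frame(node1 = rownames(a)[idx[, 1]], node2 = colnames(a)[idx[, 2]],
             weight = a[idx], stringsAsFactors = FALSE)
}

# Floyd-Warshall all-pairs shortest paths on a full distance matrix
# (Inf where no direct step exists)
floyd_warshall <- function(d) {
  n <- nrow(d)
  sp <- d
  diag(sp) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    cand <- sp[i, k] + sp[k, j]
    if (cand < sp[i, j]) sp[i, j] <- cand
  }
  sp
}

# naive triple-loop TOM
naive_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# direct per-node evaluation of the Dj proximity formula
naive_dj <- function(sp, core) {
  nodes <- rownames(sp)
  is_core <- nodes %in% core
  C <- sum(is_core); NC <- sum(!is_core)
  vapply(seq_along(nodes), function(j) {
    num <- sum(sp[!is_core, j]) / NC - sum(sp[is_core, j]) / C
    den <- sum(sp[, j]) / (NC + C)
    if (den == 0) 0 else num / den
  }, 0)
}

# naive O(m^2) Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} m p_(j) / j
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), 0)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# textbook pooled two-sample t statistic per row
pooled_t <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  sp2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# small labeled expression matrix + sheet for two or three groups
toy_expr <- function(n_genes = 50, sizes = c(normal = 5, primary = 5,
                                             metastatic = 5),
                     mu = 8, sd = 1) {
  grp <- rep(names(sizes), sizes)
  smp <- sprintf("S%02d", seq_along(grp))
  m <- matrix(rnorm(n_genes * length(grp), mu, sd), nrow = n_genes,
              dimnames = list(sprintf("g%03d", 1:n_genes), smp))
  list(expr = m,
       sheet = data.frame(sample_id = smp, dataset_id = "D01", group = grp,
                          stringsAsFactors = FALSE))
}

de_frame <- function(genes, lfc) {
  structure(data.frame(gene = genes, logFC = lfc, t = lfc, df_total = 10,
                       p = 0.01, adj_p = 0.01, stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"))
}
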
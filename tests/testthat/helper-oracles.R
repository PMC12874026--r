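# Independent brute-force oracles, written as literal loops so that they
# share no code path with the package implementations they check.

oracle_ssgsea_one <- function(v, gene_ids, set_genes, alpha) {
  n <- length(v)
  r <- rank(v)
  ord <- order(-v, toupper(gene_ids), method = "radix")
  inset <- toupper(gene_ids) %in% set_genes
  wsum <- 0
  for (i in seq_len(n)) if (inset[i]) wsum <- wsum + r[i]^alpha
  nout <- n - sum(inset)
  es <- 0; pin <- 0; pout <- 0
  for (i in ord) {
    if (inset[i]) pin <- pin + r[i]^alpha / wsum else pout <- pout + 1 / nout
    es <- es + (pin - pout)
  }
  es
}

oracle_aucell_one <- function(v, gene_ids, set_genes, top_frac) {
  n <- length(v)
  ord <- order(-v, toupper(gene_ids), method = "radix")
  inset <- toupper(gene_ids) %in% set_genes
  T <- ceiling(top_frac * n)
  area <- 0
  for (r in seq_len(T)) {
    hits <- 0
    for (i in seq_len(r)) if (inset[ord[i]]) hits <- hits + 1
    area <- area + hits
  }
  max_area <- 0
  for (r in seq_len(T)) max_area <- max_area + min(r, sum(inset))
  area / max_area
}

oracle_scse_one <- function(v, gene_ids, set_genes) {
  inset <- toupper(gene_ids) %in% set_genes
  100 * sum(v[inset]) / sum(v)
}

# whole-matrix oracle: the min-max scaling couples samples
oracle_jasmine <- function(vals, gene_ids, set_genes) {
  inset <- toupper(gene_ids) %in% set_genes
  n_samp <- ncol(vals)
  rank_comp <- numeric(n_samp)
  or_comp <- numeric(n_samp)
  for (j in seq_len(n_samp)) {
    v <- vals[, j]
    expressed <- v > 0
    ne <- sum(expressed)
    if (ne > 0 && sum(inset & expressed) > 0) {
      r <- rank(v[expressed])
      sel <- inset[expressed]
      rank_comp[j] <- mean(r[sel]) / ne
    } else {
      rank_comp[j] <- 0
    }
    a <- sum(inset & expressed); b <- sum(inset & !expressed)
    cc <- sum(!inset & expressed); d <- sum(!inset & !expressed)
    or_comp[j] <- ((a + 0.5) / (b + 0.5)) / ((cc + 0.5) / (d + 0.5))
  }
  mm <- function(z) {
    if (max(z) == min(z)) return(rep(0, length(z)))
    (z - min(z)) / (max(z) - min(z))
  }
  (mm(rank_comp) + mm(or_comp)) / 2
}

oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# leading eigenpair from a dense eigendecomposition (nnPCA oracle on
# matrices whose top eigenvector is nonnegative up to sign)
oracle_top_eigen <- function(m, center = TRUE) {
  mc <- if (center) m - rowMeans(m) else m
  S <- tcrossprod(mc) / (ncol(m) - 1)
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  list(vector = v, value = e$values[1])
}

# random factor-model matrix with all-positive loadings, so the leading
# covariance eigenvector is elementwise nonnegative (Perron-Frobenius)
positive_factor_matrix <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  a <- stats::runif(n_genes, 0.5, 2)
  f <- stats::rnorm(n_samples, sd = 2)
  a %o% f + matrix(stats::rnorm(n_genes * n_samples, sd = 0.1), n_genes)
}

# align two label vectors (binary) under the best of the two mappings
branch_accuracy <- function(called, truth, pos = "M1-dominant",
                            truth_pos = "M1") {
  a1 <- mean((called == pos) == (truth == truth_pos))
  a2 <- mean((called == pos) == (truth != truth_pos))
  max(a1, a2)
}
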
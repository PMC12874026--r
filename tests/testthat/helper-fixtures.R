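# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# attached (not just ::) because Mclust resolves helper functions through
# the search path
suppressPackageStartupMessages(library(mclust))

make_em <- function(values, genes = NULL, samples = NULL,
                    normalized = "lognorm") {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  expression_matrix(values, genes, samples, normalized = normalized)
}

# random strictly-positive expression matrix (lognorm-state) for scorer tests
random_em <- function(n_genes = 10, n_samples = 8, seed = 1) {
  set.seed(seed)
  vals <- matrix(round(stats::rexp(n_genes * n_samples, 0.5), 4),
                 n_genes, n_samples)
  make_em(vals)
}

write_tmp_gmt <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

# small E/M pair from a simulated bundle
bundle_pair <- function(bundle) {
  list(E = bundle$genesets$sets$E, M = bundle$genesets$sets$M)
}
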
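#' Specify a synthetic EMT expression dataset
#'
#' Parameters of the seeded generator used throughout the test suite and
#' worked examples. The generator plants an epithelial program (genes
#' downregulated along a latent EMT axis) and one or two mesenchymal
#' programs (genes upregulated along the axis); with two M programs, each
#' acts in a disjoint sample branch, emulating divergent EMT paths.
#'
#' @param n_samples,n_genes Matrix dimensions (defaults 500 x 1000).
#' @param n_e_genes,n_m1_genes,n_m2_genes Sizes of the planted disjoint
#'   gene programs; `n_m2_genes = 0` (default) disables divergence.
#' @param effect_size Mean log-fold shift per unit latent position
#'   (default 2.0, a strong induction on the natural-log scale).
#' @param dropout_rate Bernoulli zero-inflation probability in single-cell
#'   mode (default 0.3).
#' @param dispersion Negative-binomial size parameter (default 2.0).
#' @param latent_design `"continuous_uniform"` (latent ~ U(0,1)),
#'   `"three_state"` (well-separated E/hybrid/M subpopulations) or
#'   `"time_course"` (four ordered time labels with increasing latent
#'   means).
#' @param mode `"single_cell"` (default; applies dropout) or `"bulk"`
#'   (dropout forced to 0).
#' @param seed Integer seed; identical specs generate bit-identical data.
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_samples = 500L, n_genes = 1000L,
                           n_e_genes = 50L, n_m1_genes = 50L,
                           n_m2_genes = 0L, effect_size = 2.0,
                           dropout_rate = 0.3, dispersion = 2.0,
                           latent_design = c("continuous_uniform",
                                             "three_state", "time_course"),
                           mode = c("single_cell", "bulk"), seed = 1L) {
  latent_design <- match.arg(latent_design)
  mode <- match.arg(mode)
  if (mode == "bulk") dropout_rate <- 0
  n_samples <- as.integer(n_samples)
  n_genes <- as.integer(n_genes)
  n_e_genes <- as.integer(n_e_genes)
  n_m1_genes <- as.integer(n_m1_genes)
  n_m2_genes <- as.integer(n_m2_genes)
  if (n_e_genes + n_m1_genes + n_m2_genes > n_genes) {
    estop("planted gene programs (%d genes) exceed n_genes (%d); subsets must be disjoint",
          n_e_genes + n_m1_genes + n_m2_genes, n_genes)
  }
  if (effect_size < 0) estop("'effect_size' must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1) estop("'dropout_rate' must be in [0, 1)")
  if (dispersion <= 0) estop("'dispersion' must be > 0")
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_e_genes = n_e_genes, n_m1_genes = n_m1_genes,
                 n_m2_genes = n_m2_genes, effect_size = effect_size,
                 dropout_rate = dropout_rate, dispersion = dispersion,
                 latent_design = latent_design, mode = mode,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic EMT expression dataset
#'
#' Draws per-gene baseline log-means from Normal(1.5, 0.5); along a latent
#' EMT position in [0, 1], epithelial genes' log-means decrease by
#' `effect_size * latent` and mesenchymal genes' increase by the same
#' amount (restricted to the matching sample branch when two M programs
#' are planted). Counts are negative-binomial with that mean and the given
#' dispersion, then zero-inflated at `dropout_rate` in single-cell mode.
#' The three-state design draws latent positions near 0.05/0.5/0.95
#' (sd 0.03); the time-course design assigns labels t0..t3 with latent
#' means 0.1/0.35/0.65/0.9 (sd 0.05). Pseudotime is the latent position
#' plus Normal(0, 0.05) noise — a noisy stand-in for an externally
#' inferred trajectory.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `matrix` (raw-count [expression_matrix()]), `truth`
#'   (list: `latent`, `branch`, `state`, `time_label`, `pseudotime`,
#'   `gene_roles`), and `genesets` (a [gene_set_collection()] of the
#'   planted sets: `E`, `M`, plus `M1`/`M2` under divergence).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_samples
  p <- spec$n_genes

  state <- rep(NA_character_, n)
  time_label <- rep(NA_character_, n)
  latent <- switch(spec$latent_design,
    continuous_uniform = stats::runif(n),
    three_state = {
      state <- sample(c("E", "hybrid", "M"), n, replace = TRUE)
      centers <- c(E = 0.05, hybrid = 0.5, M = 0.95)
      pmin(pmax(centers[state] + stats::rnorm(n, 0, 0.03), 0), 1)
    },
    time_course = {
      time_label <- rep(paste0("t", 0:3), length.out = n)
      centers <- c(t0 = 0.1, t1 = 0.35, t2 = 0.65, t3 = 0.9)
      pmin(pmax(centers[time_label] + stats::rnorm(n, 0, 0.05), 0), 1)
    })
  latent <- unname(latent)
  divergent <- spec$n_m2_genes > 0L
  branch <- if (divergent) sample(c("M1", "M2"), n, replace = TRUE) else rep("none", n)

  gene_ids <- sprintf("g%04d", seq_len(p))
  roles <- rep("background", p)
  if (spec$n_e_genes > 0L) roles[seq_len(spec$n_e_genes)] <- "E"
  if (spec$n_m1_genes > 0L) {
    roles[spec$n_e_genes + seq_len(spec$n_m1_genes)] <- "M1"
  }
  if (divergent) {
    roles[spec$n_e_genes + spec$n_m1_genes + seq_len(spec$n_m2_genes)] <- "M2"
  }

  base <- stats::rnorm(p, mean = 1.5, sd = 0.5)
  logmu <- matrix(base, p, n)
  eff <- spec$effect_size
  e_idx <- which(roles == "E")
  m1_idx <- which(roles == "M1")
  m2_idx <- which(roles == "M2")
  if (length(e_idx)) {
    logmu[e_idx, ] <- logmu[e_idx, ] - outer(rep(eff, length(e_idx)), latent)
  }
  m1_on <- if (divergent) as.numeric(branch == "M1") else rep(1, n)
  if (length(m1_idx)) {
    logmu[m1_idx, ] <- logmu[m1_idx, ] +
      outer(rep(eff, length(m1_idx)), latent * m1_on)
  }
  if (length(m2_idx)) {
    logmu[m2_idx, ] <- logmu[m2_idx, ] +
      outer(rep(eff, length(m2_idx)), latent * as.numeric(branch == "M2"))
  }

  counts <- matrix(stats::rnbinom(p * n, mu = exp(logmu), size = spec$dispersion), p, n)
  if (spec$dropout_rate > 0) {
    keep <- matrix(stats::rbinom(p * n, 1L, 1 - spec$dropout_rate), p, n)
    counts <- counts * keep
  }
  sample_ids <- sprintf("s%04d", seq_len(n))
  x <- expression_matrix(counts, gene_ids, sample_ids, normalized = "raw")

  pseudotime <- latent + stats::rnorm(n, 0, 0.05)

  sets <- list(gene_set("E", gene_ids[e_idx],
                        "planted epithelial program (synthetic)"),
               gene_set("M", gene_ids[c(m1_idx, m2_idx)],
                        "planted mesenchymal program(s) (synthetic)"))
  if (divergent) {
    sets <- c(sets,
              list(gene_set("M1", gene_ids[m1_idx], "planted M1 branch program (synthetic)"),
                   gene_set("M2", gene_ids[m2_idx], "planted M2 branch program (synthetic)")))
  }
  truth <- list(latent = stats::setNames(latent, sample_ids),
                branch = stats::setNames(branch, sample_ids),
                state = stats::setNames(state, sample_ids),
                time_label = stats::setNames(time_label, sample_ids),
                pseudotime = stats::setNames(pseudotime, sample_ids),
                gene_roles = stats::setNames(roles, gene_ids))
  list(matrix = x, truth = truth,
       genesets = gene_set_collection(sets, source = "synthetic"))
}

#' Write a synthetic bundle as on-disk fixtures
#'
#' Emits exactly the formats the readers consume: a MatrixMarket triplet
#' (`matrix.mtx`, `genes.txt`, `samples.txt`), a metadata TSV
#' (`metadata.tsv` with `sample_id`, `time_label`, `state`, `branch`,
#' `pseudotime`), the planted gene sets as `planted.gmt`, and the ground
#' truth as `truth.json`.
#'
#' @param bundle A [simulate_expression()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) estop("cannot create fixture directory '%s'", dir)
  x <- bundle$matrix
  paths <- list(matrix = file.path(dir, "matrix.mtx"),
                genes = file.path(dir, "genes.txt"),
                samples = file.path(dir, "samples.txt"),
                metadata = file.path(dir, "metadata.tsv"),
                gmt = file.path(dir, "planted.gmt"),
                truth = file.path(dir, "truth.json"))
  Matrix::writeMM(methods::as(Matrix::Matrix(x$values, sparse = TRUE), "generalMatrix"),
                  paths$matrix)
  writeLines(x$gene_ids, paths$genes)
  writeLines(x$sample_ids, paths$samples)
  tr <- bundle$truth
  meta <- data.frame(sample_id = x$sample_ids,
                     time_label = unname(tr$time_label),
                     state = unname(tr$state),
                     branch = unname(tr$branch),
                     pseudotime = unname(tr$pseudotime),
                     stringsAsFactors = FALSE)
  utils::write.table(meta, paths$metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(bundle$genesets, paths$gmt)
  jsonlite::write_json(
    list(latent = as.list(tr$latent), branch = as.list(tr$branch),
         state = as.list(tr$state), time_label = as.list(tr$time_label),
         pseudotime = as.list(tr$pseudotime),
         gene_roles = as.list(tr$gene_roles)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
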
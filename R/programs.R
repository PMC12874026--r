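#' Top genes contributing to an nnPCA axis
#'
#' Ranks the genes used on one axis by their nonnegative loading, descending
#' (ties broken by gene id), and returns the top `k`. These are the genes
#' whose expression drives the corresponding mesenchymal (or epithelial)
#' program.
#'
#' @param r An nnPCA [ScoreResult].
#' @param axis Axis name, e.g. `"M1"`.
#' @param k Number of genes to return; at most the number of genes used on
#'   the axis.
#' @return A `data.frame` with columns `gene_id`, `loading`, sorted by
#'   loading descending.
#' @export
top_contributing_genes <- function(r, axis, k = 10L) {
  stopifnot(inherits(r, "ScoreResult"))
  if (r$method != "nnpca" || is.null(r$loadings)) {
    estop("loadings are only available for nnPCA results (got method '%s')", r$method)
  }
  if (!axis %in% names(r$loadings)) {
    estop("axis '%s' not found; available: %s", axis,
          paste(names(r$loadings), collapse = ", "))
  }
  w <- r$loadings[[axis]]
  k <- as.integer(k)
  if (k < 1L || k > length(w)) {
    estop("'k' must be between 1 and %d (genes used on axis '%s')", length(w), axis)
  }
  ord <- order(-w, fold_id(names(w)), method = "radix")[seq_len(k)]
  data.frame(gene_id = names(w)[ord], loading = unname(w[ord]),
             stringsAsFactors = FALSE)
}

#' Assign samples to divergent mesenchymal branches
#'
#' Formalizes the visual reading of an M1-M2 scatter plot: both axes are
#' z-scored across samples, and a sample is called `M1-dominant` when its
#' z(M1) reaches the given quantile of z(M1) and exceeds its z(M2)
#' (symmetrically for `M2-dominant`); everything else is `unpolarized`.
#'
#' @param r A [ScoreResult] containing both axes.
#' @param m_axes Character pair of axis names (default `c("M1", "M2")`).
#' @param quantile Polarization quantile in (0.5, 1), default 0.75.
#' @return A named character vector of branch labels per sample.
#' @export
assign_branches <- function(r, m_axes = c("M1", "M2"), quantile = 0.75) {
  stopifnot(inherits(r, "ScoreResult"), length(m_axes) == 2L)
  if (!(quantile > 0.5 && quantile < 1)) {
    estop("'quantile' must be in (0.5, 1)")
  }
  missing_ax <- setdiff(m_axes, colnames(r$scores))
  if (length(missing_ax)) {
    estop("axis '%s' not found in the score result", missing_ax[1L])
  }
  s1 <- r$scores[, m_axes[1L]]
  s2 <- r$scores[, m_axes[2L]]
  z1 <- zscore(s1, sprintf("scores on axis '%s'", m_axes[1L]))
  z2 <- zscore(s2, sprintf("scores on axis '%s'", m_axes[2L]))
  q1 <- stats::quantile(z1, quantile, names = FALSE)
  q2 <- stats::quantile(z2, quantile, names = FALSE)
  lab <- rep("unpolarized", length(z1))
  lab[z1 >= q1 & z1 > z2] <- paste0(m_axes[1L], "-dominant")
  lab[z2 >= q2 & z2 > z1] <- paste0(m_axes[2L], "-dominant")
  stats::setNames(lab, rownames(r$scores))
}

#' Per-gene divergence between two nnPCA axes
#'
#' Contrast of a gene's loadings on two mesenchymal axes,
#' `(w1 - w2) / (w1 + w2 + eps)`, in [-1, 1]: +1 marks a pure first-axis
#' contributor, -1 a pure second-axis contributor, 0 an evenly shared gene.
#'
#' @param r An nnPCA [ScoreResult].
#' @param m_axes Character pair of axis names (default `c("M1", "M2")`).
#' @param eps Guard against 0/0 for genes with zero loading on both axes.
#' @return A named numeric vector over the union of genes used on the two
#'   axes (a gene absent from one axis contributes loading 0 there).
#' @export
divergence_index <- function(r, m_axes = c("M1", "M2"), eps = 1e-12) {
  stopifnot(inherits(r, "ScoreResult"), length(m_axes) == 2L)
  if (r$method != "nnpca" || is.null(r$loadings)) {
    estop("divergence_index requires an nnPCA result with loadings")
  }
  missing_ax <- setdiff(m_axes, names(r$loadings))
  if (length(missing_ax)) {
    estop("axis '%s' not found in the score result", missing_ax[1L])
  }
  w1 <- r$loadings[[m_axes[1L]]]
  w2 <- r$loadings[[m_axes[2L]]]
  genes <- union(names(w1), names(w2))
  v1 <- stats::setNames(rep(0, length(genes)), genes)
  v1[names(w1)] <- w1
  v2 <- stats::setNames(rep(0, length(genes)), genes)
  v2[names(w2)] <- w2
  (v1 - v2) / (v1 + v2 + eps)
}

#' Summarize divergent mesenchymal programs
#'
#' Bundles the per-axis top contributing genes, the per-sample branch
#' assignment, the per-gene divergence index and a plot-ready M1-M2 scatter
#' table into one report.
#'
#' @param r An nnPCA [ScoreResult] with both `m_axes`.
#' @param m_axes Character pair of axis names (default `c("M1", "M2")`).
#' @param k Top genes reported per axis (default 10, capped at the number
#'   of genes used).
#' @param quantile Branch polarization quantile (default 0.75).
#' @return An object of class `ProgramReport`: list with `axes`,
#'   `top_genes`, `branch_assignment`, `divergence_index`, `scatter`.
#' @export
program_report <- function(r, m_axes = c("M1", "M2"), k = 10L,
                           quantile = 0.75) {
  stopifnot(inherits(r, "ScoreResult"))
  k_eff <- lapply(m_axes, function(ax) min(k, length(r$loadings[[ax]])))
  top <- lapply(seq_along(m_axes), function(i) {
    top_contributing_genes(r, m_axes[i], k_eff[[i]])
  })
  names(top) <- m_axes
  branches <- assign_branches(r, m_axes, quantile)
  scatter <- data.frame(sample_id = rownames(r$scores),
                        r$scores[, m_axes, drop = FALSE],
                        branch = unname(branches),
                        check.names = FALSE, stringsAsFactors = FALSE)
  structure(list(axes = m_axes, top_genes = top,
                 branch_assignment = branches,
                 divergence_index = divergence_index(r, m_axes),
                 scatter = scatter),
            class = "ProgramReport")
}

#' @export
print.ProgramReport <- function(x, ...) {
  cat(sprintf("ProgramReport over axes %s\n", paste(x$axes, collapse = ", ")))
  tab <- table(x$branch_assignment)
  cat("branches:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write a program report to disk
#'
#' Emits `top_genes.tsv` (axis, gene, loading), `branches.tsv`,
#' `divergence.tsv` and the M1-M2 scatter table `scatter.tsv`, plus a JSON
#' summary.
#'
#' @param report A [program_report()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_program_report <- function(report, dir) {
  stopifnot(inherits(report, "ProgramReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  top <- do.call(rbind, lapply(names(report$top_genes), function(ax) {
    cbind(axis = ax, report$top_genes[[ax]])
  }))
  utils::write.table(top, file.path(dir, "top_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  br <- data.frame(sample_id = names(report$branch_assignment),
                   branch = unname(report$branch_assignment),
                   stringsAsFactors = FALSE)
  utils::write.table(br, file.path(dir, "branches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dv <- data.frame(gene_id = names(report$divergence_index),
                   divergence = unname(report$divergence_index),
                   stringsAsFactors = FALSE)
  utils::write.table(dv, file.path(dir, "divergence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$scatter, file.path(dir, "scatter.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(axes = report$axes,
         branch_counts = as.list(table(report$branch_assignment))),
    file.path(dir, "programs.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
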
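#' @name ScoreResult
#' @title Per-sample gene-set score container
#'
#' @description All scorers return a `ScoreResult`: a list with
#' \describe{
#'   \item{method}{one of `nnpca`, `ssgsea`, `aucell`, `scse`, `jasmine`}
#'   \item{scores}{samples x axes numeric matrix (rownames = sample ids)}
#'   \item{axis_names}{ordered axis names, e.g. `E`, `M1`, `M2`}
#'   \item{loadings}{nnPCA only: named list, axis -> named nonnegative
#'     loading vector with unit Euclidean norm}
#'   \item{variance_explained}{nnPCA only: named numeric per axis;
#'     non-increasing across the axes of one gene set}
#'   \item{genes_used}{named list, axis -> gene ids actually used}
#' }
NULL

new_score_result <- function(method, scores, genes_used, loadings = NULL,
                             variance_explained = NULL) {
  check_finite(scores, "scores")
  structure(
    list(method = method, scores = scores, axis_names = colnames(scores),
         loadings = loadings, variance_explained = variance_explained,
         genes_used = genes_used),
    class = "ScoreResult"
  )
}

#' @export
print.ScoreResult <- function(x, ...) {
  cat(sprintf("ScoreResult (%s): %d samples x %d axes [%s]\n", x$method,
              nrow(x$scores), ncol(x$scores),
              paste(x$axis_names, collapse = ", ")))
  if (!is.null(x$variance_explained)) {
    cat("variance explained:",
        paste(sprintf("%s=%.4g", names(x$variance_explained),
                      x$variance_explained), collapse = ", "), "\n")
  }
  invisible(x)
}

default_min_genes <- function(method) {
  if (method %in% c("nnpca", "ssgsea", "jasmine")) 5L else 1L
}

# Intersect a gene set with the matrix genes (case-insensitive); returns the
# row indices in x and the matched matrix gene ids.
match_set_genes <- function(x, gs, min_genes) {
  idx <- which(fold_id(x$gene_ids) %in% gs$genes)
  if (length(idx) < min_genes) {
    estop("gene set '%s' matches only %d genes in the matrix (min_genes = %d)",
          gs$name, length(idx), min_genes)
  }
  idx
}

require_normalized <- function(x) {
  if (x$normalized != "lognorm") {
    estop("expression matrix must be log-normalized before scoring (see lognormalize(); pre-normalized input can be read with normalized = 'lognorm')")
  }
}

#' Score a gene set with nonnegative PCA
#'
#' Subsets the matrix to the genes of the set, drops zero-variance genes,
#' centers per gene and fits [nnpca_fit()]. The per-axis scores are the
#' nonnegatively-weighted projections of the centered submatrix; loadings
#' expose each gene's contribution and the achieved variances rank the axes.
#'
#' @param x A log-normalized [expression_matrix()].
#' @param gs A [gene_set()].
#' @param n_components Number of axes to extract (default 2).
#' @param min_genes Minimum matrix/set overlap (default 5).
#' @param axis_prefix Prefix for axis names; axes are named
#'   `<prefix>1..<prefix>k`. Defaults to the set name.
#' @param scale Also divide each gene by its standard deviation (default
#'   `FALSE`, center-only).
#' @param tol,max_iter,seed Passed to [nnpca_fit()].
#' @return A [ScoreResult].
#' @export
score_nnpca <- function(x, gs, n_components = 2L, min_genes = 5L,
                        axis_prefix = gs$name, scale = FALSE, tol = 1e-6,
                        max_iter = 500L, seed = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(gs, "GeneSet"))
  require_normalized(x)
  idx <- match_set_genes(x, gs, min_genes)
  sub <- x$values[idx, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  sub <- sub[sds > 0, , drop = FALSE]
  if (nrow(sub) < max(2L, min_genes)) {
    estop("gene set '%s' has only %d genes with nonzero variance (min_genes = %d)",
          gs$name, nrow(sub), min_genes)
  }
  if (scale) sub <- sub / apply(sub, 1L, stats::sd)
  fit <- nnpca_fit(sub, n_components = n_components, center = TRUE,
                   tol = tol, max_iter = max_iter, seed = seed)
  axes <- paste0(axis_prefix, seq_len(n_components))
  scores <- fit$scores
  dimnames(scores) <- list(x$sample_ids, axes)
  loadings <- lapply(seq_len(n_components), function(k) {
    stats::setNames(fit$loadings[, k], rownames(sub))
  })
  names(loadings) <- axes
  genes_used <- stats::setNames(rep(list(rownames(sub)), n_components), axes)
  new_score_result("nnpca", scores, genes_used, loadings = loadings,
                   variance_explained = stats::setNames(fit$variance_explained, axes))
}

#' Single-sample GSEA enrichment score
#'
#' For each sample, genes are ranked by expression (descending walk; average
#' ranks on ties) and the enrichment score is the sum, over the ranked list,
#' of the difference between the weighted in-set empirical CDF (weights =
#' rank value raised to `alpha`) and the unweighted out-of-set CDF — a
#' Kolmogorov-Smirnov-style running-sum statistic. No per-sample
#' significance test is produced.
#'
#' @param x A log-normalized [expression_matrix()].
#' @param gs A [gene_set()]; its complement in the matrix must be non-empty.
#' @param alpha Rank weight exponent (default 0.25).
#' @param min_genes Minimum overlap (default 5).
#' @return A [ScoreResult] with one axis named after the set.
#' @export
score_ssgsea <- function(x, gs, alpha = 0.25, min_genes = 5L) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(gs, "GeneSet"))
  require_normalized(x)
  idx <- match_set_genes(x, gs, min_genes)
  n <- nrow(x$values)
  if (length(idx) >= n) {
    estop("gene set '%s' covers every gene in the matrix; enrichment is degenerate", gs$name)
  }
  in_set <- seq_len(n) %in% idx
  scores <- apply(x$values, 2L, function(v) {
    r <- rank(v)                       # larger value -> larger rank
    ord <- order_desc_by_value(v, x$gene_ids)
    hit <- in_set[ord]
    w <- r[ord]^alpha
    p_in <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
    p_out <- cumsum(!hit) / (n - sum(hit))
    sum(p_in - p_out)
  })
  finish_single_axis("ssgsea", x, gs, idx, scores)
}

#' AUCell-style recovery-curve score
#'
#' For each sample, genes are ranked by expression descending (ties broken
#' deterministically by case-folded gene id) and the score is the area under
#' the curve counting set genes recovered among the top `r` genes, for `r`
#' up to `ceiling(top_frac * n_genes)`, normalized by the maximum achievable
#' area, so scores lie in [0, 1].
#'
#' @param x A log-normalized [expression_matrix()].
#' @param gs A [gene_set()].
#' @param top_frac Fraction of the ranking integrated (default 0.05).
#' @param min_genes Minimum overlap (default 1).
#' @return A [ScoreResult] with one axis named after the set.
#' @export
score_aucell <- function(x, gs, top_frac = 0.05, min_genes = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(gs, "GeneSet"))
  require_normalized(x)
  if (!(top_frac > 0 && top_frac <= 1)) estop("'top_frac' must be in (0, 1]")
  idx <- match_set_genes(x, gs, min_genes)
  n <- nrow(x$values)
  T <- as.integer(ceiling(top_frac * n))
  in_set <- seq_len(n) %in% idx
  max_area <- sum(pmin(seq_len(T), length(idx)))
  scores <- apply(x$values, 2L, function(v) {
    ord <- order_desc_by_value(v, x$gene_ids)
    hits <- cumsum(in_set[ord])[seq_len(T)]
    sum(hits) / max_area
  })
  finish_single_axis("aucell", x, gs, idx, scores)
}

#' Normalized-sum (SCSE) score
#'
#' The score of a sample is the summed expression of the set genes as a
#' percentage of the sample's total expression; invariant under per-sample
#' scalar rescaling.
#'
#' @param x A log-normalized [expression_matrix()].
#' @param gs A [gene_set()].
#' @param min_genes Minimum overlap (default 1).
#' @return A [ScoreResult] with one axis named after the set.
#' @export
score_scse <- function(x, gs, min_genes = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(gs, "GeneSet"))
  require_normalized(x)
  idx <- match_set_genes(x, gs, min_genes)
  totals <- colSums(x$values)
  zero <- totals == 0
  if (any(zero)) {
    estop("sample '%s' has zero total expression", x$sample_ids[which(zero)[1L]])
  }
  scores <- 100 * colSums(x$values[idx, , drop = FALSE]) / totals
  finish_single_axis("scse", x, gs, idx, scores)
}

#' JASMINE-style rank/odds-ratio score
#'
#' Combines, per sample, (i) the mean rank of the *expressed* (value > 0)
#' set genes among all expressed genes, divided by the number of expressed
#' genes, and (ii) a dropout-aware enrichment component: the odds ratio of
#' set genes being expressed versus non-set genes being expressed, with a
#' 0.5 continuity correction. Each component is min-max scaled to [0, 1]
#' across samples (a constant component scales to 0) and the final score is
#' their arithmetic mean. A sample with no expressed set gene gets a
#' rank-mean component of 0.
#'
#' @param x A log-normalized [expression_matrix()].
#' @param gs A [gene_set()].
#' @param min_genes Minimum overlap (default 5).
#' @return A [ScoreResult] with one axis named after the set.
#' @export
score_jasmine <- function(x, gs, min_genes = 5L) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(gs, "GeneSet"))
  require_normalized(x)
  idx <- match_set_genes(x, gs, min_genes)
  n <- nrow(x$values)
  in_set <- seq_len(n) %in% idx
  comp <- apply(x$values, 2L, function(v) {
    expressed <- v > 0
    ne <- sum(expressed)
    rank_mean <- 0
    if (ne > 0L && any(in_set & expressed)) {
      r <- rank(v[expressed])
      rank_mean <- mean(r[in_set[expressed]]) / ne
    }
    a <- sum(in_set & expressed)
    b <- sum(in_set & !expressed)
    cc <- sum(!in_set & expressed)
    d <- sum(!in_set & !expressed)
    or <- ((a + 0.5) / (b + 0.5)) / ((cc + 0.5) / (d + 0.5))
    c(rank_mean, or)
  })
  scores <- (minmax_scale(comp[1L, ]) + minmax_scale(comp[2L, ])) / 2
  finish_single_axis("jasmine", x, gs, idx, scores)
}

# min-max scale to [0,1]; a constant vector scales to 0 by convention
minmax_scale <- function(v) {
  rng <- range(v)
  if (rng[1L] == rng[2L]) return(rep(0, length(v)))
  (v - rng[1L]) / (rng[2L] - rng[1L])
}

finish_single_axis <- function(method, x, gs, idx, scores) {
  m <- matrix(scores, ncol = 1L, dimnames = list(x$sample_ids, gs$name))
  new_score_result(method, m,
                   genes_used = stats::setNames(list(x$gene_ids[idx]), gs$name))
}

#' Score gene sets with a chosen algorithm
#'
#' Dispatcher over the five implemented scorers. `sets` may be a
#' [gene_set_collection()] (one axis per set for the rank/sum methods, or
#' the leading nnPCA axis per set) or a named list with elements `E` and `M`
#' holding one [gene_set()] each. In the E/M-pair form with `method =
#' "nnpca"`, the result carries the axis `E` (one epithelial component) and
#' axes `M1..Mk` (`k = n_components` mesenchymal components), which is the
#' default input for the downstream program, state, and screening analyses.
#'
#' @param x A log-normalized [expression_matrix()].
#' @param sets A [gene_set_collection()] or `list(E = ..., M = ...)` of
#'   [gene_set()]s.
#' @param method One of `"nnpca"`, `"ssgsea"`, `"aucell"`, `"scse"`,
#'   `"jasmine"` (default `"nnpca"`).
#' @param n_components Mesenchymal components for nnPCA (default 2).
#' @param ... Further arguments passed to the underlying scorer
#'   (`alpha`, `top_frac`, `min_genes`, `seed`, ...).
#' @return A [ScoreResult] with one column per axis.
#' @export
score <- function(x, sets, method = c("nnpca", "ssgsea", "aucell", "scse",
                                      "jasmine"),
                  n_components = 2L, ...) {
  if (is.character(method) && length(method) == 1L &&
      !method %in% c("nnpca", "ssgsea", "aucell", "scse", "jasmine")) {
    estop("unknown scoring method '%s'; valid options: nnpca, ssgsea, aucell, scse, jasmine",
          method)
  }
  method <- match.arg(method)
  em_pair <- is.list(sets) && !inherits(sets, "GeneSetCollection") &&
    all(c("E", "M") %in% names(sets))
  if (em_pair) {
    e_set <- sets$E
    m_set <- sets$M
    stopifnot(inherits(e_set, "GeneSet"), inherits(m_set, "GeneSet"))
    if (method == "nnpca") {
      re <- score_nnpca(x, e_set, n_components = 1L, axis_prefix = "E", ...)
      rm_ <- score_nnpca(x, m_set, n_components = n_components,
                         axis_prefix = "M", ...)
      colnames(re$scores) <- "E"
      names(re$loadings) <- "E"
      names(re$variance_explained) <- "E"
      names(re$genes_used) <- "E"
      return(combine_score_results(list(re, rm_), "nnpca"))
    }
    re <- score_single(x, e_set, method, ...)
    colnames(re$scores) <- "E"
    names(re$genes_used) <- "E"
    rm_ <- score_single(x, m_set, method, ...)
    colnames(rm_$scores) <- "M"
    names(rm_$genes_used) <- "M"
    return(combine_score_results(list(re, rm_), method))
  }
  if (!inherits(sets, "GeneSetCollection")) {
    estop("'sets' must be a GeneSetCollection or a list(E = , M = ) pair of GeneSets")
  }
  res <- lapply(sets$sets, function(gs) {
    if (method == "nnpca") {
      r <- score_nnpca(x, gs, n_components = 1L, axis_prefix = gs$name, ...)
      colnames(r$scores) <- gs$name
      names(r$loadings) <- gs$name
      names(r$variance_explained) <- gs$name
      names(r$genes_used) <- gs$name
      r
    } else {
      score_single(x, gs, method, ...)
    }
  })
  combine_score_results(res, method)
}

score_single <- function(x, gs, method, ...) {
  switch(method,
         nnpca = score_nnpca(x, gs, ...),
         ssgsea = score_ssgsea(x, gs, ...),
         aucell = score_aucell(x, gs, ...),
         scse = score_scse(x, gs, ...),
         jasmine = score_jasmine(x, gs, ...))
}

combine_score_results <- function(results, method) {
  scores <- do.call(cbind, lapply(results, `[[`, "scores"))
  genes_used <- do.call(c, lapply(results, `[[`, "genes_used"))
  loadings <- do.call(c, lapply(results, `[[`, "loadings"))
  ve <- do.call(c, lapply(results, `[[`, "variance_explained"))
  new_score_result(method, scores, genes_used,
                   loadings = if (length(loadings)) loadings else NULL,
                   variance_explained = if (length(ve)) ve else NULL)
}

#' Write score tables as TSV
#'
#' Writes the per-sample score table (`sample_id` plus one column per axis);
#' for nnPCA results, optional companion tables for loadings (long format:
#' axis, gene, loading) and variance explained.
#'
#' @param r A [ScoreResult].
#' @param path Output TSV path for the scores.
#' @param loadings_path,variance_path Optional companion output paths.
#' @return `path`, invisibly.
#' @export
write_scores <- function(r, path, loadings_path = NULL, variance_path = NULL) {
  stopifnot(inherits(r, "ScoreResult"))
  df <- data.frame(sample_id = rownames(r$scores), r$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(loadings_path) && !is.null(r$loadings)) {
    ld <- do.call(rbind, lapply(names(r$loadings), function(ax) {
      data.frame(axis = ax, gene_id = names(r$loadings[[ax]]),
                 loading = unname(r$loadings[[ax]]), stringsAsFactors = FALSE)
    }))
    utils::write.table(ld, loadings_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(variance_path) && !is.null(r$variance_explained)) {
    ve <- data.frame(axis = names(r$variance_explained),
                     variance_explained = unname(r$variance_explained),
                     stringsAsFactors = FALSE)
    utils::write.table(ve, variance_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
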
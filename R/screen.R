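#' Screen a gene-set collection for correlation with an EMT score
#'
#' Scores every gene set in the collection on the expression matrix with
#' the chosen algorithm (for nnPCA, the leading component per set) and
#' computes the Pearson correlation of each set's per-sample scores with a
#' reference EMT score vector (typically the M1 scores). Sets with too few
#' matching genes or constant scores are reported as skipped with a
#' machine-readable reason, never silently dropped. Two-sided p-values come
#' from the t-distribution with n-2 degrees of freedom and are
#' Benjamini-Hochberg adjusted across all tested sets; the coefficients are
#' the primary output and the q-values are auxiliary.
#'
#' @param x A log-normalized [expression_matrix()].
#' @param collection A non-empty [gene_set_collection()].
#' @param ref_scores Numeric reference score vector aligned with the
#'   samples of `x` (non-constant).
#' @param method Scoring algorithm for the collection (default `"nnpca"`;
#'   `"scse"` is the cheapest choice for very large collections).
#' @param min_genes Minimum set/matrix overlap; defaults to 5 for
#'   nnpca/ssgsea/jasmine and 1 for scse/aucell.
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @param reference_axis Name recorded for the reference score (default
#'   `"M1"`).
#' @param ... Extra arguments for the underlying scorer.
#' @return An object of class `ScreenResult`: list with `rows`
#'   (`data.frame`: `name`, `n_genes_matched`, `pearson_r`, `p_value`,
#'   `bh_q`, in collection order), `skipped` (`data.frame`: `name`,
#'   `reason` in `low_overlap`/`constant_score`), `reference_axis`,
#'   `method`.
#' @export
screen_genesets <- function(x, collection, ref_scores, method = "nnpca",
                            min_genes = NULL, cor_method = c("pearson", "spearman"),
                            reference_axis = "M1", ...) {
  stopifnot(inherits(x, "ExpressionMatrix"),
            inherits(collection, "GeneSetCollection"))
  cor_method <- match.arg(cor_method)
  if (length(collection) == 0L) estop("empty gene-set collection")
  if (length(ref_scores) != ncol(x$values)) {
    estop("reference scores (%d) do not match sample count (%d)",
          length(ref_scores), ncol(x$values))
  }
  check_finite(ref_scores, "reference scores")
  if (stats::sd(ref_scores) == 0) estop("reference scores are constant")
  method <- match.arg(method, c("nnpca", "ssgsea", "aucell", "scse", "jasmine"))
  if (is.null(min_genes)) min_genes <- default_min_genes(method)
  fold_genes <- fold_id(x$gene_ids)

  rows <- list()
  skipped <- list()
  for (gs in collection$sets) {
    n_match <- sum(fold_genes %in% gs$genes)
    if (n_match < min_genes) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(name = gs$name, reason = "low_overlap",
                   stringsAsFactors = FALSE)
      next
    }
    s <- tryCatch({
      r <- if (method == "nnpca") {
        score_nnpca(x, gs, n_components = 1L, min_genes = min_genes, ...)
      } else {
        score_single(x, gs, method, min_genes = min_genes, ...)
      }
      r$scores[, 1L]
    }, error = function(e) NULL)
    if (is.null(s) || stats::sd(s) == 0) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(name = gs$name, reason = "constant_score",
                   stringsAsFactors = FALSE)
      next
    }
    ct <- if (cor_method == "spearman") {
      suppressWarnings(stats::cor.test(s, ref_scores, method = "spearman",
                                       exact = FALSE))
    } else {
      stats::cor.test(s, ref_scores)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(name = gs$name, n_genes_matched = n_match,
                 pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 stringsAsFactors = FALSE)
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), n_genes_matched = integer(),
               pearson_r = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE)
  rows$bh_q <- if (nrow(rows)) stats::p.adjust(rows$p_value, "BH") else numeric(0)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(name = character(), reason = character(), stringsAsFactors = FALSE)
  structure(list(rows = rows, skipped = skipped,
                 reference_axis = reference_axis, method = method,
                 cor_method = cor_method),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat(sprintf("ScreenResult (%s vs %s): %d tested, %d skipped\n", x$method,
              x$reference_axis, nrow(x$rows), nrow(x$skipped)))
  invisible(x)
}

#' Top correlated and anti-correlated gene sets
#'
#' Splits a screen into the `n` most positively correlated sets (r > 0,
#' descending) and the `n` most negatively correlated sets (r < 0,
#' ascending); either list may be shorter when fewer sets qualify. The
#' returned tables are bar-chart ready (set name plus coefficient).
#'
#' @param s A [screen_genesets()] result.
#' @param n Maximum sets per list (default 10).
#' @return List with `positive` and `negative` `data.frame`s.
#' @export
top_hits <- function(s, n = 10L) {
  stopifnot(inherits(s, "ScreenResult"))
  n <- as.integer(n)
  if (n < 1L) estop("'n' must be >= 1")
  rows <- s$rows
  pos <- rows[rows$pearson_r > 0, , drop = FALSE]
  pos <- pos[order(-pos$pearson_r, pos$name), , drop = FALSE]
  pos <- utils::head(pos, n)
  neg <- rows[rows$pearson_r < 0, , drop = FALSE]
  neg <- neg[order(neg$pearson_r, neg$name), , drop = FALSE]
  neg <- utils::head(neg, n)
  rownames(pos) <- rownames(neg) <- NULL
  list(positive = pos, negative = neg)
}

#' Write screen outputs to disk
#'
#' Emits `screen.tsv` (all tested sets), `top_hits.tsv` (positive and
#' negative lists with a `direction` column) and `skipped.tsv`.
#'
#' @param s A [screen_genesets()] result.
#' @param dir Output directory.
#' @param n Top hits per direction (default 10).
#' @return The directory, invisibly.
#' @export
write_screen <- function(s, dir, n = 10L) {
  stopifnot(inherits(s, "ScreenResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(s$rows, file.path(dir, "screen.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  th <- top_hits(s, n)
  hits <- rbind(
    if (nrow(th$positive)) cbind(direction = "positive", th$positive),
    if (nrow(th$negative)) cbind(direction = "negative", th$negative))
  if (is.null(hits)) {
    hits <- data.frame(direction = character(), name = character(),
                       n_genes_matched = integer(), pearson_r = numeric(),
                       p_value = numeric(), bh_q = numeric())
  }
  utils::write.table(hits, file.path(dir, "top_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(s$skipped, file.path(dir, "skipped.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
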
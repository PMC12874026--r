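#' Label GMM clusters as epithelial, mesenchymal or hybrid states
#'
#' States are defined relative to the dataset: both score axes are z-scored
#' across samples and each cluster gets a polarity
#' `delta = mean z(M) - mean z(E)` over its hard-assigned samples. The
#' cluster with the smallest delta is the extreme epithelial state `E`, the
#' largest is the extreme mesenchymal state `M`, and the remaining clusters
#' are `hybrid-1..hybrid-(k-2)` ordered by mean M score ascending. A
#' single-cluster fit is labeled `hybrid-1`. An empty hard cluster is
#' labeled from its model mean instead of an empirical mean.
#'
#' @param fit A [fit_gmm()] result.
#' @param e_scores,m_scores The score vectors the fit was computed on.
#' @return An object of class `EMTStateAssignment`: `data.frame` with
#'   columns `sample_id`, `cluster` (0-based), `state`, `posterior` (max
#'   responsibility).
#' @export
label_states <- function(fit, e_scores, m_scores) {
  stopifnot(inherits(fit, "GmmFit"))
  n <- nrow(fit$responsibilities)
  if (length(e_scores) != n || length(m_scores) != n) {
    estop("score vectors do not match the fitted sample count (%d)", n)
  }
  k <- fit$k
  hard <- max.col(fit$responsibilities, ties.method = "first")
  ze <- zscore(e_scores, "E scores", allow_constant = TRUE)
  zm <- zscore(m_scores, "M scores", allow_constant = TRUE)
  mu_e <- mean(e_scores); sd_e <- stats::sd(e_scores)
  mu_m <- mean(m_scores); sd_m <- stats::sd(m_scores)
  delta <- numeric(k)
  mean_m <- numeric(k)
  for (j in seq_len(k)) {
    idx <- which(hard == j)
    if (length(idx) > 0L) {
      delta[j] <- mean(zm[idx]) - mean(ze[idx])
      mean_m[j] <- mean(m_scores[idx])
    } else {
      # empty hard cluster: fall back to the model mean, standardized with
      # the same dataset-wide moments
      zmj <- if (sd_m > 0) (fit$means[j, "M"] - mu_m) / sd_m else 0
      zej <- if (sd_e > 0) (fit$means[j, "E"] - mu_e) / sd_e else 0
      delta[j] <- zmj - zej
      mean_m[j] <- fit$means[j, "M"]
    }
  }
  state_of <- character(k)
  if (k == 1L) {
    state_of[1L] <- "hybrid-1"
  } else {
    ord_delta <- order(delta, mean_m)   # ties in delta broken by mean M
    e_cl <- ord_delta[1L]
    m_cl <- ord_delta[k]
    state_of[e_cl] <- "E"
    state_of[m_cl] <- "M"
    hybrids <- setdiff(seq_len(k), c(e_cl, m_cl))
    hybrids <- hybrids[order(mean_m[hybrids])]
    if (length(hybrids)) {
      state_of[hybrids] <- paste0("hybrid-", seq_along(hybrids))
    }
  }
  sample_id <- rownames(fit$responsibilities) %||% as.character(seq_len(n))
  out <- data.frame(sample_id = sample_id, cluster = hard - 1L,
                    state = state_of[hard],
                    posterior = fit$responsibilities[cbind(seq_len(n), hard)],
                    stringsAsFactors = FALSE)
  class(out) <- c("EMTStateAssignment", class(out))
  out
}

#' Cross-tabulate EMT states against sample labels
#'
#' Builds the label-by-state contingency table underlying a Sankey diagram
#' of how experimental labels (time points, clusters) map onto EMT states,
#' together with row-normalized proportions and a flow list sorted by count
#' descending.
#'
#' @param assignment An [label_states()] result.
#' @param meta A [read_metadata()] table covering the assigned samples.
#' @param label_column Name of the categorical metadata column.
#' @return An object of class `StateCrosstab`: list with `counts` (matrix),
#'   `proportions` (rows sum to 1), and `flows` (`data.frame` with columns
#'   `label`, `state`, `count`).
#' @export
crosstab_states <- function(assignment, meta, label_column) {
  stopifnot(inherits(assignment, "EMTStateAssignment"))
  if (!label_column %in% colnames(meta)) {
    estop("label column '%s' not in metadata; available: %s", label_column,
          paste(setdiff(colnames(meta), "sample_id"), collapse = ", "))
  }
  meta <- align_metadata(meta, assignment$sample_id)
  labels <- as.character(meta[[label_column]])
  counts <- table(label = labels, state = assignment$state)
  counts <- unclass(counts)
  props <- counts / rowSums(counts)
  flows <- as.data.frame(as.table(counts), stringsAsFactors = FALSE)
  colnames(flows) <- c("label", "state", "count")
  flows <- flows[flows$count > 0, , drop = FALSE]
  flows <- flows[order(-flows$count, flows$label, flows$state), , drop = FALSE]
  rownames(flows) <- NULL
  structure(list(counts = counts, proportions = props, flows = flows),
            class = "StateCrosstab")
}

#' @export
print.StateCrosstab <- function(x, ...) {
  cat("StateCrosstab (label x state counts):\n")
  print(x$counts)
  invisible(x)
}

#' Summarize scores along pseudotime
#'
#' Splits samples into equal-count (quantile) pseudotime bins and reports,
#' per bin and per score axis, the bin center (mean pseudotime), mean,
#' standard deviation and count. Pseudotime itself is consumed from
#' metadata; it is never inferred here.
#'
#' @param scores Numeric vector or samples-by-axes matrix of scores.
#' @param pseudotime Finite numeric vector, one value per sample.
#' @param n_bins Number of bins (default 20); must not exceed the number of
#'   distinct pseudotime values.
#' @return A `data.frame` with columns `axis`, `bin`, `bin_center`, `mean`,
#'   `sd`, `n`, ordered by axis then bin.
#' @export
trend_over_pseudotime <- function(scores, pseudotime, n_bins = 20L) {
  if (is.null(dim(scores))) {
    scores <- matrix(scores, ncol = 1L, dimnames = list(NULL, "score"))
  }
  if (nrow(scores) != length(pseudotime)) {
    estop("scores and pseudotime differ in length")
  }
  check_finite(pseudotime, "pseudotime")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) estop("'n_bins' must be >= 2")
  n_distinct <- length(unique(pseudotime))
  if (n_bins > n_distinct) {
    estop("%d bins requested but pseudotime has only %d distinct values",
          n_bins, n_distinct)
  }
  # equal-count bins via rank
  r <- rank(pseudotime, ties.method = "first")
  bin <- ceiling(r / (length(pseudotime) / n_bins))
  bin <- pmin(bin, n_bins)
  out <- do.call(rbind, lapply(colnames(scores), function(ax) {
    do.call(rbind, lapply(seq_len(n_bins), function(b) {
      idx <- which(bin == b)
      data.frame(axis = ax, bin = b,
                 bin_center = mean(pseudotime[idx]),
                 mean = mean(scores[idx, ax]),
                 sd = if (length(idx) > 1L) stats::sd(scores[idx, ax]) else 0,
                 n = length(idx), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Write state-assignment outputs to disk
#'
#' Emits `states.tsv` (sample, cluster, state, posterior), `flows.tsv` and
#' `proportions.tsv` when a cross-tab is given, `trend.tsv` when a trend
#' table is given, and the mixture parameters as `gmm.json`.
#'
#' @param assignment An [label_states()] result.
#' @param fit The [fit_gmm()] result.
#' @param dir Output directory.
#' @param crosstab Optional [crosstab_states()] result.
#' @param trend Optional [trend_over_pseudotime()] table.
#' @return The directory, invisibly.
#' @export
write_states <- function(assignment, fit, dir, crosstab = NULL, trend = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(assignment, file.path(dir, "states.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(k = fit$k, weights = fit$weights, means = fit$means,
         covariances = fit$covariances, log_likelihood = fit$log_likelihood,
         bic = fit$bic, bic_table = fit$bic_table, seed = fit$seed),
    file.path(dir, "gmm.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(crosstab)) {
    utils::write.table(crosstab$flows, file.path(dir, "flows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    props <- data.frame(label = rownames(crosstab$proportions),
                        crosstab$proportions, check.names = FALSE,
                        stringsAsFactors = FALSE)
    utils::write.table(props, file.path(dir, "proportions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(trend)) {
    utils::write.table(trend, file.path(dir, "trend.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
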
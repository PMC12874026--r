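#' Nonnegative principal component analysis by projected power iteration
#'
#' Extracts successive components whose loading vectors are constrained to
#' the nonnegative orthant. Each component maximizes the sample variance of
#' the projected data subject to nonnegativity; successive components are
#' obtained by rank-one deflation of the covariance matrix. Because
#' nonnegativity and orthogonality conflict, components are not guaranteed
#' orthogonal; variances explained are reported per component and are
#' non-increasing in practice.
#'
#' @details For each component the gene-gene covariance `S` of the (row-
#'   centered) data is attacked with projected power iteration: iterate
#'   `v <- S v`, `v <- pmax(v, 0)`, `v <- v / ||v||` until the update moves
#'   by less than `tol` (max-norm) or `max_iter` is reached. The iterate is
#'   initialized from the elementwise absolute value of the leading
#'   eigenvector of the current deflated covariance, projected to the
#'   nonnegative orthant; if the iteration collapses to the zero vector, up
#'   to `n_restarts` seeded random nonnegative unit vectors are tried. After
#'   component `k` with achieved variance `lambda_k = v' S v`, the
#'   covariance is deflated as `S <- S - lambda_k v v'`. When the
#'   unconstrained leading eigenvector is already elementwise nonnegative
#'   (e.g. under an all-positive covariance), the solution coincides with
#'   standard PCA.
#'
#' @param m Numeric matrix, genes in rows, samples in columns; at least two
#'   rows must have nonzero variance.
#' @param n_components Number of components to extract.
#' @param center Center each gene (row) before fitting (default `TRUE`).
#' @param tol Convergence tolerance on the loading update (default `1e-6`).
#' @param max_iter Maximum power iterations per component (default 500).
#' @param n_restarts Random nonnegative restarts tried when an iterate
#'   collapses to zero (default 5).
#' @param seed Integer seed for the restart draws; `NULL` leaves the RNG
#'   state untouched.
#'
#' @return A list with `loadings` (genes x components, columns nonnegative
#'   with unit Euclidean norm), `scores` (samples x components, zero mean
#'   per column), `variance_explained` (achieved variance per component),
#'   and `converged` (logical per component; a non-converged component
#'   carries the best iterate and a warning is raised).
#' @export
nnpca_fit <- function(m, n_components = 2L, center = TRUE, tol = 1e-6,
                      max_iter = 500L, n_restarts = 5L, seed = NULL) {
  m <- as.matrix(m)
  check_finite(m, "input matrix")
  p <- nrow(m)
  n <- ncol(m)
  if (n < 2L) estop("nnPCA needs at least 2 samples")
  row_sd <- apply(m, 1L, stats::sd)
  if (sum(row_sd > 0) < 2L) {
    estop("nnPCA needs at least 2 rows with nonzero variance")
  }
  n_components <- as.integer(n_components)
  if (n_components < 1L) estop("'n_components' must be >= 1")
  if (n_components > min(p, n - 1L)) {
    estop("'n_components' (%d) exceeds min(genes=%d, samples-1=%d)",
          n_components, p, n - 1L)
  }
  mc <- if (center) m - rowMeans(m) else m
  S <- tcrossprod(mc) / (n - 1L)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }

  loadings <- matrix(0, p, n_components,
                     dimnames = list(rownames(m), paste0("C", seq_len(n_components))))
  lambdas <- numeric(n_components)
  converged <- logical(n_components)

  for (k in seq_len(n_components)) {
    res <- nnpca_component(S, tol = tol, max_iter = max_iter,
                           n_restarts = n_restarts)
    loadings[, k] <- res$w
    lambdas[k] <- res$lambda
    converged[k] <- res$converged
    if (!res$converged) {
      warning(sprintf("nnPCA component %d did not converge in %d iterations; best iterate returned",
                      k, max_iter))
    }
    S <- S - res$lambda * tcrossprod(res$w)
  }
  scores <- crossprod(mc, loadings)
  # loadings mix only row-centered genes, so scores are zero-mean by
  # construction; subtract residual numerical drift anyway
  scores <- sweep(scores, 2L, colMeans(scores))
  list(loadings = loadings, scores = scores, variance_explained = lambdas,
       converged = converged)
}

# one projected-power-iteration component on covariance S
nnpca_component <- function(S, tol, max_iter, n_restarts) {
  p <- nrow(S)
  init_main <- abs(eigen(S, symmetric = TRUE)$vectors[, 1L])
  inits <- c(list(init_main),
             lapply(seq_len(n_restarts), function(i) stats::runif(p)))
  for (v0 in inits) {
    v <- pmax(v0, 0)
    nv <- sqrt(sum(v^2))
    if (nv == 0) next
    v <- v / nv
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      v1 <- pmax(drop(S %*% v), 0)
      nv <- sqrt(sum(v1^2))
      if (nv == 0) break  # collapsed; try next initialization
      v1 <- v1 / nv
      delta <- max(abs(v1 - v))
      v <- v1
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    if (nv == 0) next
    lambda <- drop(crossprod(v, S %*% v))
    return(list(w = v, lambda = lambda, converged = converged))
  }
  estop("nnPCA iterate collapsed to zero for all %d restarts", n_restarts + 1L)
}
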
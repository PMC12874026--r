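#' Fit a Gaussian mixture model in E-M score space
#'
#' Clusters samples by their 2-D (E score, M score) coordinates with a full-
#' covariance Gaussian mixture fitted by expectation-maximization. For each
#' candidate component count `k` the EM is restarted `n_init` times from
#' seeded k-means initializations and the best log-likelihood is kept; the
#' returned fit is the `k` minimizing `BIC = -2 logL + p log(n)` with
#' `p = 6k - 1` free parameters (per component: 2 means, 3 covariance
#' entries, plus k-1 free weights).
#'
#' @param e_scores,m_scores Numeric per-sample score vectors of equal
#'   length (>= 20 samples and >= 5 per candidate component).
#' @param k_range Candidate component counts, a subset of 1..9
#'   (default `2:6`).
#' @param n_init Seeded restarts per `k` (default 5).
#' @param seed Integer seed controlling all restarts (default 1).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return An object of class `GmmFit`: list with `k`, `means` (k x 2),
#'   `covariances` (list of 2x2), `weights`, `responsibilities`
#'   (samples x k, rows sum to 1), `log_likelihood`, `loglik_trace`
#'   (non-decreasing), `bic`, `bic_table` (per candidate k), and `seed`.
#' @export
fit_gmm <- function(e_scores, m_scores, k_range = 2:6, n_init = 5L,
                    seed = 1L, max_iter = 500L, tol = 1e-8) {
  if (length(e_scores) != length(m_scores)) {
    estop("E and M score vectors differ in length")
  }
  check_finite(e_scores, "E scores")
  check_finite(m_scores, "M scores")
  n <- length(e_scores)
  if (n < 20L) estop("GMM fitting needs at least 20 samples (got %d)", n)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L | k_range > 9L)) estop("'k_range' must lie in 1..9")
  if (n < 5L * max(k_range)) {
    estop("only %d samples for k up to %d; need >= %d or a smaller k_range",
          n, max(k_range), 5L * max(k_range))
  }
  X <- cbind(E = as.numeric(e_scores), M = as.numeric(m_scores))
  sample_names <- names(e_scores) %||% rownames(X)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)

  fits <- vector("list", length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    best <- NULL
    for (init in seq_len(n_init)) {
      set.seed(as.integer(seed) %% 100000L * 10000L + k * 100L + init)
      f <- tryCatch(gmm_em_once(X, k, max_iter, tol),
                    error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$log_likelihood > best$log_likelihood)) {
        best <- f
      }
    }
    if (is.null(best)) {
      estop("EM failed for all %d restarts at k = %d (degenerate covariances)",
            n_init, k)
    }
    best$bic <- -2 * best$log_likelihood + (6 * k - 1) * log(n)
    fits[[ki]] <- best
  }
  bic_table <- data.frame(k = k_range,
                          log_likelihood = vapply(fits, `[[`, numeric(1L), "log_likelihood"),
                          bic = vapply(fits, `[[`, numeric(1L), "bic"))
  sel <- which.min(bic_table$bic)
  fit <- fits[[sel]]
  if (!is.null(sample_names)) rownames(fit$responsibilities) <- sample_names
  structure(
    list(k = k_range[sel], means = fit$means, covariances = fit$covariances,
         weights = fit$weights, responsibilities = fit$responsibilities,
         log_likelihood = fit$log_likelihood, loglik_trace = fit$loglik_trace,
         bic = fit$bic, bic_table = bic_table, seed = as.integer(seed),
         data = X),
    class = "GmmFit"
  )
}

#' @export
print.GmmFit <- function(x, ...) {
  cat(sprintf("GmmFit: k = %d components, n = %d samples, logL = %.3f, BIC = %.2f\n",
              x$k, nrow(x$responsibilities), x$log_likelihood, x$bic))
  invisible(x)
}

# one EM run from a k-means initialization (RNG state set by caller)
gmm_em_once <- function(X, k, max_iter, tol) {
  n <- nrow(X)
  ridge <- 1e-6 * mean(diag(stats::cov(X)))
  if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-10
  if (k == 1L) {
    hard <- rep(1L, n)
  } else {
    km <- suppressWarnings(stats::kmeans(X, centers = k, nstart = 1L,
                                         iter.max = 50L))
    hard <- km$cluster
  }
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), hard)] <- 1
  weights <- colMeans(resp)
  means <- NULL
  covs <- NULL
  ll_old <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    # M-step from current responsibilities
    nk <- colSums(resp)
    if (any(nk < 1e-8)) stop("empty component")
    weights <- nk / n
    means <- crossprod(resp, X) / nk
    covs <- lapply(seq_len(k), function(j) {
      d <- sweep(X, 2L, means[j, ])
      S <- crossprod(d * resp[, j], d) / nk[j]
      S <- S + diag(ridge, 2L)
      if (det(S) <= 0) stop("degenerate covariance")
      S
    })
    # E-step
    logdens <- vapply(seq_len(k), function(j) {
      dmvnorm2_log(X, means[j, ], covs[[j]]) + log(weights[j])
    }, numeric(n))
    m <- apply(logdens, 1L, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    resp <- exp(logdens - lse)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll < ll_old - 1e-6) {
      stop("log-likelihood decreased")  # numerical failure; restart
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(means = means, covariances = covs, weights = weights,
       responsibilities = resp, log_likelihood = ll_old, loglik_trace = trace)
}

# log density of a 2-D Gaussian via the closed-form 2x2 inverse
dmvnorm2_log <- function(X, mu, S) {
  detS <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  inv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2L) / detS
  d1 <- X[, 1L] - mu[1L]
  d2 <- X[, 2L] - mu[2L]
  q <- inv[1, 1] * d1^2 + 2 * inv[1, 2] * d1 * d2 + inv[2, 2] * d2^2
  -log(2 * pi) - 0.5 * log(detS) - 0.5 * q
}
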
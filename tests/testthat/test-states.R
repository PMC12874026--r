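three_blobs <- function(n_per = 100, seed = 51) {
  set.seed(seed)
  centers <- rbind(c(-3, -3), c(0, 0), c(3, 3))
  lab <- rep(1:3, each = n_per)
  e <- centers[lab, 1] + rnorm(3 * n_per, sd = 0.1)
  m <- centers[lab, 2] + rnorm(3 * n_per, sd = 0.1)
  list(e = e, m = m, lab = lab)
}

test_that("BIC selects three components on well-separated blobs with high ARI", {
  d <- three_blobs()
  fit <- fit_gmm(d$e, d$m, k_range = 2:6, seed = 1)
  expect_equal(fit$k, 3L)
  hard <- max.col(fit$responsibilities)
  expect_gte(mclust::adjustedRandIndex(hard, d$lab), 0.95)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(abs(rowSums(fit$responsibilities) - 1) < 1e-9))
  # EM log-likelihood is non-decreasing along the kept trace
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
})

test_that("a single Gaussian cloud selects k = 1 under BIC", {
  set.seed(3)
  e <- rnorm(200)
  m <- rnorm(200)
  fit <- fit_gmm(e, m, k_range = 1:3, seed = 2)
  expect_equal(fit$k, 1L)
})

test_that("sample-size preconditions are enforced", {
  expect_error(fit_gmm(rnorm(10), rnorm(10), k_range = 2:6, seed = 1),
               "at least 20 samples")
  expect_error(fit_gmm(rnorm(25), rnorm(25), k_range = 2:6, seed = 1),
               "smaller k_range")
  expect_error(fit_gmm(rnorm(30), rnorm(30), k_range = 10, seed = 1), "1..9")
})

test_that("seeded fits are bit-reproducible and agree with an independent EM implementation", {
  d <- three_blobs(seed = 52)
  f1 <- fit_gmm(d$e, d$m, k_range = 3, seed = 7)
  f2 <- fit_gmm(d$e, d$m, k_range = 3, seed = 7)
  expect_identical(f1$responsibilities, f2$responsibilities)
  expect_identical(f1$log_likelihood, f2$log_likelihood)

  ref <- mclust::Mclust(cbind(d$e, d$m), G = 3, modelNames = "VVV",
                        verbose = FALSE)
  expect_equal(f1$log_likelihood, ref$loglik, tolerance = 1e-3)
  ord_mine <- order(f1$means[, 1])
  ord_ref <- order(ref$parameters$mean[1, ])
  expect_equal(unname(f1$means[ord_mine, 1]),
               unname(ref$parameters$mean[1, ord_ref]), tolerance = 0.05)
})

test_that("cluster labeling maps extremes to E and M and is index-permutation invariant", {
  d <- three_blobs(seed = 53)
  # E axis decreases with the blob index, M increases: blob 1 is E-high/M-low
  fit <- fit_gmm(-d$e, d$m, k_range = 3, seed = 4)
  asn <- label_states(fit, -d$e, d$m)
  expect_setequal(unique(asn$state), c("E", "hybrid-1", "M"))
  expect_equal(round(mean(d$lab[asn$state == "E"])), 1)
  expect_equal(round(mean(d$lab[asn$state == "hybrid-1"])), 2)
  expect_equal(round(mean(d$lab[asn$state == "M"])), 3)

  # permute cluster indices in the fit: states must not change
  perm <- c(3, 1, 2)
  fitp <- fit
  fitp$responsibilities <- fit$responsibilities[, perm]
  fitp$means <- fit$means[perm, ]
  fitp$covariances <- fit$covariances[perm]
  fitp$weights <- fit$weights[perm]
  asnp <- label_states(fitp, -d$e, d$m)
  expect_equal(asnp$state, asn$state)
})

test_that("k = 2 labels the M-high cluster M, and k = 1 is hybrid-1", {
  set.seed(9)
  e <- c(rnorm(50, 2, 0.2), rnorm(50, -2, 0.2))
  m <- c(rnorm(50, -2, 0.2), rnorm(50, 2, 0.2))
  fit <- fit_gmm(e, m, k_range = 2, seed = 5)
  asn <- label_states(fit, e, m)
  expect_setequal(unique(asn$state), c("E", "M"))
  expect_true(all(asn$state[1:50] == "E"))
  expect_true(all(asn$state[51:100] == "M"))

  f1 <- fit_gmm(rnorm(40), rnorm(40), k_range = 1, seed = 6)
  a1 <- label_states(f1, rnorm(40), rnorm(40))
  expect_true(all(a1$state == "hybrid-1"))
})

test_that("state cross-tabs conserve counts and report proportions", {
  asn <- structure(data.frame(sample_id = paste0("s", 1:4),
                              cluster = c(0L, 0L, 1L, 1L),
                              state = c("E", "E", "M", "M"),
                              posterior = rep(1, 4),
                              stringsAsFactors = FALSE),
                   class = c("EMTStateAssignment", "data.frame"))
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     time = c("t0", "t0", "t1", "t1"),
                     stringsAsFactors = FALSE)
  class(meta) <- c("SampleMetadata", class(meta))
  ct <- crosstab_states(asn, meta, "time")
  expect_equal(sum(ct$counts), 4)
  expect_equal(ct$flows$count, c(2, 2))
  expect_setequal(paste(ct$flows$label, ct$flows$state),
                  c("t0 E", "t1 M"))
  expect_equal(unname(rowSums(ct$proportions)), c(1, 1), tolerance = 1e-9)
  expect_error(crosstab_states(asn, meta, "nope"),
               "label column 'nope' not in metadata.*time")
})

test_that("pseudotime trends bin by quantiles and validate input", {
  pt <- seq(0, 1, length.out = 40)
  tr <- trend_over_pseudotime(pt, pt, n_bins = 8)
  expect_equal(nrow(tr), 8)
  expect_true(all(diff(tr$mean) > 0))
  expect_equal(tr$n, rep(5, 8))

  tr2 <- trend_over_pseudotime(rep(2, 40), pt, n_bins = 4)
  expect_true(all(tr2$mean == 2))
  expect_true(all(tr2$sd == 0))

  expect_error(trend_over_pseudotime(pt, rep(1, 40), n_bins = 4),
               "only 1 distinct")
})

test_that("a planted EMT time course shifts states and trends toward M", {
  b <- simulate_expression(synthetic_spec(n_samples = 400, n_genes = 600,
                                          n_e_genes = 30, n_m1_genes = 30,
                                          latent_design = "time_course",
                                          seed = 54))
  x <- lognormalize(b$matrix)
  r <- score(x, bundle_pair(b), method = "nnpca", n_components = 2, seed = 54)
  e <- r$scores[, "E"]
  m <- r$scores[, "M1"]
  fit <- fit_gmm(e, m, seed = 54)
  asn <- label_states(fit, e, m)
  meta <- data.frame(sample_id = rownames(r$scores),
                     time_label = unname(b$truth$time_label),
                     stringsAsFactors = FALSE)
  class(meta) <- c("SampleMetadata", class(meta))
  ct <- crosstab_states(asn, meta, "time_label")
  m_prop <- ct$proportions[paste0("t", 0:3), "M"]
  expect_true(all(diff(m_prop) >= 0))
  expect_gt(m_prop[4], m_prop[1])

  tr <- trend_over_pseudotime(r$scores[, c("E", "M1")], b$truth$pseudotime,
                              n_bins = 20)
  trm <- tr[tr$axis == "M1", ]
  tre <- tr[tr$axis == "E", ]
  expect_gte(cor(trm$bin, trm$mean, method = "spearman"), 0.9)
  expect_lte(cor(tre$bin, tre$mean, method = "spearman"), -0.9)
})

test_that("state outputs serialize to disk", {
  d <- three_blobs(n_per = 40, seed = 55)
  fit <- fit_gmm(-d$e, d$m, k_range = 3, seed = 8)
  asn <- label_states(fit, -d$e, d$m)
  dir <- tempfile()
  write_states(asn, fit, dir)
  expect_true(all(file.exists(file.path(dir, c("states.tsv", "gmm.json")))))
  js <- jsonlite::read_json(file.path(dir, "gmm.json"))
  expect_equal(js$k, 3)
})
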
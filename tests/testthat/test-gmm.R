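# brute-force mixture log-density oracle used in several tests
oracle_log_dens <- function(X, weights, means, covs_fn) {
  K <- length(weights)
  sapply(seq_len(K), function(k) {
    S <- covs_fn(k)
    Si <- solve(S)
    ld <- determinant(S, logarithm = TRUE)$modulus
    apply(X, 1, function(x) {
      d <- x - means[k, ]
      log(weights[k]) - 0.5 * (length(x) * log(2 * pi) + ld +
                                 drop(t(d) %*% Si %*% d))
    })
  })
}

test_that("K = 1 EM equals sample moments (closed-form fixed point)", {
  set.seed(8)
  X <- matrix(rnorm(3000, sd = 2), ncol = 3)
  em <- event_matrix(X, c("a", "b", "c"), transformed = TRUE)
  tpl <- fit_gmm_template(em, K = 1, seed = 1, reg_covar = 0)
  expect_equal(as.numeric(tpl$means), colMeans(X), tolerance = 1e-6)
  n <- nrow(X)
  biased_cov <- cov(X) * (n - 1) / n
  expect_equal(tpl$covariances[, , 1], biased_cov, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(tpl$weights, 1)
})

test_that("assignments equal the brute-force posterior argmax", {
  set.seed(21)
  sep <- separated_clusters_em(n_per = 400)
  tpl <- fit_gmm_template(sep$em, K = 3, seed = 3)
  X <- matrix(rnorm(2000, sd = 4), ncol = 2)
  em <- event_matrix(X, sep$em$channels, transformed = TRUE)
  got <- assign_cells(tpl, em)
  ora <- max.col(oracle_log_dens(X, tpl$weights, tpl$means,
                                 function(k) tpl$covariances[, , k]),
                 ties.method = "first")
  expect_identical(got, ora)

  # dominant posterior: the component's own mean maps to it
  at_mean <- event_matrix(tpl$means, sep$em$channels, transformed = TRUE)
  expect_identical(assign_cells(tpl, at_mean), 1:3)
})

test_that("posterior ties break to the lowest component index", {
  tpl <- structure(list(K = 2L, weights = c(0.5, 0.5),
                        means = rbind(c(-1, 0), c(1, 0)),
                        covariances = array(diag(2), c(2, 2, 2)),
                        covariance_type = "full",
                        channels = c("x", "y"),
                        fit_log = list(seed = 1)),
                   class = "gmm_template")
  mid <- event_matrix(rbind(c(0, 0), c(0, 5)), c("x", "y"),
                      transformed = TRUE)
  expect_identical(assign_cells(tpl, mid), c(1L, 1L))
})

test_that("EM log-likelihood is monotone and improves with K", {
  sep <- separated_clusters_em(n_per = 600)
  for (K in c(2, 4, 8)) {
    tpl <- fit_gmm_template(sep$em, K = K, seed = 5)
    expect_true(all(diff(tpl$fit_log$loglik_trace) >= -1e-7),
                label = sprintf("monotone trace at K=%d", K))
  }
  lls <- vapply(c(2, 4, 8), function(K)
    fit_gmm_template(sep$em, K = K, seed = 5)$fit_log$loglik, 0)
  expect_true(all(diff(lls) >= -1e-9))
})

test_that("all four covariance types produce valid templates", {
  sep <- separated_clusters_em(n_per = 500)
  for (type in c("diag", "full", "spherical", "tied")) {
    tpl <- fit_gmm_template(sep$em, K = 4, covariance_type = type,
                            seed = 2)
    expect_equal(sum(tpl$weights), 1, tolerance = 1e-8)
    expect_true(all(tpl$weights >= 0))
    expect_equal(dim(tpl$means), c(4L, 2L))
    # every component covariance is symmetric positive definite
    for (k in 1:4) {
      S <- switch(type,
                  full = tpl$covariances[, , k],
                  tied = tpl$covariances,
                  diag = diag(tpl$covariances[k, ]),
                  spherical = diag(rep(tpl$covariances[k], 2)))
      expect_equal(S, t(S))
      expect_true(all(eigen(S, only.values = TRUE)$values > 0))
    }
    # labels are computable and in range
    expect_true(all(assign_cells(tpl, sep$em) %in% 1:4))
  }
})

test_that("infeasible K and raw input are rejected", {
  em <- make_em(20, seed = 1)
  expect_error(fit_gmm_template(em, K = 21, seed = 1),
               class = "cytofp_infeasible_k")
  raw <- make_em(50, seed = 1, transformed = FALSE)
  expect_error(fit_gmm_template(raw, K = 2, seed = 1),
               class = "cytofp_state_error")
})

test_that("fingerprints are row-normalized, complete and order-invariant", {
  sep <- separated_clusters_em(n_per = 500)
  tpl <- fit_gmm_template(sep$em, K = 3, seed = 4)

  # a sample from one far-separated component occupies one column
  set.seed(31)
  one <- event_matrix(matrix(rnorm(400), ncol = 2), sep$em$channels,
                      transformed = TRUE)
  ct1 <- fingerprint_samples(tpl, experiment_set(list(one)), 200, seed = 1)
  k0 <- assign_cells(tpl, event_matrix(rbind(c(0, 0)), sep$em$channels,
                                       transformed = TRUE))
  expect_equal(ncol(ct1$counts), 3L)
  expect_equal(unname(ct1$counts[1, k0]), 1)
  expect_equal(unname(rowSums(ct1$counts)), 1, tolerance = 1e-9)

  # permuting event order changes nothing
  perm <- with(list(ix = sample(nrow(one$events))),
               event_matrix(one$events[ix, ], one$channels,
                            one$sample_id, one$replicate_id, TRUE))
  ct2 <- fingerprint_samples(tpl, experiment_set(list(perm)),
                             nrow(one$events), seed = 1)
  ct3 <- fingerprint_samples(tpl, experiment_set(list(one)),
                             nrow(one$events), seed = 1)
  expect_equal(ct2$counts, ct3$counts)
})

test_that("sampling from the template itself recovers the weights", {
  sep <- separated_clusters_em(n_per = 1000)
  tpl <- fit_gmm_template(sep$em, K = 3, seed = 6)
  set.seed(17)
  n <- 10000
  comp <- sample.int(3, n, replace = TRUE, prob = tpl$weights)
  draws <- t(vapply(comp, function(k) {
    tpl$means[k, ] + drop(rnorm(2) %*% chol(tpl$covariances[, , k]))
  }, numeric(2)))
  em <- event_matrix(draws, tpl$channels, transformed = TRUE)
  ct <- fingerprint_samples(tpl, experiment_set(list(em)), n, seed = 1)
  expect_true(all(abs(ct$counts[1, ] - tpl$weights) < 0.02))
})

test_that("template JSON serialization preserves behaviour for all types", {
  sep <- separated_clusters_em(n_per = 300)
  probe <- make_em(100, channels = sep$em$channels, seed = 12)
  for (type in c("diag", "full", "spherical", "tied")) {
    tpl <- fit_gmm_template(sep$em, K = 3, covariance_type = type,
                            seed = 2)
    f <- withr::local_tempfile(fileext = ".json")
    write_template(tpl, f)
    back <- read_template(f)
    expect_equal(back$weights, tpl$weights)
    expect_equal(back$means, tpl$means, ignore_attr = TRUE)
    expect_identical(assign_cells(back, probe), assign_cells(tpl, probe))
  }
})

test_that("BIC penalizes parameters per covariance type", {
  sep <- separated_clusters_em(n_per = 400)
  full <- fit_gmm_template(sep$em, K = 3, covariance_type = "full", seed = 1)
  sph <- fit_gmm_template(sep$em, K = 3, covariance_type = "spherical",
                          seed = 1)
  # identical loglik would still give full a larger penalty
  n <- nrow(sep$em$events)
  expect_equal(gmm_bic(full, sep$em),
               -2 * gmm_loglik(full, sep$em) * n +
                 (2 + 6 + 3 * 3) * log(n))
  expect_gt(gmm_bic(sph, sep$em), 0)
})
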
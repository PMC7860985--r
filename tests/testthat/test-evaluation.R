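test_that("tau-b matches the exhaustive oracle, including ties", {
  expect_equal(kendall_tau_b(1:6, (1:6)^2)$tau_b, 1)
  expect_equal(kendall_tau_b(1:6, rev(1:6))$tau_b, -1)
  x <- c(1, 2, 2, 3); y <- c(1, 2, 3, 3)
  expect_equal(kendall_tau_b(x, y)$tau_b, oracle_tau_b(x, y),
               tolerance = 1e-12)
  expect_error(kendall_tau_b(rep(1, 5), 1:5),
               class = "cytofp_undefined_correlation")

  set.seed(6)
  for (i in 1:40) {
    n <- sample(3:30, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(kendall_tau_b(x, y)$tau_b, oracle_tau_b(x, y),
                 tolerance = 1e-12)
  }
})

test_that("tau-b is antisymmetric under negation and p-values are sane", {
  set.seed(7)
  x <- rnorm(15); y <- rnorm(15)
  kt <- kendall_tau_b(x, y)
  expect_equal(kendall_tau_b(x, -y)$tau_b, -kt$tau_b)
  expect_true(kt$p_value > 0 && kt$p_value <= 1)
  # strong signal -> small p under the normal approximation
  expect_lt(kendall_tau_b(1:20, 1:20 + rnorm(20, 0, 0.1))$p_value, 1e-4)
  # n <= 8 uses exact enumeration: known uniform null at n = 3
  p3 <- kendall_tau_b(c(1, 2, 3), c(1, 3, 2))$p_value
  expect_equal(p3, 1)  # |S| = 1 is matched or beaten by every permutation
  # perfect concordance at n = 5: p = 2/5! (both extreme orders)
  expect_equal(kendall_tau_b(1:5, 1:5)$p_value, 2 / 120)
})

test_that("R-squared matches hand evaluation", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(2, 3)), 0)
  expect_equal(r_squared(y, c(3, 2, 1)), -3)
  expect_error(r_squared(rep(1, 3), y), class = "cytofp_undefined_score")
})

test_that("Mantel statistic equals the normalized cross-product identity", {
  set.seed(8)
  m1 <- random_dissim(5); m2 <- random_dissim(5)
  mt <- mantel_test(m1, m2, n_permutations = 99, seed = 1)
  ut <- upper.tri(m1)
  z1 <- scale(m1[ut]); z2 <- scale(m2[ut])
  expect_equal(mt$statistic, sum(z1 * z2) / (sum(ut) - 1),
               tolerance = 1e-12)
  expect_equal(mt$z_m, sum(m1 * m2))

  # self-correlation: statistic 1, minimal p (n large enough that no
  # random permutation reproduces the identity)
  m8 <- random_dissim(9)
  self <- mantel_test(m8, m8, n_permutations = 199, seed = 2)
  expect_equal(self$statistic, 1)
  expect_equal(self$p_value, 1 / 200)
})

test_that("Mantel agrees with the vegan oracle and is relabel-invariant", {
  skip_if_not_installed("vegan")
  set.seed(9)
  n <- 12
  m1 <- random_dissim(n)
  m2 <- 0.6 * m1 + 0.4 * random_dissim(n)
  mt <- mantel_test(m1, m2, n_permutations = 999, seed = 3)
  vg <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = 999)
  expect_equal(mt$statistic, unname(vg$statistic), tolerance = 1e-12)
  expect_lt(abs(mt$p_value - vg$signif), 0.05)

  perm <- sample(n)
  mtp <- mantel_test(m1[perm, perm], m2[perm, perm],
                     n_permutations = 99, seed = 3)
  expect_equal(mtp$statistic, mt$statistic, tolerance = 1e-12)

  expect_error(mantel_test(m1[1:2, 1:2], m2[1:2, 1:2], 99, 1),
               class = "cytofp_invalid_input")
})

test_that("Lorenz curves match hand evaluation and are convex", {
  lc <- lorenz_curve(rep(0.2, 5))
  expect_equal(lc$cum_abundance, lc$cum_units)  # diagonal at evenness

  lc2 <- lorenz_curve(c(0.9, 0.1))
  expect_equal(lc2$cum_units, c(0, 0.5, 1))
  expect_equal(lc2$cum_abundance, c(0, 0.1, 1))

  set.seed(10)
  for (i in 1:20) {
    lc3 <- lorenz_curve(random_simplex(sample(3:15, 1)))
    expect_equal(lc3$cum_units[1], 0)
    expect_equal(tail(lc3$cum_abundance, 1), 1)
    expect_true(all(diff(diff(lc3$cum_abundance)) >= -1e-12))  # convex
  }
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  step_up_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(11)
  p <- runif(10)^2
  expect_equal(p.adjust(p, method = "BH"), step_up_bh(p))
})

test_that("mixture-strain correlation flags matching columns and controls FDR", {
  set.seed(12)
  n <- 30
  truth <- t(replicate(n, random_simplex(4)))
  colnames(truth) <- paste0("strain_", 1:4)
  # mixture 1 equals strain 2 exactly; mixtures 2-3 split the rest
  u <- runif(n)
  fp <- cbind(truth[, 2], (1 - truth[, 2]) * u, (1 - truth[, 2]) * (1 - u))
  colnames(fp) <- paste0("mix_", 1:3)
  rownames(fp) <- rownames(truth) <- paste0("s", 1:n)
  res <- mixture_strain_correlation(count_table(fp), truth, alpha = 0.05)
  expect_true(res$significant["mix_1", "strain_2"])
  expect_gt(res$tau["mix_1", "strain_2"], 0.9)
  expect_equal(dim(res$tau), c(3L, 4L))
  expect_length(res$per_strain_significant, 4L)

  # independent columns: BH keeps the false-discovery proportion low
  set.seed(13)
  fdp <- replicate(30, {
    fpr <- matrix(runif(n * 5), n); fpr <- fpr / rowSums(fpr)
    tr <- matrix(runif(n * 5), n); tr <- tr / rowSums(tr)
    colnames(fpr) <- paste0("m", 1:5); colnames(tr) <- paste0("t", 1:5)
    rownames(fpr) <- rownames(tr) <- paste0("s", 1:n)
    mean(mixture_strain_correlation(count_table(fpr), tr)$significant)
  })
  expect_lte(mean(fdp), 0.05)
})
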
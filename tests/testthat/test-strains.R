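strain_centre <- function(m)
  Reduce(`+`, Map(`*`, m$component_means, m$component_weights))

test_that("strain pools are seeded, validated and overlap-controlled", {
  expect_error(generate_strain_pool(1, 3, 0.5, 1),
               class = "cytofp_parameter_error")
  expect_error(generate_strain_pool(5, 3, 1.5, 1),
               class = "cytofp_parameter_error")

  a <- generate_strain_pool(6, 3, overlap = 0.4, seed = 9)
  b <- generate_strain_pool(6, 3, overlap = 0.4, seed = 9)
  expect_identical(a, b)
  expect_length(a, 6L)
  expect_equal(a[[1]]$channels, c("FSC-H", "SSC-H", "FL1-H"))
  for (m in a) {
    expect_equal(sum(m$component_weights), 1)
    for (S in m$component_covariances)
      expect_true(all(eigen(S, only.values = TRUE)$values > 0))
  }

  # separations: >= 6 pooled SDs at overlap 0, <= 1 at overlap 1,
  # monotone decreasing in between
  centres0 <- t(sapply(generate_strain_pool(3, 3, 0, seed = 2),
                       strain_centre))
  expect_true(all(dist(centres0) >= 6))
  centres1 <- t(sapply(generate_strain_pool(10, 3, 1, seed = 2),
                       strain_centre))
  expect_true(all(dist(centres1) <= 1))
  mean_sep <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(ov)
    mean(dist(t(sapply(generate_strain_pool(10, 3, ov, seed = 2),
                       strain_centre)))), 0)
  expect_true(all(diff(mean_sep) < 0))
})

test_that("a nearest-centre rule separates strains at overlap 0", {
  pool <- generate_strain_pool(3, 3, overlap = 0, seed = 3)
  centres <- t(sapply(pool, strain_centre))
  hits <- 0; total <- 0
  for (i in seq_along(pool)) {
    ev <- sample_strain_events(pool[[i]], 1000, seed = 4)$events
    d2 <- sapply(seq_len(3), function(k)
      rowSums(sweep(ev, 2, centres[k, ])^2))
    hits <- hits + sum(max.col(-d2) == i)
    total <- total + 1000
  }
  expect_gt(hits / total, 0.99)
})

test_that("strain event sampling matches its stated moments", {
  # single-component strain built by hand: CLT check on the mean
  mu <- c(3, 5, 7)
  model <- structure(list(strain_id = "s", component_weights = 1,
                          component_means = list(mu),
                          component_covariances = list(diag(3)),
                          replicate_shift_sd = 0, channels = c("a", "b", "c"),
                          t_tails = FALSE), class = "strain_model")
  em <- sample_strain_events(model, 5000, seed = 5)
  expect_true(all(abs(colMeans(em$events) - mu) < 4 / sqrt(5000)))
  expect_true(em$transformed)

  # replicate jitter: replicate means differ on the order of shift_sd
  model$replicate_shift_sd <- 0.2
  r1 <- colMeans(sample_strain_events(model, 4000, replicate = 1,
                                      seed = 6)$events)
  r2 <- colMeans(sample_strain_events(model, 4000, replicate = 2,
                                      seed = 6)$events)
  expect_gt(max(abs(r1 - r2)), 0.01)
  expect_lt(max(abs(r1 - r2)), 5 * 0.2)

  expect_equal(nrow(sample_strain_events(model, 1, seed = 7)$events), 1L)

  # t-tailed variant produces heavier tails than the Gaussian one
  model$t_tails <- TRUE
  ht <- sample_strain_events(model, 5000, seed = 8)$events[, 1]
  expect_gt(mean(abs(ht - mean(ht)) > 3), 0.005)
})

test_that("strain pools round-trip through JSON", {
  pool <- generate_strain_pool(4, 3, overlap = 0.6, seed = 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_strain_pool(pool, f)
  back <- read_strain_pool(f)
  expect_equal(length(back), 4L)
  # JSON serializes decimal text, so agreement is to near machine
  # precision rather than bit-exact
  for (i in 1:4) {
    expect_equal(back[[i]]$component_means, pool[[i]]$component_means,
                 tolerance = 1e-14)
    expect_equal(back[[i]]$component_covariances,
                 pool[[i]]$component_covariances, tolerance = 1e-14)
    expect_equal(
      sample_strain_events(back[[i]], 50, seed = 1)$events,
      sample_strain_events(pool[[i]], 50, seed = 1)$events,
      tolerance = 1e-9)
  }
})

test_that("overclustering recovers separable strains end to end", {
  # easy regime: overlap 0, K = n_strains -> mixtures ~ strains
  n_strains <- 6
  pool <- generate_strain_pool(n_strains, 3, overlap = 0, seed = 11)
  ems <- lapply(pool, sample_strain_events, n_cells = 1500, seed = 12)
  train <- event_matrix(do.call(rbind, lapply(ems, `[[`, "events")),
                        pool[[1]]$channels, transformed = TRUE)
  truth <- rep(seq_len(n_strains), each = 1500)
  tpl <- fit_gmm_template(train, K = n_strains, seed = 13)
  labels <- assign_cells(tpl, train)
  conf <- table(truth, labels)
  # greedy bipartite matching on the confusion matrix
  matched <- 0
  cf <- as.matrix(conf)
  for (i in seq_len(n_strains)) {
    top <- which(cf == max(cf), arr.ind = TRUE)[1, ]
    matched <- matched + cf[top[1], top[2]]
    cf[top[1], ] <- -1; cf[, top[2]] <- -1
  }
  expect_gt(matched / length(truth), 0.95)
})

test_that("heavy overlap couples mixtures to multiple strains", {
  # seeded scenario: strongly overlapping strains, varying compositions
  n_strains <- 6
  pool <- generate_strain_pool(n_strains, 3, overlap = 0.9, seed = 14)
  ids <- vapply(pool, `[[`, "", "strain_id")
  banks <- lapply(pool, sample_strain_events, n_cells = 3000, seed = 15)
  names(banks) <- ids
  comps <- simulate_compositions(40, ids, a = 1, seed = 16)
  ems <- lapply(seq_len(40), function(i)
    assemble_community(comps$p[i, ], banks, 800, seed = 100 + i,
                       sample_id = rownames(comps$p)[i]))
  set <- experiment_set(ems)
  train <- concatenate_training(set, 200, seed = 17)
  tpl <- fit_gmm_template(train, K = 10, seed = 18)
  fp <- fingerprint_samples(tpl, set, 800, seed = 19)
  res <- mixture_strain_correlation(fp, comps$p, alpha = 0.05)
  expect_true(any(rowSums(res$significant) >= 2))
  # but no mixture correlates with every strain
  expect_true(all(rowSums(res$significant) < n_strains))
})
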
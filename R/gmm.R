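#' Gaussian mixture fingerprint template
#'
#' The fingerprint model is the mixture density
#' `p(x) = sum_k pi_k N(x | mu_k, Sigma_k)` fitted to the concatenated
#' training events by expectation-maximization. For fingerprinting,
#' `K` is deliberately chosen much larger than the number of
#' biological populations ("overclustering"): components tile the
#' event density rather than identify discrete populations, and the
#' per-sample occupancy of the components is the fingerprint.
#'
#' Four covariance parameterizations are supported, mirroring the
#' usual mixture toolboxes:
#' * `full` — each component has its own general covariance (default);
#' * `diag` — each component has its own diagonal covariance;
#' * `spherical` — each component has a single variance;
#' * `tied` — all components share one general covariance.
#'
#' @param train A transformed [event_matrix()] (typically from
#'   [concatenate_training()]).
#' @param K Number of mixture components, `>= 1`.
#' @param covariance_type One of `"full"`, `"diag"`, `"spherical"`,
#'   `"tied"`.
#' @param seed Integer seed controlling initialization.
#' @param tol EM stops when the mean per-event log-likelihood improves
#'   by less than `tol` between iterations.
#' @param max_iter Maximum EM iterations per restart; hitting it
#'   records a non-convergence warning in `fit_log` but still returns
#'   the fit.
#' @param reg_covar Nonnegative ridge added to covariance diagonals;
#'   keeps components non-singular under heavy overclustering.
#' @param n_init Number of k-means-seeded restarts; the restart with
#'   the best final log-likelihood is kept.
#' @return An object of class `gmm_template` with fields `K`,
#'   `weights`, `means` (`K x D`), `covariances`, `covariance_type`,
#'   `channels` and `fit_log` (per-iteration log-likelihoods,
#'   iteration count, convergence flag, seed).
#' @export
fit_gmm_template <- function(train, K, covariance_type = "full",
                             seed = 1L, tol = 1e-3, max_iter = 100L,
                             reg_covar = 1e-6, n_init = 3L) {
  stopifnot(inherits(train, "event_matrix"), K >= 1)
  if (!train$transformed)
    stop_cytofp("cytofp_state_error", "training events must be transformed")
  covariance_type <- match.arg(covariance_type,
                               c("full", "diag", "spherical", "tied"))
  X <- train$events
  if (K > nrow(X))
    stop_cytofp("cytofp_infeasible_k",
                "K = %d exceeds the %d training events", K, nrow(X))
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- em_gmm_once(X, K, covariance_type,
                       seed = child_seed(seed, r - 1L),
                       tol = tol, max_iter = max_iter,
                       reg_covar = reg_covar)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(list(K = as.integer(K),
                 weights = best$weights,
                 means = best$means,
                 covariances = best$covariances,
                 covariance_type = covariance_type,
                 channels = train$channels,
                 fit_log = list(loglik = best$loglik,
                                loglik_trace = best$trace,
                                n_iter = best$n_iter,
                                converged = best$converged,
                                seed = seed)),
            class = "gmm_template")
}

#' @export
print.gmm_template <- function(x, ...) {
  cat(sprintf(
    "<gmm_template> K = %d, %s covariance, channels: %s\n  final loglik/event %.4f after %d iterations%s\n",
    x$K, x$covariance_type, paste(x$channels, collapse = ", "),
    x$fit_log$loglik, x$fit_log$n_iter,
    if (x$fit_log$converged) "" else " (NOT converged)"))
  invisible(x)
}

# One seeded EM run: k-means hard assignment -> M-step -> EM loop.
em_gmm_once <- function(X, K, type, seed, tol, max_iter, reg_covar) {
  n <- nrow(X); d <- ncol(X)
  resp <- with_seed(seed, {
    assign <- tryCatch({
      km <- kmeans(X, centers = min(K, n), iter.max = 30L, nstart = 3L)
      km$cluster
    }, error = function(e) {
      centers <- X[sample.int(n, K), , drop = FALSE]
      max.col(-outer(rowSums(X^2), rep(1, K)) +
                2 * X %*% t(centers) -
                outer(rep(1, n), rowSums(centers^2)),
              ties.method = "first")
    })
    r <- matrix(0, n, K)
    r[cbind(seq_len(n), assign)] <- 1
    r
  })
  params <- m_step(X, resp, type, reg_covar)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    wld <- weighted_log_dens(X, params$weights, params$means,
                             params$covariances, type)
    norm <- logsumexp_rows(wld)
    ll <- mean(norm)
    trace <- c(trace, ll)
    resp <- exp(wld - norm)
    if (is.finite(prev) && abs(ll - prev) < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    prev <- ll
    params <- m_step(X, resp, type, reg_covar)
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations (K = %d)",
                    max_iter, K))
  list(weights = params$weights, means = params$means,
       covariances = params$covariances,
       loglik = trace[length(trace)], trace = trace,
       n_iter = it, converged = converged)
}

m_step <- function(X, resp, type, reg_covar) {
  n <- nrow(X); d <- ncol(X); K <- ncol(resp)
  nk <- colSums(resp) + 10 * .Machine$double.eps
  weights <- nk / sum(nk)
  means <- crossprod(resp, X) / nk
  covariances <- switch(type,
    full = {
      cv <- array(0, dim = c(d, d, K))
      for (k in seq_len(K)) {
        Xc <- sweep(X, 2L, means[k, ])
        s <- crossprod(Xc * resp[, k], Xc) / nk[k]
        diag(s) <- diag(s) + reg_covar
        cv[, , k] <- s
      }
      cv
    },
    tied = {
      # pooled within-component scatter: (X'X - sum_k nk mu_k mu_k') / n
      s <- (crossprod(X) - crossprod(means * nk, means)) / sum(nk)
      diag(s) <- diag(s) + reg_covar
      s
    },
    diag = {
      avg_sq <- crossprod(resp, X^2) / nk
      pmax(avg_sq - means^2, 0) + reg_covar
    },
    spherical = {
      avg_sq <- crossprod(resp, X^2) / nk
      rowMeans(pmax(avg_sq - means^2, 0) + reg_covar)
    })
  list(weights = weights, means = means, covariances = covariances)
}

# N x K matrix of log(pi_k) + log N(x_i | mu_k, Sigma_k)
weighted_log_dens <- function(X, weights, means, covariances, type) {
  n <- nrow(X); d <- ncol(X); K <- length(weights)
  out <- matrix(0, n, K)
  cst <- -0.5 * d * log(2 * pi)
  if (type %in% c("full", "tied")) {
    for (k in seq_len(K)) {
      sigma <- if (type == "full") covariances[, , k] else covariances
      ch <- chol(sigma)
      z <- backsolve(ch, t(X) - means[k, ], transpose = TRUE)
      out[, k] <- cst - sum(log(diag(ch))) - 0.5 * colSums(z^2)
    }
  } else if (type == "diag") {
    for (k in seq_len(K)) {
      v <- covariances[k, ]
      z2 <- sweep(sweep(X, 2L, means[k, ])^2, 2L, v, "/")
      out[, k] <- cst - 0.5 * sum(log(v)) - 0.5 * rowSums(z2)
    }
  } else {  # spherical
    for (k in seq_len(K)) {
      v <- covariances[k]
      z2 <- rowSums(sweep(X, 2L, means[k, ])^2) / v
      out[, k] <- cst - 0.5 * d * log(v) - 0.5 * z2
    }
  }
  sweep(out, 2L, log(weights), "+")
}

#' Mean per-event log-likelihood of events under a template
#'
#' @param template A `gmm_template`.
#' @param em A transformed [event_matrix()] on the template's
#'   channels.
#' @return Mean log density per event.
#' @export
gmm_loglik <- function(template, em) {
  X <- template_events(template, em)
  mean(logsumexp_rows(weighted_log_dens(X, template$weights,
                                        template$means,
                                        template$covariances,
                                        template$covariance_type)))
}

#' Bayesian information criterion of a fitted template
#'
#' Reported for population-identification use-cases where `K` is a
#' model-selection question; fingerprinting itself simply overclusters
#' and does not select `K` by BIC.
#'
#' @inheritParams gmm_loglik
#' @return `-2 * loglik + n_params * log(N)`.
#' @export
gmm_bic <- function(template, em) {
  d <- length(template$channels); K <- template$K
  cov_params <- switch(template$covariance_type,
                       full = K * d * (d + 1) / 2,
                       tied = d * (d + 1) / 2,
                       diag = K * d,
                       spherical = K)
  n_params <- (K - 1) + K * d + cov_params
  n <- nrow(em$events)
  -2 * gmm_loglik(template, em) * n + n_params * log(n)
}

template_events <- function(template, em) {
  stopifnot(inherits(em, "event_matrix"))
  if (!em$transformed)
    stop_cytofp("cytofp_state_error", "events must be transformed")
  if (!identical(em$channels, template$channels)) {
    if (!all(template$channels %in% em$channels))
      stop_cytofp("cytofp_channel_mismatch",
                  "template channels [%s] not all present in sample [%s]",
                  paste(template$channels, collapse = ","),
                  paste(em$channels, collapse = ","))
    em <- select_channels(em, template$channels)
  }
  em$events
}

#' Assign each event to its maximum-posterior component
#'
#' @param template A `gmm_template`.
#' @param em A transformed [event_matrix()].
#' @return Integer vector of component labels in `1..K`; posterior
#'   ties break to the lowest component index.
#' @export
assign_cells <- function(template, em) {
  X <- template_events(template, em)
  wld <- weighted_log_dens(X, template$weights, template$means,
                           template$covariances,
                           template$covariance_type)
  max.col(wld, ties.method = "first")
}

#' Count table: cytometric fingerprints
#'
#' A samples x components matrix of (relative) cell counts — one
#' fingerprint per row.
#'
#' @param counts Numeric matrix; rownames are sample ids, colnames
#'   component ids.
#' @param relative `TRUE` if rows are normalized to sum to one.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, relative = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0))
    stop_cytofp("cytofp_invalid_input", "counts must be nonnegative")
  if (relative) {
    rs <- rowSums(counts)
    if (any(rs == 0))
      stop_cytofp("cytofp_empty_sample",
                  "relative count table has an all-zero row")
    if (any(abs(rs - 1) > 1e-9))
      stop_cytofp("cytofp_invalid_input",
                  "relative count table rows must sum to 1")
  }
  structure(list(counts = counts, relative = relative),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d samples x %d components (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$relative) "relative" else "raw"))
  invisible(x)
}

#' @export
as.matrix.count_table <- function(x, ...) x$counts

#' Fingerprint all samples of an experiment with a mixture template
#'
#' Per sample, every replicate is subsampled to
#' `min(n_cells_rep, smallest replicate)` events and the replicates
#' are pooled; the pooled cells are assigned to components and the
#' per-component counts are row-normalized. All `K` components appear
#' as columns even when empty, so fingerprints from different sample
#' sets stay comparable.
#'
#' @param template A `gmm_template`.
#' @param set An [experiment_set()] of transformed (and gated)
#'   samples.
#' @param n_cells_rep Target events per replicate before pooling.
#' @param seed Integer seed for the subsampling.
#' @return A relative [count_table()], rows in sample order, columns
#'   `mix_001 .. mix_K`.
#' @export
fingerprint_samples <- function(template, set, n_cells_rep, seed = 1L) {
  stopifnot(inherits(template, "gmm_template"),
            inherits(set, "experiment_set"))
  pool <- pool_replicates(set, n_cells_rep, seed)
  K <- template$K
  counts <- t(vapply(pool, function(em) {
    labels <- assign_cells(template, em)
    tabulate(labels, nbins = K)
  }, numeric(K)))
  rownames(counts) <- names(pool)
  colnames(counts) <- sprintf("mix_%03d", seq_len(K))
  count_table(counts / rowSums(counts), relative = TRUE)
}

# subsample each replicate to min(n_cells_rep, smallest replicate) and
# pool per sample
pool_replicates <- function(set, n_cells_rep, seed) {
  out <- vector("list", length(set$samples))
  names(out) <- names(set$samples)
  i <- 0L
  for (sid in names(set$samples)) {
    reps <- set$samples[[sid]]
    n_sub <- min(n_cells_rep, min(vapply(reps, function(e) nrow(e$events), 0L)))
    if (n_sub < 1L)
      stop_cytofp("cytofp_empty_sample", "sample %s has no events", sid)
    parts <- lapply(reps, function(em) {
      i <<- i + 1L
      subsample_events(em, n_sub, seed = child_seed(seed, i - 1L))$events
    })
    out[[sid]] <- event_matrix(do.call(rbind, parts), set$channels,
                               sample_id = sid, replicate_id = "pooled",
                               transformed = TRUE)
  }
  out
}

#' Serialize a fingerprint template to JSON
#'
#' A template fitted once can be reloaded to score new samples —
#' provided the new samples resemble the training conditions, since
#' fingerprints are only meaningful relative to the template's
#' training concatenation.
#'
#' @param template A `gmm_template` or `grid_template`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_template <- function(template, path) {
  if (inherits(template, "gmm_template")) {
    cv <- template$covariances
    payload <- list(kind = "gmm", K = template$K,
                    weights = template$weights,
                    means = as.numeric(template$means),
                    cov_values = as.numeric(cv),
                    cov_dim = if (is.null(dim(cv))) length(cv) else dim(cv),
                    covariance_type = template$covariance_type,
                    channels = template$channels,
                    seed = template$fit_log$seed)
  } else if (inherits(template, "grid_template")) {
    payload <- list(kind = "grid", L = template$L,
                    channel_pairs = template$channel_pairs,
                    edges = template$edges,
                    channels = template$channels)
  } else stop_cytofp("cytofp_invalid_input", "not a template object")
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized fingerprint template
#'
#' @param path JSON file written by [write_template()].
#' @return A `gmm_template` or `grid_template`.
#' @export
read_template <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(p$kind, "gmm")) {
    covs <- as.numeric(p$cov_values)
    if (length(p$cov_dim) > 1L) dim(covs) <- as.integer(p$cov_dim)
    means <- matrix(as.numeric(p$means), nrow = p$K,
                    ncol = length(p$channels))
    structure(list(K = as.integer(p$K), weights = as.numeric(p$weights),
                   means = means, covariances = covs,
                   covariance_type = p$covariance_type,
                   channels = as.character(p$channels),
                   fit_log = list(seed = p$seed)),
              class = "gmm_template")
  } else if (identical(p$kind, "grid")) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    pairs <- lapply(raw$channel_pairs,
                    function(pr) as.character(unlist(pr)))
    edges <- lapply(raw$edges, function(e)
      list(x = as.numeric(unlist(e$x)), y = as.numeric(unlist(e$y))))
    structure(list(L = as.integer(p$L), channel_pairs = pairs,
                   edges = edges,
                   channels = as.character(p$channels)),
              class = "grid_template")
  } else stop_cytofp("cytofp_invalid_input", "unrecognized template file")
}

#' Write a count table to CSV
#'
#' @param ct A [count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(ct, path) {
  stopifnot(inherits(ct, "count_table"))
  df <- data.frame(sample_id = rownames(ct$counts),
                   ct$counts, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
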
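#' Generate a pool of synthetic strain models
#'
#' Stand-in for a panel of individually measured bacterial strains:
#' each strain is a 1-3 component Gaussian mixture in transformed
#' (asinh) channel space — real monocultures are multimodal through
#' cell-size and cell-cycle heterogeneity — with near-unit component
#' covariances and a per-replicate mean jitter emulating technical
#' replicate noise.
#'
#' The single `overlap` knob interpolates between two regimes: at 0,
#' strain means sit >= 6 pooled standard deviations apart
#' (near-separable, atypically easy); at 1, all means fall within one
#' pooled SD — the realistic microbial regime where strain
#' distributions overlap heavily. Mean pairwise separation decreases
#' monotonically in `overlap`.
#'
#' @param n_strains Number of strains, `>= 2`; default 20.
#' @param D Number of channels, `>= 2`; default 3 (named `FSC-H`,
#'   `SSC-H`, `FL1-H`, then `FL2-H`, ...).
#' @param overlap Real in `[0, 1]`.
#' @param seed Integer seed; the pool is a pure function of the
#'   arguments.
#' @param n_components Components per strain are drawn uniformly from
#'   this set; default `1:3`.
#' @param replicate_shift_sd Per-channel SD of the replicate mean
#'   jitter, in transformed units; default 0.05.
#' @param t_tails If `TRUE`, events get Student-t (df = 4) tails
#'   instead of Gaussian ones — a misspecification stress for the
#'   mixture fit.
#' @return A list of `strain_model` objects (fields `strain_id`,
#'   `component_weights`, `component_means`, `component_covariances`,
#'   `replicate_shift_sd`, `channels`, `t_tails`).
#' @export
generate_strain_pool <- function(n_strains = 20L, D = 3L, overlap = 0.5,
                                 seed = 1L, n_components = 1:3,
                                 replicate_shift_sd = 0.05,
                                 t_tails = FALSE) {
  if (n_strains < 2L || D < 2L)
    stop_cytofp("cytofp_parameter_error", "need n_strains >= 2 and D >= 2")
  if (overlap < 0 || overlap > 1)
    stop_cytofp("cytofp_parameter_error", "overlap must lie in [0, 1]")
  channels <- c("FSC-H", "SSC-H",
                sprintf("FL%d-H", seq_len(max(0L, D - 2L))))[seq_len(D)]
  with_seed(seed, {
    base <- maxmin_points(n_strains, D)
    dists <- as.matrix(stats::dist(base))
    r0 <- min(dists[dists > 0])
    R0 <- max(dists)
    # geometric interpolation between the separable and the fully
    # overlapping scale keeps separation monotone in `overlap`
    scale0 <- 8 / r0    # min separation 8 units ~ >6 pooled SDs
    scale1 <- 0.8 / R0  # max separation under 1 pooled SD
    s <- exp((1 - overlap) * log(scale0) + overlap * log(scale1))
    centre <- 5  # mid-range of typical asinh-transformed intensities
    lapply(seq_len(n_strains), function(i) {
      mu_strain <- centre + s * (base[i, ] - 0.5)
      m <- sample(n_components, 1L)
      w <- rgamma(m, shape = 2); w <- w / sum(w)
      # component offsets are centered so the strain's mixture mean is
      # exactly mu_strain: multimodality never shifts strain centres
      offs <- matrix(rnorm(m * D, sd = 0.4), m, D)
      offs <- sweep(offs, 2L, colSums(offs * w))
      means <- lapply(seq_len(m), function(j) mu_strain + offs[j, ])
      covs <- lapply(seq_len(m), function(j) random_spd(D, 0.6, 1.4))
      structure(list(strain_id = sprintf("strain_%02d", i),
                     component_weights = w,
                     component_means = means,
                     component_covariances = covs,
                     replicate_shift_sd = replicate_shift_sd,
                     channels = channels,
                     t_tails = isTRUE(t_tails)),
                class = "strain_model")
    })
  })
}

#' @export
print.strain_model <- function(x, ...) {
  cat(sprintf("<strain_model> %s: %d component(s) in %d channels\n",
              x$strain_id, length(x$component_weights),
              length(x$channels)))
  invisible(x)
}

# greedy max-min design: n points in [0,1]^d spread apart
maxmin_points <- function(n, d, n_candidates = 512L) {
  cand <- matrix(runif(n_candidates * d), n_candidates, d)
  chosen <- integer(n)
  chosen[1L] <- 1L
  mind <- rowSums(sweep(cand, 2L, cand[1L, ])^2)
  for (i in 2:n) {
    chosen[i] <- which.max(mind)
    mind <- pmin(mind, rowSums(sweep(cand, 2L, cand[chosen[i], ])^2))
  }
  cand[chosen, , drop = FALSE]
}

# random SPD matrix with eigenvalues uniform in [lo, hi]
random_spd <- function(d, lo, hi) {
  q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
  q %*% diag(runif(d, lo, hi), d) %*% t(q)
}

#' Draw synthetic events for one strain replicate
#'
#' Events come from the strain's Gaussian mixture with a
#' replicate-specific mean shift (`N(0, replicate_shift_sd^2)` per
#' channel, deterministic in `(seed, replicate)`), in transformed
#' coordinates — negative values are possible and legitimate there.
#'
#' @param model A `strain_model`.
#' @param n_cells Number of events, `>= 1`.
#' @param replicate Technical replicate number; different replicates
#'   of the same seed get different mean shifts.
#' @param seed Integer seed.
#' @return A transformed [event_matrix()] with
#'   `sample_id = strain_id` and `replicate_id = replicate`.
#' @export
sample_strain_events <- function(model, n_cells, replicate = 1L,
                                 seed = 1L) {
  stopifnot(inherits(model, "strain_model"), n_cells >= 1)
  D <- length(model$channels)
  events <- with_seed(child_seed(seed, replicate), {
    shift <- rnorm(D, sd = model$replicate_shift_sd)
    m <- length(model$component_weights)
    n_per <- as.integer(stats::rmultinom(1L, n_cells,
                                         model$component_weights))
    rows <- do.call(rbind, lapply(seq_len(m), function(j) {
      if (n_per[j] == 0L) return(NULL)
      z <- matrix(rnorm(n_per[j] * D), n_per[j], D)
      if (model$t_tails) {
        g <- rgamma(n_per[j], shape = 2, rate = 2)  # chi2_4 / 4
        z <- z / sqrt(g)
      }
      sweep(z %*% chol(model$component_covariances[[j]]), 2L,
            model$component_means[[j]] + shift, "+")
    }))
    rows[sample.int(nrow(rows)), , drop = FALSE]  # shuffle component order
  })
  event_matrix(events, model$channels, sample_id = model$strain_id,
               replicate_id = as.character(replicate), transformed = TRUE)
}

#' Serialize a strain pool to JSON
#'
#' @param pool List of `strain_model` objects.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_strain_pool <- function(pool, path) {
  payload <- lapply(pool, function(m) {
    list(strain_id = m$strain_id,
         component_weights = m$component_weights,
         component_means = m$component_means,
         component_covariances = lapply(m$component_covariances,
                                        as.numeric),
         D = length(m$channels),
         replicate_shift_sd = m$replicate_shift_sd,
         channels = m$channels,
         t_tails = m$t_tails)
  })
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a strain pool written by [write_strain_pool()]
#'
#' @param path JSON file.
#' @return A list of `strain_model` objects.
#' @export
read_strain_pool <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(m) {
    D <- m$D
    structure(list(strain_id = m$strain_id,
                   component_weights = as.numeric(unlist(m$component_weights)),
                   component_means = lapply(m$component_means,
                                            function(v) as.numeric(unlist(v))),
                   component_covariances = lapply(m$component_covariances,
                     function(v) matrix(as.numeric(unlist(v)), D, D)),
                   replicate_shift_sd = m$replicate_shift_sd,
                   channels = as.character(unlist(m$channels)),
                   t_tails = isTRUE(m$t_tails)),
              class = "strain_model")
  })
}
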
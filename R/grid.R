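#' Build a fixed bivariate binning template
#'
#' The classic fingerprinting comparator: for every unordered pair of
#' channels, an `L x L` grid of equal-width bins spanning the training
#' data's `[min, max]` per channel. With `D` channels this gives
#' `choose(D, 2)` pairs and `choose(D, 2) * L^2` fingerprint columns
#' (for `D = 3`, `L = 128`: 49,152), versus `K` columns for the
#' mixture template.
#'
#' @param train A transformed [event_matrix()] with `D >= 2` channels.
#' @param L Bins per axis, default 128.
#' @return An object of class `grid_template` with `channel_pairs`,
#'   `L`, `edges` (per pair, `L + 1` edges on each axis) and
#'   `channels`.
#' @export
build_grid_template <- function(train, L = 128L) {
  stopifnot(inherits(train, "event_matrix"), L >= 2)
  if (!train$transformed)
    stop_cytofp("cytofp_state_error", "training events must be transformed")
  ch <- train$channels
  if (length(ch) < 2L)
    stop_cytofp("cytofp_invalid_input", "grid fingerprints need D >= 2")
  rng <- apply(train$events, 2L, range)
  for (j in seq_along(ch))
    if (rng[1L, j] == rng[2L, j])
      stop_cytofp("cytofp_degenerate_channel",
                  "channel %s is constant in the training data", ch[j])
  pairs <- combn(ch, 2L, simplify = FALSE)
  edges <- lapply(pairs, function(pr) {
    list(x = seq(rng[1L, pr[1L]], rng[2L, pr[1L]], length.out = L + 1L),
         y = seq(rng[1L, pr[2L]], rng[2L, pr[2L]], length.out = L + 1L))
  })
  structure(list(channel_pairs = pairs, L = as.integer(L),
                 edges = edges, channels = ch),
            class = "grid_template")
}

#' @export
print.grid_template <- function(x, ...) {
  cat(sprintf("<grid_template> %d channel pairs x %d^2 bins (%d columns)\n",
              length(x$channel_pairs), x$L,
              length(x$channel_pairs) * x$L^2))
  invisible(x)
}

# 2-D histogram counts on fixed edges; bins are [e_i, e_{i+1}) with
# the last bin closed; out-of-range events are clipped into the
# terminal bins so test-set rows keep their full mass.
hist2d_counts <- function(x, y, ex, ey) {
  L <- length(ex) - 1L
  ix <- pmin(pmax(findInterval(x, ex, left.open = FALSE), 1L), L)
  iy <- pmin(pmax(findInterval(y, ey, left.open = FALSE), 1L), L)
  # findInterval puts v == ex[i+1] into bin i+1 (half-open left-closed
  # convention); the pmin above closes the final bin.
  tabulate((iy - 1L) * L + ix, nbins = L * L)
}

#' Grid fingerprints for all samples of an experiment
#'
#' Per sample (replicates subsampled and pooled as in
#' [fingerprint_samples()]): a 2-D histogram on the template edges for
#' every channel pair; the pair histograms are flattened, concatenated
#' and the whole vector divided by its total, so each row sums to 1.
#'
#' @param template A `grid_template`.
#' @param set An [experiment_set()] of transformed samples.
#' @param n_cells_rep Target events per replicate before pooling.
#' @param seed Integer seed for the subsampling.
#' @return A relative [count_table()] with
#'   `length(channel_pairs) * L^2` columns.
#' @export
grid_fingerprint_samples <- function(template, set, n_cells_rep,
                                     seed = 1L) {
  stopifnot(inherits(template, "grid_template"),
            inherits(set, "experiment_set"))
  missing <- setdiff(template$channels, set$channels)
  if (length(missing))
    stop_cytofp("cytofp_channel_mismatch",
                "template channel(s) %s absent from samples",
                paste(missing, collapse = ", "))
  pool <- pool_replicates(set, n_cells_rep, seed)
  L <- template$L
  n_pairs <- length(template$channel_pairs)
  counts <- t(vapply(pool, function(em) {
    unlist(lapply(seq_len(n_pairs), function(i) {
      pr <- template$channel_pairs[[i]]
      e <- template$edges[[i]]
      hist2d_counts(em$events[, pr[1L]], em$events[, pr[2L]], e$x, e$y)
    }), use.names = FALSE)
  }, numeric(n_pairs * L * L)))
  rownames(counts) <- names(pool)
  colnames(counts) <- unlist(lapply(seq_len(n_pairs), function(i) {
    pr <- template$channel_pairs[[i]]
    sprintf("%s:%s_bin%05d", pr[1L], pr[2L], seq_len(L * L))
  }), use.names = FALSE)
  count_table(counts / rowSums(counts), relative = TRUE)
}
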
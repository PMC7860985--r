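#' Composition table: true community compositions
#'
#' Ground-truth relative strain abundances for simulated communities;
#' the simulator's output and the reference for all benchmark
#' correlations.
#'
#' @param p Communities x strains matrix of relative abundances; rows
#'   sum to 1, rownames are community ids, colnames strain ids.
#' @param a Dirichlet concentration parameter used to draw the rows.
#' @param split Optional character vector (`"train"`/`"test"`) per
#'   community.
#' @return An object of class `composition_table`.
#' @export
composition_table <- function(p, a = NA_real_, split = NULL) {
  p <- as.matrix(p)
  if (any(p < 0))
    stop_cytofp("cytofp_invalid_input", "abundances must be nonnegative")
  if (any(abs(rowSums(p) - 1) > 1e-9))
    stop_cytofp("cytofp_invalid_input", "composition rows must sum to 1")
  structure(list(p = p, a = a, split = split),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("<composition_table> %d communities x %d strains (a = %s)\n",
              nrow(x$p), ncol(x$p), format(x$a)))
  invisible(x)
}

#' Simulate community compositions from a Dirichlet distribution
#'
#' Per community: the number of members `S'` is drawn uniformly from
#' `{s_min, ..., s_max}`, that many strains are drawn without
#' replacement from the pool, and their abundances from a symmetric
#' Dirichlet with concentration `a`. Small `a` yields dominance by a
#' few strains (low evenness), large `a` near-equal abundances.
#'
#' @param n_communities Number of communities to draw.
#' @param strain_pool Character vector of available strain ids.
#' @param a Positive Dirichlet concentration parameter.
#' @param s_min,s_max Bounds on community size; `2 <= s_min <= s_max
#'   <= length(strain_pool)`. Defaults 2 and the full pool.
#' @param seed Integer seed.
#' @param prefix Community id prefix, default `"comm"`.
#' @return A [composition_table()].
#' @export
simulate_compositions <- function(n_communities, strain_pool, a,
                                  s_min = 2L, s_max = length(strain_pool),
                                  seed = 1L, prefix = "comm") {
  if (a <= 0)
    stop_cytofp("cytofp_parameter_error", "a must be positive")
  if (s_min < 2L || s_min > s_max || s_max > length(strain_pool))
    stop_cytofp("cytofp_parameter_error",
                "need 2 <= s_min <= s_max <= pool size (%d)",
                length(strain_pool))
  S <- length(strain_pool)
  p <- with_seed(seed, {
    t(vapply(seq_len(n_communities), function(i) {
      s_i <- s_min + sample.int(s_max - s_min + 1L, 1L) - 1L
      members <- sample.int(S, s_i, replace = FALSE)
      g <- rgamma(s_i, shape = a, rate = 1)
      # rgamma can underflow to all-zero for tiny a; redraw the rare case
      while (sum(g) == 0) g <- rgamma(s_i, shape = a, rate = 1)
      row <- numeric(S)
      row[members] <- g / sum(g)
      row
    }, numeric(S)))
  })
  dimnames(p) <- list(sprintf("%s_%03d", prefix, seq_len(n_communities)),
                      strain_pool)
  composition_table(p, a = a)
}

# largest-remainder apportionment of total among fractions p;
# remainder ties break to the lowest index
apportion_counts <- function(p, total) {
  exact <- p * total
  base <- floor(exact)
  short <- total - sum(base)
  if (short > 0) {
    rem <- exact - base
    give <- order(-rem, seq_along(p))[seq_len(short)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Assemble an in-silico community from per-strain event data
#'
#' Aggregates individually measured (or simulated) strain events
#' according to a target composition: strain `i` contributes its
#' largest-remainder share of `total_cells`, subsampled without
#' replacement from that strain's events. The output has exactly
#' `total_cells` rows; per-row strain provenance is kept in
#' `attr(, "strain")`.
#'
#' @param comp_row Named numeric vector of relative abundances (one
#'   composition-table row).
#' @param strain_events Named list mapping strain id to an
#'   [event_matrix()] of that strain's cells.
#' @param total_cells Number of cells in the assembled community.
#' @param seed Integer seed for the per-strain subsampling.
#' @param sample_id Sample id of the result.
#' @return An [event_matrix()].
#' @export
assemble_community <- function(comp_row, strain_events, total_cells,
                               seed = 1L, sample_id = "community") {
  used <- names(comp_row)[comp_row > 0]
  missing <- setdiff(used, names(strain_events))
  if (length(missing))
    stop_cytofp("cytofp_insufficient_events",
                "no event data for strain(s) %s",
                paste(missing, collapse = ", "))
  counts <- apportion_counts(as.numeric(comp_row), total_cells)
  names(counts) <- names(comp_row)
  parts <- list(); strain_of <- list()
  i <- 0L
  for (sid in names(comp_row)) {
    if (counts[[sid]] == 0L) next
    i <- i + 1L
    em <- strain_events[[sid]]
    if (nrow(em$events) < counts[[sid]])
      stop_cytofp("cytofp_insufficient_events",
                  "strain %s has %d events, %d needed",
                  sid, nrow(em$events), counts[[sid]])
    sub <- subsample_events(em, counts[[sid]],
                            seed = child_seed(seed, i - 1L))
    parts[[sid]] <- sub$events
    strain_of[[sid]] <- rep(sid, counts[[sid]])
  }
  first <- strain_events[[used[1L]]]
  out <- event_matrix(do.call(rbind, parts), first$channels,
                      sample_id = sample_id, replicate_id = "1",
                      transformed = first$transformed)
  attr(out, "strain") <- unlist(strain_of, use.names = FALSE)
  out
}

#' True Hill diversities of simulated compositions
#'
#' @param ct A [composition_table()].
#' @param qs Hill orders, default `c(0, 1, 2)`.
#' @return A data frame `sample_id`, `q`, `value` (same layout as
#'   [diversity_table()]).
#' @export
true_diversity <- function(ct, qs = c(0, 1, 2)) {
  stopifnot(inherits(ct, "composition_table"))
  diversity_table(count_table(ct$p, relative = TRUE), qs)
}

#' Write a composition table to CSV
#'
#' @param ct A [composition_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compositions <- function(ct, path) {
  df <- data.frame(community_id = rownames(ct$p), ct$p,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
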
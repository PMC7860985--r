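#' Hill number of a relative-abundance vector
#'
#' Hill numbers `D_q` express diversity as an effective number of
#' units; the order `q` sets how much abundant units are favoured:
#' * `q = 0` — richness: the count of units with positive abundance;
#' * `q = 1` — exponential Shannon entropy,
#'   `exp(-sum(p_i * log(p_i)))` (with `0 * log 0 := 0`);
#' * `q = 2` — inverse Simpson index, `1 / sum(p_i^2)`.
#'
#' Other orders are available through the general power-mean form
#' `(sum(p_i^q))^(1 / (1 - q))` for `q >= 0`, `q != 1`.
#'
#' @param p Nonnegative relative abundances summing to 1 (within
#'   1e-9), over strains, OTUs, mixtures or bins alike.
#' @param q Order of the Hill number.
#' @return The diversity `D_q`, a real `>= 1`.
#' @export
hill_number <- function(p, q) {
  p <- as.numeric(p)
  if (any(p < 0) || !all(is.finite(p)))
    stop_cytofp("cytofp_invalid_input", "abundances must be finite and >= 0")
  s <- sum(p)
  if (s == 0)
    stop_cytofp("cytofp_undefined_diversity",
                "diversity of an all-zero composition is undefined")
  if (abs(s - 1) > 1e-9) p <- p / s
  pos <- p[p > 0]
  if (q == 0) length(pos)
  else if (q == 1) exp(-sum(pos * log(pos)))
  else sum(pos^q)^(1 / (1 - q))
}

#' Bray-Curtis dissimilarity between two compositions
#'
#' `BC_AB = sum |p_A,i - p_B,i| / sum (p_A,i + p_B,i)`; for unit-sum
#' inputs the denominator is 2. Bounded in `[0, 1]`, symmetric, zero
#' iff equal — but not a metric (no triangle inequality).
#'
#' @param a,b Nonnegative abundance vectors over the same units in the
#'   same order. Names, when present on both, must agree.
#' @return The dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b))
    stop_cytofp("cytofp_alignment_error",
                "compositions have %d vs %d units", length(a), length(b))
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b)))
    stop_cytofp("cytofp_alignment_error", "unit labels disagree")
  sum(abs(a - b)) / sum(a + b)
}

#' Per-sample Hill diversities of a count table
#'
#' @param ct A relative [count_table()].
#' @param qs Orders to evaluate, default `c(0, 1, 2)`.
#' @return A data frame with columns `sample_id`, `q`, `value`.
#' @export
diversity_table <- function(ct, qs = c(0, 1, 2)) {
  stopifnot(inherits(ct, "count_table"))
  if (!ct$relative)
    stop_cytofp("cytofp_invalid_input", "count table must be relative")
  ids <- rownames(ct$counts)
  out <- expand.grid(sample_id = ids, q = qs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$value <- mapply(function(sid, q) hill_number(ct$counts[sid, ], q),
                      out$sample_id, out$q)
  out[order(match(out$sample_id, ids), out$q), , drop = FALSE]
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' @param ct A relative [count_table()] with `n >= 2` samples.
#' @return An object of class `dissimilarity_matrix`: a symmetric
#'   `n x n` matrix with zero diagonal and the sample ids as dimnames.
#' @export
dissimilarity_matrix <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  m <- ct$counts
  n <- nrow(m)
  if (n < 2L)
    stop_cytofp("cytofp_invalid_input", "need >= 2 samples")
  # |a - b| summed pairwise, vectorized one row against all later rows
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    num <- rowSums(abs(m[rest, , drop = FALSE] -
                         rep(m[i, ], each = length(rest))))
    den <- rowSums(m[rest, , drop = FALSE] +
                     rep(m[i, ], each = length(rest)))
    d[i, rest] <- num / den
    d[rest, i] <- d[i, rest]
  }
  structure(d, class = c("dissimilarity_matrix", "matrix", "array"))
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("<dissimilarity_matrix> %d x %d (Bray-Curtis)\n",
              nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(5L, ncol(x)))])
  invisible(x)
}

#' Write a dissimilarity matrix to CSV
#'
#' @param dm A [dissimilarity_matrix()].
#' @param path Output path; sample ids are written as header row and
#'   first column.
#' @return `path`, invisibly.
#' @export
write_dissimilarity <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), unclass(dm),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
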
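#' Tie-aware Kendall rank correlation (tau-b)
#'
#' `tau_B = (N_c - N_d) / sqrt((N_c + N_d + N_t) (N_c + N_d + N_u))`
#' over all `choose(n, 2)` pairs, where `N_c`/`N_d` are concordant and
#' discordant pairs, `N_t` pairs tied in `x` only and `N_u` pairs tied
#' in `y` only; pairs tied in both vectors count in neither.
#'
#' The two-sided p-value uses exact permutation enumeration for
#' `n <= 8` and otherwise the normal approximation with the standard
#' tie-corrected variance of `N_c - N_d`.
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @return A list of class `kendall_result`: `tau_b`, `p_value`, `n`.
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  n <- length(x)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  ut <- upper.tri(sx)
  prod_ut <- (sx * sy)[ut]
  s <- sum(prod_ut)                        # N_c - N_d
  tied_x <- sx[ut] == 0
  tied_y <- sy[ut] == 0
  nc_nd <- sum(!tied_x & !tied_y)          # N_c + N_d
  nt <- sum(tied_x & !tied_y)
  nu <- sum(tied_y & !tied_x)
  den <- sqrt((nc_nd + nt) * (nc_nd + nu))
  if (den == 0)
    stop_cytofp("cytofp_undefined_correlation",
                "tau_b undefined: one vector is fully tied")
  tau <- s / den

  if (n <= 8L) {
    perms <- all_perms(n)
    s_perm <- apply(perms, 1L, function(pm) sum((sx * sy[pm, pm])[ut]))
    # denominator is permutation-invariant (tie multisets fixed)
    p <- mean(abs(s_perm) >= abs(s) - 1e-12)
  } else {
    xt <- table(x); yt <- table(y)
    t1 <- sum(xt * (xt - 1)); u1 <- sum(yt * (yt - 1))
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(xt * (xt - 1) * (2 * xt + 5))
    vu <- sum(yt * (yt - 1) * (2 * yt + 5))
    v1 <- t1 * u1 / (2 * n * (n - 1))
    v2 <- sum(xt * (xt - 1) * (xt - 2)) * sum(yt * (yt - 1) * (yt - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- s / sqrt(var_s)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(tau_b = tau, p_value = min(max(p, 0), 1), n = n),
            class = "kendall_result")
}

#' @export
print.kendall_result <- function(x, ...) {
  cat(sprintf("Kendall tau_b = %.4f (n = %d, two-sided p = %.4g)\n",
              x$tau_b, x$n, x$p_value))
  invisible(x)
}

# all n! permutations of 1..n as an n! x n matrix (n <= 8)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; 1 for perfect
#' prediction, 0 for the mean predictor, negative when predictions are
#' worse than guessing the mean.
#'
#' @param y_true,y_pred Numeric vectors of equal length `>= 2`.
#' @return The R-squared value.
#' @export
r_squared <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0)
    stop_cytofp("cytofp_undefined_score",
                "R^2 undefined for constant y_true")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Mantel permutation test between two dissimilarity matrices
#'
#' The statistic is the Pearson correlation between the off-diagonal
#' entries of the two matrices — the normalized form of the raw
#' cross-product `Z_M = sum_ij m1_ij * m2_ij`, which is also reported.
#' The null distribution jointly permutes the rows and columns of the
#' second matrix; the test is one-sided against positive association,
#' `p = (#[Z_perm >= Z_obs] + 1) / (n_permutations + 1)`.
#'
#' @param m1,m2 Symmetric dissimilarity matrices over the same samples
#'   in the same order (dimnames are checked when present on both).
#' @param n_permutations Number of permutations, default 1000.
#' @param seed Integer seed for the permutation draws.
#' @return A list of class `mantel_result`: `statistic`, `p_value`,
#'   `z_m` (raw cross-product), `n_permutations`, `n`.
#' @export
mantel_test <- function(m1, m2, n_permutations = 1000L, seed = 1L) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  n <- nrow(m1)
  if (!all(dim(m1) == n) || !all(dim(m2) == n))
    stop_cytofp("cytofp_alignment_error", "matrices must be square and equal-sized")
  if (n < 3L)
    stop_cytofp("cytofp_invalid_input", "Mantel test needs n >= 3")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop_cytofp("cytofp_alignment_error", "sample ids disagree")
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  if (sd(v1) == 0 || sd(m2[ut]) == 0)
    stop_cytofp("cytofp_undefined_correlation",
                "constant off-diagonal entries")
  obs <- cor(v1, m2[ut])
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(n)
      cor(v1, m2[idx, idx][ut])
    }, 0)
  })
  p <- (sum(perm_stats >= obs) + 1) / (n_permutations + 1)
  structure(list(statistic = obs, p_value = p,
                 z_m = sum(m1 * m2),
                 n_permutations = as.integer(n_permutations), n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f (n = %d, %d permutations, one-sided p = %.4g)\n",
              x$statistic, x$n, x$n_permutations, x$p_value))
  invisible(x)
}

#' Lorenz curve of a composition
#'
#' Cumulative abundance against cumulative fraction of units, units
#' sorted by increasing abundance: the diagonal means perfect
#' evenness, a sagging curve means dominance by few units.
#'
#' @param p Nonnegative abundance vector.
#' @return A data frame with columns `cum_units` and `cum_abundance`,
#'   starting at `(0, 0)` and ending at `(1, 1)`; the curve is convex.
#' @export
lorenz_curve <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0) || sum(p) == 0)
    stop_cytofp("cytofp_invalid_input", "need a nonnegative, nonzero vector")
  srt <- sort(p)
  data.frame(cum_units = seq(0, length(p)) / length(p),
             cum_abundance = c(0, cumsum(srt)) / sum(srt))
}

#' Correlate mixture occupancies with strain abundances
#'
#' For every (mixture column, strain column) pair, the Kendall tau-b
#' between the relative cell counts and the true relative abundances
#' across samples, with Benjamini-Hochberg adjustment over the whole
#' mixture x strain family. Because strain signals overlap in channel
#' space, a mixture typically tracks several strains and vice versa.
#'
#' @param fingerprints A relative [count_table()].
#' @param truth A [composition_table()] (or plain matrix,
#'   samples x strains) of true relative abundances, same samples in
#'   the same order.
#' @param alpha Adjusted-p significance level, default 0.05.
#' @return A list: `tau` and `p_adjusted` (mixtures x strains
#'   matrices; constant columns give `NA` and are excluded from the
#'   adjustment family), `significant` (logical matrix,
#'   `p_adjusted <= alpha`), `per_strain_significant` (counts).
#' @export
mixture_strain_correlation <- function(fingerprints, truth,
                                       alpha = 0.05) {
  stopifnot(inherits(fingerprints, "count_table"))
  fp <- fingerprints$counts
  tm <- if (inherits(truth, "composition_table")) truth$p else as.matrix(truth)
  if (nrow(fp) != nrow(tm))
    stop_cytofp("cytofp_alignment_error",
                "%d fingerprint rows vs %d truth rows", nrow(fp), nrow(tm))
  K <- ncol(fp); S <- ncol(tm)
  tau <- p_raw <- matrix(NA_real_, K, S,
                         dimnames = list(colnames(fp), colnames(tm)))
  for (k in seq_len(K)) {
    if (length(unique(fp[, k])) == 1L) next
    for (s in seq_len(S)) {
      if (length(unique(tm[, s])) == 1L) next
      kt <- kendall_tau_b(fp[, k], tm[, s])
      tau[k, s] <- kt$tau_b
      p_raw[k, s] <- kt$p_value
    }
  }
  ok <- !is.na(p_raw)
  p_adj <- p_raw
  p_adj[ok] <- p.adjust(p_raw[ok], method = "BH")
  sig <- !is.na(p_adj) & p_adj <= alpha
  list(tau = tau, p_adjusted = p_adj, significant = sig,
       per_strain_significant = colSums(sig))
}
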
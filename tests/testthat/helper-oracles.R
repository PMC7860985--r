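# Independent oracles frozen for the tests: literal textbook
# evaluations, kept free of package internals.

# exhaustive pair-count evaluation of tau-b: pairs tied in both
# vectors count in neither tie term
oracle_tau_b <- function(x, y) {
  n <- length(x)
  nc <- nd <- nt <- nu <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) next
    else if (dx == 0) nt <- nt + 1
    else if (dy == 0) nu <- nu + 1
    else if (sign(dx) == sign(dy)) nc <- nc + 1
    else nd <- nd + 1
  }
  (nc - nd) / sqrt((nc + nd + nt) * (nc + nd + nu))
}

# random symmetric dissimilarity-like matrix with zero diagonal
random_dissim <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m + t(m)
}
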
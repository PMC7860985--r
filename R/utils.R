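#' Derive a child seed from an experiment-level seed
#'
#' All randomness in a multi-stage run flows from one experiment-level
#' seed; each stage receives a deterministic child seed so that stages
#' can be re-run or reordered without perturbing each other's random
#' streams.
#'
#' @param seed Integer experiment-level seed.
#' @param index Integer stage index (>= 0); distinct indices give
#'   distinct child seeds.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), length(index) == 1L)
  m <- 2147483647  # 2^31 - 1, Lehmer modulus keeps seeds in int range
  s <- (as.double(seed) %% m) + 1
  for (i in seq_len(as.integer(index) + 1L)) {
    s <- (s * 48271) %% m
  }
  as.integer(if (s < 1) 1 else s)
}

# log(sum(exp(x))) along rows of a matrix, guarded against underflow
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cytofp <- function(class, msg, ...) {
  stop(structure(class = c(class, "cytofp_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
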
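# Small in-code fixtures shared across test files.

# random event matrix
make_em <- function(n = 100, channels = c("FSC-H", "SSC-H", "FL1-H"),
                    seed = 1, transformed = TRUE, sample_id = "s1",
                    replicate_id = "1") {
  set.seed(seed)
  m <- matrix(abs(rnorm(n * length(channels), mean = 4)), nrow = n)
  event_matrix(m, channels, sample_id, replicate_id, transformed)
}

# three well-separated unit-variance clusters in 2-D
separated_clusters_em <- function(n_per = 3000, seed = 42) {
  set.seed(seed)
  true_means <- rbind(c(0, 0), c(8, 0), c(0, 8))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(2 * n_per), ncol = 2), 2, true_means[k, ], "+")))
  list(em = event_matrix(X, c("FSC-H", "FL1-H"), transformed = TRUE),
       means = true_means)
}

# write a minimal FCS 3.0 file byte-by-byte (the test oracle for the
# in-package reader): list mode, given datatype and endianness
write_tiny_fcs <- function(path, data, channels, datatype = "F",
                           endian = "little") {
  n <- nrow(data); p <- ncol(data)
  byteord <- if (endian == "little") "1,2,3,4" else "4,3,2,1"
  bits <- switch(datatype, F = 32L, D = 64L, I = 16L)
  kw <- c("$MODE", "L", "$PAR", p, "$TOT", n,
          "$DATATYPE", datatype, "$BYTEORD", byteord)
  for (i in seq_len(p))
    kw <- c(kw, sprintf("$P%dN", i), channels[i], sprintf("$P%dB", i), bits)
  text <- paste0("|", paste(kw, collapse = "|"), "|")
  text_start <- 100L
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + n * p * (bits / 8L) - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeBin(raw(text_start - nchar(header)), con)
  writeChar(text, con, eos = NULL)
  values <- as.numeric(t(data))  # event-major
  if (datatype == "I") {
    writeBin(as.integer(values), con, size = 2L, endian = endian)
  } else {
    writeBin(values, con, size = bits / 8L, endian = endian)
  }
  invisible(path)
}

# write an experiment of CSV event files plus manifest; returns the
# manifest path
write_tiny_experiment <- function(dir, n_samples = 3, n_reps = 1,
                                  n_cells = 300, seed = 7) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  k <- 0
  for (s in seq_len(n_samples)) {
    for (r in seq_len(n_reps)) {
      k <- k + 1
      em <- make_em(n_cells, seed = seed + k, transformed = FALSE,
                    sample_id = sprintf("s%d", s),
                    replicate_id = as.character(r))
      f <- sprintf("s%d_r%d.csv", s, r)
      write_events_csv(em, file.path(dir, f))
      rows[[k]] <- data.frame(path = f, sample_id = sprintf("s%d", s),
                              replicate_id = as.character(r))
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  manifest
}

# random unit-sum composition
random_simplex <- function(s) {
  g <- rgamma(s, shape = 1)
  g / sum(g)
}
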
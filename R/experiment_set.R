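#' Experiment set: samples with technical replicates
#'
#' Groups a list of [event_matrix()] objects by `sample_id`. Replicates
#' of one sample are kept separate until fingerprinting, where they are
#' subsampled per file and then pooled.
#'
#' @param ems List of [event_matrix()] objects sharing one channel
#'   list.
#' @param metadata Optional data frame keyed by `sample_id`.
#' @return An object of class `experiment_set` with elements `samples`
#'   (named list: sample_id -> list of replicates), `channels` and
#'   `metadata`.
#' @export
experiment_set <- function(ems, metadata = NULL) {
  stopifnot(length(ems) >= 1L)
  ch <- ems[[1L]]$channels
  for (em in ems) {
    stopifnot(inherits(em, "event_matrix"))
    if (!identical(em$channels, ch))
      stop_cytofp("cytofp_channel_mismatch",
                  "channel lists differ across files: [%s] vs [%s]",
                  paste(ch, collapse = ","),
                  paste(em$channels, collapse = ","))
  }
  ids <- vapply(ems, function(e) e$sample_id, "")
  samples <- split(ems, factor(ids, levels = unique(ids)))
  structure(list(samples = samples, channels = ch, metadata = metadata),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  nrep <- vapply(x$samples, length, 0L)
  cat(sprintf("<experiment_set> %d samples (%d files), channels: %s\n",
              length(x$samples), sum(nrep),
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' @export
length.experiment_set <- function(x) length(x$samples)

#' Read an experiment set from a manifest file
#'
#' The manifest is a CSV with columns `path`, `sample_id`,
#' `replicate_id`. Relative paths are resolved against the manifest's
#' directory.
#'
#' @param manifest Path to the manifest CSV.
#' @param channel_subset Channels to retain (passed to
#'   [read_events()]).
#' @param format Forwarded to [read_events()].
#' @return An [experiment_set()].
#' @export
read_experiment <- function(manifest, channel_subset = NULL, format = NULL) {
  if (!file.exists(manifest))
    stop_cytofp("cytofp_missing_file", "manifest not found: %s", manifest)
  mf <- read.csv(manifest, stringsAsFactors = FALSE)
  for (col in c("path", "sample_id", "replicate_id"))
    if (!col %in% names(mf))
      stop_cytofp("cytofp_invalid_input", "manifest lacks column '%s'", col)
  base <- dirname(manifest)
  ems <- lapply(seq_len(nrow(mf)), function(i) {
    p <- mf$path[i]
    if (!file.exists(p)) p <- file.path(base, mf$path[i])
    read_events(p, channel_subset, format,
                sample_id = as.character(mf$sample_id[i]),
                replicate_id = as.character(mf$replicate_id[i]))
  })
  experiment_set(ems, metadata = mf)
}

#' Build the template-training concatenation
#'
#' Each file is subsampled to `n_cells_min` events and all files are
#' stacked into one event matrix, so every sample contributes equally
#' to the fingerprint template. With `n` samples of `N_REP` replicates
#' each, the result has `n * N_REP * n_cells_min` rows.
#'
#' @param set An [experiment_set()].
#' @param n_cells_min Events drawn per file.
#' @param seed Integer seed; per-file child seeds are derived from it.
#' @param short_policy Passed to [subsample_events()].
#' @return An [event_matrix()] whose per-row provenance is kept in
#'   `attr(, "provenance")` (sample_id, replicate_id per row).
#' @export
concatenate_training <- function(set, n_cells_min, seed,
                                 short_policy = c("error", "take_all")) {
  stopifnot(inherits(set, "experiment_set"))
  short_policy <- match.arg(short_policy)
  files <- unlist(set$samples, recursive = FALSE, use.names = FALSE)
  parts <- vector("list", length(files))
  prov <- vector("list", length(files))
  for (i in seq_along(files)) {
    sub <- subsample_events(files[[i]], n_cells_min,
                            seed = child_seed(seed, i - 1L),
                            short_policy = short_policy)
    parts[[i]] <- sub$events
    prov[[i]] <- data.frame(sample_id = rep(sub$sample_id, nrow(sub$events)),
                            replicate_id = rep(sub$replicate_id,
                                               nrow(sub$events)))
  }
  out <- event_matrix(do.call(rbind, parts), set$channels,
                      sample_id = "training", replicate_id = "pooled",
                      transformed = files[[1L]]$transformed)
  attr(out, "provenance") <- do.call(rbind, prov)
  out
}
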
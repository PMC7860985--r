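#' Event matrix: one flow-cytometry measurement
#'
#' An `event_matrix` holds the events of a single cytometry file: an
#' `N x D` numeric matrix with one row per detected particle ("cell")
#' and one column per detector channel (e.g. `FSC-H`, `SSC-H`,
#' `FL1-H`), together with the sample and technical-replicate
#' identifiers and a flag recording whether intensities have been
#' asinh-transformed.
#'
#' @param events Numeric `N x D` matrix, `N >= 1`, `D >= 1`; all values
#'   finite.
#' @param channels Character vector of `D` unique channel names.
#' @param sample_id,replicate_id Identifiers; replicates of one sample
#'   share `sample_id`.
#' @param transformed Logical; `TRUE` once [asinh_transform()] has been
#'   applied.
#' @return An object of class `event_matrix`.
#' @seealso [read_events()], [subsample_events()], [asinh_transform()]
#' @export
event_matrix <- function(events, channels, sample_id = "sample",
                         replicate_id = "1", transformed = FALSE) {
  events <- as.matrix(events)
  storage.mode(events) <- "double"
  if (nrow(events) < 1L)
    stop_cytofp("cytofp_empty_input", "event matrix has no rows")
  if (length(channels) != ncol(events))
    stop_cytofp("cytofp_channel_error",
                "got %d channel names for %d columns",
                length(channels), ncol(events))
  if (anyDuplicated(channels))
    stop_cytofp("cytofp_channel_error", "channel names must be unique")
  if (!all(is.finite(events)))
    stop_cytofp("cytofp_invalid_input", "events contain non-finite values")
  colnames(events) <- channels
  structure(list(events = events,
                 channels = as.character(channels),
                 sample_id = as.character(sample_id),
                 replicate_id = as.character(replicate_id),
                 transformed = isTRUE(transformed)),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("<event_matrix> sample %s rep %s: %d events x %d channels (%s)%s\n",
              x$sample_id, x$replicate_id, nrow(x$events),
              length(x$channels), paste(x$channels, collapse = ", "),
              if (x$transformed) " [transformed]" else ""))
  invisible(x)
}

#' @export
dim.event_matrix <- function(x) dim(x$events)

select_channels <- function(em, channels) {
  missing <- setdiff(channels, em$channels)
  if (length(missing))
    stop_cytofp("cytofp_channel_error",
                "channel(s) %s not present; available: %s",
                paste(missing, collapse = ", "),
                paste(em$channels, collapse = ", "))
  event_matrix(em$events[, channels, drop = FALSE], channels,
               em$sample_id, em$replicate_id, em$transformed)
}

#' Read cytometry events from an FCS or CSV file
#'
#' CSV files must carry a header naming the channels, one row per
#' event. FCS 3.0/3.1 list-mode files are read with an internal parser
#' (data types F, D and I; little- or big-endian); channels are matched
#' by their `$PnN` short names.
#'
#' @param path File to read.
#' @param channel_subset Channels to retain, in the requested order.
#'   `NULL` keeps all channels in file order.
#' @param format `"csv"` or `"fcs"`; `NULL` guesses from the file
#'   extension.
#' @param sample_id,replicate_id Identifiers attached to the result;
#'   default `sample_id` is the file name without extension.
#' @return An [event_matrix()] with `transformed = FALSE`; row order is
#'   preserved from the file.
#' @export
read_events <- function(path, channel_subset = NULL, format = NULL,
                        sample_id = NULL, replicate_id = "1") {
  if (!file.exists(path))
    stop_cytofp("cytofp_missing_file", "file not found: %s", path)
  if (is.null(format)) {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  format <- match.arg(format, c("csv", "fcs"))
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "csv") {
    df <- read.csv(path, check.names = FALSE)
    if (nrow(df) == 0L)
      stop_cytofp("cytofp_empty_input", "no events in %s", path)
    em <- event_matrix(as.matrix(df), colnames(df), sample_id, replicate_id)
  } else {
    parsed <- read_fcs_raw(path)
    em <- event_matrix(parsed$data, parsed$channels, sample_id, replicate_id)
  }
  if (!is.null(channel_subset)) {
    if (!length(channel_subset))
      stop_cytofp("cytofp_invalid_input", "channel_subset is empty")
    em <- select_channels(em, channel_subset)
  }
  em
}

#' Write an event matrix to headered CSV
#'
#' Values round-trip bit-exactly through [read_events()] (17
#' significant digits).
#'
#' @param em An [event_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(em, path) {
  stopifnot(inherits(em, "event_matrix"))
  df <- as.data.frame(em$events)
  colnames(df) <- em$channels
  # format() with 17 digits preserves doubles exactly through text
  df[] <- lapply(df, function(v) sprintf("%.17g", v))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Minimal FCS 3.0/3.1 list-mode reader. The header is 6 ASCII offset
# fields; TEXT is delimiter-separated keyword/value pairs; DATA is a
# packed event-major array. Only what microbial cytometry files need is
# supported: $DATATYPE F/D/I, $MODE L, common $BYTEORD values.
read_fcs_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58L))
  version <- substr(header, 1, 6)
  if (!grepl("^FCS3\\.", version))
    stop_cytofp("cytofp_invalid_input", "unsupported FCS version '%s'", version)
  off <- function(a, b) as.numeric(trimws(substr(header, a, b)))
  text_start <- off(11, 18); text_end <- off(19, 26)
  data_start <- off(27, 34); data_end <- off(35, 42)

  seek(con, text_start)
  text <- rawToChar(readBin(con, "raw", text_end - text_start + 1L))
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- trimws(parts[seq(2, length(parts), by = 2)])
  names(kw) <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))

  need <- function(k) {
    if (is.na(kw[k]) || !nzchar(kw[k]))
      stop_cytofp("cytofp_invalid_input", "FCS keyword %s missing", k)
    kw[[k]]
  }
  if (data_start == 0) data_start <- as.numeric(need("$BEGINDATA"))
  if (data_end == 0) data_end <- as.numeric(need("$ENDDATA"))
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.numeric(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- need("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little" else "big"
  channels <- vapply(seq_len(n_par),
                     function(i) kw[[paste0("$P", i, "N")]], "")
  bits <- as.integer(vapply(seq_len(n_par),
                            function(i) kw[[paste0("$P", i, "B")]], ""))

  seek(con, data_start)
  n_values <- n_par * n_tot
  data <- switch(dtype,
    F = readBin(con, "double", n_values, size = 4L, endian = endian),
    D = readBin(con, "double", n_values, size = 8L, endian = endian),
    I = {
      if (length(unique(bits)) != 1L || !unique(bits) %in% c(16L, 32L))
        stop_cytofp("cytofp_invalid_input",
                    "integer FCS data needs uniform 16- or 32-bit widths")
      readBin(con, "integer", n_values, size = unique(bits) / 8L,
              signed = unique(bits) > 16L, endian = endian)
    },
    stop_cytofp("cytofp_invalid_input", "unsupported $DATATYPE '%s'", dtype))
  if (length(data) < n_values)
    stop_cytofp("cytofp_invalid_input", "FCS data segment truncated")
  list(data = matrix(as.double(data), nrow = n_tot, ncol = n_par,
                     byrow = TRUE),
       channels = channels)
}

#' Subsample events uniformly without replacement
#'
#' Used to even out cell numbers across samples before template
#' fitting, so no sample dominates the mixture fit.
#'
#' @param em An [event_matrix()].
#' @param n_cells Number of events to keep.
#' @param seed Integer seed; the draw is a pure function of
#'   `(em, n_cells, seed)`.
#' @param short_policy What to do when `n_cells > N`: `"error"`
#'   (default) or `"take_all"` (keep all rows, with a warning).
#' @return An [event_matrix()] with `n_cells` rows (or `N` under
#'   `"take_all"`).
#' @export
subsample_events <- function(em, n_cells, seed,
                             short_policy = c("error", "take_all")) {
  stopifnot(inherits(em, "event_matrix"), n_cells >= 1)
  short_policy <- match.arg(short_policy)
  n <- nrow(em$events)
  if (n_cells > n) {
    if (short_policy == "error")
      stop_cytofp("cytofp_insufficient_events",
                  "sample %s has %d events, %d requested",
                  em$sample_id, n, n_cells)
    warning(sprintf("sample %s: only %d of %d requested events available",
                    em$sample_id, n, n_cells))
    n_cells <- n
  }
  idx <- with_seed(seed, sample.int(n, n_cells, replace = FALSE))
  event_matrix(em$events[idx, , drop = FALSE], em$channels,
               em$sample_id, em$replicate_id, em$transformed)
}

# save/restore the global RNG state so seeded package internals do not
# disturb the caller's random stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  expr
}
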
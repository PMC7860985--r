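#' Inverse-hyperbolic-sine transform of raw intensities
#'
#' Raw detector pulses span several decades; `asinh` is
#' logarithm-like at high intensity yet linear (and defined) through
#' zero, so dim debris and bright cells share one usable scale. The
#' transform applied is `asinh(x / cofactor)`; the default cofactor of
#' 1 gives the plain `f(x) = asinh(x)`.
#'
#' @param em An [event_matrix()] with `transformed = FALSE`.
#' @param cofactor Positive scale divisor, default 1. Larger values
#'   compress less; useful on instruments with different gain.
#' @return The transformed [event_matrix()], `transformed = TRUE`.
#' @export
asinh_transform <- function(em, cofactor = 1) {
  stopifnot(inherits(em, "event_matrix"), cofactor > 0)
  if (em$transformed)
    stop_cytofp("cytofp_state_error",
                "sample %s is already transformed", em$sample_id)
  event_matrix(asinh(em$events / cofactor), em$channels,
               em$sample_id, em$replicate_id, transformed = TRUE)
}

#' Polygon gate in transformed coordinates
#'
#' A single fixed two-dimensional gate separates bacterial signal from
#' background and debris. Vertices are given in transformed (asinh)
#' coordinates so the gate is robust to instrument gain.
#'
#' @param channel_x,channel_y Channel names spanning the gating plane.
#' @param vertices Numeric matrix (or two-column data frame) of >= 3
#'   polygon vertices, columns x and y, in order.
#' @param keep_inside If `TRUE` (default) events inside the polygon
#'   are kept, otherwise the outside ones.
#' @return An object of class `gate`.
#' @export
gate <- function(channel_x, channel_y, vertices, keep_inside = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (nrow(vertices) < 3L)
    stop_cytofp("cytofp_invalid_input", "a gate needs >= 3 vertices")
  if (!all(is.finite(vertices)))
    stop_cytofp("cytofp_invalid_input", "gate vertices must be finite")
  structure(list(channel_x = channel_x, channel_y = channel_y,
                 vertices = vertices[, 1:2, drop = FALSE],
                 keep_inside = isTRUE(keep_inside)),
            class = "gate")
}

#' Read a gate definition from YAML or JSON
#'
#' Expected fields: `channel_x`, `channel_y`, `vertices` (list of
#' `[x, y]` pairs) and optionally `keep_inside` (default true).
#'
#' @param path Gate file (`.yml`/`.yaml` or `.json`).
#' @return A [gate()].
#' @export
read_gate <- function(path) {
  if (!file.exists(path))
    stop_cytofp("cytofp_missing_file", "gate file not found: %s", path)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  verts <- spec$vertices
  if (is.list(verts)) verts <- do.call(rbind, lapply(verts, unlist))
  gate(spec$channel_x, spec$channel_y, verts,
       keep_inside = spec$keep_inside %||% TRUE)
}

# Even-odd (crossing-number) point-in-polygon; points on an edge are
# reported inside so the boundary tie rule is deterministic.
points_in_polygon <- function(px, py, verts) {
  n <- nrow(verts)
  xs <- verts[, 1L]; ys <- verts[, 2L]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # collinear and within the segment's bounding box -> on boundary
    cross <- (xj - xi) * (py - yi) - (px - xi) * (yj - yi)
    on_seg <- cross == 0 &
      px >= pmin(xi, xj) & px <= pmax(xi, xj) &
      py >= pmin(yi, yj) & py <= pmax(yi, yj)
    on_edge <- on_edge | on_seg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Apply a polygon gate to transformed events
#'
#' @param em A transformed [event_matrix()].
#' @param g A [gate()]; its channels must be present in `em`.
#' @return The gated [event_matrix()]. Events exactly on the polygon
#'   boundary count as inside.
#' @export
apply_gate <- function(em, g) {
  stopifnot(inherits(em, "event_matrix"), inherits(g, "gate"))
  if (!em$transformed)
    stop_cytofp("cytofp_state_error",
                "gates are defined in transformed coordinates; transform first")
  missing <- setdiff(c(g$channel_x, g$channel_y), em$channels)
  if (length(missing))
    stop_cytofp("cytofp_channel_error",
                "gate channel(s) %s not present; available: %s",
                paste(missing, collapse = ", "),
                paste(em$channels, collapse = ", "))
  inside <- points_in_polygon(em$events[, g$channel_x],
                              em$events[, g$channel_y], g$vertices)
  keep <- if (g$keep_inside) inside else !inside
  if (!any(keep))
    stop_cytofp("cytofp_empty_sample",
                "no events of sample %s survive the gate", em$sample_id)
  event_matrix(em$events[keep, , drop = FALSE], em$channels,
               em$sample_id, em$replicate_id, em$transformed)
}

# transform + optional gate over every file of an experiment set
preprocess_set <- function(set, g = NULL, cofactor = 1,
                           already_transformed = FALSE) {
  ems <- unlist(set$samples, recursive = FALSE, use.names = FALSE)
  ems <- lapply(ems, function(em) {
    if (!already_transformed && !em$transformed)
      em <- asinh_transform(em, cofactor)
    if (!is.null(g)) em <- apply_gate(em, g)
    em
  })
  experiment_set(ems, metadata = set$metadata)
}
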
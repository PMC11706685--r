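#' Construct a root centerline trace
#'
#' A `root_trace` holds the ordered 2D coordinates of one digitized root
#' centerline in centimetres, base first: the first point is the
#' root--hypocotyl junction (the basal point) and the last point is the root
#' tip. The internal frame is y-up, so a root growing with gravity has
#' decreasing y.
#'
#' Consecutive duplicate points (an occasional artefact of manual clicking)
#' are collapsed with a warning; a trace that degenerates to fewer than 3
#' distinct points is rejected.
#'
#' @param points Two-column numeric matrix (or data frame) of x, y
#'   coordinates in cm, ordered base to tip.
#' @param root_id Identifier for the root.
#' @param group Group label (genotype or treatment), `NA` if unknown.
#' @param scale_applied Logical; `TRUE` once coordinates are in cm.
#' @return An object of class `root_trace` with fields `root_id`, `group`,
#'   `points`, `n_points`, `scale_applied`.
#' @export
root_trace <- function(points, root_id = "root", group = NA_character_,
                       scale_applied = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || !is.numeric(points)) {
    stop("`points` must be a two-column numeric matrix.", call. = FALSE)
  }
  if (anyNA(points) || any(!is.finite(points))) {
    stop("Trace '", root_id, "' contains non-finite coordinates.", call. = FALSE)
  }
  dimnames(points) <- list(NULL, c("x", "y"))
  if (nrow(points) >= 2) {
    seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                           points[-nrow(points), , drop = FALSE])^2))
    if (any(seg == 0)) {
      warning("Trace '", root_id, "': collapsed ", sum(seg == 0),
              " consecutive duplicate point(s).", call. = FALSE)
      points <- points[c(TRUE, seg > 0), , drop = FALSE]
    }
  }
  if (nrow(points) < 3) {
    stop("Degenerate trace '", root_id,
         "': fewer than 3 distinct points.", call. = FALSE)
  }
  structure(
    list(root_id = as.character(root_id), group = as.character(group),
         points = points, n_points = nrow(points),
         scale_applied = isTRUE(scale_applied)),
    class = "root_trace"
  )
}

#' @export
print.root_trace <- function(x, ...) {
  cat("<root_trace> ", x$root_id,
      if (!is.na(x$group)) paste0(" [", x$group, "]"), ": ",
      x$n_points, " points\n", sep = "")
  invisible(x)
}

#' Bundle traces into a collection
#'
#' @param traces List of [root_trace()] objects with unique `root_id`s.
#' @param gravity_direction 2D gravity vector; normalized to unit length.
#'   Default `c(0, -1)`: gravity points toward decreasing y (y-up frame).
#' @param provenance Optional free-form provenance (source file, scale).
#' @return An object of class `trace_collection`.
#' @export
trace_collection <- function(traces, gravity_direction = c(0, -1),
                             provenance = NULL) {
  if (!is.list(traces) || !all(vapply(traces, inherits, TRUE, "root_trace"))) {
    stop("`traces` must be a list of root_trace objects.", call. = FALSE)
  }
  ids <- vapply(traces, `[[`, "", "root_id")
  if (anyDuplicated(ids)) {
    stop("Duplicated root_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(traces) <- ids
  structure(
    list(traces = traces, gravity_direction = unit_gravity(gravity_direction),
         provenance = provenance),
    class = "trace_collection"
  )
}

#' @export
print.trace_collection <- function(x, ...) {
  grp <- vapply(x$traces, `[[`, "", "group")
  cat("<trace_collection> ", length(x$traces), " trace(s), ",
      length(unique(grp[!is.na(grp)])), " group(s)\n", sep = "")
  invisible(x)
}

#' @export
length.trace_collection <- function(x) length(x$traces)

#' Read a single-root XY coordinate export
#'
#' Reads the two-column text files produced by ImageJ/Fiji's "Save XY
#' Coordinates" (whitespace- or comma-delimited; an optional header line is
#' auto-detected). Coordinates are multiplied by `scale_cm_per_unit`; image
#' exports are usually y-down, in which case `y_axis = "down"` negates y so
#' the internal frame is y-up.
#'
#' @param path Path to the coordinate file.
#' @param scale_cm_per_unit Positive scale factor converting file units
#'   (typically pixels) to cm. There is no default: the image scale must be
#'   known.
#' @param y_axis `"up"` if the file's y grows upward, `"down"` (image
#'   convention) if it grows downward.
#' @param root_id,group Metadata attached to the trace; `root_id` defaults
#'   to the file name.
#' @return A [root_trace()].
#' @export
read_xy_trace <- function(path, scale_cm_per_unit, y_axis = c("up", "down"),
                          root_id = NULL, group = NA_character_) {
  y_axis <- match.arg(y_axis)
  if (!is.numeric(scale_cm_per_unit) || length(scale_cm_per_unit) != 1 ||
      !is.finite(scale_cm_per_unit) || scale_cm_per_unit <= 0) {
    stop("`scale_cm_per_unit` must be a positive number.", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("Empty coordinate file: ", path, call. = FALSE)

  parse_line <- function(l) {
    tok <- strsplit(l, "[,;[:space:]]+")[[1]]
    suppressWarnings(as.numeric(tok[nzchar(tok)]))
  }
  first <- parse_line(lines[[1]])
  header <- anyNA(first)
  if (header) {
    lines <- lines[-1]
    line_no <- line_no[-1]
  }
  vals <- lapply(lines, parse_line)
  bad <- which(vapply(vals, function(v) anyNA(v) || length(v) < 2, TRUE))
  if (length(bad)) {
    stop("Non-numeric or short row at line ", line_no[bad[1]], " of ", path,
         call. = FALSE)
  }
  xy <- do.call(rbind, lapply(vals, function(v) v[1:2])) * scale_cm_per_unit
  if (y_axis == "down") xy[, 2] <- -xy[, 2]
  if (is.null(root_id)) root_id <- sub("\\.[^.]*$", "", basename(path))
  root_trace(xy, root_id = root_id, group = group, scale_applied = TRUE)
}

#' Read a long-format trace table
#'
#' Expects a CSV with columns `root_id`, `group`, `point_index`, `x`, `y`
#' (one row per digitized point); rows may appear in any order and are
#' sorted by `point_index` within each root.
#'
#' @inheritParams read_xy_trace
#' @param scale_cm_per_unit Scale factor applied to x and y (default 1:
#'   coordinates already in cm).
#' @param gravity_direction Gravity vector for the returned collection.
#' @return A [trace_collection()].
#' @export
read_trace_table <- function(path, scale_cm_per_unit = 1,
                             y_axis = c("up", "down"),
                             gravity_direction = c(0, -1)) {
  y_axis <- match.arg(y_axis)
  if (scale_cm_per_unit <= 0) {
    stop("`scale_cm_per_unit` must be positive.", call. = FALSE)
  }
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("Cannot read trace table ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  need <- c("root_id", "group", "point_index", "x", "y")
  miss <- setdiff(need, names(df))
  if (nrow(df) == 0 || length(miss)) {
    stop("Trace table ", path, " lacks required column(s): ",
         if (length(miss)) paste(miss, collapse = ", ") else "no rows",
         call. = FALSE)
  }
  key <- paste(df$root_id, df$point_index, sep = "\r")
  if (anyDuplicated(key)) {
    stop("Duplicated (root_id, point_index) in ", path, ": ",
         key[anyDuplicated(key)], call. = FALSE)
  }
  traces <- lapply(split(df, df$root_id), function(d) {
    d <- d[order(d$point_index), ]
    xy <- cbind(d$x, d$y) * scale_cm_per_unit
    if (y_axis == "down") xy[, 2] <- -xy[, 2]
    root_trace(xy, root_id = d$root_id[1], group = d$group[1])
  })
  trace_collection(traces[unique(df$root_id)],
                   gravity_direction = gravity_direction,
                   provenance = list(path = path, scale = scale_cm_per_unit))
}

#' Write a trace collection as a long-format CSV
#'
#' @param collection A [trace_collection()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(collection, path) {
  stopifnot(inherits(collection, "trace_collection"))
  rows <- lapply(collection$traces, function(tr) {
    tibble::tibble(root_id = tr$root_id, group = tr$group,
                   point_index = seq_len(tr$n_points),
                   x = tr$points[, 1], y = tr$points[, 2])
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' Write per-root results to CSV
#'
#' One row per root, fixed column order, full float precision (RFC 4180).
#'
#' @param indices Tibble of per-root indices as returned by
#'   [measure_collection()] (or any non-empty data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(indices, path) {
  if (!is.data.frame(indices) || nrow(indices) == 0) {
    stop("`indices` must be a non-empty data frame; refusing to write ",
         path, call. = FALSE)
  }
  readr::write_csv(tibble::as_tibble(indices), path)
  invisible(path)
}

#' Read back a per-root results CSV
#'
#' @param path CSV path written by [write_results()].
#' @return A tibble.
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
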
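#' A pressure-mat recording of one test trial
#'
#' Bundles an ordered sequence of force frames with the mat geometry, the
#' target layout and trial metadata (subject, group, leg). Frame
#' timestamps must be strictly increasing and spaced within 10% of the
#' nominal frame period; touch timing only needs frame order, so larger
#' jitter is treated as a corrupt file rather than silently resampled.
#'
#' @param geometry A [mat_geometry()].
#' @param layout A [target_layout()].
#' @param times Numeric vector of frame timestamps in seconds.
#' @param frames List of `n_rows x n_cols` non-negative force matrices
#'   (device units), one per timestamp.
#' @param duration Trial duration in seconds (default 20, the standard
#'   test length).
#' @param meta Named list; recognised fields `subject`, `group`
#'   (`"stroke"`/`"control"`), `leg` (`"paretic"`, `"non-paretic"`,
#'   `"dominant"`, `"non-dominant"`).
#' @return An object of class `lemocot_recording`.
#' @export
recording <- function(geometry, layout, times, frames, duration = 20,
                      meta = list()) {
  stopifnot(inherits(geometry, "mat_geometry"),
            inherits(layout, "target_layout"))
  if (length(frames) < 1L) stop("a recording must contain at least 1 frame")
  if (length(times) != length(frames))
    stop("times and frames lengths differ")
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || nrow(f) != geometry$n_rows ||
        ncol(f) != geometry$n_cols)
      stop("frame ", i, " dimensions do not match the mat geometry")
    if (any(f < 0)) stop("frame ", i, " contains negative forces")
  }
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0))
      stop("frame timestamps must be strictly increasing (violated at frame ",
           which(dt <= 0)[1] + 1L, ")")
    nominal <- 1 / geometry$sampling_rate
    if (any(abs(dt - nominal) > 0.1 * nominal))
      stop("frame spacing deviates more than 10% from 1/sampling_rate ",
           "(first at frame ", which(abs(dt - nominal) > 0.1 * nominal)[1] + 1L,
           ")")
  }
  structure(list(geometry = geometry, layout = layout,
                 times = as.numeric(times), frames = frames,
                 duration = as.numeric(duration), meta = meta),
            class = "lemocot_recording")
}

#' @export
print.lemocot_recording <- function(x, ...) {
  cat(sprintf("<lemocot_recording> %d frames (%.2f s), %d x %d grid\n",
              length(x$frames), diff(range(x$times)),
              x$geometry$n_rows, x$geometry$n_cols))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

format_num <- function(x) {
  # 17 significant digits round-trip any double exactly
  sprintf("%.17g", x)
}

header_fields <- function(geometry) {
  sprintf("rows=%d cols=%d pitch_mm=%s rate_hz=%s origin_cell=%g,%g y_axis=%s",
          geometry$n_rows, geometry$n_cols,
          format_num(geometry$cell_pitch), format_num(geometry$sampling_rate),
          geometry$origin_cell[1], geometry$origin_cell[2], geometry$y_axis)
}

parse_header_tokens <- function(tokens, where) {
  kv <- strsplit(tokens, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed header token '", tokens[bad][1], "' in ", where)
  vals <- vapply(kv, `[`, "", 2L)
  names(vals) <- vapply(kv, `[`, "", 1L)
  need <- c("rows", "cols", "pitch_mm", "rate_hz", "origin_cell", "y_axis")
  missing <- setdiff(need, names(vals))
  if (length(missing))
    stop("header in ", where, " is missing field(s): ",
         paste(missing, collapse = ", "))
  oc <- as.numeric(strsplit(vals[["origin_cell"]], ",")[[1]])
  mat_geometry(as.integer(vals[["rows"]]), as.integer(vals[["cols"]]),
               cell_pitch = as.numeric(vals[["pitch_mm"]]),
               sampling_rate = as.numeric(vals[["rate_hz"]]),
               origin_cell = oc, y_axis = vals[["y_axis"]])
}

layout_to_list <- function(layout) {
  list(proximal_center = layout$proximal_center,
       distal_center = layout$distal_center,
       target_radius = layout$target_radius,
       zone_half_width = layout$zone_half_width)
}

layout_from_list <- function(l) {
  target_layout(proximal_center = as.numeric(unlist(l$proximal_center)),
                distal_center = as.numeric(unlist(l$distal_center)),
                target_radius = as.numeric(l$target_radius),
                zone_half_width = as.numeric(l$zone_half_width))
}

#' Save a recording to disk
#'
#' Two open text dialects are supported:
#' \describe{
#'   \item{`frame_text`}{A single self-contained file: a header line
#'     `rows=.. cols=.. pitch_mm=.. rate_hz=.. origin_cell=r,c y_axis=..`,
#'     a `layout=<json>` line and a `meta=<json>` line, then per frame a
#'     `t=<seconds>` line followed by `n_rows` whitespace-separated rows
#'     of forces.}
#'   \item{`long_csv`}{A sparse CSV with columns `t,row,col,force` (only
#'     nonzero cells listed) plus a JSON sidecar `<path>.json` holding the
#'     geometry header fields, the target layout, the metadata and the
#'     frame timestamps (so all-zero frames survive the round trip).}
#' }
#' Forces round-trip exactly and timestamps to better than 1e-6 s.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @param format `"frame_text"` or `"long_csv"`.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path, format = c("frame_text", "long_csv")) {
  stopifnot(inherits(rec, "lemocot_recording"))
  format <- match.arg(format)
  g <- rec$geometry
  if (format == "frame_text") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(header_fields(g), con)
    writeLines(paste0("layout=", as.character(jsonlite::toJSON(
      layout_to_list(rec$layout), auto_unbox = TRUE, digits = NA))), con)
    writeLines(paste0("meta=", as.character(jsonlite::toJSON(
      c(rec$meta, list(duration = rec$duration)),
      auto_unbox = TRUE, digits = NA))), con)
    for (i in seq_along(rec$frames)) {
      writeLines(sprintf("t=%.17g", rec$times[i]), con)
      m <- rec$frames[[i]]
      writeLines(apply(m, 1L, function(r) paste(format_num(r), collapse = " ")),
                 con)
    }
  } else {
    nz <- lapply(seq_along(rec$frames), function(i) {
      idx <- which(rec$frames[[i]] != 0, arr.ind = TRUE)
      if (nrow(idx) == 0L) return(NULL)
      data.frame(t = rec$times[i], row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                 force = rec$frames[[i]][idx])
    })
    tab <- do.call(rbind, nz)
    con <- file(path, open = "wt")
    writeLines("t,row,col,force", con)
    if (!is.null(tab) && nrow(tab))
      writeLines(sprintf("%.17g,%d,%d,%s", tab$t, tab$row, tab$col,
                         format_num(tab$force)), con)
    close(con)
    sidecar <- list(
      rows = g$n_rows, cols = g$n_cols, pitch_mm = g$cell_pitch,
      rate_hz = g$sampling_rate, origin_cell = g$origin_cell,
      y_axis = g$y_axis, layout = layout_to_list(rec$layout),
      meta = rec$meta, duration = rec$duration,
      # timestamps as %.17g strings: JSON numbers lose the last bits
      times = format_num(rec$times))
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Load a recording from disk
#'
#' Reads either dialect written by [save_recording()]. For `long_csv` the
#' sidecar `<path>.json` (or `<path>.yaml`) must sit next to the data
#' file. Validation errors (non-monotone timestamps, dimension mismatches)
#' are raised with the offending frame named.
#'
#' @inheritParams save_recording
#' @return A [recording()].
#' @export
load_recording <- function(path, format = c("frame_text", "long_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "frame_text") {
    lines <- readLines(path)
    if (length(lines) < 1L || !grepl("^rows=", lines[1]))
      stop("malformed frame_text header at line 1 of ", path)
    geometry <- parse_header_tokens(strsplit(lines[1], "[[:space:]]+")[[1]],
                                    path)
    i <- 2L
    layout <- target_layout(); meta <- list(); duration <- 20
    while (i <= length(lines) && !grepl("^t=", lines[i])) {
      if (grepl("^layout=", lines[i])) {
        layout <- layout_from_list(
          jsonlite::fromJSON(sub("^layout=", "", lines[i])))
      } else if (grepl("^meta=", lines[i])) {
        m <- jsonlite::fromJSON(sub("^meta=", "", lines[i]))
        duration <- if (!is.null(m$duration)) m$duration else duration
        m$duration <- NULL
        meta <- m
      } else stop("malformed header at line ", i, " of ", path)
      i <- i + 1L
    }
    times <- numeric(); frames <- list()
    while (i <= length(lines)) {
      if (!grepl("^t=", lines[i]))
        stop("expected 't=' at line ", i, " of ", path)
      times <- c(times, as.numeric(sub("^t=", "", lines[i])))
      block <- lines[(i + 1L):(i + geometry$n_rows)]
      vals <- lapply(strsplit(trimws(block), "[[:space:]]+"), as.numeric)
      if (any(lengths(vals) != geometry$n_cols))
        stop("frame block starting at line ", i + 1L, " of ", path,
             " has a row with the wrong number of columns")
      frames[[length(frames) + 1L]] <- do.call(rbind, vals)
      i <- i + 1L + geometry$n_rows
    }
  } else {
    sidecar_path <- if (file.exists(paste0(path, ".json")))
      paste0(path, ".json") else paste0(path, ".yaml")
    if (!file.exists(sidecar_path))
      stop("long_csv sidecar not found next to ", path)
    sc <- if (grepl("\\.json$", sidecar_path))
      jsonlite::fromJSON(sidecar_path) else yaml::read_yaml(sidecar_path)
    geometry <- mat_geometry(sc$rows, sc$cols, cell_pitch = sc$pitch_mm,
                             sampling_rate = sc$rate_hz,
                             origin_cell = as.numeric(unlist(sc$origin_cell)),
                             y_axis = sc$y_axis)
    layout <- layout_from_list(sc$layout)
    meta <- if (length(sc$meta)) as.list(sc$meta) else list()
    duration <- if (!is.null(sc$duration)) sc$duration else 20
    times <- as.numeric(unlist(sc$times))
    tab <- utils::read.csv(path)
    need <- c("t", "row", "col", "force")
    if (!all(need %in% names(tab)))
      stop("malformed long_csv header in ", path,
           ": need columns t,row,col,force")
    frames <- lapply(times, function(tt) {
      m <- matrix(0, geometry$n_rows, geometry$n_cols)
      sel <- tab[abs(tab$t - tt) < 1e-7, , drop = FALSE]
      if (nrow(sel))
        m[cbind(sel$row + 1L, sel$col + 1L)] <- sel$force
      m
    })
  }
  recording(geometry, layout, times, frames, duration = duration, meta = meta)
}
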
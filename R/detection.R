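#' Touch-detection configuration
#'
#' Tuning constants for segmenting contact episodes from the force time
#' series. Forces are in raw device units.
#'
#' @param force_threshold Per-cell activation threshold (default 1): a
#'   sensor counts as active when its force is at or above this value.
#' @param min_total_force Episode gate (default 3): a frame belongs to a
#'   contact only if its summed above-threshold force reaches this value.
#' @param min_duration Minimum episode length in frames (default 2, which
#'   rejects single-frame noise bursts).
#' @param toe_radius Radius in mm (default 20) of the neighbourhood around
#'   the anchor cell used to localise the big toe; roughly the width of a
#'   big toe, 2-3 sensor cells.
#' @param anchor_min_frac The endpoint anchor — the active cell nearest
#'   the intended target — is chosen among cells carrying at least this
#'   fraction of the region's peak force (default 0.2), so lightly
#'   grazing flesh between the toe pad and the ball of the foot cannot
#'   anchor the toe neighbourhood.
#' @param connectivity Cell adjacency for connected components, 4 or 8
#'   (default 8).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(force_threshold = 1, min_total_force = 3,
                             min_duration = 2, toe_radius = 20,
                             anchor_min_frac = 0.2, connectivity = 8) {
  stopifnot(force_threshold > 0, min_total_force > 0, min_duration >= 1,
            toe_radius > 0, anchor_min_frac >= 0, anchor_min_frac <= 1,
            connectivity %in% c(4, 8))
  structure(list(force_threshold = force_threshold,
                 min_total_force = min_total_force,
                 min_duration = as.integer(min_duration),
                 toe_radius = toe_radius,
                 anchor_min_frac = anchor_min_frac,
                 connectivity = as.integer(connectivity)),
            class = "detection_config")
}

# Label connected components among active cells. `cells` is an n x 2
# matrix of 1-based (row, col) grid indices. Returns an integer label per
# cell. BFS over a hash of occupied indices; active sets are tiny (a foot)
# so this is O(n) with small constants.
connected_components <- function(cells, n_rows, connectivity = 8L) {
  n <- nrow(cells)
  if (n == 0L) return(integer(0))
  key <- cells[, 1] + (cells[, 2] - 1L) * n_rows
  pos <- new.env(hash = TRUE, size = max(64L, 2L * n))
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = pos)
  if (connectivity == 8L) {
    off <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                 dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  } else {
    off <- cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  }
  labels <- integer(n)
  lab <- 0L
  for (s in seq_len(n)) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    queue <- s
    labels[s] <- lab
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      for (k in seq_len(nrow(off))) {
        nb <- as.character((cells[i, 1] + off[k, 1]) +
                             (cells[i, 2] + off[k, 2] - 1L) * n_rows)
        j <- pos[[nb]]
        if (!is.null(j) && labels[j] == 0L) {
          labels[j] <- lab
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

# Extract the active region of one frame: the largest connected component
# of cells with force >= threshold. Ties on size go to the component with
# greater total force, then to the one containing the lowest row index.
# Returns NULL when no cell is active, else list(cells [0-based n x 2],
# forces, n_secondary) where n_secondary counts discarded components.
frame_active_region <- function(forces, cfg) {
  idx <- which(forces >= cfg$force_threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  labels <- connected_components(idx, nrow(forces), cfg$connectivity)
  nlab <- max(labels)
  if (nlab > 1L) {
    size <- tabulate(labels, nlab)
    fsum <- vapply(seq_len(nlab),
                   function(l) sum(forces[idx[labels == l, , drop = FALSE]]),
                   0)
    minrow <- vapply(seq_len(nlab),
                     function(l) min(idx[labels == l, 1]), 0L)
    ord <- order(-size, -fsum, minrow)
    keep <- ord[1L]
  } else keep <- 1L
  sel <- labels == keep
  list(cells = cbind(row = idx[sel, 1] - 1L, col = idx[sel, 2] - 1L),
       forces = forces[idx[sel, , drop = FALSE]],
       n_secondary = nlab - 1L)
}

#' Segment contact episodes from a recording
#'
#' A frame is a contact frame when its total above-threshold force reaches
#' `min_total_force`; maximal runs of at least `min_duration` consecutive
#' contact frames form episodes, separated by at least one sub-threshold
#' frame. Within each frame the active region is the largest connected
#' component of cells at or above `force_threshold`; smaller simultaneous
#' components (stray noisy cells) are discarded and counted.
#'
#' @param rec A [recording()].
#' @param cfg A [detection_config()].
#' @return A list of episodes, each a list with `start_frame` and
#'   `end_frame` (1-based, inclusive) and `regions`, one active region per
#'   frame in the span. An empty recording yields an empty list.
#' @export
detect_episodes <- function(rec, cfg = detection_config()) {
  stopifnot(inherits(rec, "lemocot_recording"),
            inherits(cfg, "detection_config"))
  n <- length(rec$frames)
  regions <- vector("list", n)
  contact <- logical(n)
  for (i in seq_len(n)) {
    reg <- frame_active_region(rec$frames[[i]], cfg)
    if (!is.null(reg) && sum(reg$forces) +
        sum_secondary_force(rec$frames[[i]], reg, cfg) >= cfg$min_total_force) {
      regions[[i]] <- reg
      contact[i] <- TRUE
    }
  }
  runs <- rle(contact)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= cfg$min_duration
  lapply(which(keep), function(k) {
    span <- starts[k]:ends[k]
    list(start_frame = starts[k], end_frame = ends[k],
         regions = regions[span])
  })
}

# total above-threshold force outside the primary component (the episode
# gate is judged on all above-threshold cells, not just the kept region)
sum_secondary_force <- function(forces, region, cfg) {
  tot <- sum(forces[forces >= cfg$force_threshold])
  tot - sum(region$forces)
}

#' Centre of pressure of an active region
#'
#' The force-weighted mean of the active cells' centre coordinates,
#' `sum(f_i p_i) / sum(f_i)`; always inside the convex hull of the
#' region's cell centres.
#'
#' @param region An active region as produced by [detect_episodes()]
#'   (list with 0-based `cells` and `forces`).
#' @param geometry A [mat_geometry()].
#' @return Numeric `c(x, y)` in mm.
#' @export
cop_location <- function(region, geometry) {
  if (is.null(region) || nrow(region$cells) == 0L)
    stop("cop_location: empty active region")
  w <- region$forces
  if (sum(w) <= 0) stop("cop_location: zero total force (degenerate input)")
  pts <- cell_to_point(region$cells[, 1], region$cells[, 2], geometry)
  c(x = sum(pts[, 1] * w) / sum(w), y = sum(pts[, 2] * w) / sum(w))
}

#' Endpoint (big-toe) location of an active region
#'
#' The big toe is the part of the contact closest to the aimed-at target,
#' so the endpoint is the force-weighted centroid of the active cells
#' lying within `toe_radius` of the anchor cell — the cell nearest the
#' intended target centre among cells carrying at least
#' `anchor_min_frac` of the region's peak force (a lightly grazing flesh
#' band must not anchor the toe). For a compact region (everything
#' within `toe_radius`) this reduces to the region's COP; for a
#' whole-foot contact it isolates the toe from the heel.
#'
#' @inheritParams cop_location
#' @param intended_center Numeric `c(x, y)` mm of the aimed-at target.
#' @param cfg A [detection_config()] (supplies `toe_radius`).
#' @return Numeric `c(x, y)` in mm.
#' @export
endpoint_location <- function(region, geometry, intended_center,
                              cfg = detection_config()) {
  if (is.null(region) || nrow(region$cells) == 0L)
    stop("endpoint_location: empty active region")
  pts <- cell_to_point(region$cells[, 1], region$cells[, 2], geometry)
  d_target <- sqrt((pts[, 1] - intended_center[1])^2 +
                     (pts[, 2] - intended_center[2])^2)
  eligible <- region$forces >= cfg$anchor_min_frac * max(region$forces)
  ext <- which(eligible)[which.min(d_target[eligible])]
  d_ext <- sqrt((pts[, 1] - pts[ext, 1])^2 + (pts[, 2] - pts[ext, 2])^2)
  sel <- d_ext <= cfg$toe_radius
  w <- region$forces[sel]
  c(x = sum(pts[sel, 1] * w) / sum(w), y = sum(pts[sel, 2] * w) / sum(w))
}

#' Contact surface of an active region
#'
#' Number of active cells times the cell area, in cm^2: one 8 mm cell
#' contributes 0.64 cm^2.
#'
#' @inheritParams cop_location
#' @return Area in cm^2.
#' @export
contact_surface <- function(region, geometry) {
  if (is.null(region) || nrow(region$cells) == 0L)
    stop("contact_surface: empty active region")
  nrow(region$cells) * (geometry$cell_pitch / 10)^2
}

#' Time of touch within an episode
#'
#' The touch is timed at the first frame in the episode at which the
#' endpoint location is closest to the intended target's centre; exact
#' ties go to the earlier frame.
#'
#' @param episode One episode from [detect_episodes()].
#' @param rec The source [recording()].
#' @param intended_center Numeric `c(x, y)` mm of the aimed-at target.
#' @param cfg A [detection_config()].
#' @return The 1-based frame index of the touch.
#' @export
time_of_touch <- function(episode, rec, intended_center,
                          cfg = detection_config()) {
  span <- episode$start_frame:episode$end_frame
  d <- vapply(seq_along(span), function(i) {
    ep <- endpoint_location(episode$regions[[i]], rec$geometry,
                            intended_center, cfg)
    sqrt(sum((ep - intended_center)^2))
  }, 0)
  span[which.min(d)]  # which.min returns the first minimum: earliest frame
}

#' Infer which target an episode was aimed at
#'
#' If the final-frame contact lies inside a target zone, that zone's
#' target is the intended one. Otherwise (a between-zone drag) the
#' alternation protocol decides: the opposite of the previous scored
#' (in/out) touch's target, or the proximal target for the first episode
#' of a trial.
#'
#' @inheritParams time_of_touch
#' @param previous_target `"proximal"`, `"distal"`, or `NULL` if no in/out
#'   touch precedes this episode.
#' @return `"proximal"` or `"distal"`.
#' @export
infer_intended_target <- function(episode, rec, previous_target = NULL) {
  last_region <- episode$regions[[length(episode$regions)]]
  pos <- cop_location(last_region, rec$geometry)
  zone <- classify_zone(pos, rec$layout)
  if (zone != "between") return(zone)
  if (is.null(previous_target)) "proximal"
  else if (previous_target == "proximal") "distal" else "proximal"
}

#' Detect and characterise all touches in a recording
#'
#' Runs the full per-trial detection pipeline: episode segmentation, one
#' touch event per episode, intended-target inference by zone/alternation,
#' time-of-touch selection, then endpoint, COP, contact surface, zone and
#' in/out classification at the touch frame. Deterministic: the same
#' recording and configuration always yield the same table.
#'
#' @inheritParams detect_episodes
#' @return A data frame with one row per touch: `touch_index`,
#'   `touch_frame`, `t_touch_s`, `intended_target`, `endpoint_x_mm`,
#'   `endpoint_y_mm`, `cop_x_mm`, `cop_y_mm`, `surface_cm2`, `zone`,
#'   `hit` (`"in"`, `"out"` or `"between"`).
#' @export
detect_touches <- function(rec, cfg = detection_config()) {
  episodes <- detect_episodes(rec, cfg)
  out <- vector("list", length(episodes))
  prev_target <- NULL
  for (i in seq_along(episodes)) {
    ep <- episodes[[i]]
    intended <- infer_intended_target(ep, rec, prev_target)
    center <- if (intended == "proximal") rec$layout$proximal_center
              else rec$layout$distal_center
    tf <- time_of_touch(ep, rec, center, cfg)
    region <- ep$regions[[tf - ep$start_frame + 1L]]
    endpoint <- endpoint_location(region, rec$geometry, center, cfg)
    cop <- cop_location(region, rec$geometry)
    zone <- classify_zone(endpoint, rec$layout)
    if (zone != "between" && zone != intended) {
      # the endpoint settled in the other target's zone: score it there
      intended <- zone
      center <- if (intended == "proximal") rec$layout$proximal_center
                else rec$layout$distal_center
    }
    hit <- if (zone == "between") "between"
           else classify_hit(endpoint, center, rec$layout$target_radius)
    if (hit != "between") prev_target <- intended
    out[[i]] <- data.frame(
      touch_index = i, touch_frame = tf, t_touch_s = rec$times[tf],
      intended_target = intended,
      endpoint_x_mm = unname(endpoint[1]), endpoint_y_mm = unname(endpoint[2]),
      cop_x_mm = unname(cop[1]), cop_y_mm = unname(cop[2]),
      surface_cm2 = contact_surface(region, rec$geometry),
      zone = zone, hit = hit)
  }
  if (!length(out))
    return(data.frame(touch_index = integer(), touch_frame = integer(),
                      t_touch_s = numeric(), intended_target = character(),
                      endpoint_x_mm = numeric(), endpoint_y_mm = numeric(),
                      cop_x_mm = numeric(), cop_y_mm = numeric(),
                      surface_cm2 = numeric(), zone = character(),
                      hit = character()))
  do.call(rbind, out)
}
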
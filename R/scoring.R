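#' Zone and in/out classification
#'
#' `classify_zone()` assigns a point to the proximal-target, distal-target
#' or between-target zone. Zones are bands along y only (a touch far off
#' to the side of a target is still in that target's zone, and is then
#' classified out-of-target by the disc test): proximal when
#' `|y - y_proximal| <= zone_half_width`, distal likewise, else between.
#' Bands are closed, so a point exactly on a boundary belongs to the
#' target zone — boundary conventions favour the participant.
#'
#' `classify_hit()` labels a zoned touch `"in"` when its Euclidean
#' distance to the target centre is at most the target radius (closed
#' disc), else `"out"`.
#'
#' @param point Numeric `c(x, y)` in mm.
#' @param layout A [target_layout()].
#' @return `classify_zone()`: `"proximal"`, `"distal"` or `"between"`.
#' @export
classify_zone <- function(point, layout) {
  y <- point[2]
  if (abs(y - layout$proximal_center[2]) <= layout$zone_half_width)
    "proximal"
  else if (abs(y - layout$distal_center[2]) <= layout$zone_half_width)
    "distal"
  else "between"
}

#' @param target_center Numeric `c(x, y)` in mm.
#' @param radius Target disc radius in mm.
#' @rdname classify_zone
#' @export
classify_hit <- function(point, target_center, radius) {
  if (absolute_error(point[1], point[2],
                     target_center[1], target_center[2]) <= radius)
    "in"
  else "out"
}

#' Accuracy and consistency error measures
#'
#' `absolute_error()` is the Euclidean distance of a touch position from
#' the target centre, `sqrt((X_i - X_target)^2 + (Y_i - Y_target)^2)` —
#' the accuracy of a single touch, computed separately for the endpoint
#' and the COP.
#'
#' `variable_error()` is each touch's Euclidean distance from the mean
#' position of all repetitions aimed at the same target with the same
#' leg, `sqrt((X_i - Xbar)^2 + (Y_i - Ybar)^2)` — the consistency of the
#' touch set. It is undefined for fewer than two touches and then returns
#' `NA` rather than erroring (a participant who manages a single touch
#' per target simply has no variable error).
#'
#' @param x,y Touch coordinates in mm (vectorised).
#' @param target_x,target_y Target centre in mm.
#' @return A numeric vector of distances in mm.
#' @export
absolute_error <- function(x, y, target_x, target_y) {
  sqrt((x - target_x)^2 + (y - target_y)^2)
}

#' @rdname absolute_error
#' @export
variable_error <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) return(rep(NA_real_, length(x)))
  sqrt((x - mean(x))^2 + (y - mean(y))^2)
}

#' Endpoint-to-COP distance
#'
#' Euclidean distance between the endpoint (big-toe) location and the
#' centre of pressure at the time of touch; zero exactly when the two
#' coincide. Congruent endpoint and COP indicate a controlled placement;
#' a large separation indicates whole-foot, less dexterous contact.
#'
#' @param endpoint,cop Numeric `c(x, y)` in mm, or n x 2 matrices.
#' @return Distance(s) in mm.
#' @export
endpoint_cop_distance <- function(endpoint, cop) {
  if (is.matrix(endpoint))
    sqrt((endpoint[, 1] - cop[, 1])^2 + (endpoint[, 2] - cop[, 2])^2)
  else
    sqrt(sum((endpoint - cop)^2))
}

#' Per-touch error parameters for a detected touch table
#'
#' Augments the table from [detect_touches()] with the error measures:
#' absolute error of endpoint and COP from the touched target's centre,
#' endpoint-COP distance, and variable error of endpoint and COP within
#' each leg-and-target group. Between-target touches carry `NA` for all
#' parameters (they are drags, not aimed touches); variable error is
#' computed over the in/out touches of each target and is `NA` when a
#' target has fewer than two such touches.
#'
#' @param touches Data frame from [detect_touches()].
#' @param layout The [target_layout()] the touches were scored under.
#' @return The input with columns `abs_err_ep_mm`, `abs_err_cop_mm`,
#'   `ep_cop_dist_mm`, `var_err_ep_mm`, `var_err_cop_mm` appended.
#' @export
touch_metrics <- function(touches, layout) {
  n <- nrow(touches)
  res <- touches
  res$abs_err_ep_mm <- rep(NA_real_, n)
  res$abs_err_cop_mm <- rep(NA_real_, n)
  res$ep_cop_dist_mm <- rep(NA_real_, n)
  res$var_err_ep_mm <- rep(NA_real_, n)
  res$var_err_cop_mm <- rep(NA_real_, n)
  if (n == 0L) return(res)
  scored <- res$hit %in% c("in", "out")
  for (tgt in c("proximal", "distal")) {
    center <- if (tgt == "proximal") layout$proximal_center
              else layout$distal_center
    sel <- scored & res$intended_target == tgt
    if (!any(sel)) next
    res$abs_err_ep_mm[sel] <- absolute_error(
      res$endpoint_x_mm[sel], res$endpoint_y_mm[sel], center[1], center[2])
    res$abs_err_cop_mm[sel] <- absolute_error(
      res$cop_x_mm[sel], res$cop_y_mm[sel], center[1], center[2])
    res$ep_cop_dist_mm[sel] <- endpoint_cop_distance(
      cbind(res$endpoint_x_mm[sel], res$endpoint_y_mm[sel]),
      cbind(res$cop_x_mm[sel], res$cop_y_mm[sel]))
    res$var_err_ep_mm[sel] <- variable_error(res$endpoint_x_mm[sel],
                                             res$endpoint_y_mm[sel])
    res$var_err_cop_mm[sel] <- variable_error(res$cop_x_mm[sel],
                                              res$cop_y_mm[sel])
  }
  res
}

#' Summarise one trial
#'
#' Counts the in-, out- and between-target touches (their sum always
#' equals the number of detected episodes), reports the traditional score
#' — the number of in-target touches in the 20 s trial — and the trial
#' means of the motor-performance parameters. Parameter means are taken
#' over the scored touches only: by default the in and out touches
#' (`params_scope = "in_out"`), optionally the in touches alone; between
#' touches never contribute. Variable errors are computed within each
#' target and averaged across the leg's scored touches.
#'
#' @param metrics Data frame from [touch_metrics()].
#' @param meta Named list of trial metadata (`subject`, `group`, `leg`).
#' @param params_scope `"in_out"` (default) or `"in_only"`.
#' @return An object of class `trial_summary`: counts, per-target counts,
#'   `traditional_score`, parameter means, and the metadata.
#' @export
summarize_trial <- function(metrics, meta = list(),
                            params_scope = c("in_out", "in_only")) {
  params_scope <- match.arg(params_scope)
  counts <- c(`in` = sum(metrics$hit == "in"),
              out = sum(metrics$hit == "out"),
              between = sum(metrics$hit == "between"))
  per_target <- lapply(c(proximal = "proximal", distal = "distal"),
    function(tgt) {
      sel <- metrics$intended_target == tgt & metrics$hit != "between"
      c(`in` = sum(metrics$hit[sel] == "in"),
        out = sum(metrics$hit[sel] == "out"))
    })
  scope <- if (params_scope == "in_only") metrics$hit == "in"
           else metrics$hit %in% c("in", "out")
  mean_or_na <- function(v) {
    v <- v[scope]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  structure(list(
    counts = counts,
    per_target = per_target,
    traditional_score = unname(counts["in"]),
    mean_surface_cm2 = mean_or_na(metrics$surface_cm2),
    mean_ep_cop_dist_mm = mean_or_na(metrics$ep_cop_dist_mm),
    mean_abs_err_ep_mm = mean_or_na(metrics$abs_err_ep_mm),
    mean_abs_err_cop_mm = mean_or_na(metrics$abs_err_cop_mm),
    mean_var_err_ep_mm = mean_or_na(metrics$var_err_ep_mm),
    mean_var_err_cop_mm = mean_or_na(metrics$var_err_cop_mm),
    n_touches = nrow(metrics),
    params_scope = params_scope,
    meta = meta), class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat("<trial_summary>")
  if (length(x$meta))
    cat(" ", paste(names(x$meta), unlist(x$meta), sep = "=",
                   collapse = ", "))
  cat("\n  counts: in =", x$counts["in"], " out =", x$counts["out"],
      " between =", x$counts["between"],
      " | traditional score =", x$traditional_score, "\n")
  cat(sprintf(paste0("  means: surface %.2f cm2, ep-cop %.1f mm, ",
                     "abs err (ep/cop) %.1f/%.1f mm, ",
                     "var err (ep/cop) %.1f/%.1f mm\n"),
              x$mean_surface_cm2, x$mean_ep_cop_dist_mm,
              x$mean_abs_err_ep_mm, x$mean_abs_err_cop_mm,
              x$mean_var_err_ep_mm, x$mean_var_err_cop_mm))
  invisible(x)
}

#' Score a recording end to end
#'
#' Convenience wrapper: [detect_touches()], [touch_metrics()] and
#' [summarize_trial()] in one call.
#'
#' @inheritParams detect_episodes
#' @inheritParams summarize_trial
#' @return A list with `touches` (the per-touch metrics table) and
#'   `summary` (the [summarize_trial()] result).
#' @export
score_recording <- function(rec, cfg = detection_config(),
                            params_scope = "in_out") {
  touches <- detect_touches(rec, cfg)
  metrics <- touch_metrics(touches, rec$layout)
  list(touches = metrics,
       summary = summarize_trial(metrics, meta = rec$meta,
                                 params_scope = params_scope))
}

#' Write a per-touch table to CSV
#'
#' One row per touch with subject/group/leg identification prepended, in
#' the exchange schema shared by the command-line tools. A header comment
#' records the target radius in force of the run.
#'
#' @param metrics Data frame from [touch_metrics()].
#' @param meta Named list with `subject`, `group`, `leg`.
#' @param path Output CSV path.
#' @param layout The [target_layout()] used (its radius is echoed).
#' @return `path`, invisibly.
#' @export
write_touch_table <- function(metrics, meta, path, layout) {
  tab <- cbind(data.frame(subject = meta$subject %||% NA,
                          group = meta$group %||% NA,
                          leg = meta$leg %||% NA),
               metrics)
  con <- file(path, "wt")
  writeLines(sprintf("# target_radius_mm=%g zone_half_width_mm=%g",
                     layout$target_radius, layout$zone_half_width), con)
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
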
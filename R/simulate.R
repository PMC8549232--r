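#' Default simulated mat geometry
#'
#' A grid large enough to hold both targets, endpoint scatter, heel
#' contacts behind the proximal target and between-target drags: 88 x 32
#' sensors at the reference 8 mm pitch and 60 Hz, with the origin cell
#' placed so the mat spans roughly -176..520 mm along y and -120..128 mm
#' along x.
#'
#' @return A [mat_geometry()].
#' @export
default_sim_geometry <- function() {
  mat_geometry(88, 32, cell_pitch = 8, sampling_rate = 60,
               origin_cell = c(22, 15), y_axis = "+row")
}

#' Simulation configuration
#'
#' Parameters of the synthetic-trial generator. The generator emulates
#' the standard test: alternating proximal/distal big-toe touches for
#' `trial_duration` seconds, each rendered as an isotropic 2-D Gaussian
#' pressure blob (truncated at the activation threshold) that dwells
#' `dwell_frames` frames after a 1-frame approach ramp, plus optional
#' between-target drag contacts, a ball-of-foot counter-blob that shifts
#' the COP away from the toe, an optional heel blob connected through a
#' low-force arch band, and i.i.d. sub-threshold sensor noise.
#'
#' @param trial_duration Trial length in s (default 20, the test
#'   protocol).
#' @param touch_rate Scheduled touches per second (default 1.5; healthy
#'   adults reach ~1.8/s, stroke ~1.0/s).
#' @param endpoint_bias Constant aiming bias in mm: either `c(x, y)` for
#'   both targets or `list(proximal = , distal = )`.
#' @param endpoint_scatter_sd Per-axis SD of the endpoint around
#'   target + bias, mm; scalar or `c(proximal, distal)`.
#' @param cop_offset_mean,cop_offset_sd Per-touch COP displacement from
#'   the endpoint, mm (drawn from a normal truncated at 0, directed
#'   towards the body, i.e. -y); realised by a ball-of-foot blob rendered
#'   `ball_offset` mm behind the toe with its force scaled so the
#'   whole-contact force balance puts the COP near the drawn offset.
#' @param ball_offset Anatomical distance from the big-toe pad to the
#'   ball of the foot along -y, mm (default 70).
#' @param blob_peak,blob_sd Peak force (device units) and spatial SD (mm)
#'   of the toe blob. The default (peak 100, SD 3.5) truncates at a
#'   ~10.6 mm radius — a big-toe pad roughly 2-3 sensor cells across,
#'   compact enough to sit inside the endpoint toe-localisation radius.
#' @param blob_trunc Forces below this are zeroed when rendering
#'   (default 1, the default activation threshold).
#' @param p_between Probability of an extra between-zone drag contact per
#'   reach.
#' @param heel_contact Logical; render a heel blob plus connecting arch
#'   band (default FALSE).
#' @param heel_offset Heel distance behind the toe along -y, mm.
#' @param noise_sd SD of i.i.d. Gaussian sensor noise (device units),
#'   truncated at 0; keep below `blob_trunc` so noise stays sub-threshold.
#' @param dwell_frames Contact duration in frames including the ramp
#'   (default 9, i.e. 150 ms at 60 Hz).
#' @param seed Integer seed; every random draw of the generator flows
#'   from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(trial_duration = 20, touch_rate = 1.5,
                              endpoint_bias = c(0, 0),
                              endpoint_scatter_sd = 10,
                              cop_offset_mean = 10, cop_offset_sd = 4,
                              ball_offset = 70,
                              blob_peak = 100, blob_sd = 3.5,
                              blob_trunc = 1,
                              p_between = 0, heel_contact = FALSE,
                              heel_offset = 100, noise_sd = 0,
                              dwell_frames = 9, seed = NULL) {
  stopifnot(trial_duration > 0, touch_rate > 0,
            all(endpoint_scatter_sd >= 0), cop_offset_sd >= 0,
            ball_offset > 0, blob_peak > 0, blob_sd > 0, blob_trunc > 0,
            p_between >= 0, p_between <= 1, heel_offset > 0,
            noise_sd >= 0, dwell_frames >= 2)
  structure(list(trial_duration = trial_duration, touch_rate = touch_rate,
                 endpoint_bias = endpoint_bias,
                 endpoint_scatter_sd = endpoint_scatter_sd,
                 cop_offset_mean = cop_offset_mean,
                 cop_offset_sd = cop_offset_sd,
                 ball_offset = ball_offset,
                 blob_peak = blob_peak, blob_sd = blob_sd,
                 blob_trunc = blob_trunc, p_between = p_between,
                 heel_contact = heel_contact, heel_offset = heel_offset,
                 noise_sd = noise_sd,
                 dwell_frames = as.integer(dwell_frames), seed = seed),
            class = "simulation_config")
}

bias_for <- function(cfg, target) {
  b <- cfg$endpoint_bias
  if (is.list(b)) as.numeric(b[[target]]) else as.numeric(b)
}

scatter_for <- function(cfg, target) {
  s <- cfg$endpoint_scatter_sd
  if (length(s) == 2L) {
    if (!is.null(names(s))) unname(s[target])
    else if (target == "proximal") s[1] else s[2]
  } else s
}

# Add one truncated-Gaussian blob to a frame matrix. Errors if the
# truncation disc does not fit on the mat.
render_blob <- function(m, center, peak, sd_mm, geometry, trunc,
                        touch_index = NA) {
  r_max <- sd_mm * sqrt(2 * log(peak / trunc))
  p <- geometry$cell_pitch
  lims <- rbind(center - r_max, center + r_max)
  cells <- tryCatch(point_to_cell(lims[, 1], lims[, 2], geometry),
                    error = function(e)
                      stop("touch ", touch_index,
                           ": pressure blob leaves the mat bounds", call. = FALSE))
  rows <- (min(cells[, "row"]):max(cells[, "row"])) + 1L
  cols <- (min(cells[, "col"]):max(cells[, "col"])) + 1L
  pts <- cell_to_point(rep(rows - 1L, times = length(cols)),
                       rep(cols - 1L, each = length(rows)), geometry)
  d2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2
  f <- peak * exp(-d2 / (2 * sd_mm^2))
  f[f < trunc] <- 0
  m[rows, cols] <- m[rows, cols] + matrix(f, length(rows), length(cols))
  m
}

# low-force band of cells along the toe->heel segment so the two blobs
# form one connected contact region, as a real foot arch does
render_arch <- function(m, from, to, geometry, force = 3) {
  len <- sqrt(sum((to - from)^2))
  steps <- seq(0, 1, length.out = max(2L, ceiling(len / 4)))
  xy <- cbind(from[1] + steps * (to[1] - from[1]),
              from[2] + steps * (to[2] - from[2]))
  idx <- unique(point_to_cell(xy[, 1], xy[, 2], geometry)) + 1L
  m[idx] <- pmax(m[idx], force)
  m
}

#' Simulate one test recording with ground truth
#'
#' Generates a synthetic pressure-mat recording of one trial under the
#' given configuration and returns it together with the exact truth used
#' to build it: per scheduled contact the intended target, true endpoint,
#' true COP (force-weighted mean of the rendered contact frame before
#' noise), rendered cell count, and the zone/hit labels obtained by
#' applying the configured layout to the true endpoint; plus per-trial
#' in/out/between counts.
#'
#' @param cfg A [simulation_config()].
#' @param layout A [target_layout()].
#' @param geometry A [mat_geometry()]; must be large enough for the
#'   configured blobs, or the offending touch index is named in an error.
#' @param meta Trial metadata list passed into the recording.
#' @return A list with `recording` (a [recording()]) and `truth` (list
#'   with a per-contact `touches` data frame and a `counts` vector).
#' @export
simulate_recording <- function(cfg = simulation_config(),
                               layout = target_layout(),
                               geometry = default_sim_geometry(),
                               meta = list()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  rate <- geometry$sampling_rate
  n_frames <- round(cfg$trial_duration * rate)
  fpt <- rate / cfg$touch_rate  # frames per scheduled reach
  if (fpt < cfg$dwell_frames + 2)
    stop("touch_rate too high for dwell_frames at this sampling rate")
  n_touch <- floor((n_frames - 1) / fpt - 1e-9) + 1L
  starts <- 1L + round((seq_len(n_touch) - 1L) * fpt)
  n_touch <- sum(starts + cfg$dwell_frames - 1L <= n_frames)
  starts <- starts[seq_len(n_touch)]

  frames <- lapply(seq_len(n_frames),
                   function(i) matrix(0, geometry$n_rows, geometry$n_cols))
  truth_rows <- list()

  add_contact <- function(center, intended, start, n_dwell, idx,
                          with_ramp = TRUE, kind = "touch") {
    # ramp frame: blob short of the target along the approach direction
    full <- matrix(0, geometry$n_rows, geometry$n_cols)
    full <- render_blob(full, center, cfg$blob_peak, cfg$blob_sd, geometry,
                        cfg$blob_trunc, idx)
    if (kind == "touch") {
      offs <- max(0, stats::rnorm(1, cfg$cop_offset_mean, cfg$cop_offset_sd))
      offs <- min(offs, 0.45 * cfg$ball_offset)
      if (offs >= 2) {
        # light ball-of-foot contact at the anatomical distance, its
        # force chosen so the lever balance puts the COP ~offs behind
        # the toe; connected to the toe through a low-force band, as
        # continuous flesh is
        ball <- center + c(0, -cfg$ball_offset)
        ball_peak <- cfg$blob_peak * offs / (cfg$ball_offset - offs)
        full <- render_blob(full, ball, max(ball_peak, cfg$blob_trunc + 0.5),
                            cfg$blob_sd, geometry, cfg$blob_trunc, idx)
        full <- render_arch(full, center, ball, geometry)
      }
      if (cfg$heel_contact) {
        heel <- center + c(0, -cfg$heel_offset)
        full <- render_blob(full, heel, 0.7 * cfg$blob_peak,
                            1.8 * cfg$blob_sd, geometry, cfg$blob_trunc, idx)
        full <- render_arch(full, center, heel, geometry)
      }
    }
    act <- which(full >= cfg$blob_trunc, arr.ind = TRUE)
    pts <- cell_to_point(act[, 1] - 1L, act[, 2] - 1L, geometry)
    w <- full[act]
    cop <- c(sum(pts[, 1] * w), sum(pts[, 2] * w)) / sum(w)
    span <- start:(start + n_dwell - 1L)
    if (with_ramp) {
      # the landing frame undershoots: 12 mm radially outward from the
      # target through the settled endpoint, so it is always farther
      # from the target than the dwell frames
      tgt_center <- if (intended == "proximal") layout$proximal_center
                    else layout$distal_center
      u <- center - tgt_center
      if (sqrt(sum(u^2)) < 1e-9)
        u <- if (intended == "proximal") c(0, 1) else c(0, -1)
      else u <- u / sqrt(sum(u^2))
      ramp <- render_blob(matrix(0, geometry$n_rows, geometry$n_cols),
                          center + 12 * u, 0.5 * cfg$blob_peak, cfg$blob_sd,
                          geometry, cfg$blob_trunc, idx)
      frames[[span[1]]] <<- frames[[span[1]]] + ramp
      for (f in span[-1]) frames[[f]] <<- frames[[f]] + full
      touch_frame <- span[2]
    } else {
      for (f in span) frames[[f]] <<- frames[[f]] + full
      touch_frame <- span[1]
    }
    list(cop = cop, n_cells = nrow(act), touch_frame = touch_frame)
  }

  targets <- rep(c("proximal", "distal"), length.out = n_touch)
  idx <- 0L
  for (k in seq_len(n_touch)) {
    tgt <- targets[k]
    center <- if (tgt == "proximal") layout$proximal_center
              else layout$distal_center
    ep <- center + bias_for(cfg, tgt) +
      stats::rnorm(2, 0, scatter_for(cfg, tgt))
    idx <- idx + 1L
    info <- add_contact(ep, tgt, starts[k], cfg$dwell_frames, idx)
    zone <- classify_zone(ep, layout)
    hit <- if (zone == "between") "between"
           else classify_hit(ep, center, layout$target_radius)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      index = idx, kind = "touch", intended_target = tgt,
      touch_frame = info$touch_frame,
      true_x = ep[1], true_y = ep[2],
      true_cop_x = info$cop[1], true_cop_y = info$cop[2],
      n_cells = info$n_cells, zone = zone, hit = hit)
    # optional drag contact on the way to the next target
    if (k < n_touch && cfg$p_between > 0 &&
        stats::runif(1) < cfg$p_between) {
      ds <- starts[k] + round(fpt / 2)
      if (ds >= starts[k] + cfg$dwell_frames + 1L &&
          ds + 2L <= starts[k + 1L] - 2L) {
        mid_y <- (layout$proximal_center[2] + layout$zone_half_width +
                  layout$distal_center[2] - layout$zone_half_width) / 2
        dp <- c(stats::rnorm(1, 0, 15),
                stats::runif(1, mid_y - 25, mid_y + 25))
        idx <- idx + 1L
        info <- add_contact(dp, tgt, ds, 2L, idx, with_ramp = FALSE,
                            kind = "drag")
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          index = idx, kind = "drag", intended_target = targets[k + 1L],
          touch_frame = info$touch_frame,
          true_x = dp[1], true_y = dp[2],
          true_cop_x = info$cop[1], true_cop_y = info$cop[2],
          n_cells = info$n_cells, zone = classify_zone(dp, layout),
          hit = "between")
      }
    }
  }

  if (cfg$noise_sd > 0) {
    nr <- geometry$n_rows; nc <- geometry$n_cols
    for (i in seq_len(n_frames))
      frames[[i]] <- frames[[i]] +
        pmax(0, matrix(stats::rnorm(nr * nc, 0, cfg$noise_sd), nr, nc))
  }

  touches <- do.call(rbind, truth_rows)
  counts <- c(`in` = sum(touches$hit == "in"),
              out = sum(touches$hit == "out"),
              between = sum(touches$hit == "between"))
  rec <- recording(geometry, layout, times = (seq_len(n_frames) - 1) / rate,
                   frames = frames, duration = cfg$trial_duration,
                   meta = meta)
  list(recording = rec,
       truth = list(touches = touches, counts = counts,
                    config = cfg, layout = layout))
}

#' Emulate a human tester's in-target count
#'
#' Field testers tend to over-count: they register movements rather than
#' in-target contacts, so the bias grows with the touch total. The
#' emulated count is the true in-target count plus a binomial overcount
#' with the given per-contact rate.
#'
#' @param truth The `truth` element of [simulate_recording()], or any
#'   list with `counts` and a `touches` data frame.
#' @param miscount_rate Per-contact probability of an extra count, in
#'   `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Integer emulated manual count.
#' @export
emulate_manual_count <- function(truth, miscount_rate, seed = NULL) {
  stopifnot(miscount_rate >= 0, miscount_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth$touches)
  unname(truth$counts["in"] + stats::rbinom(1, n, miscount_rate))
}

#' Per-leg generator parameters for cohort simulation
#'
#' @param touch_rate Reaches per second.
#' @param scatter_sd Endpoint scatter SD per axis, mm.
#' @param cop_offset_mean,cop_offset_sd COP displacement draw, mm.
#' @param surface_cm2 Median contact surface, cm^2.
#' @param surface_cv Lognormal coefficient of variation of the surface.
#' @param p_between Per-reach drag probability.
#' @return A named list of class `leg_params`.
#' @export
leg_params <- function(touch_rate = 1.6, scatter_sd = 10,
                       cop_offset_mean = 10, cop_offset_sd = 4,
                       surface_cm2 = 6, surface_cv = 0.25,
                       p_between = 0.05) {
  structure(list(touch_rate = touch_rate, scatter_sd = scatter_sd,
                 cop_offset_mean = cop_offset_mean,
                 cop_offset_sd = cop_offset_sd,
                 surface_cm2 = surface_cm2, surface_cv = surface_cv,
                 p_between = p_between), class = "leg_params")
}

#' Cohort effect profiles
#'
#' `cohort_profile_null()` gives every group x leg cell identical
#' parameters (for calibration studies); `cohort_profile_study()` mirrors
#' the qualitative clinical pattern: stroke subjects reach more slowly,
#' scatter more (worst in the paretic leg), land with a larger surface
#' and a larger endpoint-COP offset, and drag between targets more often.
#'
#' @param subject_sd_log_rate,subject_sd_log_err Between-subject SDs of
#'   the log touch rate and log error scale (shared by both legs, the
#'   random-intercept structure of the analysis models).
#' @param miscount_rate Tester overcount probability per contact.
#' @return A list of class `cohort_profile` with one [leg_params()] per
#'   group x leg cell.
#' @export
cohort_profile_null <- function(subject_sd_log_rate = 0.15,
                                subject_sd_log_err = 0.12,
                                miscount_rate = 0.05) {
  lp <- leg_params()
  structure(list(stroke = list(first = lp, second = lp),
                 control = list(first = lp, second = lp),
                 subject_sd_log_rate = subject_sd_log_rate,
                 subject_sd_log_err = subject_sd_log_err,
                 miscount_rate = miscount_rate),
            class = "cohort_profile")
}

#' @rdname cohort_profile_null
#' @export
cohort_profile_study <- function(subject_sd_log_rate = 0.15,
                                 subject_sd_log_err = 0.12,
                                 miscount_rate = 0.06) {
  structure(list(
    stroke = list(
      first = leg_params(touch_rate = 1.0, scatter_sd = 15.5,
                         cop_offset_mean = 16, cop_offset_sd = 6,
                         surface_cm2 = 7.5, p_between = 0.20),
      second = leg_params(touch_rate = 1.25, scatter_sd = 13,
                          cop_offset_mean = 14, cop_offset_sd = 5,
                          surface_cm2 = 7.0, p_between = 0.13)),
    control = list(
      first = leg_params(touch_rate = 1.85, scatter_sd = 9.5,
                         cop_offset_mean = 10, cop_offset_sd = 4,
                         surface_cm2 = 6.0, p_between = 0.02),
      second = leg_params(touch_rate = 1.75, scatter_sd = 9.5,
                          cop_offset_mean = 10, cop_offset_sd = 4,
                          surface_cm2 = 6.0, p_between = 0.02)),
    subject_sd_log_rate = subject_sd_log_rate,
    subject_sd_log_err = subject_sd_log_err,
    miscount_rate = miscount_rate), class = "cohort_profile")
}

#' Simulate a two-group cohort observation table
#'
#' Draws per-subject latent rate and error scales, then per leg simulates
#' the touch endpoints and COPs analytically (no frame rendering) and
#' reduces them with the package's own error formulas, yielding the
#' subject-leg observation table the statistics layer consumes. The
#' `first` leg of a stroke subject is the paretic leg; of a control, the
#' dominant leg — matching the protocol's testing order and the
#' paretic/dominant pairing used in the leg factor.
#'
#' Set `render = TRUE` to additionally build one [simulation_config()]
#' per subject-leg (attribute `"configs"`) from which full recordings can
#' be generated with [simulate_recording()].
#'
#' @param n_stroke,n_control Subjects per group (each contributes 2
#'   rows).
#' @param profile A [cohort_profile_null()]-style profile.
#' @param duration Trial length in s.
#' @param layout A [target_layout()].
#' @param include_clinical Add plausible `fugl_meyer`, `tug_s`,
#'   `walk_10m` columns (stroke rows only).
#' @param render Attach per-row simulation configs.
#' @param seed Integer seed.
#' @return A data frame (one row per subject-leg) with counts, parameter
#'   means and `manual_count`; attributes `profile` and `seed`.
#' @export
simulate_cohort <- function(n_stroke = 20, n_control = 20,
                            profile = cohort_profile_study(),
                            duration = 20, layout = target_layout(),
                            include_clinical = TRUE, render = FALSE,
                            seed = NULL) {
  stopifnot(n_stroke >= 2, n_control >= 2,
            inherits(profile, "cohort_profile"))
  if (!is.null(seed)) set.seed(seed)
  leg_names <- list(stroke = c("paretic", "non-paretic"),
                    control = c("dominant", "non-dominant"))
  rows <- list(); configs <- list()
  sid <- 0L
  for (group in c("stroke", "control")) {
    ns <- if (group == "stroke") n_stroke else n_control
    for (s in seq_len(ns)) {
      sid <- sid + 1L
      u_rate <- stats::rnorm(1, 0, profile$subject_sd_log_rate)
      u_err <- stats::rnorm(1, 0, profile$subject_sd_log_err)
      for (l in 1:2) {
        lp <- profile[[group]][[l]]
        rate <- lp$touch_rate * exp(u_rate)
        scatter <- lp$scatter_sd * exp(u_err)
        n_reach <- max(2L, stats::rpois(1, rate * duration))
        tgt <- rep(c("proximal", "distal"), length.out = n_reach)
        centers <- rbind(layout$proximal_center, layout$distal_center)[
          ifelse(tgt == "proximal", 1, 2), , drop = FALSE]
        ep <- centers + matrix(stats::rnorm(2 * n_reach, 0, scatter),
                               ncol = 2)
        zone <- apply(ep, 1, classify_zone, layout = layout)
        d <- absolute_error(ep[, 1], ep[, 2], centers[, 1], centers[, 2])
        hit <- ifelse(zone == "between", "between",
                      ifelse(d <= layout$target_radius, "in", "out"))
        offs <- pmax(0, stats::rnorm(n_reach, lp$cop_offset_mean,
                                     lp$cop_offset_sd))
        cop <- cbind(ep[, 1], ep[, 2] - offs)
        n_drag <- stats::rbinom(1, n_reach, lp$p_between)
        scored <- hit != "between"
        var_ep <- rep(NA_real_, n_reach)
        var_cop <- rep(NA_real_, n_reach)
        for (tg in c("proximal", "distal")) {
          sel <- scored & tgt == tg
          if (sum(sel) >= 2) {
            var_ep[sel] <- variable_error(ep[sel, 1], ep[sel, 2])
            var_cop[sel] <- variable_error(cop[sel, 1], cop[sel, 2])
          }
        }
        abs_cop <- absolute_error(cop[, 1], cop[, 2],
                                  centers[, 1], centers[, 2])
        surface <- stats::rlnorm(n_reach, log(lp$surface_cm2),
                                 lp$surface_cv)
        in_count <- sum(hit == "in")
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sprintf("S%02d", sid), group = group,
          leg = leg_names[[group]][l],
          in_count = in_count, out_count = sum(hit == "out"),
          between_count = sum(zone == "between") + n_drag,
          surface_cm2 = mean(surface[scored]),
          ep_cop_dist_mm = mean(offs[scored]),
          abs_err_ep_mm = mean(d[scored]),
          abs_err_cop_mm = mean(abs_cop[scored]),
          var_err_ep_mm = if (all(is.na(var_ep))) NA_real_
                          else mean(var_ep[scored], na.rm = TRUE),
          var_err_cop_mm = if (all(is.na(var_cop))) NA_real_
                           else mean(var_cop[scored], na.rm = TRUE),
          manual_count = in_count +
            stats::rbinom(1, n_reach + n_drag, profile$miscount_rate))
        if (render)
          configs[[length(configs) + 1L]] <- simulation_config(
            trial_duration = duration, touch_rate = rate,
            endpoint_scatter_sd = scatter,
            cop_offset_mean = lp$cop_offset_mean,
            cop_offset_sd = lp$cop_offset_sd,
            p_between = lp$p_between)
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (include_clinical) {
    tab$fugl_meyer <- NA_real_; tab$tug_s <- NA_real_
    tab$walk_10m <- NA_real_
    st <- tab$group == "stroke"
    # impairment tracks error magnitude; gait speed tracks the count
    tab$fugl_meyer[st] <- pmin(34, pmax(10, round(
      46 - 6 * log(tab$var_err_cop_mm[st]) + stats::rnorm(sum(st), 0, 2))))
    tab$tug_s[st] <- pmax(6, 4 + 220 / pmax(2, tab$in_count[st]) +
                            stats::rnorm(sum(st), 0, 3))
    tab$walk_10m[st] <- pmax(0.2, 0.04 * tab$in_count[st] +
                               stats::rnorm(sum(st), 0.3, 0.1))
  }
  attr(tab, "profile") <- profile
  attr(tab, "seed") <- seed
  if (render) attr(tab, "configs") <- configs
  tab
}
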
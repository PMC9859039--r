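#' Simulation configuration for synthetic TIRF movies
#'
#' Defines the conditions of a simulated surface-templated nucleation
#' assay: the nucleation kinetics, a constant plus-end growth speed, the
#' imaging plane and sampling, and the random stream for placement and
#' orientation. Defaults follow the deterministic simulation of the
#' assay: MTs appear on a 40x40-pixel plane at the discrete-time rate
#' law, each at a random position with one of eight discrete
#' orientations, and elongate at a constant speed; frames are sampled
#' every 2 s for 300 s.
#'
#' @param kinetics a [nucleation_kinetics()] object (single phase), or a
#'   `count_trajectory` to drive births from (e.g. a two-phase
#'   trajectory).
#' @param growth_speed plus-end growth speed, um/min (constant for all
#'   MTs). Default 1.5 um/min, a typical templated-assay speed.
#' @param plane_px plane size in pixels, `c(nx, ny)`; default
#'   `c(40, 40)`; each side must be >= 8.
#' @param pixel_size um per pixel; default 0.1587 (a 40 um field over
#'   252 pixels).
#' @param dt_sim kinetics integration step, s; default 1.
#' @param frame_interval imaging interval, s; default 2; must be >=
#'   `dt_sim`.
#' @param duration total time, s; default 300.
#' @param n_orientations number of discrete growth directions (equally
#'   spaced, starting at 0 degrees); default 8.
#' @param templated_fraction fraction of MTs nucleated from an anchored
#'   template (minus end fixed); the rest are "spontaneous" and grow
#'   from both ends. Default 1.
#' @param minus_speed_fraction minus-end speed of spontaneous MTs as a
#'   fraction of `growth_speed`; default 0.5 (minus ends elongate more
#'   slowly than plus ends).
#' @param seed integer seed for the placement/orientation stream.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(kinetics,
                              growth_speed = 1.5,
                              plane_px = c(40, 40),
                              pixel_size = 0.1587,
                              dt_sim = 1,
                              frame_interval = 2,
                              duration = 300,
                              n_orientations = 8,
                              templated_fraction = 1,
                              minus_speed_fraction = 0.5,
                              seed = 1L) {
  if (!inherits(kinetics, c("nucleation_kinetics", "count_trajectory")))
    stop("'kinetics' must be nucleation_kinetics or a count_trajectory",
         call. = FALSE)
  .check_scalar(growth_speed, "growth_speed", lower = 0, strict = TRUE)
  if (length(plane_px) != 2L || any(plane_px < 8))
    stop("'plane_px' must be c(nx, ny) with both sides >= 8", call. = FALSE)
  .check_scalar(pixel_size, "pixel_size", lower = 0, strict = TRUE)
  .check_scalar(dt_sim, "dt_sim", lower = 0, strict = TRUE)
  .check_scalar(frame_interval, "frame_interval", lower = dt_sim)
  .check_scalar(duration, "duration", lower = 0, strict = TRUE)
  if (templated_fraction < 0 || templated_fraction > 1)
    stop("'templated_fraction' must be in [0, 1]", call. = FALSE)
  structure(list(kinetics = kinetics, growth_speed = growth_speed,
                 plane_px = as.integer(plane_px), pixel_size = pixel_size,
                 dt_sim = dt_sim, frame_interval = frame_interval,
                 duration = duration,
                 n_orientations = as.integer(n_orientations),
                 templated_fraction = templated_fraction,
                 minus_speed_fraction = minus_speed_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Evaluate (or pass through) the driving count trajectory of a config.
.config_trajectory <- function(config) {
  if (inherits(config$kinetics, "count_trajectory")) config$kinetics
  else nucleation_trajectory(config$kinetics, config$duration, config$dt_sim)
}

# Run a block with a private RNG stream, restoring the caller's state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Simulate microtubule tracks
#'
#' Turns the (real-valued) discrete-time nucleation trajectory into
#' whole MT tracks: fractional births accumulate and a track is spawned
#' each time the accumulated count crosses an integer (floor with a
#' 1e-6 snap against floating-point shortfall near saturation). Each
#' track gets a uniform position on the plane, one of the discrete
#' orientations, and an anchored/spontaneous class drawn with
#' `templated_fraction`. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A list with `tracks` (data frame: `id`, `birth_time_s`,
#'   `x_px`, `y_px`, `orientation_deg`, `class`) and `trajectory`, the
#'   driving real-valued count trajectory.
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  traj <- .config_trajectory(config)
  n_int <- floor(traj$count + 1e-6)
  births <- diff(c(0, n_int))
  birth_times <- rep(traj$time_s, times = pmax(0, births))
  n <- length(birth_times)
  tracks <- .with_seed(config$seed, {
    if (n == 0L) {
      data.frame(id = integer(), birth_time_s = numeric(),
                 x_px = numeric(), y_px = numeric(),
                 orientation_deg = numeric(), class = character())
    } else {
      angles <- (seq_len(config$n_orientations) - 1L) *
        360 / config$n_orientations
      data.frame(
        id = seq_len(n),
        birth_time_s = birth_times,
        x_px = runif(n, 0, config$plane_px[1] - 1),
        y_px = runif(n, 0, config$plane_px[2] - 1),
        orientation_deg = sample(angles, n, replace = TRUE),
        class = ifelse(runif(n) < config$templated_fraction,
                       "templated", "spontaneous"))
    }
  })
  list(tracks = tracks, trajectory = traj)
}

# Liang-Barsky clipping of segment p0->p1 to [0, xmax] x [0, ymax].
# Returns NULL when fully outside, else endpoints and retained fraction.
.clip_segment <- function(p0, p1, xmax, ymax) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  p <- c(-d[1], d[1], -d[2], d[2])
  q <- c(p0[1], xmax - p0[1], p0[2], ymax - p0[2])
  for (i in 1:4) {
    if (p[i] == 0) {
      if (q[i] < 0) return(NULL)
    } else {
      r <- q[i] / p[i]
      if (p[i] < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
    }
  }
  if (t0 > t1) return(NULL)
  list(p0 = p0 + t0 * d, p1 = p0 + t1 * d, fraction = t1 - t0)
}

#' Track geometry at a time point
#'
#' Computes, for every track alive at time `t`, the true minus- and
#' plus-end positions (pixels, continuous), the segment clipped to the
#' imaging plane for rendering, and true and in-plane lengths.
#' Anchored (templated) tracks keep their minus end at the nucleation
#' site; spontaneous tracks also extend their minus end at
#' `minus_speed_fraction * growth_speed`. Tracks whose ends leave the
#' plane are flagged `censored`; their true length is retained.
#'
#' @param tracks track table from [simulate_tracks()].
#' @param t time, s (>= 0).
#' @param config the [simulation_config()] used to make the tracks.
#' @return Data frame with one row per live track: ids, endpoint
#'   coordinates (`mx`, `my`, `px`, `py` true; `cx0 ... cy1` clipped,
#'   NA when fully out of plane), `length_um` (true),
#'   `inplane_length_um`, and `censored`.
#' @export
grow_tracks <- function(tracks, t, config) {
  .check_scalar(t, "t", lower = 0)
  live <- tracks[tracks$birth_time_s <= t, , drop = FALSE]
  n <- nrow(live)
  v_um_s <- config$growth_speed / 60
  xmax <- config$plane_px[1] - 1
  ymax <- config$plane_px[2] - 1
  out <- data.frame(id = live$id, class = live$class,
                    mx = numeric(n), my = numeric(n),
                    px = numeric(n), py = numeric(n),
                    cx0 = rep(NA_real_, n), cy0 = rep(NA_real_, n),
                    cx1 = rep(NA_real_, n), cy1 = rep(NA_real_, n),
                    length_um = numeric(n),
                    inplane_length_um = numeric(n),
                    censored = logical(n))
  if (n == 0L) return(out)
  th <- live$orientation_deg * pi / 180
  dir <- cbind(cos(th), sin(th))
  age <- t - live$birth_time_s
  plus_um <- v_um_s * age
  minus_um <- ifelse(live$class == "spontaneous",
                     config$minus_speed_fraction * v_um_s * age, 0)
  for (i in seq_len(n)) {
    o <- c(live$x_px[i], live$y_px[i])
    pplus <- o + dir[i, ] * plus_um[i] / config$pixel_size
    pminus <- o - dir[i, ] * minus_um[i] / config$pixel_size
    out$mx[i] <- pminus[1]; out$my[i] <- pminus[2]
    out$px[i] <- pplus[1];  out$py[i] <- pplus[2]
    out$length_um[i] <- plus_um[i] + minus_um[i]
    cl <- .clip_segment(pminus, pplus, xmax, ymax)
    if (!is.null(cl)) {
      out$cx0[i] <- cl$p0[1]; out$cy0[i] <- cl$p0[2]
      out$cx1[i] <- cl$p1[1]; out$cy1[i] <- cl$p1[2]
      out$inplane_length_um[i] <- cl$fraction * out$length_um[i]
    }
    out$censored[i] <- out$inplane_length_um[i] < out$length_um[i] - 1e-9
  }
  out
}

#' Ground truth for a simulated movie
#'
#' Per-frame record of the simulation: live tracks with end positions
#' and lengths, the cumulative (integerized) nucleation count, and the
#' total in-plane MT length (the quantity a mass trace is proportional
#' to).
#'
#' @param sim result of [simulate_tracks()].
#' @param config the [simulation_config()].
#' @return List of class `ground_truth`: `counts` (data frame `time_s`,
#'   `count`), `total_inplane_um` per frame, `frames` (list of
#'   [grow_tracks()] tables), `tracks`, `frame_times`.
#' @export
ground_truth <- function(sim, config) {
  frame_times <- seq(0, config$duration, by = config$frame_interval)
  frames <- lapply(frame_times, function(t) grow_tracks(sim$tracks, t, config))
  counts <- vapply(frame_times,
                   function(t) sum(sim$tracks$birth_time_s <= t), numeric(1))
  structure(list(
    counts = data.frame(time_s = frame_times, count = counts),
    total_inplane_um = vapply(frames,
                              function(f) sum(f$inplane_length_um), numeric(1)),
    frames = frames, tracks = sim$tracks, frame_times = frame_times),
    class = "ground_truth")
}

#' Write ground truth to disk
#'
#' The track table goes to `<stem>_tracks.csv`, per-frame summaries
#' (cumulative count, total in-plane length) to `<stem>_truth.json`.
#'
#' @param gt a [ground_truth()] object.
#' @param stem output path stem.
#' @return Invisibly, the two paths written.
#' @export
write_ground_truth <- function(gt, stem) {
  csv <- paste0(stem, "_tracks.csv")
  js <- paste0(stem, "_truth.json")
  write.csv(gt$tracks, csv, row.names = FALSE)
  jsonlite::write_json(
    list(frame_times = gt$frame_times,
         counts = gt$counts$count,
         total_inplane_um = gt$total_inplane_um),
    js, digits = NA, auto_unbox = TRUE)
  invisible(c(tracks = csv, truth = js))
}
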
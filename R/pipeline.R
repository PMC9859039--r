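#' Per-frame microtubule mass trace
#'
#' Measures total MT signal over time the way the assay's mass macro
#' does: each frame is thresholded with Otsu's method, sub-threshold
#' pixels are zeroed, and the mean intensity of the whole (masked)
#' frame is recorded; the first-frame mean is then subtracted from all
#' frames as background. Before masking, the frame median (camera
#' offset plus diffuse background) is removed, so supra-threshold
#' pixels contribute their fluorophore signal only; this keeps the
#' masked whole-frame mean proportional to total polymer signal - the
#' quantity "MT mass" denotes - even when the thresholded area
#' fluctuates. When a control trace is supplied, the corrected trace
#' is additionally divided by the control's corrected value at
#' `reference_time`, giving the normalized fold-mass.
#'
#' Frames on which the threshold is undefined (constant intensity, e.g.
#' a blank movie) are recorded as 0.
#'
#' @param movie a `movie_stack` with at least 2 frames.
#' @param control optional `mass_trace` of the buffer control.
#' @param reference_time normalization time, s; default 300.
#' @param smooth compute the Otsu mask on a 3x3 mean-smoothed copy of
#'   the frame (intensities are still read from the raw frame); makes
#'   the mask far more stable under camera noise. Default TRUE.
#' @return A data frame of class `mass_trace` with columns `time_s`,
#'   `raw_mean` (masked per-frame mean), `corrected`, `normalized`
#'   (NA without a control).
#' @export
measure_mass_trace <- function(movie, control = NULL, reference_time = 300,
                               smooth = TRUE) {
  stopifnot(inherits(movie, "movie_stack"))
  if (length(movie$frames) < 2L)
    stop("mass trace needs at least 2 frames", call. = FALSE)
  raw <- vapply(movie$frames, function(f) {
    ref <- if (smooth)
      as.matrix(EBImage::filter2(EBImage::Image(f), matrix(1 / 9, 3, 3),
                                 boundary = "replicate"))
    else f
    th <- threshold_otsu(ref)
    if (is.na(th)) return(0)
    mean((f - median(f)) * (ref > th))
  }, numeric(1))
  corrected <- raw - raw[1L]
  normalized <- rep(NA_real_, length(raw))
  if (!is.null(control)) {
    stopifnot(inherits(control, "mass_trace"))
    i <- which.min(abs(control$time_s - reference_time))
    ref <- control$corrected[i]
    if (!is.finite(ref) || ref <= 0)
      stop("control trace is not positive at the reference time",
           call. = FALSE)
    normalized <- corrected / ref
  }
  structure(data.frame(time_s = movie$times, raw_mean = raw,
                       corrected = corrected, normalized = normalized),
            class = c("mass_trace", "data.frame"))
}

# Bilinear interpolation at continuous 0-based (x, y); NA outside.
.interp <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, nx - 1); y1 <- pmin(y0 + 1, ny - 1)
  ok <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1
  out <- rep(NA_real_, length(x))
  i <- which(ok)
  if (length(i)) {
    out[i] <- img[cbind(y0[i] + 1, x0[i] + 1)] * (1 - fx[i]) * (1 - fy[i]) +
      img[cbind(y0[i] + 1, x1[i] + 1)] * fx[i] * (1 - fy[i]) +
      img[cbind(y1[i] + 1, x0[i] + 1)] * (1 - fx[i]) * fy[i] +
      img[cbind(y1[i] + 1, x1[i] + 1)] * fx[i] * fy[i]
  }
  out
}

#' Count plus-end spots in a frame
#'
#' Implements the spot-counting macro used to score MT number from a
#' plus-end marker channel: crop a window, smooth with a 3x3 mean
#' filter, threshold with Yen's method, outline the binary mask with a
#' Sobel gradient (so each particle becomes a closed edge ring), and
#' count connected components within a size band. Two spots closer
#' than the resolution limit merge into one component and are counted
#' once.
#'
#' @param frame numeric matrix (one movie frame), camera units.
#' @param pixel_size um per pixel.
#' @param window_um crop size `c(w, h)` in um (default `c(50, 50)`, the
#'   assay's counting window), or `NULL` for the full frame. The window
#'   must fit inside the frame.
#' @param window_origin_um top-left corner of the crop, um.
#' @param min_px,max_px component size band in pixels; default 2-200.
#' @return List of class `spot_count`: `count`, `window_px`, `labels`
#'   (labelled edge image of the crop).
#' @export
count_plus_end_spots <- function(frame, pixel_size, window_um = c(50, 50),
                                 window_origin_um = c(0, 0),
                                 min_px = 2, max_px = 200) {
  ny <- nrow(frame); nx <- ncol(frame)
  if (is.null(window_um)) {
    xs <- 1:nx; ys <- 1:ny
    window_px <- c(0, 0, nx - 1, ny - 1)
  } else {
    x0 <- round(window_origin_um[1] / pixel_size)
    y0 <- round(window_origin_um[2] / pixel_size)
    x1 <- x0 + round(window_um[1] / pixel_size) - 1
    y1 <- y0 + round(window_um[2] / pixel_size) - 1
    if (x0 < 0 || y0 < 0 || x1 > nx - 1 || y1 > ny - 1)
      stop("counting window does not fit in the frame", call. = FALSE)
    xs <- (x0 + 1):(x1 + 1); ys <- (y0 + 1):(y1 + 1)
    window_px <- c(x0, y0, x1, y1)
  }
  crop <- frame[ys, xs, drop = FALSE]
  out <- structure(list(count = 0L, window_px = window_px, labels = NULL),
                   class = "spot_count")
  sm <- as.matrix(EBImage::filter2(EBImage::Image(crop),
                                   matrix(1 / 9, 3, 3),
                                   boundary = "replicate"))
  th <- threshold_yen(sm)
  if (is.na(th)) return(out)
  mask <- (sm > th) * 1
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(EBImage::Image(mask), kx,
                                   boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(EBImage::Image(mask), t(kx),
                                   boundary = "replicate"))
  edge <- sqrt(gx^2 + gy^2) > 1e-6
  lab <- EBImage::bwlabel(EBImage::Image(edge * 1))
  lab <- as.matrix(lab)
  sizes <- tabulate(lab[lab > 0])
  out$count <- sum(sizes >= min_px & sizes <= max_px)
  out$labels <- lab
  out
}

#' Spot counts over a whole movie
#'
#' Applies [count_plus_end_spots()] to every frame.
#'
#' @param movie a `movie_stack` (typically the plus-end channel).
#' @param ... passed to [count_plus_end_spots()].
#' @return Data frame with `time_s` and `count`.
#' @export
count_spots_movie <- function(movie, ...) {
  counts <- vapply(movie$frames, function(f)
    count_plus_end_spots(f, movie$pixel_size, ...)$count, integer(1))
  data.frame(time_s = movie$times, count = counts)
}

#' Extract a kymograph along a line
#'
#' Builds the space-time plot of intensity along a polyline: the line
#' is resampled at 1-pixel spacing and, at each position and frame,
#' the maximum intensity across `width_px` parallel offsets
#' (perpendicular to the line) is taken. Positions outside the frame
#' are dropped from the maximum.
#'
#' @param movie a `movie_stack`.
#' @param line numeric matrix or data frame with columns (x, y), >= 2
#'   points, pixel coordinates within the frame.
#' @param width_px integration width in pixels; default 3.
#' @return An object of class `kymograph`: `matrix`
#'   (position x frame), `positions_px` (arclength), `times`, `line`,
#'   `pixel_size`, `frame_interval`.
#' @export
extract_kymograph <- function(movie, line, width_px = 3) {
  stopifnot(inherits(movie, "movie_stack"))
  line <- as.matrix(line)
  if (nrow(line) < 2L) stop("'line' needs at least 2 points", call. = FALSE)
  seg <- diff(line)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  if (total <= 0) stop("'line' has zero length", call. = FALSE)
  s_grid <- seq(0, total, by = 1)
  cum <- c(0, cumsum(seg_len))
  # position and unit tangent at each arclength sample
  pts <- matrix(0, length(s_grid), 2)
  tan_v <- matrix(0, length(s_grid), 2)
  for (i in seq_along(s_grid)) {
    j <- max(1L, min(findInterval(s_grid[i], cum, rightmost.closed = TRUE),
                     nrow(seg)))
    f <- (s_grid[i] - cum[j]) / seg_len[j]
    pts[i, ] <- line[j, ] + f * seg[j, ]
    tan_v[i, ] <- seg[j, ] / seg_len[j]
  }
  normal <- cbind(-tan_v[, 2], tan_v[, 1])
  offsets <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, by = 1)
  mat <- matrix(NA_real_, length(s_grid), length(movie$frames))
  for (fi in seq_along(movie$frames)) {
    img <- movie$frames[[fi]]
    prof <- matrix(NA_real_, length(s_grid), length(offsets))
    for (oi in seq_along(offsets))
      prof[, oi] <- .interp(img, pts[, 1] + offsets[oi] * normal[, 1],
                            pts[, 2] + offsets[oi] * normal[, 2])
    mat[, fi] <- apply(prof, 1, function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  }
  structure(list(matrix = mat, positions_px = s_grid, times = movie$times,
                 line = line, pixel_size = movie$pixel_size,
                 frame_interval = movie$frame_interval),
            class = "kymograph")
}

# Detected signal extent (low/high boundary, 1-based position index)
# per frame, from a global Otsu threshold on the kymograph.
.kymo_edges <- function(kymo) {
  m <- kymo$matrix
  th <- threshold_otsu(m[!is.na(m)])
  n_frames <- ncol(m)
  low <- high <- rep(NA_real_, n_frames)
  if (!is.na(th)) {
    for (f in seq_len(n_frames)) {
      idx <- which(!is.na(m[, f]) & m[, f] > th)
      if (length(idx)) { low[f] <- min(idx); high[f] <- max(idx) }
    }
  }
  list(low = low, high = high, threshold = th,
       valid = which(!is.na(low)))
}

# Is one boundary of the signal extent a growing edge?
.edge_motion <- function(pos, times, valid, min_disp_px) {
  if (length(valid) < 3L) return(list(growing = FALSE, slope = NA_real_,
                                      disp = NA_real_))
  p <- pos[valid]; tt <- times[valid]
  disp <- p[length(p)] - p[1]
  slope <- unname(coef(lm(p ~ tt))[2])
  list(growing = abs(disp) >= min_disp_px && sign(slope) == sign(disp) &&
         abs(slope) > 0, slope = slope, disp = disp)
}

#' Classify a kymograph as templated or spontaneous
#'
#' A templated (surface-nucleated) MT has an anchored minus end, so its
#' kymograph shows a single growing edge while the opposite boundary
#' stays put (a right-triangle wedge). A spontaneously nucleated MT
#' elongates at both ends, producing two growing edges (a scalene
#' wedge). The signal extent per frame is found with a global Otsu
#' threshold; a boundary counts as growing when it moves at least
#' `min_disp_px` with a consistently signed fitted slope.
#'
#' @param kymo a [extract_kymograph()] record.
#' @param min_disp_px minimum boundary displacement, px; default 2.
#' @return `"templated"`, `"spontaneous"`, or `"indeterminate"` (no
#'   growing edge; such records are excluded from rate counts).
#' @export
classify_nucleation <- function(kymo, min_disp_px = 2) {
  stopifnot(inherits(kymo, "kymograph"))
  ed <- .kymo_edges(kymo)
  lo <- .edge_motion(ed$low, kymo$times, ed$valid, min_disp_px)
  hi <- .edge_motion(ed$high, kymo$times, ed$valid, min_disp_px)
  n_grow <- lo$growing + hi$growing
  if (n_grow == 0L) {
    .log_msg("kymograph: no growing edge detected; classified indeterminate")
    return("indeterminate")
  }
  if (n_grow == 1L) "templated" else "spontaneous"
}

#' Growth speed and maximum length from a kymograph
#'
#' The growing edge (the boundary with the larger displacement) is
#' fitted by least squares against time; the slope, converted with the
#' pixel size, is the growth speed in um/min. The maximum length is
#' the largest end-to-end signal extent observed. The record is
#' flagged censored when the signal reaches either end of the line
#' (the true length then exceeds the measured one).
#'
#' @param kymo a [extract_kymograph()] record.
#' @param min_frames minimum frames with detected signal; default 3.
#' @return List: `growth_speed_um_min`, `max_length_um`, `censored`.
#' @export
growth_speed_and_length <- function(kymo, min_frames = 3) {
  stopifnot(inherits(kymo, "kymograph"))
  ed <- .kymo_edges(kymo)
  if (length(ed$valid) < min_frames)
    stop("kymograph has fewer than 'min_frames' frames with signal",
         call. = FALSE)
  lo <- .edge_motion(ed$low, kymo$times, ed$valid, 0)
  hi <- .edge_motion(ed$high, kymo$times, ed$valid, 0)
  grow <- if (abs(hi$disp) >= abs(lo$disp)) hi else lo
  speed <- abs(grow$slope) * kymo$pixel_size * 60
  max_len <- max(ed$high[ed$valid] - ed$low[ed$valid]) * kymo$pixel_size
  n_pos <- length(kymo$positions_px)
  censored <- any(ed$high[ed$valid] >= n_pos) || any(ed$low[ed$valid] <= 1)
  list(growth_speed_um_min = speed, max_length_um = max_len,
       censored = censored)
}

#' Cumulative nucleation counts from a movie
#'
#' Automated MT discovery by connected-component birth detection: per
#' frame (up to `max_time_s`), the analysis window is optionally
#' smoothed, thresholded, and connected components of at least
#' `min_px` pixels are labelled. A component counts as a new
#' nucleation event when it lies farther than `link_radius_px` from
#' everything detected in the previous frame; its centroid at first
#' detection is recorded as the nucleation origin. The cumulative
#' number of origins per frame is the count trajectory. This is plain
#' birth detection, not comet tracking: it works on a plus-end channel
#' (compact spots of constant brightness from birth) and on a polymer
#' channel (anchored MTs always overlap their previous-frame
#' footprint). An MT born closer than the linking radius to an
#' existing one is merged and missed, so counts are exact only for
#' well-separated events.
#'
#' @param movie a `movie_stack` covering at least `max_time_s`.
#' @param window_px optional crop `c(x0, y0, x1, y1)` (0-based, px);
#'   `NULL` for the full frame.
#' @param max_time_s analysis window end, s; default 150 (the standard
#'   counting window of the assay). The movie must reach it; pass a
#'   smaller value explicitly for shorter movies.
#' @param threshold `"otsu"`, `"yen"`, or a numeric absolute threshold.
#' @param min_px minimum component size, px; default 2.
#' @param link_radius_px linking radius to the previous frame's
#'   detections, px; default 3.
#' @param smooth apply a 3x3 mean filter before thresholding (helps
#'   under camera noise); default TRUE.
#' @param min_contrast_mads a frame is treated as signal-free when the
#'   automatic threshold is less than this many median absolute
#'   deviations above the frame median (guards against thresholding
#'   pure camera noise); default 3.
#' @return List: `trajectory` (a `count_trajectory` over the analyzed
#'   frames) and `origins` (data frame `id`, `birth_time_s`, `x_px`,
#'   `y_px`).
#' @export
count_trajectory_from_movie <- function(movie, window_px = NULL,
                                        max_time_s = 150,
                                        threshold = "otsu", min_px = 2,
                                        link_radius_px = 3, smooth = TRUE,
                                        min_contrast_mads = 3) {
  stopifnot(inherits(movie, "movie_stack"))
  if (max(movie$times) < max_time_s)
    stop(sprintf("movie ends at %g s, before the %g s analysis window; pass max_time_s explicitly",
                 max(movie$times), max_time_s), call. = FALSE)
  sel <- which(movie$times <= max_time_s)
  origins <- data.frame(id = integer(), birth_time_s = numeric(),
                        x_px = numeric(), y_px = numeric())
  counts <- integer(length(sel))
  prev_pix <- NULL   # x/y coordinates of the previous frame's mask
  for (si in seq_along(sel)) {
    f <- movie$frames[[sel[si]]]
    off <- c(0, 0)
    if (!is.null(window_px)) {
      f <- f[(window_px[2] + 1):(window_px[4] + 1),
             (window_px[1] + 1):(window_px[3] + 1), drop = FALSE]
      off <- window_px[1:2]
    }
    if (smooth)
      f <- as.matrix(EBImage::filter2(EBImage::Image(f), matrix(1 / 9, 3, 3),
                                      boundary = "replicate"))
    th <- if (is.numeric(threshold)) threshold
          else if (threshold == "yen") threshold_yen(f) else threshold_otsu(f)
    if (!is.na(th) && !is.numeric(threshold)) {
      noise <- stats::mad(f)
      if (noise > 0 && th < stats::median(f) + min_contrast_mads * noise)
        th <- NA_real_
    }
    cur_pix <- NULL
    if (!is.na(th)) {
      lab <- as.matrix(EBImage::bwlabel(EBImage::Image((f > th) * 1)))
      nlab <- max(lab)
      for (l in seq_len(nlab)) {
        pix <- which(lab == l, arr.ind = TRUE)
        px_x <- pix[, 2] - 1 + off[1]
        px_y <- pix[, 1] - 1 + off[2]
        cur_pix <- rbind(cur_pix, cbind(px_x, px_y))
        if (nrow(pix) >= min_px) {
          known <- FALSE
          if (!is.null(prev_pix) && nrow(prev_pix)) {
            d2min <- min(outer(px_x, prev_pix[, 1], "-")^2 +
                           outer(px_y, prev_pix[, 2], "-")^2)
            known <- d2min <= link_radius_px^2
          }
          if (!known)
            origins[nrow(origins) + 1L, ] <- list(nrow(origins) + 1L,
                                                  movie$times[sel[si]],
                                                  mean(px_x), mean(px_y))
        }
      }
    }
    prev_pix <- cur_pix
    counts[si] <- nrow(origins)
  }
  list(trajectory = count_trajectory(movie$times[sel], counts),
       origins = origins)
}
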
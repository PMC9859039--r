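# Deterministic track layouts and small configs used across tests.
# Tracks are laid out on a grid of horizontal rows so that they never
# cross; this isolates the property under test from track-overlap
# effects, which are exercised (and documented) separately.

noise_free <- function(...) {
  render_settings(noise_model = "none", min_visible_um = 0, ...)
}

grid_tracks <- function(n_templated, n_spontaneous = 0, x0 = 14,
                        row_spacing = 5, y0 = 3, birth_time = 0) {
  n <- n_templated + n_spontaneous
  data.frame(
    id = seq_len(n),
    birth_time_s = rep(birth_time, n),
    x_px = rep(x0, n),
    y_px = y0 + (seq_len(n) - 1) * row_spacing,
    orientation_deg = rep(0, n),
    class = rep(c("templated", "spontaneous"),
                c(n_templated, n_spontaneous)))
}

grid_config <- function(tracks, duration = 120, plane = c(64, 160),
                        pixel_size = 0.25, ...) {
  # kinetics irrelevant when tracks are supplied by hand; any valid one
  simulation_config(nucleation_kinetics(1, 1e9), duration = duration,
                    plane_px = plane, pixel_size = pixel_size, ...)
}

# horizontal kymograph line through one grid track, pre-extended
track_line <- function(tracks, i, config, margin_px = 4, t_end = NULL) {
  if (is.null(t_end)) t_end <- config$duration
  geo <- grow_tracks(tracks, t_end, config)
  j <- which(geo$id == tracks$id[i])
  len_px <- geo$length_um[j] / config$pixel_size
  minus_px <- if (tracks$class[i] == "spontaneous")
    config$minus_speed_fraction * len_px / (1 + config$minus_speed_fraction)
  else 0
  x0 <- max(0, tracks$x_px[i] - minus_px - margin_px)
  x1 <- min(config$plane_px[1] - 1,
            tracks$x_px[i] + len_px - minus_px + margin_px)
  cbind(c(x0, x1), c(tracks$y_px[i], tracks$y_px[i]))
}
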
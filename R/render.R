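#' Rendering settings for synthetic TIRF frames
#'
#' Optics and camera model used to turn abstract MT segments into
#' TIRF-like images. Each MT contributes a line integral of
#' `mt_intensity` per um along its in-plane segment, blurred by a
#' Gaussian point-spread function; sub-resolution objects (newborn MTs)
#' are rendered with an effective length floor of `min_visible_um`, the
#' apparent size of a diffraction-limited object. The optional plus-end
#' channel places a Gaussian comet of fixed peak amplitude at every
#' growing plus end, mimicking an end-binding marker. Camera noise is
#' Poisson shot noise on the signal plus Gaussian read noise, with a
#' constant offset added last; pixel values are quantized to integer
#' camera units.
#'
#' @param psf_sigma Gaussian PSF sigma, um; default 0.17 (lateral
#'   sigma of a high-NA TIRF objective at ~570 nm emission).
#' @param mt_intensity signal per um of polymer, camera units; default
#'   600.
#' @param eb1_channel render a plus-end (comet) channel too; default
#'   FALSE.
#' @param comet_sigma comet Gaussian sigma, um; default 0.17.
#' @param comet_peak comet peak amplitude, camera units; default 400.
#' @param background uniform fluorescence background, camera units;
#'   default 20.
#' @param noise_model one of "none", "gaussian", "poisson-gaussian".
#' @param read_noise_sd Gaussian read noise sigma, camera units;
#'   default 3.
#' @param camera_offset constant camera offset, camera units; default
#'   100.
#' @param bit_depth camera bit depth; default 16.
#' @param min_visible_um effective rendered length floor, um; default
#'   0.2.
#' @return An object of class `render_settings`.
#' @export
render_settings <- function(psf_sigma = 0.17, mt_intensity = 600,
                            eb1_channel = FALSE, comet_sigma = 0.17,
                            comet_peak = 400, background = 20,
                            noise_model = c("poisson-gaussian", "gaussian",
                                            "none"),
                            read_noise_sd = 3, camera_offset = 100,
                            bit_depth = 16, min_visible_um = 0.2) {
  noise_model <- match.arg(noise_model)
  .check_scalar(psf_sigma, "psf_sigma", lower = 0, strict = TRUE)
  for (nm in c("mt_intensity", "comet_sigma", "comet_peak", "background",
               "read_noise_sd", "camera_offset", "min_visible_um"))
    .check_scalar(get(nm), nm, lower = 0)
  structure(list(psf_sigma = psf_sigma, mt_intensity = mt_intensity,
                 eb1_channel = eb1_channel, comet_sigma = comet_sigma,
                 comet_peak = comet_peak, background = background,
                 noise_model = noise_model, read_noise_sd = read_noise_sd,
                 camera_offset = camera_offset, bit_depth = bit_depth,
                 min_visible_um = min_visible_um),
            class = "render_settings")
}

#' Movie stack container
#'
#' A loaded or rendered single-channel image stack together with its
#' calibration: pixel size (um) and frame interval (s).
#'
#' @param frames list of numeric matrices (row = y, column = x), one
#'   per frame, in camera units.
#' @param pixel_size um per pixel.
#' @param frame_interval s between frames.
#' @param channel label, e.g. "tubulin" or "eb1".
#' @param bit_depth camera bit depth used for quantization/IO.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(frames, pixel_size, frame_interval,
                        channel = "tubulin", bit_depth = 16) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  .check_scalar(pixel_size, "pixel_size", lower = 0, strict = TRUE)
  .check_scalar(frame_interval, "frame_interval", lower = 0, strict = TRUE)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 times = (seq_along(frames) - 1) * frame_interval,
                 channel = channel, bit_depth = bit_depth),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("movie_stack '%s': %d frames of %dx%d px, %g um/px, %g s/frame\n",
              x$channel, length(x$frames), d[2], d[1],
              x$pixel_size, x$frame_interval))
  invisible(x)
}

# Deposit a weighted point into an accumulator matrix by bilinear
# spreading; coordinates 0-based, (x right, y down).
.deposit <- function(img, x, y, w) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  for (k in seq_along(x)) {
    ix <- x0[k]; iy <- y0[k]
    for (dxy in list(c(0, 0, (1 - fx[k]) * (1 - fy[k])),
                     c(1, 0, fx[k] * (1 - fy[k])),
                     c(0, 1, (1 - fx[k]) * fy[k]),
                     c(1, 1, fx[k] * fy[k]))) {
      cx <- ix + dxy[1]; cy <- iy + dxy[2]
      if (cx >= 0 && cx < nx && cy >= 0 && cy < ny)
        img[cy + 1, cx + 1] <- img[cy + 1, cx + 1] + w[k] * dxy[3]
    }
  }
  img
}

# Rasterize one clipped segment: total deposited intensity equals
# intensity_per_um * inplane_len_um exactly (split over samples).
.draw_segment <- function(img, p0, p1, inplane_len_um, intensity_per_um) {
  total <- intensity_per_um * inplane_len_um
  if (total <= 0) return(img)
  len_px <- sqrt(sum((p1 - p0)^2))
  n <- max(1L, ceiling(len_px / 0.25))
  ts <- (seq_len(n) - 0.5) / n
  xs <- p0[1] + ts * (p1[1] - p0[1])
  ys <- p0[2] + ts * (p1[2] - p0[2])
  .deposit(img, xs, ys, rep(total / n, n))
}

# Gaussian comet at a plus end (amplitude model, not a line integral).
.draw_comet <- function(img, x, y, sigma_px, peak) {
  ny <- nrow(img); nx <- ncol(img)
  r <- ceiling(4 * sigma_px)
  xs <- max(0, floor(x) - r):min(nx - 1, ceiling(x) + r)
  ys <- max(0, floor(y) - r):min(ny - 1, ceiling(y) + r)
  if (length(xs) == 0 || length(ys) == 0) return(img)
  g <- outer(ys - y, xs - x, function(dy, dx)
    peak * exp(-(dx^2 + dy^2) / (2 * sigma_px^2)))
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + g
  img
}

.blur <- function(img, sigma_px) {
  # circular-boundary Gaussian convolution (flux conserving)
  as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma_px))
}

#' Render a synthetic TIRF movie
#'
#' Renders the tracks of a simulation into one (or two) image stacks.
#' Per frame: each live MT's clipped segment is rasterized as a line
#' integral of `mt_intensity` per um and blurred with the Gaussian PSF;
#' the uniform background is added; noise is applied according to the
#' noise model; the camera offset is added last and pixel values are
#' quantized to integers in `[0, 2^bit_depth - 1]`. With
#' `render$eb1_channel = TRUE`, a second stack marks every in-plane
#' plus end with a Gaussian comet. Identical config, settings and seed
#' give bit-identical stacks.
#'
#' @param sim result of [simulate_tracks()].
#' @param config the [simulation_config()].
#' @param render a [render_settings()].
#' @param seed seed for the noise stream; default `config$seed + 1`.
#' @return A `movie_stack` (tubulin channel); if `render$eb1_channel`,
#'   a list with components `tubulin` and `eb1`.
#' @export
render_movie <- function(sim, config, render = render_settings(),
                         seed = config$seed + 1L) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(render, "render_settings"))
  frame_times <- seq(0, config$duration, by = config$frame_interval)
  nx <- config$plane_px[1]; ny <- config$plane_px[2]
  sigma_px <- render$psf_sigma / config$pixel_size
  comet_px <- render$comet_sigma / config$pixel_size
  maxval <- 2^render$bit_depth - 1

  tub <- vector("list", length(frame_times))
  eb1 <- if (render$eb1_channel) vector("list", length(frame_times))
  for (fi in seq_along(frame_times)) {
    geo <- grow_tracks(sim$tracks, frame_times[fi], config)
    img <- matrix(0, ny, nx)
    for (i in seq_len(nrow(geo))) {
      if (is.na(geo$cx0[i])) next
      eff_len <- max(geo$inplane_length_um[i], render$min_visible_um)
      img <- .draw_segment(img, c(geo$cx0[i], geo$cy0[i]),
                           c(geo$cx1[i], geo$cy1[i]),
                           eff_len, render$mt_intensity)
    }
    img <- .blur(img, sigma_px) + render$background
    tub[[fi]] <- img
    if (render$eb1_channel) {
      cimg <- matrix(0, ny, nx)
      for (i in seq_len(nrow(geo))) {
        x <- geo$px[i]; y <- geo$py[i]
        if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1) next
        cimg <- .draw_comet(cimg, x, y, comet_px, render$comet_peak)
      }
      eb1[[fi]] <- cimg + render$background
    }
  }

  finish <- function(frames) {
    .with_seed(seed, lapply(frames, function(img) {
      img <- switch(render$noise_model,
        "none" = img,
        "gaussian" = img + rnorm(length(img), 0, render$read_noise_sd),
        "poisson-gaussian" = {
          shot <- matrix(rpois(length(img), lambda = pmax(0, img)),
                         nrow(img), ncol(img))
          shot + rnorm(length(img), 0, render$read_noise_sd)
        })
      img <- img + render$camera_offset
      matrix(pmin(maxval, pmax(0, round(img))), nrow(img), ncol(img))
    }))
  }
  mk <- function(frames, channel)
    movie_stack(finish(frames), config$pixel_size, config$frame_interval,
                channel = channel, bit_depth = render$bit_depth)
  if (render$eb1_channel)
    list(tubulin = mk(tub, "tubulin"), eb1 = mk(eb1, "eb1"))
  else mk(tub, "tubulin")
}

#' Write / read a movie stack as multi-frame TIFF
#'
#' Pixel values are stored as 16-bit (or `bit_depth`-bit) samples; the
#' calibration (pixel size, frame interval, channel, bit depth) goes to
#' a JSON sidecar `<path>.meta.json`, since baseline TIFF tags cannot
#' carry it portably. `read_movie` restores camera units; calibration
#' is taken from the sidecar or from the explicit arguments (which
#' override).
#'
#' @param movie a `movie_stack`.
#' @param path TIFF file path.
#' @param pixel_size,frame_interval calibration overrides for
#'   `read_movie` when no sidecar exists.
#' @return `write_movie`: the path, invisibly. `read_movie`: a
#'   `movie_stack`.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  maxval <- 2^movie$bit_depth - 1
  tiff::writeTIFF(lapply(movie$frames, function(f) f / maxval), path,
                  bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(pixel_size_um = movie$pixel_size,
         frame_interval_s = movie$frame_interval,
         channel = movie$channel, bit_depth = movie$bit_depth),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path, pixel_size = NULL, frame_interval = NULL) {
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
  if (is.null(frame_interval)) frame_interval <- meta$frame_interval_s
  if (is.null(pixel_size) || is.null(frame_interval))
    stop("no calibration sidecar found; supply pixel_size and frame_interval",
         call. = FALSE)
  bit_depth <- if (!is.null(meta$bit_depth)) meta$bit_depth else 16
  channel <- if (!is.null(meta$channel)) meta$channel else "unknown"
  raw <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(raw)) raw <- list(raw)
  frames <- lapply(raw, function(f) round(f * (2^bit_depth - 1)))
  movie_stack(frames, pixel_size, frame_interval, channel = channel,
              bit_depth = bit_depth)
}
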
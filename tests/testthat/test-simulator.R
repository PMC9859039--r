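test_that("track births follow the integerized trajectory", {
  # zero rate -> no tracks
  cfg0 <- simulation_config(nucleation_kinetics(0, 10), duration = 30)
  expect_identical(nrow(simulate_tracks(cfg0)$tracks), 0L)
  # linear regime: one birth per second
  cfg1 <- simulation_config(nucleation_kinetics(1, 1e9), duration = 10)
  tr1 <- simulate_tracks(cfg1)$tracks
  expect_equal(nrow(tr1), 10L)
  expect_equal(tr1$birth_time_s, 1:10)
  # saturating case, birth times pinned from the integerized recursion
  cfg2 <- simulation_config(nucleation_kinetics(2, 4), duration = 50)
  tr2 <- simulate_tracks(cfg2)$tracks
  expect_equal(nrow(tr2), 4L)
  expect_equal(tr2$birth_time_s, c(1, 1, 2, 22))
})

test_that("ground-truth counts match the integerized trajectory", {
  cfg <- simulation_config(nucleation_kinetics(3.7, 25), duration = 100,
                           seed = 3)
  sim <- simulate_tracks(cfg)
  gt <- ground_truth(sim, cfg)
  model <- floor(sim$trajectory$count + 1e-6)
  at_frames <- model[match(gt$counts$time_s, sim$trajectory$time_s)]
  expect_true(all(abs(gt$counts$count - at_frames) <= 1))
})

test_that("placement and orientation are deterministic and uniform", {
  cfg <- simulation_config(nucleation_kinetics(5, 1e9), duration = 100,
                           seed = 21)
  a <- simulate_tracks(cfg)$tracks
  b <- simulate_tracks(cfg)$tracks
  expect_identical(a, b)
  expect_true(all(a$x_px >= 0 & a$x_px <= cfg$plane_px[1] - 1))
  # each of the 8 discrete orientations at frequency 1/8 +- 4 sigma
  n <- nrow(a)
  freq <- table(factor(a$orientation_deg, levels = (0:7) * 45)) / n
  tol <- 4 * sqrt((1 / 8) * (7 / 8) / n)
  expect_length(freq, 8L)
  expect_true(all(abs(freq - 1 / 8) < tol))
})

test_that("track growth is linear with an anchored minus end", {
  tracks <- grid_tracks(1)
  cfg <- grid_config(tracks, duration = 200)
  # zero length at birth
  expect_equal(grow_tracks(tracks, 0, cfg)$length_um, 0)
  # v * dt: 1.5 um/min for 120 s -> 3 um
  g <- grow_tracks(tracks, 120, cfg)
  expect_equal(g$length_um, 3)
  # minus end time-invariant for a templated track
  expect_equal(g$mx, tracks$x_px); expect_equal(g$my, tracks$y_px)
  # strictly increasing length
  lens <- vapply(c(10, 50, 90, 130), function(t)
    grow_tracks(tracks, t, cfg)$length_um, numeric(1))
  expect_true(all(diff(lens) > 0))
})

test_that("segments are clipped to the plane but true length is kept", {
  # 45-degree track nucleated near the corner; independent line-box
  # intersection: from (2,2) the diagonal exits a 64x160 plane at x=63,
  # i.e. after 61*sqrt(2) px
  tracks <- data.frame(id = 1L, birth_time_s = 0, x_px = 2, y_px = 2,
                       orientation_deg = 45, class = "templated")
  cfg <- grid_config(tracks, duration = 200, pixel_size = 0.25)
  t_long <- 61 * sqrt(2) * 0.25 / (1.5 / 60) * 1.2   # 20% past the exit
  g <- grow_tracks(tracks, t_long, cfg)
  expect_true(g$censored)
  expect_lt(g$inplane_length_um, g$length_um)
  expect_equal(g$inplane_length_um, 61 * sqrt(2) * 0.25, tolerance = 1e-9)
  expect_equal(g$length_um, (1.5 / 60) * t_long)
})

test_that("rendering is linear in MT length and reproducible", {
  tracks <- grid_tracks(1)
  cfg <- grid_config(tracks, duration = 120, plane = c(64, 32))
  rs <- noise_free(background = 10)
  mv <- render_movie(list(tracks = tracks), cfg, rs)
  base <- 10 + rs$camera_offset
  # blank first frame (track has zero length, no visibility floor)
  npix <- prod(dim(mv$frames[[1]]))
  tot <- vapply(mv$frames, function(f) sum(f) - base * npix, numeric(1))
  gt <- ground_truth(list(tracks = tracks), cfg)
  fit <- lm(tot ~ 0 + gt$total_inplane_um)
  expect_gt(summary(fit)$r.squared, 0.999)
  # deposited signal per um close to the configured intensity
  expect_equal(unname(coef(fit)), rs$mt_intensity, tolerance = 0.05)
  # bit-identical re-render under the same seed
  mv2 <- render_movie(list(tracks = tracks), cfg, rs)
  expect_identical(mv$frames, mv2$frames)
})

test_that("a rendered MT has the expected blurred extent", {
  # one 5 um horizontal track, psf 0.2 um, pixel 0.1 um
  tracks <- data.frame(id = 1L, birth_time_s = 0, x_px = 20, y_px = 20,
                       orientation_deg = 0, class = "templated")
  cfg <- simulation_config(nucleation_kinetics(1, 1e9), duration = 200,
                           plane_px = c(100, 40), pixel_size = 0.1,
                           frame_interval = 200)
  # 5 um at 1.5 um/min takes 200 s
  rs <- noise_free(psf_sigma = 0.2, background = 0)
  mv <- render_movie(list(tracks = tracks), cfg, rs)
  f <- mv$frames[[2]] - rs$camera_offset
  th <- threshold_otsu(f)
  cols <- which(apply(f > th, 2, any)) - 1
  extent_um <- (max(cols) - min(cols)) * 0.1
  expect_equal(extent_um, 5, tolerance = 2 * 0.2 / 5)
})

test_that("blank renders are flat and movies reproduce byte-identically", {
  cfg <- simulation_config(nucleation_kinetics(0, 10), duration = 20)
  rs <- noise_free(background = 7)
  mv <- render_movie(simulate_tracks(cfg), cfg, rs)
  expect_true(all(vapply(mv$frames, function(f)
    all(f == 7 + rs$camera_offset), logical(1))))
  # with noise: same seed -> identical TIFF bytes
  cfg2 <- simulation_config(nucleation_kinetics(2, 40), duration = 30,
                            seed = 9)
  sim <- simulate_tracks(cfg2)
  p1 <- tempfile(fileext = ".tif"); p2 <- tempfile(fileext = ".tif")
  write_movie(render_movie(sim, cfg2, render_settings()), p1)
  write_movie(render_movie(sim, cfg2, render_settings()), p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})
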
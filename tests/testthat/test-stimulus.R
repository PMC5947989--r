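test_that("angular subtense follows the looming closed form", {
  p <- loom_params(l_over_v = 50)
  # at t = -(l/|v|) the half-angle is 45 deg, so the full angle is 90
  expect_equal(angular_subtense(-0.05, p), 90)
  # approaching collision the full angle tends to 180 deg
  expect_gt(angular_subtense(-1e-9, p), 179.99)
  # invert t = -(l/|v|) / tan(0.6 deg) for the 1.2 deg onset angle
  t_onset <- -(0.05 / tan(0.6 * pi / 180))
  expect_equal(loom_start_time(p), t_onset, tolerance = 1e-12)
  expect_equal(angular_subtense(t_onset, p), 1.2, tolerance = 1e-9)
  expect_equal(t_onset, -4.7746, tolerance = 1e-4)
  # strictly increasing toward collision
  tt <- seq(-4, -0.01, length.out = 200)
  expect_true(all(diff(angular_subtense(tt, p)) > 0))
  expect_error(angular_subtense(0, p), "collision")
  expect_error(angular_subtense(1, p), "collision")
})

test_that("parameter validation enforces the stimulus invariants", {
  expect_error(loom_params(l_over_v = -5))
  expect_error(loom_params(initial_full_angle = 90, max_full_angle = 80))
  expect_error(loom_params(frame_rate = 0))
  expect_error(loom_params(background_luminance = 64))
  p <- loom_params()
  expect_lt(p$speed_v, 0)
})

test_that("coarse rendering matches the area-coverage rule", {
  p <- small_loom()
  g <- small_grid()
  mv <- render_coarse_loom(p, g)
  lum <- mv$luminance

  # at most 2^bits distinct quantized levels
  expect_lte(length(unique(as.vector(lum))), 2^p$luminance_bits)
  # darkening loom: luminance non-increasing in time for every pixel
  expect_true(all(apply(lum, 1, function(x) all(diff(x) <= 0))))

  # last frame: the square has frozen at 20 deg, half-width 10
  f <- ncol(lum)
  inside <- abs(g$centers$az) <= 9 - 1e-9 & abs(g$centers$el) <= 9 - 1e-9
  outside <- abs(g$centers$az) >= 11 + 1e-9 | abs(g$centers$el) >= 11 + 1e-9
  expect_true(all(lum[inside, f] == p$dark_luminance))
  expect_true(all(lum[outside, ] == p$background_luminance))

  # half-covered pixel: centered on the frozen square's edge
  half <- which(abs(abs(g$centers$az) - 10) < 1e-9 & abs(g$centers$el) < 9)
  mid <- round(p$background_luminance +
                 (p$dark_luminance - p$background_luminance) * 0.5)
  expect_true(all(lum[half, f] == mid))

  # independent area-overlap oracle for one intermediate frame
  f2 <- which.min(abs(angular_subtense(mv$frame_times, p) - 13))
  h <- angular_subtense(mv$frame_times[f2], p) / 2
  frac <- pmax(0, pmin(g$centers$az + 1, h) - pmax(g$centers$az - 1, -h)) *
    pmax(0, pmin(g$centers$el + 1, h) - pmax(g$centers$el - 1, -h)) / 4
  expect_equal(lum[, f2],
               as.integer(round(63 - 63 * frac)))
})

test_that("grid must cover the final stimulus", {
  expect_error(render_coarse_loom(loom_params(max_full_angle = 80),
                                  small_grid()), "cover")
})

test_that("jitter displaces once per presentation without overlap", {
  mv <- render_coarse_loom(small_loom(), small_grid())
  expect_identical(jitter_layout(mv, 0)$layout, mv$layout)
  for (seed in 1:5) {
    j <- jitter_layout(mv, 8, sigma_max = 40, seed = seed)
    expect_false(anyDuplicated(paste(j$layout$az, j$layout$el)) > 0)
    expect_identical(j$luminance, mv$luminance)
    # deterministic given the seed
    j2 <- jitter_layout(mv, 8, sigma_max = 40, seed = seed)
    expect_identical(j$layout, j2$layout)
  }
  expect_error(jitter_layout(mv, 50, sigma_max = 40))
})

test_that("large jitter is indistinguishable from a fully random layout", {
  mv <- render_coarse_loom(small_loom(), small_grid())
  base <- coherence_baseline(mv, n_draws = 10, seed = 3)
  # under the displacement metric, heavy jitter should look like the
  # uniform-draw baseline: coherence near 0%
  cs <- vapply(1:8, function(seed) {
    j <- jitter_layout(mv, 40, sigma_max = 40, seed = seed)
    coherence_percent(j, mv, baseline = base)$coherence_percent
  }, numeric(1))
  expect_lt(abs(mean(cs)), 10)
})
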
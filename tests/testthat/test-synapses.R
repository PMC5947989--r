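fixture_map_model <- function() {
  model <- reference_model()
  grid <- small_grid()
  list(model = model, grid = grid,
       map = build_facet_map(grid, model, spread = 3, k = 6))
}

test_that("facet map weights are normalized and retinotopically local", {
  fx <- fixture_map_model()
  map <- fx$map
  sums <- tapply(map$weight, map$facet, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  centers <- fx$grid$centers
  # adjacent facets share target compartments
  f1 <- centers$pixel[centers$az == 1 & centers$el == 1]
  f2 <- centers$pixel[centers$az == 3 & centers$el == 1]
  s1 <- map$comp[map$facet == f1]
  s2 <- map$comp[map$facet == f2]
  expect_gt(length(intersect(s1, s2)), 0)
  # opposite corners map to disjoint compartment sets
  c1 <- centers$pixel[which.min(centers$az + centers$el)]
  c2 <- centers$pixel[which.max(centers$az + centers$el)]
  expect_length(intersect(map$comp[map$facet == c1],
                          map$comp[map$facet == c2]), 0)
  expect_error(build_facet_map(fx$grid, single_comp_model()), "field A")
})

test_that("stimulus focus maps onto proximal branch segments", {
  fx <- fixture_map_model()
  rf <- attr(fx$map, "rf_centers")
  model <- fx$model
  # eccentricity increases with path depth into field A
  expect_gt(stats::cor(abs(rf$el), model$path_um[rf$comp]), 0.9)
})

test_that("luminance decrements drive events; constant facets are silent", {
  fx <- fixture_map_model()
  mv <- render_coarse_loom(small_loom(), fx$grid)
  ev <- stimulus_to_events(mv, fx$map, unit_g_nS = 6, jitter_sd_ms = 0,
                           seed = 1)
  expect_s3_class(ev, "synaptic_train")
  expect_true(all(ev$g_nS > 0))
  # facets whose pixels never darken emit nothing
  bg <- mv$params$background_luminance
  silent_pixels <- which(apply(mv$luminance, 1, function(x) all(x == bg)))
  silent_facets <- mv$grid$centers$pixel[silent_pixels]
  expect_length(intersect(unique(ev$facet), silent_facets), 0)

  # a single full-contrast one-frame darkening yields the unit conductance
  fl <- flash_movie(fx$grid, az = 1, el = 1, duration_s = 0.5)
  evf <- stimulus_to_events(fl, fx$map, unit_g_nS = 6, jitter_sd_ms = 0,
                            train_n = 1, seed = 1)
  expect_equal(sum(evf$g_nS), 6, tolerance = 1e-9)
})

test_that("jitter preserves the total synaptic drive", {
  fx <- fixture_map_model()
  mv <- render_coarse_loom(small_loom(), fx$grid)
  ev0 <- stimulus_to_events(mv, fx$map, unit_g_nS = 6, seed = 2)
  jit <- jitter_layout(mv, 8, seed = 5)
  ev1 <- stimulus_to_events(jit, fx$map, unit_g_nS = 6, seed = 2)
  expect_equal(sum(ev1$g_nS), sum(ev0$g_nS), tolerance = 1e-9)
  expect_equal(nrow(ev1), nrow(ev0))
  # but the spatial arrangement differs
  expect_false(identical(sort(table(ev1$comp)), sort(table(ev0$comp))) &&
                 identical(ev1$comp, ev0$comp))
})

test_that("randomization changes only the spatial dimension", {
  fx <- fixture_map_model()
  mv <- render_coarse_loom(small_loom(), fx$grid)
  ev <- stimulus_to_events(mv, fx$map, unit_g_nS = 6, seed = 3)
  rnd <- randomize_locations(ev, fx$map, seed = 4)
  expect_identical(rnd$time_ms, ev$time_ms)
  expect_identical(rnd$g_nS, ev$g_nS)
  expect_equal(nrow(rnd), nrow(ev))
  expect_true(all(rnd$comp %in% attr(fx$map, "field_a_comps")))

  # retinotopic events visit eccentric compartments progressively later;
  # randomization destroys that spatiotemporal correlation
  rf <- attr(fx$map, "rf_centers")
  ecc <- abs(rf$el)[match(ev$comp, rf$comp)]
  r_ret <- stats::cor(ev$time_ms, ecc)
  r_rnd <- stats::cor(rnd$time_ms, abs(rf$el)[match(rnd$comp, rf$comp)])
  expect_gt(r_ret, 0.3)
  expect_lt(abs(r_rnd), 0.1)
})
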
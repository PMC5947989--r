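#' Looming-stimulus parameters
#'
#' A looming stimulus simulates a dark square of half-size `l` approaching at
#' constant speed `v < 0` on a collision course. Its angular size is fully
#' characterized by the ratio `l/|v|`: the full subtended angle at time
#' `t < 0` before collision is `2*theta(t) = 2*atan(l / (v t))`.
#'
#' @param l_over_v Ratio `l/|v|` in ms (50 or 80 are typical).
#' @param half_size_l Object half-size in arbitrary length units.
#' @param initial_full_angle Full angle subtended at stimulus onset (degrees).
#' @param max_full_angle Full angle at which the stimulus stops expanding and
#'   is held (degrees); 80 for a restrained preparation, 136 for freely
#'   behaving animals.
#' @param frame_rate Display refresh rate in Hz.
#' @param background_luminance,dark_luminance Gray levels of the background
#'   and of the dark square, on the quantized luminance scale.
#' @param luminance_bits Bit depth of the (linear) luminance control.
#' @return An object of class `loom_params`.
#' @export
loom_params <- function(l_over_v = 50, half_size_l = 1,
                        initial_full_angle = 1.2, max_full_angle = 80,
                        frame_rate = 200, background_luminance = 63,
                        dark_luminance = 0, luminance_bits = 6) {
  stopifnot(l_over_v > 0, frame_rate > 0, half_size_l > 0,
            initial_full_angle > 0, initial_full_angle < max_full_angle,
            max_full_angle <= 180, luminance_bits >= 1)
  lev <- 2^luminance_bits
  if (background_luminance < 0 || background_luminance > lev - 1 ||
      dark_luminance < 0 || dark_luminance > lev - 1)
    stop("luminance levels must lie within the quantized range [0, 2^bits - 1]")
  structure(list(
    l_over_v = l_over_v,
    half_size_l = half_size_l,
    speed_v = -half_size_l / (l_over_v / 1000),
    initial_full_angle = initial_full_angle,
    max_full_angle = max_full_angle,
    frame_rate = frame_rate,
    background_luminance = background_luminance,
    dark_luminance = dark_luminance,
    luminance_bits = luminance_bits
  ), class = "loom_params")
}

#' Angular size of a looming stimulus
#'
#' Full subtended angle `2*theta(t) = 2*atan(l/(v t))` in degrees, for times
#' `t < 0` before collision.
#'
#' @param t Time in seconds relative to projected collision (negative).
#' @param params A [loom_params()] object.
#' @return Full angle in degrees (not clipped at `max_full_angle`).
#' @export
angular_subtense <- function(t, params) {
  if (any(t >= 0))
    stop("angular size is only defined before collision (t < 0)")
  2 * atan((params$l_over_v / 1000) / abs(t)) * 180 / pi
}

#' Stimulus onset and freeze times
#'
#' `loom_start_time()` is the time at which the stimulus subtends its initial
#' angle; `loom_freeze_time()` the time at which it reaches `max_full_angle`,
#' after which frames are held at final size.
#'
#' @param params A [loom_params()] object.
#' @return Time in seconds (negative).
#' @export
loom_start_time <- function(params) {
  -(params$l_over_v / 1000) / tan(params$initial_full_angle / 2 * pi / 180)
}

#' @rdname loom_start_time
#' @export
loom_freeze_time <- function(params) {
  -(params$l_over_v / 1000) / tan(params$max_full_angle / 2 * pi / 180)
}

#' Coarse pixel grid
#'
#' A regular grid of "coarse" pixels at the spatial resolution of the locust
#' eye (2-3 degrees per pixel), covering a screen area centered on the
#' stimulus focus. Positions are pixel centers in screen-degree coordinates.
#'
#' @param pixel_size Pixel side length in degrees (2-3).
#' @param azimuth_halfwidth,elevation_halfwidth Screen half-extents in
#'   degrees; must be integer multiples of `pixel_size`.
#' @return An object of class `coarse_grid` with a `centers` tibble
#'   (`pixel`, `az`, `el`), 0-based grid indexing.
#' @export
coarse_grid <- function(pixel_size = 2, azimuth_halfwidth = 52,
                        elevation_halfwidth = 40) {
  stopifnot(pixel_size > 0, azimuth_halfwidth > 0, elevation_halfwidth > 0)
  nx <- round(2 * azimuth_halfwidth / pixel_size)
  ny <- round(2 * elevation_halfwidth / pixel_size)
  az <- -azimuth_halfwidth + (seq_len(nx) - 0.5) * pixel_size
  el <- -elevation_halfwidth + (seq_len(ny) - 0.5) * pixel_size
  centers <- tidyr::expand_grid(el = el, az = az)
  centers <- tibble::tibble(pixel = seq_len(nrow(centers)) - 1L,
                            az = centers$az, el = centers$el)
  structure(list(pixel_size = pixel_size, nx = nx, ny = ny,
                 azimuth_halfwidth = azimuth_halfwidth,
                 elevation_halfwidth = elevation_halfwidth,
                 centers = centers),
            class = "coarse_grid")
}

# fraction of each pixel's area covered by the centered dark square of
# half-width h degrees (flat screen-angle coordinates)
pixel_coverage <- function(grid, h) {
  ps <- grid$pixel_size
  x0 <- grid$centers$az - ps / 2; x1 <- grid$centers$az + ps / 2
  y0 <- grid$centers$el - ps / 2; y1 <- grid$centers$el + ps / 2
  ox <- pmax(0, pmin(x1, h) - pmax(x0, -h))
  oy <- pmax(0, pmin(y1, h) - pmax(y0, -h))
  ox * oy / ps^2
}

#' Render a coarse looming stimulus
#'
#' Pixelates a looming stimulus on a coarse grid: each coarse pixel's gray
#' level at each frame is the background level plus the luminance step scaled
#' by the fraction of the pixel covered by the dark square, quantized to the
#' display's bit depth. After the stimulus reaches `max_full_angle`, frames
#' are held at final size until the projected collision time.
#'
#' @param params A [loom_params()] object.
#' @param grid A [coarse_grid()]; must cover the final stimulus size.
#' @return An object of class `coarse_loom`: frame times (s, negative before
#'   collision), an integer luminance matrix (pixels x frames), and a
#'   `layout` tibble mapping each pixel id to its occupied screen position.
#' @export
render_coarse_loom <- function(params, grid) {
  stopifnot(inherits(params, "loom_params"), inherits(grid, "coarse_grid"))
  if (2 * grid$elevation_halfwidth < params$max_full_angle ||
      2 * grid$azimuth_halfwidth < params$max_full_angle)
    stop("grid does not cover the final stimulus size")
  t0 <- loom_start_time(params)
  n_frames <- ceiling(-t0 * params$frame_rate)
  frame_times <- -(n_frames:1) / params$frame_rate
  h_max <- params$max_full_angle / 2
  bg <- params$background_luminance
  dk <- params$dark_luminance
  lum <- matrix(0L, nrow = nrow(grid$centers), ncol = n_frames)
  for (f in seq_len(n_frames)) {
    h <- min(angular_subtense(frame_times[f], params) / 2, h_max)
    frac <- pixel_coverage(grid, h)
    lum[, f] <- as.integer(round(bg + (dk - bg) * frac))
  }
  structure(list(params = params, grid = grid, frame_times = frame_times,
                 luminance = lum,
                 layout = grid$centers,
                 sigma = 0, seed = NULL),
            class = "coarse_loom")
}

#' Single-pixel flash stimulus
#'
#' A localized luminance transient: one coarse pixel switches from background
#' to the given level for a fixed duration. Used as a spatially trivial
#' control stimulus.
#'
#' @param grid A [coarse_grid()].
#' @param az,el Screen position of the flashed pixel (degrees; snapped to the
#'   nearest pixel center).
#' @param duration_s Flash duration in seconds.
#' @param frame_rate Hz.
#' @param level Gray level during the flash.
#' @param background Background gray level.
#' @return A `coarse_loom` object (times measured from flash onset).
#' @export
flash_movie <- function(grid, az = 0, el = 0, duration_s = 1,
                        frame_rate = 200, level = 0, background = 63) {
  i <- which.min((grid$centers$az - az)^2 + (grid$centers$el - el)^2)
  n <- ceiling(duration_s * frame_rate)
  lum <- matrix(as.integer(background), nrow(grid$centers), n)
  lum[i, ] <- as.integer(level)
  structure(list(params = NULL, grid = grid,
                 frame_times = (seq_len(n) - 1) / frame_rate,
                 luminance = lum, layout = grid$centers,
                 sigma = 0, seed = NULL),
            class = "coarse_loom")
}

#' Jitter the layout of a coarse movie
#'
#' Adds a two-dimensional Gaussian displacement with zero mean and standard
#' deviation `sigma` (degrees) to each coarse pixel's screen location, once
#' per stimulus presentation (fixed across frames). Jittered positions are
#' rounded to the nearest available coarse pixel location so that no two
#' coarse pixels overlap; on a collision, pixels are placed in order of
#' descending displacement magnitude and take the nearest free grid cell
#' (ties broken by lowest azimuth, then elevation). Luminance time courses
#' are unchanged.
#'
#' @param movie A `coarse_loom` object.
#' @param sigma Jitter standard deviation in degrees.
#' @param sigma_max Maximal allowed sigma (40 for restrained, 80 for
#'   behavioral configurations).
#' @param seed Optional integer seed (layout is drawn from R's RNG stream
#'   otherwise).
#' @return A `coarse_loom` with a displaced `layout`.
#' @export
jitter_layout <- function(movie, sigma, sigma_max = 40, seed = NULL) {
  stopifnot(inherits(movie, "coarse_loom"), sigma >= 0, sigma <= sigma_max)
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) {
    movie$sigma <- 0
    return(movie)
  }
  lay <- movie$layout
  n <- nrow(lay)
  ideal_az <- lay$az + rnorm(n, 0, sigma)
  ideal_el <- lay$el + rnorm(n, 0, sigma)
  movie$layout <- place_on_grid(movie$grid, ideal_az, ideal_el, lay$pixel)
  movie$sigma <- sigma
  movie
}

#' Fully random layout
#'
#' Draws uniformly random, non-overlapping screen positions for all coarse
#' pixels: the limiting case of infinite jitter, used as the normalization
#' baseline of the coherence metric.
#'
#' @inheritParams jitter_layout
#' @return A `coarse_loom` with uniformly permuted layout.
#' @export
random_layout <- function(movie, seed = NULL) {
  stopifnot(inherits(movie, "coarse_loom"))
  if (!is.null(seed)) set.seed(seed)
  lay <- movie$layout
  perm <- sample.int(nrow(lay))
  cells <- movie$grid$centers
  movie$layout <- tibble::tibble(pixel = lay$pixel,
                                 az = cells$az[perm], el = cells$el[perm])
  movie$sigma <- Inf
  movie
}

# Round ideal positions to nearest free grid cells. Pixels are placed in
# order of descending displacement magnitude; collisions take the nearest
# free cell (Euclidean angular distance; ties by lowest azimuth then
# elevation).
place_on_grid <- function(grid, ideal_az, ideal_el, pixel_ids) {
  cells <- grid$centers
  n_cells <- nrow(cells)
  n <- length(ideal_az)
  if (n > n_cells) stop("grid too small to place all pixels")
  home_az <- cells$az[match(pixel_ids, cells$pixel)]
  home_el <- cells$el[match(pixel_ids, cells$pixel)]
  disp <- sqrt((ideal_az - home_az)^2 + (ideal_el - home_el)^2)
  ord <- order(disp, decreasing = TRUE)
  free <- rep(TRUE, n_cells)
  assigned <- integer(n)
  # ties in cell distance: prefer lowest azimuth, then elevation
  tie_rank <- order(cells$az, cells$el)
  tie_key <- integer(n_cells); tie_key[tie_rank] <- seq_len(n_cells)
  for (i in ord) {
    d2 <- (cells$az - ideal_az[i])^2 + (cells$el - ideal_el[i])^2
    d2[!free] <- Inf
    best <- which(d2 == min(d2))
    if (length(best) > 1) best <- best[which.min(tie_key[best])]
    assigned[i] <- best
    free[best] <- FALSE
  }
  tibble::tibble(pixel = pixel_ids,
                 az = cells$az[assigned], el = cells$el[assigned])
}

#' Minimum-cost assignment
#'
#' Solves the dense linear sum assignment problem (Jonker-Volgenant shortest
#' augmenting path). Used to compute the minimal total angular distance with
#' which jittered coarse pixels can be moved back onto the reference
#' stimulus.
#'
#' @param cost A square numeric cost matrix.
#' @return A list with `assignment` (column index matched to each row) and
#'   `cost` (the minimal total cost).
#' @export
min_cost_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost), all(is.finite(cost)))
  lapjv_cpp(cost)
}

#' Minimal displacement distance between two coarse movies
#'
#' For every frame, matches the jittered movie's non-background pixels to
#' reference pixel positions of equal luminance by minimum-cost assignment
#' (total angular distance) and sums the per-frame minimal distances over
#' frames.
#'
#' @param jittered,reference `coarse_loom` objects sharing grid, frame times
#'   and per-pixel luminance time courses.
#' @return A list with `total` (degrees) and `per_frame` distances.
#' @export
movie_distance <- function(jittered, reference) {
  stopifnot(inherits(jittered, "coarse_loom"), inherits(reference, "coarse_loom"))
  if (!identical(dim(jittered$luminance), dim(reference$luminance)))
    stop("movies must share grid and frame times")
  if (!identical(jittered$luminance, reference$luminance)) {
    # jitter preserves time courses; anything else cannot reconstitute the
    # reference unless each frame's luminance multisets still agree
    for (f in seq_len(ncol(reference$luminance))) {
      if (!identical(sort(jittered$luminance[, f]),
                     sort(reference$luminance[, f])))
        stop("frame ", f, ": luminance multisets differ; the jittered movie ",
             "cannot reconstitute the reference")
    }
    stop("luminance matrices differ in pixel identity; movies are not ",
         "jittered versions of one another")
  }
  ord_j <- order(jittered$layout$pixel)
  ord_r <- order(reference$layout$pixel)
  jp <- cbind(jittered$layout$az, jittered$layout$el)[ord_j, , drop = FALSE]
  rp <- cbind(reference$layout$az, reference$layout$el)[ord_r, , drop = FALSE]
  movie_distance_cpp(jp, rp, reference$luminance,
                     as.integer(reference$params$background_luminance %||% 63),
                     as.integer(reference$params$dark_luminance %||% 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random-layout normalization baseline
#'
#' Average over `n_draws` pseudo-random draws of the minimal total angular
#' distance between the reference coarse loom and a movie with uniformly
#' drawn random pixel positions. Results are cached per reference movie
#' within the session.
#'
#' @param reference A `coarse_loom`.
#' @param n_draws Number of random draws to average (30 by default).
#' @param seed Integer seed for the draws.
#' @return Baseline distance in degrees (scalar).
#' @export
coherence_baseline <- function(reference, n_draws = 30, seed = 1L) {
  key <- paste("baseline",
               rlang::hash(list(reference$luminance, reference$grid$centers,
                                n_draws, seed)))
  if (!is.null(the[[key]])) return(the[[key]])
  draws <- vapply(seq_len(n_draws), function(i) {
    rnd <- random_layout(reference, seed = seed + i - 1L)
    movie_distance(rnd, reference)$total
  }, numeric(1))
  the[[key]] <- mean(draws)
  the[[key]]
}

#' Spatial coherence of a jittered coarse looming stimulus
#'
#' The percent spatial coherence is `100 * (1 - d / d_random)`, where `d` is
#' the minimal total angular distance the jittered coarse pixels must be
#' moved, in each movie frame, to reconstitute the unaltered coarse looming
#' stimulus (summed over frames), and `d_random` is the same quantity
#' averaged over `n_draws` movies with uniformly drawn random pixel
#' positions. An unjittered movie has coherence 100%; a fully random layout
#' is near 0%.
#'
#' @param jittered A jittered `coarse_loom`.
#' @param reference The unaltered coarse loom.
#' @param n_draws Random draws for the normalization baseline.
#' @param seed Seed for the baseline draws.
#' @param baseline Optional precomputed [coherence_baseline()].
#' @return A one-row tibble: `coherence_percent`, `raw_distance`,
#'   `random_baseline_distance`, `n_draws`.
#' @export
coherence_percent <- function(jittered, reference, n_draws = 30, seed = 1L,
                              baseline = NULL) {
  d <- movie_distance(jittered, reference)$total
  if (is.null(baseline))
    baseline <- coherence_baseline(reference, n_draws = n_draws, seed = seed)
  tibble::tibble(coherence_percent = 100 * (1 - d / baseline),
                 raw_distance = d,
                 random_baseline_distance = baseline,
                 n_draws = as.integer(n_draws))
}

#' Coherence as a function of jitter strength
#'
#' Renders the reference coarse loom once, then evaluates the coherence
#' metric for jittered versions across a range of jitter standard
#' deviations.
#'
#' @param params A [loom_params()].
#' @param grid A [coarse_grid()].
#' @param sigmas Jitter standard deviations (degrees).
#' @param n_reps Jitter draws per sigma.
#' @param n_draws Random draws for the baseline.
#' @param sigma_max Maximal sigma for validation.
#' @param seed Integer seed.
#' @return A tibble with one row per (`sigma`, `rep`) and the summary column
#'   `coherence_percent`; mean curves can be obtained by grouping on
#'   `sigma`.
#' @export
sigma_coherence_curve <- function(params, grid, sigmas, n_reps = 3,
                                  n_draws = 30, sigma_max = 40, seed = 1L) {
  stopifnot(all(sigmas >= 0), all(sigmas <= sigma_max))
  reference <- render_coarse_loom(params, grid)
  base <- coherence_baseline(reference, n_draws = n_draws, seed = seed)
  purrr::map_dfr(seq_along(sigmas), function(i) {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      jit <- jitter_layout(reference, sigmas[i], sigma_max = sigma_max,
                           seed = seed + 1000L * i + r)
      res <- coherence_percent(jit, reference, baseline = base)
      tibble::tibble(sigma = sigmas[i], rep = r,
                     coherence_percent = res$coherence_percent)
    })
  })
}
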
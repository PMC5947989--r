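#' Retinotopic facet map
#'
#' Maps visual facets (coarse grid cells) onto excitatory synaptic sites in
#' dendritic field A as a continuous 2-D-to-tree embedding. Each primary
#' field A branch is assigned a receptive-field sector: azimuth orders
#' branches along the arbor's main axis, and eccentricity from the stimulus
#' focus maps onto path depth within the branch, so the focus falls on the
#' proximal branch segments and expansion sweeps distally along each
#' branch. Each facet spreads over its `k` nearest compartments (Gaussian
#' weights summing to one), so neighboring facets target overlapping,
#' electrotonically nearby compartments.
#'
#' @param grid A [coarse_grid()].
#' @param model A [compartmental_model()] with a nonempty field A.
#' @param spread Gaussian spread of a facet's footprint, in coarse pixels.
#' @param k Number of target compartments per facet.
#' @return A `facet_map`: tibble (`facet`, `comp`, `weight`) plus the grid
#'   and the compartment receptive-field centers stored as attributes.
#' @export
build_facet_map <- function(grid, model, spread = 2, k = 3) {
  ia <- comps_in_region(model, "fieldA")
  if (length(ia) == 0) stop("model has no field A compartments")
  morph <- model$morph
  in_a <- morph$region == "fieldA"

  # primary branches (subtrees entering field A) and depth within branch
  branch <- integer(nrow(morph))
  depth <- integer(nrow(morph))
  n_branch <- 0L
  for (i in ia) {
    p <- morph$parent[i]
    if (p == 0 || !in_a[p]) {
      n_branch <- n_branch + 1L
      branch[i] <- n_branch
      depth[i] <- 1L
    } else {
      branch[i] <- branch[p]
      depth[i] <- depth[p] + 1L
    }
  }

  # receptive-field center per compartment: branches tile azimuth sectors
  # alternating above/below the focus; depth maps to eccentricity
  el_hw <- grid$elevation_halfwidth
  az_hw <- grid$azimuth_halfwidth
  n_slices <- max(1L, ceiling(n_branch / 2))
  b <- branch[ia]
  slice <- (b - 1L) %/% 2L + 1L
  el_sign <- ifelse(b %% 2L == 1L, 1, -1)
  if (n_branch == 1) el_sign[] <- 1
  az_c <- -az_hw + (slice - 0.5) / n_slices * 2 * az_hw
  max_d <- max(depth[ia])
  el_c <- el_sign * el_hw * (depth[ia] - 0.5) / max_d

  centers <- grid$centers
  sd_deg <- spread * grid$pixel_size
  rows <- vector("list", nrow(centers))
  for (f in seq_len(nrow(centers))) {
    d2 <- (centers$az[f] - az_c)^2 + (centers$el[f] - el_c)^2
    near <- order(d2)[seq_len(min(k, length(ia)))]
    w <- exp(-d2[near] / (2 * sd_deg^2))
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(near), length(near))
    rows[[f]] <- tibble::tibble(facet = centers$pixel[f], comp = ia[near],
                                weight = w)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "grid") <- grid
  attr(out, "field_a_comps") <- ia
  attr(out, "rf_centers") <- tibble::tibble(comp = ia, az = az_c, el = el_c)
  class(out) <- c("facet_map", class(out))
  out
}

#' Convert a coarse movie into excitatory synaptic events
#'
#' Each per-facet luminance decrement between consecutive frames (and from
#' the background at the first frame) emits excitatory events whose summed
#' peak conductance is proportional to the decrement, delivered at a fixed
#' latency plus Gaussian timing jitter to the facet's mapped field A
#' compartments. The facet a pixel drives is the one at the pixel's current
#' (possibly jittered) screen location, so jitter moves inputs across the
#' dendritic arbor while leaving each pixel's luminance time course and the
#' total synaptic drive unchanged.
#'
#' Each luminance decrement triggers a short adapting train of synaptic
#' events (single-facet stimulation evokes a sustained, adapting EPSP train
#' rather than one unitary event): `train_n` sub-events at `train_gap_ms`
#' intervals with geometrically decaying amplitudes, whose summed peak
#' conductance equals the decrement's total.
#'
#' @param movie A `coarse_loom`.
#' @param map A [build_facet_map()] result.
#' @param unit_g_nS Summed peak conductance of a full-contrast darkening of
#'   one facet (nS).
#' @param latency_ms Fixed synaptic latency (ms).
#' @param jitter_sd_ms Gaussian latency jitter (ms).
#' @param train_n,train_gap_ms,train_decay Number, spacing (ms) and
#'   geometric amplitude decay of the sub-events evoked per decrement.
#' @param contrast_gamma Exponent of the saturating contrast transform:
#'   per-frame event conductance scales as `(decrement/full)^gamma`.
#'   Values below 1 mimic the saturating, change-detecting response of the
#'   presynaptic pathway to a single facet.
#' @param seed Optional integer seed.
#' @return A `synaptic_train` tibble: `time_ms`, `g_nS`, `comp`, `facet`;
#'   attribute `window_ms` is the stimulus window
#'   `c(0, time of projected collision)`.
#' @export
stimulus_to_events <- function(movie, map, unit_g_nS = 4, latency_ms = 30,
                               jitter_sd_ms = 2, train_n = 6,
                               train_gap_ms = 80, train_decay = 0.6,
                               contrast_gamma = 0.4, seed = NULL) {
  stopifnot(inherits(movie, "coarse_loom"), inherits(map, "facet_map"))
  if (!is.null(seed)) set.seed(seed)
  grid <- attr(map, "grid")
  lum <- movie$luminance
  bg <- movie$params$background_luminance %||% 63
  dk <- movie$params$dark_luminance %||% 0
  full <- abs(bg - dk)
  n_frames <- ncol(lum)
  ft_ms <- (movie$frame_times - movie$frame_times[1]) * 1000

  # pixel -> facet at its (possibly jittered) location
  lay <- movie$layout[order(movie$layout$pixel), ]
  cell <- match(paste(lay$az, lay$el),
                paste(grid$centers$az, grid$centers$el))
  if (any(is.na(cell))) stop("movie layout positions are not grid cells")
  facet_of_pixel <- grid$centers$pixel[cell]

  stopifnot(train_n >= 1, train_gap_ms > 0, train_decay > 0)
  w_train <- train_decay^(seq_len(train_n) - 1)
  w_train <- w_train / sum(w_train)

  prev <- rep(as.integer(bg), nrow(lum))
  ev <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    dec <- prev - lum[, f]
    act <- which(dec > 0)
    if (length(act)) {
      n_act <- length(act)
      ev[[f]] <- tibble::tibble(
        facet = rep(facet_of_pixel[act], each = train_n),
        g_total = rep(unit_g_nS * (dec[act] / full)^contrast_gamma,
                      each = train_n) * rep(w_train, n_act),
        t_ms = rep(ft_ms[f] + latency_ms +
                     rnorm(n_act, 0, jitter_sd_ms), each = train_n) +
          rep((seq_len(train_n) - 1) * train_gap_ms, n_act))
    }
    prev <- lum[, f]
  }
  ev <- dplyr::bind_rows(ev)
  out <- dplyr::inner_join(ev, map, by = "facet",
                           relationship = "many-to-many")
  out <- tibble::tibble(time_ms = pmax(out$t_ms, 0),
                        g_nS = out$g_total * out$weight,
                        comp = out$comp, facet = out$facet)
  out <- dplyr::arrange(out, .data$time_ms)
  attr(out, "window_ms") <- c(0, -movie$frame_times[1] * 1000)
  class(out) <- c("synaptic_train", class(out))
  out
}

#' Spatially randomize synaptic input locations
#'
#' Redraws each event's target compartment uniformly over the field A
#' synaptic sites, preserving event times and conductances exactly: the
#' temporal pattern of excitation is untouched and only its spatial
#' arrangement on the dendrite changes.
#'
#' @param train A `synaptic_train`.
#' @param map The [build_facet_map()] used to generate it (defines the
#'   synaptic sites).
#' @param seed Optional integer seed.
#' @return A `synaptic_train` with randomized `comp`.
#' @export
randomize_locations <- function(train, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sites <- attr(map, "field_a_comps")
  out <- train
  out$comp <- sample(sites, nrow(train), replace = TRUE)
  out
}
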
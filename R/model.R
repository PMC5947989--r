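#' Default channel density table
#'
#' Conductance densities (S/cm^2) per channel and region. HCN and the
#' inactivating K+ conductance (K_D-like) are confined to dendritic field A
#' with density increasing toward the distal endings; fast Na+ is excluded
#' from dendritic branches; the delayed rectifier is distributed throughout
#' the cell; M is restricted to axon, SIZ and trunk with its peak at the
#' SIZ; Ca_T and K_Ca sit at the SIZ and the proximal half of the trunk.
#'
#' @return A tibble with columns `channel`, `region`, `density`.
#' @export
default_densities <- function() {
  tibble::tribble(
    ~channel, ~region,   ~density,
    "HCN",    "fieldA",  4e-4,
    "KD",     "fieldA",  2e-3,
    "Na",     "SIZ",     2.0,
    "Na",     "axon",    0.25,
    "KDR",    "SIZ",     0.12,
    "KDR",    "axon",    0.08,
    "KDR",    "trunk",   2e-3,
    "KDR",    "fieldA",  2e-3,
    "KDR",    "fieldB",  2e-3,
    "KDR",    "fieldC",  2e-3,
    "M",      "SIZ",     3e-3,
    "M",      "axon",    1e-3,
    "M",      "trunk",   1e-3,
    "CaT",    "SIZ",     1.5e-3,
    "KCa",    "SIZ",     4e-3
  )
}

#' Build a conductance-based compartmental model
#'
#' Attaches passive properties and channel densities to a morphology and
#' precomputes everything the integrator needs: per-compartment membrane
#' area, capacitance, leak and axial conductances and maximal channel
#' conductances. HCN and K_D-like densities in field A follow a linear
#' gradient in normalized path distance from the field A base with a
#' configurable base:tip ratio (mean density preserved). The leak reversal
#' is calibrated per compartment so the target resting potential is a
#' steady state with all channels at their resting activation.
#'
#' @param morph A [neuron_morphology()].
#' @param passive A [passive_props()].
#' @param channels Named list of [channel_spec()]s
#'   ([default_channel_library()]).
#' @param densities Density table as in [default_densities()].
#' @param gradient_ratio Tip:base density ratio of the field A gradient.
#' @param target_rmp Resting membrane potential (mV) used for leak
#'   calibration.
#' @param calcium Calcium pool parameters: `tau` (ms), `rest`
#'   (concentration, arbitrary units), `phi` (concentration per nA ms).
#' @param syn_gain_ratio Distance-dependent synaptic scaling: tip:base
#'   ratio of synaptic conductance gain across field A (area-weighted mean
#'   1), compensating dendritic attenuation of distal inputs ("synaptic
#'   democracy"). 1 disables scaling.
#' @return A `compartmental_model` object.
#' @export
compartmental_model <- function(morph, passive = passive_props(),
                                channels = default_channel_library(),
                                densities = default_densities(),
                                gradient_ratio = 3,
                                target_rmp = -65,
                                calcium = list(tau = 150, rest = 0.05,
                                               phi = 0.02),
                                syn_gain_ratio = 2.5) {
  stopifnot(inherits(morph, "neuron_morphology"))
  n <- nrow(morph)
  area_cm2 <- pi * morph$diam_um * morph$length_um * 1e-8
  cm_nF <- passive$cm * area_cm2 * 1e3
  g_leak <- passive$g_pas * area_cm2 * 1e6   # uS

  # axial conductance between each compartment and its parent (uS)
  half_r <- passive$ra * (morph$length_um * 1e-4 / 2) /
    (pi * (morph$diam_um * 1e-4 / 2)^2)      # Ohm
  g_ax <- numeric(n)
  for (i in seq_len(n)[-1]) {
    p <- morph$parent[i]
    g_ax[i] <- 1e6 / (half_r[i] + half_r[p])
  }

  # path distance from root (midpoint-based, um)
  path <- numeric(n)
  for (i in seq_len(n)) {
    p <- morph$parent[i]
    path[i] <- (if (p == 0) 0 else path[p] + morph$length_um[p] / 2) +
      morph$length_um[i] / 2
  }

  # field A gradient factor (mean 1 over field A area)
  grad <- rep(1, n)
  ia <- which(morph$region == "fieldA")
  if (length(ia) > 0 && gradient_ratio != 1) {
    x <- path[ia] - min(path[ia])
    x <- if (max(x) > 0) x / max(x) else x
    f <- 1 + (gradient_ratio - 1) * x
    f <- f / sum(f * area_cm2[ia]) * sum(area_cm2[ia])
    grad[ia] <- f
  }

  dens_mat <- matrix(0, n, length(channels),
                     dimnames = list(NULL, names(channels)))
  for (r in seq_len(nrow(densities))) {
    ch <- densities$channel[r]
    if (!ch %in% names(channels)) next
    sel <- morph$region == densities$region[r]
    dens_mat[sel, ch] <- dens_mat[sel, ch] + densities$density[r]
  }
  graded <- intersect(c("HCN", "KD"), colnames(dens_mat))
  for (ch in graded) dens_mat[, ch] <- dens_mat[, ch] * grad

  # distance-dependent synaptic gain over field A (area-weighted mean 1)
  syn_gain <- rep(1, n)
  if (length(ia) > 0 && syn_gain_ratio != 1) {
    x <- path[ia] - min(path[ia])
    x <- if (max(x) > 0) x / max(x) else x
    f <- 1 + (syn_gain_ratio - 1) * x
    f <- f / sum(f * area_cm2[ia]) * sum(area_cm2[ia])
    syn_gain[ia] <- f
  }

  gbar <- dens_mat * area_cm2 * 1e6          # uS

  model <- structure(list(
    morph = morph, passive = passive, channels = channels,
    densities = densities, density_mat = dens_mat,
    area_cm2 = area_cm2, cm_nF = cm_nF, g_leak = g_leak, g_ax = g_ax,
    path_um = path, gbar = gbar, target_rmp = target_rmp,
    calcium = calcium, syn_gain = syn_gain,
    block = setNames(rep(1, length(channels)),
                     names(channels))
  ), class = "compartmental_model")
  model$e_leak <- calibrate_leak(model, target_rmp)
  model$v_init <- target_rmp
  model
}

# resting open conductance (uS) of every channel at potential v
resting_conductance <- function(model, v) {
  g <- matrix(0, nrow(model$morph), length(model$channels),
              dimnames = list(NULL, names(model$channels)))
  for (ch in names(model$channels)) {
    spec <- model$channels[[ch]]
    open <- 1
    for (gt in spec$gates) {
      x <- gate_inf(gt, v, ca = model$calcium$rest)
      open <- open * x^gt$power
    }
    g[, ch] <- model$gbar[, ch] * model$block[ch] * open
  }
  g
}

# per-compartment leak reversal making `target` a uniform steady state
calibrate_leak <- function(model, target) {
  g <- resting_conductance(model, target)
  erev <- vapply(model$channels, function(s) s$e_rev, numeric(1))
  i_ch <- as.numeric(g %*% (target - erev))   # nA, outward positive
  target + i_ch / model$g_leak
}

#' Scale or remove channel conductances (pharmacological blockade)
#'
#' Blockade is idealized as scaling maximal conductances; 0 corresponds to
#' a complete block (ZD7288/Cs+ for HCN, 4AP for the inactivating K+
#' conductance). The leak reversal is not recalibrated, so blockade shifts
#' the resting potential as in the experiments.
#'
#' @param model A [compartmental_model()].
#' @param ... Named scale factors, e.g. `HCN = 0` or `KD = 0.5`.
#' @return The modified model.
#' @export
set_channel_block <- function(model, ...) {
  sc <- list(...)
  stopifnot(all(names(sc) %in% names(model$channels)))
  for (ch in names(sc)) {
    stopifnot(sc[[ch]] >= 0)
    model$block[ch] <- sc[[ch]]
  }
  model
}

#' @export
print.compartmental_model <- function(x, ...) {
  cat("<compartmental_model> ", nrow(x$morph), " compartments (",
      sum(x$morph$region == "fieldA"), " in field A), channels: ",
      paste0(names(x$channels), ifelse(x$block != 1,
                                       paste0(" [x", x$block, "]"), ""),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Compartments in a region / base of field A
#'
#' `field_a_base()` returns the most proximal field A compartment (the one
#' whose parent lies outside field A), the reference recording site for
#' dendritic measurements.
#'
#' @param model A [compartmental_model()].
#' @param region A region label.
#' @return Integer compartment indices (1-based).
#' @export
comps_in_region <- function(model, region) {
  which(model$morph$region == region)
}

#' @rdname comps_in_region
#' @export
field_a_base <- function(model) {
  ia <- comps_in_region(model, "fieldA")
  base <- ia[model$morph$parent[ia] == 0 |
             model$morph$region[pmax(model$morph$parent[ia], 1)] != "fieldA"]
  base[which.min(model$path_um[base])]
}

#' @rdname comps_in_region
#' @export
siz_comp <- function(model) {
  i <- comps_in_region(model, "SIZ")
  if (length(i) == 0) stop("model has no SIZ compartment")
  i[1]
}

# solve (D + L) x = b on the tree, D diagonal, L weighted Laplacian of
# axial conductances; Hines elimination (parent < child ordering)
solve_tree <- function(model, diag_extra, b) {
  n <- nrow(model$morph)
  parent <- model$morph$parent
  g_ax <- model$g_ax
  sum_gax <- numeric(n)
  for (i in seq_len(n)[-1]) {
    sum_gax[i] <- sum_gax[i] + g_ax[i]
    sum_gax[parent[i]] <- sum_gax[parent[i]] + g_ax[i]
  }
  d <- diag_extra + sum_gax
  a <- c(0, -g_ax[-1])
  for (i in n:2) {
    p <- parent[i]
    f <- a[i] / d[i]
    d[p] <- d[p] - f * a[i]
    b[p] <- b[p] - f * b[i]
  }
  x <- numeric(n)
  x[1] <- b[1] / d[1]
  for (i in 2:n) x[i] <- (b[i] - a[i] * x[parent[i]]) / d[i]
  x
}

#' Steady-state space-clamp attenuation
#'
#' For an ideal voltage-clamp electrode in a given compartment, computes the
#' steady-state ratio of the local membrane-potential change to the
#' commanded change in every compartment of the resting-linearized model
#' (conductances frozen at their resting values), and the area-weighted
#' mean over a region.
#'
#' @param model A [compartmental_model()].
#' @param electrode Compartment index of the electrode.
#' @param region Region over which to average (default `"fieldA"`).
#' @return A list: `per_compartment` tibble (`comp`, `region`, `fraction`)
#'   and `mean_fraction` (area-weighted over `region`).
#' @export
space_clamp_attenuation <- function(model, electrode, region = "fieldA") {
  n <- nrow(model$morph)
  g_rest <- rowSums(resting_conductance(model, model$target_rmp)) +
    model$g_leak
  # pin the electrode with a large conductance to the command
  pin <- numeric(n); pin[electrode] <- 1e9
  b <- numeric(n); b[electrode] <- 1e9 * 1   # command deltaV = 1
  dv <- solve_tree(model, g_rest + pin, b)
  frac <- dv / dv[electrode]
  sel <- comps_in_region(model, region)
  list(per_compartment = tibble::tibble(comp = seq_len(n),
                                        region = model$morph$region,
                                        fraction = frac),
       mean_fraction = sum(frac[sel] * model$area_cm2[sel]) /
         sum(model$area_cm2[sel]))
}

#' Steady-state input resistance (resting-linearized)
#'
#' @param model A [compartmental_model()].
#' @param comp Compartment index.
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(model, comp) {
  g_rest <- rowSums(resting_conductance(model, model$target_rmp)) +
    model$g_leak
  b <- numeric(nrow(model$morph)); b[comp] <- 1   # 1 nA
  dv <- solve_tree(model, g_rest, b)
  dv[comp]                                        # mV/nA = MOhm
}

#' Rall equivalent-cylinder reduction of a dendritic region
#'
#' Iterates through the region's compartments by electrotonic distance from
#' the region base in steps of `step_fraction` times the local space
#' constant lambda, replacing each group with a single equivalent cylinder
#' whose diameter follows Rall's 3/2-power law,
#' `d_eq = (sum d_i^(3/2))^(2/3)`. Channel densities of the equivalent
#' cylinder are surface-area-weighted means over the replaced compartments;
#' synaptic attachment sites map onto their bin's cylinder. Grouping
#' `"per_subtree"` reduces each primary subtree separately (the least
#' reduction); `"merged"` collapses the whole region into one chain.
#'
#' @param model A [compartmental_model()].
#' @param region Region to reduce (default `"fieldA"`).
#' @param step_fraction Electrotonic bin width as a fraction of lambda.
#' @param grouping `"merged"` or `"per_subtree"`.
#' @return A new `compartmental_model`; attribute `comp_map` gives, for
#'   every compartment of the input model, its compartment in the reduced
#'   model.
#' @export
rall_reduce <- function(model, region = "fieldA", step_fraction = 0.04,
                        grouping = c("merged", "per_subtree")) {
  grouping <- match.arg(grouping)
  morph <- model$morph
  n <- nrow(morph)
  sel <- morph$region == region
  if (!any(sel)) stop("region ", region, " is empty")
  idx <- which(sel)

  lam <- lambda_um(morph$diam_um, model$passive)
  # electrotonic distance from region entry (at each compartment midpoint)
  X <- rep(NA_real_, n)
  subtree <- rep(NA_integer_, n)
  n_subtrees <- 0L
  for (i in idx) {
    p <- morph$parent[i]
    if (p == 0 || !sel[p]) {
      X[i] <- 0.5 * morph$length_um[i] / lam[i]
      n_subtrees <- n_subtrees + 1L
      subtree[i] <- n_subtrees
    } else {
      X[i] <- X[p] + 0.5 * morph$length_um[p] / lam[p] +
        0.5 * morph$length_um[i] / lam[i]
      subtree[i] <- subtree[p]
    }
  }
  bin <- floor(X[idx] / step_fraction)
  grp <- if (grouping == "merged") rep(1L, length(idx)) else subtree[idx]

  # unbranched chains: the parallel paths crossing an electrotonic shell
  n_kids <- tabulate(morph$parent[idx][morph$parent[idx] > 0], nbins = n)
  chain <- rep(NA_integer_, n)
  n_chains <- 0L
  for (i in idx) {
    p <- morph$parent[i]
    if (p == 0 || !sel[p] || n_kids[p] > 1L) {
      n_chains <- n_chains + 1L
      chain[i] <- n_chains
    } else {
      chain[i] <- chain[p]
    }
  }

  # attachment compartment of the region (parent of its first entry point)
  entry_parents <- unique(morph$parent[idx][!sel[pmax(morph$parent[idx], 1)] |
                                            morph$parent[idx] == 0])
  attach_comp <- entry_parents[1]
  if (attach_comp == 0) stop("cannot reduce a region containing the root")

  keep <- which(!sel)
  new_id_of_old <- integer(n)
  new_id_of_old[keep] <- seq_along(keep)
  out <- tibble::tibble(comp = seq_along(keep),
                        parent = ifelse(morph$parent[keep] == 0, 0L,
                                        new_id_of_old[pmax(morph$parent[keep],
                                                           1L)]),
                        length_um = morph$length_um[keep],
                        diam_um = morph$diam_um[keep],
                        region = morph$region[keep])

  comp_map <- integer(n)
  comp_map[keep] <- new_id_of_old[keep]
  dens_rows <- list()

  ell_all <- morph$length_um / lam        # electrotonic length per comp
  for (g in sort(unique(grp))) {
    gsel <- idx[grp == g]
    gbins <- sort(unique(bin[grp == g]))
    parent_new <- new_id_of_old[attach_comp]
    for (bk in gbins) {
      members <- gsel[bin[grp == g] == bk]
      # parallel paths (chains) contribute d^(3/2); series members of the
      # same chain contribute their summed electrotonic length
      msub <- chain[members]
      ar <- model$area_cm2[members]
      d_paths <- vapply(unique(msub), function(ss) {
        w <- ar[msub == ss]
        sum(morph$diam_um[members][msub == ss] * w) / sum(w)
      }, numeric(1))
      ell_paths <- vapply(unique(msub), function(ss)
        sum(ell_all[members][msub == ss]), numeric(1))
      w_paths <- vapply(unique(msub), function(ss) sum(ar[msub == ss]),
                        numeric(1))
      d_eq <- (sum(d_paths^1.5))^(2 / 3)
      ell_eq <- sum(ell_paths * w_paths) / sum(w_paths)
      l_eq <- ell_eq * lambda_um(d_eq, model$passive)
      newc <- nrow(out) + 1L
      out <- dplyr::bind_rows(out, tibble::tibble(
        comp = newc, parent = parent_new, length_um = l_eq,
        diam_um = d_eq, region = region))
      a <- model$area_cm2[members]
      for (ch in colnames(model$density_mat)) {
        dmean <- sum(model$density_mat[members, ch] * a) / sum(a)
        if (dmean > 0)
          dens_rows[[length(dens_rows) + 1]] <-
            tibble::tibble(channel = ch, comp = newc, density = dmean)
      }
      comp_map[members] <- newc
      parent_new <- newc
    }
  }

  new_morph <- neuron_morphology(out)
  red <- compartmental_model(new_morph, passive = model$passive,
                             channels = model$channels,
                             densities = model$densities,
                             gradient_ratio = 1,
                             target_rmp = model$target_rmp,
                             calcium = model$calcium)
  # overwrite densities: kept compartments keep their original values,
  # equivalent cylinders take the area-weighted means
  dm <- matrix(0, nrow(new_morph), length(model$channels),
               dimnames = list(NULL, names(model$channels)))
  dm[new_id_of_old[keep], ] <- model$density_mat[keep, ]
  for (r in dens_rows) dm[r$comp, r$channel] <- r$density
  red$density_mat <- dm
  red$gbar <- dm * red$area_cm2 * 1e6
  # transfer the distance-dependent synaptic gain by area-weighted mean
  sg <- rep(1, nrow(new_morph))
  sg[new_id_of_old[keep]] <- model$syn_gain[keep]
  for (cnew in unique(comp_map[idx])) {
    members <- idx[comp_map[idx] == cnew]
    sg[cnew] <- sum(model$syn_gain[members] * model$area_cm2[members]) /
      sum(model$area_cm2[members])
  }
  red$syn_gain <- sg
  red$block <- model$block
  red$e_leak <- calibrate_leak(red, red$target_rmp)
  attr(red, "comp_map") <- comp_map
  red
}

#' Tidy a compartmental model
#'
#' @param x A [compartmental_model()].
#' @param ... Unused.
#' @return A tibble with one row per compartment: geometry, region, path
#'   distance from the root, membrane area and maximal conductances (uS).
#' @exportS3Method generics::tidy
tidy.compartmental_model <- function(x, ...) {
  g <- tibble::as_tibble(x$gbar * rep(x$block, each = nrow(x$gbar)))
  names(g) <- paste0("gbar_", names(g))
  dplyr::bind_cols(tibble::as_tibble(x$morph),
                   tibble::tibble(path_um = x$path_um,
                                  area_cm2 = x$area_cm2), g)
}

#' @exportS3Method generics::glance
glance.compartmental_model <- function(x, ...) {
  tibble::tibble(n_comp = nrow(x$morph),
                 n_field_a = sum(x$morph$region == "fieldA"),
                 total_area_cm2 = sum(x$area_cm2),
                 rmp_target_mV = x$target_rmp)
}
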
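REGIONS <- c("fieldA", "fieldB", "fieldC", "trunk", "SIZ", "axon")

#' Neuron morphology
#'
#' A branched tree of cylindrical sections. Each section has a length and
#' diameter (um), a parent (0 for the root) and a region label: `fieldA`
#' (excitatory dendritic field), `fieldB`/`fieldC` (inhibitory fields),
#' `trunk` (main neurite), `SIZ` (spike initiation zone) or `axon`.
#'
#' @param sections A data frame with columns `comp`, `parent`, `length_um`,
#'   `diam_um`, `region`. Compartments must be topologically ordered
#'   (`parent < comp`) with a single root.
#' @return A `neuron_morphology` tibble.
#' @export
neuron_morphology <- function(sections) {
  sections <- tibble::as_tibble(sections)
  req <- c("comp", "parent", "length_um", "diam_um", "region")
  stopifnot(all(req %in% names(sections)))
  n <- nrow(sections)
  if (!identical(as.integer(sections$comp), seq_len(n)))
    stop("comp must be 1..n in order")
  if (sum(sections$parent == 0) != 1 || sections$parent[1] != 0)
    stop("exactly one root (parent 0) required, as the first compartment")
  if (any(sections$parent[-1] >= sections$comp[-1]) ||
      any(sections$parent[-1] < 1))
    stop("sections must be topologically ordered (parent < comp)")
  if (any(sections$diam_um <= 0) || any(sections$length_um <= 0))
    stop("lengths and diameters must be positive")
  if (!all(sections$region %in% REGIONS))
    stop("unknown region label(s): ",
         paste(setdiff(unique(sections$region), REGIONS), collapse = ", "))
  class(sections) <- c("neuron_morphology", class(sections))
  sections
}

#' Synthetic test morphologies
#'
#' Desk-scale labeled morphologies: a `fan` (parallel field A branches off
#' the distal trunk, facet-mappable along two axes), a `rall_symmetric`
#' binary tree whose every branch point satisfies the 3/2-power diameter
#' rule exactly (so equivalent-cylinder reduction is electrically exact),
#' and an `asymmetric` random tree.
#'
#' @param kind `"fan"`, `"rall_symmetric"` or `"asymmetric"`.
#' @param n_branches Number of field A branches (fan) or terminal branches
#'   (rall_symmetric: rounded down to a power of two).
#' @param comps_per_branch Compartments per field A branch.
#' @param seed Integer seed (used by `"asymmetric"`).
#' @return A [neuron_morphology()] tibble.
#' @export
gen_toy_morphology <- function(kind = c("fan", "rall_symmetric", "asymmetric"),
                               n_branches = 8, comps_per_branch = 8,
                               seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  add <- function(parent, length_um, diam_um, region) {
    rows[[length(rows) + 1]] <<- list(parent = parent, length_um = length_um,
                                      diam_um = diam_um, region = region)
    length(rows)
  }
  # axon (root) -> SIZ -> trunk
  a1 <- add(0, 100, 4, "axon")
  a2 <- add(a1, 100, 4, "axon")
  a3 <- add(a2, 100, 4, "axon")
  siz <- add(a3, 25, 7, "SIZ")
  t1 <- add(siz, 60, 9, "trunk")
  t2 <- add(t1, 60, 9, "trunk")
  base <- add(t2, 60, 9, "trunk")

  if (kind == "fan") {
    for (b in seq_len(n_branches)) {
      p <- base
      d <- seq(4.5, 2.5, length.out = comps_per_branch)
      for (k in seq_len(comps_per_branch))
        p <- add(p, 45, d[k], "fieldA")
    }
  } else if (kind == "rall_symmetric") {
    depth <- max(1, floor(log2(max(2, n_branches))))
    d0 <- 4
    grow <- function(parent, diam, level) {
      # two compartments per branch segment
      p <- add(parent, 40, diam, "fieldA")
      p <- add(p, 40, diam, "fieldA")
      if (level < depth) {
        dc <- (diam^1.5 / 2)^(2 / 3)
        grow(p, dc, level + 1)
        grow(p, dc, level + 1)
      }
    }
    grow(base, d0, 1)
  } else {
    n_target <- n_branches * comps_per_branch
    tips <- c(base)
    diam <- c(3)
    count <- 0
    while (count < n_target) {
      i <- sample.int(length(tips), 1)
      p <- add(tips[i], 20 + runif(1, 0, 30), max(0.8, diam[i] * runif(1, 0.7, 1)),
               "fieldA")
      count <- count + 1
      if (runif(1) < 0.25) {  # branch
        tips <- c(tips, p); diam <- c(diam, diam[i] * 0.8)
      } else {
        tips[i] <- p
      }
    }
  }
  df <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  df$comp <- seq_len(nrow(df))
  neuron_morphology(df[, c("comp", "parent", "length_um", "diam_um", "region")])
}

#' Read a morphology from an SWC file
#'
#' Standard SWC format: one point per line (`id type x y z radius parent`).
#' Consecutive points form cylindrical sections; the region label of each
#' section comes from the SWC type code through `region_map`.
#'
#' @param path Path to an SWC file.
#' @param region_map Named character vector mapping SWC type codes to region
#'   labels.
#' @return A [neuron_morphology()] tibble.
#' @export
read_swc <- function(path,
                     region_map = c("1" = "SIZ", "2" = "axon", "3" = "fieldA",
                                    "4" = "trunk", "5" = "fieldB",
                                    "6" = "fieldC")) {
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z", "r",
                                         "parent"))
  raw <- raw[order(raw$id), ]
  idx <- match(raw$parent, raw$id)
  keep <- !is.na(idx)  # non-root points become cylinders to their parent
  len <- sqrt((raw$x - raw$x[idx])^2 + (raw$y - raw$y[idx])^2 +
              (raw$z - raw$z[idx])^2)
  region <- region_map[as.character(raw$type)]
  if (any(is.na(region)))
    stop("SWC type codes without a region mapping: ",
         paste(unique(raw$type[is.na(region)]), collapse = ", "))
  # the root point has no cylinder; its first child starts the tree
  child_rows <- which(keep)
  new_id <- integer(nrow(raw))
  new_id[child_rows] <- seq_along(child_rows)
  root_pt <- which(!keep)[1]
  parent_new <- vapply(child_rows, function(i) {
    p <- idx[i]
    if (p == root_pt) 0L else new_id[p]
  }, integer(1))
  df <- tibble::tibble(comp = seq_along(child_rows),
                       parent = parent_new,
                       length_um = pmax(len[child_rows], 0.1),
                       diam_um = 2 * raw$r[child_rows],
                       region = unname(region[child_rows]))
  neuron_morphology(df)
}

#' Passive membrane properties
#'
#' @param ra Axial resistivity (Ohm cm).
#' @param cm Specific membrane capacitance (uF/cm^2).
#' @param g_pas Leak conductance density (S/cm^2).
#' @param e_pas Leak reversal (mV); per-compartment values are recalibrated
#'   when building a model so the resting potential with channels at rest is
#'   the target RMP.
#' @return A `passive_props` list.
#' @export
passive_props <- function(ra = 300, cm = 1, g_pas = 1e-4, e_pas = -65) {
  stopifnot(ra > 0, cm > 0, g_pas > 0)
  structure(list(ra = ra, cm = cm, g_pas = g_pas, e_pas = e_pas),
            class = "passive_props")
}

# space constant in um for a cylinder of diameter d_um
lambda_um <- function(d_um, passive) {
  d_cm <- d_um * 1e-4
  rm <- 1 / passive$g_pas                       # Ohm cm^2
  sqrt(rm * d_cm / (4 * passive$ra)) * 1e4
}

#' Spatially discretize a morphology
#'
#' Splits sections so that no compartment is longer than a stated fraction
#' of its local space constant lambda. Total membrane area is conserved
#' exactly (cylinders are split, never resized).
#'
#' @param morph A [neuron_morphology()].
#' @param passive A [passive_props()] (sets lambda).
#' @param max_frac_lambda Maximal compartment length as a fraction of
#'   lambda.
#' @return A finer [neuron_morphology()].
#' @export
discretize <- function(morph, passive, max_frac_lambda = 0.1) {
  stopifnot(inherits(morph, "neuron_morphology"), max_frac_lambda > 0)
  lam <- lambda_um(morph$diam_um, passive)
  n_pieces <- pmax(1L, ceiling(morph$length_um / (max_frac_lambda * lam)))
  rows <- vector("list", nrow(morph))
  new_last <- integer(nrow(morph))  # new id of each old section's distal end
  counter <- 0L
  out <- list()
  for (i in seq_len(nrow(morph))) {
    k <- n_pieces[i]
    p_old <- morph$parent[i]
    parent_new <- if (p_old == 0) 0L else new_last[p_old]
    for (j in seq_len(k)) {
      counter <- counter + 1L
      out[[counter]] <- list(comp = counter, parent = parent_new,
                             length_um = morph$length_um[i] / k,
                             diam_um = morph$diam_um[i],
                             region = morph$region[i])
      parent_new <- counter
    }
    new_last[i] <- counter
  }
  neuron_morphology(dplyr::bind_rows(lapply(out, tibble::as_tibble)))
}
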
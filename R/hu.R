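#' HU decoration of DNA chains
#'
#' HU is an abundant, sequence-neutral bacterial architectural protein
#' that bends DNA sharply over a 14-step binding site.  Bound HU is
#' modeled as a rigid footprint: the 14 base-pair steps of the site are
#' assigned the fixed step parameters of a bent footprint variant and
#' carry no elastic deformation energy.  Binding levels are specified as
#' one dimer per `mean_spacing` base pairs of unconstrained linear DNA and
#' converted to a per-site acceptance probability by inverting the
#' random-sequential-placement expectation.
#'
#' @name hu
NULL

#' Length of an HU footprint in base-pair steps
#' @export
hu_footprint_length <- function() 14L

#' Construct an HU footprint
#'
#' @param id short label.
#' @param steps 14 x 6 matrix of step parameters (columns tilt, roll,
#'   twist, shift, slide, rise).
#' @param provenance free text describing where the parameters came from.
#' @return Object of class `hu_footprint`.
#' @export
hu_footprint <- function(id, steps, provenance = "") {
  steps <- as.matrix(steps)
  if (nrow(steps) != hu_footprint_length() || ncol(steps) != 6L)
    stop("an HU footprint must be a 14 x 6 step-parameter matrix")
  colnames(steps) <- c("tilt", "roll", "twist", "shift", "slide", "rise")
  structure(list(id = id, steps = steps, provenance = provenance),
            class = "hu_footprint")
}

#' Net bend of a footprint
#'
#' Angle (degrees) between the normals of the base pairs entering and
#' leaving the footprint.
#'
#' @param fp an [hu_footprint()].
#' @export
footprint_net_bend <- function(fp) {
  frames <- build_chain_frames(dna_chain(fp$steps))
  z1 <- frames[[1]]$axes[, 3]
  z2 <- frames[[length(frames)]]$axes[, 3]
  acos(min(1, max(-1, sum(z1 * z2)))) / DEG
}

#' Synthetic HU footprint variants
#'
#' Four parametric, clearly non-crystallographic footprints emulating the
#' published HU-DNA complexes: two sharp roll kinks (the proline
#' intercalation sites) nine steps apart, mild bending elsewhere, and
#' slight untwisting, giving net bends of roughly 105 to 140 degrees.
#' User-supplied footprints derived from actual structures can be read
#' with [read_par()] and wrapped with [hu_footprint()].
#'
#' @return List of four [hu_footprint()] objects.
#' @export
hu_fixture_footprints <- function() {
  kink <- c(62, 70, 80, 90)
  lapply(seq_along(kink), function(v) {
    roll <- rep(4, 14)
    roll[c(3, 12)] <- kink[v]
    twist <- rep(33.5, 14)
    twist[c(3, 12)] <- 28
    hu_footprint(
      id = sprintf("synthetic-%d", v),
      steps = cbind(tilt = 0, roll = roll, twist = twist,
                    shift = 0, slide = 0, rise = 3.4),
      provenance = "synthetic two-kink fixture (not from a structure)")
  })
}

#' Per-site start density of random sequential placement
#'
#' Expected number of placed 14-step footprints per base-pair site on an
#' infinitely long free chain when each site, visited once in random
#' order, accepts a footprint with probability `p` if its window is free.
#' Mapping the uniform visit order to exponential arrival times makes the
#' process identical to classical random sequential adsorption of k-mers
#' observed at time `-log(1 - p)`, whose placement rate has the standard
#' closed form used here.
#'
#' @param p per-site acceptance probability in [0, 1].
#' @param k footprint length in steps.
#' @return Expected placed footprints per site.
#' @export
rsa_density <- function(p, k = hu_footprint_length()) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  tau <- if (p >= 1) 40 else min(40, -log1p(-p))
  l <- seq_len(k - 1)
  rate <- function(t) {
    vapply(t, function(ti)
      exp(-ti - 2 * sum((1 - exp(-l * ti)) / l)), numeric(1))
  }
  stats::integrate(rate, 0, tau, rel.tol = 1e-10)$value
}

#' Calibrate the per-site acceptance probability for a binding level
#'
#' Finds `p` such that the expected number of footprints placed on a free
#' linear chain equals `chain_length / mean_spacing`, i.e. one HU dimer
#' per `mean_spacing` bp on average, accounting for overlap exclusion
#' through the [rsa_density()] expectation.  Edge effects on finite chains
#' are of order `14 / chain_length` and are neglected.
#'
#' @param mean_spacing target bp per bound dimer on free DNA (>= 14).
#' @param chain_length chain length used to validate feasibility (>= 14).
#' @return Acceptance probability in (0, 1).
#' @export
calibrate_site_probability <- function(mean_spacing, chain_length = 1e4) {
  if (chain_length < hu_footprint_length())
    stop("chain_length must be at least one footprint")
  target <- 1 / mean_spacing
  max_rho <- rsa_density(1)
  if (target >= max_rho)
    stop("infeasible binding level: at most ", signif(max_rho, 4),
         " footprints per bp can be placed (jamming limit)")
  stats::uniroot(function(p) rsa_density(p) - target,
                 interval = c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

#' HU binding configuration
#'
#' @param mean_spacing bp of free linear DNA per bound dimer (e.g. 150 for
#'   exponential-growth levels, 1000 for trace binding).
#' @param footprints list of [hu_footprint()] variants; a variant is
#'   chosen uniformly at random at each placed site.
#' @param site_probability per-site acceptance probability; calibrated
#'   from `mean_spacing` when omitted.
#' @export
binding_config <- function(mean_spacing, footprints = hu_fixture_footprints(),
                           site_probability = NULL) {
  if (mean_spacing < hu_footprint_length())
    stop("mean_spacing must be at least the footprint length")
  if (inherits(footprints, "hu_footprint")) footprints <- list(footprints)
  if (!length(footprints)) stop("at least one footprint is required")
  if (is.null(site_probability))
    site_probability <- calibrate_site_probability(mean_spacing)
  if (site_probability <= 0 || site_probability >= 1)
    stop("site_probability must lie in (0, 1)")
  structure(list(mean_spacing = mean_spacing, footprints = footprints,
                 site_probability = site_probability),
            class = "binding_config")
}

# core placement pass: returns start sites and footprint variant indices.
# `occ` may pre-mark occupied steps.
.place_footprints <- function(n, p, n_variants, occ = logical(n)) {
  L <- hu_footprint_length()
  ns <- n - L + 1L
  sites <- integer(0); variants <- integer(0)
  if (ns < 1L) return(list(sites = sites, variants = variants))
  order <- sample.int(ns)
  coins <- stats::runif(ns) <= p
  for (s in order) {
    if (!coins[s]) next
    win <- s:(s + L - 1L)
    if (any(occ[win])) next
    occ[win] <- TRUE
    sites <- c(sites, s)
    if (n_variants > 1L)
      variants <- c(variants, sample.int(n_variants, 1L))
    else variants <- c(variants, 1L)
  }
  list(sites = sites, variants = variants)
}

#' Decorate a chain with rigid HU footprints
#'
#' Visits candidate sites in a random permutation; every free,
#' non-overlapping 14-step window is accepted with the configured
#' probability, its steps are replaced by the parameters of a footprint
#' variant chosen uniformly at random, and an annotation is recorded.
#' Previously annotated (occupied) steps are never overwritten.
#'
#' @param chain a [dna_chain()].
#' @param cfg a [binding_config()].
#' @return The decorated [dna_chain()].
#' @export
decorate <- function(chain, cfg) {
  pl <- .place_footprints(n_steps(chain), cfg$site_probability,
                          length(cfg$footprints), occupied_steps(chain))
  L <- hu_footprint_length()
  for (idx in seq_along(pl$sites)) {
    s <- pl$sites[idx]
    fp <- cfg$footprints[[pl$variants[idx]]]
    chain$steps[s:(s + L - 1L), ] <- fp$steps
  }
  if (length(pl$sites))
    chain$annotations <- rbind(
      chain$annotations,
      data.frame(site = pl$sites,
                 footprint = vapply(cfg$footprints[pl$variants],
                                    function(f) f$id, "")))
  chain
}

# vector version used inside half-chain sampling (angles in degrees)
.decorate_angles <- function(tilt, roll, twist, cfg) {
  pl <- .place_footprints(length(tilt), cfg$site_probability,
                          length(cfg$footprints))
  L <- hu_footprint_length()
  for (idx in seq_along(pl$sites)) {
    s <- pl$sites[idx]
    fp <- cfg$footprints[[pl$variants[idx]]]$steps
    win <- s:(s + L - 1L)
    tilt[win] <- fp[, "tilt"]; roll[win] <- fp[, "roll"]
    twist[win] <- fp[, "twist"]
  }
  list(tilt = tilt, roll = roll, twist = twist,
       n_placed = length(pl$sites))
}

#' Simulate HU occupancy on free linear chains
#'
#' @param cfg a [binding_config()].
#' @param chain_length chain length in steps.
#' @param reps number of independent chains.
#' @return Integer vector of bound-dimer counts, one per chain.
#' @export
simulate_free_occupancy <- function(cfg, chain_length, reps = 100) {
  vapply(seq_len(reps), function(i)
    length(.place_footprints(chain_length, cfg$site_probability,
                             1L)$sites), integer(1))
}

#' Distribution of bound-HU counts per loop type
#'
#' @param loop_type character vector, one entry per closed configuration.
#' @param n_hu integer vector of bound-HU counts, parallel to `loop_type`.
#' @return Data frame with columns `loop_type`, `n_hu`, `count`,
#'   `fraction`; fractions sum to 1 within each loop type.
#' @export
uptake_histogram <- function(loop_type, n_hu) {
  if (length(loop_type) != length(n_hu))
    stop("loop_type and n_hu must have equal length")
  tab <- as.data.frame(table(loop_type = loop_type, n_hu = n_hu),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab$n_hu <- as.integer(as.character(tab$n_hu))
  totals <- tapply(tab$count, tab$loop_type, sum)
  tab$fraction <- tab$count / as.numeric(totals[tab$loop_type])
  tab[order(tab$loop_type, tab$n_hu), ]
}
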
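#' Elastic model of an ideal, inextensible, naturally straight DNA helix
#'
#' Per-step rest values and fluctuation scales of the quadratic, diagonal
#' deformation energy.  Force constants follow the variance-reciprocal
#' convention `k = kBT / sigma^2`, so an rms fluctuation of one sigma in a
#' single component costs 1/2 kBT.  Defaults: bending rms 4.84 deg in each
#' of tilt and roll (persistence length close to 500 Angstrom), twist rms
#' 4.09 deg (1.4 times more restricted than bending, in variance), a
#' helical rest state of 10.5 bp per turn, and a fixed rise of 3.4
#' Angstrom.  Selected steps can be softened: their angular rms values are
#' multiplied by `soft_factor` (bending and twisting alike).
#'
#' @param n_steps number of base-pair steps described by the model.
#' @param rest_twist intrinsic twist per step, degrees.
#' @param rest_tilt,rest_roll intrinsic bending components, degrees
#'   (naturally straight helix: 0).
#' @param sigma_tilt,sigma_roll,sigma_twist rms fluctuations, degrees.
#' @param rise fixed rise per step, Angstrom (inextensible model).
#' @param soft_steps integer indices (1-based) of softened steps.
#' @param soft_factor rms multiplier applied at `soft_steps`.
#' @return Object of class `elastic_model`.
#' @examples
#' m <- elastic_model(78)
#' (m$sigma_tilt / m$sigma_twist)^2  # twisting 1.4x more restricted
#' @export
elastic_model <- function(n_steps,
                          rest_twist = 360 / 10.5,
                          rest_tilt = 0, rest_roll = 0,
                          sigma_tilt = 4.84, sigma_roll = 4.84,
                          sigma_twist = 4.09,
                          rise = 3.4,
                          soft_steps = integer(0),
                          soft_factor = 1.5) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (sigma_tilt <= 0 || sigma_roll <= 0 || sigma_twist <= 0)
    stop("fluctuation scales (sigmas) must be positive")
  if (rest_twist <= 0 || rest_twist >= 180)
    stop("rest_twist must lie in (0, 180) degrees")
  if (soft_factor <= 0) stop("soft_factor must be positive")
  soft_steps <- sort(unique(as.integer(soft_steps)))
  if (length(soft_steps) && (min(soft_steps) < 1L || max(soft_steps) > n_steps))
    stop("soft_steps out of range [1, n_steps]")
  structure(list(n_steps = n_steps, rest_twist = rest_twist,
                 rest_tilt = rest_tilt, rest_roll = rest_roll,
                 sigma_tilt = sigma_tilt, sigma_roll = sigma_roll,
                 sigma_twist = sigma_twist, rise = rise,
                 soft_steps = soft_steps, soft_factor = soft_factor),
            class = "elastic_model")
}

#' @export
print.elastic_model <- function(x, ...) {
  cat("<elastic_model> ", x$n_steps, " steps; rest twist ",
      signif(x$rest_twist, 6), " deg (", signif(360 / x$rest_twist, 4),
      " bp/turn); sigmas (t,r,w) = ", x$sigma_tilt, ", ", x$sigma_roll,
      ", ", x$sigma_twist, " deg; ", length(x$soft_steps),
      " softened step(s)\n", sep = "")
  invisible(x)
}

# per-step sigma matrix (n x 3), soft factor applied
.step_sigmas <- function(model) {
  s <- matrix(c(model$sigma_tilt, model$sigma_roll, model$sigma_twist),
              model$n_steps, 3, byrow = TRUE)
  if (length(model$soft_steps))
    s[model$soft_steps, ] <- s[model$soft_steps, , drop = FALSE] *
      model$soft_factor
  s
}

#' Elastic deformation energy of a chain, in kBT
#'
#' `E = sum over steps of (1/2) [(tilt - tilt0)^2 / s_t^2 +
#' (roll - roll0)^2 / s_r^2 + (twist - twist0)^2 / s_w^2]`, with the rms
#' scales enlarged by the soft factor at softened steps.  Steps occupied by
#' a rigid protein footprint (chain annotations) are excluded from the sum.
#'
#' @param chain a [dna_chain()] with `n_steps(chain) == model$n_steps`.
#' @param model an [elastic_model()].
#' @return List with `E_total`, `E_bend`, `E_twist` (kBT);
#'   `E_total = E_bend + E_twist`.
#' @export
elastic_energy <- function(chain, model) {
  if (n_steps(chain) != model$n_steps)
    stop("chain length (", n_steps(chain), ") does not match model n_steps (",
         model$n_steps, ")")
  s <- .step_sigmas(model)
  dt <- chain$steps[, "tilt"] - model$rest_tilt
  dr <- chain$steps[, "roll"] - model$rest_roll
  dw <- chain$steps[, "twist"] - model$rest_twist
  free <- !occupied_steps(chain)
  eb <- 0.5 * ((dt / s[, 1])^2 + (dr / s[, 2])^2)
  ew <- 0.5 * (dw / s[, 3])^2
  E_bend <- sum(eb[free])
  E_twist <- sum(ew[free])
  list(E_total = E_bend + E_twist, E_bend = E_bend, E_twist = E_twist)
}

#' Logical mask of protein-occupied steps
#'
#' Each annotation marks a rigid footprint of [hu_footprint_length()] steps
#' starting at its `site` index.
#'
#' @param chain a [dna_chain()].
#' @export
occupied_steps <- function(chain) {
  occ <- logical(n_steps(chain))
  for (s in chain$annotations$site)
    occ[s:(s + hu_footprint_length() - 1L)] <- TRUE
  occ
}

#' Soften selected steps of an elastic model
#'
#' Multiplies the angular rms fluctuations (bending and twisting
#' components) at the given steps, emulating the enhanced deformability of
#' pyrimidine-purine steps.
#'
#' @param model an [elastic_model()].
#' @param sites integer step indices (1-based).
#' @param factor rms multiplier (> 0); 1.5 reproduces the enhanced
#'   flexibility assigned to pyrimidine-purine steps.
#' @return A new model; the energy of any fixed chain is non-increasing in
#'   `factor` at the softened sites.
#' @export
apply_softening <- function(model, sites, factor = 1.5) {
  sites <- sort(unique(as.integer(sites)))
  if (length(sites) && (min(sites) < 1L || max(sites) > model$n_steps))
    stop("softening sites out of range")
  if (factor <= 0) stop("factor must be positive")
  model$soft_steps <- sites
  model$soft_factor <- factor
  model
}

#' Change the intrinsic twist of the helix
#'
#' @param model an [elastic_model()].
#' @param twist0 new rest twist per step, degrees in (0, 180).  36 degrees
#'   corresponds to an overtwisted helix with a 10-bp repeat.
#' @export
set_intrinsic_twist <- function(model, twist0) {
  if (twist0 <= 0 || twist0 >= 180)
    stop("twist0 must lie in (0, 180) degrees")
  model$rest_twist <- twist0
  model
}

#' Persistence length implied by the model's bending fluctuations
#'
#' For independent per-component bending with rms `sigma` (radians) the
#' directional correlation of the helix axis decays per step by
#' `(sigma_tilt^2 + sigma_roll^2) / 2`, giving
#' `P = 2 rise / (sigma_tilt^2 + sigma_roll^2)`.
#'
#' @param model an [elastic_model()].
#' @return Persistence length in Angstrom (about 476 at the defaults).
#' @export
model_persistence_length <- function(model) {
  2 * model$rise / ((model$sigma_tilt * DEG)^2 + (model$sigma_roll * DEG)^2)
}

#' Serialize an elastic model to JSON
#' @param model an [elastic_model()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
model_to_json <- function(model, path = NULL) {
  x <- unclass(model)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read an elastic model from JSON
#' @param path file path or JSON string produced by [model_to_json()].
#' @export
model_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  elastic_model(n_steps = x$n_steps, rest_twist = x$rest_twist,
                rest_tilt = x$rest_tilt, rest_roll = x$rest_roll,
                sigma_tilt = x$sigma_tilt, sigma_roll = x$sigma_roll,
                sigma_twist = x$sigma_twist, rise = x$rise,
                soft_steps = x$soft_steps, soft_factor = x$soft_factor)
}

#' Read a base-pair-step parameter file (.par layout)
#'
#' The text layout follows the 3DNA convention for step-parameter tables:
#' a header line giving the number of steps, a column-header line, then one
#' row per step with six whitespace-separated values in the order
#' shift, slide, rise, tilt, roll, twist (Angstrom, Angstrom, Angstrom,
#' degrees, degrees, degrees).
#'
#' @param path file path.
#' @return A [dna_chain()].
#' @export
read_par <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  if (is.na(n) || n < 1) stop("malformed .par header: ", lines[1])
  rows <- lines[3:(2 + n)]
  vals <- t(vapply(strsplit(trimws(rows), "\\s+"),
                   function(x) as.numeric(x[1:6]), numeric(6)))
  if (any(!is.finite(vals))) stop("malformed .par rows")
  # file order: shift slide rise tilt roll twist -> internal order
  dna_chain(vals[, c(4, 5, 6, 1, 2, 3), drop = FALSE])
}

#' Write a chain to a base-pair-step parameter file (.par layout)
#'
#' Columns are written in the order shift, slide, rise, tilt, roll, twist
#' (see [read_par()]).
#'
#' @param chain a [dna_chain()].
#' @param path file path.
#' @export
write_par <- function(chain, path) {
  s <- chain$steps
  out <- c(sprintf("%5d # base-pair steps", n_steps(chain)),
           sprintf("#%9s %10s %10s %10s %10s %10s",
                   "Shift", "Slide", "Rise", "Tilt", "Roll", "Twist"),
           sprintf("%10.4f %10.4f %10.4f %10.4f %10.4f %10.4f",
                   s[, "shift"], s[, "slide"], s[, "rise"],
                   s[, "tilt"], s[, "roll"], s[, "twist"]))
  writeLines(out, path)
  invisible(path)
}
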
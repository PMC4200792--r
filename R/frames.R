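#' Base-pair reference frames and rigid-body step algebra
#'
#' A base pair is represented by a right-handed orthonormal triad and an
#' origin; successive base pairs are related by six rigid-body step
#' parameters (tilt, roll, twist in degrees; shift, slide, rise in
#' Angstrom) composed in the mid-step (dimeric frame) convention of the
#' 3DNA/CEHS standard, so that the magnitudes of the translational
#' components are independent of chain direction.
#'
#' @name frames
NULL

DEG <- pi / 180

# skew generators used throughout the frame algebra
.Lz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 0), 3, 3)

.rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

# exp([v x]) for v = (v1, v2, 0) (radians), Rodrigues form
.rot_bend <- function(v1, v2) {
  th2 <- v1 * v1 + v2 * v2
  th <- sqrt(th2)
  if (th < 1e-12) {
    a <- 1 - th2 / 6
    b <- 0.5 - th2 / 24
  } else {
    a <- sin(th) / th
    b <- (1 - cos(th)) / th2
  }
  K <- matrix(c(0, 0, -v2, 0, 0, v1, v2, -v1, 0), 3, 3)
  diag(3) + a * K + b * (K %*% K)
}

#' Construct a base-pair frame
#'
#' @param origin numeric 3-vector, Angstrom.
#' @param axes 3x3 rotation matrix whose columns are the short axis, the
#'   long axis, and the normal of the base pair.
#' @return An object of class `bp_frame`.
#' @examples
#' f <- bp_frame()
#' compose_step(f, step_params(twist = 360 / 10.5))
#' @export
bp_frame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  origin <- as.numeric(origin)
  axes <- matrix(as.numeric(axes), 3, 3)
  f <- structure(list(origin = origin, axes = axes), class = "bp_frame")
  validate_bp_frame(f)
  f
}

#' @rdname bp_frame
#' @param f object to validate.
#' @param tol orthonormality tolerance.
#' @export
validate_bp_frame <- function(f, tol = 1e-10) {
  if (!inherits(f, "bp_frame")) stop("not a 'bp_frame' object")
  if (length(f$origin) != 3L || !all(is.finite(f$origin)))
    stop("frame origin must be a finite 3-vector")
  R <- f$axes
  if (!all(is.finite(R))) stop("frame axes must be finite")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("frame axes are not orthonormal (tolerance ", tol, ")")
  if (det(R) < 0) stop("frame axes are left-handed (det < 0)")
  invisible(f)
}

#' Six rigid-body base-pair-step parameters
#'
#' Angles are in degrees, distances in Angstrom.  The inextensible-helix
#' model used throughout the package freezes shift and slide at 0 and rise
#' at its canonical value, so the three angles are the only fluctuating
#' components.
#'
#' @param tilt,roll,twist step angles in degrees.
#' @param shift,slide,rise step displacements in Angstrom.
#' @return Named numeric vector of length 6 with class `step_params`.
#' @export
step_params <- function(tilt = 0, roll = 0, twist = 0,
                        shift = 0, slide = 0, rise = 3.4) {
  p <- c(tilt = tilt, roll = roll, twist = twist,
         shift = shift, slide = slide, rise = rise)
  if (!all(is.finite(p))) stop("step parameters must be finite")
  structure(p, class = "step_params")
}

# internal: rotation T and mid-frame M from angles in radians
.step_rotations <- function(tilt, roll, twist) {
  Z <- .rot_z(twist / 2)
  list(T = Z %*% .rot_bend(tilt, roll) %*% Z,
       M = Z %*% .rot_bend(tilt / 2, roll / 2))
}

#' Advance a base-pair frame by one step
#'
#' Applies the CEHS mid-step composition: the full step rotation is
#' `Rz(twist/2) %*% exp([(tilt, roll, 0) x]) %*% Rz(twist/2)` and the
#' displacement is expressed in the mid-step frame.
#'
#' @param frame a [bp_frame()].
#' @param p a [step_params()] vector (or any numeric vector of the six
#'   values in the same order).
#' @return The frame of the next base pair.
#' @export
compose_step <- function(frame, p) {
  validate_bp_frame(frame)
  p <- as.numeric(p)
  rot <- .step_rotations(p[1] * DEG, p[2] * DEG, p[3] * DEG)
  bp_frame(origin = frame$origin + frame$axes %*% rot$M %*% p[4:6],
           axes = frame$axes %*% rot$T)
}

#' Recover step parameters relating two base-pair frames
#'
#' Inverse of [compose_step()]: decomposes the relative rotation
#' `t(f1$axes) %*% f2$axes` in ZYZ Euler form to obtain the bend magnitude
#' and phase (hence tilt and roll) and the twist, and expresses the
#' displacement in the mid-step frame.  Twist is returned in
#' (-180, 180] degrees.
#'
#' @param f1,f2 base-pair frames.
#' @return A [step_params()] vector such that `compose_step(f1, result)`
#'   reproduces `f2` to numerical tolerance.
#' @export
params_from_frames <- function(f1, f2) {
  validate_bp_frame(f1)
  validate_bp_frame(f2)
  A <- crossprod(f1$axes, f2$axes)
  # twist about the mean normal, numerically robust down to zero bend:
  # for A = Rz(tw/2) exp([b x]) Rz(tw/2) the (1 + cos(bend)) factor
  # cancels in this arctangent
  tw <- atan2(A[2, 1] - A[1, 2], A[1, 1] + A[2, 2])
  Z <- .rot_z(-tw / 2)
  B <- Z %*% A %*% Z          # pure bend rotation about an in-plane axis
  cb <- min(1, max(-1, (sum(diag(B)) - 1) / 2))
  beta <- acos(cb)
  if (beta < 1e-8) {
    # small-angle: skew part is the bend vector itself
    tilt <- (B[3, 2] - B[2, 3]) / 2
    roll <- (B[1, 3] - B[3, 1]) / 2
  } else if (pi - beta < 1e-6) {
    # 180-degree bend: axis from the symmetric part (sign convention:
    # roll >= 0)
    u2 <- sqrt(max(0, (1 + B[2, 2]) / 2))
    u1 <- if (u2 > 1e-8) (B[1, 2] + B[2, 1]) / (4 * u2 / 2) / 2
    else sqrt(max(0, (1 + B[1, 1]) / 2))
    nrm <- sqrt(u1^2 + u2^2)
    tilt <- beta * u1 / nrm
    roll <- beta * u2 / nrm
  } else {
    s <- beta / (2 * sin(beta))
    tilt <- (B[3, 2] - B[2, 3]) * s
    roll <- (B[1, 3] - B[3, 1]) * s
  }
  M <- f1$axes %*% .step_rotations(tilt, roll, tw)$M
  d <- as.numeric(crossprod(M, f2$origin - f1$origin))
  step_params(tilt = tilt / DEG, roll = roll / DEG, twist = tw / DEG,
              shift = d[1], slide = d[2], rise = d[3])
}

#' Ordered collection of base-pair steps
#'
#' A chain is an `n x 6` matrix of step parameters (columns tilt, roll,
#' twist, shift, slide, rise) plus annotations marking protein-occupied
#' sites.  Annotated footprints are rigid: their steps carry no elastic
#' deformation energy.
#'
#' @param steps numeric matrix (or vector of six) of step parameters.
#' @param annotations data frame with columns `site` (1-based index of the
#'   first step of a footprint) and `footprint` (identifier).
#' @return Object of class `dna_chain`.
#' @export
dna_chain <- function(steps, annotations = NULL) {
  if (is.null(dim(steps))) steps <- matrix(steps, nrow = 1)
  steps <- as.matrix(steps)
  if (ncol(steps) != 6L) stop("steps must have six columns")
  if (nrow(steps) < 1L) stop("chain must contain at least one step")
  if (!all(is.finite(steps))) stop("step parameters must be finite")
  colnames(steps) <- c("tilt", "roll", "twist", "shift", "slide", "rise")
  if (is.null(annotations))
    annotations <- data.frame(site = integer(0), footprint = character(0))
  structure(list(steps = steps, annotations = annotations),
            class = "dna_chain")
}

#' @export
print.dna_chain <- function(x, ...) {
  cat("<dna_chain> ", nrow(x$steps), " steps, ",
      nrow(x$annotations), " bound footprint(s)\n", sep = "")
  invisible(x)
}

#' Number of steps in a chain
#' @param chain a [dna_chain()].
#' @export
n_steps <- function(chain) nrow(chain$steps)

#' Rest-state (straight B-DNA) chain
#'
#' @param n number of steps.
#' @param model an [elastic_model()] supplying the rest twist and rise.
#' @return A [dna_chain()] at the model's rest state (zero energy).
#' @export
rest_chain <- function(n, model = elastic_model(n)) {
  dna_chain(cbind(tilt = 0, roll = 0, twist = rep(model$rest_twist, n),
                  shift = 0, slide = 0, rise = model$rise))
}

#' Build all base-pair frames of a chain
#'
#' @param chain a [dna_chain()].
#' @param start frame of the first base pair.
#' @return List of `n_steps + 1` [bp_frame()] objects.
#' @export
build_chain_frames <- function(chain, start = bp_frame()) {
  validate_bp_frame(start)
  n <- n_steps(chain)
  frames <- vector("list", n + 1L)
  frames[[1L]] <- start
  for (i in seq_len(n))
    frames[[i + 1L]] <- compose_step(frames[[i]], chain$steps[i, ])
  frames
}

#' Extract frame origins as a matrix
#' @param frames list of [bp_frame()] objects.
#' @return `length(frames) x 3` matrix of origins.
#' @export
frame_origins <- function(frames) {
  t(vapply(frames, function(f) f$origin, numeric(3)))
}

#' Extract frame normals (base-pair z axes) as a matrix
#' @param frames list of [bp_frame()] objects.
#' @export
frame_normals <- function(frames) {
  t(vapply(frames, function(f) f$axes[, 3], numeric(3)))
}
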
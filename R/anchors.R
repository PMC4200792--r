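#' Loop anchors: repressor-imposed boundary conditions
#'
#' A loop anchor fixes the global frames of the base pairs at the free
#' ends of the two operator arms of the repressor assembly and carries the
#' phantom closing step that relates the last base pair of the loop back
#' to the first.  Absolute repressor coordinates are not taken from any
#' crystal structure: anchors are built from a parametric, synthetic
#' V-shaped geometry chosen so that antiparallel 92-bp loops describe
#' gradual U-turns.  All results that depend on the V geometry are
#' therefore qualitative.
#'
#' @name anchors
NULL

# general Rodrigues rotation from a rotation vector (radians)
.rotvec <- function(v) {
  th2 <- sum(v * v)
  th <- sqrt(th2)
  if (th < 1e-12) {
    a <- 1 - th2 / 6; b <- 0.5 - th2 / 24
  } else {
    a <- sin(th) / th; b <- (1 - cos(th)) / th2
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + a * K + b * (K %*% K)
}

#' Construct a loop anchor from its components
#'
#' @param first_frame,last_frame [bp_frame()]s of the base pairs at the
#'   free ends of the two operator arms (loop runs 5' to 3' from
#'   `first_frame` to `last_frame`).
#' @param orientation one of `"A1"`, `"A2"`, `"P1"`, `"P2"`.
#' @param label free-text label.
#' @param closing_step optional [step_params()]; computed from the frames
#'   when omitted.  The phantom base pair appended to the loop end through
#'   this step coincides with `first_frame` in the reference complex.
#' @param hinge optional list (`point`, `axis`, `arm`) describing the
#'   bending axis used by [open_repressor()].
#' @export
loop_anchor <- function(first_frame, last_frame,
                        orientation = c("A1", "A2", "P1", "P2"),
                        label = "", closing_step = NULL, hinge = NULL) {
  orientation <- match.arg(orientation)
  validate_bp_frame(first_frame)
  validate_bp_frame(last_frame)
  if (is.null(closing_step))
    closing_step <- params_from_frames(last_frame, first_frame)
  structure(list(first_frame = first_frame, last_frame = last_frame,
                 closing_step = closing_step, orientation = orientation,
                 label = label, hinge = hinge),
            class = "loop_anchor")
}

#' @export
print.loop_anchor <- function(x, ...) {
  cat("<loop_anchor> ", x$orientation,
      if (nzchar(x$label)) paste0(" (", x$label, ")"),
      "; end separation ",
      signif(sqrt(sum((x$first_frame$origin - x$last_frame$origin)^2)), 4),
      " A\n", sep = "")
  invisible(x)
}

#' Parametric V-shaped repressor geometry
#'
#' Synthetic stand-in for the crystallographic V-shaped assembly: two
#' straight arms in the xz-plane opening symmetrically about +z by the
#' virtual valence angle `arm_angle`, each carrying a 14-step operator
#' whose center sits `arm_length` Angstrom from the vertex, displaced
#' `operator_offset` Angstrom out of the V plane.
#'
#' @param arm_angle virtual valence angle between the arms, degrees.
#' @param arm_length vertex-to-operator-center distance, Angstrom.
#' @param operator_offset out-of-plane displacement of the operator
#'   centers, Angstrom.
#' @param delta_alpha opening change applied to one arm (see
#'   [open_repressor()]), degrees.
#' @param rest_twist,rise helical parameters of the rigid operator DNA.
#' @export
v_geometry <- function(arm_angle = 60, arm_length = 80,
                       operator_offset = 0, delta_alpha = 0,
                       rest_twist = 360 / 10.5, rise = 3.4) {
  if (arm_angle <= 0 || arm_angle >= 180)
    stop("arm_angle must lie in (0, 180) degrees")
  if (arm_length <= 0) stop("arm_length must be positive")
  structure(list(arm_angle = arm_angle, arm_length = arm_length,
                 operator_offset = operator_offset,
                 delta_alpha = delta_alpha,
                 rest_twist = rest_twist, rise = rise),
            class = "v_geometry")
}

# frame with z along d (unit), x chosen in-plane, right-handed
.frame_along <- function(origin, d) {
  z <- d / sqrt(sum(d * d))
  ref <- if (abs(z[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  x <- ref - sum(ref * z) * z
  x <- x / sqrt(sum(x * x))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  # columns: short axis, long axis, normal -> (x, y, z) with y = z cross x
  bp_frame(origin, cbind(x, y, z))
}

# advance a frame k rest-state steps along its own normal
.advance_rest <- function(f, k, rest_twist, rise) {
  bp_frame(f$origin + f$axes %*% c(0, 0, k * rise),
           f$axes %*% .rot_z(k * rest_twist * DEG))
}

#' Build a V-shaped repressor anchor in one of the four orientations
#'
#' Each operator is placed on an arm with its 5'-to-3' direction pointing
#' toward the outside (`+`) or the inside (`-`) of the V; the four
#' combinations generate the two antiparallel (A1, A2) and two parallel
#' (P1, P2) loop types.  The anchor frames are the operator-center frames
#' advanced seven rigid helical steps toward the free DNA, so loop lengths
#' are counted between operator centers (see [loop_free_steps()]).
#'
#' @param g a [v_geometry()].
#' @param orientation `"A1"` (+,-), `"A2"` (-,+), `"P1"` (+,+) or
#'   `"P2"` (-,-).
#' @return A [loop_anchor()].
#' @export
make_v_anchor <- function(g, orientation = c("A1", "A2", "P1", "P2")) {
  orientation <- match.arg(orientation)
  dirs <- switch(orientation,
                 A1 = c(1, -1), A2 = c(-1, 1), P1 = c(1, 1), P2 = c(-1, -1))
  th <- (g$arm_angle / 2) * DEG
  u1 <- c(-sin(th), 0, cos(th))
  u2 <- c(sin(th), 0, cos(th))
  off <- c(0, g$operator_offset, 0)
  c1 <- .frame_along(g$arm_length * u1 + off, dirs[1] * u1)
  c2 <- .frame_along(g$arm_length * u2 + off, dirs[2] * u2)
  # the loop leaves operator 1 at its 3' end and enters operator 2 at its
  # 5' end: advance +7 steps from center 1, -7 steps from center 2
  first <- .advance_rest(c1, 7, g$rest_twist, g$rise)
  last <- .advance_rest(c2, -7, g$rest_twist, g$rise)
  a <- loop_anchor(first, last, orientation,
                   label = sprintf("V alpha=%g%+g deg", g$arm_angle,
                                   g$delta_alpha),
                   hinge = list(point = c(0, 0, 0), axis = c(0, 1, 0),
                                arm = 2L))
  if (g$delta_alpha != 0) a <- open_repressor(a, g$delta_alpha)
  a
}

#' Open or close the repressor by rotating one arm
#'
#' Rigidly rotates the frame on the hinge arm about the bending axis
#' (perpendicular to the long axes of the two arms, through their point of
#' closest approach).  Positive `delta_alpha` opens the V.  The moved
#' frame is transformed isometrically and the closing step is recomputed.
#'
#' @param a a [loop_anchor()] with a `hinge` component.
#' @param delta_alpha opening change, degrees; |delta_alpha| < 120.
#' @export
open_repressor <- function(a, delta_alpha) {
  if (abs(delta_alpha) >= 120) stop("|delta_alpha| must be < 120 degrees")
  if (is.null(a$hinge)) stop("anchor carries no hinge definition")
  if (delta_alpha == 0) return(a)
  R <- .rotvec(a$hinge$axis / sqrt(sum(a$hinge$axis^2)) *
                 delta_alpha * DEG)
  move <- function(f) bp_frame(a$hinge$point +
                                 R %*% (f$origin - a$hinge$point),
                               R %*% f$axes)
  if (a$hinge$arm == 2L) a$last_frame <- move(a$last_frame)
  else a$first_frame <- move(a$first_frame)
  a$closing_step <- params_from_frames(a$last_frame, a$first_frame)
  a$label <- sprintf("%s; opened %+g deg", a$label, delta_alpha)
  a
}

## ---- serialization -------------------------------------------------------

.frame_to_list <- function(f) {
  list(origin = f$origin, axes = as.numeric(f$axes))
}

.frame_from_list <- function(x) {
  bp_frame(as.numeric(x$origin), matrix(as.numeric(x$axes), 3, 3))
}

#' Write anchors to a JSON file
#'
#' Frames are stored as origins plus full 3x3 triads (column-major) to
#' avoid Euler-angle convention drift; triads are validated on load.
#'
#' @param anchors a [loop_anchor()] or list thereof.
#' @param path file path.
#' @param header optional named list stored alongside the anchors (e.g.
#'   the generating seed).
#' @export
write_anchors <- function(anchors, path, header = list()) {
  if (inherits(anchors, "loop_anchor")) anchors <- list(anchors)
  payload <- list(
    header = header,
    anchors = lapply(anchors, function(a) list(
      first_frame = .frame_to_list(a$first_frame),
      last_frame = .frame_to_list(a$last_frame),
      closing_step = as.numeric(a$closing_step),
      orientation = a$orientation,
      label = a$label)))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}

#' Read anchors from a JSON file written by [write_anchors()]
#' @param path file path.
#' @return List of [loop_anchor()] objects.
#' @export
read_anchors <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(x$anchors, function(a)
    loop_anchor(.frame_from_list(a$first_frame),
                .frame_from_list(a$last_frame),
                orientation = a$orientation, label = a$label,
                closing_step = step_params(
                  tilt = a$closing_step[[1]], roll = a$closing_step[[2]],
                  twist = a$closing_step[[3]], shift = a$closing_step[[4]],
                  slide = a$closing_step[[5]], rise = a$closing_step[[6]])))
}

#' Load an ensemble of anchors as a cross-product of per-arm variants
#'
#' The file lists end-frame variants for each arm (`left`, `right`,
#' each an array of frames with `origin` and column-major `axes`), plus an
#' `orientation` label.  Every left variant is paired with every right
#' variant, so `n_left x n_right` anchors are returned, emulating
#' ensembles of operator models bound to the same repressor.
#'
#' @param path JSON file path.
#' @return List of [loop_anchor()] objects of length `n_left * n_right`.
#' @export
load_anchor_ensemble <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  left <- lapply(x$left, .frame_from_list)
  right <- lapply(x$right, .frame_from_list)
  orientation <- if (is.null(x$orientation)) "A1" else x$orientation
  out <- vector("list", length(left) * length(right))
  k <- 0L
  for (i in seq_along(left)) for (j in seq_along(right)) {
    k <- k + 1L
    out[[k]] <- loop_anchor(left[[i]], right[[j]], orientation,
                            label = sprintf("variant %d x %d", i, j))
  }
  out
}

#' Generate a synthetic anchor-ensemble file
#'
#' Perturbs the two end frames of a V anchor by Gaussian rotations and
#' translations, standing in for the ensembles of operator structures seen
#' in solution: the double helix flexes to different degrees and in
#' different directions at each arm.  The seed is recorded in the file
#' header and the file round-trips through [load_anchor_ensemble()].
#'
#' @param g a [v_geometry()].
#' @param orientation loop type of the base anchor.
#' @param n_left,n_right number of variants per arm.
#' @param jitter_rot rms rotation perturbation per axis, degrees.
#' @param jitter_trans rms translation perturbation per axis, Angstrom.
#' @param path output JSON path.
#' @param seed integer seed (recorded in the header).
#' @return `path`, invisibly.
#' @export
generate_fixture_ensemble <- function(g, orientation = "A1",
                                      n_left = 11, n_right = 11,
                                      jitter_rot = 2, jitter_trans = 2,
                                      path, seed = 1L) {
  if (jitter_rot < 0 || jitter_trans < 0)
    stop("jitter scales must be >= 0")
  set.seed(seed)
  base <- make_v_anchor(g, orientation)
  jit <- function(f) {
    R <- .rotvec(stats::rnorm(3, 0, jitter_rot * DEG))
    bp_frame(f$origin + stats::rnorm(3, 0, jitter_trans), R %*% f$axes)
  }
  payload <- list(
    header = list(seed = seed, jitter_rot = jitter_rot,
                  jitter_trans = jitter_trans,
                  provenance = "synthetic fixture (parametric V anchor)"),
    orientation = orientation,
    left = lapply(seq_len(n_left), function(i)
      .frame_to_list(jit(base$first_frame))),
    right = lapply(seq_len(n_right), function(i)
      .frame_to_list(jit(base$last_frame))))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}
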
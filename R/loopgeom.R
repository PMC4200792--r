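#' Geometric and topological characterization of loops
#'
#' Bending is measured as the angle between the normals of successive base
#' pairs; twist as the rotation of the base-pair short axes about a
#' discrete ribbon built on the polygonal axis through the base-pair
#' origins (the twist of supercoiling); and writhe by the exact Gauss
#' double sum over segment pairs of the closed pathway formed by
#' connecting the terminal base pairs with a straight line.  Twist and
#' writhe so defined combine to the (integer) linking number of the closed
#' structure.
#'
#' @name loopgeom
NULL

#' Per-step bend angles along a chain
#'
#' @param frames list of [bp_frame()]s (from [build_chain_frames()]).
#' @return Vector of angles `gamma_i` (degrees) between the normals of
#'   successive base pairs.
#' @export
bend_profile <- function(frames) {
  z <- frame_normals(frames)
  n <- nrow(z) - 1L
  d <- rowSums(z[seq_len(n), , drop = FALSE] *
                 z[seq_len(n) + 1L, , drop = FALSE])
  acos(pmin(1, pmax(-1, d))) / DEG
}

#' Ribbon twist (twist of supercoiling) along a loop
#'
#' Builds the discrete ribbon on the polygonal axis through the base-pair
#' origins, generated by the base-pair short (x) axes projected
#' perpendicular to each axis segment, and accumulates the signed rotation
#' of the reference vector about each segment.  With `closed = TRUE` the
#' pathway is completed by the straight segment joining the terminal
#' origins, transporting the last reference back to the first so that
#' `Tw + Wr` equals the linking number of the closed ribbon.
#'
#' @param frames list of [bp_frame()]s.
#' @param closed complete the pathway with the terminal straight segment.
#' @return List with `theta` (per-segment twist, degrees; the closure
#'   segment last when `closed`) and `Tw` (total twist, turns).
#' @export
ribbon_twist <- function(frames, closed = TRUE) {
  o <- frame_origins(frames)
  xax <- t(vapply(frames, function(f) f$axes[, 1], numeric(3)))
  n <- nrow(o) - 1L
  # segment tangents; the closure segment joins the terminal origins (a
  # degenerate closure falls back to the bisector of the adjoining
  # segments)
  tans <- lapply(seq_len(n), function(i) {
    t_i <- o[i + 1L, ] - o[i, ]
    t_i / sqrt(sum(t_i * t_i))
  })
  mats <- lapply(seq_len(n + 1L), function(i) xax[i, ])
  if (closed) {
    e <- o[1L, ] - o[n + 1L, ]
    len <- sqrt(sum(e * e))
    t_c <- if (len > 1e-9) e / len else {
      s <- tans[[n]] + tans[[1L]]
      s / sqrt(sum(s * s))
    }
    tans <- c(tans, list(t_c))
    mats <- c(mats, list(xax[1L, ]))
  }
  proj <- function(x, t) {
    p <- x - sum(x * t) * t
    m <- sqrt(sum(p * p))
    if (m < 1e-12) stop("material vector parallel to the axis segment")
    p / m
  }
  m_seg <- length(tans)
  theta <- numeric(m_seg)
  f <- proj(mats[[1L]], tans[[1L]])
  for (i in seq_len(m_seg)) {
    t_i <- tans[[i]]
    p_next <- proj(mats[[i + 1L]], t_i)
    theta[i] <- atan2(sum(t_i * crossprod_vec(f, p_next)),
                      sum(f * p_next))
    if (i < m_seg || closed) {
      # re-anchor to the material vector, then parallel-transport the
      # reference through the vertex (rotation about the binormal)
      t_next <- tans[[if (i < m_seg) i + 1L else 1L]]
      f <- p_next
      b <- crossprod_vec(t_i, t_next)
      sb <- sqrt(sum(b * b))
      if (sb > 1e-12) {
        beta <- atan2(sb, sum(t_i * t_next))
        f <- as.numeric(.rotvec(b / sb * beta) %*% f)
      }
    }
  }
  if (closed) {
    # close the reference through the final vertex back onto the first
    # material vector
    t_1 <- tans[[1L]]
    p_first <- proj(mats[[1L]], t_1)
    theta[m_seg] <- theta[m_seg] +
      atan2(sum(t_1 * crossprod_vec(f, p_first)), sum(f * p_first))
  }
  list(theta = theta / DEG, Tw = sum(theta) / (2 * pi))
}

#' Writhe of a closed polygonal curve
#'
#' Exact evaluation of the Gauss double integral over all pairs of
#' segments of the closed polygon (the solid-angle formula of the
#' standard pairwise method); adjacent segments contribute zero.
#'
#' @param vertices `n x 3` matrix of polygon vertices; the polygon is
#'   closed from the last vertex back to the first.  A duplicated closing
#'   vertex is dropped.
#' @return The writhing number (dimensionless).
#' @export
writhe <- function(vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  if (n >= 2 && sqrt(sum((v[1, ] - v[n, ])^2)) < 1e-9) {
    v <- v[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L) stop("a closed polygon needs at least 3 distinct vertices")
  nxt <- c(seq_len(n)[-1], 1L)
  wr <- 0
  for (i in seq_len(n - 1L)) {
    p1 <- v[i, ]; p2 <- v[nxt[i], ]
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent
      p3 <- v[j, ]; p4 <- v[nxt[j], ]
      wr <- wr + .gauss_pair(p1, p2, p3, p4)
    }
  }
  wr / (2 * pi)
}

# signed solid angle swept by the Gauss map over a segment pair: the
# spherical quadrilateral spanned by the four end-to-end directions,
# split into two triangles evaluated with the robust
# Van Oosterom-Strackee arctangent form (no branch failures for long or
# close segments)
.gauss_pair <- function(p1, p2, p3, p4) {
  un <- function(x) {
    m <- sqrt(sum(x * x)); if (m < 1e-14) return(NULL); x / m
  }
  a <- un(p3 - p1); b <- un(p4 - p1); cc <- un(p4 - p2); d <- un(p3 - p2)
  if (is.null(a) || is.null(b) || is.null(cc) || is.null(d)) return(0)
  tri <- function(u, v, w) {
    num <- sum(u * crossprod_vec(v, w))
    den <- 1 + sum(u * v) + sum(v * w) + sum(w * u)
    2 * atan2(num, den)
  }
  -(tri(a, b, cc) + tri(a, cc, d))
}

#' Topological summary of a loop
#'
#' @param frames list of [bp_frame()]s of the loop pathway.
#' @return List with the bend profile `gamma`, ribbon twist `theta` and
#'   `Tw` (turns), `Wr`, and `Lk = Tw + Wr` (turns) of the pathway closed
#'   by the terminal straight segment.
#' @export
loop_geometry <- function(frames) {
  tw <- ribbon_twist(frames, closed = TRUE)
  wr <- writhe(frame_origins(frames))
  list(gamma = bend_profile(frames), theta = tw$theta, Tw = tw$Tw,
       Wr = wr, Lk = tw$Tw + wr)
}

#' Boltzmann populations from loop energies
#'
#' `sigma_i = exp(-E_i) / sum_j exp(-E_j)` for energies in kBT
#' (invariant to adding a constant to all energies).
#'
#' @param E numeric vector of energies, kBT; names are preserved.
#' @return Fractions summing to 1.
#' @export
populations <- function(E) {
  if (!length(E)) stop("at least one energy is required")
  w <- exp(-(E - min(E)))
  w / sum(w)
}

#' Fractional contributions of per-type J factors
#'
#' @param J numeric vector of J factors; names are preserved.
#' @return `J / sum(J)`.
#' @export
j_fractions <- function(J) {
  if (!length(J)) stop("at least one J factor is required")
  if (any(J < 0)) stop("J factors must be non-negative")
  J / sum(J)
}

#' Per-base-pair displacement between two loop pathways
#'
#' Euclidean distances between corresponding base-pair origins.  By
#' default no superposition is performed, matching the comparison of loops
#' that share fixed anchor frames; optionally a best-fit rigid
#' superposition (Kabsch) of B onto A is removed first.
#'
#' @param frames_a,frames_b equal-length lists of [bp_frame()]s.
#' @param superpose remove the best-fit rigid-body difference first.
#' @return List with `d` (per-bp distances, Angstrom), `mean`, `max`.
#' @export
displacement_profile <- function(frames_a, frames_b, superpose = FALSE) {
  A <- frame_origins(frames_a)
  B <- frame_origins(frames_b)
  if (nrow(A) != nrow(B)) stop("pathways must have equal length")
  if (superpose) {
    ca <- colMeans(A); cb <- colMeans(B)
    H <- crossprod(sweep(B, 2, cb), sweep(A, 2, ca))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    B <- sweep(sweep(B, 2, cb) %*% t(R), 2, -ca)
  }
  d <- sqrt(rowSums((A - B)^2))
  list(d = d, mean = mean(d), max = max(d))
}
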
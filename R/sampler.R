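#' Monte Carlo sampling of DNA chain configurations and J factors
#'
#' Chains are generated by direct Gaussian Monte Carlo: tilt, roll and
#' twist of every step are drawn independently from the elastic model's
#' rest values and rms fluctuation scales, with translations frozen
#' (inextensible helix).  Loop closure against a repressor anchor is
#' detected by appending a phantom base pair through the anchor's closing
#' step and measuring its residual displacement, global bend and net twist
#' relative to the first base pair.  The half-chain pairwise-combination
#' technique turns m sampled half-chains from each end into m^2 effective
#' full-chain samples.
#'
#' @name sampler
NULL

#' Loop-closure criteria
#'
#' A configuration is counted as looped when the phantom base pair falls
#' within `r_max` of the first base pair, the global bend angle is at most
#' `gamma_max` and the magnitude of the net twist is at most `omega_max`.
#' The default angular windows of 11.5 degrees correspond to
#' `cos(gamma) >= 0.98`.
#'
#' @param r_max maximum end-to-end displacement, Angstrom.
#' @param gamma_max maximum global bend angle, degrees.
#' @param omega_max maximum |net twist|, degrees.
#' @export
closure_criteria <- function(r_max = 15, gamma_max = 11.5, omega_max = 11.5) {
  if (r_max <= 0 || gamma_max <= 0 || omega_max <= 0)
    stop("closure tolerances must be positive")
  structure(list(r_max = r_max, gamma_max = gamma_max,
                 omega_max = omega_max), class = "closure_criteria")
}

#' Draw a random chain from the elastic model
#'
#' @param model an [elastic_model()].
#' @param n number of steps (defaults to `model$n_steps`); must not exceed
#'   `model$n_steps`.
#' @return A [dna_chain()] whose angles are Gaussian about the rest state
#'   (softened steps use enlarged sigmas) and whose translations are the
#'   fixed canonical values.
#' @export
sample_steps <- function(model, n = model$n_steps) {
  n <- as.integer(n)
  if (n < 1L || n > model$n_steps) stop("n must lie in [1, model$n_steps]")
  s <- .step_sigmas(model)[seq_len(n), , drop = FALSE]
  dna_chain(cbind(tilt = stats::rnorm(n, model$rest_tilt, s[, 1]),
                  roll = stats::rnorm(n, model$rest_roll, s[, 2]),
                  twist = stats::rnorm(n, model$rest_twist, s[, 3]),
                  shift = 0, slide = 0, rise = model$rise))
}

## ---- batched SE(3) transforms (quaternion + origin), internal ----------

.tf_identity <- function(m) {
  list(qw = rep(1, m), qx = numeric(m), qy = numeric(m), qz = numeric(m),
       ox = numeric(m), oy = numeric(m), oz = numeric(m))
}

# quaternion product (a then b: rotation a$R %*% b$R)
.q_mul <- function(aw, ax, ay, az, bw, bx, by, bz) {
  list(w = aw * bw - ax * bx - ay * by - az * bz,
       x = aw * bx + ax * bw + ay * bz - az * by,
       y = aw * by - ax * bz + ay * bw + az * bx,
       z = aw * bz + ax * by - ay * bx + az * bw)
}

# rotate vectors (vx,vy,vz) by quaternions
.q_rot <- function(qw, qx, qy, qz, vx, vy, vz) {
  tx <- 2 * (qy * vz - qz * vy)
  ty <- 2 * (qz * vx - qx * vz)
  tz <- 2 * (qx * vy - qy * vx)
  list(x = vx + qw * tx + qy * tz - qz * ty,
       y = vy + qw * ty + qz * tx - qx * tz,
       z = vz + qw * tz + qx * ty - qy * tx)
}

# step quaternion from angles in radians: Rz(w/2) exp([(t,r,0)x]) Rz(w/2)
.step_quat <- function(tl, rl, tw) {
  G <- sqrt(tl * tl + rl * rl)
  hg <- G / 2
  sh <- ifelse(G < 1e-12, 0.5, sin(hg) / G)
  bw <- cos(hg); bx <- tl * sh; by <- rl * sh
  cw <- cos(tw / 4); sw <- sin(tw / 4)
  # a = qz(w/2) * qb (qb has no z component), then t = a * qz(w/2)
  aw <- cw * bw; ax <- cw * bx - sw * by; ay <- cw * by + sw * bx
  az <- sw * bw
  list(w = aw * cw - az * sw, x = ax * cw + ay * sw,
       y = ay * cw - ax * sw, z = aw * sw + az * cw)
}

# advance a batch of transforms by per-chain step angles (radians) and a
# common rise
.tf_step <- function(tf, tl, rl, tw, rise) {
  st <- .step_quat(tl, rl, tw)
  # mid-frame displacement: o += R * M * (0,0,h); M = Rz(w/2) exp(b/2).
  # z-column of exp([(t/2, r/2, 0)x]):
  th2 <- (tl * tl + rl * rl) / 4
  th <- sqrt(th2)
  a <- ifelse(th < 1e-12, 1 - th2 / 6, sin(th) / th)
  b <- ifelse(th < 1e-12, 0.5 - th2 / 24, (1 - cos(th)) / th2)
  ezx <- a * (rl / 2)
  ezy <- -a * (tl / 2)
  ezz <- 1 - b * th2
  # then rotate by Rz(w/2): (x,y) -> (x cos - y sin, x sin + y cos)
  cw <- cos(tw / 2); sw <- sin(tw / 2)
  mx <- rise * (ezx * cw - ezy * sw)
  my <- rise * (ezx * sw + ezy * cw)
  mz <- rise * ezz
  d <- .q_rot(tf$qw, tf$qx, tf$qy, tf$qz, mx, my, mz)
  q <- .q_mul(tf$qw, tf$qx, tf$qy, tf$qz, st$w, st$x, st$y, st$z)
  list(qw = q$w, qx = q$x, qy = q$y, qz = q$z,
       ox = tf$ox + d$x, oy = tf$oy + d$y, oz = tf$oz + d$z)
}

# compose two transform batches elementwise: result = a then b
.tf_compose <- function(a, b) {
  d <- .q_rot(a$qw, a$qx, a$qy, a$qz, b$ox, b$oy, b$oz)
  q <- .q_mul(a$qw, a$qx, a$qy, a$qz, b$qw, b$qx, b$qy, b$qz)
  list(qw = q$w, qx = q$x, qy = q$y, qz = q$z,
       ox = a$ox + d$x, oy = a$oy + d$y, oz = a$oz + d$z)
}

.tf_from_frame <- function(f, m = 1L) {
  R <- f$axes
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    k <- which.max(diag(R))
    i <- k; j <- k %% 3 + 1; l <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[l, l] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[l, j] - R[j, l]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[l + 1] <- (R[l, i] + R[i, l]) / s
  }
  list(qw = rep(q[1], m), qx = rep(q[2], m), qy = rep(q[3], m),
       qz = rep(q[4], m),
       ox = rep(f$origin[1], m), oy = rep(f$origin[2], m),
       oz = rep(f$origin[3], m))
}

# closure metrics of transform batch relative to the identity frame:
# r (Angstrom), cos(gamma), omega (degrees, in (-180, 180])
.tf_closure_metrics <- function(tf) {
  r <- sqrt(tf$ox^2 + tf$oy^2 + tf$oz^2)
  cg <- pmin(1, pmax(-1, 1 - 2 * (tf$qx^2 + tf$qy^2)))
  om <- 2 * atan2(tf$qz, tf$qw)
  om <- om - 2 * pi * ceiling((om - pi) / (2 * pi))
  list(r = r, cos_gamma = cg, gamma = acos(cg) / DEG, omega = om / DEG)
}

## ---- end states and closure --------------------------------------------

#' End state of a chain against a loop anchor
#'
#' Builds the chain from the identity frame, appends the phantom base pair
#' through the anchor's closing step, and reports the residual relative to
#' base pair 1: the end-to-end vector `r`, the global bend angle `Gamma`
#' (angle between the normals of base pair 1 and the phantom pair) and the
#' net twist `omega` (residual rotation about the mean normal, from the
#' ZYZ decomposition of the residual rotation).
#'
#' @param chain a [dna_chain()].
#' @param anchor a [loop_anchor()] supplying the closing step.
#' @return List with `end_frame` (phantom pair relative to base pair 1),
#'   `r` (3-vector, Angstrom), `r_norm`, `Gamma` and `omega` (degrees).
#' @export
end_state <- function(chain, anchor) {
  frames <- build_chain_frames(chain, bp_frame())
  phantom <- compose_step(frames[[length(frames)]], anchor$closing_step)
  p <- params_from_frames(bp_frame(), phantom)
  Q <- phantom$axes
  cg <- min(1, max(-1, Q[3, 3]))
  list(end_frame = phantom,
       r = phantom$origin,
       r_norm = sqrt(sum(phantom$origin^2)),
       Gamma = acos(cg) / DEG,
       omega = as.numeric(p["twist"]))
}

#' Test a loop-closure end state against the criteria
#'
#' @param s an end state from [end_state()] (or any list with `r_norm`,
#'   `Gamma`, `omega`).
#' @param c a [closure_criteria()].
#' @return `TRUE` iff `|r| <= r_max`, `Gamma <= gamma_max` and
#'   `|omega| <= omega_max`.
#' @export
is_closed <- function(s, c = closure_criteria()) {
  s$r_norm <= c$r_max && s$Gamma <= c$gamma_max && abs(s$omega) <= c$omega_max
}

## ---- half-chain ensembles ----------------------------------------------

#' Sample an ensemble of half-chains
#'
#' Draws `m` independent chains of `n_half` steps and records both the
#' sampled angles and the end-to-end transform of every chain.  Optionally
#' decorates each chain with rigid HU footprints before the transform is
#' computed (footprints are confined within the half; see [decorate()]).
#'
#' @param model an [elastic_model()].
#' @param n_half number of steps per half-chain.
#' @param m ensemble size.
#' @param hu optional [binding_config()]; when supplied each half-chain is
#'   independently decorated before propagation.
#' @return Object of class `half_ensemble`: sampled angles (`tilt`,
#'   `roll`, `twist`; `m x n_half` matrices, degrees), end transforms,
#'   and the per-chain bound-HU count `n_hu`.
#' @export
sample_half_chains <- function(model, n_half, m, hu = NULL) {
  n_half <- as.integer(n_half); m <- as.integer(m)
  if (n_half < 1L) stop("n_half must be >= 1")
  if (m < 1L) stop("m must be >= 1")
  s <- .step_sigmas(model)[seq_len(n_half), , drop = FALSE]
  tilt <- matrix(stats::rnorm(m * n_half, model$rest_tilt,
                              rep(s[, 1], each = m)), m, n_half)
  roll <- matrix(stats::rnorm(m * n_half, model$rest_roll,
                              rep(s[, 2], each = m)), m, n_half)
  twist <- matrix(stats::rnorm(m * n_half, model$rest_twist,
                               rep(s[, 3], each = m)), m, n_half)
  n_hu <- integer(m)
  if (!is.null(hu)) {
    fp_len <- hu_footprint_length()
    for (i in seq_len(m)) {
      dec <- .decorate_angles(tilt[i, ], roll[i, ], twist[i, ], hu)
      tilt[i, ] <- dec$tilt; roll[i, ] <- dec$roll; twist[i, ] <- dec$twist
      n_hu[i] <- dec$n_placed
    }
  }
  tf <- .tf_identity(m)
  for (j in seq_len(n_half))
    tf <- .tf_step(tf, tilt[, j] * DEG, roll[, j] * DEG, twist[, j] * DEG,
                   model$rise)
  structure(list(tilt = tilt, roll = roll, twist = twist, tf = tf,
                 n_hu = n_hu, rise = model$rise),
            class = "half_ensemble")
}

#' Reconstruct one chain of a half-ensemble
#' @param h a `half_ensemble`.
#' @param i chain index.
#' @export
half_chain <- function(h, i) {
  dna_chain(cbind(tilt = h$tilt[i, ], roll = h$roll[i, ],
                  twist = h$twist[i, ], shift = 0, slide = 0,
                  rise = h$rise))
}

#' Combine two half-chain ensembles against an anchor
#'
#' Forms all `m_a * m_b` pairwise combinations of the end transforms, adds
#' the phantom base pair through the anchor's closing step, and counts the
#' configurations satisfying the closure criteria.  Pairs are processed in
#' chunks so memory stays bounded.
#'
#' @param ha,hb `half_ensemble` objects for the first and second half of
#'   the loop (the full loop is `ha` followed by `hb`).
#' @param anchor a [loop_anchor()].
#' @param criteria a [closure_criteria()].
#' @param max_chunk maximum number of pairs held in memory at once.
#' @return List with `hits`, `samples` (= `m_a * m_b`), the indices
#'   (`i`, `j`) of the closed pairs, their closure metrics, and the
#'   bound-HU count of each closed configuration.
#' @export
combine_half_chains <- function(ha, hb, anchor,
                                criteria = closure_criteria(),
                                max_chunk = 4e6) {
  ma <- length(ha$tf$qw); mb <- length(hb$tf$qw)
  # fold the closing step into the second-half transforms once
  tc <- .tf_from_frame(compose_step(bp_frame(), anchor$closing_step), 1L)
  bt <- .tf_compose(hb$tf, lapply(tc, rep, mb))
  rows <- max(1L, min(ma, as.integer(max_chunk %/% mb)))
  hit_i <- list(); hit_j <- list(); met <- list()
  cg_min <- cos(criteria$gamma_max * DEG)
  n_chunk <- 0L
  for (lo in seq(1L, ma, by = rows)) {
    hi <- min(ma, lo + rows - 1L)
    idx <- lo:hi
    c_len <- length(idx)
    A <- lapply(ha$tf, function(v) rep(v[idx], each = mb))
    B <- lapply(bt, function(v) rep(v, times = c_len))
    W <- .tf_compose(A, B)
    mm <- .tf_closure_metrics(W)
    ok <- which(mm$r <= criteria$r_max & mm$cos_gamma >= cg_min &
                  abs(mm$omega) <= criteria$omega_max)
    if (length(ok)) {
      n_chunk <- n_chunk + 1L
      hit_i[[n_chunk]] <- idx[(ok - 1L) %/% mb + 1L]
      hit_j[[n_chunk]] <- (ok - 1L) %% mb + 1L
      met[[n_chunk]] <- data.frame(r = mm$r[ok], Gamma = mm$gamma[ok],
                                   omega = mm$omega[ok])
    }
  }
  i <- unlist(hit_i); j <- unlist(hit_j)
  if (is.null(i)) { i <- integer(0); j <- integer(0) }
  metrics <- if (length(met)) do.call(rbind, met) else
    data.frame(r = numeric(0), Gamma = numeric(0), omega = numeric(0))
  list(hits = length(i), samples = as.numeric(ma) * mb, i = i, j = j,
       metrics = metrics, n_hu = ha$n_hu[i] + hb$n_hu[j])
}

## ---- J factor ------------------------------------------------------------

#' Normalization constant of the J-factor estimate
#'
#' Probability that a freely and uniformly placed end frame falls inside
#' the closure window at 1 M effective concentration: the product of the
#' molar volume of the capture sphere `N_A * (4 pi / 3) r_max^3` (in
#' liters), the fraction of the orientation sphere with bend within
#' `gamma_max`, `(1 - cos gamma_max) / 2`, and the twist fraction
#' `omega_max / 180`.  About 5.44e-3 at the default criteria.
#'
#' @param c a [closure_criteria()].
#' @export
j_normalization <- function(c = closure_criteria()) {
  avogadro <- 6.02214076e23
  dv_liter <- (4 * pi / 3) * c$r_max^3 * 1e-27  # 1 A^3 = 1e-27 L
  f_gamma <- (1 - cos(c$gamma_max * DEG)) / 2
  f_omega <- (c$omega_max * DEG) / pi
  avogadro * dv_liter * f_gamma * f_omega
}

#' Jacobson-Stockmayer J factor from closure counts
#'
#' `J = (hits / samples) / j_normalization(criteria)`, in mol/L; the
#' standard error follows binomial counting statistics.  With zero hits the
#' estimate is 0 and a 95 percent upper bound (rule of three) is reported.
#'
#' @param hits number of closed configurations.
#' @param samples effective number of sampled configurations.
#' @param criteria the [closure_criteria()] used for the counts.
#' @return Object of class `j_estimate` with fields `hits`, `samples`,
#'   `J` (mol/L), `stderr`, `upper95` (only meaningful at zero hits) and
#'   `criteria`.
#' @export
estimate_J <- function(hits, samples, criteria = closure_criteria()) {
  if (samples <= 0) stop("samples must be positive")
  if (hits < 0 || hits > samples) stop("hits must lie in [0, samples]")
  const <- j_normalization(criteria)
  p <- hits / samples
  J <- p / const
  se <- sqrt(p * (1 - p) / samples) / const
  upper <- if (hits == 0) (3 / samples) / const else NA_real_
  structure(list(hits = hits, samples = samples, J = J, stderr = se,
                 upper95 = upper, criteria = criteria),
            class = "j_estimate")
}

#' @export
print.j_estimate <- function(x, ...) {
  cat("<j_estimate> J =", signif(x$J, 4), "M (", x$hits, "hits /",
      format(x$samples, big.mark = ","), "samples; se",
      signif(x$stderr, 3), ")\n")
  invisible(x)
}

#' Relative statistical weight of a modified loop
#'
#' `exp(-(E_i - E_0))` for energies in kBT: the Boltzmann factor by which
#' a change in minimum energy alters the ease of looping.
#'
#' @param E_i energy of the modified state, kBT.
#' @param E_0 energy of the reference state, kBT.
#' @export
relative_weight <- function(E_i, E_0) exp(-(E_i - E_0))

## ---- whole-pipeline profiles --------------------------------------------

#' Naive full-chain J estimate (reference sampler)
#'
#' Samples complete chains (no half-chain combination) and counts closures.
#' Serves as the unbiased reference for [combine_half_chains()] and for
#' small toy problems.
#'
#' @param model an [elastic_model()].
#' @param n number of steps in the loop.
#' @param anchor a [loop_anchor()].
#' @param criteria a [closure_criteria()].
#' @param n_chains number of chains to draw.
#' @param hu optional [binding_config()].
#' @return A `j_estimate` with an extra `n_hu` field (bound-HU counts of
#'   the closed configurations).
#' @export
naive_J <- function(model, n, anchor, criteria = closure_criteria(),
                    n_chains = 1e4, hu = NULL) {
  h <- sample_half_chains(model, n, n_chains, hu = hu)
  tc <- .tf_from_frame(compose_step(bp_frame(), anchor$closing_step), 1L)
  tf <- .tf_compose(h$tf, lapply(tc, rep, n_chains))
  mm <- .tf_closure_metrics(tf)
  ok <- which(mm$r <= criteria$r_max &
                mm$cos_gamma >= cos(criteria$gamma_max * DEG) &
                abs(mm$omega) <= criteria$omega_max)
  est <- estimate_J(length(ok), n_chains, criteria)
  est$n_hu <- h$n_hu[ok]
  est
}

#' J-factor profile over loop length and loop type
#'
#' For every loop length `N` (base-pair steps between operator centers;
#' the free segment excludes the 7 + 7 operator steps folded into the
#' anchors) and every anchor in `anchors`, samples half-chain ensembles,
#' combines them, and estimates the J factor.  All anchors at a given `N`
#' are scored against the same pair of half-chain ensembles so the
#' loop-type fractions share sampling noise.
#'
#' @param model_for_n function taking the free-segment step count and
#'   returning an [elastic_model()] (defaults to the ideal model).
#' @param anchors named list of [loop_anchor()] objects (typically the
#'   four orientations from [make_v_anchor()]).
#' @param N_range integer vector of loop lengths.
#' @param m half-chain ensemble size (m^2 effective samples per N).
#' @param criteria a [closure_criteria()].
#' @param hu optional [binding_config()].
#' @param seed optional integer seed.
#' @return Data frame with one row per (N, loop type): hits, samples,
#'   `J_molar`, `stderr`, `upper95`, `mean_hu` and the per-N J-fraction
#'   of each loop type (`j_fraction`, summing to 1 over types with any
#'   hits).
#' @export
j_profile <- function(anchors, N_range, model_for_n = NULL, m = 2e4,
                      criteria = closure_criteria(), hu = NULL,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model_for_n))
    model_for_n <- function(n_free) elastic_model(n_free)
  if (is.null(names(anchors)))
    names(anchors) <- vapply(anchors, function(a) a$orientation, "")
  out <- list()
  for (N in N_range) {
    n_free <- loop_free_steps(N)
    k <- n_free %/% 2L
    model <- model_for_n(n_free)
    ha <- sample_half_chains(model, k, m, hu = hu)
    hb <- sample_half_chains(model, n_free - k, m, hu = hu)
    rows <- lapply(names(anchors), function(nm) {
      cm <- combine_half_chains(ha, hb, anchors[[nm]], criteria)
      est <- estimate_J(cm$hits, cm$samples, criteria)
      data.frame(N = N, loop_type = nm, hits = cm$hits,
                 samples = cm$samples, J_molar = est$J,
                 stderr = est$stderr, upper95 = est$upper95,
                 mean_hu = if (cm$hits) mean(cm$n_hu) else NA_real_)
    })
    tab <- do.call(rbind, rows)
    tot <- sum(tab$J_molar)
    tab$j_fraction <- if (tot > 0) tab$J_molar / tot else NA_real_
    out[[as.character(N)]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Free-segment step count of a loop of length N
#'
#' Loop lengths are counted between the centers of the bound operators:
#' seven of the 14 steps attached to each repressor arm plus the free
#' steps, so a 92-bp-step loop has 78 steps subject to configurational
#' change.
#'
#' @param N loop length in base-pair steps between operator centers.
#' @export
loop_free_steps <- function(N) {
  n <- as.integer(N) - 14L
  if (any(n < 2L)) stop("loop length N must be at least 16 steps")
  n
}

#' Persistence length from simulated free chains
#'
#' Samples free chains, records the mean directional correlation
#' `<cos Gamma(s)> = <z_1 . z_s>` of the base-pair normals at increasing
#' contour length, and fits the exponential decay
#' `<cos Gamma(s)> = exp(-s / P)`.
#'
#' @param model an [elastic_model()] (softening ignored: uniform sigmas).
#' @param n_chains number of chains.
#' @param len chain length in steps.
#' @param checkpoint_every spacing (steps) of correlation checkpoints.
#' @param seed optional integer seed.
#' @return List with `P` (fitted persistence length, Angstrom), `model_P`
#'   (closed-form [model_persistence_length()]), and the checkpoint data.
#' @export
persistence_length_mc <- function(model = elastic_model(300),
                                  n_chains = 1e5, len = 300,
                                  checkpoint_every = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sd_t <- model$sigma_tilt * DEG
  sd_r <- model$sigma_roll * DEG
  sd_w <- model$sigma_twist * DEG
  tw0 <- model$rest_twist * DEG
  ck <- seq(checkpoint_every, len, by = checkpoint_every)
  corr <- numeric(length(ck)); ci <- 1L
  qw <- rep(1, n_chains); qx <- qy <- qz <- numeric(n_chains)
  for (s in seq_len(len)) {
    st <- .step_quat(stats::rnorm(n_chains, 0, sd_t),
                     stats::rnorm(n_chains, 0, sd_r),
                     stats::rnorm(n_chains, tw0, sd_w))
    q <- .q_mul(qw, qx, qy, qz, st$w, st$x, st$y, st$z)
    qw <- q$w; qx <- q$x; qy <- q$y; qz <- q$z
    if (ci <= length(ck) && s == ck[ci]) {
      corr[ci] <- mean(1 - 2 * (qx * qx + qy * qy))
      ci <- ci + 1L
    }
  }
  s_len <- ck * model$rise
  fit <- stats::lm(log(corr) ~ s_len + 0)
  list(P = -1 / unname(stats::coef(fit)[1]),
       model_P = model_persistence_length(model),
       contour = s_len, mean_cos = corr)
}
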
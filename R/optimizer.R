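#' Minimum-energy DNA loops with fixed terminal base-pair frames
#'
#' The elastic energy of a loop whose first and last base-pair frames are
#' held fixed is minimized over the step angles (tilt, roll, twist) of all
#' steps; translations stay frozen at their canonical values
#' (inextensible helix).  The six end-frame constraints (three positional,
#' three orientational) are enforced by an augmented-Lagrangian scheme:
#' a sequence of unconstrained smooth problems, solved by L-BFGS with an
#' analytic adjoint gradient, whose multiplier updates drive the terminal
#' residual below 1e-6 Angstrom and 1e-6 degrees.  A plain quadratic
#' penalty at fixed large weight is retained as an independent
#' cross-check of the constrained minima (see [loop_energy()] /
#' [energy_gradient()]).
#'
#' @name optimizer
NULL

# derivative of exp([v x]) with respect to v_k (Gallego & Yezzi closed form)
.d_expm <- function(v, R, k) {
  th2 <- sum(v * v)
  e_k <- c(0, 0, 0); e_k[k] <- 1
  if (th2 < 1e-14) {
    K <- matrix(c(0, e_k[3], -e_k[2], -e_k[3], 0, e_k[1],
                  e_k[2], -e_k[1], 0), 3, 3)
    return(K %*% R)
  }
  w <- v * e_k[k]
  u <- crossprod_vec(v, as.numeric((diag(3) - R) %*% e_k))
  Kv <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  Ku <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ((v[k] * Kv + Ku) %*% R) / th2
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# forward/backward evaluation of the augmented-Lagrangian objective.
# x: step angles in radians, length 3n (tilt, roll, twist per step).
# Returns value and, when want_grad, the gradient.
.al_eval <- function(x, ctx, lam, mu, want_grad = TRUE) {
  n <- ctx$n
  tl <- x[seq(1, 3 * n, 3)]; rl <- x[seq(2, 3 * n, 3)]
  tw <- x[seq(3, 3 * n, 3)]
  dt <- tl - ctx$t0; dr <- rl - ctx$r0; dw <- tw - ctx$w0
  E <- 0.5 * sum(dt^2 * ctx$iv[, 1] + dr^2 * ctx$iv[, 2] +
                   dw^2 * ctx$iv[, 3])
  # forward pass
  R <- ctx$R_f; o <- ctx$o_f
  Ts <- vector("list", n); ms <- vector("list", n)
  Rs <- if (want_grad) vector("list", n) else NULL
  for (i in seq_len(n)) {
    Z <- .rot_z(tw[i] / 2)
    Eb <- .rot_bend(tl[i], rl[i])
    Ti <- Z %*% Eb %*% Z
    Hb <- .rot_bend(tl[i] / 2, rl[i] / 2)
    mi <- ctx$rise * (Z %*% Hb[, 3])
    if (want_grad) Rs[[i]] <- R
    Ts[[i]] <- Ti; ms[[i]] <- mi
    o <- o + R %*% mi
    R <- R %*% Ti
  }
  c_pos <- as.numeric(o - ctx$o_l) / ctx$ell
  B <- crossprod(ctx$R_l, R)
  a <- c(B[3, 2] - B[2, 3], B[1, 3] - B[3, 1], B[2, 1] - B[1, 2]) / 2
  cc <- c(c_pos, a)
  val <- E + sum(lam * cc) + 0.5 * mu * sum(cc * cc)
  if (!want_grad)
    return(list(value = val, c_pos = c_pos * ctx$ell, a = a, E = E))
  # end adjoints
  gl <- lam + mu * cc
  obar <- gl[1:3] / ctx$ell
  g <- gl[4:6]
  Gb <- 0.5 * matrix(c(0, g[3], -g[2], -g[3], 0, g[1], g[2], -g[1], 0),
                     3, 3)
  Gbar <- ctx$R_l %*% Gb
  grad <- numeric(3 * n)
  for (i in n:1) {
    Ri <- Rs[[i]]; Ti <- Ts[[i]]; mi <- ms[[i]]
    C <- crossprod(Ri, Gbar)
    wv <- as.numeric(crossprod(Ri, obar))
    Z <- .rot_z(tw[i] / 2)
    v <- c(tl[i], rl[i], 0)
    Eb <- .rot_bend(tl[i], rl[i])
    Hb <- .rot_bend(tl[i] / 2, rl[i] / 2)
    dT_t <- Z %*% .d_expm(v, Eb, 1) %*% Z
    dT_r <- Z %*% .d_expm(v, Eb, 2) %*% Z
    dT_w <- 0.5 * (.Lz %*% Ti + Ti %*% .Lz)
    hv <- v / 2
    dm_t <- ctx$rise * 0.5 * (Z %*% (.d_expm(hv, Hb, 1)[, 3]))
    dm_r <- ctx$rise * 0.5 * (Z %*% (.d_expm(hv, Hb, 2)[, 3]))
    dm_w <- 0.5 * (.Lz %*% mi)
    k <- 3 * (i - 1)
    grad[k + 1] <- dt[i] * ctx$iv[i, 1] + sum(C * dT_t) + sum(wv * dm_t)
    grad[k + 2] <- dr[i] * ctx$iv[i, 2] + sum(C * dT_r) + sum(wv * dm_r)
    grad[k + 3] <- dw[i] * ctx$iv[i, 3] + sum(C * dT_w) + sum(wv * dm_w)
    # propagate adjoints to frame i
    Gbar <- Gbar %*% t(Ti) + obar %o% as.numeric(mi)
  }
  list(value = val, grad = grad, c_pos = c_pos * ctx$ell, a = a, E = E)
}

# context shared by all evaluations of one constrained problem
.loop_ctx <- function(anchor, model) {
  n <- model$n_steps
  s <- .step_sigmas(model) * DEG
  list(n = n,
       R_f = anchor$first_frame$axes, o_f = anchor$first_frame$origin,
       R_l = anchor$last_frame$axes, o_l = anchor$last_frame$origin,
       t0 = rep(model$rest_tilt * DEG, n),
       r0 = rep(model$rest_roll * DEG, n),
       w0 = rep(model$rest_twist * DEG, n),
       iv = 1 / s^2, rise = model$rise, ell = 10)
}

#' Penalty-form loop energy and its analytic gradient
#'
#' The elastic energy plus a quadratic penalty `mu/2 * |c|^2` on the
#' six end-frame constraint components (positions scaled by 10 Angstrom;
#' orientations as the skew part of the residual rotation).  With
#' `mu = 0` this is the unconstrained elastic energy of the chain built
#' from the given angles.  [energy_gradient()] returns the exact adjoint
#' gradient, suitable for checking against finite differences.
#'
#' @param angles numeric vector of step angles in degrees, ordered
#'   (tilt, roll, twist) per step, length `3 * model$n_steps`.
#' @param model an [elastic_model()].
#' @param anchor a [loop_anchor()].
#' @param mu penalty weight.
#' @return `loop_energy`: the scalar objective (kBT).
#' @export
loop_energy <- function(angles, model, anchor, mu = 0) {
  ctx <- .loop_ctx(anchor, model)
  .al_eval(angles * DEG, ctx, numeric(6), mu, want_grad = FALSE)$value
}

#' @rdname loop_energy
#' @return `energy_gradient`: gradient of the objective with respect to
#'   the angles in degrees (kBT per degree).
#' @export
energy_gradient <- function(angles, model, anchor, mu = 0) {
  ctx <- .loop_ctx(anchor, model)
  .al_eval(angles * DEG, ctx, numeric(6), mu, want_grad = TRUE)$grad * DEG
}

# circular-arc initial chain: bends the rest-state helix smoothly from the
# first frame toward the last origin (falls back to a full turn for
# ring-like anchors whose terminal origins coincide)
.init_arc <- function(ctx) {
  n <- ctx$n
  d <- ctx$o_l - ctx$o_f
  z <- ctx$R_f[, 3]
  dn <- sqrt(sum(d * d))
  if (dn < 1e-8) {
    axis <- ctx$R_f[, 2]
    psi <- 2 * pi
  } else {
    ch <- d / dn
    cx <- crossprod_vec(z, ch)
    sx <- sqrt(sum(cx * cx))
    if (sx < 1e-10) { axis <- ctx$R_f[, 2]; psi <- 0 }
    else {
      axis <- cx / sx
      psi <- 2 * atan2(sx, sum(z * ch))
    }
  }
  beta <- psi / n
  x <- numeric(3 * n)
  R <- ctx$R_f
  for (i in seq_len(n)) {
    al <- as.numeric(crossprod(R, axis))
    nl <- sqrt(al[1]^2 + al[2]^2)
    b <- if (nl < 1e-12) c(0, 0) else beta * al[1:2] / nl
    k <- 3 * (i - 1)
    x[k + 1] <- ctx$t0[i] + b[1]
    x[k + 2] <- ctx$r0[i] + b[2]
    x[k + 3] <- ctx$w0[i]
    Ti <- .rot_z(x[k + 3] / 2) %*% .rot_bend(x[k + 1], x[k + 2]) %*%
      .rot_z(x[k + 3] / 2)
    R <- R %*% Ti
  }
  x
}

#' Minimize the elastic energy of a loop with fixed end frames
#'
#' @param n_bp number of base pairs in the configurable segment, including
#'   the two fixed terminal pairs; the chain has `n_bp - 1` steps.
#' @param model an [elastic_model()] with `n_steps = n_bp - 1`.
#' @param anchor a [loop_anchor()] fixing the terminal frames.
#' @param init `"arc"` (default: rest-state helix bent along a circular
#'   arc toward the target), `"rest"` (straight rest-state chain), a
#'   [dna_chain()], or a previous `loop_optimum` to warm-start from.
#' @param n_starts number of starts; starts beyond the first perturb the
#'   initial angles by Gaussian noise of sd `perturb_sd` degrees to escape
#'   symmetric or shallow local minima.  All starts are reported; the
#'   lowest converged minimum is returned.
#' @param perturb_sd initial-angle perturbation, degrees.
#' @param tol_pos,tol_rot convergence tolerances on the terminal residual
#'   (Angstrom, degrees).
#' @param max_outer maximum augmented-Lagrangian rounds per start.
#' @param inner_maxit L-BFGS iteration cap per round.
#' @return Object of class `loop_optimum`: `chain`, `E_total`, `E_bend`,
#'   `E_twist` (kBT), `converged`, `gradient_norm`, `constraint_residual`
#'   (Angstrom, degrees), `iterations`, and a `starts` data frame with
#'   one row per start.
#' @export
minimize_loop <- function(n_bp, model = elastic_model(n_bp - 1), anchor,
                          init = "arc", n_starts = 1, perturb_sd = 1,
                          tol_pos = 1e-6, tol_rot = 1e-6,
                          max_outer = 40, inner_maxit = 1000) {
  n_bp <- as.integer(n_bp)
  if (n_bp < 3L) stop("n_bp must be >= 3")
  if (model$n_steps != n_bp - 1L)
    stop("model$n_steps must equal n_bp - 1")
  ctx <- .loop_ctx(anchor, model)
  x0 <- if (is.character(init) && init == "arc") .init_arc(ctx)
  else if (is.character(init) && init == "rest")
    as.numeric(t(cbind(ctx$t0, ctx$r0, ctx$w0)))
  else if (inherits(init, "loop_optimum"))
    as.numeric(t(init$chain$steps[, 1:3])) * DEG
  else if (inherits(init, "dna_chain"))
    as.numeric(t(init$steps[, 1:3])) * DEG
  else stop("unknown init")
  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    xs <- x0
    if (s > 1L) xs <- xs + stats::rnorm(length(xs), 0, perturb_sd * DEG)
    runs[[s]] <- .al_minimize(xs, ctx, tol_pos, tol_rot, max_outer,
                              inner_maxit)
  }
  starts <- do.call(rbind, lapply(seq_len(n_starts), function(s)
    data.frame(start = s, E_total = runs[[s]]$E,
               residual_pos = runs[[s]]$res_pos,
               residual_rot = runs[[s]]$res_rot,
               converged = runs[[s]]$converged)))
  conv <- which(starts$converged)
  best <- if (length(conv)) conv[which.min(starts$E_total[conv])]
  else which.min(starts$residual_pos)
  r <- runs[[best]]
  chain <- dna_chain(cbind(tilt = r$x[seq(1, length(r$x), 3)] / DEG,
                           roll = r$x[seq(2, length(r$x), 3)] / DEG,
                           twist = r$x[seq(3, length(r$x), 3)] / DEG,
                           shift = 0, slide = 0, rise = model$rise))
  en <- elastic_energy(chain, model)
  structure(list(chain = chain, E_total = en$E_total, E_bend = en$E_bend,
                 E_twist = en$E_twist, converged = r$converged,
                 gradient_norm = r$grad_norm,
                 constraint_residual = c(pos = r$res_pos, rot = r$res_rot),
                 iterations = r$iterations, starts = starts,
                 anchor = anchor, model = model),
            class = "loop_optimum")
}

#' @export
print.loop_optimum <- function(x, ...) {
  cat("<loop_optimum> E =", signif(x$E_total, 5), "kBT (bend",
      signif(x$E_bend, 5), "+ twist", signif(x$E_twist, 5), ");",
      if (x$converged) "converged;" else "NOT converged;",
      "residual", signif(x$constraint_residual[1], 3), "A /",
      signif(x$constraint_residual[2], 3), "deg\n")
  invisible(x)
}

# augmented-Lagrangian driver for one start
.al_minimize <- function(x, ctx, tol_pos, tol_rot, max_outer,
                         inner_maxit) {
  lam <- numeric(6)
  mu <- 10
  prev_norm <- Inf
  iterations <- 0L
  converged <- FALSE
  cache <- new.env(parent = emptyenv())
  for (outer in seq_len(max_outer)) {
    fn <- function(p) {
      ev <- .al_eval(p, ctx, lam, mu, want_grad = TRUE)
      cache$ev <- ev; cache$p <- p
      ev$value
    }
    gr <- function(p) {
      if (!is.null(cache$p) && identical(cache$p, p)) return(cache$ev$grad)
      .al_eval(p, ctx, lam, mu, want_grad = TRUE)$grad
    }
    op <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                       control = list(maxit = inner_maxit, factr = 1e2))
    x <- op$par
    iterations <- iterations + unname(op$counts[1])
    ev <- .al_eval(x, ctx, lam, mu, want_grad = TRUE)
    res_pos <- max(abs(ev$c_pos))
    rot_angle <- asin(min(1, sqrt(sum(ev$a^2)))) / DEG
    if (res_pos < tol_pos && rot_angle < tol_rot) {
      converged <- TRUE
      break
    }
    cc <- c(ev$c_pos / ctx$ell, ev$a)
    lam <- lam + mu * cc
    cn <- sqrt(sum(cc^2))
    if (cn > 0.25 * prev_norm) mu <- min(mu * 10, 1e12)
    prev_norm <- cn
  }
  ev <- .al_eval(x, ctx, lam, mu, want_grad = TRUE)
  list(x = x, E = ev$E, converged = converged,
       res_pos = max(abs(ev$c_pos)),
       res_rot = asin(min(1, sqrt(sum(ev$a^2)))) / DEG,
       grad_norm = max(abs(ev$grad)), iterations = iterations)
}

#' Scan loop energies over repressor opening angles
#'
#' For every opening change in `dalpha_grid` and every requested
#' orientation, opens the reference V anchor, minimizes the loop energy
#' (warm-started from the neighboring grid point), and reports the
#' Boltzmann populations of the loop types at each opening.
#'
#' @param n_bp base pairs in the configurable segment.
#' @param model an [elastic_model()].
#' @param geometry a [v_geometry()] for the reference (closed) repressor.
#' @param dalpha_grid numeric vector of opening changes, degrees.
#' @param orientations loop types to include.
#' @param ... passed to [minimize_loop()].
#' @return Data frame with one row per (delta_alpha, orientation):
#'   energies, convergence flag and `sigma_loop` (populations summing to 1
#'   within each delta_alpha).
#' @export
scan_delta_alpha <- function(n_bp, model, geometry,
                             dalpha_grid = 0,
                             orientations = c("A1", "A2", "P1"), ...) {
  dalpha_grid <- sort(dalpha_grid)
  prev <- stats::setNames(vector("list", length(orientations)),
                          orientations)
  rows <- list()
  for (da in dalpha_grid) {
    Es <- stats::setNames(numeric(length(orientations)), orientations)
    for (or in orientations) {
      anchor <- make_v_anchor(geometry, or)
      if (da != 0) anchor <- open_repressor(anchor, da)
      fit <- minimize_loop(n_bp, model, anchor,
                           init = if (is.null(prev[[or]])) "arc"
                           else prev[[or]], ...)
      prev[[or]] <- fit
      Es[or] <- fit$E_total
      rows[[length(rows) + 1L]] <-
        data.frame(delta_alpha = da, orientation = or,
                   E_bend = fit$E_bend, E_twist = fit$E_twist,
                   E_total = fit$E_total, converged = fit$converged)
    }
    sig <- populations(Es)
    for (k in seq_along(orientations))
      rows[[length(rows) - length(orientations) + k]]$sigma_loop <-
        sig[orientations[k]]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Energetic effect of local model modifications on an optimized loop
#'
#' Minimizes the same anchored loop under a set of model variants
#' (e.g. softened pyrimidine-purine steps, overtwisted helix) and reports
#' the energy change against the reference variant together with the
#' relative statistical weight `exp(-dE)`.
#'
#' @param n_bp base pairs in the configurable segment.
#' @param variants named list of [elastic_model()]s; the first entry is
#'   the reference.
#' @param anchor a [loop_anchor()].
#' @param ... passed to [minimize_loop()].
#' @return Data frame with one row per variant: energies, `dE` and
#'   `weight = exp(-dE)`, plus the fitted `loop_optimum` objects as an
#'   attribute `fits`.
#' @export
modification_study <- function(n_bp, variants, anchor, ...) {
  if (is.null(names(variants)) || any(!nzchar(names(variants))))
    stop("variants must be a named list of elastic models")
  fits <- vector("list", length(variants))
  names(fits) <- names(variants)
  ref_fit <- NULL
  rows <- list()
  for (k in seq_along(variants)) {
    fits[[k]] <- minimize_loop(n_bp, variants[[k]], anchor,
                               init = if (k == 1L) "arc" else ref_fit,
                               ...)
    if (k == 1L) ref_fit <- fits[[k]]
    rows[[k]] <- data.frame(variant = names(variants)[k],
                            E_bend = fits[[k]]$E_bend,
                            E_twist = fits[[k]]$E_twist,
                            E_total = fits[[k]]$E_total,
                            converged = fits[[k]]$converged)
  }
  out <- do.call(rbind, rows)
  out$dE <- out$E_total - out$E_total[1]
  out$weight <- exp(-out$dE)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
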
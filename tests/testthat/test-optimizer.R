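test_that("a rest-state end transform minimizes to zero energy", {
  n <- 15
  model <- elastic_model(n)
  anchor <- loop_anchor(bp_frame(),
                        build_chain_frames(rest_chain(n, model))[[n + 1]],
                        "A1")
  fit <- minimize_loop(n + 1, model, anchor, init = "rest")
  expect_true(fit$converged)
  expect_lt(fit$E_total, 1e-10)
  expect_lt(max(abs(fit$chain$steps[, "tilt"])), 1e-5)
  expect_equal(fit$chain$steps[, "twist"], rep(360 / 10.5, n),
               tolerance = 1e-7)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(71)
  n <- 8
  model <- apply_softening(elastic_model(n), c(2, 5), 1.5)
  anchor <- make_v_anchor(v_geometry(), "P1")
  ang <- as.numeric(t(cbind(stats::rnorm(n, 0, 5), stats::rnorm(n, 0, 5),
                            stats::rnorm(n, 360 / 10.5, 5))))
  for (mu in c(0, 50)) {
    g <- energy_gradient(ang, model, anchor, mu = mu)
    fd <- vapply(seq_along(ang), function(k) {
      h <- 1e-5
      ap <- ang; am <- ang
      ap[k] <- ap[k] + h; am[k] <- am[k] - h
      (loop_energy(ap, model, anchor, mu) -
          loop_energy(am, model, anchor, mu)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-6)
  }
  # gradient is invariant under rigid motion of the whole anchor
  R <- random_frame()$axes
  shift <- c(5, -3, 11)
  move <- function(f) bp_frame(R %*% f$origin + shift, R %*% f$axes)
  moved <- loop_anchor(move(anchor$first_frame), move(anchor$last_frame),
                       anchor$orientation)
  g1 <- energy_gradient(ang, model, anchor, mu = 50)
  g2 <- energy_gradient(ang, model, moved, mu = 50)
  expect_equal(g1, g2, tolerance = 1e-8)
})

test_that("ring closure reproduces the continuum elastic-rod energy", {
  # 147 steps at 10.5 bp/turn close exactly 14 helical turns: a
  # torsionally relaxed circle
  nst <- 147
  model <- elastic_model(nst)
  fit <- minimize_loop(nst + 1, model, ring_anchor())
  expect_true(fit$converged)
  expect_lt(fit$constraint_residual["pos"], 1e-6)
  expect_lt(fit$constraint_residual["rot"], 1e-6)
  E_rod <- 2 * pi^2 * model_persistence_length(model) / (nst * model$rise)
  expect_equal(fit$E_total, E_rod, tolerance = 0.02)
  # twist stays at rest and its deviation is uniform across steps
  dtw <- fit$chain$steps[, "twist"] - model$rest_twist
  expect_lt(max(dtw) - min(dtw), 1e-4)
  expect_lt(fit$E_twist, 1e-6)
})

test_that("constrained minimum equals a fixed-penalty minimum", {
  set.seed(72)
  n <- 20
  model <- elastic_model(n)
  anchor <- toy_bent_anchor(n)
  fit <- minimize_loop(n + 1, model, anchor)
  expect_true(fit$converged)
  # independent route: plain quadratic penalty at a large fixed weight,
  # minimized from the same start with numeric-free analytic gradient
  mu <- 1e8
  x0 <- as.numeric(t(fit$chain$steps[, 1:3])) * pi / 180
  pen <- stats::optim(x0,
                      fn = function(p) loop_energy(p * 180 / pi, model,
                                                   anchor, mu = mu),
                      gr = function(p) energy_gradient(p * 180 / pi, model,
                                                       anchor, mu = mu) *
                        180 / pi,
                      method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 1e1))
  E_pen <- loop_energy(pen$par * 180 / pi, model, anchor, mu = 0)
  expect_equal(fit$E_total, E_pen, tolerance = 1e-4 / max(fit$E_total, 1))
})

test_that("optimum lies below every sampled closed configuration", {
  set.seed(73)
  n <- 20
  model <- toy_soft_model(n)
  anchor <- toy_bent_anchor(n)
  crit <- closure_criteria(15, 35, 35)
  h <- sample_half_chains(model, n, 4000)
  E_closed <- c()
  for (i in 1:4000) {
    ch <- half_chain(h, i)
    s <- end_state(ch, anchor)
    if (is_closed(s, crit))
      E_closed <- c(E_closed, elastic_energy(ch, model)$E_total)
  }
  expect_gt(length(E_closed), 5)
  fit <- minimize_loop(n + 1, model, anchor)
  expect_true(fit$converged)
  expect_lt(fit$E_total, min(E_closed))
})

test_that("multi-start reporting keeps every start and picks the best", {
  set.seed(74)
  n <- 20
  model <- elastic_model(n)
  fit <- minimize_loop(n + 1, model, toy_bent_anchor(n), n_starts = 3)
  expect_equal(nrow(fit$starts), 3)
  conv <- fit$starts[fit$starts$converged, ]
  expect_equal(fit$E_total, min(conv$E_total), tolerance = 1e-9)
})

test_that("opening scans report smooth energies and populations", {
  # compact V so a 20-step segment can span the anchor gap
  g <- v_geometry(arm_angle = 34, arm_length = 45)
  tab <- scan_delta_alpha(21, elastic_model(20), g,
                          dalpha_grid = c(-2, 0, 2),
                          orientations = c("A1", "P1"))
  expect_equal(nrow(tab), 6)
  sums <- tapply(tab$sigma_loop, tab$delta_alpha, sum)
  expect_equal(as.numeric(sums), rep(1, 3))
  expect_true(all(tab$converged))
  # warm-started neighbours vary smoothly (no > 5 kBT jumps)
  for (or in c("A1", "P1")) {
    E <- tab$E_total[tab$orientation == or]
    expect_lt(max(abs(diff(E))), 5)
  }
})

test_that("antiparallel 92-bp loops bend less than parallel ones", {
  # default closed V fixture; the dominant antiparallel loop forms a
  # U-turn and pays the smallest bending penalty
  g <- v_geometry()
  n_bp <- loop_free_steps(92) + 1
  E <- vapply(c("A1", "P1", "P2"), function(or) {
    fit <- minimize_loop(n_bp, elastic_model(n_bp - 1),
                         make_v_anchor(g, or))
    expect_true(fit$converged)
    fit$E_bend
  }, numeric(1))
  expect_lt(E["A1"], E["P1"])
  expect_lt(E["A1"], E["P2"])
})

test_that("repressor opening shifts the A/P energy balance monotonically", {
  g <- v_geometry()
  n_bp <- loop_free_steps(92) + 1
  tab <- scan_delta_alpha(n_bp, elastic_model(n_bp - 1), g,
                          dalpha_grid = seq(-8, 8, 4),
                          orientations = c("A1", "P1"))
  gap <- tab$E_total[tab$orientation == "A1"] -
    tab$E_total[tab$orientation == "P1"]
  # relative energies of A- vs P-type loops change monotonically with
  # the opening angle
  expect_true(all(diff(gap) > 0) || all(diff(gap) < 0))
})

test_that("softening lowers loop energy and localizes bending", {
  # 92-bp antiparallel loop on the default V fixture
  n <- loop_free_steps(92)
  model <- elastic_model(n)
  anchor <- make_v_anchor(v_geometry(), "A1")
  soft_sites <- c(30, 45)
  tab <- modification_study(
    n + 1,
    list(reference = model,
         softened = apply_softening(model, soft_sites, 1.5),
         overtwisted = set_intrinsic_twist(model, 36)),
    anchor)
  expect_equal(tab$dE[1], 0)
  expect_equal(tab$weight[1], 1)
  # softened pyrimidine-purine-like sites reduce the energy of any bent
  # loop, and the weight reflects exp(-dE)
  expect_lt(tab$dE[tab$variant == "softened"], 0)
  expect_equal(tab$weight, exp(-tab$dE))
  fits <- attr(tab, "fits")
  # larger bend at the softened sites than at their neighbours
  gam <- bend_profile(build_chain_frames(fits$softened$chain))
  for (s in soft_sites)
    expect_gt(gam[s], max(gam[c(s - 2, s + 2)]))
  # overtwisting displaces the optimized pathway
  d <- displacement_profile(build_chain_frames(fits$reference$chain,
                                               anchor$first_frame),
                            build_chain_frames(fits$overtwisted$chain,
                                               anchor$first_frame))
  expect_gt(d$max, 1)
})
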
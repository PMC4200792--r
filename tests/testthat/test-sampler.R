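test_that("sampled steps reproduce the model moments", {
  set.seed(51)
  model <- elastic_model(1)
  n <- 1e5
  ch <- sample_steps(elastic_model(n), n)
  tw <- ch$steps[, "twist"]
  se_mean <- 4.09 / sqrt(n)
  expect_lt(abs(mean(tw) - 360 / 10.5), 3 * se_mean)
  se_sd <- 4.09 / sqrt(2 * n)
  expect_lt(abs(stats::sd(tw) - 4.09), 3 * se_sd)
  # equipartition: mean per-step energy 3/2 kBT (half chi-squared, 3 df)
  e <- 0.5 * ((ch$steps[, "tilt"] / 4.84)^2 + (ch$steps[, "roll"] / 4.84)^2 +
                ((tw - 360 / 10.5) / 4.09)^2)
  expect_lt(abs(mean(e) - 1.5), 3 * stats::sd(e) / sqrt(n))
  # translations are frozen
  expect_equal(unique(ch$steps[, "shift"]), 0)
  expect_equal(unique(ch$steps[, "rise"]), 3.4)
  # softened sites use enlarged sigmas
  soft <- apply_softening(elastic_model(n), seq_len(n %/% 2), 1.5)
  set.seed(52)
  ch2 <- sample_steps(soft, n)
  sd_soft <- stats::sd(ch2$steps[seq_len(n %/% 2), "roll"])
  sd_hard <- stats::sd(ch2$steps[(n %/% 2 + 1):n, "roll"])
  expect_equal(sd_soft / sd_hard, 1.5, tolerance = 0.05)
})

test_that("end states measure residual closure exactly", {
  # a chain that exactly matches the anchor's reference path closes to zero
  n <- 20
  ref <- dna_chain(cbind(tilt = 0, roll = rep(360 / n, n),
                         twist = 360 / 10.5, shift = 0, slide = 0,
                         rise = 3.4))
  anchor <- toy_bent_anchor(n)
  s <- end_state(ref, anchor)
  expect_lt(s$r_norm, 1e-9)
  expect_lt(s$Gamma, 1e-5)   # acos at perfect alignment amplifies noise
  expect_lt(abs(s$omega), 1e-9)
  # pure 3.4 A z-offset of the phantom
  a0 <- loop_anchor(bp_frame(), bp_frame(origin = c(0, 0, 3.4)), "A1",
                    closing_step = step_params(twist = 0, rise = 0))
  s0 <- end_state(dna_chain(c(0, 0, 0, 0, 0, 3.4)), a0)
  expect_equal(s0$r_norm, 3.4)
  expect_equal(s0$Gamma, 0)
  expect_equal(s0$omega, 0)
  # random chains: agrees with the rotation-decomposition oracle
  set.seed(53)
  model <- toy_soft_model(n)
  for (k in 1:20) {
    ch <- sample_steps(model)
    s <- end_state(ch, anchor)
    ph <- compose_step(build_chain_frames(ch)[[n + 1]],
                       anchor$closing_step)
    expect_equal(s$r_norm, sqrt(sum(ph$origin^2)), tolerance = 1e-10)
    expect_equal(cos(s$Gamma * pi / 180), ph$axes[3, 3],
                 tolerance = 1e-10)
    p <- params_from_frames(bp_frame(), ph)
    expect_equal(s$omega, as.numeric(p["twist"]), tolerance = 1e-10)
  }
})

test_that("closure test applies the criteria on all three residuals", {
  crit <- closure_criteria()
  expect_equal(cos(crit$gamma_max * pi / 180), 0.98, tolerance = 5e-4)
  ok <- function(r, G, w)
    is_closed(list(r_norm = r, Gamma = G, omega = w), crit)
  expect_true(ok(0, 0, 0))
  expect_false(ok(15.1, 0, 0))
  expect_true(ok(14, 11.4, -11.4))
  expect_false(ok(14, 11.6, 0))
  expect_false(ok(14, 0, 11.6))
  expect_error(closure_criteria(r_max = -1), "positive")
})

test_that("a 1 x 1 half-chain combination equals the full-chain build", {
  set.seed(54)
  model <- elastic_model(12)
  anchor <- make_v_anchor(v_geometry(), "A1")
  ha <- sample_half_chains(model, 6, 1)
  hb <- sample_half_chains(model, 6, 1)
  cm <- combine_half_chains(ha, hb, anchor,
                            closure_criteria(1e9, 180, 180))
  expect_equal(cm$hits, 1)
  expect_equal(cm$samples, 1)
  full <- dna_chain(rbind(half_chain(ha, 1)$steps,
                          half_chain(hb, 1)$steps))
  s <- end_state(full, anchor)
  expect_equal(cm$metrics$r, s$r_norm, tolerance = 1e-10)
  expect_equal(cm$metrics$Gamma, s$Gamma, tolerance = 1e-8)
  expect_equal(cm$metrics$omega, s$omega, tolerance = 1e-8)
})

test_that("half-chain combination is unbiased against naive sampling", {
  set.seed(42)
  n <- 20
  model <- toy_soft_model(n)
  anchor <- toy_bent_anchor(n)
  crit <- closure_criteria(15, 40, 40)
  nj <- naive_J(model, n, anchor, crit, n_chains = 2e5)
  ha <- sample_half_chains(model, n %/% 2, 450)
  hb <- sample_half_chains(model, n %/% 2, 450)
  cm <- combine_half_chains(ha, hb, anchor, crit)
  expect_equal(cm$samples, 450^2)
  hj <- estimate_J(cm$hits, cm$samples, crit)
  expect_gt(nj$hits, 100)
  expect_gt(cm$hits, 100)
  expect_lt(abs(nj$J - hj$J), 2 * sqrt(nj$stderr^2 + hj$stderr^2))
})

test_that("the J normalization constant matches first principles", {
  # independent oracle: molar capture volume x bend fraction x twist
  # fraction, computed directly from the defaults
  avogadro <- 6.02214076e23
  oracle <- avogadro * (4 * pi / 3) * 15^3 * 1e-27 *
    ((1 - cos(11.5 * pi / 180)) / 2) * (11.5 / 180)
  expect_equal(j_normalization(), oracle, tolerance = 1e-12)
  expect_equal(oracle, 5.4597e-3, tolerance = 1e-4)
  # a hit fraction equal to the constant gives exactly 1 M
  hits <- round(oracle * 1e8)
  expect_equal(estimate_J(hits, 1e8)$J, 1, tolerance = 1e-4)
  # zero hits: J = 0 with a rule-of-three upper bound
  z <- estimate_J(0, 1e6)
  expect_equal(z$J, 0)
  expect_equal(z$upper95, 3e-6 / j_normalization())
  expect_error(estimate_J(10, 5), "hits")
})

test_that("J is stable under tolerance halving at matched density", {
  set.seed(42)
  n <- 30
  model <- toy_soft_model(n, scale = 2)
  anchor <- loop_anchor(bp_frame(),
                        build_chain_frames(rest_chain(n, model))[[n + 1]],
                        "A1")
  ha <- sample_half_chains(model, n %/% 2, 3000)
  hb <- sample_half_chains(model, n %/% 2, 3000)
  crit <- closure_criteria()
  cm <- combine_half_chains(ha, hb, anchor, crit)
  e1 <- estimate_J(cm$hits, cm$samples, crit)
  crit2 <- closure_criteria(15 / 2, 11.5 / 2, 11.5 / 2)
  cm2 <- combine_half_chains(ha, hb, anchor, crit2)
  e2 <- estimate_J(cm2$hits, cm2$samples, crit2)
  expect_gt(cm2$hits, 20)
  expect_lt(abs(e1$J - e2$J), 2 * sqrt(e1$stderr^2 + e2$stderr^2))
})

test_that("relative weights translate energy gaps into orders of magnitude", {
  expect_equal(relative_weight(5, 5), 1)
  # a 7 kBT drop: about three orders of magnitude easier looping
  expect_equal(relative_weight(10, 17), exp(7))
  expect_equal(log10(relative_weight(10, 17)), 3.04, tolerance = 1e-2)
  # an 18 kBT rise: about eight orders harder
  expect_equal(log10(relative_weight(28, 10)), -7.82, tolerance = 1e-2)
})

test_that("net twist variance grows linearly along free chains", {
  set.seed(55)
  n <- 30
  model <- elastic_model(n)
  anchor <- loop_anchor(bp_frame(),
                        build_chain_frames(rest_chain(n, model))[[n + 1]],
                        "A1")
  m <- 4000
  h <- sample_half_chains(model, n, m)
  om <- vapply(1:m, function(i) {
    s <- end_state(half_chain(h, i), anchor)
    s$omega
  }, numeric(1))
  v <- stats::var(om)
  target <- n * 4.09^2
  se <- target * sqrt(2 / (m - 1))
  expect_lt(abs(v - target), 3 * se + 0.05 * target)
})

test_that("persistence length is recovered from free-chain decay", {
  pl <- persistence_length_mc(n_chains = 2e4, len = 150, seed = 56)
  expect_equal(pl$model_P, 476, tolerance = 0.01)
  expect_equal(pl$P, pl$model_P, tolerance = 0.05)
  # correlations decay monotonically on average
  expect_true(all(diff(log(pl$mean_cos)) < 0))
})

test_that("stochastic outputs are reproducible under a fixed seed", {
  model <- toy_soft_model(16)
  set.seed(60)
  a <- sample_half_chains(model, 8, 50)
  set.seed(60)
  b <- sample_half_chains(model, 8, 50)
  expect_identical(a, b)
  anchors <- list(A1 = toy_bent_anchor(16))
  p1 <- j_profile(anchors, 30, model_for_n = function(nf)
    toy_soft_model(nf), m = 300, criteria = closure_criteria(15, 30, 30),
    seed = 61)
  p2 <- j_profile(anchors, 30, model_for_n = function(nf)
    toy_soft_model(nf), m = 300, criteria = closure_criteria(15, 30, 30),
    seed = 61)
  expect_identical(p1, p2)
})

test_that("J profiles oscillate with helical phase and HU fills valleys", {
  # compact V fixture so that short toy loops can close at desk scale
  g <- v_geometry(arm_angle = 34, arm_length = 45)
  anchors <- list(A1 = make_v_anchor(g, "A1"))
  mfn <- function(nf) toy_soft_model(nf, scale = 2.5)
  crit <- closure_criteria(15, 25, 25)
  Ns <- c(46, 47, 48, 51, 52, 53)
  bare <- j_profile(anchors, Ns, model_for_n = mfn, m = 2000,
                    criteria = crit, seed = 7)
  hu <- j_profile(anchors, Ns, model_for_n = mfn, m = 2000,
                  criteria = crit, hu = binding_config(150), seed = 7)
  trough <- bare$N %in% c(46, 47, 48)
  peak <- !trough
  # helical-phase oscillation: peak J well above trough J
  expect_gt(sum(bare$J_molar[peak]), 3 * sum(bare$J_molar[trough]))
  # HU raises J in the trough and damps the oscillation amplitude
  expect_gt(sum(hu$J_molar[trough]), sum(bare$J_molar[trough]))
  ratio_bare <- sum(bare$J_molar[peak]) / max(sum(bare$J_molar[trough]),
                                              1e-12)
  ratio_hu <- sum(hu$J_molar[peak]) / sum(hu$J_molar[trough])
  expect_lt(ratio_hu, ratio_bare)
  # closed loops take up at least the free-chain HU level
  hits <- hu$hits > 0
  mean_closed <- sum(hu$mean_hu[hits] * hu$hits[hits]) / sum(hu$hits[hits])
  set.seed(8)
  free_level <- mean(simulate_free_occupancy(binding_config(150),
                                             max(Ns) - 14, reps = 400))
  expect_gte(mean_closed, free_level)
})
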
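test_that("sensor signals follow first-order kinetics in closed form", {
  p <- model_params(tau1 = 2, tau2 = 3, alpha1 = 0.05, alpha2 = 0.1)
  # constant light from c1_0 = 0: c1(tau1) = alpha1*I*(1 - 1/e)
  pr <- light_protocol(4, 20)
  sig <- sensor_signals(pr, p, c1_0 = 0, c2_0 = 0, times = p$tau1)
  expect_equal(sig$c1, 0.05 * 4 * (1 - exp(-1)), tolerance = 1e-12)
  # darkness: c1 stays 0, c2 relaxes to alpha2 (dark is below threshold)
  dark <- light_protocol(0, 10)
  sig <- sensor_signals(dark, p, c1_0 = 0, c2_0 = 0,
                        times = seq(0, 10, 0.5))
  expect_true(all(sig$c1 == 0))
  expect_equal(sig$c2, 0.1 * (1 - exp(-sig$time_min / 3)), tolerance = 1e-12)
})

test_that("sensor signals match a fine-step RK4 oracle on a 3-segment protocol", {
  p <- lunula_params()
  pr <- light_protocol(c(10, 0.5, 5), c(3, 2, 3))
  # oracle integrates the signal ODEs numerically; the package solves
  # them in closed form
  orc <- oracle_rk4(pr, p, x0 = 0, c1_0 = 0, c2_0 = p$alpha2, dt = 1e-3)
  sig <- sensor_signals(pr, p, times = orc$time)
  expect_lt(max(abs(sig$c1 - orc$c1)) / max(orc$c1), 1e-6)
  expect_lt(max(abs(sig$c2 - orc$c2)) / max(orc$c2), 1e-6)
  # the full mechanical response agrees too (kinks limit RK4 locally)
  sim <- simulate_response(pr, p)
  at <- orc$at(sim$time_min)
  expect_lt(max(abs(sim$x - at)) / max(at), 5e-4)
})

test_that("forcing position is the clipped, capped net signal", {
  p <- model_params(beta = 1, x_max = 0.4)
  expect_equal(forcing_position(0.3, 0.3, p), 0)
  expect_equal(forcing_position(0.1, 0.3, p), 0)   # c2 > c1 clips to 0
  expect_equal(forcing_position(0.3, 0.1, p), 0.2)
  expect_equal(forcing_position(2, 0, p), 0.4)     # capped at x_max
})

test_that("response to a step of strong light has the observed shape", {
  p <- lunula_params()
  pr <- light_protocol(10, 30)
  sim <- simulate_response(pr, p, x0 = 0, c1_0 = 0, c2_0 = 0)
  # zero initial slope, early positive curvature, monotone rise
  i2 <- which(sim$time_min <= 2)
  expect_lt(sim$x[2] - sim$x[1], 1e-4)
  expect_true(all(diff(sim$x, differences = 2)[seq_len(20)] > 0))
  expect_true(all(diff(sim$x) >= -1e-12))
  x_ss <- min(p$beta * p$alpha1 * 10, p$x_max)
  expect_equal(tail(sim$x, 1), x_ss, tolerance = 1e-3)
})

test_that("relaxation in darkness decays with the expansion time constant", {
  p <- lunula_params()
  pr <- light_protocol(0, 40)
  x0 <- 0.3
  sim <- simulate_response(pr, p, x0 = x0, c1_0 = 0, c2_0 = p$alpha2)
  # signals already at dark rest: p = -beta*alpha2 clipped to 0, so
  # x(t) = x0 exp(-t / tau_kv_star) for all t
  expect_equal(sim$x, x0 * exp(-sim$time_min / p$tau_kv_star),
               tolerance = 1e-5)
})

test_that("p identically x0 keeps the response constant", {
  # darkness with alpha2 = 0 and x0 = 0: p = 0 = x0 throughout
  p <- model_params(alpha2 = 0)
  sim <- simulate_response(light_protocol(0, 10), p, x0 = 0, c2_0 = 0)
  expect_true(all(sim$x == 0))
})

test_that("closed-form constant-light solution matches simulation (property)", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    p <- model_params(tau_kv = runif(1, 0.5, 6), tau_kv_star = runif(1, 0.5, 10),
                      tau1 = runif(1, 0.5, 5), tau2 = runif(1, 0.5, 5),
                      alpha1 = runif(1, 0.005, 0.08), alpha2 = runif(1, 0, 0.3),
                      beta = runif(1, 0.5, 3), i_th = 2.8)
    I <- sample(c(0, 0.6, 2, 5, 20), 1)
    x0 <- runif(1, 0, p$x_max)
    c1_0 <- runif(1, 0, 0.3); c2_0 <- runif(1, 0, 0.3)
    sim <- simulate_response(light_protocol(I, 25), p, x0 = x0,
                             dt = min(p$tau_kv, p$tau_kv_star, p$tau1,
                                      p$tau2) / 200,
                             c1_0 = c1_0, c2_0 = c2_0)
    cl <- constant_light_solution(I, p, x0 = x0, c1_0 = c1_0, c2_0 = c2_0,
                                  t = sim$time_min)
    worst <- max(worst, max(abs(sim$x - cl)))
  }
  expect_lt(worst, 1e-5)
})

test_that("closed form handles coincident time constants and endpoints", {
  p <- model_params(tau_kv = 2, tau_kv_star = 5, tau1 = 2, tau2 = 2,
                    alpha1 = 0.02, alpha2 = 0.05)
  x0 <- 0.1
  expect_equal(constant_light_solution(8, p, x0 = x0, t = 0), x0)
  sim <- simulate_response(light_protocol(8, 30), p, x0 = x0)
  cl <- constant_light_solution(8, p, x0 = x0, t = sim$time_min)
  expect_lt(max(abs(sim$x - cl)), 1e-5)
  # t -> infinity under strong light reaches min(beta*alpha1*I, x_max)
  expect_equal(constant_light_solution(8, p, x0 = x0, t = 500),
               min(p$beta * p$alpha1 * 8, p$x_max), tolerance = 1e-6)
})

test_that("steady states and the sub-threshold transient behave as observed", {
  p <- lunula_params()
  expect_equal(steady_state_contraction(12, p), 0.4)
  expect_equal(steady_state_contraction(41.4, p), 0.4)
  expect_equal(steady_state_contraction(6, p), 0.2)
  expect_equal(steady_state_contraction(0, p), 0)
  # prolonged darkness: complete expansion
  sim <- simulate_response(light_protocol(0, 80), p, x0 = 0.4,
                           c1_0 = 0.3, c2_0 = 0)
  expect_lt(tail(sim$x, 1), 1e-3)
  # sub-threshold transient: slower repressor (tau2 > tau1) and net
  # negative drive produce a rise followed by decay toward zero
  pt <- model_params(tau1 = 1, tau2 = 3, alpha1 = 0.05, alpha2 = 0.08,
                     beta = 2, i_th = 2.8)
  expect_lt(pt$beta * (pt$alpha1 * 1.5 - pt$alpha2), 0)
  st <- simulate_response(light_protocol(1.5, 60), pt, c1_0 = 0, c2_0 = 0)
  pk <- which.max(st$x)
  expect_gt(st$x[pk], 0.02)
  expect_gt(pk, 2)
  expect_lt(tail(st$x, 1), 0.25 * st$x[pk])
})

test_that("transfer magnitude is a DC-normalized two-pole low-pass", {
  p <- lunula_params()
  expect_equal(transfer_magnitude(0, p), 1)
  om <- seq(0, 5, 0.1)
  expect_true(all(diff(transfer_magnitude(om, p)) < 0))
  expect_lt(transfer_magnitude(1e4, p), 1e-6)
  # tau_kv -> 0: single pole, half power at omega = 1/tau1
  p1 <- model_params(tau_kv = 1e-9, tau1 = 2)
  expect_equal(transfer_magnitude(1 / 2, p1), 1 / sqrt(2), tolerance = 1e-6)
})

test_that("simulated sinusoidal response amplitude matches the filter gain", {
  # symmetric mechanical element: the cascade gain describes the
  # linear response, so expansion must share the contraction timescale
  p <- model_params(tau_kv_star = lunula_params()$tau_kv)
  I0 <- 9; amp <- 2
  for (omega in c(0.15, 0.6)) {
    period <- 2 * pi / omega
    dt_seg <- period / 60
    n_per <- 12
    tt <- seq(0, n_per * period, by = dt_seg)
    irr <- I0 + amp * sin(omega * utils::head(tt, -1) + omega * dt_seg / 2)
    pr <- light_protocol(irr, rep(dt_seg, length(irr)))
    sim <- simulate_response(pr, p, x0 = p$beta * p$alpha1 * I0,
                             c1_0 = p$alpha1 * I0, c2_0 = 0)
    late <- sim$time_min > (n_per - 3) * period
    x_amp <- (max(sim$x[late]) - min(sim$x[late])) / 2
    gain_pred <- transfer_magnitude(omega, p)
    x_amp_pred <- p$beta * p$alpha1 * amp * gain_pred
    expect_equal(x_amp, x_amp_pred, tolerance = 0.05)
  }
})

test_that("cutoff frequency solves the half-power condition", {
  p1 <- model_params(tau_kv = 1, tau1 = 1)
  expect_equal(cutoff_frequency(p1), sqrt(sqrt(2) - 1), tolerance = 1e-9)
  # scaling symmetry: doubling both time constants halves the cutoff
  p2 <- model_params(tau_kv = 2, tau1 = 2)
  expect_equal(cutoff_frequency(p2), cutoff_frequency(p1) / 2,
               tolerance = 1e-9)
  # population-mean parameters put the cutoff at 0.3/min to 1 significant
  # figure, the scale of ocean surface-wave flicker the cell ignores
  expect_equal(signif(cutoff_frequency(lunula_params()), 1), 0.3)
})

test_that("dose-response recovers the printed correlation structure", {
  expect_equal(dose_response(list(c(1, 0.9), c(1, 0.8), c(1, 0.7)),
                             c(1, 2, 3))$pearson_rho, 1)
  expect_equal(dose_response(list(c(1, 0.7), c(1, 0.8), c(1, 0.9)),
                             c(1, 2, 3))$pearson_rho, -1)
  expect_error(dose_response(list(c(1, 0.8), c(1, 0.8), c(1, 0.8)),
                             c(1, 2, 3)), "zero-variance")
  # model-generated response at the eight printed irradiances, checked
  # against the textbook correlation formula
  p <- lunula_params()
  irr <- c(0.6, 2.8, 4.9, 7.6, 14.5, 23.4, 32.4, 41.4)
  traces <- lapply(irr, function(I)
    simulate_area_trace(p, light_protocol(I, 20), noise_sd = 0, seed = 1))
  dr <- dose_response(traces, irr)
  d <- dr$delta_a_max
  rho_direct <- sum((irr - mean(irr)) * (d - mean(d))) /
    sqrt(sum((irr - mean(irr))^2) * sum((d - mean(d))^2))
  expect_equal(dr$pearson_rho, rho_direct, tolerance = 1e-12)
  expect_gt(dr$pearson_rho, 0)
  # saturation: strongest stimuli hit the core-area cap
  expect_equal(max(d), 0.4, tolerance = 0.01)
})

test_that("maximal contraction reads the trace minimum", {
  expect_equal(max_contraction(c(1, 1, 1)), 0)
  expect_equal(max_contraction(c(1, 0.8, 0.6, 0.9)), 0.4)
  expect_error(max_contraction(numeric(0)))
  p <- lunula_params()
  tr <- simulate_area_trace(p, light_protocol(40, 40), noise_sd = 0, seed = 1)
  expect_equal(max_contraction(tr), 0.4, tolerance = 5e-3)
})

test_that("signal diffusion estimate is exactly L^2/tau", {
  expect_equal(estimate_signal_diffusion(80, 40)$diffusion_um2_s, 160)
  expect_equal(estimate_signal_diffusion(100, 20)$diffusion_um2_s, 500)
  expect_equal(estimate_signal_diffusion(10, 1)$diffusion_um2_s, 100)
  # multiplicative scaling: L -> aL scales D by a^2
  a <- 3.7
  expect_equal(estimate_signal_diffusion(a * 80, 40)$diffusion_um2_s,
               a^2 * estimate_signal_diffusion(80, 40)$diffusion_um2_s)
  expect_error(estimate_signal_diffusion(-1, 1))
})
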
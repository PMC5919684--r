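test_that("simulation handles the degenerate zero-length case", {
  out <- simulate_envelope(unif_params(), 0, rate = 100)
  expect_equal(nrow(out$seq), 0)
  expect_equal(length(out$envelope$samples), 0)
})

test_that("fixed durations carve notches at multiples of 1/D", {
  p <- seq_model_params(rate = 1, amplitude_mean = 1, amplitude_sd = 0,
                        duration_mean = 0.1, duration_sd = 0,
                        duration_dist = "fixed")
  sim <- simulate_envelope(p, 2000, rate = 500, seed = 11)
  s <- multitaper_amps(sim$envelope)
  pw <- function(f) s$power[which.min(abs(s$freq - f))]
  expect_lt(10 * log10(pw(10) / pw(9)), -10)
  expect_lt(10 * log10(pw(20) / pw(19)), -10)
})

test_that("the simulated AMPS matches the closed form at low duty cycle", {
  p <- unif_params(rate = 0.5)
  sim <- simulate_envelope(p, 2000, rate = 1000, seed = 42)
  s <- multitaper_amps(sim$envelope)
  tp <- theory_params(rate = nrow(sim$seq) / 2000, amp_second_moment = 1,
                      T1 = 0.05, T2 = 0.5)
  expect_lt(rms_db_error(s, theory_overlay(tp, s), range = c(0.1, 100)), 1)
})

test_that("constant-amplitude perturbation preserves envelope variance", {
  sim <- simulate_envelope(species_preset("infant")$params, 400,
                           rate = 1000, seed = 3)
  pert <- perturb(sim$seq, "constant_amplitude")
  # onsets and durations bitwise identical, amplitudes constant
  expect_identical(pert$onset, sim$seq$onset)
  expect_identical(pert$duration, sim$seq$duration)
  expect_equal(length(unique(pert$amplitude)), 1)
  v0 <- var(render_model_envelope(sim$seq, 1000)$samples)
  v1 <- var(render_model_envelope(pert, 1000)$samples)
  expect_lt(abs(v1 / v0 - 1), 0.01)
})

test_that("constant-interval perturbation produces a periodic train", {
  sim <- simulate_envelope(unif_params(rate = 1), 100, rate = 500, seed = 5)
  pert <- perturb(sim$seq, "constant_interval", interval = 1)
  expect_equal(pert$onset, seq_len(nrow(sim$seq)) * 1.0)
  expect_identical(pert$amplitude, sim$seq$amplitude)
  expect_true(all(pert$duration <= 0.9))
  # durations longer than the slot trigger a truncation warning
  long_seq <- pulse_seq(c(1, 3), c(1.5, 0.2), c(1, 1), 5)
  expect_warning(perturb(long_seq, "constant_interval", interval = 1),
                 "truncated")
})

test_that("zero-duration perturbation keeps onsets and amplitudes", {
  sim <- simulate_envelope(unif_params(rate = 1), 200, rate = 500, seed = 6)
  pert <- perturb(sim$seq, "zero_duration")
  expect_identical(pert$onset, sim$seq$onset)
  expect_identical(pert$amplitude, sim$seq$amplitude)
  expect_true(all(pert$duration == 0))
  s <- multitaper_amps(render_model_envelope(pert, 500))
  expect_lt(abs(fit_scaling_exponent(s, c(1, 100))$exponent), 0.2)
})

test_that("duration-distribution swaps preserve moments and structure", {
  sim <- simulate_envelope(unif_params(rate = 0.5), 1000, rate = 500,
                           seed = 7)
  for (dist in c("uniform", "exponential", "gamma")) {
    pert <- perturb(sim$seq, "swap_duration_dist", target_dist = dist,
                    seed = 8)
    expect_identical(pert$onset, sim$seq$onset)
    expect_identical(pert$amplitude, sim$seq$amplitude)
    expect_lt(abs(mean(pert$duration) - mean(sim$seq$duration)) /
                mean(sim$seq$duration), 0.15)
  }
})

test_that("matched-moment duration distributions give similar AMPS", {
  sim <- simulate_envelope(unif_params(rate = 0.5), 2000, rate = 1000,
                           seed = 9)
  s_base <- multitaper_amps(sim$envelope)
  pg <- perturb(sim$seq, "swap_duration_dist", target_dist = "gamma",
                seed = 10)
  s_g <- multitaper_amps(render_model_envelope(pg, 1000))
  expect_lt(rms_db_error(s_base, s_g, range = c(1, 100)), 1.5)
})

test_that("doubling amplitudes multiplies the AMPS by four exactly", {
  sim <- simulate_envelope(unif_params(rate = 0.5), 300, rate = 500,
                           seed = 12)
  s1 <- multitaper_amps(sim$envelope)
  doubled <- pulse_seq(sim$seq$onset, sim$seq$duration,
                       2 * sim$seq$amplitude,
                       attr(sim$seq, "total_duration"))
  s2 <- multitaper_amps(render_model_envelope(doubled, 500))
  ok <- s1$power > 1e-12
  expect_equal(s2$power[ok] / s1$power[ok], rep(4, sum(ok)),
               tolerance = 1e-9)
})

test_that("the periodic-train AMPS has a 1 Hz comb following 1/f^2", {
  p <- seq_model_params(rate = 1, amplitude_mean = 1, amplitude_sd = 0.3,
                        duration_mean = 0.3, duration_sd = 0.1,
                        duration_dist = "gamma")
  base <- draw_pulse_sequence(p, 650, seed = 9)
  pert <- perturb(base, "constant_interval", interval = 1)
  s <- multitaper_amps(render_model_envelope(pert, 1000), nfft = 262144)
  f0 <- harmonic_fundamental(s, f_min = 0.1)
  expect_lt(abs(f0 - 1), 1000 / 262144 + 1e-9)   # within one bin
  # per-harmonic peak amplitudes decay roughly as 1/f^2
  hpk <- vapply(1:12, function(k) {
    i <- which(s$freq > k - 0.05 & s$freq < k + 0.05)
    max(s$power[i])
  }, numeric(1))
  slope <- unname(coef(lm(log10(hpk) ~ log10(1:12)))[2])
  expect_gt(slope, -3); expect_lt(slope, -1)
})

test_that("the perturbation experiment table is complete and seeded", {
  p <- unif_params(rate = 0.5)
  tab <- suppressWarnings(
    perturbation_experiment(p, 200, modes = c("constant_amplitude",
                                              "zero_duration"),
                            rate = 500, seed = 2, nfft = 4096))
  expect_equal(tab$mode, c("baseline", "constant_amplitude",
                           "zero_duration"))
  expect_true(all(c("alpha", "f_c", "spectrum") %in% names(tab)))
  tab2 <- suppressWarnings(
    perturbation_experiment(p, 200, modes = c("constant_amplitude",
                                              "zero_duration"),
                            rate = 500, seed = 2, nfft = 4096))
  expect_equal(tab$alpha, tab2$alpha)
  # empty mode list: baseline only
  tab0 <- perturbation_experiment(p, 200, modes = character(0), rate = 500,
                                  seed = 2, nfft = 4096)
  expect_equal(tab0$mode, "baseline")
})
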
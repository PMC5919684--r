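test_that("degenerate duration distribution gives exactly fixed durations", {
  p <- seq_model_params(rate = 2, duration_mean = 0.1, duration_sd = 0,
                        duration_dist = "fixed", amplitude_mean = 1,
                        amplitude_sd = 0)
  sq <- draw_pulse_sequence(p, 200, seed = 1)
  expect_true(all(sq$duration[-nrow(sq)] == 0.1))  # last may hit T
  expect_true(all(sq$amplitude == 1))
})

test_that("pulse count matches the requested rate", {
  sq <- draw_pulse_sequence(unif_params(rate = 2), 1000, seed = 7)
  expect_lt(abs(nrow(sq) - 2000), 3 * sqrt(2000))
})

test_that("sequences are sorted, non-overlapping, and inside [0, T]", {
  for (seed in 1:5) {
    p <- species_preset(sample(c("infant", "speech", "bird"), 1))$params
    sq <- draw_pulse_sequence(p, 100, seed = seed)
    expect_false(is.unsorted(sq$onset))
    n <- nrow(sq)
    expect_true(all(sq$onset[-n] + sq$duration[-n] <= sq$onset[-1] + 1e-12))
    expect_true(all(sq$duration >= 0))
    expect_true(all(sq$amplitude > 0))
    expect_lte(max(sq$onset + sq$duration), 100 + 1e-9)
  }
})

test_that("method-of-moments draws reproduce the requested moments", {
  set.seed(42)
  n <- 1e5
  for (dist in c("uniform", "gamma", "lognormal")) {
    x <- vocamps:::draw_dist(n, dist, 0.33, 0.2)
    expect_lt(abs(mean(x) - 0.33) / 0.33, 0.01)
    expect_lt(abs(sd(x) - 0.2) / 0.2, 0.02)
  }
  # exponential matches the mean only (its sd equals the mean)
  x <- vocamps:::draw_dist(n, "exponential", 0.33, 0.2)
  expect_lt(abs(mean(x) - 0.33) / 0.33, 0.02)
})

test_that("sequence-level duration and interval moments match the model", {
  p <- species_preset("infant")$params
  sq <- draw_pulse_sequence(p, 20000, seed = 3)
  expect_lt(abs(mean(sq$duration) - 0.33) / 0.33, 0.03)
  expect_lt(abs(sd(sq$duration) - 0.20) / 0.20, 0.05)
  ivl <- diff(sq$onset)
  expect_lt(abs(mean(ivl) - 1.06) / 1.06, 0.03)      # rate preserved
  expect_gte(min(ivl), p$interval_dead_time + min(sq$duration[-nrow(sq)]))
})

test_that("infeasible moment requests raise parameter errors", {
  expect_error(seq_model_params(rate = 1, duration_mean = 0.1,
                                duration_sd = 0.2,
                                duration_dist = "uniform"),
               "Infeasible uniform")
  # durations longer than the mean interval cannot fit without overlap
  p <- seq_model_params(rate = 2, duration_mean = 0.6, duration_sd = 0.1,
                        duration_dist = "gamma")
  expect_error(draw_pulse_sequence(p, 100), "Infeasible moments")
  expect_error(seq_model_params(rate = -1), "positive")
})

test_that("rendering is reproducible bit-for-bit for a fixed seed", {
  p <- unif_params(rate = 1)
  tr <- draw_pulse_sequence(p, 10, seed = 5)
  spec <- scene_spec(c(500, 3500), 8000, 10, snr_db = 20, seed = 9)
  w1 <- render_scene(spec, tr)
  w2 <- render_scene(spec, tr)
  expect_identical(w1$samples, w2$samples)
  spec2 <- scene_spec(c(500, 3500), 8000, 10, snr_db = 20, seed = 10)
  expect_false(identical(render_scene(spec2, tr)$samples, w1$samples))
})

test_that("an empty sequence renders as pure background noise", {
  empty <- pulse_seq(total_duration = 5)
  spec <- scene_spec(c(500, 3500), 8000, 5, noise_floor_sd = 0.05, seed = 2)
  w <- render_scene(spec, empty)
  expect_lt(abs(sd(w$samples) - 0.05) / 0.05, 0.05)
})

test_that("a high-SNR pulse is recovered by the envelope front end", {
  sc <- toy_scene(n_pulses = 1, amp = 1, dur = 0.4, snr_db = 40)
  e <- sc$env$analysis
  truth_env <- render_model_envelope(sc$truth, e$rate,
                                     n_samples = length(e$samples))
  # correlation with the ideal rectangle, and amplitude within rise time
  expect_gt(cor(e$samples, truth_env$samples), 0.95)
  on <- sc$truth$onset[1]; off <- on + sc$truth$duration[1]
  inside <- which(sample_times(e) > on + 0.02 & sample_times(e) < off - 0.02)
  raw <- e$samples * sc$env$scale   # undo the unit-SD normalization
  expect_lt(abs(mean(raw[inside]) - 1), 0.1)
})

test_that("a vocal-fold modulation shows up as an envelope spectral peak", {
  p <- seq_model_params(rate = 1, amplitude_mean = 1, amplitude_sd = 0.2,
                        duration_mean = 0.4, duration_sd = 0.1,
                        duration_dist = "gamma")
  tr <- draw_pulse_sequence(p, 40, seed = 2)
  spec <- scene_spec(c(500, 3500), 8000, 40, snr_db = 30,
                     vocal_fold_f0 = 190, seed = 3)
  w <- render_scene(spec, tr)
  env <- extract_envelopes(w, 500, 3500, DF = 2)
  s <- multitaper_amps(env$analysis)
  band <- s$freq > 150 & s$freq < 230
  f_peak <- s$freq[band][which.max(s$power[band])]
  expect_lt(abs(f_peak - 190), 2)
})

test_that("scenes round-trip through WAV, CSV and JSON sidecars", {
  dir <- withr::local_tempdir()
  p <- unif_params(rate = 1)
  truth <- draw_pulse_sequence(p, 5, seed = 4)
  spec <- scene_spec(c(500, 3500), 8000, 5, snr_db = 20, seed = 4)
  scene <- list(truth = truth, audio = render_scene(spec, truth),
                spec = spec, preset = list(species = "custom"))
  write_scene(scene, dir, "sc")
  w2 <- read_wav(file.path(dir, "sc.wav"))
  expect_equal(w2$rate, 8000)
  expect_lt(max(abs(w2$samples - scene$audio$samples)), 1e-6)  # float32
  gt <- read.csv(file.path(dir, "sc_truth.csv"))
  expect_equal(gt$onset_s, truth$onset)
  man <- jsonlite::read_json(file.path(dir, "sc.json"))
  expect_equal(man$sample_rate, 8000)
  expect_equal(man$seed, 4L)
})
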
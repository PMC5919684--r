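# brute-force oracle: exhaustive search over every (start, length) support
# at one-sample resolution, same tie-break (smallest duration, earliest
# start on strict-improvement scanning)
oracle_fit <- function(x) {
  w <- length(x)
  cs <- c(0, cumsum(x))
  best <- list(a = 1L, d = 1L, score = -Inf)
  for (d in 1:w) for (a in 1:(w - d + 1)) {
    s1 <- cs[a + d] - cs[a]
    if (s1 <= 0) next
    sc <- s1 * s1 / d
    thr <- if (is.finite(best$score)) {
      best$score + 1e-10 * max(1, abs(best$score))
    } else -Inf
    if (sc > thr) best <- list(a = a, d = d, score = sc)
  }
  best
}

test_that("a rectangular envelope is recovered exactly with zero SSE", {
  e <- rect_envelope(rate = 1000, total = 1, onset = 0.3, dur = 0.3, amp = 2)
  seg <- segment_tbl(e, 0.28, 0.62)
  fit <- fit_pulse(e, seg[1, ], pad = 0.1)
  expect_equal(fit$onset, 0.3)
  expect_equal(fit$duration, 0.3)
  expect_equal(fit$amplitude, 2)
  expect_lt(fit$sse, 1e-18)
})

test_that("noisy rectangles are recovered within tolerance (Monte Carlo)", {
  rate <- 1000
  miss_d <- miss_t <- 0
  for (seed in 1:100) {
    set.seed(seed)
    e <- rect_envelope(rate = rate, total = 1, onset = 0.31, dur = 0.3,
                       amp = 1, noise_sd = 0.1)
    seg <- segment_tbl(e, 0.3, 0.62)
    fit <- fit_pulse(e, seg[1, ], pad = 0.1)
    if (abs(fit$duration - 0.3) / 0.3 > 0.05) miss_d <- miss_d + 1
    if (abs(fit$onset - 0.31) > 2 / rate) miss_t <- miss_t + 1
  }
  expect_lte(miss_d, 5)
  expect_lte(miss_t, 5)
})

test_that("fits agree with the exhaustive oracle on awkward shapes", {
  rate <- 200
  shapes <- list(
    triangle = c(numeric(20), seq(0, 1, length.out = 30),
                 seq(1, 0, length.out = 30), numeric(20)),
    ramp_step = c(numeric(15), seq(0, 2, length.out = 25), rep(2, 20),
                  numeric(20)),
    two_bumps = c(numeric(10), rep(1, 15), numeric(8), rep(1.2, 12),
                  numeric(15)))
  for (nm in names(shapes)) {
    x <- shapes[[nm]]
    e <- envelope_signal(x, rate)
    seg <- tibble::tibble(start_index = 1L, end_index = length(x),
                          start_s = 0, end_s = (length(x) - 1) / rate)
    fit <- fit_pulse(e, seg[1, ], pad = 0)
    orc <- oracle_fit(x)
    expect_equal(fit$duration, orc$d / rate, info = nm)
    expect_equal(fit$onset, (orc$a - 1) / rate, info = nm)
  }
})

test_that("fitting scales linearly with envelope amplitude", {
  e <- rect_envelope(rate = 500, onset = 0.2, dur = 0.25, amp = 1,
                     noise_sd = 0.05)
  e5 <- envelope_signal(5 * e$samples, e$rate)
  seg <- segment_tbl(e, 0.18, 0.48)
  f1 <- fit_pulse(e, seg[1, ])
  f5 <- fit_pulse(e5, seg[1, ])
  expect_equal(f5$onset, f1$onset)
  expect_equal(f5$duration, f1$duration)
  expect_equal(f5$amplitude, 5 * f1$amplitude, tolerance = 1e-12)
})

test_that("degenerate segments raise an error", {
  e <- rect_envelope()
  expect_error(fit_pulse(e, list(start_index = 5L, end_index = 6L), pad = 0),
               "Degenerate")
})

test_that("the model envelope renderer honors the sample-grid convention", {
  sq <- pulse_seq(0, 1, 1, 2)
  e <- render_model_envelope(sq, 100)
  expect_equal(sum(e$samples), 100)             # exactly 100 unit samples
  expect_equal(length(e$samples), 200)
  # energy identity within one sample per pulse
  sq2 <- pulse_seq(c(0.1, 1.0, 2.5), c(0.3, 0.55, 0.21), c(2, 1, 3), 4)
  e2 <- render_model_envelope(sq2, 250)
  analytic <- sum(sq2$amplitude^2 * sq2$duration) * 250
  expect_lt(abs(sum(e2$samples^2) - analytic),
            nrow(sq2) * max(sq2$amplitude^2))
  # empty sequence renders to silence
  expect_true(all(render_model_envelope(pulse_seq(total_duration = 1),
                                        100)$samples == 0))
  # zero-duration pulse becomes a single impulse sample
  e3 <- render_model_envelope(pulse_seq(0.5, 0, 2, 1), 100)
  expect_equal(sum(e3$samples > 0), 1)
  expect_equal(max(e3$samples), 2)
})

test_that("assembling fits enforces ordering and non-overlap", {
  expect_equal(nrow(assemble_sequence(fit_pulses(
    rect_envelope(), tibble::tibble()), 1)), 0)
  fits <- tibble::tibble(onset = c(0.5, 0.1), duration = c(0.3, 0.45),
                         amplitude = c(1, 2), sse = 0,
                         window_start = 0, window_end = 1)
  sq <- assemble_sequence(fits, 2)
  expect_equal(sq$onset[1], 0.1)
  # overlap [0.5, 0.55] truncated at its midpoint 0.525
  expect_equal(sq$onset[1] + sq$duration[1], 0.525)
  expect_equal(sq$onset[2], 0.525)
  expect_equal(voc_rate(sq), 1)
})

test_that("fitted pulses on a rendered scene recover the ground truth", {
  sc <- toy_scene(n_pulses = 8, amp = 1, dur = 0.35, gap = 1.0,
                  snr_db = 35, seed = 41)
  ns <- estimate_noise(sc$env$segmentation, c(0.15, 2.85))
  seg <- detect_segments(sc$env$segmentation, ns, threshold_sd = 30)
  fits <- fit_pulses(sc$env$analysis, seg)
  sq <- assemble_sequence(fits, duration(sc$env$analysis))
  expect_equal(nrow(sq), 8)
  expect_lt(abs(voc_rate(sq) - voc_rate(sc$truth)) / voc_rate(sc$truth),
            0.1)
  expect_true(all(abs(sq$onset - sc$truth$onset) < 0.02))
  expect_true(all(abs(sq$duration - sc$truth$duration) /
                    sc$truth$duration < 0.1))
})
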
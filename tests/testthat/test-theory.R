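test_that("the single-pulse spectrum matches its analytic values", {
  expect_equal(single_pulse_spectrum(0, 1, 1), 1)        # sinc limit
  expect_equal(single_pulse_spectrum(1, 1, 1), 0)        # first notch
  expect_equal(single_pulse_spectrum(1, 2, 0.5), 4 / pi^2,
               tolerance = 1e-12)
  expect_equal(single_pulse_spectrum(1e-9, 1, 1), 1, tolerance = 1e-6)
})

test_that("the single-pulse spectrum matches a squared FFT oracle", {
  # numerically squared Fourier magnitude of a rendered pulse
  rate <- 2000; T <- 64
  e <- render_model_envelope(pulse_seq(10, 0.5, 2, T), rate)
  X <- fft(e$samples) / rate                 # continuous-FT approximation
  fgrid <- (0:(length(e$samples) - 1)) / T
  for (f in c(0.25, 1, 1.5, 3.7)) {
    i <- which.min(abs(fgrid - f))
    expect_equal(Mod(X[i])^2, single_pulse_spectrum(fgrid[i], 2, 0.5),
                 tolerance = 1e-3)
  }
})

test_that("the closed-form AMPS has the right limits and values", {
  p <- theory_params(rate = 1, amp_second_moment = 1, T1 = 0, T2 = 1)
  expect_equal(closed_form_amps(0, p), 1 / 3)            # E[D^2]/3 limit
  expect_equal(amps_low_limit(p), 1 / 3)
  # continuity at f -> 0
  expect_equal(closed_form_amps(1e-6, p), amps_low_limit(p),
               tolerance = 1e-6)
  # high-frequency asymptote with bracket-term bound
  s10 <- closed_form_amps(10, p)
  asym <- amps_high_asymptote(10, p)
  expect_equal(asym, 1 / (2 * pi^2 * 100), tolerance = 1e-12)
  expect_lt(abs(s10 - asym) / asym, 1 / (2 * pi * 10 * (1 - 0)))
  # ratio -> 1 far above the cutoff
  f_far <- 100 / (p$T2 - p$T1)
  expect_equal(closed_form_amps(f_far, p) / amps_high_asymptote(f_far, p),
               1, tolerance = 0.005)
})

test_that("the AMPS is linear in rate and amplitude second moment", {
  p1 <- theory_params(rate = 1, amp_second_moment = 1, T1 = 0.05, T2 = 0.5)
  p2 <- theory_params(rate = 2, amp_second_moment = 1, T1 = 0.05, T2 = 0.5)
  p3 <- theory_params(rate = 1, amp_second_moment = 3, T1 = 0.05, T2 = 0.5)
  f <- c(0, 0.1, 1, 7, 50)
  expect_equal(closed_form_amps(f, p2), 2 * closed_form_amps(f, p1))
  expect_equal(closed_form_amps(f, p3), 3 * closed_form_amps(f, p1))
  expect_equal(amps_low_limit(p2), 2 * amps_low_limit(p1))
  expect_equal(amps_high_asymptote(5, p2), 2 * amps_high_asymptote(5, p1))
})

test_that("the closed form is nonnegative and continuous everywhere", {
  p <- theory_params(rate = 1.5, amp_second_moment = 2, T1 = 0.02,
                     T2 = 0.9)
  f <- c(0, 10^seq(-4, 3, length.out = 2000))
  s <- closed_form_amps(f, p)
  expect_true(all(s >= 0))
  expect_true(all(is.finite(s)))
})

test_that("a fixed duration collapses to the single-pulse form", {
  p <- theory_params(rate = 2, amp_second_moment = 1, T1 = 0.3, T2 = 0.3)
  f <- c(0, 0.5, 2, 10 / 3)
  expect_equal(closed_form_amps(f, p),
               2 * single_pulse_spectrum(f, 1, 0.3), tolerance = 1e-12)
})

test_that("the empirical-duration expectation matches the uniform form", {
  set.seed(8)
  d <- runif(1e5, 0.05, 0.5)
  pu <- theory_params(rate = 1, amp_second_moment = 1, T1 = 0.05, T2 = 0.5)
  pe <- theory_params(rate = 1, amp_second_moment = 1, durations = d)
  f <- c(0, 10^seq(-1, 2, length.out = 60))
  db_diff <- 10 * log10(closed_form_amps(f, pe) / closed_form_amps(f, pu))
  expect_lt(sqrt(mean(db_diff^2)), 0.2)
})

test_that("the cutoff approximation follows the duration second moment", {
  expect_equal(cutoff_approx(1, 0), 1 / pi, tolerance = 1e-12)
  # speech-like duration moments
  expect_equal(cutoff_approx(0.22, 0.27), 0.914, tolerance = 0.001)
  # strictly decreasing in both arguments
  mu <- seq(0.05, 1, length.out = 20)
  expect_true(all(diff(cutoff_approx(mu, 0.1)) < 0))
  sdd <- seq(0, 0.5, length.out = 20)
  expect_true(all(diff(cutoff_approx(0.3, sdd)) < 0))
})

test_that("the approximate cutoff tracks the numeric half-power solution", {
  # the bracket-term bound guarantees |f_a/f_n - 1| <= sqrt(1 + b) - 1
  # with b = 1/(2 pi f_n (T2 - T1)); the error shrinks as the validity
  # condition f_c > 1/(2 pi (T2 - T1)) is met by a wider margin, reaching
  # 10% when T1 is small relative to T2
  cases <- list(c(0, 0.55), c(0.02, 1.5), c(0.05, 0.5), c(0.1, 0.9),
                c(0.2, 1.5))
  err <- margin <- numeric(length(cases))
  for (i in seq_along(cases)) {
    T1 <- cases[[i]][1]; T2 <- cases[[i]][2]
    p <- theory_params(rate = 1, amp_second_moment = 1, T1 = T1, T2 = T2)
    mu <- (T1 + T2) / 2; sdd <- (T2 - T1) / sqrt(12)
    fa <- cutoff_approx(mu, sdd)
    fn <- cutoff_numeric(p)
    expect_gt(fa, 1 / (2 * pi * (T2 - T1)))  # validity condition holds
    # the numeric solution really is the half-power point
    expect_equal(closed_form_amps(fn, p), amps_low_limit(p) / 2,
                 tolerance = 1e-6)
    err[i] <- abs(fa - fn) / fn
    margin[i] <- 2 * pi * fn * (T2 - T1)
    expect_lt(err[i], sqrt(1 + 1 / margin[i]) - 1 + 1e-9)  # derived bound
  }
  # strongest-margin cases achieve 10% accuracy
  expect_lt(err[1], 0.1)
  expect_lt(err[2], 0.1)
  # accuracy improves monotonically with the validity margin
  expect_true(all(diff(err[order(margin, decreasing = TRUE)]) >= 0))
})

test_that("an out-of-bracket cutoff reports a bracket failure", {
  p <- theory_params(rate = 1, amp_second_moment = 1,
                     durations = c(1e-5, 2e-5))
  expect_error(cutoff_numeric(p), "bracket")
})

test_that("fit summaries tidy into one-row tables", {
  f <- seq(0, 300, by = 0.05)
  s <- vocamps:::new_amps_spectrum(f, 2 / (f^2 + 9), rate = 600,
                                   nfft = 12000)
  lf <- fit_lowpass(s)
  expect_equal(glance(lf)$cutoff, 3, tolerance = 0.01)
  expect_equal(nrow(tidy(lf)), 2)
  sf <- fit_scaling_exponent(s, c(30, 300))
  expect_equal(nrow(tidy(sf)), 1)
  expect_lt(abs(glance(sf)$exponent - 2), 0.05)
})
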
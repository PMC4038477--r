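test_that("noiseless damped cosine is recovered to 1e-3 (strong-oscillator regime)", {
  # parameter values in the range reported for U2OS reporter rhythms
  t <- seq(0, 144, by = 1 / 6)
  tau <- 24.2; A <- 0.78; phi <- 16.6; lam <- 0.005
  y <- 1 + A * exp(-lam * t) * cos(2 * pi * (t - phi) / tau)
  fit <- fit_damped_cosine(lumi_trace(t, y, detrended = TRUE))
  expect_true(fit$converged)
  expect_lt(abs(fit$tau_h - tau), 1e-3)
  expect_lt(abs(fit$amplitude - A), 1e-3)
  expect_lt(abs(fit$phase_h - phi), 1e-2)
  expect_lt(abs(fit$damping_per_h - lam), 1e-4)
  expect_gt(fit$r2, 0.999)
})

test_that("noiseless recovery holds across the circadian period range", {
  t <- seq(0, 144, by = 1 / 6)
  for (tau in c(20, 22, 24, 26, 28)) {
    y <- 1 + 0.4 * exp(-0.01 * t) * cos(2 * pi * (t - 8) / tau)
    fit <- fit_damped_cosine(lumi_trace(t, y, detrended = TRUE))
    expect_lt(abs(fit$tau_h - tau) / tau, 1e-3)
    expect_lt(abs(fit$amplitude - 0.4) / 0.4, 1e-3)
    expect_lt(abs(fit$damping_per_h - 0.01), 1e-4)
    expect_true(fit$phase_h >= 0 && fit$phase_h < fit$tau_h)
  }
})

test_that("flat trace fits with near-zero amplitude and is classified weak", {
  t <- seq(0, 96, by = 0.5)
  fit <- fit_damped_cosine(lumi_trace(t, rep(1, length(t)),
                                      detrended = TRUE))
  expect_true(fit$converged)
  expect_lt(fit$amplitude, 1e-8)
  expect_equal(classify_oscillator(fit)$label, "weak")
})

test_that("period recovery under noise: median error within 0.2 h over 20 seeds", {
  errs <- vapply(1:20, function(s) {
    tr <- gen_luminescence(tau_h = 22, amplitude = 0.4, phase_h = 10,
                           damping_per_h = 0.005, baseline_decay = 0,
                           baseline = 1, noise_sd = 0.05,
                           duration_h = 144, sampling_per_h = 6, seed = s)
    fit <- fit_damped_cosine(lumi_trace(tr$time_h, tr$value,
                                        detrended = TRUE))
    abs(fit$tau_h - 22)
  }, 0.0)
  expect_lte(median(errs), 0.2)
})

test_that("fit requires 48 h of record and a detrended flag", {
  t <- seq(0, 40, 0.5)
  tr <- lumi_trace(t, 1 + 0.3 * cos(2 * pi * t / 24), detrended = TRUE)
  expect_error(fit_damped_cosine(tr), "48 h")
  t2 <- seq(0, 96, 0.5)
  raw <- lumi_trace(t2, 1 + 0.3 * cos(2 * pi * t2 / 24))
  expect_error(fit_damped_cosine(raw), "allow_raw")
  expect_true(fit_damped_cosine(raw, allow_raw = TRUE)$converged)
})

test_that("oscillator classification follows amplitude, band and fit quality", {
  mk <- function(tau, A, r2) structure(
    list(tau_h = tau, amplitude = A, phase_h = 1, damping_per_h = 0,
         mesor = 1, r2 = r2, converged = TRUE), class = "rhythm_fit")
  expect_equal(classify_oscillator(mk(22.0, 0.41, 0.9))$label, "strong")
  expect_equal(classify_oscillator(mk(24.0, 0.10, 0.9))$label, "weak")
  expect_equal(classify_oscillator(mk(40.0, 0.50, 0.9))$label, "weak")
  expect_equal(classify_oscillator(mk(24.0, 0.50, 0.2))$label, "weak")
  bad <- structure(list(converged = FALSE), class = "rhythm_fit")
  expect_equal(classify_oscillator(bad)$reason, "no fit")
})

test_that("classification is monotone in amplitude", {
  mk <- function(A) structure(
    list(tau_h = 23, amplitude = A, phase_h = 1, damping_per_h = 0,
         mesor = 1, r2 = 0.8, converged = TRUE), class = "rhythm_fit")
  labels <- vapply(seq(0.05, 0.9, by = 0.05),
                   function(A) classify_oscillator(mk(A))$label, "")
  # once strong, never flips back to weak as amplitude rises
  first_strong <- match("strong", labels)
  expect_false(is.na(first_strong))
  expect_true(all(labels[first_strong:length(labels)] == "strong"))
})
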
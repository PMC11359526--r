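test_that("Butterworth designs match the reference coefficients", {
  # frozen from scipy.signal.butter(4, 1, fs=4) and butter(1, 0.05, fs=4, 'high')
  lp <- butter_design(4, 1, 4, "low")
  expect_equal(lp$b, c(0.09398085, 0.37592341, 0.56388511, 0.37592341,
                       0.09398085), tolerance = 1e-7)
  expect_equal(lp$a, c(1, 0, 0.48602882, 0, 0.01766480), tolerance = 1e-7)
  hp <- butter_design(1, 0.05, 4, "high")
  expect_equal(hp$b, c(0.96219525, -0.96219525), tolerance = 1e-7)
  expect_equal(hp$a, c(1, -0.92439049), tolerance = 1e-7)
  expect_error(butter_design(4, 2, 4, "low"), "Nyquist")
})

test_that("low-pass denoising passes DC, kills high frequency, reduces noise power", {
  x_const <- rep(3.2, 400)
  expect_lt(max(abs(lowpass_denoise(x_const, 4) - 3.2)), 1e-9)
  t <- (0:1599) / 4
  x_hi <- sin(2 * pi * 1.9 * t)
  y <- lowpass_denoise(x_hi, 4)
  mid <- 200:1400
  expect_lt(max(abs(y[mid])), 0.25)  # designed |H(1.9 Hz)|^2 is tiny
  set.seed(1)
  x_n <- rnorm(2000)
  expect_lt(var(lowpass_denoise(x_n, 4)), var(x_n))
})

test_that("phasic high-pass removes tonic level and drift, keeps the SCR", {
  expect_lt(max(abs(highpass_phasic(rep(5, 1000), 4))), 1e-6)
  # 20-min linear ramp: response bounded far below the ramp range
  ramp <- seq(0, 2, length.out = 4800)
  y <- highpass_phasic(ramp, 4)
  expect_lt(max(abs(y[500:4300])), 0.05 * diff(range(ramp)))
  # tonic + SCR: peak matches the kernel fed through the same filter
  # (linearity oracle), tonic offset removed
  k <- gen_scr_kernel(1.5, 2.5, 6, 1, 4)
  x <- rep(5, 1200)
  x[400:(399 + length(k))] <- x[400:(399 + length(k))] + k
  yp <- highpass_phasic(x, 4)
  k_only <- highpass_phasic(c(rep(0, 200), k, rep(0, 200)), 4)
  expect_lt(abs(max(yp) - max(k_only)) / max(k_only), 0.2)
  expect_lt(abs(mean(yp[1:300])), 0.05)
  expect_error(highpass_phasic(c(1, 2, 3), 4), "too short")
})

test_that("skin-temperature filter rejects DC and responds to steps", {
  expect_lt(max(abs(filter_st(rep(33, 800), 4))), 1e-6)
  x <- c(rep(33, 400), rep(33.5, 400))
  y <- filter_st(x, 4)
  expect_gt(max(y[390:440]), 0.1)   # transient has the sign of the step
  expect_identical(filter_st(x, 4), filter_st(x, 4))
})

test_that("downsampling decimates with anti-aliasing", {
  expect_length(downsample(rnorm(64), 4, 1), 16)
  x <- rnorm(100)
  expect_identical(downsample(x, 4, 4), x)
  y <- downsample(rep(2.5, 400), 4, 1)
  expect_length(y, 100)
  expect_lt(max(abs(y - 2.5)), 1e-9)
  expect_error(downsample(rnorm(100), 4, 3), "integer multiple")
})

test_that("standardization: population sd, degenerate guard, idempotence", {
  z <- standardize(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_lt(abs(mean(z)), 1e-8)
  expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-6)
  expect_warning(zc <- standardize(rep(7, 10)), "constant")
  expect_identical(zc, numeric(10))
  set.seed(2)
  x <- rnorm(50, 3, 5)
  expect_equal(standardize(standardize(x)), standardize(x), tolerance = 1e-12)
  expect_error(standardize(1), "at least 2")
})

test_that("windowing counts, shapes and labels follow the sliding-window rule", {
  co <- fx_cohort()
  fr <- preprocess_recording(co$recordings[[1]])
  expect_equal(fr$sampling_rate, 1)
  n <- length(fr$phasic_eda)
  wd1 <- make_windows(fr, stride_s = 1)
  expect_identical(dim(wd1$windows), c(n - 16L + 1L, 16L, 2L))
  wd16 <- make_windows(fr, stride_s = 16)
  expect_identical(dim(wd16$windows)[1], n %/% 16L)
  # labeling rule
  proto <- structure(list(session_duration = 300, stressor_times = 100,
                          n_stressors = 1, baseline_s = 60),
                     class = "stimulus_protocol")
  expect_identical(label_window(98, proto), 1L)
  expect_identical(label_window(106, proto), 1L)
  expect_identical(label_window(97, proto), 0L)
  expect_identical(label_window(107, proto), 0L)
  expect_identical(label_window(200, proto), 0L)
  # every positive window overlaps exactly one stressor's interval
  tt <- fr$protocol$stressor_times
  for (s in wd1$window_start_s[wd1$labels == 1]) {
    expect_identical(sum(s >= tt - 2 & s <= tt + 6), 1L)
  }
  short <- structure(list(subject_id = "x", sampling_rate = 1,
                          phasic_eda = rnorm(10), protocol = proto),
                     class = "filtered_recording")
  expect_error(make_windows(short), "shorter")
})

test_that("pre-standardization chain is linear and preserves alignment", {
  set.seed(3)
  x <- rnorm(1200) + 2
  chain <- function(u) downsample(highpass_phasic(lowpass_denoise(u, 4), 4), 4, 1)
  expect_equal(chain(3 * x), 3 * chain(x), tolerance = 1e-9)
  # noiseless easy subject: stress windows carry the largest phasic values
  proto <- gen_protocol(1100, 10, rng_seed = 21)
  ph <- phenotype(responder_prob = 1, spurious_rate = 0, noise_sd = 0,
                  tonic_drift = 0)
  rec <- gen_recording(proto, ph, rng_seed = 22)
  # the zero-noise ST channel is constant: the degenerate guard must fire
  expect_warning(fr <- preprocess_recording(rec), "constant signal")
  wd <- make_windows(fr, stride_s = 1)
  mx <- apply(wd$windows[, , 1], 1, max)
  tt <- proto$stressor_times
  # negative windows adjacent to the labeling boundary (start just outside
  # [t-2, t+6]) still overlap the response, so the separation claim is made
  # against negatives clear of any stressor's response support [t, t+16]
  clear <- wd$labels == 0 &
    !vapply(wd$window_start_s, function(s)
      any(s + 16 >= tt & s <= tt + 16), logical(1))
  expect_gt(min(mx[wd$labels == 1]), max(mx[clear]))
})
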
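test_that("gen_protocol places stressors with bounded uniform gaps", {
  p <- gen_protocol(1200, 10, rng_seed = 1)
  expect_s3_class(p, "stimulus_protocol")
  expect_length(p$stressor_times, 10)
  expect_true(all(diff(p$stressor_times) >= 52 & diff(p$stressor_times) <= 125))
  expect_true(all(p$stressor_times >= p$baseline_s &
                  p$stressor_times <= p$session_duration))
  expect_identical(p$stressor_times, gen_protocol(1200, 10, rng_seed = 1)$stressor_times)
  expect_false(identical(p$stressor_times, gen_protocol(1200, 10, rng_seed = 2)$stressor_times))
  # degenerate single-stressor protocol
  p1 <- gen_protocol(NULL, 1, rng_seed = 3)
  expect_length(p1$stressor_times, 1)
  expect_gte(p1$stressor_times, p1$baseline_s)
  # infeasible duration errors and names the minimum
  expect_error(gen_protocol(100, 10, rng_seed = 1), "at least")
})

test_that("empirical mean gap converges to the uniform midpoint 88.5", {
  gaps <- unlist(lapply(1:2000, function(s)
    diff(gen_protocol(NULL, 10, rng_seed = s)$stressor_times)))
  expect_lt(abs(mean(gaps) - 88.5), 2)
})

test_that("SCR kernel has the latency/rise/recovery structure", {
  k <- gen_scr_kernel(latency = 1, rise = 3, recovery = 6, amplitude = 1,
                      sampling_rate = 4)
  # zero before latency, peak exactly at (latency + rise) * rate
  expect_true(all(k[1:4] == 0))
  expect_identical(which.max(k), as.integer(round((1 + 3) * 4)) + 1L)  # 0-based index 16
  expect_lt(abs(max(k) - 1), 1e-9)
  # monotone rise to the peak, monotone decay after it
  expect_true(all(diff(k[5:17]) > 0))
  expect_true(all(diff(k[17:length(k)]) < 0))
  # amplitude normalization holds for other parameter draws
  for (amp in c(0.25, 2)) {
    k2 <- gen_scr_kernel(2, 2, 5, amp, 4)
    expect_lt(abs(max(k2) - amp), 1e-9)
  }
  expect_identical(gen_scr_kernel(1, 3, 6, 0, 4),
                   numeric(length(gen_scr_kernel(1, 3, 6, 0, 4))))
  expect_error(gen_scr_kernel(1, 3, 6, -1, 4), "non-negative")
  expect_error(gen_scr_kernel(1, 7, 6, 1, 4), "smaller than recovery")
})

test_that("noiseless full-responder recording has exactly one EDA peak per stressor", {
  proto <- gen_protocol(1100, 10, rng_seed = 4)
  ph <- phenotype(responder_prob = 1, spurious_rate = 0, noise_sd = 0,
                  tonic_drift = 0)
  rec <- gen_recording(proto, ph, rng_seed = 5)
  x <- rec$eda
  n <- length(x)
  peaks <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1
  peaks <- peaks[x[peaks] > ph$tonic_level + 0.1]
  expect_identical(length(peaks), 10L)
  # each peak sits latency + rise after its stressor
  peak_t <- (peaks - 1) / rec$sampling_rate
  expect_true(all(abs(sort(peak_t) -
                      (proto$stressor_times + ph$scr_latency + ph$scr_rise)) < 0.5))
})

test_that("responder probability and spurious rate follow their distributions", {
  proto <- gen_protocol(NULL, 10, rng_seed = 6)
  ph <- phenotype(responder_prob = 0.4, spurious_rate = 0, noise_sd = 0)
  responded <- vapply(1:200, function(s)
    sum(gen_recording(proto, ph, rng_seed = s)$responded), 0)
  expect_lt(abs(mean(responded) - 4), 0.4)  # Binomial(10, 0.4) mean

  proto20 <- gen_protocol(duration = 1200, n_stressors = 10, rng_seed = 7)
  ph2 <- phenotype(spurious_rate = 1, noise_sd = 0)
  n_sp <- vapply(1:400, function(s)
    length(gen_recording(proto20, ph2, rng_seed = s)$spurious_times), 0)
  expect_lt(abs(mean(n_sp) - 20), 1)  # Poisson(1/min * 20 min)
})

test_that("cohort generation matches the study design and is reproducible", {
  co <- fx_cohort()
  expect_length(co$recordings, 6)
  co28 <- gen_cohort(28, cohort_preset("default"), rng_seed = 9)
  durs <- vapply(co28$recordings, function(r) r$protocol$session_duration, 0)
  expect_length(co28$recordings, 28)
  expect_true(all(durs >= 15 * 60 & durs <= 22 * 60))
  expect_true(all(vapply(co28$recordings, function(r)
    length(r$eda) == round(r$protocol$session_duration * 4), logical(1))))
  # point ranges pin the phenotype exactly
  rg <- phenotype_ranges(scr_amplitude = c(0.5, 0.5), noise_sd = c(0.02, 0.02))
  co1 <- gen_cohort(1, rg, rng_seed = 10)
  expect_equal(co1$manifest$scr_amplitude, 0.5)
  expect_equal(co1$manifest$noise_sd, 0.02)
  # same seed -> identical serialized cohorts
  coA <- gen_cohort(3, rng_seed = 11); coB <- gen_cohort(3, rng_seed = 11)
  fA <- tempfile(); fB <- tempfile()
  write_recording_csv(coA$recordings[[2]], fA)
  write_recording_csv(coB$recordings[[2]], fB)
  expect_identical(readLines(fA), readLines(fB))
  expect_identical(coA$manifest, coB$manifest)
  expect_error(gen_cohort(2, ranges = list()), "empty")
})

test_that("label stream and stressor times are mutually recoverable", {
  proto <- gen_protocol(1000, 8, rng_seed = 12)
  lab <- labels_from_protocol(proto)
  expect_identical(sum(lab), 8L)
  expect_identical(stressors_from_labels(lab), floor(proto$stressor_times))
})

test_that("recording and protocol serialization round-trips", {
  co <- fx_cohort()
  rec <- co$recordings[[1]]
  f_csv <- tempfile(fileext = ".csv"); f_json <- tempfile(fileext = ".json")
  write_recording_csv(rec, f_csv)
  write_protocol_json(rec$protocol, f_json, subject_id = rec$subject_id)
  back <- read_recording_csv(f_csv, f_json)
  expect_equal(back$eda, rec$eda, tolerance = 1e-8)
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_equal(back$protocol$stressor_times, rec$protocol$stressor_times,
               tolerance = 1e-8)
})
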
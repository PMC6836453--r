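# steady-state amplitude of a sinusoid estimated over whole periods
sine_amplitude <- function(y, idx) sqrt(2 * mean(y[idx]^2))

test_that("band-pass filter matches its own designed frequency response", {
  fs <- 1000
  flt <- butter_bandpass(4, 35, 450, fs)
  t <- (0:9999) / fs
  mid <- 4001:8000  # steady-state region, away from edges

  # DC is rejected essentially completely
  dc <- emg_recording(matrix(1, 1, length(t), dimnames = list("m1", NULL)), fs = fs)
  expect_lt(max(abs(bandpass_filter(dc)$samples[1, mid])), 1e-6)

  # in-band 100 Hz tone: amplitude equals |H|^2 (forward-backward) within 1%
  x <- matrix(sin(2 * pi * 100 * t), 1, dimnames = list("m1", NULL))
  y <- bandpass_filter(emg_recording(x, fs = fs))$samples[1, ]
  expect_equal(sine_amplitude(y, mid), Mod(freq_response(flt, 100))^2,
               tolerance = 0.01)

  # out-of-band 5 Hz tone: attenuated to at most the designed response + 1%
  x5 <- matrix(sin(2 * pi * 5 * t), 1, dimnames = list("m1", NULL))
  y5 <- bandpass_filter(emg_recording(x5, fs = fs))$samples[1, ]
  expect_lt(sine_amplitude(y5, mid), Mod(freq_response(flt, 5))^2 + 0.01)

  # Nyquist violation is reported as such
  expect_error(bandpass_filter(emg_recording(x, fs = 800)), "Nyquist")
})

test_that("fixed RMS envelope equals the brute-force sliding window", {
  fs <- 1000
  set.seed(5)
  n <- 2000
  # square-wave amplitude modulated noise
  amp <- rep(c(0.2, 1), each = 250, length.out = n)
  x <- amp * rnorm(n)
  rec <- emg_recording(matrix(x, 1, dimnames = list("m1", NULL)), fs = fs)
  env <- compute_envelope(rec, "fixed_rms", window_ms = 100)$samples[1, ]

  w <- 100; half <- floor(w / 2)
  oracle <- vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    sqrt(mean(x[idx]^2))
  }, numeric(1))
  expect_equal(env, oracle, tolerance = 1e-12, ignore_attr = TRUE)

  # all-zero input -> all-zero envelope
  z <- emg_recording(matrix(0, 1, 500, dimnames = list("m1", NULL)), fs = fs)
  expect_equal(max(compute_envelope(z)$samples), 0)

  # stationary carrier of RMS a -> envelope ~ a away from edges
  xc <- rnorm(5000)
  a <- 0.7
  recc <- emg_recording(matrix(a * xc / sqrt(mean(xc^2)), 1,
                               dimnames = list("m1", NULL)), fs = fs)
  for (method in c("fixed_rms", "adaptive_rms")) {
    ec <- compute_envelope(recc, method)$samples[1, 500:4500]
    expect_equal(mean(ec), a, tolerance = 0.05)
    expect_true(all(ec >= 0))
  }

  expect_error(compute_envelope(z, window_ms = 2000), "longer than the signal")
})

test_that("parse_phases implements the half-open sub-phase definitions", {
  ev <- gait_events(data.frame(stride_id = 1, HS_ref = 0, TO_contra = 0.12,
                               HS_contra = 0.50, TO_ref = 0.62,
                               HS_ref_next = 1.00))
  ph <- parse_phases(ev)
  expect_equal(as.character(ph$phase), c("DS1", "Stance", "DS2", "Swing"))
  expect_equal(ph$start, c(0, 0.12, 0.50, 0.62))
  expect_equal(ph$end, c(0.12, 0.50, 0.62, 1.00))
  # contiguity: phase durations sum to the stride duration exactly
  expect_equal(sum(ph$end - ph$start), 1.00)

  expect_error(gait_events(data.frame(stride_id = 7, HS_ref = 0.2,
                                      TO_contra = 0.1, HS_contra = 0.5,
                                      TO_ref = 0.6, HS_ref_next = 1)),
               "stride 7")
})

test_that("synthetic events round-trip through parse_phases exactly", {
  co <- tiny_cohort(n_subjects = 1, strides = 3, seed = 12)
  s <- co$subjects[[1]]
  ph <- parse_phases(s$events)
  # every boundary is an integer number of samples by construction
  expect_equal(round(ph$start * 1000), ph$start * 1000, tolerance = 1e-12)
  expect_equal(ph$start[ph$phase == "DS1"], s$events$HS_ref)
  expect_equal(ph$end[ph$phase == "Swing"], s$events$HS_ref_next)
})

test_that("amplitude normalization divides by the median per-stride peak", {
  mk_env <- function(peaks) {
    # 1 muscle, strides of 10 samples with a single peak each
    blocks <- lapply(peaks, function(p) {
      v <- rep(p / 2, 10); v[5] <- p; matrix(v, 1)
    })
    rec <- emg_recording(do.call(cbind, blocks),
                         muscle_labels = "m1", fs = 10)
    ev <- gait_events(data.frame(stride_id = seq_along(peaks),
                                 HS_ref = (seq_along(peaks) - 1),
                                 TO_contra = (seq_along(peaks) - 1) + 0.2,
                                 HS_contra = (seq_along(peaks) - 1) + 0.5,
                                 TO_ref = (seq_along(peaks) - 1) + 0.7,
                                 HS_ref_next = seq_along(peaks)))
    segment_strides(rec, ev)
  }
  n3 <- normalize_amplitude(mk_env(c(2, 4, 6)))
  expect_equal(unname(attr(n3, "divisors")), 4)
  expect_equal(max(n3$values), 6 / 4)

  n1 <- normalize_amplitude(mk_env(5))
  expect_equal(max(n1$values), 1.0)

  # even stride count: median is the mean of the two central peaks
  n4 <- normalize_amplitude(mk_env(c(1, 2, 3, 10)))
  expect_equal(unname(attr(n4, "divisors")), 2.5)

  # idempotence: renormalizing changes nothing (second divisor is 1)
  n3b <- normalize_amplitude(n3)
  expect_equal(unname(attr(n3b, "divisors")), 1, tolerance = 1e-12)
  expect_equal(n3b$values, n3$values, tolerance = 1e-12)

  # an all-zero muscle is reported by name
  co <- tiny_cohort(n_subjects = 1, strides = 2, seed = 4)
  s <- co$subjects[[1]]
  rec <- s$recording
  rec$samples["TA", ] <- 0
  expect_error(normalize_amplitude(segment_strides(rec, s$events)), "TA")
})

test_that("time normalization emits 200 samples and preserves linear structure", {
  co <- tiny_cohort(n_subjects = 1, strides = 2, seed = 6)
  s <- co$subjects[[1]]
  env <- segment_strides(s$recording, s$events)
  ph <- parse_phases(s$events)

  # constant input -> constant 200-sample output
  cst <- env
  cst$values[] <- 1
  np <- time_normalize(cst, ph)
  expect_equal(dim(np$mean), c(12, 200))
  expect_equal(unname(np$mean), matrix(1, 12, 200), tolerance = 1e-12)

  # linear ramp across the stride: resampled values match the closed form
  # (linear interpolation reproduces an affine signal exactly)
  ramp <- env
  for (idx in gaitsynergy:::stride_index_ranges(env)) {
    ramp$values[, idx] <- matrix(seq(0, 1, length.out = length(idx)),
                                 nrow = 12, ncol = length(idx), byrow = TRUE)
  }
  npr <- time_normalize(ramp, ph)
  sb <- s$events
  for (st in 1:2) {
    idx <- gaitsynergy:::stride_index_ranges(env)[[st]]
    len <- length(idx)
    bnd <- round((as.numeric(sb[st, c("HS_ref", "TO_contra", "HS_contra",
                                      "TO_ref", "HS_ref_next")]) -
                    sb$HS_ref[st]) * 1000)
    expected <- numeric(0)
    for (p in 1:4) {
      seg <- (bnd[p] + 1):bnd[p + 1]
      m <- c(20, 80, 20, 80)[p]
      grid <- seq(seg[1], seg[length(seg)], length.out = m)
      expected <- c(expected, (grid - 1) / (len - 1))
    }
    expect_equal(npr$profiles[1, , st], expected, tolerance = 1e-9)
  }

  # resampling cannot overshoot the per-phase range
  np2 <- time_normalize(env, ph)
  blocks <- gaitsynergy:::phase_blocks()
  for (st in 1:2) {
    idx <- gaitsynergy:::stride_index_ranges(env)[[st]]
    for (p in 1:4) {
      got <- np2$profiles[3, blocks[[p]], st]
      expect_gte(min(got), min(env$values[3, idx]) - 1e-12)
      expect_lte(max(got), max(env$values[3, idx]) + 1e-12)
    }
  }
})
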
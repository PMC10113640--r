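# Independent oracle for the digital band-pass response: first-order analog
# Butterworth band-pass prototype mapped through the (prewarped) bilinear
# transform; |H| evaluated at the warped analog frequency. The filtfilt
# (zero-phase) gain is |H|^2.
analytic_bp_gain <- function(f, fs, low = 250, high = 3000) {
  wl <- 2 * fs * tan(pi * low / fs)
  wh <- 2 * fs * tan(pi * high / fs)
  b <- wh - wl
  w0sq <- wl * wh
  w <- 2 * fs * tan(pi * f / fs)
  h <- (1i * w * b) / ((1i * w)^2 + 1i * w * b + w0sq)
  Mod(h)^2
}

test_that("band-pass filter matches the analytic Butterworth response", {
  fs <- 24414
  t <- seq(0, 1, by = 1 / fs)
  measure <- function(f) {
    y <- bandpass_filter(sin(2 * pi * f * t), fs)
    mid <- y[round(length(y) * 0.25):round(length(y) * 0.75)]
    (max(mid) - min(mid)) / 2
  }
  expect_equal(measure(1000), analytic_bp_gain(1000, fs), tolerance = 0.01)
  ratio <- measure(10000) / measure(1000)
  expect_equal(ratio, analytic_bp_gain(10000, fs) / analytic_bp_gain(1000, fs),
               tolerance = 0.02)
  # DC is rejected
  dc <- bandpass_filter(rep(1, fs), fs)
  expect_lt(max(abs(dc[1000:(fs - 1000)])), 1e-6)
  expect_error(bandpass_filter(t, fs, low = 0), "cutoffs")
  expect_error(bandpass_filter(t, fs, high = 13000), "cutoffs")
})

test_that("robust noise estimator matches its definition and is equivariant", {
  expect_equal(estimate_noise(rep(0, 100)), 0)
  expect_equal(estimate_noise(rep(c(-0.675, 0.675), 50)), 1)
  set.seed(42)
  x <- rnorm(1e5)
  s <- estimate_noise(x)
  expect_equal(s, 1, tolerance = 0.02)
  # scale equivariance: sigma(c x) = |c| sigma(x)
  expect_equal(estimate_noise(-3.7 * x), 3.7 * s, tolerance = 1e-12)
  expect_error(estimate_noise(numeric(0)), "valid samples")
  expect_error(estimate_noise(x, valid = rep(FALSE, length(x))),
               "valid samples")
})

test_that("artifact invalidation masks only simultaneous transients", {
  fs <- 24414
  n <- fs %/% 4
  set.seed(7)
  traces <- matrix(rnorm(n * 8), n, 8)
  # large transient on one channel only: its window is not masked
  # (not simultaneous across channels)
  t1 <- traces
  t1[5000, 1] <- 50
  v1 <- invalidate_artifacts(t1, fs)
  expect_true(all(v1[4990:5020]))
  # synchronous near-peak transient on all channels: window masked
  t2 <- traces
  t2[5000:5010, ] <- 40
  for (ch in 1:8) t2[600 + 70 * ch, ch] <- 42 # isolated per-channel peaks
  v <- invalidate_artifacts(t2, fs)
  expect_false(all(v[5000:5010]))
  expect_true(mean(v) > 0.99)
  # recovered mask removes exactly the injected artifact windows
  win <- floor(fs / 1000)
  bad_windows <- unique((5000:5010 - 1) %/% win)
  masked_windows <- unique(((which(!v)) - 1) %/% win)
  expect_setequal(masked_windows, bad_windows)
  expect_error(invalidate_artifacts(t2, fs, window_ms = 0.01), "one sample")
})

test_that("threshold detection finds troughs and honours the dead time", {
  fs <- 24414
  set.seed(8)
  x <- rnorm(fs) * 2
  sig <- estimate_noise(x)
  # noise alone, nothing below 4 sigma
  x_capped <- pmax(x, -3.9 * sig)
  expect_length(detect_spikes(x_capped, sig, fs), 0)
  # single injected trough
  x2 <- rep(0, fs)
  x2[1000] <- -5
  expect_equal(detect_spikes(x2, 1, fs), 1000)
  # two troughs 0.5 ms apart merge to the larger one
  x3 <- rep(0, fs)
  x3[1000] <- -5
  x3[1000 + round(fs * 5e-4)] <- -7
  expect_equal(detect_spikes(x3, 1, fs), 1000 + round(fs * 5e-4))
  expect_error(detect_spikes(x2, 1, fs, k = 0), "positive")
})

test_that("every injected large spike is detected exactly once", {
  # 10 Hz Poisson train at peak-to-peak amplitude 8 sigma; each injected
  # trough must be matched by exactly one detection (isolated noise
  # crossings at 4 sigma are expected over long traces and are later
  # rejected by the spike-count acceptance rule, so they are not counted
  # against detection here)
  des <- tiny_design()
  amp <- profile_amplitude(amplitude_profile(), des$depths_um[1])
  clean <- vapply(1:20, function(seed) {
    ses <- simulate_session(des, rates_hz = c(10, rep(0, 15)),
                            duration_s = 2, noise_sigma_uv = amp / 8,
                            seed = seed)
    x <- bandpass_filter(ses$traces[, 1], des$fs)
    ev <- detect_spikes(x, estimate_noise(x), des$fs)
    tol <- round(des$fs * 5e-4)
    matches <- vapply(ses$truth$spike_index[[1]],
                      function(t) sum(abs(ev - t) <= tol), integer(1))
    all(matches == 1)
  }, logical(1))
  expect_gte(mean(clean), 0.99)
})

test_that("detection count is non-increasing in the threshold multiplier", {
  des <- tiny_design()
  ses <- simulate_session(des, rates_hz = 30, duration_s = 1,
                          noise_sigma_uv = 8, seed = 3)
  x <- bandpass_filter(ses$traces[, 5], des$fs)
  sig <- estimate_noise(x)
  counts <- vapply(c(3, 3.5, 4, 4.5, 5, 6),
                   function(k) length(detect_spikes(x, sig, des$fs, k = k)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("sorting separates distinct amplitude populations", {
  des <- tiny_design()
  tmpl <- spike_template(des$fs)
  set.seed(21)
  mk <- function(amp, n) {
    t(replicate(n, amp * tmpl$samples + rnorm(length(tmpl$samples), sd = 5)))
  }
  two <- rbind(mk(50 / abs(min(tmpl$samples)) * 0.7, 120),
               mk(150 / abs(min(tmpl$samples)) * 0.7, 120))
  truth <- rep(1:2, each = 120)
  srt <- sort_units(two)
  expect_equal(srt$k, 2)
  tab <- table(srt$labels, truth)
  acc <- sum(apply(tab, 2, max)) / length(truth)
  expect_gte(acc, 0.95)
  # single population selects k = 1
  one <- mk(100, 150)
  expect_equal(sort_units(one)$k, 1)
  # degenerate identical snippets collapse to one cluster
  same <- matrix(rep(tmpl$samples, 10), nrow = 10, byrow = TRUE)
  expect_equal(sort_units(same)$k, 1)
  expect_error(sort_units(one[1, , drop = FALSE]), "at least 2")
})

test_that("unit metrics implement the SNR definition", {
  snips <- matrix(c(-25, 25), nrow = 3, ncol = 2, byrow = TRUE)
  m <- unit_metrics(snips, sigma_n = 12.5)
  expect_equal(m$mean_amp_uv, 50)
  expect_equal(m$snr, 2)
  # one snippet: its own peak-to-peak
  m1 <- unit_metrics(matrix(c(-10, 30), 1), sigma_n = 5)
  expect_equal(m1$mean_amp_uv, 40)
  # mixed amplitudes average
  mix <- rbind(c(-20, 20), c(-30, 30))
  expect_equal(unit_metrics(mix, 10)$mean_amp_uv, 50)
  expect_error(unit_metrics(mix, 0), "positive")
  # SNR is invariant to uniform rescaling of signal and noise
  expect_equal(unit_metrics(7 * mix, 7 * 10)$snr, unit_metrics(mix, 10)$snr)
})

test_that("channels without accepted units are inactive with absent metrics", {
  des <- tiny_design()
  # ~60 spikes on channel 1, nothing elsewhere; 200-spike rule rejects all
  ses <- simulate_session(des, rates_hz = c(30, rep(0, 15)), duration_s = 2,
                          noise_sigma_uv = 4, seed = 6)
  p <- process_session(ses)
  sm <- summarize_session(p)
  expect_false(any(sm$active))
  expect_true(all(is.na(sm$mean_amp_uv)))
  expect_true(all(sm$n_units == 0))
  # with a scaled acceptance rule the spiking channel becomes active
  p2 <- process_session(ses, min_spikes = 40)
  sm2 <- summarize_session(p2)
  expect_true(sm2$active[1])
  expect_false(any(sm2$active[-1]))
  expect_equal(sum(active_site_counts(sm2)$cumulative_active), 1)
})

test_that("recordings round-trip through the binary + sidecar format", {
  des <- tiny_design()
  ses <- simulate_session(des, duration_s = 0.2, seed = 12)
  dir <- withr::local_tempdir()
  write_recording(ses, dir)
  back <- read_recording(dir)
  expect_equal(back$fs, ses$fs)
  expect_equal(back$depths_um, ses$depths_um)
  expect_equal(back$traces, ses$traces,
               tolerance = max(abs(ses$traces)) / 32000)
})
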
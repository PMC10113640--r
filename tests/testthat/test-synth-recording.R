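test_that("amplitude profile is continuous and piecewise linear", {
  prof <- amplitude_profile()
  peak <- prof$peak_depth_um
  eps <- 1e-6
  expect_equal(profile_amplitude(prof, peak - eps),
               profile_amplitude(prof, peak + eps), tolerance = 1e-6)
  # exact slopes on each side
  d1 <- c(0, 500, 1000)
  expect_equal(diff(profile_amplitude(prof, d1)) / diff(d1) * 1000,
               rep(prof$rising_slope_uv_mm, 2))
  d2 <- c(1100, 1300, 1500)
  expect_equal(diff(profile_amplitude(prof, d2)) / diff(d2) * 1000,
               rep(prof$falling_slope_uv_mm, 2))
  expect_error(profile_amplitude(prof, 1700), "domain")
})

test_that("zero rates give pure noise with empty ground truth", {
  ses <- simulate_session(tiny_design(), rates_hz = 0, duration_s = 0.2,
                          noise_sigma_uv = 3, seed = 5)
  expect_true(all(lengths(ses$truth$spike_index) == 0))
  expect_equal(sd(ses$traces[, 1]), 3, tolerance = 0.1)
})

test_that("a noiseless session is exactly the template train", {
  des <- tiny_design()
  ses <- simulate_session(des, rates_hz = c(20, rep(0, 15)),
                          noise_sigma_uv = 0, duration_s = 0.5, seed = 2)
  tmpl <- spike_template(des$fs)
  rebuilt <- numeric(nrow(ses$traces))
  for (i in ses$truth$spike_index[[1]]) {
    at <- (i - tmpl$trough_index + 1):(i - tmpl$trough_index + length(tmpl$samples))
    rebuilt[at] <- rebuilt[at] + ses$truth$amp_uv[1] * tmpl$samples
  }
  expect_equal(ses$traces[, 1], rebuilt)
  expect_true(all(ses$traces[, 2] == 0))
  # measured template amplitude equals the profile amplitude exactly
  sn <- extract_snippets(ses$traces[, 1], ses$truth$spike_index[[1]], des$fs)
  expect_equal(as.numeric(mean_waveform_amplitude(sn$snippets)),
               ses$truth$amp_uv[1], tolerance = 1e-10)
})

test_that("refractory period is respected and seeds reproduce exactly", {
  des <- tiny_design()
  s1 <- simulate_session(des, rates_hz = 80, duration_s = 1, seed = 11)
  s2 <- simulate_session(des, rates_hz = 80, duration_s = 1, seed = 11)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$truth, s2$truth)
  gaps <- unlist(lapply(s1$truth$spike_index, diff))
  expect_true(all(gaps >= des$fs * 1e-3 - 1))
})

test_that("ground-truth amplitudes recover the generator slopes exactly", {
  des <- tiny_design()
  ses <- simulate_session(des, seed = 1)
  tt <- tibble::tibble(depth_um = des$depths_um, amp = ses$truth$amp_uv)
  fit <- piecewise_depth_fit(tt, "amp", breakpoint_um = 1050)
  expect_equal(fit$slope_per_mm[fit$segment == "rising"], 13.9,
               tolerance = 1e-8)
  expect_equal(fit$slope_per_mm[fit$segment == "falling"], -31.6,
               tolerance = 1e-8)
})

test_that("study SNR schedule declines linearly at the requested rate", {
  des <- study_design(session_weeks = c(1, 8, 16))
  st <- simulate_study(des, decay_per_month = 0, duration_s = 0.02,
                       rates_hz = 0, seed = 3,
                       layer_survival_weeks = c("L1" = Inf, "L2/3" = Inf,
                                                "L4" = Inf, "L5" = Inf,
                                                "L6" = Inf))
  snr_by_week <- tapply(st$truth$true_snr, st$truth$week, mean)
  expect_equal(as.numeric(diff(snr_by_week)), c(0, 0))

  st2 <- simulate_study(des, decay_per_month = -0.34, snr0 = 2.7,
                        duration_s = 0.02, rates_hz = 0, seed = 3)
  final <- mean(st2$truth$true_snr[st2$truth$week == 16])
  expect_equal(final, 2.7 - 0.34 * (16 * 7 / 30.44), tolerance = 1e-10)
})

test_that("shorter L1 half-life yields more cumulative L5 activity", {
  des <- study_design()
  wins <- vapply(1:100, function(run) {
    st <- simulate_study(des, rates_hz = 0, duration_s = 0.02,
                         seed = 40000 + run)
    cnt <- tapply(st$truth$alive, st$truth$layer, sum)
    cnt[["L5"]] > cnt[["L1"]]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("study rejects degenerate inputs", {
  expect_error(simulate_study(study_design(session_weeks = numeric(0))),
               "empty")
  expect_error(simulate_study(study_design(),
                              layer_survival_weeks = c("L1" = 0, "L2/3" = 1,
                                                       "L4" = 1, "L5" = 1,
                                                       "L6" = 1)),
               "positive")
})
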
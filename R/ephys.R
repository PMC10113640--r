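#' Zero-phase Butterworth spike-band filter
#'
#' Applies a first-order Butterworth band-pass (default 250 Hz - 3 kHz)
#' forward and backward (zero phase), so detected trough times are not
#' biased by filter delay.
#'
#' @param x Numeric vector or samples-by-channels matrix of raw voltages, uV.
#' @param fs Sampling rate, Hz.
#' @param low,high Band edges, Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Butterworth order (default 1, i.e. one pole per band edge).
#' @return Filtered series with the same dimensions as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 250, high = 3000, order = 1) {
  if (!(low > 0 && high > low && high < fs / 2)) {
    stop("cutoffs must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  if (is.matrix(x)) {
    apply(x, 2, function(col) signal::filtfilt(bf, col))
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Robust noise level of a filtered trace
#'
#' The noise standard deviation is estimated as
#' `sigma_N = median(|signal|) / 0.675` over valid samples, which is
#' insensitive to the spikes riding on the noise.
#'
#' @param x Filtered voltage trace, uV.
#' @param valid Optional logical mask of samples to use (e.g. from
#'   [invalidate_artifacts()]).
#' @return `sigma_N` in uV.
#' @examples
#' estimate_noise(rnorm(1e4)) # ~1
#' @export
estimate_noise <- function(x, valid = NULL) {
  if (!is.null(valid)) x <- x[valid]
  if (length(x) == 0) stop("no valid samples to estimate noise from")
  median(abs(x)) / 0.675
}

#' Invalidate simultaneous high-amplitude artifacts
#'
#' Samples exceeding `frac` (default 90%) of a channel's session peak
#' amplitude on at least `min_channels` channels within the same time window
#' are treated as movement/stimulation artifacts, and the whole window is
#' masked on all channels.
#'
#' @param traces Samples-by-channels matrix of filtered voltages, uV.
#' @param fs Sampling rate, Hz.
#' @param frac Fraction of the per-channel peak that defines "high
#'   amplitude" (0 < frac < 1).
#' @param min_channels Minimum number of channels that must exceed their
#'   threshold simultaneously.
#' @param window_ms Width of the simultaneity window, ms; must be at least
#'   one sample.
#' @return Logical vector of length `nrow(traces)`: `TRUE` for valid
#'   samples (the mask applies to every channel).
#' @export
invalidate_artifacts <- function(traces, fs, frac = 0.9, min_channels = 2,
                                 window_ms = 1) {
  stopifnot(is.matrix(traces), frac > 0, frac < 1)
  win <- floor(window_ms / 1000 * fs)
  if (win < 1) stop("`window_ms` is shorter than one sample")
  n <- nrow(traces)
  peaks <- apply(abs(traces), 2, max)
  exceed <- sweep(abs(traces), 2, frac * peaks, `>`)
  window_id <- (seq_len(n) - 1L) %/% win
  hit <- rowsum(exceed + 0, window_id) > 0          # window x channel
  bad_windows <- rowSums(hit) >= min_channels
  !bad_windows[window_id + 1L]
}

#' Threshold detection of extracellular spikes
#'
#' Detects negative-going crossings of `-k * sigma_n` (extracellular spikes
#' are downward deflections) and returns the trough sample of each event.
#' Events closer than the dead time are merged, keeping the larger trough.
#'
#' @param x Filtered voltage trace, uV.
#' @param sigma_n Noise level of the same trace ([estimate_noise()]).
#' @param fs Sampling rate, Hz.
#' @param k Threshold multiplier (default 4).
#' @param dead_time_ms Minimum separation between events, ms.
#' @param valid Optional logical sample mask; events in masked regions are
#'   discarded.
#' @return Integer vector of trough sample indices.
#' @export
detect_spikes <- function(x, sigma_n, fs, k = 4, dead_time_ms = 1,
                          valid = NULL) {
  if (k <= 0) stop("`k` must be positive")
  thr <- -k * sigma_n
  below <- x < thr
  if (!is.null(valid)) below <- below & valid
  if (!any(below)) return(integer(0))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  troughs <- vapply(runs, function(i) {
    s <- starts[i]; e <- ends[i]
    s + which.min(x[s:e]) - 1L
  }, integer(1))
  dead <- dead_time_ms / 1000 * fs
  if (length(troughs) > 1) {
    keep <- rep(TRUE, length(troughs))
    last <- 1L
    for (i in seq_along(troughs)[-1]) {
      if (troughs[i] - troughs[last] < dead) {
        if (x[troughs[i]] < x[troughs[last]]) {
          keep[last] <- FALSE; last <- i
        } else {
          keep[i] <- FALSE
        }
      } else {
        last <- i
      }
    }
    troughs <- troughs[keep]
  }
  troughs
}

#' Extract trough-aligned spike snippets
#'
#' @param x Filtered voltage trace, uV.
#' @param events Trough sample indices from [detect_spikes()].
#' @param fs Sampling rate, Hz.
#' @param pre_ms,post_ms Window before and after the trough, ms.
#' @return List with `snippets` (events x samples matrix) and `events`
#'   (indices kept; events too close to the trace edges are dropped).
#' @export
extract_snippets <- function(x, events, fs, pre_ms = 0.6, post_ms = 1.0) {
  pre <- round(pre_ms / 1000 * fs)
  post <- round(post_ms / 1000 * fs)
  ok <- events - pre >= 1 & events + post <= length(x)
  events <- events[ok]
  snips <- matrix(0, nrow = length(events), ncol = pre + post + 1L)
  for (i in seq_along(events)) {
    snips[i, ] <- x[(events[i] - pre):(events[i] + post)]
  }
  list(snippets = snips, events = events, trough_col = pre + 1L)
}

#' Sort spike snippets into putative units
#'
#' Projects trough-aligned snippets onto their first principal components
#' and scans k-means solutions for `k = 1..k_max` (fixed seed, multiple
#' restarts). The cluster count is chosen by mean silhouette width; when the
#' best silhouette falls below `sil_threshold` the snippets are treated as a
#' single unit. Ties break toward smaller `k`.
#'
#' @param snippets Events x samples matrix of aligned waveforms.
#' @param k_max Largest cluster count to consider.
#' @param n_pcs Number of principal components used (2-3 typical).
#' @param restarts k-means restarts per `k`.
#' @param sil_threshold Minimum mean silhouette to accept `k >= 2`.
#' @param max_sil_n Silhouette is evaluated on at most this many snippets
#'   (seeded subsample) to bound the distance-matrix cost.
#' @param seed Seed controlling k-means restarts and subsampling.
#' @return List with `labels` (integer per snippet), `k`, and `silhouette`
#'   (tibble of `k`, `mean_silhouette`).
#' @export
sort_units <- function(snippets, k_max = 5, n_pcs = 3, restarts = 10,
                       sil_threshold = 0.5, max_sil_n = 2000, seed = 42) {
  stopifnot(is.matrix(snippets))
  n <- nrow(snippets)
  if (n < 2) stop("need at least 2 snippets to sort")
  if (all(apply(snippets, 2, function(col) diff(range(col))) == 0)) {
    return(list(labels = rep(1L, n), k = 1L,
                silhouette = tibble::tibble(k = 1L, mean_silhouette = NA_real_)))
  }
  ks <- if (min(k_max, n - 1) >= 2) seq(2, min(k_max, n - 1)) else integer(0)
  if (length(ks) == 0) {
    return(list(labels = rep(1L, n), k = 1L,
                silhouette = tibble::tibble(k = integer(),
                                            mean_silhouette = numeric())))
  }
  pcs <- prcomp(snippets, center = TRUE, scale. = FALSE)
  scores <- pcs$x[, seq_len(min(n_pcs, ncol(pcs$x))), drop = FALSE]
  withr::with_seed(seed, {
    sub <- if (n > max_sil_n) sample.int(n, max_sil_n) else seq_len(n)
    d_sub <- dist(scores[sub, , drop = FALSE])
    fits <- lapply(ks, function(k) {
      tryCatch(
        suppressWarnings(kmeans(scores, centers = k, nstart = restarts,
                                iter.max = 50)),
        error = function(e) NULL # fewer distinct points than centers
      )
    })
  })
  sil <- vapply(seq_along(ks), function(i) {
    if (is.null(fits[[i]])) return(-Inf)
    cl <- fits[[i]]$cluster[sub]
    if (length(unique(cl)) < 2) return(-1)
    mean(cluster::silhouette(cl, d_sub)[, "sil_width"])
  }, numeric(1))
  sil_tbl <- tibble::tibble(k = as.integer(ks), mean_silhouette = sil)
  if (length(ks) == 0 || max(sil) < sil_threshold) {
    return(list(labels = rep(1L, n), k = 1L, silhouette = sil_tbl))
  }
  best <- which.max(sil) # first max: ties toward smaller k
  list(labels = as.integer(fits[[best]]$cluster), k = as.integer(ks[best]),
       silhouette = sil_tbl)
}

#' Amplitude and SNR of a sorted unit
#'
#' The unit amplitude `mu_pp` is the mean over spikes of each snippet's
#' peak-to-peak excursion (max - min); the signal-to-noise ratio is
#' `mu_pp / (2 * sigma_n)`.
#'
#' @param snippets Events x samples matrix of the unit's waveforms.
#' @param sigma_n Channel noise level, uV; must be positive (an SNR at zero
#'   noise is undefined).
#' @return Tibble with `n_spikes`, `mean_amp_uv`, `snr`.
#' @examples
#' snips <- matrix(c(-25, 25), nrow = 3, ncol = 2, byrow = TRUE)
#' unit_metrics(snips, sigma_n = 12.5) # mu_pp = 50, SNR = 2
#' @export
unit_metrics <- function(snippets, sigma_n) {
  stopifnot(is.matrix(snippets), nrow(snippets) >= 1)
  if (sigma_n <= 0) stop("`sigma_n` must be positive; SNR is undefined at 0")
  pp <- apply(snippets, 1, max) - apply(snippets, 1, min)
  mu_pp <- mean(pp)
  tibble::tibble(n_spikes = nrow(snippets), mean_amp_uv = mu_pp,
                 snr = mu_pp / (2 * sigma_n))
}

#' Peak-to-peak amplitude of a unit's average waveform
#'
#' Noise cancels in the spike-triggered average, so this estimator is free
#' of the extreme-value inflation that per-spike peak-to-peak excursions
#' suffer at low SNR (which inflates small spikes more than large ones and
#' flattens amplitude-depth gradients). Aligning each snippet at its own
#' noisy minimum leaves a residual inflation, so snippets are first
#' realigned by cross-correlation against the running average (one pass,
#' integer shifts up to `max_shift`) before averaging. Used for laminar
#' amplitude fits.
#'
#' @param snippets Events x samples matrix of trough-aligned waveforms.
#' @param max_shift Largest realignment shift, samples.
#' @param shifts Optional precomputed per-snippet shifts (e.g. from the
#'   filtered snippets, applied to the wideband ones).
#' @return Peak-to-peak amplitude of the realigned mean waveform, uV, with
#'   the shifts used in attribute `"shifts"`.
#' @export
mean_waveform_amplitude <- function(snippets, max_shift = 3, shifts = NULL) {
  stopifnot(is.matrix(snippets), nrow(snippets) >= 1)
  n <- nrow(snippets); p <- ncol(snippets)
  if (p <= 2 * max_shift + 2) max_shift <- 0
  if (is.null(shifts)) {
    shifts <- rep(0L, n)
    if (max_shift > 0 && n > 1) {
      core <- (max_shift + 1):(p - max_shift)
      ref <- colMeans(snippets)[core]
      for (i in seq_len(n)) {
        sc <- vapply(-max_shift:max_shift, function(s) {
          sum(snippets[i, core + s] * ref)
        }, numeric(1))
        shifts[i] <- (-max_shift:max_shift)[which.max(sc)]
      }
    }
  }
  core <- if (max_shift > 0) (max_shift + 1):(p - max_shift) else seq_len(p)
  aligned <- t(vapply(seq_len(n), function(i) snippets[i, core + shifts[i]],
                      numeric(length(core))))
  m <- colMeans(aligned)
  structure(max(m) - min(m), shifts = shifts)
}

# mean per-snippet peak-to-peak without apply() overhead
mean_snippet_pp <- function(snips) {
  df <- as.data.frame(snips)
  mean(do.call(pmax, df) - do.call(pmin, df))
}

#' Run the full spike pipeline on one recording session
#'
#' Filters every channel, masks simultaneous artifacts, estimates the robust
#' noise level, detects threshold crossings, sorts snippets into units, and
#' keeps units with at least `min_spikes` spikes (default 200, the
#' acceptance rule for a 5-minute session; scale down for shorter synthetic
#' sessions).
#'
#' @param session A `recording_session` (see [simulate_session()] or
#'   [read_recording()]).
#' @param low,high Filter band, Hz.
#' @param k Detection threshold multiplier.
#' @param min_spikes Minimum spikes for an accepted unit.
#' @param artifact_frac,artifact_min_channels,artifact_window_ms Artifact
#'   invalidation parameters, see [invalidate_artifacts()].
#' @param sort_args List of overrides passed to [sort_units()].
#' @return List of class `ephys_session`: `units` (tibble: `channel`,
#'   `unit`, `n_spikes`, `mean_amp_uv` and `snr` measured per spike on the
#'   filtered trace, `wf_amp_uv` / `wf_amp_raw_uv` from the unit's average
#'   waveform on the filtered / wideband trace — the wideband average is
#'   the estimator of choice for amplitude-depth fits, since a first-order
#'   band-pass shaves a few percent off every spike and per-spike extremes
#'   inflate weak units — `accepted`), `sigma_n` per channel,
#'   `valid_fraction`, `spike_index` (accepted-unit trough indices per
#'   channel), `week`, `depths_um`.
#' @export
process_session <- function(session, low = 250, high = 3000, k = 4,
                            min_spikes = 200, artifact_frac = 0.9,
                            artifact_min_channels = 2,
                            artifact_window_ms = 1, sort_args = list()) {
  stopifnot(inherits(session, "recording_session"))
  filtered <- bandpass_filter(session$traces, session$fs, low, high)
  valid <- invalidate_artifacts(filtered, session$fs, frac = artifact_frac,
                                min_channels = artifact_min_channels,
                                window_ms = artifact_window_ms)
  n_ch <- ncol(filtered)
  sigma_n <- numeric(n_ch)
  spike_index <- vector("list", n_ch)
  u_ch <- integer(0); u_id <- integer(0); u_n <- integer(0)
  u_amp <- numeric(0); u_snr <- numeric(0)
  u_wf <- numeric(0); u_wfr <- numeric(0)
  for (ch in seq_len(n_ch)) {
    x <- filtered[, ch]
    sigma_n[ch] <- estimate_noise(x, valid)
    ev <- detect_spikes(x, sigma_n[ch], session$fs, k = k, valid = valid)
    spike_index[[ch]] <- integer(0)
    if (length(ev) < 2) next
    sn <- extract_snippets(x, ev, session$fs)
    if (nrow(sn$snippets) < 2) next
    sn_raw <- extract_snippets(session$traces[, ch], ev, session$fs)
    srt <- do.call(sort_units, c(list(snippets = sn$snippets), sort_args))
    for (u in sort(unique(srt$labels))) {
      rows <- srt$labels == u
      snips <- sn$snippets[rows, , drop = FALSE]
      pp <- mean_snippet_pp(snips)
      wf <- mean_waveform_amplitude(snips)
      u_ch <- c(u_ch, ch); u_id <- c(u_id, u); u_n <- c(u_n, nrow(snips))
      u_amp <- c(u_amp, pp); u_snr <- c(u_snr, pp / (2 * sigma_n[ch]))
      u_wf <- c(u_wf, as.numeric(wf))
      u_wfr <- c(u_wfr, as.numeric(mean_waveform_amplitude(
        sn_raw$snippets[rows, , drop = FALSE], shifts = attr(wf, "shifts")
      )))
    }
    acc <- u_id[u_ch == ch & u_n >= min_spikes]
    spike_index[[ch]] <- sort(sn$events[srt$labels %in% acc])
  }
  units <- tibble::tibble(channel = u_ch, unit = u_id, n_spikes = u_n,
                          mean_amp_uv = u_amp, snr = u_snr,
                          wf_amp_uv = u_wf, wf_amp_raw_uv = u_wfr,
                          accepted = u_n >= min_spikes)
  structure(
    list(units = units, sigma_n = sigma_n, valid_fraction = mean(valid),
         spike_index = spike_index, week = session$week,
         depths_um = session$depths_um),
    class = "ephys_session"
  )
}

#' Per-channel metrics for a processed session
#'
#' One row per channel: a channel is active when it carries at least one
#' accepted unit; amplitude and SNR are spike-count-weighted means over the
#' channel's accepted units (absent for inactive channels).
#'
#' @param processed An `ephys_session` from [process_session()].
#' @param map A [layer_map()] used to label channel depths.
#' @return Tibble with columns `channel`, `depth_um`, `layer`, `week`,
#'   `active`, `n_units`, `mean_amp_uv`, `wf_amp_raw_uv`, `snr`.
#' @export
summarize_session <- function(processed, map = default_layer_map()) {
  stopifnot(inherits(processed, "ephys_session"))
  acc <- dplyr::filter(processed$units, .data$accepted)
  per_ch <- acc |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      n_units = dplyr::n(),
      mean_amp_uv = sum(.data$mean_amp_uv * .data$n_spikes) / sum(.data$n_spikes),
      wf_amp_raw_uv = sum(.data$wf_amp_raw_uv * .data$n_spikes) /
        sum(.data$n_spikes),
      snr = sum(.data$snr * .data$n_spikes) / sum(.data$n_spikes),
      .groups = "drop"
    )
  tibble::tibble(channel = seq_along(processed$depths_um),
                 depth_um = processed$depths_um,
                 layer = assign_layer(processed$depths_um, map),
                 week = processed$week) |>
    dplyr::left_join(per_ch, by = "channel") |>
    dplyr::mutate(n_units = dplyr::coalesce(.data$n_units, 0L),
                  active = .data$n_units >= 1L) |>
    dplyr::relocate("active", .after = "week")
}

#' Process every session of a longitudinal study
#'
#' @param sessions List of `recording_session` objects (e.g.
#'   `simulate_study()$sessions`).
#' @param map A [layer_map()].
#' @param ... Passed to [process_session()].
#' @return Tibble of per-channel metrics ([summarize_session()]) stacked
#'   over sessions.
#' @export
process_study <- function(sessions, map = default_layer_map(), ...) {
  purrr::map_dfr(sessions, function(s) {
    summarize_session(process_session(s, ...), map)
  })
}

#' Cumulative active-site counts per layer
#'
#' Sums per-session active flags over the study, per layer: the number of
#' channel-sessions in which a site of that layer carried at least one
#' accepted unit.
#'
#' @param metrics Channel-metrics tibble from [process_study()].
#' @return Tibble with `layer`, `cumulative_active`.
#' @export
active_site_counts <- function(metrics) {
  metrics |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(cumulative_active = sum(.data$active), .groups = "drop")
}
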
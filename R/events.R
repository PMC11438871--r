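## Event detection: NREM segmentation from the field potential, population-
## burst frame detection in sleep and awake rest, ripple detection, theta
## trough/cycle extraction and the peak theta frequency.

#' Segment NREM sleep from the field potential and immobility
#'
#' NREM = immobility (velocity below `vmax`, trivially satisfied when no
#' velocity trace is supplied) AND a theta/delta ratio below its session
#' mean. The ratio uses the amplitude envelopes of the 5--9 Hz and 1--4 Hz
#' bands, each envelope smoothed with a 10-s Gaussian. With no field
#' potential available, segmentation falls back to immobility only and the
#' result carries `lfp_used = FALSE`.
#'
#' @param lfp list with `time`, `samples`, `fs` (the sleep segment of an
#'   `lfp_trace`), or `NULL`.
#' @param velocity optional list with `time` and `speed` (cm/s).
#' @param vmax immobility threshold, cm/s (default 2).
#' @param smooth_s envelope smoothing SD, s (default 10).
#' @return an `epoch_set` data.frame (label, start, end) where label is
#'   "nrem"; attribute `lfp_used`.
#' @export
segment_nrem <- function(lfp, velocity = NULL, vmax = 2, smooth_s = 10) {
  if (is.null(lfp)) {
    if (is.null(velocity)) stop("need lfp or velocity")
    immobile <- velocity$speed < vmax
    iv <- mask_to_intervals(immobile)
    dt <- stats::median(diff(velocity$time))
    out <- data.frame(label = "nrem",
                      start = velocity$time[iv[, 1]],
                      end = velocity$time[iv[, 2]] + dt)
    attr(out, "lfp_used") <- FALSE
    warning("no field potential: immobility-only NREM segmentation")
    return(out)
  }
  fs <- lfp$fs
  ## decimate to ~100 Hz first: narrow low-frequency bands are numerically
  ## unstable for an IIR band-pass at kHz sampling rates, and the bands of
  ## interest live below 10 Hz
  dec0 <- max(1L, floor(fs / 100))
  x <- gauss_smooth(lfp$samples, dec0 / 2)[seq(1L, length(lfp$samples),
                                               by = dec0)]
  fs1 <- fs / dec0
  tt1 <- lfp$time[seq(1L, length(lfp$time), by = dec0)]
  th <- envelope(bandpass(x, fs1, c(5, 9)))
  de <- envelope(bandpass(x, fs1, c(1, 4)))
  ## envelopes vary slowly: decimate again before the 10-s smoothing
  dec1 <- max(1L, floor(fs1 / 25))
  keep <- seq(1L, length(th), by = dec1)
  tt <- tt1[keep]
  fs_d <- fs1 / dec1
  th <- gauss_smooth(th[keep], smooth_s * fs_d)
  de <- gauss_smooth(de[keep], smooth_s * fs_d)
  ratio <- th / pmax(de, 1e-12)
  low <- ratio < mean(ratio)
  if (!is.null(velocity)) {
    sp <- stats::approx(velocity$time, velocity$speed, xout = tt, rule = 2)$y
    low <- low & (sp < vmax)
  }
  iv <- mask_to_intervals(low)
  if (is.null(dim(iv)) || nrow(iv) == 0) {
    out <- data.frame(label = character(0), start = numeric(0),
                      end = numeric(0))
  } else {
    out <- data.frame(label = "nrem", start = tt[iv[, 1]], end = tt[iv[, 2]])
    out <- out[out$end - out$start > 1, ]  # drop sub-second fragments
  }
  attr(out, "lfp_used") <- TRUE
  out
}

#' Detect population-burst frames
#'
#' The summed population activity in 1-ms bins is convolved with a 15-ms
#' Gaussian kernel; epochs inside the context epochs where it surpasses the
#' mean + `sd_threshold` SD (mean and SD computed within the context epochs
#' only), lasting 100--800 ms and recruiting at least `min_units` distinct
#' units, become frames. Frame boundaries are the threshold up/down
#' crossings. Each frame is binned at 20 ms.
#'
#' @param spikes per-unit spike-time list.
#' @param epochs epoch data.frame (label/start/end) delimiting the context
#'   (e.g. NREM from [segment_nrem()]); label is not interpreted.
#' @param t_range overall time range c(t0, t1), s.
#' @param sd_threshold threshold in SD above the mean (default 2).
#' @param min_units minimum distinct active units (default 5).
#' @param min_dur,max_dur duration bounds, s (defaults 0.1, 0.8).
#' @param bin_s frame bin width, s (default 0.02).
#' @return list of frames, each with `start`, `end`, `duration`, `counts`
#'   (units x bins), `n_active_units`; plus attribute `table`.
#' @export
detect_frames <- function(spikes, epochs, t_range = NULL, sd_threshold = 2,
                          min_units = 5, min_dur = 0.1, max_dur = 0.8,
                          bin_s = 0.02) {
  if (length(spikes) < min_units) {
    warning("fewer recorded units than the frame participation minimum")
    return(structure(list(), table = NULL))
  }
  all_sp <- sort(unlist(spikes))
  if (is.null(t_range)) {
    t_range <- c(0, max(c(all_sp, epochs$end), na.rm = TRUE))
  }
  n_ms <- ceiling((t_range[2] - t_range[1]) * 1000) + 1L
  ms_idx <- floor((all_sp - t_range[1]) * 1000) + 1L
  ms_idx <- ms_idx[ms_idx >= 1 & ms_idx <= n_ms]
  pop <- tabulate(ms_idx, n_ms)
  rate <- gauss_smooth(pop, 15)
  tt <- t_range[1] + (seq_len(n_ms) - 1) / 1000

  in_ctx <- rep(FALSE, n_ms)
  for (k in seq_len(nrow(epochs))) {
    in_ctx[tt >= epochs$start[k] & tt < epochs$end[k]] <- TRUE
  }
  if (!any(in_ctx)) return(structure(list(), table = NULL))
  thr <- mean(rate[in_ctx]) + sd_threshold * stats::sd(rate[in_ctx])
  above <- rate > thr & in_ctx
  iv <- mask_to_intervals(above)
  frames <- list()
  if (!is.null(dim(iv))) {
    for (k in seq_len(nrow(iv))) {
      t0 <- tt[iv[k, 1]]; t1 <- tt[iv[k, 2]]
      dur <- t1 - t0
      if (dur < min_dur || dur > max_dur) next
      n_bins <- max(1L, floor(dur / bin_s))
      edges <- t0 + (0:n_bins) * bin_s
      cnt <- bin_spike_counts(spikes, edges)
      active <- sum(rowSums(cnt) > 0)
      if (active < min_units) next
      frames[[length(frames) + 1L]] <-
        list(start = t0, end = t1, duration = dur, counts = cnt,
             n_active_units = active)
    }
  }
  tab <- if (length(frames)) {
    data.frame(frame = seq_along(frames),
               start = vapply(frames, `[[`, numeric(1), "start"),
               end = vapply(frames, `[[`, numeric(1), "end"),
               n_active = vapply(frames, `[[`, numeric(1), "n_active_units"))
  } else NULL
  structure(frames, table = tab)
}

#' Detect high-frequency ripple events
#'
#' Band-pass filters the trace at 140--250 Hz, takes the amplitude envelope,
#' and keeps events whose peak exceeds the mean + `sd_threshold` SD of the
#' envelope; event boundaries are the crossings of mean + 1 SD around each
#' peak.
#'
#' @param lfp list with `time`, `samples`, `fs` (needs `fs >= 600`).
#' @param sd_threshold peak threshold in SD (default 3).
#' @return data.frame (start, end, peak_time, peak_z).
#' @export
detect_ripples <- function(lfp, sd_threshold = 3) {
  if (lfp$fs < 600) stop("sampling rate too low for ripple detection")
  env <- envelope(bandpass(lfp$samples, lfp$fs, c(140, 250)))
  env <- gauss_smooth(env, 0.004 * lfp$fs)
  mu <- mean(env); sdv <- stats::sd(env)
  if (sdv == 0) return(data.frame(start = numeric(0), end = numeric(0),
                                  peak_time = numeric(0), peak_z = numeric(0)))
  z <- (env - mu) / sdv
  iv <- mask_to_intervals(z > 1)
  rows <- list()
  if (!is.null(dim(iv))) {
    for (k in seq_len(nrow(iv))) {
      seg <- iv[k, 1]:iv[k, 2]
      pk <- seg[which.max(z[seg])]
      if (z[pk] > sd_threshold) {
        rows[[length(rows) + 1L]] <-
          data.frame(start = lfp$time[iv[k, 1]], end = lfp$time[iv[k, 2]],
                     peak_time = lfp$time[pk], peak_z = z[pk])
      }
    }
  }
  if (!length(rows)) return(data.frame(start = numeric(0), end = numeric(0),
                                       peak_time = numeric(0),
                                       peak_z = numeric(0)))
  do.call(rbind, rows)
}

#' Flag frames that co-occur with ripples
#' @param frame_table frame table (start, end).
#' @param ripples ripple table from [detect_ripples()].
#' @return logical vector per frame.
#' @export
ripple_cooccurrence <- function(frame_table, ripples) {
  vapply(seq_len(nrow(frame_table)), function(k) {
    any(interval_overlap(frame_table$start[k], frame_table$end[k],
                         cbind(ripples$start, ripples$end)) > 0)
  }, logical(1))
}

#' Peak theta frequency during movement
#'
#' Spectrum (FFT periodogram) of the concatenated movement epochs
#' (velocity above `vmin`), peak within 5--9 Hz.
#'
#' @param lfp list with `time`, `samples`, `fs`.
#' @param velocity list with `time`, `speed`; `NULL` uses the whole trace.
#' @param vmin movement threshold, cm/s (default 10).
#' @return peak frequency, Hz.
#' @export
peak_theta_frequency <- function(lfp, velocity = NULL, vmin = 10) {
  x <- lfp$samples
  if (!is.null(velocity)) {
    sp <- stats::approx(velocity$time, velocity$speed, xout = lfp$time,
                        rule = 2)$y
    x <- x[sp > vmin]
    if (!length(x)) stop("no movement epochs")
  }
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))^2
  freq <- (seq_len(n) - 1) * lfp$fs / n
  band <- freq >= 5 & freq <= 9
  freq[band][which.max(spec[band])]
}

#' Extract theta-cycle windows for sequence analysis
#'
#' Finds theta troughs (local minima of the 5--9 Hz band-passed trace),
#' keeps cycles where the animal moves above `vmin` within the middle 2/5 of
#' the track, opens a 400-ms window centred on each trough, and bins spikes
#' at 20 ms. Cycles with fewer than `min_units` active units are dropped
#' (use 2 for averaged analyses, 5 for single-cycle significance).
#'
#' @param lfp run-segment field potential (`time`, `samples`, `fs`).
#' @param run a `run_session`.
#' @param vmin movement threshold (default 10 cm/s).
#' @param min_units minimum active units per cycle (default 2).
#' @param window_s window length, s (default 0.4).
#' @param bin_s bin width, s (default 0.02).
#' @return list of cycles: `trough_time`, `animal_pos`, `counts` (units x
#'   bins).
#' @export
extract_theta_cycles <- function(lfp, run, vmin = 10, min_units = 2,
                                 window_s = 0.4, bin_s = 0.02) {
  if (!length(run$time)) stop("no movement")
  L <- run$config$track_length
  th <- bandpass(lfp$samples, lfp$fs, c(5, 9))
  n <- length(th)
  is_min <- c(FALSE, th[2:(n - 1)] < th[1:(n - 2)] &
                th[2:(n - 1)] < th[3:n], FALSE)
  troughs <- lfp$time[is_min]
  sp <- stats::approx(run$time, abs(run$velocity), xout = troughs, rule = 2)$y
  px <- stats::approx(run$time, run$position, xout = troughs, rule = 2)$y
  keep <- sp > vmin & px > 0.3 * L & px < 0.7 * L &
    troughs > window_s / 2 & troughs < max(lfp$time) - window_s / 2
  troughs <- troughs[keep]; px <- px[keep]
  cycles <- list()
  n_bins <- round(window_s / bin_s)
  for (k in seq_along(troughs)) {
    edges <- troughs[k] - window_s / 2 + (0:n_bins) * bin_s
    cnt <- bin_spike_counts(run$spikes, edges)
    if (sum(rowSums(cnt) > 0) < min_units) next
    cycles[[length(cycles) + 1L]] <-
      list(trough_time = troughs[k], animal_pos = px[k], counts = cnt)
  }
  cycles
}
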
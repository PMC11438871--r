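## Direction-specific rate maps, place-cell classification and single-cell
## tuning metrics (spatial information, stability, primary field length,
## SMV/symmetry-index rate-map classes).

#' Direction-specific occupancy-normalized rate map
#'
#' Spike counts (at samples with velocity above `vmin` in the requested
#' direction) and occupancy time are binned in non-overlapping `bin_cm` bins,
#' each smoothed by the same Gaussian kernel (`kernel_sd_cm` SD, truncated at
#' +/- 3 SD), and divided. Bins never occupied get rate 0 and are flagged.
#'
#' @param spike_times spike times of one unit, s.
#' @param time position-sample times, s (uniform sampling).
#' @param position position at each sample, cm.
#' @param velocity signed velocity at each sample, cm/s.
#' @param direction_labels per-sample direction labels (e.g. "fwd"/"bwd");
#'   `NULL` selects all samples above the velocity threshold.
#' @param direction which label to analyze.
#' @param track_length track length, cm.
#' @param bin_cm spatial bin width (default 2 cm).
#' @param kernel_sd_cm Gaussian kernel SD (default 2 cm).
#' @param vmin velocity threshold, cm/s (default 5).
#' @param unit_id optional identifier stored on the map.
#' @return a `rate_map`: `rates` (Hz per bin), `occupancy_prob` (sums to 1),
#'   `mean_rate`, `peak_rate`, `bin_centres`, `unoccupied`, `direction`.
#' @export
compute_rate_map <- function(spike_times, time, position, velocity,
                             direction_labels = NULL, direction = "fwd",
                             track_length = 100, bin_cm = 2,
                             kernel_sd_cm = 2, vmin = 5, unit_id = NA) {
  stopifnot(length(time) == length(position))
  nb <- max(1L, round(track_length / bin_cm))
  edges <- seq(0, track_length, length.out = nb + 1L)
  dt <- if (length(time) > 1) stats::median(diff(time)) else 0

  sel <- abs(velocity) > vmin
  if (!is.null(direction_labels)) sel <- sel & direction_labels == direction
  if (!any(sel) || dt == 0) stop("empty-map error: zero filtered occupancy")

  bin_of <- function(x) pmin(nb, pmax(1L, findInterval(x, edges,
                                                       rightmost.closed = TRUE)))
  occ <- tabulate(bin_of(position[sel]), nb) * dt

  ## spike selection: nearest position sample must pass the same filter
  sp <- spike_times[spike_times >= min(time) & spike_times <= max(time)]
  idx <- pmin(length(time), pmax(1L, round((sp - time[1]) / dt) + 1L))
  sp_ok <- sel[idx]
  cnt <- tabulate(bin_of(position[idx[sp_ok]]), nb)

  sd_bins <- kernel_sd_cm / bin_cm
  cnt_s <- gauss_smooth(cnt, sd_bins)
  occ_s <- gauss_smooth(occ, sd_bins)
  rates <- ifelse(occ_s > 0, cnt_s / occ_s, 0)
  occp <- if (sum(occ_s) > 0) occ_s / sum(occ_s) else occ_s

  structure(list(rates = rates, occupancy_prob = occp,
                 mean_rate = sum(occp * rates), peak_rate = max(rates),
                 bin_centres = (edges[-1] + edges[-length(edges)]) / 2,
                 bin_cm = bin_cm, unoccupied = occ_s == 0,
                 direction = direction, unit_id = unit_id,
                 n_spikes = sum(cnt)),
            class = "rate_map")
}

#' Rate maps for every unit of a run session
#'
#' @param session a `run_session`.
#' @param direction direction label.
#' @param ... passed to [compute_rate_map()].
#' @return list of `rate_map`s, one per unit.
#' @export
rate_maps <- function(session, direction = "fwd", ...) {
  lapply(seq_along(session$spikes), function(i) {
    compute_rate_map(session$spikes[[i]], session$time, session$position,
                     session$velocity, session$direction, direction,
                     track_length = session$config$track_length,
                     unit_id = i, ...)
  })
}

#' Stack rate maps into a units x bins matrix
#' @param maps list of `rate_map`s.
#' @return numeric matrix of rates (Hz).
#' @export
rate_map_matrix <- function(maps) {
  do.call(rbind, lapply(maps, function(m) m$rates))
}

#' Spatial information of a rate map (bits/spike)
#'
#' \deqn{SpInfo = \sum_j Pr(loc_j) (fr_j / fr_{mean}) \log_2(fr_j / fr_{mean})}
#' Bins with zero rate contribute 0. Undefined (NA, with attribute
#' `undefined`) when the mean rate is 0.
#'
#' @param map a `rate_map`.
#' @return bits per spike.
#' @export
spatial_information <- function(map) {
  fr <- map$rates
  pr <- map$occupancy_prob
  fm <- sum(pr * fr)
  if (fm <= 0) return(structure(NA_real_, undefined = TRUE))
  rel <- fr / fm
  pos <- rel > 0
  sum(pr[pos] * rel[pos] * log2(rel[pos]))
}

## Lap segmentation: end-zone-to-opposite-end-zone traversals, with end zones
## 5% of track length. Returns one row per traversal with its direction.
#' Detect laps (full end-to-end traversals)
#' @param time,position trajectory samples (s, cm).
#' @param track_length track length, cm.
#' @param end_zone_frac end-zone width as fraction of track length.
#' @return data.frame (lap, direction, start, end).
#' @export
detect_laps <- function(time, position, track_length = 100,
                        end_zone_frac = 0.05) {
  if (!length(time)) {
    return(data.frame(lap = integer(0), direction = character(0),
                      start = numeric(0), end = numeric(0)))
  }
  zone <- ifelse(position <= end_zone_frac * track_length, 1L,
                 ifelse(position >= (1 - end_zone_frac) * track_length, 2L, 0L))
  laps <- list()
  cur_zone <- zone[1]
  t_leave <- time[1]
  for (k in which(zone != 0L)) {
    if (cur_zone == 0L) { cur_zone <- zone[k]; t_leave <- time[k]; next }
    if (zone[k] != cur_zone) {
      laps[[length(laps) + 1L]] <-
        data.frame(direction = if (cur_zone == 1L) "fwd" else "bwd",
                   start = t_leave, end = time[k])
      cur_zone <- zone[k]
    }
    t_leave <- time[k]
  }
  out <- if (length(laps)) do.call(rbind, laps) else
    data.frame(direction = character(0), start = numeric(0), end = numeric(0))
  cbind(lap = seq_len(nrow(out)), out)
}

#' Within-session map stability
#'
#' Spearman correlation between the rate maps built from the first and the
#' last one-fifth of laps in one direction.
#'
#' @param spike_times one unit's spike times, s.
#' @param session a `run_session` (or any list with `time`, `position`,
#'   `velocity`, `direction`, `config`).
#' @param direction direction label.
#' @param ... passed to [compute_rate_map()].
#' @return Spearman rank correlation in `[-1, 1]`.
#' @export
map_stability <- function(spike_times, session, direction = "fwd", ...) {
  L <- session$config$track_length
  laps <- detect_laps(session$time, session$position, L)
  laps <- laps[laps$direction == direction, ]
  if (nrow(laps) < 5) stop("insufficient-data error: fewer than 5 laps")
  k <- max(1L, floor(nrow(laps) / 5))
  sub_map <- function(lapset) {
    keep <- rep(FALSE, length(session$time))
    for (r in seq_len(nrow(lapset))) {
      keep <- keep | (session$time >= lapset$start[r] &
                        session$time <= lapset$end[r])
    }
    tt <- session$time[keep]
    sp <- spike_times[vapply(spike_times, function(s) {
      any(s >= lapset$start & s <= lapset$end)
    }, logical(1))]
    compute_rate_map(sp, tt, session$position[keep], session$velocity[keep],
                     session$direction[keep], direction, track_length = L, ...)
  }
  m1 <- sub_map(laps[seq_len(k), ])
  m2 <- sub_map(laps[(nrow(laps) - k + 1):nrow(laps), ])
  ok <- !(m1$unoccupied & m2$unoccupied)
  suppressWarnings(stats::cor(m1$rates[ok], m2$rates[ok], method = "spearman"))
}

#' Primary place-field length (cm)
#'
#' Contiguous distance around the peak bin where the rate stays at or above
#' 20% of the peak rate. Defined only for place cells (peak rate > 1 Hz);
#' otherwise returns NA with attribute `not_applicable`.
#'
#' @param map a `rate_map`.
#' @param rel_threshold fraction of peak defining the field boundary.
#' @return field length in cm.
#' @export
primary_field_length <- function(map, rel_threshold = 0.2) {
  if (map$peak_rate <= 1) return(structure(NA_real_, not_applicable = TRUE))
  thr <- rel_threshold * map$peak_rate
  pk <- which.max(map$rates)
  lo <- pk
  while (lo > 1 && map$rates[lo - 1] >= thr) lo <- lo - 1
  hi <- pk
  while (hi < length(map$rates) && map$rates[hi + 1] >= thr) hi <- hi + 1
  (hi - lo + 1) * map$bin_cm
}

#' Classify a rate map as low-tuned, symmetric or well-tuned
#'
#' Two-step rule. Step 1: the squared-mean-to-variance ratio
#' \eqn{SMV = E(fr)^2 / Var(fr)} flags low-tuned maps when it exceeds
#' `smv_threshold` (a flat map has infinite SMV). Step 2: among the
#' remainder whose peak lies within `end_zone_cm` of a track end, the
#' symmetry index \eqn{SI = 1 - (PF - PF_{sym}) / (PF + PF_{sym})} -- with PF
#' the mean rate over the 5 bins centred on the peak and PF_sym over the 5
#' bins centred on the mirrored location -- flags symmetric maps when it
#' exceeds `si_threshold`; everything else (including middle-peaked maps,
#' for which the symmetry step is skipped) is well-tuned.
#'
#' @param map a `rate_map`.
#' @param smv_threshold default 3.62 (99th percentile of an adult reference
#'   population; see [smv_threshold_from_reference()]).
#' @param si_threshold default 0.67.
#' @param end_zone_cm symmetry step restricted to peaks within this distance
#'   of a track end (default 30 cm).
#' @return list with `smv`, `si`, `category`, `symmetry_tested`, `flag`.
#' @export
classify_rate_map <- function(map, smv_threshold = 3.62, si_threshold = 0.67,
                              end_zone_cm = 30) {
  fr <- map$rates
  if (length(fr) < 10) stop("rate map needs at least 10 bins")
  v <- stats::var(fr)
  smv <- if (v == 0) Inf else mean(fr)^2 / v
  if (smv > smv_threshold) {
    return(list(smv = smv, si = NA_real_, category = "low_tuned",
                symmetry_tested = FALSE, flag = NULL))
  }
  L <- max(map$bin_centres) + map$bin_cm / 2
  pk <- which.max(fr)
  pk_cm <- map$bin_centres[pk]
  near_end <- pk_cm <= end_zone_cm || pk_cm >= L - end_zone_cm
  if (!near_end) {
    return(list(smv = smv, si = NA_real_, category = "well_tuned",
                symmetry_tested = FALSE, flag = "middle_peak"))
  }
  win <- function(centre_bin) {
    idx <- (centre_bin - 2):(centre_bin + 2)
    idx <- idx[idx >= 1 & idx <= length(fr)]
    mean(fr[idx])
  }
  sym_bin <- which.min(abs(map$bin_centres - (L - pk_cm)))
  pf <- win(pk)
  pf_sym <- win(sym_bin)
  if (pf + pf_sym == 0) {
    return(list(smv = smv, si = NA_real_, category = "well_tuned",
                symmetry_tested = TRUE, flag = "si_undefined"))
  }
  si <- 1 - (pf - pf_sym) / (pf + pf_sym)
  list(smv = smv, si = si,
       category = if (si > si_threshold) "symmetric" else "well_tuned",
       symmetry_tested = TRUE, flag = NULL)
}

#' Recalibrate the low-tuning SMV threshold from a reference map population
#'
#' The default threshold is the 99th percentile of SMV over a reference
#' (adult, well-tuned) rate-map population; supply such a population to
#' recompute it.
#'
#' @param reference_maps list of `rate_map`s.
#' @param prob percentile (default 0.99).
#' @return numeric threshold.
#' @export
smv_threshold_from_reference <- function(reference_maps, prob = 0.99) {
  smv <- vapply(reference_maps, function(m) {
    v <- stats::var(m$rates)
    if (v == 0) Inf else mean(m$rates)^2 / v
  }, numeric(1))
  as.numeric(stats::quantile(smv[is.finite(smv)], prob))
}

#' Per-unit tuning metrics table
#'
#' @param maps list of `rate_map`s.
#' @param session optional `run_session` for stability (needs >= 5 laps).
#' @return data.frame with peak rate, spatial information, primary field
#'   length, place-cell flag and (if available) stability per unit.
#' @export
tuning_metrics <- function(maps, session = NULL) {
  out <- data.frame(
    unit = vapply(maps, function(m) as.integer(m$unit_id), integer(1)),
    direction = vapply(maps, function(m) m$direction, character(1)),
    peak_rate = vapply(maps, function(m) m$peak_rate, numeric(1)),
    mean_rate = vapply(maps, function(m) m$mean_rate, numeric(1)),
    spatial_information = vapply(maps, function(m)
      as.numeric(spatial_information(m)), numeric(1)),
    primary_field_length = vapply(maps, function(m)
      as.numeric(primary_field_length(m)), numeric(1)))
  out$is_place_cell <- out$peak_rate > 1
  if (!is.null(session)) {
    out$stability <- vapply(seq_len(nrow(out)), function(k) {
      tryCatch(map_stability(session$spikes[[out$unit[k]]], session,
                             out$direction[k]),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  out
}
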
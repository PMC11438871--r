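## Synthetic-data generator: lap-running linear-track sessions with
## direction-specific Gaussian place tuning and inhomogeneous-Poisson spiking,
## NREM-like sleep with planted population-burst frames (optionally carrying
## time-compressed trajectory sequences, ensemble clusters and assembly
## reactivations), and a band-structured field-potential trace. Every planted
## feature is recorded as ground truth so downstream detectors can be
## validated end to end.

#' Configuration for the synthetic session generator
#'
#' Defaults describe the study conditions the rest of the package is
#' validated under: a 1-m linear track, a few dozen simultaneously recorded
#' pyramidal units with Gaussian place fields, theta at 7 Hz during running,
#' and a 10-minute sleep in which brief (100--800 ms) high-activity frames
#' occur inside NREM epochs.
#'
#' @param seed integer root seed; all session randomness derives from it
#'   through named substreams.
#' @param track_length track length in cm.
#' @param n_cells number of units.
#' @param field_width_range range (cm) for the Gaussian field SD draw.
#' @param peak_rate_range range (Hz) for the in-field peak rate draw.
#' @param mirror_weight weight in `[0,1]` of a field component mirrored about
#'   the track middle (symmetric mapping of equidistant locations). The
#'   effective per-field weight is end-anchored: scaled by the field
#'   centre's normalized distance from the track middle, so end fields
#'   mirror fully and middle fields not at all.
#' @param low_tuned_fraction fraction of units given position-independent
#'   rates.
#' @param n_laps number of out-and-back lap cycles.
#' @param run_speed running speed, cm/s.
#' @param theta_freq theta frequency, Hz, used by [generate_lfp()].
#' @param seq_frame_fraction fraction of sleep frames carrying an embedded
#'   time-compressed trajectory sequence.
#' @param seq_compression fraction of the track traversed per 20-ms bin in
#'   embedded sequences.
#' @param n_clusters_planted number of planted frame-ensemble clusters
#'   (disjoint participating-cell subsets).
#' @param n_assemblies_planted number of planted co-activation assemblies.
#' @param frame_rate planted sleep frames per minute of NREM.
#' @param sleep_duration sleep-session length, s.
#' @param seq_gain rate multiplier applied to template tuning inside embedded
#'   sequence frames (time compression concentrates spiking).
#' @param assembly_event_rate rate (Hz) of planted assembly co-firing events
#'   during running.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             track_length = 100,
                             n_cells = 50L,
                             field_width_range = c(5, 12),
                             peak_rate_range = c(8, 25),
                             mirror_weight = 0,
                             low_tuned_fraction = 0.1,
                             n_laps = 20L,
                             run_speed = 30,
                             theta_freq = 7,
                             seq_frame_fraction = 0.2,
                             seq_compression = 0.1,
                             n_clusters_planted = 3L,
                             n_assemblies_planted = 2L,
                             frame_rate = 12,
                             sleep_duration = 600,
                             seq_gain = 2,
                             assembly_event_rate = 1) {
  fracs <- c(mirror_weight = mirror_weight,
             low_tuned_fraction = low_tuned_fraction,
             seq_frame_fraction = seq_frame_fraction)
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) {
    stop("config error: ", paste(names(fracs)[bad], collapse = ", "),
         " must lie in [0, 1]")
  }
  if (track_length <= 0) stop("config error: track_length must be positive")
  if (n_cells < 1) stop("empty-session error: n_cells must be >= 1")
  if (seq_frame_fraction > 0 && seq_compression <= 0) {
    stop("config error: seq_compression must be positive when sequences are embedded")
  }
  cfg <- list(seed = as.integer(seed), track_length = track_length,
              n_cells = as.integer(n_cells),
              field_width_range = field_width_range,
              peak_rate_range = peak_rate_range,
              mirror_weight = mirror_weight,
              low_tuned_fraction = low_tuned_fraction,
              n_laps = as.integer(n_laps), run_speed = run_speed,
              theta_freq = theta_freq,
              seq_frame_fraction = seq_frame_fraction,
              seq_compression = seq_compression,
              n_clusters_planted = as.integer(n_clusters_planted),
              n_assemblies_planted = as.integer(n_assemblies_planted),
              frame_rate = frame_rate, sleep_duration = sleep_duration,
              seq_gain = seq_gain, assembly_event_rate = assembly_event_rate,
              pos_fs = 25, spike_fs = 1000, lfp_fs = 1250)
  class(cfg) <- "generator_config"
  cfg
}

## Gaussian tuning with an optional mirrored component about the track middle.
## Returns rate in Hz at positions x for one unit.
tuning_rate <- function(x, centre, width, peak, mirror_weight, track_length) {
  g1 <- exp(-0.5 * ((x - centre) / width)^2)
  g2 <- exp(-0.5 * (((track_length - x) - centre) / width)^2)
  peak * ((1 - mirror_weight) * g1 + mirror_weight * g2)
}

## Draw per-unit, per-direction ground-truth tuning parameters. The mirror
## component is end-anchored: a field's effective mirror weight is
## mirror_weight scaled by the centre's normalized distance from the track
## middle (|2c/L - 1|), so symmetric mapping is strongest for end fields and
## absent at the middle -- distant symmetric locations become more similar,
## nearby ones stay distinct.
draw_ground_truth <- function(cfg) {
  n <- cfg$n_cells
  out <- do.call(rbind, lapply(c("fwd", "bwd"), function(d) {
    centre <- stats::runif(n, 0, cfg$track_length)
    data.frame(unit = seq_len(n), direction = d, centre = centre,
               width = stats::runif(n, cfg$field_width_range[1],
                                    cfg$field_width_range[2]),
               peak = stats::runif(n, cfg$peak_rate_range[1],
                                   cfg$peak_rate_range[2]),
               mirror_weight = cfg$mirror_weight *
                 abs(2 * centre / cfg$track_length - 1),
               stringsAsFactors = FALSE)
  }))
  low <- stats::runif(n) < cfg$low_tuned_fraction
  out$low_tuned <- low[out$unit]
  out$flat_rate <- stats::runif(n, 0.5, 3)[out$unit]
  out
}

#' Generate a lap-running linear-track session with ground-truth tuning
#'
#' The animal runs `n_laps` out-and-back lap cycles at constant speed with
#' 1-s pauses at the track ends; position is sampled at 25 Hz. Each unit's
#' rate follows a direction-specific Gaussian field (independent draws per
#' direction), optionally mixed with a component mirrored about the track
#' middle with weight `mirror_weight`; a `low_tuned_fraction` of units fire
#' at a position-independent rate. Spikes are drawn by thinning a 1-kHz
#' Bernoulli approximation of the inhomogeneous Poisson process. Planted
#' assemblies add co-occurring extra spikes within shared 20-ms windows for
#' their member units during movement.
#'
#' @param config a [generator_config()].
#' @return a `run_session`: `time`, `position`, `velocity`, `direction`
#'   (per-sample labels), `spikes` (per-unit sorted spike times, s),
#'   `ground_truth` (per unit x direction), `assemblies` (planted member
#'   sets), `config`.
#' @export
generate_run_session <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(substream_seed(cfg$seed, "run"))
  L <- cfg$track_length
  truth <- draw_ground_truth(cfg)

  ## trajectory: fwd pass, pause, bwd pass, pause, per lap cycle
  pause <- 1
  leg <- L / cfg$run_speed
  dt <- 1 / cfg$pos_fs
  if (cfg$n_laps == 0L) {
    pos <- numeric(0); tt <- numeric(0); dirlab <- character(0)
  } else {
    one_fwd <- seq(0, L, by = cfg$run_speed * dt)
    one_bwd <- rev(one_fwd)
    n_pause <- round(pause / dt)
    lap_pos <- c(one_fwd, rep(L, n_pause), one_bwd, rep(0, n_pause))
    lap_dir <- c(rep("fwd", length(one_fwd)), rep("rest", n_pause),
                 rep("bwd", length(one_bwd)), rep("rest", n_pause))
    pos <- rep(lap_pos, cfg$n_laps)
    dirlab <- rep(lap_dir, cfg$n_laps)
    tt <- seq_along(pos) * dt - dt
  }
  vel <- if (length(pos) > 1) c(0, diff(pos) / dt) else numeric(length(pos))

  ## assemblies: disjoint member sets among tuned units
  assemblies <- list()
  if (cfg$n_assemblies_planted > 0 && cfg$n_cells >= 5 * cfg$n_assemblies_planted) {
    pool <- sample(seq_len(cfg$n_cells))
    for (a in seq_len(cfg$n_assemblies_planted)) {
      assemblies[[a]] <- sort(pool[(5 * (a - 1) + 1):(5 * a)])
    }
  }

  spikes <- rep(list(numeric(0)), cfg$n_cells)
  if (length(tt)) {
    ## per-ms rate via position interpolated to the 1-kHz grid
    tms <- seq(0, max(tt), by = 1 / cfg$spike_fs)
    pms <- stats::approx(tt, pos, xout = tms, rule = 2)$y
    dir_ms <- dirlab[pmin(length(tt), floor(tms / dt) + 1L)]
    moving_f <- dir_ms == "fwd"
    moving_b <- dir_ms == "bwd"
    for (i in seq_len(cfg$n_cells)) {
      gt_f <- truth[truth$unit == i & truth$direction == "fwd", ]
      gt_b <- truth[truth$unit == i & truth$direction == "bwd", ]
      lam <- rep(0.1, length(tms))
      if (gt_f$low_tuned) {
        lam[moving_f | moving_b] <- gt_f$flat_rate
      } else {
        lam[moving_f] <- tuning_rate(pms[moving_f], gt_f$centre, gt_f$width,
                                     gt_f$peak, gt_f$mirror_weight, L)
        lam[moving_b] <- tuning_rate(pms[moving_b], gt_b$centre, gt_b$width,
                                     gt_b$peak, gt_b$mirror_weight, L)
      }
      hit <- stats::runif(length(tms)) < lam / cfg$spike_fs
      spikes[[i]] <- tms[hit] + stats::runif(sum(hit), 0, 1 / cfg$spike_fs)
    }
    ## planted assembly co-firing events in shared 20-ms windows
    if (length(assemblies)) {
      move_t <- tt[dirlab != "rest"]
      n_ev <- stats::rpois(1, cfg$assembly_event_rate * length(move_t) * dt)
      if (n_ev > 0) {
        ev_t <- sample(move_t, min(n_ev, length(move_t)))
        for (et in ev_t) {
          a <- sample(length(assemblies), 1)
          for (m in assemblies[[a]]) {
            k <- 1 + stats::rpois(1, 1)
            spikes[[m]] <- c(spikes[[m]], stats::runif(k, et, et + 0.02))
          }
        }
      }
    }
    spikes <- lapply(spikes, sort)
  }

  structure(list(time = tt, position = pos, velocity = vel,
                 direction = dirlab, spikes = spikes, ground_truth = truth,
                 assemblies = assemblies, config = cfg),
            class = "run_session")
}

## Coerce templates (encoding model, rate-map list, or bare matrix) into a
## units x bins rate matrix with bin centres in cm and the unit id of every
## row, so embedded-sequence spikes land on the right units.
as_template_matrix <- function(templates, track_length) {
  if (inherits(templates, "encoding_model")) {
    return(list(rates = templates$f, centres = templates$bin_centres,
                unit_ids = templates$included_units))
  }
  if (is.matrix(templates)) {
    L <- ncol(templates)
    return(list(rates = templates,
                centres = (seq_len(L) - 0.5) * track_length / L,
                unit_ids = seq_len(nrow(templates))))
  }
  if (is.list(templates) && length(templates) &&
      inherits(templates[[1]], "rate_map")) {
    rates <- do.call(rbind, lapply(templates, function(m) m$rates))
    ids <- vapply(templates, function(m) {
      if (is.na(m$unit_id)) NA_integer_ else as.integer(m$unit_id)
    }, integer(1))
    if (anyNA(ids)) ids <- seq_len(nrow(rates))
    return(list(rates = rates, centres = templates[[1]]$bin_centres,
                unit_ids = ids))
  }
  stop("templates must be an encoding model, a rate-map list, or a matrix")
}

## Normalize the templates argument to a list of template matrices (one per
## track template).
as_template_list <- function(templates, track_length) {
  if (is.list(templates) && length(templates) &&
      !inherits(templates, c("encoding_model")) &&
      !inherits(templates[[1]], "rate_map")) {
    return(lapply(templates, as_template_matrix, track_length = track_length))
  }
  list(as_template_matrix(templates, track_length))
}

#' Generate an NREM-like sleep session with planted frames
#'
#' Sleep alternates NREM and non-NREM epochs. Population-burst frames are
#' planted inside NREM at `frame_rate` per minute. A `seq_frame_fraction` of
#' frames emit spikes from a template-ordered virtual trajectory advancing
#' `seq_compression * track_length` per 20-ms bin (forward or reverse);
#' remaining frames draw per-unit counts from Poisson rates elevated for the
#' frame's planted cluster's participating-cell subset. Planted assemblies
#' reactivate in a random subset of frames by co-firing within one shared
#' 20-ms bin. All labels are recorded in `frame_truth`.
#'
#' @param config a [generator_config()].
#' @param templates tuning templates used for embedded sequences: an encoding
#'   model, a list of `rate_map`s, or a units x bins rate matrix.
#' @return a `sleep_session`: `spikes`, `epochs` (label/start/end),
#'   `frame_truth`, `duration`, `config`.
#' @export
generate_sleep_session <- function(config, templates) {
  cfg <- config
  stopifnot(inherits(cfg, "generator_config"))
  tpls <- as_template_list(templates, cfg$track_length)
  if (!length(tpls) || !nrow(tpls[[1]]$rates)) {
    stop("templates non-empty required")
  }
  set.seed(substream_seed(cfg$seed, "sleep"))
  n <- cfg$n_cells
  dur <- cfg$sleep_duration

  ## alternating NREM (120 s) / other (30 s) epochs
  starts <- seq(5, dur - 30, by = 150)
  nrem <- cbind(start = starts, end = pmin(starts + 120, dur - 5))
  nrem <- nrem[nrem[, 2] > nrem[, 1], , drop = FALSE]
  other0 <- c(0, nrem[, 2])
  other1 <- c(nrem[, 1], dur)
  epochs <- rbind(
    data.frame(label = "nrem", start = nrem[, 1], end = nrem[, 2]),
    data.frame(label = "other", start = other0, end = other1)[other1 > other0, ])
  epochs <- epochs[order(epochs$start), ]
  nrem_total <- sum(nrem[, 2] - nrem[, 1])

  ## background spiking: low homogeneous Poisson per unit
  base_rate <- stats::runif(n, 0.2, 1)
  spikes <- lapply(seq_len(n), function(i) {
    k <- stats::rpois(1, base_rate[i] * dur)
    sort(stats::runif(k, 0, dur))
  })

  ## cluster membership: disjoint partition of units
  n_cl <- max(1L, cfg$n_clusters_planted)
  cl_members <- split(sample(seq_len(n)), rep_len(seq_len(n_cl), n))

  ## frame placement inside NREM, >= 0.9 s gap between starts
  n_frames <- round(cfg$frame_rate * nrem_total / 60)
  cand <- sort(stats::runif(4 * n_frames, 0, nrem_total))
  keep <- c(TRUE, diff(cand) > 0.95)
  cand <- cand[keep][seq_len(min(n_frames, sum(keep)))]
  ## map the NREM-relative clock onto absolute time
  offs <- c(0, cumsum(nrem[, 2] - nrem[, 1]))
  abs_start <- vapply(cand, function(u) {
    k <- findInterval(u, offs, rightmost.closed = TRUE)
    k <- min(k, nrow(nrem))
    nrem[k, 1] + (u - offs[k])
  }, numeric(1))

  assemblies <- list()
  if (cfg$n_assemblies_planted > 0 && n >= 5 * cfg$n_assemblies_planted) {
    set.seed(substream_seed(cfg$seed, "run"))  # same member draw as the run
    pool <- sample(seq_len(n))
    for (a in seq_len(cfg$n_assemblies_planted)) {
      assemblies[[a]] <- sort(pool[(5 * (a - 1) + 1):(5 * a)])
    }
    set.seed(substream_seed(cfg$seed, "sleep-frames"))
  }

  ft <- data.frame(frame = seq_along(abs_start), start = abs_start,
                   end = NA_real_, template = "none", template_id = NA_integer_,
                   orientation = 0L, cluster = NA_integer_,
                   assembly = NA_integer_)
  for (f in seq_along(abs_start)) {
    t0 <- abs_start[f]
    is_seq <- stats::runif(1) < cfg$seq_frame_fraction
    if (is_seq) {
      tid <- sample(length(tpls), 1)
      tpl <- tpls[[tid]]
      span <- stats::runif(1, 0.5, 0.9)
      n_bins <- max(6L, min(40L, round(span / cfg$seq_compression)))
      o <- sample(c(1L, -1L), 1)
      start_frac <- stats::runif(1, 0, max(0, 1 - n_bins * cfg$seq_compression))
      fracs <- start_frac + (seq_len(n_bins) - 0.5) * cfg$seq_compression
      if (o < 0) fracs <- rev(fracs)
      vpos <- pmin(fracs, 1) * cfg$track_length
      jbin <- pmax(1L, pmin(ncol(tpl$rates),
                            findInterval(vpos, c(tpl$centres, Inf))))
      for (k in seq_len(nrow(tpl$rates))) {
        i <- tpl$unit_ids[k]
        if (is.na(i) || i > n) next
        lam <- tpl$rates[k, jbin] * 0.02 * cfg$seq_gain
        cnt <- stats::rpois(n_bins, lam)
        if (any(cnt > 0)) {
          bt <- t0 + (rep(seq_len(n_bins), cnt) - 1) * 0.02
          spikes[[i]] <- c(spikes[[i]], bt + stats::runif(sum(cnt), 0, 0.02))
        }
      }
      t1 <- t0 + n_bins * 0.02
      ft$template[f] <- "seq"
      ft$template_id[f] <- tid
      ft$orientation[f] <- o
    } else {
      dbins <- sample(8:30, 1)
      t1 <- t0 + dbins * 0.02
      cl <- sample(n_cl, 1)
      members <- cl_members[[cl]]
      for (i in seq_len(n)) {
        lam <- (if (i %in% members) 5 else 0.5) * (t1 - t0) / 0.4
        k <- stats::rpois(1, lam)
        if (k > 0) spikes[[i]] <- c(spikes[[i]], stats::runif(k, t0, t1))
      }
      ft$cluster[f] <- cl
    }
    if (length(assemblies) && stats::runif(1) < 0.5) {
      a <- sample(length(assemblies), 1)
      bin0 <- t0 + 0.02 * (sample(floor((t1 - t0) / 0.02), 1) - 1)
      for (m in assemblies[[a]]) {
        k <- 1 + stats::rpois(1, 1)
        spikes[[m]] <- c(spikes[[m]], stats::runif(k, bin0, bin0 + 0.02))
      }
      ft$assembly[f] <- a
    }
    ft$end[f] <- t1
  }
  spikes <- lapply(spikes, sort)

  structure(list(spikes = spikes, epochs = epochs, frame_truth = ft,
                 clusters = cl_members, assemblies = assemblies,
                 duration = dur, config = cfg),
            class = "sleep_session")
}

#' Generate a band-structured field-potential trace
#'
#' The run segment carries a theta sinusoid at `theta_freq` while the animal
#' moves; the sleep segment carries delta-band (1--4 Hz) noise during NREM, a
#' theta component outside NREM (REM-like), and 140--250 Hz ripple bursts
#' coincident with every planted frame.
#'
#' @param config a [generator_config()].
#' @param run a `run_session` from the same config.
#' @param sleep a `sleep_session` from the same config.
#' @return an `lfp_trace`: `run` and `sleep`, each `time`, `samples`, `fs`.
#' @export
generate_lfp <- function(config, run, sleep) {
  cfg <- config
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(substream_seed(cfg$seed, "lfp"))
  fs <- cfg$lfp_fs

  run_tr <- NULL
  if (length(run$time)) {
    tt <- seq(0, max(run$time), by = 1 / fs)
    mv <- stats::approx(run$time, as.numeric(abs(run$velocity) > 5),
                        xout = tt, method = "constant", rule = 2)$y
    amp <- 0.2 + 0.8 * mv
    x <- amp * sin(2 * pi * cfg$theta_freq * tt) + stats::rnorm(length(tt), 0, 0.3)
    run_tr <- list(time = tt, samples = x, fs = fs)
  }

  tt <- seq(0, sleep$duration, by = 1 / fs)
  delta <- 1.2 * sin(2 * pi * 2 * tt + 2 * pi * stats::runif(1)) +
    0.8 * sin(2 * pi * 3.1 * tt + 2 * pi * stats::runif(1))
  x <- stats::rnorm(length(tt), 0, 0.3)
  in_nrem <- rep(FALSE, length(tt))
  ep <- sleep$epochs
  for (k in which(ep$label == "nrem")) {
    in_nrem[tt >= ep$start[k] & tt < ep$end[k]] <- TRUE
  }
  x[in_nrem] <- x[in_nrem] + delta[in_nrem]
  x[!in_nrem] <- x[!in_nrem] + sin(2 * pi * cfg$theta_freq * tt[!in_nrem])
  for (f in seq_len(nrow(sleep$frame_truth))) {
    i0 <- findInterval(sleep$frame_truth$start[f], tt)
    i1 <- findInterval(sleep$frame_truth$end[f], tt)
    if (i1 > i0) {
      idx <- i0:i1
      w <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
      x[idx] <- x[idx] + 1.5 * w * sin(2 * pi * 180 * tt[idx])
    }
  }
  structure(list(run = run_tr,
                 sleep = list(time = tt, samples = x, fs = fs)),
            class = "lfp_trace")
}

#' Write a synthetic session to flat delimited tables
#'
#' Writes `units.tsv` (unit_id, spike_time_s), `position.tsv`
#' (time_s, x_cm, direction), `epochs.tsv` and the ground-truth tables into
#' `dir`.
#'
#' @param session a `run_session` or `sleep_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  units <- data.frame(
    unit_id = rep(seq_along(session$spikes),
                  vapply(session$spikes, length, integer(1))),
    spike_time_s = unlist(session$spikes))
  utils::write.table(units, file.path(dir, "units.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (inherits(session, "run_session")) {
    pos <- data.frame(time_s = session$time, x_cm = session$position,
                      direction = session$direction)
    utils::write.table(pos, file.path(dir, "position.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(session$ground_truth, file.path(dir, "truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(session$epochs, file.path(dir, "epochs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(session$frame_truth, file.path(dir, "frame_truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
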
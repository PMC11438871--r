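## Memoryless Bayesian position decoding from binned ensemble spiking.
## Under Poisson spiking and unit independence the posterior over L spatial
## bins for a time bin of width tau with counts sp_i is
##   Pr(loc | spk) propto Pr(loc) * prod_i f_i(loc)^sp_i * exp(-tau sum_i f_i(loc))
## with a uniform prior; computed in the log domain and row-normalized.

#' Build a per-direction encoding model
#'
#' Tuning curves f_i are occupancy-normalized firing maps binned at
#' `bin_cm` (1 cm) and smoothed by a `kernel_sd_cm` (5 cm) Gaussian, using
#' samples above `vmin`. Units must have at least `min_spikes` run spikes in
#' the direction (and, when `place_responsive`, a peak rate above 1 Hz) to
#' be included.
#'
#' @param run a `run_session`.
#' @param direction direction label ("fwd"/"bwd"); directions are never
#'   pooled.
#' @param bin_cm spatial bin, cm (default 1).
#' @param kernel_sd_cm Gaussian kernel SD, cm (default 5).
#' @param min_spikes inclusion threshold on run spike count (default 10).
#' @param vmin velocity threshold for the tuning estimate (default 5 cm/s).
#' @param place_responsive additionally require peak rate > 1 Hz.
#' @param rate_floor floor (Hz) added to f_i before logs; set 0 for exact
#'   oracle comparisons.
#' @param laps optional subset of lap indices to build from (cross-validated
#'   decoding); default all laps.
#' @return an `encoding_model`: `f` (units x L matrix, Hz), `bin_centres`,
#'   `included_units`, `direction`, `rate_floor`.
#' @export
build_encoding_model <- function(run, direction = "fwd", bin_cm = 1,
                                 kernel_sd_cm = 5, min_spikes = 10,
                                 vmin = 5, place_responsive = TRUE,
                                 rate_floor = 0.01, laps = NULL) {
  L <- run$config$track_length
  sel_session <- run
  if (!is.null(laps)) {
    lp <- detect_laps(run$time, run$position, L)
    lp <- lp[lp$direction == direction, ][laps, ]
    keep <- rep(FALSE, length(run$time))
    for (r in seq_len(nrow(lp))) {
      keep <- keep | (run$time >= lp$start[r] & run$time <= lp$end[r])
    }
    sel_session <- list(time = run$time[keep], position = run$position[keep],
                        velocity = run$velocity[keep],
                        direction = run$direction[keep], config = run$config)
    sel_session$spikes <- lapply(run$spikes, function(s) {
      s[vapply(s, function(x) any(x >= lp$start & x <= lp$end), logical(1))]
    })
  } else {
    sel_session <- run
  }
  maps <- lapply(seq_along(sel_session$spikes), function(i) {
    compute_rate_map(sel_session$spikes[[i]], sel_session$time,
                     sel_session$position, sel_session$velocity,
                     sel_session$direction, direction, track_length = L,
                     bin_cm = bin_cm, kernel_sd_cm = kernel_sd_cm,
                     vmin = vmin, unit_id = i)
  })
  nsp <- vapply(maps, function(m) m$n_spikes, numeric(1))
  keep <- nsp >= min_spikes
  if (place_responsive) {
    keep <- keep & vapply(maps, function(m) m$peak_rate > 1, logical(1))
  }
  if (!any(keep)) stop("empty-model error: no unit passes the spike filter")
  f <- rate_map_matrix(maps[keep])
  structure(list(f = f, bin_centres = maps[[1]]$bin_centres,
                 bin_cm = bin_cm, included_units = which(keep),
                 direction = direction, rate_floor = rate_floor,
                 track_length = L),
            class = "encoding_model")
}

#' Decode binned spike counts into a posterior over positions
#'
#' @param counts units x T matrix of spike counts for the model's included
#'   units (rows must match `model$included_units` order).
#' @param model an `encoding_model`.
#' @param tau time-bin width, s (0.5 for run, 0.02 for frames).
#' @return a `posterior`: `prob` (T x L, rows sum to 1), `bin_centres`,
#'   `tau`, `uniform_rows` (rows that fell back to uniform).
#' @export
decode_counts <- function(counts, model, tau) {
  stopifnot(tau > 0)
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1)
  f <- pmax(model$f, model$rate_floor)
  stopifnot(nrow(counts) == nrow(f))
  logf <- log(f)
  logf[!is.finite(logf)] <- -Inf
  ## T x L log-likelihood; 0 * -Inf handled as 0 (no spike, silent bin)
  ll <- crossprod(counts, ifelse(is.finite(logf), logf, 0))
  if (any(!is.finite(logf))) {
    bad <- crossprod(counts, (!is.finite(logf)) * 1) > 0
    ll[bad] <- -Inf
  }
  ll <- sweep(ll, 2, tau * colSums(f))
  mx <- apply(ll, 1, max)
  uniform_rows <- !is.finite(mx)
  P <- exp(ll - ifelse(is.finite(mx), mx, 0))
  P[uniform_rows, ] <- 1
  P <- P / rowSums(P)
  structure(list(prob = P, bin_centres = model$bin_centres, tau = tau,
                 uniform_rows = uniform_rows),
            class = "posterior")
}

## Spike counts per unit in arbitrary time-bin edges (s).
bin_spike_counts <- function(spikes, edges) {
  nb <- length(edges) - 1L
  do.call(rbind, lapply(spikes, function(s) {
    if (!length(s)) return(integer(nb))
    tabulate(findInterval(s, edges, rightmost.closed = TRUE,
                          left.open = FALSE)[s >= edges[1] & s < edges[nb + 1L]],
             nb)
  }))
}

#' Run decoding error with a time-bin permutation null
#'
#' Decodes non-overlapping `tau`-second bins during movement (mean speed
#' above `vmin` and direction matching the model), takes the location of
#' maximum posterior probability as the point estimate (ties toward the
#' lower bin), and summarizes the absolute error to the animal's mean
#' position per bin. Significance: the data median must fall below the 5th
#' percentile of medians from `n_shuffles` permutations of the decoded
#' posterior rows in time.
#'
#' @param run a `run_session`.
#' @param model an `encoding_model` (same or held-out laps).
#' @param tau time bin, s (default 0.5).
#' @param vmin movement threshold, cm/s (default 10).
#' @param n_shuffles time-bin permutations (default 500).
#' @param seed RNG seed for the permutations.
#' @return list: `median_error`, `errors`, `shuffle_medians`, `significant`,
#'   `n_bins`.
#' @export
run_decoding_error <- function(run, model, tau = 0.5, vmin = 10,
                               n_shuffles = 500, seed = 1L) {
  if (!length(run$time)) stop("insufficient-data error: empty session")
  dt <- stats::median(diff(run$time))
  edges <- seq(0, max(run$time), by = tau)
  if (length(edges) < 3) stop("insufficient-data error: session too short")
  idx <- findInterval(run$time, edges, rightmost.closed = TRUE)
  ok_bin <- function(b) {
    s <- idx == b
    any(s) && mean(abs(run$velocity[s])) > vmin &&
      mean(run$direction[s] == model$direction) > 0.5
  }
  bins <- which(vapply(seq_len(length(edges) - 1L), ok_bin, logical(1)))
  if (!length(bins)) stop("insufficient-data error: no movement bins")
  true_pos <- vapply(bins, function(b) mean(run$position[idx == b]), numeric(1))
  counts <- bin_spike_counts(run$spikes[model$included_units], edges)[, bins,
                                                                      drop = FALSE]
  post <- decode_counts(counts, model, tau)
  dec <- model$bin_centres[max.col(post$prob, ties.method = "first")]
  errors <- abs(dec - true_pos)
  set.seed(substream_seed(seed, "run-decode-shuffle"))
  shuffle_medians <- vapply(seq_len(n_shuffles), function(k) {
    stats::median(abs(dec[sample(length(dec))] - true_pos))
  }, numeric(1))
  med <- stats::median(errors)
  list(median_error = med, errors = errors,
       shuffle_medians = shuffle_medians,
       significant = med < stats::quantile(shuffle_medians, 0.05),
       n_bins = length(bins))
}
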
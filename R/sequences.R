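## Trajectory-sequence quantification for decoded frames: weighted space-time
## correlation, its circular-linear variant, the shuffle-normalized sequence
## score, jump distances, the within-frame time-bin permutation null, frame
## significance proportions, joint threshold grids, track-specific events,
## robustness variants and the theta quadrant ratio.

as_post_matrix <- function(post) {
  if (inherits(post, "posterior")) post$prob else as.matrix(post)
}

post_locations <- function(post, loc) {
  if (!is.null(loc)) return(loc)
  if (inherits(post, "posterior")) post$bin_centres else
    seq_len(ncol(as_post_matrix(post)))
}

#' Weighted space-time correlation of a decoded frame
#'
#' Product-moment correlation between time-bin index and spatial location,
#' weighted by the posterior probabilities: with weighted means
#' \eqn{m_{loc}, m_t}, weighted covariances
#' \eqn{covar(loc,t) = \sum_{ij} Pr_{ij}(loc_j - m_{loc})(t_i - m_t) / \sum_{ij} Pr_{ij}}
#' and \eqn{r = covar(loc,t)/\sqrt{covar(loc,loc)\,covar(t,t)}}.
#' A frame with zero weighted variance in time or space is degenerate and
#' returns 0 with attribute `degenerate`.
#'
#' @param post a `posterior` or a T x L probability matrix.
#' @param loc optional spatial coordinates per column.
#' @param t optional temporal coordinates per row.
#' @return the weighted correlation in `[-1, 1]`.
#' @export
weighted_correlation <- function(post, loc = NULL, t = NULL) {
  P <- as_post_matrix(post)
  if (nrow(P) < 2) stop("frame needs at least 2 time bins")
  loc <- post_locations(post, loc)
  if (is.null(t)) t <- seq_len(nrow(P))
  W <- sum(P)
  cs <- colSums(P); rs <- rowSums(P)
  m_loc <- sum(cs * loc) / W
  m_t <- sum(rs * t) / W
  cov_lt <- sum((t - m_t) * (P %*% (loc - m_loc))) / W
  cov_ll <- sum(cs * (loc - m_loc)^2) / W
  cov_tt <- sum(rs * (t - m_t)^2) / W
  den <- sqrt(cov_ll * cov_tt)
  if (!is.finite(den) || den < 1e-12 || rows_constant(P)) {
    return(structure(0, degenerate = TRUE))
  }
  cov_lt / den
}

## A posterior whose rows are all (numerically) identical -- e.g. uniform --
## is invariant under any time-bin permutation: the correlation is 0 by
## symmetry and no shuffle test is possible. Such frames are degenerate.
rows_constant <- function(P) {
  max(abs(sweep(P, 2, P[1, ]))) < 1e-12
}

## Weighted correlations over n time-bin permutations of a row-stochastic
## posterior. Exploits that for rows with equal mass only the pairing of the
## per-row location means a_i with the times changes under permutation, so
## each shuffle costs O(T). Falls back to full recomputation otherwise.
shuffled_weighted_correlations <- function(post, n, loc = NULL) {
  P <- as_post_matrix(post)
  loc <- post_locations(post, loc)
  t <- seq_len(nrow(P))
  rs <- rowSums(P)
  if (max(abs(rs - rs[1])) > 1e-9) {
    return(vapply(seq_len(n), function(k)
      as.numeric(weighted_correlation(P[sample(nrow(P)), , drop = FALSE],
                                      loc = loc)), numeric(1)))
  }
  W <- sum(P)
  cs <- colSums(P)
  m_loc <- sum(cs * loc) / W
  m_t <- sum(rs * t) / W
  a <- as.numeric(P %*% (loc - m_loc))
  cc <- t - m_t
  cov_ll <- sum(cs * (loc - m_loc)^2) / W
  cov_tt <- sum(rs * cc^2) / W
  den <- W * sqrt(cov_ll * cov_tt)
  if (!is.finite(den) || den < 1e-12) return(rep(0, n))
  Tn <- nrow(P)
  vapply(seq_len(n), function(k) sum(cc * a[sample(Tn)]) / den, numeric(1))
}

#' Circular-linear weighted correlation of a decoded frame
#'
#' Treats location as an angle (2 pi loc / track span) so that trajectories
#' wrapping across the track ends remain coherent. Implemented as the
#' posterior-weighted form of the standard circular-linear coefficient (the
#' square root of R^2 from the sine/cosine regression of angle on time),
#' signed by the fitted direction of angular drift.
#'
#' @inheritParams weighted_correlation
#' @return signed circular-linear correlation, `|r_circ|` in `[0, 1]`.
#' @export
circular_weighted_correlation <- function(post, loc = NULL, t = NULL) {
  P <- as_post_matrix(post)
  if (nrow(P) < 2) stop("frame needs at least 2 time bins")
  loc <- post_locations(post, loc)
  if (is.null(t)) t <- seq_len(nrow(P))
  span <- max(loc) - min(loc) + (if (length(loc) > 1) diff(loc)[1] else 1)
  th <- 2 * pi * (loc - min(loc)) / span
  W <- sum(P); cs <- colSums(P); rs <- rowSums(P)
  s <- sin(th); co <- cos(th)
  m <- function(colv) sum(cs * colv) / W
  mt <- sum(rs * t) / W
  cross_t <- function(colv) sum((t - mt) * (P %*% (colv - m(colv)))) / W
  col_cov <- function(u, v) sum(cs * (u - m(u)) * (v - m(v))) / W
  var_t <- sum(rs * (t - mt)^2) / W
  v_s <- col_cov(s, s); v_c <- col_cov(co, co)
  if (var_t < 1e-12 || v_s < 1e-12 || v_c < 1e-12 || rows_constant(P)) {
    return(structure(0, degenerate = TRUE))
  }
  r_ts <- cross_t(s) / sqrt(var_t * v_s)
  r_tc <- cross_t(co) / sqrt(var_t * v_c)
  r_cs <- col_cov(co, s) / sqrt(v_c * v_s)
  R2 <- (r_tc^2 + r_ts^2 - 2 * r_tc * r_ts * r_cs) / (1 - r_cs^2)
  r_circ <- sqrt(max(0, min(1, R2)))
  b_s <- cross_t(s) / var_t
  b_c <- cross_t(co) / var_t
  drift <- b_s * m(co) - b_c * m(s)
  if (drift < 0) r_circ <- -r_circ
  r_circ
}

#' Per-frame sequence statistics with a time-bin shuffle null
#'
#' Computes the weighted correlation r, the circular-linear variant, the
#' sequence score \eqn{r_Z = (|r| - mean|r_{shuf}|) / sd|r_{shuf}|}, the
#' median and maximum jump distance (absolute displacement of the per-bin
#' maximum-posterior location between consecutive 20-ms bins, as a fraction
#' of track length) and two-sided shuffle significance: forward if r exceeds
#' the 97.5th, reverse if below the 2.5th percentile of the shuffled r.
#' Frames with fewer than `min_bins` bins are skipped with a reason code;
#' degenerate frames count as non-significant.
#'
#' @param post a `posterior` or T x L matrix (one frame).
#' @param n_shuffles within-frame time-bin permutations (default 500).
#' @param seed RNG seed for this frame's shuffles.
#' @param track_length track length in the units of the location axis.
#' @param min_bins minimum number of time bins (default 5).
#' @param forward_q,reverse_q percentile cutoffs (defaults 0.975 / 0.025).
#' @return list of statistics (class `sequence_stats`).
#' @export
sequence_metrics <- function(post, n_shuffles = 500, seed = 1L,
                             track_length = NULL, min_bins = 5,
                             forward_q = 0.975, reverse_q = 0.025) {
  P <- as_post_matrix(post)
  if (nrow(P) < min_bins) {
    return(structure(list(skipped = TRUE, reason = "too_few_bins",
                          n_bins = nrow(P)), class = "sequence_stats"))
  }
  loc <- post_locations(post, NULL)
  if (is.null(track_length)) {
    track_length <- max(loc) - min(loc) + (if (length(loc) > 1) diff(loc)[1] else 1)
  }
  r <- weighted_correlation(P, loc = loc)
  degenerate <- isTRUE(attr(r, "degenerate"))
  r_circ <- circular_weighted_correlation(P, loc = loc)
  set.seed(substream_seed(seed, "frame-shuffle"))
  r_sh <- shuffled_weighted_correlations(P, n_shuffles, loc = loc)
  sd_abs <- stats::sd(abs(r_sh))
  r_z <- if (is.finite(sd_abs) && sd_abs > 0) {
    (abs(r) - mean(abs(r_sh))) / sd_abs
  } else NA_real_
  peaks <- loc[max.col(P, ties.method = "first")]
  jumps <- abs(diff(peaks)) / track_length
  sig_f <- !degenerate && r > stats::quantile(r_sh, forward_q)
  sig_r <- !degenerate && r < stats::quantile(r_sh, reverse_q)
  structure(list(skipped = FALSE, r = as.numeric(r),
                 r_circ = as.numeric(r_circ), r_z = r_z,
                 median_jump = stats::median(jumps), max_jump = max(jumps),
                 n_bins = nrow(P), degenerate = degenerate,
                 sig_forward = sig_f, sig_reverse = sig_r,
                 significant = sig_f || sig_r,
                 shuffle_r = r_sh),
            class = "sequence_stats")
}

## Collect per-frame sequence stats into a table.
stats_table <- function(stat_list) {
  keep <- !vapply(stat_list, function(s) isTRUE(s$skipped), logical(1))
  rows <- lapply(which(keep), function(k) {
    s <- stat_list[[k]]
    data.frame(frame = k, r = s$r, r_circ = s$r_circ, r_z = s$r_z,
               median_jump = s$median_jump, max_jump = s$max_jump,
               n_bins = s$n_bins, degenerate = s$degenerate,
               sig_forward = s$sig_forward, sig_reverse = s$sig_reverse,
               significant = s$significant)
  })
  if (!length(rows)) {
    return(data.frame(frame = integer(0), r = numeric(0), r_circ = numeric(0),
                      r_z = numeric(0), median_jump = numeric(0),
                      max_jump = numeric(0), n_bins = integer(0),
                      degenerate = logical(0), sig_forward = logical(0),
                      sig_reverse = logical(0), significant = logical(0)))
  }
  do.call(rbind, rows)
}

#' Classify decoded frames and test the significant proportion against chance
#'
#' Applies [sequence_metrics()] to every frame and reports the proportion of
#' significant frames together with the three chance comparisons: (1) the
#' proportion observed in a time-bin shuffled dataset passed through the
#' same procedure, (2) a binomial test against the nominal chance level,
#' (3) the t-type comparison is left to the caller across rat-directions
#' (per-session proportions are what this function returns).
#'
#' @param posteriors list of per-frame posteriors (or matrices).
#' @param n_shuffles shuffles per frame (default 500).
#' @param seed root seed; per-frame shuffle seeds are derived from it.
#' @param chance nominal chance level (default 0.05).
#' @param shuffled_dataset also run one time-bin-shuffled copy of every
#'   frame through the identical procedure (default TRUE).
#' @param ... passed to [sequence_metrics()].
#' @return list: `table` (per-frame stats), `proportion`, `n_significant`,
#'   `n_frames`, `binomial_p`, `shuffle_proportion`.
#' @export
classify_frames <- function(posteriors, n_shuffles = 500, seed = 1L,
                            chance = 0.05, shuffled_dataset = TRUE, ...) {
  if (!length(posteriors)) stop("zero frames: proportion undefined")
  stats_l <- lapply(seq_along(posteriors), function(k) {
    sequence_metrics(posteriors[[k]], n_shuffles = n_shuffles,
                     seed = substream_seed(seed, paste0("frame", k)), ...)
  })
  tab <- stats_table(stats_l)
  n_sig <- sum(tab$significant)
  n_tot <- nrow(tab)
  prop <- if (n_tot) n_sig / n_tot else NA_real_
  binp <- if (n_tot) stats::binom.test(n_sig, n_tot, chance,
                                       alternative = "greater")$p.value else NA
  shuf_prop <- NA_real_
  if (shuffled_dataset && n_tot) {
    set.seed(substream_seed(seed, "dataset-shuffle"))
    shuf_posts <- lapply(posteriors, function(p) {
      P <- as_post_matrix(p)
      P[sample(nrow(P)), , drop = FALSE]
    })
    shuf_stats <- lapply(seq_along(shuf_posts), function(k) {
      sequence_metrics(shuf_posts[[k]], n_shuffles = n_shuffles,
                       seed = substream_seed(seed, paste0("shufframe", k)), ...)
    })
    stab <- stats_table(shuf_stats)
    shuf_prop <- if (nrow(stab)) mean(stab$significant) else NA_real_
  }
  list(table = tab, proportion = prop, n_significant = n_sig,
       n_frames = n_tot, binomial_p = binp, shuffle_proportion = shuf_prop)
}

#' Joint threshold-grid comparison of sequence statistics
#'
#' Two printed grids. `"score_jump"`: sequence-score thresholds (no
#' threshold, then 0 to 2.8 in steps of 0.4, increasing) crossed with
#' median-jump thresholds (0.125 to 1 in steps of 0.125, decreasing
#' stringency), proportions of frames passing both compared between two
#' populations by a one-sided two-proportion z-test. `"corr_maxjump"`:
#' absolute-weighted-correlation thresholds (0 to 0.9 by 0.1) crossed with
#' maximum-jump thresholds (0.1 to 1 by 0.1); the data proportion is ranked
#' against the same proportion in surrogate datasets and p = 1 - percentile.
#'
#' @param statsA data-frame of frame stats (from [classify_frames()]
#'   `$table`).
#' @param statsB for `"score_jump"` a second stats table; for
#'   `"corr_maxjump"` a list of surrogate stats tables.
#' @param mode `"score_jump"` or `"corr_maxjump"`.
#' @return list with threshold vectors, proportion matrices and the p-value
#'   matrix.
#' @export
joint_threshold_comparison <- function(statsA, statsB,
                                       mode = c("score_jump", "corr_maxjump")) {
  mode <- match.arg(mode)
  if (!nrow(statsA)) stop("empty stat set")
  if (mode == "score_jump") {
    if (!nrow(statsB)) stop("empty stat set")
    s_thr <- c(-Inf, seq(0, 2.8, by = 0.4))
    j_thr <- seq(0.125, 1, by = 0.125)
    pass <- function(tab, s, j) sum(tab$r_z > s & tab$median_jump < j,
                                    na.rm = TRUE)
    p <- propA <- propB <- matrix(NA_real_, length(s_thr), length(j_thr),
                                  dimnames = list(paste0("rz>", s_thr),
                                                  paste0("jump<", j_thr)))
    for (a in seq_along(s_thr)) for (b in seq_along(j_thr)) {
      xa <- pass(statsA, s_thr[a], j_thr[b])
      xb <- pass(statsB, s_thr[a], j_thr[b])
      propA[a, b] <- xa / nrow(statsA)
      propB[a, b] <- xb / nrow(statsB)
      p[a, b] <- two_proportion_z(xa, nrow(statsA), xb, nrow(statsB))$p.value
    }
    return(list(mode = mode, score_thresholds = s_thr,
                jump_thresholds = j_thr, propA = propA, propB = propB,
                p = p))
  }
  ## corr_maxjump: statsB is a list of surrogate tables
  if (!length(statsB)) stop("empty stat set")
  r_thr <- seq(0, 0.9, by = 0.1)
  m_thr <- seq(0.1, 1, by = 0.1)
  prop_of <- function(tab, r0, m0) mean(abs(tab$r) > r0 & tab$max_jump < m0,
                                        na.rm = TRUE)
  p <- propA <- matrix(NA_real_, length(r_thr), length(m_thr),
                       dimnames = list(paste0("|r|>", r_thr),
                                       paste0("maxjump<", m_thr)))
  for (a in seq_along(r_thr)) for (b in seq_along(m_thr)) {
    da <- prop_of(statsA, r_thr[a], m_thr[b])
    sur <- vapply(statsB, prop_of, numeric(1), r0 = r_thr[a], m0 = m_thr[b])
    propA[a, b] <- da
    p[a, b] <- 1 - shuffle_percentile(da, sur)
  }
  list(mode = mode, r_thresholds = r_thr, maxjump_thresholds = m_thr,
       propA = propA, p = p)
}

#' Proportion of frames with track-specific sequences
#'
#' A frame counts as track-specific when it is significant for exactly one
#' of the supplied tracks and non-significant for all others. Shuffled
#' frames must pass the same two criteria.
#'
#' @param sig_matrix logical frames x tracks matrix of per-track
#'   significance.
#' @return list: `proportion`, `n_specific`, `per_track` counts.
#' @export
track_specific_events <- function(sig_matrix) {
  sig_matrix <- as.matrix(sig_matrix)
  if (ncol(sig_matrix) < 2) stop("at least 2 track models required")
  hits <- rowSums(sig_matrix) == 1
  per_track <- colSums(sig_matrix & hits)
  list(proportion = mean(hits), n_specific = sum(hits),
       n_frames = nrow(sig_matrix), per_track = per_track)
}

## Truncate an encoding model's place-map activity in a spatial zone (cm).
truncate_model <- function(model, zone) {
  sel <- model$bin_centres >= zone[1] & model$bin_centres <= zone[2]
  m <- model
  m$f[, sel] <- 0
  m
}

#' Robustness variants for frame-sequence significance
#'
#' Recomputes significant-frame proportions under a perturbation:
#' `bin_removal_start_end` removes 0--3 time bins from the frame start or
#' end (cumulative significant proportion: originally significant frames
#' plus frames newly significant after removal; frames must keep >= 5
#' bins); `bin_removal_middle` removes bins from the frame middle;
#' `map_truncation_ends` zeroes the encoding model's place-map activity
#' within 0--30 cm of one track end at a time before decoding;
#' `map_truncation_middle` zeroes a 30-cm middle zone;
#' `poisson_surrogate_single` rebuilds every frame from rate-matched
#' homogeneous Poisson counts and reruns the identical analysis;
#' `poisson_surrogate_500` generates `n_surrogates` such datasets and
#' returns their per-frame r / max-jump tables for grid comparison.
#'
#' @param frame_counts list of per-frame spike-count matrices (model units x
#'   20-ms bins).
#' @param model an `encoding_model`.
#' @param variant one of the six variant names.
#' @param tau frame bin width, s (default 0.02).
#' @param n_shuffles per-frame shuffles (default 500).
#' @param seed root seed.
#' @param n_surrogates surrogate count for `poisson_surrogate_500`.
#' @return variant-specific list; all include what is needed for pooled
#'   two-proportion comparison (counts and totals).
#' @export
robustness_suite <- function(frame_counts, model,
                             variant = c("bin_removal_start_end",
                                         "bin_removal_middle",
                                         "map_truncation_ends",
                                         "map_truncation_middle",
                                         "poisson_surrogate_single",
                                         "poisson_surrogate_500"),
                             tau = 0.02, n_shuffles = 500, seed = 1L,
                             n_surrogates = 500) {
  variant <- match.arg(variant)
  decode_all <- function(counts_list, mdl) {
    lapply(counts_list, function(cc) decode_counts(cc, mdl, tau))
  }
  classify <- function(posts, tag) {
    classify_frames(posts, n_shuffles = n_shuffles,
                    seed = substream_seed(seed, tag),
                    shuffled_dataset = FALSE)
  }
  base_posts <- decode_all(frame_counts, model)
  base <- classify(base_posts, "base")

  if (variant %in% c("bin_removal_start_end", "bin_removal_middle")) {
    sides <- if (variant == "bin_removal_start_end") c("start", "end") else "middle"
    out <- list()
    for (side in sides) {
      sig_cum <- base$table$significant
      frames_used <- base$table$frame
      rows <- data.frame(k = 0L, side = side,
                         prop = mean(sig_cum), n = length(sig_cum))
      for (k in 1:3) {
        trimmed <- lapply(frame_counts, function(cc) {
          Tn <- ncol(cc)
          if (Tn - k < 5) return(NULL)
          idx <- switch(side,
                        start = (k + 1):Tn,
                        end = 1:(Tn - k),
                        middle = {
                          mid <- ceiling(Tn / 2)
                          drop <- (mid - floor((k - 1) / 2)):(mid + ceiling((k - 1) / 2))
                          setdiff(1:Tn, drop)
                        })
          cc[, idx, drop = FALSE]
        })
        keep <- !vapply(trimmed, is.null, logical(1))
        res <- classify(decode_all(trimmed[keep], model),
                        paste0(side, k))
        new_sig <- logical(length(frame_counts))
        new_sig[which(keep)[res$table$frame]] <- res$table$significant
        sig_cum <- sig_cum | new_sig[frames_used]
        rows <- rbind(rows, data.frame(k = k, side = side,
                                       prop = mean(sig_cum),
                                       n = length(sig_cum)))
      }
      out[[side]] <- rows
    }
    return(list(variant = variant, baseline = base,
                cumulative = do.call(rbind, out)))
  }

  if (variant %in% c("map_truncation_ends", "map_truncation_middle")) {
    L <- model$track_length
    zones <- if (variant == "map_truncation_ends") {
      list(low_end = c(0, 30), high_end = c(L - 30, L))
    } else {
      list(middle = c(L / 2 - 15, L / 2 + 15))
    }
    res <- lapply(names(zones), function(z) {
      classify(decode_all(frame_counts, truncate_model(model, zones[[z]])), z)
    })
    names(res) <- names(zones)
    return(list(variant = variant, baseline = base, truncated = res))
  }

  ## Poisson surrogates: rate-matched homogeneous counts per unit
  mean_rate <- rowMeans(do.call(cbind, lapply(frame_counts, function(cc) {
    rowSums(cc) / (ncol(cc) * tau)
  })))
  make_surrogate <- function() {
    lapply(frame_counts, function(cc) {
      matrix(stats::rpois(length(cc), mean_rate * tau), nrow = nrow(cc))
    })
  }
  if (variant == "poisson_surrogate_single") {
    set.seed(substream_seed(seed, "poisson1"))
    sur <- classify(decode_all(make_surrogate(), model), "poisson1")
    return(list(variant = variant, baseline = base, surrogate = sur))
  }
  set.seed(substream_seed(seed, "poisson500"))
  sur_tabs <- lapply(seq_len(n_surrogates), function(s) {
    posts <- decode_all(make_surrogate(), model)
    stats_table(lapply(posts, function(p) {
      P <- p$prob
      if (nrow(P) < 5) return(list(skipped = TRUE))
      loc <- p$bin_centres
      r <- weighted_correlation(P, loc = loc)
      peaks <- loc[max.col(P, ties.method = "first")]
      list(skipped = FALSE, r = as.numeric(r), r_circ = NA_real_,
           r_z = NA_real_, median_jump = stats::median(abs(diff(peaks))) /
             model$track_length,
           max_jump = max(abs(diff(peaks))) / model$track_length,
           n_bins = nrow(P), degenerate = isTRUE(attr(r, "degenerate")),
           sig_forward = NA, sig_reverse = NA, significant = NA)
    }))
  })
  list(variant = variant, baseline = base, surrogate_tables = sur_tabs)
}

#' Quadrant ratio of a space-time decoded matrix
#'
#' Splits the animal-centred decoded matrix into four quadrants around its
#' centre (centre row/column excluded when odd) and returns
#' \eqn{(Q1 + Q3 - Q2 - Q4) / (Q1 + Q2 + Q3 + Q4)}, with Q1 the
#' ahead-in-space/future-in-time and Q3 the behind/past quadrant.
#'
#' @param mat time x relative-location probability matrix, time centred on
#'   the theta trough and location centred on the animal.
#' @return quadrant ratio in `[-1, 1]`.
#' @export
quadrant_ratio <- function(mat) {
  Tn <- nrow(mat); Ln <- ncol(mat)
  tlo <- seq_len(floor(Tn / 2)); thi <- (Tn - floor(Tn / 2) + 1):Tn
  xlo <- seq_len(floor(Ln / 2)); xhi <- (Ln - floor(Ln / 2) + 1):Ln
  q1 <- sum(mat[thi, xhi]); q3 <- sum(mat[tlo, xlo])
  q2 <- sum(mat[tlo, xhi]); q4 <- sum(mat[thi, xlo])
  tot <- q1 + q2 + q3 + q4
  if (tot == 0) return(0)
  (q1 + q3 - q2 - q4) / tot
}

#' Theta quadrant ratio over cycles with a time-bin shuffle test
#'
#' Averages animal-centred cycle matrices (equal weight per cycle), keeps
#' the 100-ms window centred on the trough (5 of the 20-ms rows), computes
#' the quadrant ratio, and compares it with `n_shuffles` datasets in which
#' each cycle's time bins are independently permuted before averaging.
#' Significant when the ratio exceeds the 95th shuffle percentile.
#'
#' @param cycle_mats list of equally sized time x relative-location
#'   matrices (rows: 20-ms bins across the 400-ms cycle window; columns:
#'   +/- 30 cm around the animal).
#' @param n_shuffles default 500.
#' @param seed RNG seed.
#' @param window_bins rows kept around the trough (default 5 = 100 ms).
#' @return list: `qr`, `shuffle_qr`, `percentile`, `significant`.
#' @export
theta_quadrant_ratio <- function(cycle_mats, n_shuffles = 500, seed = 1L,
                                 window_bins = 5L) {
  if (!length(cycle_mats)) stop("no cycles")
  Tn <- nrow(cycle_mats[[1]])
  mid <- ceiling(Tn / 2)
  half <- floor(window_bins / 2)
  rows <- max(1, mid - half):min(Tn, mid + half)
  avg <- Reduce(`+`, cycle_mats) / length(cycle_mats)
  qr_obs <- quadrant_ratio(avg[rows, , drop = FALSE])
  set.seed(substream_seed(seed, "theta-shuffle"))
  qr_sh <- vapply(seq_len(n_shuffles), function(k) {
    sh <- Reduce(`+`, lapply(cycle_mats, function(m)
      m[sample(Tn), , drop = FALSE])) / length(cycle_mats)
    quadrant_ratio(sh[rows, , drop = FALSE])
  }, numeric(1))
  pct <- shuffle_percentile(qr_obs, qr_sh)
  list(qr = qr_obs, shuffle_qr = qr_sh, percentile = pct,
       significant = qr_obs > stats::quantile(qr_sh, 0.95))
}

#' Centre a decoded cycle posterior on the animal's position
#'
#' Shifts columns so the animal's spatial bin sits at the centre of a
#' `2 * half_bins + 1` wide window; positions outside the track contribute
#' zero probability.
#'
#' @param post a `posterior` or T x L matrix for one theta cycle.
#' @param animal_bin the animal's spatial bin index.
#' @param half_bins half-window in spatial bins (default 30 bins = 30 cm at
#'   1 cm).
#' @return T x (2*half_bins+1) matrix of relative-location probabilities.
#' @export
centred_cycle_matrix <- function(post, animal_bin, half_bins = 30L) {
  P <- as_post_matrix(post)
  Ln <- ncol(P)
  out <- matrix(0, nrow(P), 2L * half_bins + 1L)
  for (kk in -half_bins:half_bins) {
    j <- animal_bin + kk
    if (j >= 1 && j <= Ln) out[, kk + half_bins + 1L] <- P[, j]
  }
  out
}
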
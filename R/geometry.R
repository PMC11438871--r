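## Population-vector geometry of linear space: location-by-location PV
## correlation matrices, track-end similarity, the symmetric-location warp
## profile, manifold PCA, pattern separation across tracks, and the T-1
## time-space contingency / end-specificity analysis of decoded frames.

#' Location-by-location population-vector correlation matrix
#'
#' Stacks all rate maps (2-cm bins) and correlates the population vector at
#' every location with every other location (Pearson, across units).
#' Locations whose population vector has zero variance (e.g. never covered)
#' get NA rows/columns and are flagged.
#'
#' @param maps list of `rate_map`s or a units x bins rate matrix.
#' @return a `pv_matrix`: `corr` (L x L), `undefined_bins`, `bin_centres`.
#' @export
pv_matrix <- function(maps) {
  R <- if (is.matrix(maps)) maps else rate_map_matrix(maps)
  if (nrow(R) < 2) stop("need >= 2 units")
  centres <- if (!is.matrix(maps)) maps[[1]]$bin_centres else
    seq_len(ncol(R)) * 2 - 1
  sds <- apply(R, 2, stats::sd)
  corr <- suppressWarnings(stats::cor(R))
  corr[sds == 0, ] <- NA
  corr[, sds == 0] <- NA
  structure(list(corr = corr, undefined_bins = which(sds == 0),
                 bin_centres = centres),
            class = "pv_matrix")
}

#' Similarity of the two track ends
#'
#' Mean PV correlation between every pair of bins drawn from the two
#' end zones (each `end_fraction` of the track length).
#'
#' @param maps rate maps (list or matrix) or a `pv_matrix`.
#' @param end_fraction end-zone fraction of track length (default 0.15).
#' @return mean correlation.
#' @export
track_end_similarity <- function(maps, end_fraction = 0.15) {
  pv <- if (inherits(maps, "pv_matrix")) maps else pv_matrix(maps)
  L <- ncol(pv$corr)
  k <- max(1L, floor(L * end_fraction))
  if (2 * k >= L) stop("end zones cover the whole track")
  sub <- pv$corr[seq_len(k), (L - k + 1):L, drop = FALSE]
  mean(sub, na.rm = TRUE)
}

#' Symmetric-location warp profile
#'
#' Pairs two-bin (4-cm) segments placed symmetrically about the track
#' middle, excluding the terminal two-bin segments, and records the mean PV
#' correlation between each segment and its mirror against their
#' separation. Reports the Pearson R and least-squares slope over
#' separations of `fit_range` (default 24--88 cm): warped (mirror-symmetric)
#' representations give a positive slope, linear ones a flat or negative
#' slope.
#'
#' @param maps rate maps (list or matrix of 2-cm binned rates).
#' @param bin_cm spatial bin width of the maps (default 2).
#' @param fit_range separations (cm) used for the R/slope fit.
#' @return a `warp_profile`: `profile` (separation_cm, correlation), `R`,
#'   `R_p`, `slope`, `dropped_segments`.
#' @export
warp_profile <- function(maps, bin_cm = 2, fit_range = c(24, 88)) {
  pv <- if (inherits(maps, "pv_matrix")) maps else pv_matrix(maps)
  L <- ncol(pv$corr)
  half <- floor(L / 2)
  n_seg <- floor(half / 2)
  rows <- list()
  dropped <- 0L
  ## segment s (1 = innermost) occupies bins on each side of the middle
  for (s in seq_len(n_seg - 1L)) {          # exclude the terminal segment
    left <- (half - 2 * s + 1):(half - 2 * s + 2)
    right <- (half + 2 * s - 1):(half + 2 * s)
    right <- right[right <= L]
    vals <- pv$corr[left, right]
    if (all(is.na(vals))) { dropped <- dropped + 1L; next }
    sep <- mean(pv$bin_centres[right]) - mean(pv$bin_centres[left])
    rows[[length(rows) + 1L]] <-
      data.frame(separation_cm = sep, correlation = mean(vals, na.rm = TRUE))
  }
  prof <- do.call(rbind, rows)
  sel <- prof$separation_cm >= fit_range[1] & prof$separation_cm <= fit_range[2]
  fitR <- NA_real_; fitP <- NA_real_; slope <- NA_real_
  if (sum(sel) >= 3 && stats::sd(prof$correlation[sel]) > 0) {
    ct <- suppressWarnings(stats::cor.test(prof$separation_cm[sel],
                                           prof$correlation[sel]))
    fitR <- unname(ct$estimate); fitP <- ct$p.value
    slope <- unname(stats::coef(stats::lm(correlation ~ separation_cm,
                                          data = prof[sel, ]))[2])
  }
  structure(list(profile = prof, R = fitR, R_p = fitP, slope = slope,
                 dropped_segments = dropped),
            class = "warp_profile")
}

#' Pool warp profiles across animals/directions and refit
#'
#' Averages the symmetric-segment correlations of several [warp_profile()]s
#' at matched separations (the group-effect variant) and recomputes the
#' Pearson R and least-squares slope over the same separation range.
#'
#' @param profiles list of `warp_profile`s.
#' @param fit_range separations (cm) used for the fit.
#' @return a `warp_profile` on the pooled means.
#' @export
pool_warp_profiles <- function(profiles, fit_range = c(24, 88)) {
  all_prof <- do.call(rbind, lapply(profiles, function(p) p$profile))
  agg <- stats::aggregate(correlation ~ separation_cm, all_prof, mean)
  sel <- agg$separation_cm >= fit_range[1] & agg$separation_cm <= fit_range[2]
  fitR <- NA_real_; fitP <- NA_real_; slope <- NA_real_
  if (sum(sel) >= 3 && stats::sd(agg$correlation[sel]) > 0) {
    ct <- suppressWarnings(stats::cor.test(agg$separation_cm[sel],
                                           agg$correlation[sel]))
    fitR <- unname(ct$estimate); fitP <- ct$p.value
    slope <- unname(stats::coef(stats::lm(correlation ~ separation_cm,
                                          data = agg[sel, ]))[2])
  }
  structure(list(profile = agg, R = fitR, R_p = fitP, slope = slope,
                 dropped_segments = 0L),
            class = "warp_profile")
}

#' Manifold PCA of the population place-map activity
#'
#' Min-max normalizes each spatial bin's population vector (the maximally
#' active unit set to 1), then PCA over locations; returns the 3-D
#' embedding of the track and the cumulative variance curve.
#'
#' @param maps rate maps (list or matrix).
#' @return list: `coords` (locations x 3), `cum_variance`, `dropped_bins`.
#' @export
manifold_pca <- function(maps) {
  R <- if (is.matrix(maps)) maps else rate_map_matrix(maps)
  if (nrow(R) < 4) stop("need >= 4 units")
  mx <- apply(R, 2, max)
  drop <- mx == 0
  Rn <- sweep(R[, !drop, drop = FALSE], 2, mx[!drop], "/")
  pc <- stats::prcomp(t(Rn), center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  list(coords = pc$x[, seq_len(min(3, ncol(pc$x))), drop = FALSE],
       cum_variance = cumsum(v) / sum(v), dropped_bins = which(drop))
}

#' Pattern separation of two tracks
#'
#' `mode = "full"`: PV correlation at every matched location between the two
#' stacked map sets, with a chance distribution from `n_shuffles` cell-ID
#' shuffles of one map set. `mode = "corners"` / `"middles"`: correlation of
#' the 10-bin (20-cm) windows centred on opposite track ends (windows at
#' least `0.9 * track length` apart) or on the two track middles.
#' `mode = "rates"`: Pearson correlation of the per-unit peak-rate and
#' mean-rate population vectors across the tracks.
#'
#' @param mapsA,mapsB rate maps (lists or units x bins matrices) for the
#'   two tracks; same unit universe and equal length.
#' @param mode analysis mode.
#' @param n_shuffles cell-ID shuffles for the chance reference.
#' @param seed RNG seed.
#' @return mode-specific list; `full` gives `correlations` (per location),
#'   `mean_correlation`, `chance` (shuffle means).
#' @export
pattern_separation <- function(mapsA, mapsB,
                               mode = c("full", "corners", "middles", "rates"),
                               n_shuffles = 500, seed = 1L) {
  mode <- match.arg(mode)
  A <- if (is.matrix(mapsA)) mapsA else rate_map_matrix(mapsA)
  B <- if (is.matrix(mapsB)) mapsB else rate_map_matrix(mapsB)
  if (!all(dim(A) == dim(B))) stop("unit universe / track length mismatch")
  n <- nrow(A); L <- ncol(A)
  if (mode == "full") {
    per_loc <- vapply(seq_len(L), function(j) {
      suppressWarnings(stats::cor(A[, j], B[, j]))
    }, numeric(1))
    set.seed(substream_seed(seed, "patsep"))
    chance <- vapply(seq_len(n_shuffles), function(k) {
      Bp <- B[sample(n), , drop = FALSE]
      mean(vapply(seq_len(L), function(j) {
        suppressWarnings(stats::cor(A[, j], Bp[, j]))
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    return(list(mode = mode, correlations = per_loc,
                mean_correlation = mean(per_loc, na.rm = TRUE),
                chance = chance))
  }
  if (mode == "rates") {
    peakA <- apply(A, 1, max); peakB <- apply(B, 1, max)
    meanA <- rowMeans(A); meanB <- rowMeans(B)
    return(list(mode = mode,
                peak_rate_r = suppressWarnings(stats::cor(peakA, peakB)),
                mean_rate_r = suppressWarnings(stats::cor(meanA, meanB))))
  }
  ## 10-bin (20-cm) windows at the opposite ends or both middles
  idx <- if (mode == "corners") {
    list(a = seq_len(10L), b = (L - 9L):L)
  } else {
    mid <- round(L / 2)
    list(a = (mid - 4L):(mid + 5L), b = (mid - 4L):(mid + 5L))
  }
  va <- as.numeric(A[, idx$a]); vb <- as.numeric(B[, idx$b])
  r <- suppressWarnings(stats::cor(va, vb))
  set.seed(substream_seed(seed, "patsep-win"))
  chance <- vapply(seq_len(n_shuffles), function(k) {
    Bp <- B[sample(n), , drop = FALSE]
    suppressWarnings(stats::cor(va, as.numeric(Bp[, idx$b])))
  }, numeric(1))
  list(mode = mode, r = r, chance = chance)
}

#' T-1 time-space contingency and track-end specificity of decoded frames
#'
#' Groups all frame time bins by their peak decoded location and averages
#' the full posterior of each bin's preceding (T-1) bin. The end
#' specificity is the ratio of the mean averaged T-1 probability in the
#' correct 15-cm end zone over that in the opposite end zone, for bins
#' peaking at either end (continuous sequences give a ratio well above 1; a
#' 50% end-swapped process gives about 1). A middle-vs-ends control analog
#' is reported alongside.
#'
#' @param posteriors list of frame `posterior`s or T x L matrices.
#' @param end_cm end-zone width, cm (default 15).
#' @param track_length track length, cm; inferred from bin centres if
#'   omitted.
#' @return a `contingency_result`: `contingency` (peak-location x location
#'   mean T-1 posterior), `end_specificity`, `middle_specificity`,
#'   `n_bins_used`.
#' @export
end_specificity <- function(posteriors, end_cm = 15, track_length = NULL) {
  if (!length(posteriors)) stop("no frames")
  P1 <- as_post_matrix(posteriors[[1]])
  L <- ncol(P1)
  centres <- post_locations(posteriors[[1]], NULL)
  if (is.null(track_length)) {
    track_length <- max(centres) + (centres[2] - centres[1]) / 2
  }
  acc <- matrix(0, L, L)
  cnt <- numeric(L)
  used <- 0L
  for (p in posteriors) {
    P <- as_post_matrix(p)
    if (nrow(P) < 2) next
    peaks <- max.col(P, ties.method = "first")
    for (i in 2:nrow(P)) {
      j <- peaks[i]
      acc[j, ] <- acc[j, ] + P[i - 1, ]
      cnt[j] <- cnt[j] + 1
      used <- used + 1L
    }
  }
  contingency <- acc / pmax(cnt, 1)
  contingency[cnt == 0, ] <- NA
  endA <- centres <= end_cm
  endB <- centres >= track_length - end_cm
  midZ <- abs(centres - track_length / 2) <= end_cm / 2
  ratio_for <- function(peak_zone, correct, opposite) {
    rows <- which(peak_zone & cnt > 0)
    if (!length(rows)) return(NA_real_)
    m <- colSums(acc[rows, , drop = FALSE]) / sum(cnt[rows])
    mean(m[correct]) / mean(m[opposite])
  }
  es <- mean(c(ratio_for(endA, endA, endB), ratio_for(endB, endB, endA)),
             na.rm = TRUE)
  ms <- ratio_for(midZ, midZ, endA | endB)
  structure(list(contingency = contingency, end_specificity = es,
                 middle_specificity = ms, n_bins_used = used,
                 bin_centres = centres),
            class = "contingency_result")
}
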
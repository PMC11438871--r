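## Frame-level ensemble structure: per-frame spike-count vectors, cell-pair
## and frame-pair correlations normalized by ID shuffles, cosine k-means
## clustering of the binarized similarity matrix with silhouette model
## selection, the cluster specificity index, and frame-run similarity.

#' Units x frames spike-count matrix
#' @param spikes per-unit spike-time list.
#' @param frame_table data.frame with `start`, `end` (s).
#' @return integer matrix, units x frames.
#' @export
frame_count_matrix <- function(spikes, frame_table) {
  n <- length(spikes)
  FF <- nrow(frame_table)
  out <- matrix(0L, n, FF)
  for (f in seq_len(FF)) {
    out[, f] <- vapply(spikes, function(s) {
      sum(s >= frame_table$start[f] & s < frame_table$end[f])
    }, numeric(1))
  }
  out
}

#' Shuffle-normalized cell-pair correlations across frames
#'
#' Pearson correlation of the two units' per-frame spike-count vectors for
#' every unordered pair, normalized as its percentile (0..1) against
#' `n_shuffles` frame-ID shuffles (random reassignment of one vector's frame
#' identities). Pairs involving a constant count vector are skipped with a
#' flag. Significant pairs exceed the 0.95 percentile.
#'
#' @param counts units x frames count matrix.
#' @param n_shuffles default 500.
#' @param seed RNG seed.
#' @return list: `pairs` data.frame (unit_a, unit_b, r, percentile,
#'   significant), `proportion_significant`, `skipped_units`.
#' @export
cell_pair_correlations <- function(counts, n_shuffles = 500, seed = 1L) {
  n <- nrow(counts); FF <- ncol(counts)
  if (n < 2 || FF < 10) stop("need >= 2 units and >= 10 frames")
  sds <- apply(counts, 1, stats::sd)
  ok <- sds > 0
  set.seed(substream_seed(seed, "cellpair"))
  ## shared permutation bank: percentile validity is unaffected and the
  ## standardized crossprod makes all pair x shuffle correlations one BLAS call
  X <- t(scale(t(counts[ok, , drop = FALSE])))  # unit-standardized rows
  perms <- replicate(n_shuffles, sample(FF))
  units <- which(ok)
  rows <- list()
  for (a in seq_len(length(units) - 1L)) {
    xa <- X[a, ]
    B <- X[(a + 1):length(units), , drop = FALSE]
    r_real <- as.numeric(B %*% xa) / (FF - 1)
    ## shuffle unit a's frame ids against every partner at once
    A_sh <- matrix(xa[perms], ncol = n_shuffles)
    r_sh <- B %*% A_sh / (FF - 1)          # partners x shuffles
    pct <- rowMeans(r_sh < r_real)
    rows[[a]] <- data.frame(unit_a = units[a],
                            unit_b = units[(a + 1):length(units)],
                            r = unname(r_real), percentile = unname(pct),
                            significant = unname(pct > 0.95),
                            row.names = NULL)
  }
  pairs <- do.call(rbind, rows)
  list(pairs = pairs, proportion_significant = mean(pairs$significant),
       skipped_units = which(!ok))
}

#' Frame-pair ensemble similarity scores
#'
#' For every frame pair, the Pearson correlation of the two per-unit
#' spike-count vectors is ranked against `n_shuffles` cell-ID permutations
#' of one vector; the percentile (0..1) is the neuronal ensemble similarity
#' score. Pairs are significant above 0.95. Frames with zero spikes or
#' constant counts are flagged and their pairs left NA.
#'
#' @param counts units x frames count matrix.
#' @param n_shuffles default 500.
#' @param seed RNG seed.
#' @return a `similarity_matrix`: `scores` (frames x frames, diagonal 0),
#'   `r` (raw correlations), `significant` (binary, diagonal 0),
#'   `flagged_frames`.
#' @export
frame_similarity <- function(counts, n_shuffles = 500, seed = 1L) {
  FF <- ncol(counts); n <- nrow(counts)
  if (FF < 2) stop("need >= 2 frames")
  sds <- apply(counts, 2, stats::sd)
  ok <- sds > 0
  set.seed(substream_seed(seed, "framesim"))
  Xs <- scale(counts)                       # column-standardized
  scores <- r_mat <- matrix(NA_real_, FF, FF)
  perms <- replicate(n_shuffles, sample(n))
  for (b in which(ok)) {
    xb <- Xs[, b]
    B_sh <- matrix(xb[perms], ncol = n_shuffles)  # n x shuffles
    partners <- which(ok & seq_len(FF) < b)
    if (!length(partners)) next
    A <- Xs[, partners, drop = FALSE]
    r_real <- as.numeric(crossprod(A, xb)) / (n - 1)
    r_sh <- crossprod(A, B_sh) / (n - 1)          # partners x shuffles
    pct <- rowMeans(r_sh < r_real)
    scores[partners, b] <- scores[b, partners] <- pct
    r_mat[partners, b] <- r_mat[b, partners] <- r_real
  }
  diag(scores) <- 0; diag(r_mat) <- 0
  sig <- (scores > 0.95) * 1
  sig[is.na(scores)] <- 0
  diag(sig) <- 0
  structure(list(scores = scores, r = r_mat, significant = sig,
                 flagged_frames = which(!ok)),
            class = "similarity_matrix")
}

## ---- cosine k-means -------------------------------------------------------

cosine_normalize <- function(X) {
  nr <- sqrt(rowSums(X^2))
  X[nr > 0, ] <- X[nr > 0, , drop = FALSE] / nr[nr > 0]
  list(X = X, zero = nr == 0)
}

## One Lloyd run of k-means under cosine dissimilarity on row-normalized X.
kmeans_cosine_once <- function(Xn, k, max_iter = 25L) {
  FF <- nrow(Xn)
  centres <- Xn[sample(FF, k), , drop = FALSE]
  labels <- rep(1L, FF)
  for (it in seq_len(max_iter)) {
    sim <- Xn %*% t(centres)                   # cosine similarity
    new_labels <- max.col(sim, ties.method = "first")
    if (all(new_labels == labels) && it > 1) break
    labels <- new_labels
    for (c in seq_len(k)) {
      members <- labels == c
      if (!any(members)) {
        centres[c, ] <- Xn[sample(FF, 1), ]
      } else {
        v <- colMeans(Xn[members, , drop = FALSE])
        nv <- sqrt(sum(v^2))
        centres[c, ] <- if (nv > 0) v / nv else Xn[sample(FF, 1), ]
      }
    }
  }
  labels
}

## Cluster-level silhouette (a - w) / max(w, a): w = average within-cluster
## cosine distance, a = average distance to the nearest other cluster.
cluster_silhouettes <- function(D, labels) {
  ks <- sort(unique(labels))
  vapply(ks, function(c) {
    inside <- which(labels == c)
    w <- if (length(inside) > 1) {
      mean(D[inside, inside][upper.tri(matrix(0, length(inside),
                                              length(inside)))])
    } else 0
    a <- min(vapply(setdiff(ks, c), function(o) {
      mean(D[inside, labels == o, drop = FALSE])
    }, numeric(1)))
    if (max(w, a) == 0) 0 else (a - w) / max(w, a)
  }, numeric(1))
}

#' Cluster sleep frames by binarized ensemble similarity
#'
#' Runs `n_iter` iterations of k-means with cosine dissimilarity on the
#' rows of the binarized similarity matrix (diagonal zeroed), for every k in
#' `k_range`. Per iteration, the k maximizing the mean cluster silhouette
#' \eqn{(a - w)/\max(w, a)} is recorded; the optimal k is the mode of those
#' votes (ties broken toward smaller k), and the final labels come from the
#' iteration with the highest mean silhouette at that k. For cell-ID
#' shuffled datasets use `k_range = c(2, 60)`.
#'
#' @param sim a `similarity_matrix` or a binary frames x frames matrix.
#' @param k_range c(min, max) cluster counts (default c(2, 30)).
#' @param n_iter k-means iterations (default 100).
#' @param seed RNG seed.
#' @return a `cluster_result`: `labels`, `k_optimal`, `silhouette`
#'   (per final cluster), `mean_silhouette`, `k_votes`, `zero_rows`.
#' @export
cluster_frames <- function(sim, k_range = c(2, 30), n_iter = 100, seed = 1L) {
  B <- if (inherits(sim, "similarity_matrix")) sim$significant else as.matrix(sim)
  diag(B) <- 0
  if (all(B == 0)) {
    return(structure(list(labels = NULL, k_optimal = NA_integer_,
                          flag = "all_zero"), class = "cluster_result"))
  }
  FF <- nrow(B)
  ks <- seq(k_range[1], min(k_range[2], FF - 1L))
  cn <- cosine_normalize(B)
  Xn <- cn$X
  ## pairwise cosine distances are fixed across runs
  D <- 1 - Xn %*% t(Xn)
  D[D < 0] <- 0
  set.seed(substream_seed(seed, "kmeans"))
  votes <- integer(0)
  best <- list()   # per k: best labels + silhouette over iterations
  for (it in seq_len(n_iter)) {
    sil_by_k <- numeric(length(ks))
    lab_by_k <- vector("list", length(ks))
    for (ki in seq_along(ks)) {
      lab <- kmeans_cosine_once(Xn, ks[ki])
      sil_by_k[ki] <- mean(cluster_silhouettes(D, lab))
      lab_by_k[[ki]] <- lab
    }
    kbest <- ks[which.max(sil_by_k)]
    votes <- c(votes, kbest)
    for (ki in seq_along(ks)) {
      key <- as.character(ks[ki])
      if (is.null(best[[key]]) || sil_by_k[ki] > best[[key]]$sil) {
        best[[key]] <- list(sil = sil_by_k[ki], labels = lab_by_k[[ki]])
      }
    }
  }
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  k_opt <- min(winners)                     # parsimony on ties
  final <- best[[as.character(k_opt)]]
  structure(list(labels = final$labels, k_optimal = k_opt,
                 silhouette = cluster_silhouettes(D, final$labels),
                 mean_silhouette = final$sil,
                 k_votes = table(factor(votes, levels = ks)),
                 zero_rows = which(cn$zero),
                 tie = length(winners) > 1),
            class = "cluster_result")
}

#' Cluster specificity index
#'
#' For each cluster, \eqn{CSI = \max_i Pr_i / \sum_i Pr_i} where
#' \eqn{Pr_i} is the probability that a frame in the cluster is significant
#' for track i. CSI lies in `[1/I, 1]`; clusters with no significant frame
#' are flagged NA.
#'
#' @param labels cluster label per frame.
#' @param sig_matrix logical frames x tracks significance matrix.
#' @return data.frame (cluster, csi, dominant_track, n_frames).
#' @export
cluster_specificity <- function(labels, sig_matrix) {
  sig_matrix <- as.matrix(sig_matrix)
  if (ncol(sig_matrix) < 2) stop("need significance for >= 2 tracks")
  ks <- sort(unique(labels))
  do.call(rbind, lapply(ks, function(c) {
    pr <- colMeans(sig_matrix[labels == c, , drop = FALSE])
    tot <- sum(pr)
    data.frame(cluster = c,
               csi = if (tot > 0) max(pr) / tot else NA_real_,
               dominant_track = if (tot > 0) which.max(pr) else NA_integer_,
               n_frames = sum(labels == c))
  }))
}

#' Frame-to-run ensemble similarity
#'
#' Correlates each frame's per-unit spike-count vector with the run
#' population vector of per-unit peak rates; significance at the 95th
#' percentile of `n_shuffles` cell-ID shuffles of the frame vector.
#'
#' @param counts units x frames count matrix.
#' @param peak_rates per-unit peak-rate vector (same unit order).
#' @param n_shuffles default 500.
#' @param seed RNG seed.
#' @return data.frame (frame, r, percentile, significant, degenerate).
#' @export
frame_run_similarity <- function(counts, peak_rates, n_shuffles = 500,
                                 seed = 1L) {
  stopifnot(nrow(counts) == length(peak_rates))
  n <- nrow(counts)
  if (stats::sd(peak_rates) == 0) {
    return(data.frame(frame = seq_len(ncol(counts)), r = NA_real_,
                      percentile = NA_real_, significant = FALSE,
                      degenerate = TRUE))
  }
  set.seed(substream_seed(seed, "framerun"))
  perms <- replicate(n_shuffles, sample(n))
  pv <- as.numeric(scale(peak_rates))
  do.call(rbind, lapply(seq_len(ncol(counts)), function(f) {
    x <- counts[, f]
    if (stats::sd(x) == 0) {
      return(data.frame(frame = f, r = NA_real_, percentile = NA_real_,
                        significant = FALSE, degenerate = TRUE))
    }
    xs <- as.numeric(scale(x))
    r <- sum(xs * pv) / (n - 1)
    r_sh <- as.numeric(crossprod(matrix(xs[perms], ncol = n_shuffles), pv)) /
      (n - 1)
    pct <- shuffle_percentile(r, r_sh)
    data.frame(frame = f, r = r, percentile = pct,
               significant = pct > 0.95, degenerate = FALSE)
  }))
}
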
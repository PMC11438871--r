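test_that("cell-pair correlations flag co-active pairs and calibrate on noise", {
  set.seed(51)
  FF <- 60
  base <- rpois(FF, 6)
  counts <- rbind(base, base * 2,                  # perfectly co-active pair
                  matrix(rpois(8 * FF, 2), 8))
  res <- cell_pair_correlations(counts, n_shuffles = 300, seed = 2)
  top <- res$pairs[res$pairs$unit_a == 1 & res$pairs$unit_b == 2, ]
  expect_equal(top$r, 1, tolerance = 1e-9)
  expect_gt(top$percentile, 0.95)
  # silent unit is skipped
  counts2 <- rbind(counts, 0)
  res2 <- cell_pair_correlations(counts2, n_shuffles = 100, seed = 2)
  expect_true(nrow(counts2) %in% res2$skipped_units)
  # independent Poisson counts: ~5% significant pairs
  set.seed(52)
  indep <- matrix(rpois(30 * 200, 3), 30)
  cal <- cell_pair_correlations(indep, n_shuffles = 300, seed = 3)
  expect_lt(abs(cal$proportion_significant - 0.05), 0.03)
})

test_that("frame similarity scores rank identical high and disjoint low", {
  set.seed(53)
  a <- rpois(40, 4) + 1
  b <- numeric(40); b[1:20] <- rpois(20, 5) + 1
  c_ <- numeric(40); c_[21:40] <- rpois(20, 5) + 1
  counts <- cbind(a, a, b, c_)
  sim <- frame_similarity(counts, n_shuffles = 400, seed = 4)
  expect_gt(sim$scores[1, 2], 0.95)            # identical frames
  expect_lt(sim$r[3, 4], 0)                    # disjoint ensembles
  expect_lt(sim$scores[3, 4], 0.9)
  expect_equal(sim$scores, t(sim$scores), tolerance = 1e-12)
  expect_true(all(diag(sim$scores) == 0))
})

test_that("similarity percentile matches exhaustive permutation on 6 cells", {
  # with 6 cells the cell-ID shuffle distribution can be enumerated exactly
  x <- c(5, 1, 0, 2, 8, 3)
  y <- c(4, 2, 1, 0, 7, 2)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  r_real <- cor(x, y)
  r_all <- apply(perms, 1, function(p) cor(x, y[p]))
  exact <- mean(r_all < r_real)
  sim <- frame_similarity(cbind(x, y), n_shuffles = 500, seed = 6)
  expect_equal(sim$scores[1, 2], exact, tolerance = 0.07)
})

test_that("percentile scores are invariant under joint cell relabeling", {
  set.seed(54)
  counts <- matrix(rpois(12 * 20, 3), 12)
  s1 <- frame_similarity(counts, n_shuffles = 500, seed = 9)
  ord <- sample(12)
  s2 <- frame_similarity(counts[ord, ], n_shuffles = 500, seed = 9)
  expect_equal(s1$r, s2$r, tolerance = 1e-9)
  # percentiles are Monte-Carlo estimates: tolerate a few SE of 1/sqrt(500)
  expect_lt(max(abs(s1$scores - s2$scores), na.rm = TRUE), 0.12)
  expect_lt(mean(abs(s1$scores - s2$scores), na.rm = TRUE), 0.04)
})

test_that("frame-pair significance calibrates near 5% on IID frames", {
  set.seed(55)
  counts <- matrix(rpois(25 * 60, 3), 25)
  sim <- frame_similarity(counts, n_shuffles = 300, seed = 5)
  up <- sim$significant[upper.tri(sim$significant)]
  expect_lt(abs(mean(up) - 0.05), 0.025)
})

test_that("duplicated frame groups cluster into two clean clusters", {
  f1 <- c(rep(1, 10), rep(0, 10))
  f2 <- c(rep(0, 10), rep(1, 10))
  B <- matrix(0, 40, 40)
  g <- rep(1:2, each = 20)
  B[outer(g, g, "==")] <- 1
  diag(B) <- 0
  res <- cluster_frames(B, k_range = c(2, 6), n_iter = 20, seed = 2)
  expect_equal(res$k_optimal, 2)
  # zeroed diagonals keep within-group rows from being exactly identical,
  # so the silhouette approaches but does not reach 1
  expect_gt(mean(res$silhouette), 0.9)
  expect_equal(length(unique(table(res$labels, g)[table(res$labels, g) > 0])),
               1)
})

test_that("planted ensemble clusters are recovered from detected frames", {
  sleep <- fix_sleep_cl()
  fr <- detected_frames(sleep)
  tab <- attr(fr, "table")
  counts <- do.call(cbind, lapply(fr, function(f) rowSums(f$counts)))
  sim <- frame_similarity(counts, n_shuffles = 300, seed = 7)
  res <- cluster_frames(sim, n_iter = 30, seed = 7)
  expect_equal(res$k_optimal, 3)
  mt <- match_frames_to_truth(tab, sleep$frame_truth)
  truth_cl <- sleep$frame_truth$cluster[mt]
  ok <- !is.na(truth_cl)
  agree <- max(vapply(seq_len(nrow(table(res$labels[ok], truth_cl[ok]))),
                      function(i) 0, numeric(1)), 0)
  conf <- table(res$labels[ok], truth_cl[ok])
  expect_gte(sum(apply(conf, 2, max)) / sum(conf), 0.9)
  # within-cluster similarity exceeds across-cluster similarity
  S <- sim$r
  same <- outer(res$labels, res$labels, "==") & upper.tri(S)
  diff_ <- !outer(res$labels, res$labels, "==") & upper.tri(S)
  expect_gt(mean(S[same], na.rm = TRUE), mean(S[diff_], na.rm = TRUE))
  # cell-ID shuffled counts lose the planted structure
  set.seed(8)
  sh_counts <- apply(counts, 2, sample)
  sh_sim <- frame_similarity(sh_counts, n_shuffles = 300, seed = 8)
  if (!all(sh_sim$significant == 0)) {
    sh <- cluster_frames(sh_sim, k_range = c(2, 60), n_iter = 20, seed = 8)
    confs <- table(sh$labels[ok], truth_cl[ok])
    expect_lt(sum(apply(confs, 2, max)) / sum(confs), 0.9)
  }
})

test_that("cluster specificity index matches its definition", {
  labels <- rep(1:3, each = 10)
  sig <- matrix(FALSE, 30, 3)
  sig[1:10, 2] <- TRUE                     # cluster 1 only track 2
  sig[11:20, ] <- TRUE                     # cluster 2 equal across 3 tracks
  sig[21:30, 1] <- c(rep(TRUE, 6), rep(FALSE, 4))   # Pr = (0.6, 0.3, 0.3)
  sig[21:30, 2] <- c(rep(TRUE, 3), rep(FALSE, 7))
  sig[21:30, 3] <- c(rep(TRUE, 3), rep(FALSE, 7))
  res <- cluster_specificity(labels, sig)
  expect_equal(res$csi[1], 1)
  expect_equal(res$csi[2], 1 / 3, tolerance = 1e-12)
  expect_equal(res$csi[3], 0.6 / 1.2, tolerance = 1e-12)  # Pr=(.2,.1,.1) scaled
  # cluster with no significant frames is flagged
  res2 <- cluster_specificity(c(labels, rep(4, 5)),
                              rbind(sig, matrix(FALSE, 5, 3)))
  expect_true(is.na(res2$csi[4]))
})

test_that("frame-run similarity detects rate-matched frames", {
  set.seed(56)
  peaks <- runif(30, 1, 20)
  matched <- rpois(30, peaks)          # counts proportional to run peaks
  anti <- rpois(30, rev(sort(peaks))[rank(peaks)])
  flat <- rpois(30, 5)
  res <- frame_run_similarity(cbind(matched, anti, flat), peaks,
                              n_shuffles = 400, seed = 10)
  expect_true(res$significant[1])
  expect_false(res$significant[2])
  # all-equal peak vector is degenerate
  dg <- frame_run_similarity(cbind(matched), rep(3, 30), n_shuffles = 50,
                             seed = 1)
  expect_true(all(dg$degenerate))
})
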
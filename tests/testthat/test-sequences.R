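test_that("weighted correlation hits the diagonal/anti-diagonal extremes", {
  D <- diag(5)
  expect_equal(weighted_correlation(D), 1, tolerance = 1e-12)
  expect_equal(weighted_correlation(D[5:1, ]), -1, tolerance = 1e-12)
  u <- matrix(1 / 10, 5, 10)
  r <- weighted_correlation(u)
  expect_equal(as.numeric(r), 0)
  expect_true(isTRUE(attr(r, "degenerate")))
})

test_that("weighted correlation agrees with the double-summation oracle", {
  set.seed(21)
  for (k in 1:10) {
    P <- matrix(runif(5 * 10), 5, 10)
    P <- P / rowSums(P)
    expect_equal(as.numeric(weighted_correlation(P)), wc_oracle(P),
                 tolerance = 1e-9)
    loc <- sort(runif(10, 0, 100))
    expect_equal(as.numeric(weighted_correlation(P, loc = loc)),
                 wc_oracle(P, loc = loc), tolerance = 1e-9)
  }
})

test_that("time-bin shuffles preserve every bin's decoded content", {
  set.seed(22)
  P <- matrix(runif(8 * 20), 8, 20)
  P <- P / rowSums(P)
  # permuting rows keeps the multiset of rows identical
  perm <- P[sample(8), ]
  expect_equal(P[do.call(order, as.data.frame(P)), ],
               perm[do.call(order, as.data.frame(perm)), ])
  # and the fast shuffle statistic equals a full recomputation
  set.seed(1); fast <- hipposeq:::shuffled_weighted_correlations(P, 50)
  set.seed(1)
  slow <- vapply(1:50, function(k)
    as.numeric(weighted_correlation(P[sample(8), ])), numeric(1))
  expect_equal(fast, slow, tolerance = 1e-9)
})

test_that("the shuffle ensemble is centred on zero", {
  set.seed(23)
  for (k in 1:5) {
    P <- matrix(rexp(10 * 30), 10, 30)
    P <- P / rowSums(P)
    r_sh <- hipposeq:::shuffled_weighted_correlations(P, 400)
    expect_lt(abs(mean(r_sh)), 3 * sd(r_sh) / sqrt(400) + 1e-3)
  }
})

test_that("circular correlation stays high when a trajectory wraps", {
  # trajectory that runs off the end and wraps to the start
  peaks <- c(41, 61, 81, 1, 21) + 4
  P <- bump_posterior(peaks, 100, width = 3)
  r_lin <- abs(as.numeric(weighted_correlation(P)))
  r_circ <- abs(as.numeric(circular_weighted_correlation(P)))
  expect_gt(r_circ, 0.8)
  expect_lt(r_lin, 0.6)
  # plain diagonal: both agree qualitatively
  Pd <- bump_posterior(seq(10, 90, by = 20), 100, width = 3)
  expect_gt(abs(as.numeric(circular_weighted_correlation(Pd))), 0.8)
  expect_gt(abs(as.numeric(weighted_correlation(Pd))), 0.9)
  # uniform is degenerate
  rc <- circular_weighted_correlation(matrix(1 / 10, 5, 10))
  expect_true(isTRUE(attr(rc, "degenerate")))
})

test_that("jump distances follow the peak trajectory", {
  # stationary: all peaks in one bin
  P <- bump_posterior(rep(50, 6), 100)
  s <- sequence_metrics(P, n_shuffles = 50, seed = 1, track_length = 100)
  expect_equal(s$median_jump, 0)
  expect_equal(s$max_jump, 0)
  # perfect 5-bin diagonal with 20-cm steps on a 100-cm track
  P2 <- bump_posterior(c(10, 30, 50, 70, 90), 100, width = 0.8)
  s2 <- sequence_metrics(P2, n_shuffles = 50, seed = 1, track_length = 100)
  expect_equal(s2$median_jump, 0.2)
  expect_equal(s2$max_jump, 0.2)
  # frames under 5 bins are skipped with a reason
  s3 <- sequence_metrics(bump_posterior(c(1, 2), 10), seed = 1)
  expect_true(s3$skipped)
  expect_equal(s3$reason, "too_few_bins")
})

test_that("sequence scores are near zero for structureless frames", {
  set.seed(24)
  rz <- vapply(1:40, function(k) {
    P <- matrix(rexp(8 * 50), 8, 50)
    P <- P / rowSums(P)
    sequence_metrics(P, n_shuffles = 200, seed = k)$r_z
  }, numeric(1))
  expect_lt(abs(mean(rz)), 3 * sd(rz) / sqrt(40))
})

test_that("embedded sequences are detected; sequence-free frames are not", {
  run <- fix_run(); model <- fix_model()
  sleep <- fix_sleep_seq()
  fr <- detected_frames(sleep)
  tab <- attr(fr, "table")
  mt <- match_frames_to_truth(tab, sleep$frame_truth)
  posts <- lapply(fr, function(f)
    decode_counts(f$counts[model$included_units, , drop = FALSE], model, 0.02))
  cls <- classify_frames(posts, n_shuffles = 500, seed = 9,
                         shuffled_dataset = FALSE)
  truth_seq <- sleep$frame_truth$template[mt[cls$table$frame]] == "seq"
  ok <- !is.na(truth_seq)
  sens <- mean(cls$table$significant[ok & truth_seq])
  spec <- mean(!cls$table$significant[ok & !truth_seq])
  expect_gte(sens, 0.8)
  expect_gte(spec, 0.9)
})

test_that("the joint threshold grid has the printed shape and trivial corner", {
  set.seed(25)
  mk <- function(n) data.frame(r = runif(n, -1, 1), r_z = rnorm(n),
                               median_jump = runif(n), max_jump = runif(n))
  res <- joint_threshold_comparison(mk(200), mk(200), mode = "score_jump")
  expect_equal(dim(res$p), c(9, 8))
  # no threshold on score, jump < 1 passes nearly everything
  expect_gt(res$propA[1, 8], 0.95)
  sur <- lapply(1:40, function(k) mk(200))
  res2 <- joint_threshold_comparison(mk(200), sur, mode = "corr_maxjump")
  expect_equal(dim(res2$p), c(10, 10))
  expect_true(all(res2$p >= 0 & res2$p <= 1, na.rm = TRUE))
})

test_that("track specificity requires significance for exactly one track", {
  sig <- cbind(c(TRUE, TRUE, FALSE, FALSE),
               c(TRUE, FALSE, FALSE, TRUE))
  res <- track_specific_events(sig)
  expect_equal(res$proportion, 0.5)   # frames 2 and 4
  # identical models: any significant frame is significant for all
  same <- cbind(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(track_specific_events(same)$proportion, 0)
  expect_error(track_specific_events(matrix(TRUE, 3, 1)), "2 track")
})

test_that("removing zero bins reproduces the baseline exactly", {
  model <- fix_model()
  sleep <- fix_sleep_seq()
  fr <- detected_frames(sleep)[1:15]
  counts <- lapply(fr, function(f)
    f$counts[model$included_units, , drop = FALSE])
  res <- robustness_suite(counts, model, "bin_removal_start_end",
                          n_shuffles = 100, seed = 3)
  k0 <- res$cumulative[res$cumulative$k == 0, ]
  expect_equal(unique(k0$prop), res$baseline$proportion)
  # cumulative proportions never decrease with more bins removed
  for (side in unique(res$cumulative$side)) {
    pr <- res$cumulative$prop[res$cumulative$side == side]
    expect_true(all(diff(pr) >= 0))
  }
})

test_that("map truncation rescues a constructed end-swapped frame", {
  # trajectory decodes cleanly except the first bin sits at the wrong end
  L <- 100
  f <- do.call(rbind, lapply(seq(2.5, 97.5, by = 2.5), function(c0) {
    20 * exp(-0.5 * ((1:L - c0) / 3)^2)
  }))
  model <- structure(list(f = f, bin_centres = (1:L) - 0.5, bin_cm = 1,
                          included_units = seq_len(nrow(f)),
                          direction = "fwd", rate_floor = 0.01,
                          track_length = L),
                     class = "encoding_model")
  mk_counts <- function(path_cm) {
    vapply(path_cm, function(x) {
      rates <- f[, pmax(1, pmin(L, round(x)))]
      as.integer(rates > 10)
    }, integer(nrow(f)))
  }
  # the first bin carries competing depictions of the true start (10 cm)
  # and the opposite end (95 cm); the spurious end depiction wins until the
  # end-zone place-map activity is removed
  swapped <- mk_counts(c(10, seq(17.5, 70, length.out = 8)))
  swapped[, 1] <- swapped[, 1] + 2 * mk_counts(95)[, 1]
  base <- sequence_metrics(decode_counts(swapped, model, 0.02),
                           n_shuffles = 300, seed = 5)
  expect_false(base$significant)
  trunc <- hipposeq:::truncate_model(model, c(L - 30, L))
  fixed <- sequence_metrics(decode_counts(swapped, trunc, 0.02),
                            n_shuffles = 300, seed = 5)
  expect_gt(abs(fixed$r), abs(base$r))
  expect_true(fixed$significant)
})

test_that("rate-matched Poisson surrogates mimic sequence-free data", {
  model <- fix_model()
  sleep <- fix_sleep_cl()
  fr <- detected_frames(sleep)[1:20]
  counts <- lapply(fr, function(f)
    f$counts[model$included_units, , drop = FALSE])
  res <- robustness_suite(counts, model, "poisson_surrogate_single",
                          n_shuffles = 100, seed = 11)
  z <- hipposeq:::two_proportion_z(res$baseline$n_significant,
                                   res$baseline$n_frames,
                                   res$surrogate$n_significant,
                                   res$surrogate$n_frames)
  expect_gt(z$p.value, 0.05)
})

test_that("quadrant ratio matches its definition and trivial extremes", {
  # all mass in the ahead-future and behind-past quadrants
  m <- matrix(0, 4, 4)
  m[3:4, 3:4] <- 1; m[1:2, 1:2] <- 1
  expect_equal(quadrant_ratio(m), 1)
  expect_equal(quadrant_ratio(matrix(1, 6, 6)), 0)
  # brute-force oracle on a random odd-sized matrix (centre row/col excluded)
  set.seed(26)
  mm <- matrix(runif(25), 5, 5)
  q1 <- sum(mm[4:5, 4:5]); q3 <- sum(mm[1:2, 1:2])
  q2 <- sum(mm[1:2, 4:5]); q4 <- sum(mm[4:5, 1:2])
  expect_equal(quadrant_ratio(mm), (q1 + q3 - q2 - q4) / (q1 + q2 + q3 + q4),
               tolerance = 1e-12)
})

test_that("forward-sweep cycles give a significant theta quadrant ratio", {
  set.seed(27)
  # cycles sweep from behind to ahead of the animal across the 400-ms window
  mk_cycle <- function() {
    peaks <- round(seq(11, 51, length.out = 20) + rnorm(20, 0, 2))
    bump_posterior(pmax(1, pmin(61, peaks)), 61, width = 3) +
      matrix(runif(20 * 61, 0, 0.002), 20)
  }
  cyc <- lapply(1:30, function(k) mk_cycle())
  res <- theta_quadrant_ratio(cyc, n_shuffles = 200, seed = 3)
  expect_gt(res$qr, 0)
  expect_true(res$significant)
  # uniform cycles are not significant
  unif <- lapply(1:10, function(k) matrix(1 / 61, 20, 61))
  res0 <- theta_quadrant_ratio(unif, n_shuffles = 100, seed = 3)
  expect_equal(res0$qr, 0, tolerance = 1e-9)
  expect_false(res0$significant)
})
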
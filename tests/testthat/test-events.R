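test_that("planted frames are recovered with high recall and precision", {
  sleep <- fix_sleep_seq()
  fr <- detected_frames(sleep)
  tab <- attr(fr, "table")
  ft <- sleep$frame_truth
  mt <- match_frames_to_truth(tab, ft)
  recall <- mean(vapply(seq_len(nrow(ft)), function(j)
    any(mt == j, na.rm = TRUE), logical(1)))
  expect_gte(recall, 0.85)
  expect_gte(mean(!is.na(mt)), 0.9)
  # structural invariants: duration bounds, participation, 20-ms bins,
  # no overlap, all inside NREM
  durs <- tab$end - tab$start
  expect_true(all(durs >= 0.1 & durs <= 0.8))
  expect_true(all(tab$n_active >= 5))
  expect_true(all(diff(tab$start) > 0))
  expect_true(all(tab$start[-1] >= tab$end[-nrow(tab)]))
  nrem <- sleep$epochs[sleep$epochs$label == "nrem", ]
  inside <- vapply(seq_len(nrow(tab)), function(k)
    any(tab$start[k] >= nrem$start & tab$end[k] <= nrem$end), logical(1))
  expect_true(all(inside))
})

test_that("silent input and over-long bursts yield no frames", {
  ep <- data.frame(label = "nrem", start = 0, end = 60)
  silent <- rep(list(numeric(0)), 10)
  expect_length(detect_frames(silent, ep, t_range = c(0, 60)), 0)
  # a single 900-ms burst violates the duration bound
  set.seed(31)
  burst <- lapply(1:10, function(i) sort(runif(60, 30, 30.9)))
  fr <- detect_frames(burst, ep, t_range = c(0, 60))
  expect_length(fr, 0)
})

test_that("lowering the detection threshold never loses burst coverage", {
  # with crossing-defined boundaries a lower threshold can merge neighbours,
  # so the monotone quantity is the total supra-threshold time captured
  sleep <- fix_sleep_cl()
  ep <- sleep$epochs[sleep$epochs$label == "nrem", ]
  cov_of <- function(thr) {
    fr <- detect_frames(sleep$spikes, ep, t_range = c(0, sleep$duration),
                        sd_threshold = thr, max_dur = Inf)
    sum(vapply(fr, `[[`, numeric(1), "duration"))
  }
  expect_gte(cov_of(1.5), cov_of(2))
})

test_that("NREM segmentation recovers the planted epochs", {
  cfg <- generator_config(seed = 41, n_laps = 6, sleep_duration = 400)
  run <- generate_run_session(cfg)
  sleep <- generate_sleep_session(cfg, fix_model())
  lfp <- generate_lfp(cfg, run, sleep)
  ep <- segment_nrem(lfp$sleep)
  truth <- sleep$epochs[sleep$epochs$label == "nrem", ]
  rec <- sum(vapply(seq_len(nrow(truth)), function(k)
    sum(hipposeq:::interval_overlap(truth$start[k], truth$end[k],
                                    as.matrix(ep[, c("start", "end")]))),
    numeric(1)))
  expect_gte(rec / sum(truth$end - truth$start), 0.95)
  # a theta/delta ratio below its own mean everywhere is impossible:
  # segmentation can never cover the full trace
  expect_lt(sum(ep$end - ep$start), sleep$duration)
  # constant movement suppresses NREM entirely
  vel <- list(time = seq(0, sleep$duration, by = 0.04),
              speed = rep(10, length(seq(0, sleep$duration, by = 0.04))))
  ep_mv <- segment_nrem(lfp$sleep, velocity = vel)
  expect_equal(nrow(ep_mv), 0)
})

test_that("ripple detection matches the planted bursts and is quiet on noise", {
  cfg <- generator_config(seed = 43, n_laps = 4, sleep_duration = 300)
  run <- generate_run_session(cfg)
  sleep <- generate_sleep_session(cfg, fix_model())
  lfp <- generate_lfp(cfg, run, sleep)
  rip <- detect_ripples(lfp$sleep)
  ft <- sleep$frame_truth
  hit <- vapply(seq_len(nrow(ft)), function(k)
    any(hipposeq:::interval_overlap(ft$start[k], ft$end[k],
                                    cbind(rip$start, rip$end)) > 0),
    logical(1))
  expect_gte(mean(hit), 0.9)
  # flat zero signal: no events
  flat <- list(time = seq(0, 10, by = 1 / 1250),
               samples = numeric(length(seq(0, 10, by = 1 / 1250))),
               fs = 1250)
  expect_equal(nrow(detect_ripples(flat)), 0)
  expect_error(detect_ripples(list(time = 1:10, samples = rnorm(10),
                                   fs = 100)), "sampling rate")
  # white noise: only threshold-level false alarms
  set.seed(1)
  wn <- list(time = seq(0, 60, by = 1 / 1250),
             samples = rnorm(length(seq(0, 60, by = 1 / 1250))), fs = 1250)
  rate <- nrow(detect_ripples(wn)) / 60
  expect_lt(rate, 1.5)  # events/s; Gaussian envelope exceeds 3 SD rarely
})

test_that("theta cycles obey the position and participation rules", {
  cfg <- generator_config(seed = 47, n_laps = 10)
  run <- generate_run_session(cfg)
  sleep <- generate_sleep_session(cfg, fix_model())
  lfp <- generate_lfp(cfg, run, sleep)
  cyc <- extract_theta_cycles(lfp$run, run, min_units = 2)
  expect_gt(length(cyc), 10)
  pos <- vapply(cyc, `[[`, numeric(1), "animal_pos")
  expect_true(all(pos > 30 & pos < 70))
  active <- vapply(cyc, function(c) sum(rowSums(c$counts) > 0), numeric(1))
  expect_true(all(active >= 2))
  cyc5 <- extract_theta_cycles(lfp$run, run, min_units = 5)
  expect_true(all(vapply(cyc5, function(c)
    sum(rowSums(c$counts) > 0), numeric(1)) >= 5))
  expect_lte(length(cyc5), length(cyc))
})
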
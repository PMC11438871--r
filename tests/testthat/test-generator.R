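test_that("identical seeds give bit-identical sessions", {
  cfg <- generator_config(seed = 7, n_cells = 15, n_laps = 4,
                          sleep_duration = 200)
  r1 <- generate_run_session(cfg)
  r2 <- generate_run_session(cfg)
  expect_identical(r1, r2)
  s1 <- generate_sleep_session(cfg, fix_model())
  s2 <- generate_sleep_session(cfg, fix_model())
  expect_identical(s1, s2)
})

test_that("config invariants are enforced", {
  expect_error(generator_config(mirror_weight = 1.2), "config error")
  expect_error(generator_config(n_cells = 0), "empty-session")
  expect_error(generator_config(track_length = -1), "config error")
  expect_error(generator_config(seq_frame_fraction = 0.5, seq_compression = 0),
               "config error")
})

test_that("n_laps = 0 yields a degenerate session with empty spike trains", {
  run <- generate_run_session(generator_config(seed = 1, n_cells = 5,
                                               n_laps = 0))
  expect_length(run$time, 0)
  expect_true(all(lengths(run$spikes) == 0))
})

test_that("trajectory respects track bounds and velocity consistency", {
  run <- fix_run()
  L <- run$config$track_length
  expect_true(all(run$position >= 0 & run$position <= L))
  fd <- c(0, diff(run$position) * run$config$pos_fs)
  expect_lt(max(abs(fd - run$velocity)), 1e-6)
  expect_true(all(unlist(run$spikes) >= 0 &
                    unlist(run$spikes) <= max(run$time) + 0.001))
})

test_that("spike generation conserves the configured rate", {
  # total spikes of each unit within 3 SE of the trajectory-integrated rate
  cfg <- generator_config(seed = 13, n_cells = 12, n_laps = 15,
                          n_assemblies_planted = 0, low_tuned_fraction = 0)
  run <- generate_run_session(cfg)
  dtms <- 1 / cfg$spike_fs
  tms <- seq(0, max(run$time), by = dtms)
  pms <- approx(run$time, run$position, xout = tms, rule = 2)$y
  dir_ms <- run$direction[pmin(length(run$time),
                               floor(tms * cfg$pos_fs) + 1L)]
  gt <- run$ground_truth
  bad <- 0
  for (i in seq_len(cfg$n_cells)) {
    lam <- rep(0.1, length(tms))
    for (d in c("fwd", "bwd")) {
      g <- gt[gt$unit == i & gt$direction == d, ]
      sel <- dir_ms == d
      lam[sel] <- hipposeq:::tuning_rate(pms[sel], g$centre, g$width, g$peak,
                                         g$mirror_weight, cfg$track_length)
    }
    expected <- sum(lam) * dtms
    se <- sqrt(expected)
    if (abs(length(run$spikes[[i]]) - expected) > 3 * se) bad <- bad + 1
  }
  expect_lte(bad, 1)  # ~99.7% coverage per unit
})

test_that("recovered rate-map peaks match planted field centres", {
  run <- fix_run()
  maps <- rate_maps(run, "fwd")
  gt <- run$ground_truth
  gt <- gt[gt$direction == "fwd" & !gt$low_tuned, ]
  pk <- vapply(maps[gt$unit], function(m) m$bin_centres[which.max(m$rates)],
               numeric(1))
  expect_lt(median(abs(pk - gt$centre)), 2)
})

test_that("an equal mirror mixture yields maps symmetric about the track middle", {
  # at mirror weight 0.5 the mirrored component equals the primary one
  cfg <- generator_config(seed = 23, mirror_weight = 0.5, n_cells = 20,
                          low_tuned_fraction = 0, n_laps = 15)
  run <- generate_run_session(cfg)
  maps <- rate_maps(run, "fwd")
  # the mirror component is end-anchored: end-peaked cells become symmetric
  gt <- run$ground_truth
  endc <- gt$unit[gt$direction == "fwd" &
                    (gt$centre < 20 | gt$centre > 80)]
  sym_r <- vapply(maps[endc], function(m) {
    suppressWarnings(cor(m$rates, rev(m$rates)))
  }, numeric(1))
  expect_gt(median(sym_r, na.rm = TRUE), 0.6)
})

test_that("planted sleep frames respect duration bounds and NREM placement", {
  sleep <- fix_sleep_seq()
  ft <- sleep$frame_truth
  dur <- ft$end - ft$start
  expect_true(all(dur >= 0.1 & dur <= 0.8))
  nrem <- sleep$epochs[sleep$epochs$label == "nrem", ]
  inside <- vapply(seq_len(nrow(ft)), function(k) {
    any(ft$start[k] >= nrem$start & ft$end[k] <= nrem$end + 0.85)
  }, logical(1))
  expect_true(all(inside))
})

test_that("generated field potential carries the configured band structure", {
  cfg <- generator_config(seed = 31, theta_freq = 6.7, n_laps = 8,
                          sleep_duration = 300)
  run <- generate_run_session(cfg)
  model <- build_encoding_model(run, "fwd")
  sleep <- generate_sleep_session(cfg, model)
  lfp <- generate_lfp(cfg, run, sleep)
  vel <- list(time = run$time, speed = abs(run$velocity))
  expect_equal(peak_theta_frequency(lfp$run, vel), 6.7, tolerance = 0.1 / 6.7)
  rip <- detect_ripples(lfp$sleep)
  ft <- sleep$frame_truth
  overlap <- vapply(seq_len(nrow(ft)), function(k) {
    any(hipposeq:::interval_overlap(ft$start[k], ft$end[k],
                                    cbind(rip$start, rip$end)) > 0)
  }, logical(1))
  expect_gte(mean(overlap), 0.9)
})

test_that("sessions round-trip through flat delimited tables", {
  run <- generate_run_session(generator_config(seed = 3, n_cells = 6,
                                               n_laps = 2))
  d <- tempfile()
  write_session(run, d)
  units <- read.delim(file.path(d, "units.tsv"))
  expect_equal(nrow(units), sum(lengths(run$spikes)))
  pos <- read.delim(file.path(d, "position.tsv"))
  expect_equal(pos$x_cm, run$position)
  unlink(d, recursive = TRUE)
})
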
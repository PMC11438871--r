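make_map <- function(rates, occ = NULL, bin_cm = 2) {
  L <- length(rates)
  if (is.null(occ)) occ <- rep(1 / L, L)
  structure(list(rates = rates, occupancy_prob = occ,
                 mean_rate = sum(occ * rates), peak_rate = max(rates),
                 bin_centres = (seq_len(L) - 0.5) * bin_cm, bin_cm = bin_cm,
                 unoccupied = rep(FALSE, L), direction = "fwd",
                 unit_id = 1, n_spikes = 100), class = "rate_map")
}

test_that("spatial information matches closed-form cases", {
  # uniform firing carries no information
  expect_equal(spatial_information(make_map(rep(5, 20))), 0)
  # all firing in 1 of 4 equally occupied bins: 2 bits
  expect_equal(spatial_information(make_map(c(8, 0, 0, 0))), 2)
  # occupancy (0.9, 0.1), all spikes in the rare bin: log2(10)
  m <- make_map(c(0, 10), occ = c(0.9, 0.1))
  expect_equal(spatial_information(m), 0.1 * 10 * log2(10), tolerance = 1e-12)
  # zero mean rate undefined
  z <- spatial_information(make_map(rep(0, 10)))
  expect_true(is.na(z) && isTRUE(attr(z, "undefined")))
})

test_that("spatial information is non-negative on generated maps", {
  maps <- rate_maps(fix_run(), "fwd")
  si <- vapply(maps, function(m) as.numeric(spatial_information(m)),
               numeric(1))
  expect_true(all(si[!is.na(si)] >= 0))
})

test_that("rate map recovers a homogeneous rate and honors filters", {
  run <- fix_run()
  # homogeneous unit: uniform spiking over session time
  set.seed(4)
  dur <- max(run$time)
  hom <- sort(runif(round(5 * dur), 0, dur))
  m <- compute_rate_map(hom, run$time, run$position, run$velocity,
                        run$direction, "fwd")
  expect_equal(sum(m$occupancy_prob), 1, tolerance = 1e-9)
  expect_equal(m$mean_rate, sum(m$occupancy_prob * m$rates), tolerance = 1e-9)
  # ~13 spikes expected per 2-cm bin: Poisson noise leaves ~20% deviations
  expect_lt(mean(abs(m$rates - 5)) / 5, 0.25)
  expect_equal(median(m$rates), 5, tolerance = 0.15)
  # no spikes: all-zero map
  m0 <- compute_rate_map(numeric(0), run$time, run$position, run$velocity,
                         run$direction, "fwd")
  expect_true(all(m0$rates == 0) && m0$mean_rate == 0)
  # spikes only while resting are excluded by the velocity filter
  rest_t <- run$time[run$direction == "rest"]
  m_rest <- compute_rate_map(rest_t[seq(1, length(rest_t), by = 3)],
                             run$time, run$position, run$velocity,
                             run$direction, "fwd")
  expect_true(all(m_rest$rates == 0))
})

test_that("primary field length matches the analytic Gaussian crossing", {
  # Gaussian field, sigma = 8 cm: width at 20% of peak = 2*8*sqrt(2*ln 5)
  centres <- seq(1, 199, by = 2)
  rates <- 10 * exp(-0.5 * ((centres - 100) / 8)^2)
  m <- make_map(rates)
  m$bin_centres <- centres
  expect_equal(primary_field_length(m), 2 * 8 * sqrt(2 * log(5)),
               tolerance = 2 / 28.7)
  # single-bin field: one 2-cm bin
  expect_equal(primary_field_length(make_map(c(0, 0, 5, 0, 0))), 2)
  # plateau across the whole track: full track length
  expect_equal(primary_field_length(make_map(rep(4, 50))), 100)
  # sub-threshold peak is not a place cell
  na <- primary_field_length(make_map(rep(0.5, 10)))
  expect_true(is.na(na) && isTRUE(attr(na, "not_applicable")))
})

test_that("mean field length grows with generator field width", {
  mean_pfl <- vapply(c(4, 10), function(w) {
    cfg <- generator_config(seed = 37, field_width_range = c(w, w + 1),
                            n_cells = 25, n_laps = 12, low_tuned_fraction = 0,
                            n_assemblies_planted = 0)
    maps <- rate_maps(generate_run_session(cfg), "fwd")
    mean(vapply(maps, function(m) as.numeric(primary_field_length(m)),
                numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean_pfl[2], mean_pfl[1])
})

test_that("rate-map classification follows the two-step SMV/SI rule", {
  # constant map: zero variance, infinite SMV -> low tuned
  expect_equal(classify_rate_map(make_map(rep(3, 50)))$category, "low_tuned")
  # end-peaked map with an equal symmetric partner: SI = 1 -> symmetric
  rates <- numeric(50)
  rates[5] <- 10; rates[46] <- 10
  cl <- classify_rate_map(make_map(rates))
  expect_equal(cl$si, 1)
  expect_equal(cl$category, "symmetric")
  # no symmetric firing: SI = 0 -> well tuned
  rates2 <- numeric(50); rates2[5] <- 10
  cl2 <- classify_rate_map(make_map(rates2))
  expect_equal(cl2$si, 0)
  expect_equal(cl2$category, "well_tuned")
  # middle peak skips the symmetry step
  rates3 <- numeric(50); rates3[25] <- 10
  cl3 <- classify_rate_map(make_map(rates3))
  expect_equal(cl3$category, "well_tuned")
  expect_false(cl3$symmetry_tested)
})

test_that("SI matches a direct evaluation on an arbitrary map", {
  set.seed(11)
  rates <- runif(50, 0, 8)
  m <- make_map(rates)
  cl <- classify_rate_map(m, smv_threshold = Inf)
  pk <- which.max(rates)
  if (cl$symmetry_tested) {
    win <- function(b) mean(rates[max(1, b - 2):min(50, b + 2)])
    pf <- win(pk)
    sym <- which.min(abs(m$bin_centres - (100 - m$bin_centres[pk])))
    pfs <- win(sym)
    expect_equal(cl$si, 1 - (pf - pfs) / (pf + pfs), tolerance = 1e-12)
  } else {
    expect_true(m$bin_centres[pk] > 30 && m$bin_centres[pk] < 70)
  }
})

test_that("classification counts are robust over the stated threshold ranges", {
  maps <- rate_maps(fix_run(), "fwd")
  cats <- function(smv, si) {
    table(factor(vapply(maps, function(m)
      classify_rate_map(m, smv, si)$category, character(1)),
      levels = c("low_tuned", "symmetric", "well_tuned")))
  }
  base <- cats(3.62, 0.67)
  for (smv in c(2.5, 4.0)) for (si in c(0.6, 0.75)) {
    delta <- abs(cats(smv, si) - base)
    expect_lt(max(delta) / length(maps), 0.1)
  }
})

test_that("SMV threshold recalibration returns the reference 99th percentile", {
  set.seed(2)
  ref <- lapply(1:50, function(k) make_map(runif(50, 0, 10)))
  thr <- smv_threshold_from_reference(ref)
  smv <- vapply(ref, function(m) mean(m$rates)^2 / var(m$rates), numeric(1))
  expect_equal(thr, unname(quantile(smv, 0.99)))
})

test_that("map stability is high for stationary fields and 1 for identical halves", {
  run <- fix_run()
  gt <- run$ground_truth
  well <- gt$unit[gt$direction == "fwd" & !gt$low_tuned][1:8]
  st <- vapply(well, function(u) map_stability(run$spikes[[u]], run, "fwd"),
               numeric(1))
  expect_gt(median(st), 0.9)
  short <- generate_run_session(generator_config(seed = 2, n_cells = 6,
                                                 n_laps = 3))
  expect_error(map_stability(short$spikes[[1]], short, "fwd"),
               "insufficient-data")
})

test_that("lap detection finds every out-and-back traversal", {
  run <- fix_run()
  laps <- detect_laps(run$time, run$position, run$config$track_length)
  expect_equal(sum(laps$direction == "fwd"), run$config$n_laps)
  expect_equal(sum(laps$direction == "bwd"), run$config$n_laps)
})
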
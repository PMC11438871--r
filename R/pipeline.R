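## Study-level orchestration: multi-animal synthetic studies, the
## pattern-separation multiple regression with likelihood-ratio tests, and
## the geometric-experience recovery index.

#' Run a two-group synthetic study end to end
#'
#' For each animal, generates a run and a sleep session from its group's
#' generator configuration, then computes rate maps and tuning metrics, the
#' encoding model and run decoding error, detects sleep frames and
#' classifies their trajectory content, scores frame-ensemble similarity
#' and clusters, detects run assemblies and their sleep activation, and
#' summarizes population-vector geometry. Results come back as tidy
#' per-animal tables; with `out_dir` set they are also written as CSV plus
#' a JSON summary.
#'
#' @param design data.frame with one row per animal: `animal` (id), `group`
#'   (label), `mirror_weight` (group tuning warp), optionally `n_cells`,
#'   `seed_offset`.
#' @param seed root seed; per-animal seeds derive from it.
#' @param n_shuffles shuffles for frame classification (default 100 at
#'   study scale; individual analyses expose 500).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param config_fn optional function(animal_row, seed) returning a
#'   [generator_config()]; the default builds one from the row.
#' @return list: `animals` (per-animal result lists), `summary` (tidy
#'   data.frame), `seed`.
#' @export
run_study <- function(design, seed = 1L, n_shuffles = 100, out_dir = NULL,
                      config_fn = NULL) {
  if (!nrow(design)) {
    warning("empty design: nothing to do")
    return(list(animals = list(), summary = data.frame(), seed = seed))
  }
  if (is.null(config_fn)) {
    config_fn <- function(row, sd) {
      generator_config(seed = sd,
                       mirror_weight = row$mirror_weight,
                       n_cells = if ("n_cells" %in% names(row)) row$n_cells else 40L,
                       n_laps = 12L, sleep_duration = 300)
    }
  }
  animals <- list()
  rows <- list()
  for (k in seq_len(nrow(design))) {
    row <- design[k, ]
    a_seed <- substream_seed(seed, paste0("animal-", row$animal))
    cfg <- config_fn(row, a_seed)
    run <- generate_run_session(cfg)
    model <- build_encoding_model(run, "fwd")
    maps <- rate_maps(run, "fwd")
    mets <- tuning_metrics(maps)
    dec <- run_decoding_error(run, model, n_shuffles = n_shuffles,
                              seed = a_seed)
    sleep <- generate_sleep_session(cfg, model)
    frames <- detect_frames(sleep$spikes,
                            sleep$epochs[sleep$epochs$label == "nrem", ],
                            t_range = c(0, sleep$duration))
    posts <- lapply(frames, function(fr)
      decode_counts(fr$counts[model$included_units, , drop = FALSE],
                    model, 0.02))
    cls <- classify_frames(posts, n_shuffles = n_shuffles,
                           seed = a_seed, shuffled_dataset = FALSE)
    counts <- do.call(cbind, lapply(frames, function(fr) rowSums(fr$counts)))
    sim <- if (!is.null(counts) && ncol(counts) >= 10) {
      frame_similarity(counts, n_shuffles = n_shuffles, seed = a_seed)
    } else NULL
    clus <- if (!is.null(sim)) {
      cluster_frames(sim, n_iter = 20, seed = a_seed)
    } else NULL
    move <- mask_to_intervals(run$direction != "rest")
    move_iv <- cbind(run$time[move[, 1]], run$time[move[, 2]])
    act <- bin_activity(run$spikes, move_iv)
    amod <- detect_assemblies(act)
    pv <- pv_matrix(maps)
    wp <- warp_profile(pv)
    ends <- track_end_similarity(pv)
    frame_rates <- if (!is.null(counts)) rowSums(counts) /
      sum(vapply(frames, `[[`, numeric(1), "duration")) else numeric(0)
    mean_sim <- if (!is.null(sim)) mean(sim$scores[upper.tri(sim$scores)],
                                        na.rm = TRUE) else NA_real_
    animals[[as.character(row$animal)]] <-
      list(config = cfg, metrics = mets, decoding = dec, frames = cls,
           clusters = clus, assemblies = amod, warp = wp,
           end_similarity = ends)
    rows[[k]] <- data.frame(
      animal = row$animal, group = row$group,
      n_place_cells = sum(mets$is_place_cell),
      median_decode_error = dec$median_error,
      prop_significant_frames = cls$proportion,
      n_frames = cls$n_frames,
      k_clusters = if (!is.null(clus)) clus$k_optimal else NA_integer_,
      n_assemblies = amod$n_significant,
      end_similarity = ends, warp_slope = wp$slope,
      mean_spatial_info = mean(mets$spatial_information, na.rm = TRUE),
      mean_frame_rate = if (length(frame_rates)) mean(frame_rates) else NA,
      var_frame_rate = if (length(frame_rates)) stats::var(frame_rates) else NA,
      mean_frame_similarity = mean_sim)
  }
  summary <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "study_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(seed = seed, n_animals = nrow(design),
                              groups = as.list(table(design$group))),
                         file.path(out_dir, "study_meta.json"),
                         auto_unbox = TRUE)
  }
  list(animals = animals, summary = summary, seed = seed)
}

#' Pattern-separation multiple regression with likelihood-ratio tests
#'
#' Ordinary least-squares regression of the across-track PV correlation on
#' the six study predictors (age, rearing label, mean sleep firing rate,
#' across-neuron sleep rate variance, mean frame-pair similarity, run
#' spatial information), followed by one likelihood-ratio test per
#' predictor: the full model against the model with that predictor removed,
#' with the deviance difference referred to a chi-square on the dropped
#' degrees of freedom.
#'
#' @param data data.frame of complete cases.
#' @param response response column name.
#' @param predictors character vector of predictor column names.
#' @param condition_cutoff condition-number warning threshold (default
#'   1e6).
#' @return list: `fit` (the full `lm`), `coefficients` (table),
#'   `lrt` (predictor, deviance_diff, df, p), `condition_number`.
#' @export
pattern_separation_regression <- function(data, response,
                                          predictors,
                                          condition_cutoff = 1e6) {
  keep <- stats::complete.cases(data[, c(response, predictors)])
  data <- data[keep, ]
  zero_var <- predictors[vapply(predictors, function(p) {
    v <- data[[p]]
    is.numeric(v) && stats::var(v) == 0
  }, logical(1))]
  if (length(zero_var)) {
    stop("zero-variance predictor(s): ", paste(zero_var, collapse = ", "))
  }
  if (nrow(data) < length(predictors) + 2) {
    stop("need at least predictors + 2 complete rows")
  }
  full_f <- stats::reformulate(predictors, response)
  full <- stats::lm(full_f, data = data)
  X <- stats::model.matrix(full)
  cn <- kappa(X, exact = TRUE)
  if (cn > condition_cutoff) {
    warning("collinear predictors (condition number ", format(cn, digits = 3),
            "); fit retained")
  }
  ll_full <- stats::logLik(full)
  lrt <- do.call(rbind, lapply(predictors, function(p) {
    red <- stats::lm(stats::reformulate(setdiff(predictors, p), response),
                     data = data)
    dd <- as.numeric(2 * (ll_full - stats::logLik(red)))
    df <- attr(ll_full, "df") - attr(stats::logLik(red), "df")
    data.frame(predictor = p, deviance_diff = dd, df = df,
               p = stats::pchisq(dd, df, lower.tail = FALSE))
  }))
  list(fit = full, coefficients = summary(full)$coefficients, lrt = lrt,
       condition_number = cn, n = nrow(data))
}

#' Geometric-experience recovery index
#'
#' For each named parameter, the index is the ratio of the between-group
#' difference after extended experience with geometric linearity to the
#' difference before it: 0 means full recovery, 1 none. The summary index
#' is the equal-weight mean, reported with leave-one-out sensitivity
#' indices; ratios are clipped to `[0, 1]` for the reported scale with the
#' raw values retained.
#'
#' @param baseline_diff named numeric vector: group difference per
#'   parameter before the experience.
#' @param final_diff named numeric vector (same names): difference after.
#'   Parameters the design scores as fully recovered should be supplied
#'   as 0.
#' @return a `recovery_index`: `per_parameter` (raw and clipped ratios),
#'   `index`, `leave_one_out`.
#' @export
recovery_index <- function(baseline_diff, final_diff) {
  if (!all(names(baseline_diff) %in% names(final_diff))) {
    stop("missing parameter without imputation rule")
  }
  final_diff <- final_diff[names(baseline_diff)]
  if (any(baseline_diff == 0)) stop("zero baseline difference: ratio undefined")
  raw <- as.numeric(final_diff) / as.numeric(baseline_diff)
  clipped <- pmin(1, pmax(0, raw))
  names(raw) <- names(clipped) <- names(baseline_diff)
  loo <- vapply(seq_along(clipped), function(k) mean(clipped[-k]), numeric(1))
  names(loo) <- names(clipped)
  structure(list(per_parameter = data.frame(parameter = names(raw),
                                            raw_ratio = raw,
                                            ratio = clipped),
                 index = mean(clipped), leave_one_out = loo),
            class = "recovery_index")
}
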
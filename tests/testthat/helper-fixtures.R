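# Shared synthetic fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Standard run session: 50 cells, 20 lap cycles, no warp.
fix_run <- function() fixture("run", function() {
  generate_run_session(generator_config(seed = 101))
})

fix_model <- function() fixture("model", function() {
  build_encoding_model(fix_run(), "fwd")
})

# Sleep with 40% embedded sequences, matching templates.
fix_sleep_seq <- function() fixture("sleep_seq", function() {
  generate_sleep_session(generator_config(seed = 101, seq_frame_fraction = 0.4),
                         fix_model())
})

# Sleep with cluster frames only.
fix_sleep_cl <- function() fixture("sleep_cl", function() {
  generate_sleep_session(generator_config(seed = 101, seq_frame_fraction = 0),
                         fix_model())
})

detected_frames <- function(sleep) {
  detect_frames(sleep$spikes, sleep$epochs[sleep$epochs$label == "nrem", ],
                t_range = c(0, sleep$duration))
}

# Match detected frames (table rows) to planted frame indices by overlap.
match_frames_to_truth <- function(frame_table, frame_truth, min_ov = 0.05) {
  vapply(seq_len(nrow(frame_table)), function(k) {
    ov <- pmax(0, pmin(frame_table$end[k], frame_truth$end) -
                 pmax(frame_table$start[k], frame_truth$start))
    if (max(ov) > min_ov) which.max(ov) else NA_integer_
  }, integer(1))
}

# Gaussian-bump posterior matrix over given peak locations (bin index).
bump_posterior <- function(peaks, n_loc, width = 2) {
  P <- do.call(rbind, lapply(peaks, function(p) {
    v <- exp(-0.5 * ((seq_len(n_loc) - p) / width)^2)
    v / sum(v)
  }))
  P
}

# Brute-force weighted correlation by direct double summation.
wc_oracle <- function(P, loc = seq_len(ncol(P)), t = seq_len(nrow(P))) {
  W <- 0; sl <- 0; st <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    W <- W + P[i, j]; sl <- sl + P[i, j] * loc[j]; st <- st + P[i, j] * t[i]
  }
  ml <- sl / W; mt <- st / W
  cll <- clt <- ctt <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    cll <- cll + P[i, j] * (loc[j] - ml)^2
    ctt <- ctt + P[i, j] * (t[i] - mt)^2
    clt <- clt + P[i, j] * (loc[j] - ml) * (t[i] - mt)
  }
  clt / sqrt(cll * ctt)
}
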
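## Co-activation cell assemblies: PCA of z-scored 20-ms binned run activity
## with the Marcenko-Pastur eigenvalue bound, zero-diagonal projection
## matrices, sleep activation strength A_c(t) = z(t)' P_c z(t), and
## experience-dependent reactivation plasticity.

#' Z-scored binned population activity
#'
#' Bins each unit's spikes at `bin_s` within the supplied intervals and
#' z-scores each unit's counts across bins (limiting bias toward
#' high-firing units). Units with zero count variance are dropped with a
#' flag.
#'
#' @param spikes per-unit spike-time list.
#' @param intervals matrix/data.frame of (start, end) intervals, s, to bin
#'   within (e.g. movement epochs or NREM epochs); contiguous bins are laid
#'   inside each interval.
#' @param bin_s bin width, s (default 0.02).
#' @return a `binned_activity`: `Z` (units x bins, row mean 0 / SD 1),
#'   `counts` (raw), `units` (kept ids), `dropped`, `bin_s`.
#' @export
bin_activity <- function(spikes, intervals, bin_s = 0.02) {
  intervals <- as.matrix(intervals)[, 1:2, drop = FALSE]
  edges_l <- lapply(seq_len(nrow(intervals)), function(k) {
    nb <- floor((intervals[k, 2] - intervals[k, 1]) / bin_s)
    if (nb < 1) return(NULL)
    intervals[k, 1] + (0:nb) * bin_s
  })
  cnt <- do.call(cbind, lapply(edges_l[!vapply(edges_l, is.null, logical(1))],
                               function(e) bin_spike_counts(spikes, e)))
  sds <- apply(cnt, 1, stats::sd)
  keep <- sds > 0
  Z <- t(scale(t(cnt[keep, , drop = FALSE])))
  structure(list(Z = Z, counts = cnt[keep, , drop = FALSE],
                 units = which(keep), dropped = which(!keep), bin_s = bin_s),
            class = "binned_activity")
}

#' Detect cell assemblies by PCA with the Marcenko-Pastur bound
#'
#' Eigen-decomposes the correlation matrix of the z-scored activity and
#' keeps components whose eigenvalue exceeds the Marcenko-Pastur upper
#' bound \eqn{\lambda_{max} = (1 + \sqrt{n/M})^2} for an n x M matrix of
#' IID unit-variance entries. `normalization = "correlation"` uses
#' \eqn{(1/M) Z Z^T}, the correlation matrix of row-z-scored Z, which is
#' the scale the bound assumes; `"as_printed"` uses \eqn{(1/n) Z Z^T} for
#' compatibility. Each significant component's outer product with zeroed
#' diagonal becomes its projection matrix.
#'
#' @param act a `binned_activity` (run movement epochs).
#' @param normalization `"correlation"` (default) or `"as_printed"`.
#' @return an `assembly_model`: `eigenvalues` (descending), `lambda_max`,
#'   `n_significant`, `patterns` (unit-weight vectors, columns),
#'   `projections` (list of zero-diagonal matrices), `members` (per
#'   assembly, units with |weight| > 2 SD of the component weights),
#'   `units`.
#' @export
detect_assemblies <- function(act, normalization = c("correlation",
                                                     "as_printed")) {
  normalization <- match.arg(normalization)
  Z <- act$Z
  n <- nrow(Z); M <- ncol(Z)
  if (n < 2 || M < n) stop("need n >= 2 units and M >= n bins")
  ## sample-SD z-scored rows: dividing by M - 1 makes C the exact sample
  ## correlation matrix (unit diagonal, trace n)
  C <- if (normalization == "correlation") {
    Z %*% t(Z) / (M - 1)
  } else {
    Z %*% t(Z) / n
  }
  eig <- eigen(C, symmetric = TRUE)
  lambda_max <- (1 + sqrt(n / M))^2
  sig <- which(eig$values > lambda_max)
  patterns <- eig$vectors[, sig, drop = FALSE]
  projections <- lapply(seq_along(sig), function(k) {
    p <- patterns[, k]
    P <- tcrossprod(p)
    diag(P) <- 0
    P
  })
  ## membership (validation only): near-degenerate eigenvalues mix the
  ## eigenvectors of co-equal assemblies, so extract members from the
  ## varimax-rotated significant subspace; projections stay on the raw
  ## components as defined
  mem_basis <- patterns
  if (length(sig) > 1) {
    mem_basis <- patterns %*% stats::varimax(patterns)$rotmat
  }
  members <- lapply(seq_along(sig), function(k) {
    w <- mem_basis[, k]
    act$units[abs(w) > 2 * stats::sd(w)]
  })
  structure(list(eigenvalues = eig$values, lambda_max = lambda_max,
                 n_significant = length(sig), patterns = patterns,
                 projections = projections, members = members,
                 units = act$units, normalization = normalization),
            class = "assembly_model")
}

#' Assembly activation strength in binned activity
#'
#' \eqn{A_c(t) = z(t)^T P_c z(t)} per 20-ms bin, with the projection
#' diagonal zeroed so single-unit firing cannot drive activation.
#' Significant activation events are contiguous supra-threshold runs
#' collapsed to their peak bin, and must contain at least `min_active`
#' spiking units of which at least one is a place cell (when
#' `place_cells` is supplied).
#'
#' @param model an `assembly_model` (from run activity).
#' @param act a `binned_activity` for the epoch to score (e.g. NREM sleep);
#'   its units must cover the model's units -- model units missing here are
#'   treated as silent (zero) rows and flagged.
#' @param threshold activation threshold (default 5).
#' @param min_active minimum spiking units per event bin (default 2).
#' @param place_cells optional unit ids counted as place cells.
#' @return an `assembly_activation`: `A` (assemblies x bins), `events`
#'   (per-assembly event bins and strengths), `mean_activation` (over event
#'   peaks), `missing_units`.
#' @export
activation_strength <- function(model, act, threshold = 5, min_active = 2,
                                place_cells = NULL) {
  idx <- match(model$units, act$units)
  missing <- model$units[is.na(idx)]
  M <- ncol(act$Z)
  Z <- matrix(0, length(model$units), M)
  Z[!is.na(idx), ] <- act$Z[idx[!is.na(idx)], , drop = FALSE]
  cnt <- matrix(0, length(model$units), M)
  cnt[!is.na(idx), ] <- act$counts[idx[!is.na(idx)], , drop = FALSE]
  nC <- model$n_significant
  A <- matrix(0, nC, M)
  for (c in seq_len(nC)) {
    p <- model$patterns[, c]
    s <- as.numeric(crossprod(Z, p))          # p' z(t)
    q <- as.numeric(crossprod(Z^2, p^2))      # diagonal part
    A[c, ] <- s^2 - q
  }
  events <- vector("list", nC)
  mean_act <- rep(NA_real_, nC)
  act_units <- cnt > 0
  for (c in seq_len(nC)) {
    above <- A[c, ] > threshold
    iv <- mask_to_intervals(above)
    ev <- list()
    if (!is.null(dim(iv))) {
      for (k in seq_len(nrow(iv))) {
        seg <- iv[k, 1]:iv[k, 2]
        pk <- seg[which.max(A[c, seg])]
        n_on <- sum(act_units[, pk])
        has_pc <- is.null(place_cells) ||
          any(model$units[act_units[, pk]] %in% place_cells)
        if (n_on >= min_active && has_pc) {
          ev[[length(ev) + 1L]] <- c(bin = pk, strength = A[c, pk])
        }
      }
    }
    if (length(ev)) {
      em <- do.call(rbind, ev)
      events[[c]] <- data.frame(bin = em[, "bin"], strength = em[, "strength"])
      mean_act[c] <- mean(em[, "strength"])
    } else {
      events[[c]] <- data.frame(bin = integer(0), strength = numeric(0))
    }
  }
  structure(list(A = A, events = events, mean_activation = mean_act,
                 missing_units = missing, threshold = threshold),
            class = "assembly_activation")
}

#' Reactivation plasticity of assemblies across sleeps
#'
#' Per assembly, the mean activation over significant events in the
#' post-run sleep minus that in the pre-run sleep, with a two-sided
#' rank-sum test across activation instances; plus a group-level signed-rank
#' test across assemblies.
#'
#' @param model an `assembly_model`.
#' @param pre,post `binned_activity` for the pre- and post-run NREM sleep.
#' @param ... passed to [activation_strength()].
#' @return list: `table` (assembly, pre_mean, post_mean, delta, p_ranksum,
#'   n_pre, n_post), `group_p` (signed-rank across assemblies).
#' @export
reactivation_plasticity <- function(model, pre, post, ...) {
  a_pre <- activation_strength(model, pre, ...)
  a_post <- activation_strength(model, post, ...)
  nC <- model$n_significant
  rows <- lapply(seq_len(nC), function(c) {
    sp <- a_pre$events[[c]]$strength
    so <- a_post$events[[c]]$strength
    d <- if (length(sp) && length(so)) mean(so) - mean(sp) else NA_real_
    p <- if (length(sp) >= 1 && length(so) >= 1) {
      suppressWarnings(stats::wilcox.test(so, sp)$p.value)
    } else NA_real_
    data.frame(assembly = c, pre_mean = if (length(sp)) mean(sp) else NA,
               post_mean = if (length(so)) mean(so) else NA, delta = d,
               p_ranksum = p, n_pre = length(sp), n_post = length(so))
  })
  tab <- do.call(rbind, rows)
  deltas <- tab$delta[!is.na(tab$delta)]
  group_p <- if (length(deltas) >= 2) {
    suppressWarnings(stats::wilcox.test(deltas, mu = 0,
                                        alternative = "two.sided",
                                        exact = FALSE)$p.value)
  } else NA_real_
  list(table = tab, group_p = group_p, pre = a_pre, post = a_post)
}
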
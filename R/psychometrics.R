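# Psychometrics: proportion-coincident curves, the empirical d' statistic
# referenced to pc_max, its closed-form prediction for the difference-
# criterion observer, and subject-resampling bootstrap confidence intervals.

#' Proportion of coincidence responses per stimulus cell
#'
#' @param responses data.frame of trial rows (`subject_id`, `visual_m`,
#'   `auditory_m`, `trial_idx`, `response`), e.g. from
#'   [simulate_coincidence_responses()].
#' @param pooled if `TRUE` (default), pool trials across subjects per
#'   (visual, auditory) cell; if `FALSE`, keep cells per subject.
#' @return data.frame with columns (`subject_id` unless pooled,) `visual_m`,
#'   `auditory_m`, `n` (trial count), `pc` (proportion coincident).
#' @examples
#' r <- simulate_coincidence_responses(default_design(), observer_params())
#' head(proportion_coincident(r))
#' @export
proportion_coincident <- function(responses, pooled = TRUE) {
  validate_responses(responses)
  keys <- if (pooled) c("visual_m", "auditory_m") else
    c("subject_id", "visual_m", "auditory_m")
  agg <- stats::aggregate(responses$response, responses[keys],
                          function(x) c(n = length(x), k = sum(x)))
  out <- agg[keys]
  out$n <- as.integer(agg$x[, "n"])
  out$pc <- agg$x[, "k"] / agg$x[, "n"]
  if (any(out$n == 0)) stop("empty cell after grouping")
  ord <- do.call(order, out[keys])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# clamp pc away from 0/1 so the z-transform stays finite
clamp_pc <- function(pc, n) pmin(pmax(pc, 1 / (2 * n)), 1 - 1 / (2 * n))

# index of the reference (pc_max) cell; ties go to the distance closest to
# the visual target, remaining ties to the smaller distance
ref_index <- function(pc, auditory_m, visual_m) {
  tie <- which(pc >= max(pc) - 1e-12)
  tie <- tie[order(abs(auditory_m[tie] - visual_m), auditory_m[tie])]
  tie[1]
}

#' Empirical d' curve from proportions coincident
#'
#' Converts a block's proportion-coincident values to the discriminability
#' statistic `d' = z(pc_max) - z(pc)`, where `z` is the standard-normal
#' quantile and `pc_max` is the maximum proportion coincident across the
#' block's auditory distances. Before the z-transform each `pc` is clamped
#' to `[1/(2n), 1 - 1/(2n)]` so that cells with all-or-none responding stay
#' finite. `d'` is 0 at the reference distance and positive elsewhere,
#' measuring perceptual mismatch relative to the point of strongest capture.
#'
#' @param auditory_m auditory distances (m), length >= 2.
#' @param pc proportions coincident in \[0, 1\], same length.
#' @param n trial count per cell (scalar or vector).
#' @param visual_m the block's visual-target distance (m); used to break
#'   `pc_max` ties in favor of the distance closest to the visual target.
#' @return data.frame with columns `visual_m`, `auditory_m`, `n`, `pc`,
#'   `dprime`, plus attribute `ref_distance_m` (distance where `pc_max`
#'   occurs).
#' @examples
#' dprime_curve(c(2, 3, 4), pc = c(0.5, 0.9, 0.7), n = 330, visual_m = 3)
#' @export
dprime_curve <- function(auditory_m, pc, n, visual_m) {
  stopifnot(length(auditory_m) >= 2, length(pc) == length(auditory_m))
  if (any(pc < 0 | pc > 1)) stop("pc must lie in [0, 1]")
  if (any(n < 1)) stop("n must be >= 1")
  n <- rep_len(n, length(pc))
  z <- stats::qnorm(clamp_pc(pc, n))
  i <- ref_index(pc, auditory_m, visual_m)
  out <- data.frame(visual_m = visual_m, auditory_m = auditory_m,
                    n = n, pc = pc, dprime = z[i] - z)
  attr(out, "ref_distance_m") <- auditory_m[i]
  out
}

#' Empirical d' curves for every block of a response table
#'
#' Convenience wrapper: computes proportions coincident with
#' [proportion_coincident()] and a [dprime_curve()] per visual-target block
#' (and per subject when `pooled = FALSE`).
#'
#' @inheritParams proportion_coincident
#' @return data.frame stacking the per-block curves, with columns
#'   (`subject_id`,) `visual_m`, `auditory_m`, `n`, `pc`, `dprime`,
#'   `ref_distance_m`.
#' @examples
#' r <- simulate_coincidence_responses(default_design(), observer_params())
#' d <- empirical_dprime(r)
#' subset(d, visual_m == 3)
#' @export
empirical_dprime <- function(responses, pooled = TRUE) {
  pcs <- proportion_coincident(responses, pooled = pooled)
  keys <- if (pooled) list(pcs$visual_m) else list(pcs$subject_id, pcs$visual_m)
  parts <- split(pcs, keys, drop = TRUE)
  out <- lapply(parts, function(p) {
    cur <- dprime_curve(p$auditory_m, p$pc, p$n, visual_m = p$visual_m[1])
    cur$ref_distance_m <- attr(cur, "ref_distance_m")
    if (!pooled) cur <- cbind(subject_id = p$subject_id[1], cur)
    cur
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Closed-form proportion coincident for the difference-criterion observer
#'
#' For log-percept difference `D ~ N(mu_diff, sd_diff^2)` and acceptance
#' region `|D| <= criterion`, returns `P(|D| <= criterion)`:
#' `pnorm((c - mu)/sd) - pnorm((-c - mu)/sd)`. This is the analytic oracle
#' for [simulate_coincidence_responses()]; `mu_diff` is the difference of the
#' two log-space percept means and `sd_diff^2 = s_aud^2 + s_vis^2 -
#' 2 r s_aud s_vis`.
#'
#' @param mu_diff mean of the log-percept difference.
#' @param sd_diff standard deviation of the difference (> 0).
#' @param criterion acceptance half-width (> 0).
#' @return probability vector, same length as `mu_diff`.
#' @examples
#' predict_pc(0, 1, 1.96)  # ~0.95
#' @export
predict_pc <- function(mu_diff, sd_diff, criterion) {
  if (any(sd_diff <= 0)) stop("sd_diff must be positive")
  if (any(criterion <= 0)) stop("criterion must be positive")
  stats::pnorm((criterion - mu_diff) / sd_diff) -
    stats::pnorm((-criterion - mu_diff) / sd_diff)
}

#' Subject-resampling bootstrap confidence intervals for d'
#'
#' Resamples subjects with replacement `B` times, recomputes the pooled
#' proportion coincident and the d' curve for each resample (including
#' re-finding the `pc_max` reference), and reports percentile confidence
#' bounds per auditory distance. Trials within a subject are kept intact;
#' only subjects are resampled.
#'
#' @param responses trial-level response table (>= 2 subjects).
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed for the resampling.
#' @param conf confidence level (default 0.95).
#' @return the pooled [empirical_dprime()] table with added columns
#'   `ci_low`, `ci_high`.
#' @examples
#' r <- simulate_coincidence_responses(default_design(), observer_params())
#' head(bootstrap_dprime(r, B = 200, seed = 7))
#' @export
bootstrap_dprime <- function(responses, B = 1000, seed = 1L, conf = 0.95) {
  validate_responses(responses)
  if (B < 1) stop("B must be >= 1")
  subjects <- sort(unique(responses$subject_id))
  S <- length(subjects)
  if (S < 2) stop("subject-level bootstrap needs at least 2 subjects")
  point <- empirical_dprime(responses, pooled = TRUE)
  alpha <- (1 - conf) / 2

  set.seed(as.integer(seed))
  # multiplicity matrix: row = resample, col = subject
  M <- t(vapply(seq_len(B),
                function(i) tabulate(sample.int(S, S, replace = TRUE), S),
                integer(S)))

  point$ci_low <- NA_real_
  point$ci_high <- NA_real_
  for (v in unique(responses$visual_m)) {
    blk <- responses[responses$visual_m == v, ]
    C <- stats::xtabs(response ~ factor(subject_id, levels = subjects) +
                        factor(auditory_m), data = blk)
    N <- stats::xtabs(~ factor(subject_id, levels = subjects) +
                        factor(auditory_m), data = blk)
    dist <- as.numeric(colnames(C))
    kb <- M %*% C          # B x ndist coincident counts
    nb <- M %*% N          # B x ndist trial counts
    pcb <- kb / nb
    dmat <- matrix(NA_real_, B, length(dist))
    for (i in seq_len(B)) {
      z <- stats::qnorm(clamp_pc(pcb[i, ], nb[i, ]))
      dmat[i, ] <- z[ref_index(pcb[i, ], dist, v)] - z
    }
    ci <- apply(dmat, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    sel <- which(point$visual_m == v)
    idx <- match(round(point$auditory_m[sel], 9), round(dist, 9))
    point$ci_low[sel] <- ci[1, idx]
    point$ci_high[sel] <- ci[2, idx]
  }
  point
}
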
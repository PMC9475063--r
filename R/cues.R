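# Acoustic distance cues: dB-per-doubling fits for broadband level and
# direct-to-reverberant energy ratio (DRR), and the critical distance (the
# distance at which direct and reverberant energies are equal, DRR = 0 dB).

#' Fit a dB-per-doubling function to an acoustic cue
#'
#' Ordinary least squares of the cue (dB) on `log2(distance)`; the slope is
#' the cue's change in dB per doubling of source distance (negative for
#' level and DRR, which decay with distance).
#'
#' @param distance_m source distances (m), >= 2 distinct positive values.
#' @param cue_db cue values (dB), same length.
#' @return list of class `av_cuefit`: `slope_db_per_doubling`,
#'   `intercept_db` (cue value at 1 m), `r_squared`, `n`, and the fitted
#'   distance range `range_m`.
#' @examples
#' x <- c(1, 2, 4)
#' fit_db_per_doubling(x, 60 - 6 * log2(x))  # slope -6 dB/doubling
#' @export
fit_db_per_doubling <- function(distance_m, cue_db) {
  if (length(distance_m) != length(cue_db)) stop("input lengths differ")
  if (any(distance_m <= 0)) stop("distances must be positive")
  if (length(unique(distance_m)) < 2)
    stop("need at least 2 distinct distances")
  l2 <- log2(distance_m)
  fit <- stats::lm(cue_db ~ l2)
  sse <- sum(stats::resid(fit)^2)
  sst <- sum((cue_db - mean(cue_db))^2)
  structure(list(
    slope_db_per_doubling = unname(stats::coef(fit)[2]),
    intercept_db = unname(stats::coef(fit)[1]),
    r_squared = if (sst > 0) max(0, min(1, 1 - sse / sst)) else
      as.numeric(sse < 1e-12),
    n = length(distance_m),
    range_m = range(distance_m)), class = "av_cuefit")
}

#' @export
print.av_cuefit <- function(x, ...) {
  cat(sprintf("Cue fit: %.3f dB/doubling, %.2f dB at 1 m (R^2 = %.4f, n = %d)\n",
              x$slope_db_per_doubling, x$intercept_db, x$r_squared, x$n))
  invisible(x)
}

#' Critical distance from a fitted DRR function
#'
#' Solves `intercept + slope * log2(x) = 0` for the distance at which the
#' direct-to-reverberant ratio crosses 0 dB, i.e. where direct and
#' reverberant energies are equal: `x = 2^(-intercept / slope)`.
#'
#' @param drr_fit an `av_cuefit` for the DRR cue (nonzero slope).
#' @return critical distance (m), with attribute `extrapolated = TRUE` when
#'   the crossing lies outside the fitted distance range.
#' @examples
#' fit <- fit_db_per_doubling(c(1, 2, 4), 10 - 10 * log2(c(1, 2, 4)))
#' critical_distance(fit)  # 2 m
#' @export
critical_distance <- function(drr_fit) {
  if (!inherits(drr_fit, "av_cuefit")) stop("drr_fit must come from fit_db_per_doubling()")
  s <- drr_fit$slope_db_per_doubling
  if (abs(s) < 1e-12)
    stop("DRR does not cross 0 dB: fitted slope is zero")
  x <- 2^(-drr_fit$intercept_db / s)
  attr(x, "extrapolated") <- x < drr_fit$range_m[1] || x > drr_fit$range_m[2]
  x
}

#' Synthetic cue table for a point source in a diffuse reverberant field
#'
#' Builds a synthetic `cues` table with direct energy following the
#' inverse-square law and a constant (diffuse) reverberant energy, so the
#' DRR crossing (critical distance) is known by construction:
#' `x_c = 10^(drr_at_1m_db / 20)`. Broadband level is the energy sum of the
#' two components. Intended for tests and demonstrations; real cue tables
#' come from room impulse-response measurements, which are out of scope
#' here.
#'
#' @param distance_m source distances (m).
#' @param level_at_1m_db direct-path level at 1 m (dB).
#' @param drr_at_1m_db direct-to-reverberant ratio at 1 m (dB); the implied
#'   critical distance is `10^(drr_at_1m_db / 20)` m.
#' @return data.frame with columns `distance_m`, `level_db`, `drr_db`, and
#'   attribute `critical_distance_m` (the construction's exact crossing).
#' @examples
#' ct <- synthetic_cue_table(seq(1, 5, 0.25), drr_at_1m_db = 7.5)
#' attr(ct, "critical_distance_m")  # 10^(7.5/20) ~ 2.37 m
#' @export
synthetic_cue_table <- function(distance_m, level_at_1m_db = 60,
                                drr_at_1m_db = 7.5) {
  if (any(distance_m <= 0)) stop("distances must be positive")
  e_direct <- 10^(level_at_1m_db / 10) / distance_m^2
  e_reverb <- 10^((level_at_1m_db - drr_at_1m_db) / 10)
  out <- data.frame(distance_m = distance_m,
                    level_db = 10 * log10(e_direct + e_reverb),
                    drr_db = 10 * log10(e_direct / e_reverb))
  attr(out, "critical_distance_m") <- 10^(drr_at_1m_db / 20)
  out
}
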
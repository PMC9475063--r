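# Coincidence models M1-M3: predicted discriminability between the
# perceived-auditory-distance and perceived-visual-distance distributions,
# as a function of auditory target distance.
#
# M1: normal percepts on a linear distance scale, variances fixed at the
#     value implied by a 3 m reference target.
# M2: as M1, but variances scale with each target's own perceived distance.
# M3: normal percepts on a logarithmic distance scale, i.e. log-normal in
#     linear space; log-normal moments are fed into the same d' expression.

#' Sensitivity index between two correlated percept distributions
#'
#' `d' = |mu_a - mu_v| / sqrt(sigma_a^2 + sigma_v^2 - 2 r sigma_a sigma_v)`,
#' the signal-detection measure of overlap between the perceived auditory
#' and visual distance distributions. `r` is the correlation between the
#' two percepts; `r > 0` shrinks the variance of their difference and so
#' sharpens discriminability.
#'
#' @param mu_a,mu_v distribution means (m).
#' @param sigma_a,sigma_v distribution standard deviations (m), >= 0.
#' @param r percept correlation in \[0, 1\].
#' @return d' (>= 0), vectorized over the inputs.
#' @examples
#' sensitivity_dprime(2, 1, 1, 0.5, 0)  # 1 / sqrt(1.25)
#' @export
sensitivity_dprime <- function(mu_a, mu_v, sigma_a, sigma_v, r = 0) {
  if (any(sigma_a < 0) || any(sigma_v < 0)) stop("sigmas must be >= 0")
  if (any(r < 0 | r > 1)) stop("r must lie in [0, 1]")
  v <- sigma_a^2 + sigma_v^2 - 2 * r * sigma_a * sigma_v
  if (any(v <= 0))
    stop("degenerate model: variance of the percept difference is not positive")
  abs(mu_a - mu_v) / sqrt(v)
}

#' Linear-space moments of a log-normal percept distribution
#'
#' Maps log-space parameters (`m_log`, `s_log`) of a normal distribution of
#' log distance to the mean and standard deviation of the corresponding
#' log-normal distribution of linear distance. Standard moments:
#' `mu = exp(m + s^2/2)`, `sigma^2 = (exp(s^2) - 1) exp(2m + s^2)`.
#'
#' `printed_formula = TRUE` switches the mean to `exp(m + s^2)`, an
#' alternative (non-standard) transform retained for comparison with
#' published variants of the conversion; the variance expression is the
#' same under both modes.
#'
#' @param m_log log-space mean (natural log of meters).
#' @param s_log log-space standard deviation (>= 0).
#' @param printed_formula use the alternative mean transform?
#' @return list with components `mu` and `sigma` (linear-space mean and SD,
#'   vectorized).
#' @examples
#' lognormal_moments(log(3), 0)            # mu = 3, sigma = 0
#' lognormal_moments(0, log(1.6982))$mu    # ~1.1505
#' @export
lognormal_moments <- function(m_log, s_log, printed_formula = FALSE) {
  if (any(s_log < 0)) stop("s_log must be >= 0")
  s2 <- s_log^2
  mu <- if (printed_formula) exp(m_log + s2) else exp(m_log + s2 / 2)
  sigma <- sqrt((exp(s2) - 1) * exp(2 * m_log + s2))
  list(mu = mu, sigma = sigma)
}

#' Specify a coincidence model
#'
#' Bundles the ingredients of a model-predicted d' curve: the variant
#' (`"M1"`, `"M2"`, `"M3"`), the auditory and visual power-law fits mapping
#' physical to mean perceived distance, the modality variability factors
#' (multiplicative spread of perceived distance; defaults `10^0.23` auditory
#' and `10^0.15` visual), the reference distance at which M1 freezes its
#' variances (default 3 m, the mean target distance of the standard design),
#' and the percept correlation `r`. `k_aud` optionally overrides the
#' auditory power-law constant — the free parameter of the model fits,
#' motivated by visual percepts serving as an absolute reference for
#' auditory judgments under bimodal stimulation.
#'
#' @param variant `"M1"`, `"M2"`, or `"M3"`.
#' @param aud_fit,vis_fit power-law parameters per modality: an
#'   `av_powerfit` or any list with `k` and `a`.
#' @param aud_factor,vis_factor variability factors (> 1).
#' @param reference_distance_m distance (m) at which M1 evaluates its fixed
#'   sigmas.
#' @param r percept correlation in \[0, 1\].
#' @param k_aud optional override of `aud_fit$k`.
#' @param printed_formula passed to [lognormal_moments()] (M3 only).
#' @return object of class `av_model`.
#' @examples
#' spec <- model_spec("M3", aud_fit = list(k = 1.32, a = 0.54),
#'                    vis_fit = list(k = 1, a = 0.98), r = 0.5)
#' predict_dprime(spec, visual_m = 3, auditory_m = c(2, 3, 4))
#' @export
model_spec <- function(variant = c("M3", "M1", "M2"),
                       aud_fit, vis_fit,
                       aud_factor = 10^0.23, vis_factor = 10^0.15,
                       reference_distance_m = 3,
                       r = 0, k_aud = NULL,
                       printed_formula = FALSE) {
  variant <- match.arg(variant)
  for (f in list(aud_fit, vis_fit))
    if (!is.numeric(f$k) || !is.numeric(f$a) || f$k <= 0)
      stop("aud_fit and vis_fit need positive k and numeric a")
  if (aud_factor <= 1 || vis_factor <= 1)
    stop("variability factors must exceed 1")
  if (reference_distance_m <= 0) stop("reference_distance_m must be positive")
  if (r < 0 || r > 1) stop("r must lie in [0, 1]")
  if (!is.null(k_aud) && k_aud <= 0) stop("k_aud override must be positive")
  structure(list(variant = variant,
                 aud_fit = list(k = aud_fit$k, a = aud_fit$a),
                 vis_fit = list(k = vis_fit$k, a = vis_fit$a),
                 aud_factor = aud_factor, vis_factor = vis_factor,
                 reference_distance_m = reference_distance_m,
                 r = r, k_aud = k_aud,
                 printed_formula = isTRUE(printed_formula)),
            class = "av_model")
}

#' @export
print.av_model <- function(x, ...) {
  k_a <- if (is.null(x$k_aud)) x$aud_fit$k else x$k_aud
  cat(sprintf(
    "%s coincidence model: aud %.3g x^%.3g (factor %.4f), vis %.3g x^%.3g (factor %.4f), r = %.3f\n",
    x$variant, k_a, x$aud_fit$a, x$aud_factor,
    x$vis_fit$k, x$vis_fit$a, x$vis_factor, x$r))
  invisible(x)
}

#' Model-predicted d' as a function of auditory target distance
#'
#' Computes the percept-distribution means and standard deviations implied
#' by the model variant and feeds them into [sensitivity_dprime()]:
#' \describe{
#'   \item{M1}{means `k x^a` per modality; sigmas fixed at
#'     `factor * k * ref^a` (evaluated at the reference distance).}
#'   \item{M2}{as M1 but sigmas scale with each target's own perceived
#'     distance, `factor * k * x^a`.}
#'   \item{M3}{log-space means `ln(k x^a)` and spreads `ln(factor)` are
#'     converted to linear-space log-normal moments via
#'     [lognormal_moments()] before entering the d' expression.}
#' }
#'
#' @param spec an `av_model` from [model_spec()].
#' @param visual_m the block's visual-target distance (m).
#' @param auditory_m auditory target distances (m), vectorized.
#' @return numeric vector of predicted d' values.
#' @export
predict_dprime <- function(spec, visual_m, auditory_m) {
  if (!inherits(spec, "av_model")) stop("spec must come from model_spec()")
  if (any(visual_m <= 0) || any(auditory_m <= 0))
    stop("distances must be positive")
  k_a <- if (is.null(spec$k_aud)) spec$aud_fit$k else spec$k_aud
  a_a <- spec$aud_fit$a
  k_v <- spec$vis_fit$k
  a_v <- spec$vis_fit$a
  mean_a <- k_a * auditory_m^a_a
  mean_v <- k_v * visual_m^a_v

  if (spec$variant == "M1") {
    ref <- spec$reference_distance_m
    sig_a <- spec$aud_factor * k_a * ref^a_a
    sig_v <- spec$vis_factor * k_v * ref^a_v
    sensitivity_dprime(mean_a, mean_v, sig_a, sig_v, spec$r)
  } else if (spec$variant == "M2") {
    sig_a <- spec$aud_factor * mean_a
    sig_v <- spec$vis_factor * mean_v
    sensitivity_dprime(mean_a, mean_v, sig_a, sig_v, spec$r)
  } else {
    mom_a <- lognormal_moments(log(mean_a), log(spec$aud_factor),
                               spec$printed_formula)
    mom_v <- lognormal_moments(log(mean_v), log(spec$vis_factor),
                               spec$printed_formula)
    sensitivity_dprime(mom_a$mu, mom_v$mu, mom_a$sigma, mom_v$sigma, spec$r)
  }
}

#' Explore predicted d' curves across a parameter sweep
#'
#' Reproduces the standard parameter exploration: one predicted curve per
#' swept value of `k_aud` (auditory power-law constant; controls where the
#' curve's minimum falls on the distance axis) or `r` (percept correlation;
#' controls the sharpness of the curve). Following the convention of that
#' exploration, `r` is held at 0 while sweeping `k_aud`, and `k_aud` is held
#' at 1 while sweeping `r`; all other parameters stay at the values in
#' `spec`.
#'
#' @param spec an `av_model`.
#' @param visual_m block visual-target distance (m).
#' @param auditory_m vector of auditory distances (m).
#' @param sweep `"k_aud"` or `"r"`.
#' @param values swept parameter values (`k_aud` > 0, or `r` in \[0, 1\]).
#' @return long data.frame with columns `model`, `sweep`, `value`,
#'   `visual_m`, `auditory_m`, `dprime`.
#' @export
parameter_sweep <- function(spec, visual_m, auditory_m,
                            sweep = c("k_aud", "r"), values) {
  sweep <- match.arg(sweep)
  if (sweep == "k_aud" && any(values <= 0))
    stop("swept k_aud values must be positive")
  if (sweep == "r" && any(values < 0 | values > 1))
    stop("swept r values must lie in [0, 1]")
  out <- lapply(values, function(v) {
    s <- spec
    if (sweep == "k_aud") {
      s$k_aud <- v
      s$r <- 0
    } else {
      s$r <- v
      s$k_aud <- 1
    }
    data.frame(model = spec$variant, sweep = sweep, value = v,
               visual_m = visual_m, auditory_m = auditory_m,
               dprime = predict_dprime(s, visual_m, auditory_m))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
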
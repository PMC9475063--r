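# Distance scaling: power-function fits y = k x^a to absolute distance
# judgments, geometric-mean aggregation across subjects.

#' Geometric mean
#'
#' `exp(mean(log(x)))`, the standard average for magnitude-estimation data
#' whose errors are multiplicative.
#'
#' @param x positive numeric vector.
#' @return scalar geometric mean.
#' @examples
#' geometric_mean(c(2, 8))  # 4
#' @export
geometric_mean <- function(x) {
  if (any(x <= 0) || length(x) == 0) stop("geometric mean needs positive values")
  exp(mean(log(x)))
}

#' Fit a power function y = k x^a to distance judgments
#'
#' Default method: ordinary least squares of `log(judged)` on `log(target)`
#' (`a` = slope, `k` = exp(intercept), `r_squared` from the log-space
#' regression). The log-space fit is exactly linear, has a unique solution,
#' and matches a multiplicative (log-normal) error model and geometric-mean
#' averaging. `method = "linear"` instead minimizes linear-space squared
#' error by nonlinear least squares started from the log-space solution.
#'
#' @param target_m physical target distances (m), >= 2 distinct values.
#' @param judged_m judged distances (m), positive.
#' @param method `"log"` (default) or `"linear"`.
#' @return list of class `av_powerfit`: `k`, `a`, `r_squared`, `n`, `method`.
#' @examples
#' x <- c(1, 2, 3, 4, 5)
#' fit_power(x, 2 * sqrt(x))  # k = 2, a = 0.5
#' @export
fit_power <- function(target_m, judged_m, method = c("log", "linear")) {
  method <- match.arg(method)
  if (length(target_m) != length(judged_m)) stop("input lengths differ")
  if (any(target_m <= 0) || any(judged_m <= 0))
    stop("distances and judgments must be positive")
  if (length(unique(target_m)) < 2)
    stop("need at least 2 distinct target distances")

  lx <- log(target_m)
  ly <- log(judged_m)
  fit <- stats::lm(ly ~ lx)
  a <- unname(stats::coef(fit)[2])
  k <- exp(unname(stats::coef(fit)[1]))
  sse <- sum(stats::resid(fit)^2)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst > 0) 1 - sse / sst else as.numeric(sse < 1e-12)

  if (method == "linear") {
    nl <- stats::optim(c(k, a), function(p) {
      if (p[1] <= 0) return(1e12)
      sum((judged_m - p[1] * target_m^p[2])^2)
    }, method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-12))
    k <- nl$par[1]
    a <- nl$par[2]
    sst_lin <- sum((judged_m - mean(judged_m))^2)
    r2 <- if (sst_lin > 0) 1 - nl$value / sst_lin else
      as.numeric(nl$value < 1e-12)
  }
  structure(list(k = k, a = a, r_squared = max(0, min(1, r2)),
                 n = length(target_m), method = method),
            class = "av_powerfit")
}

#' @export
print.av_powerfit <- function(x, ...) {
  cat(sprintf("Power fit: y = %.4g x^%.4g  (R^2 = %.4f, n = %d, %s-space)\n",
              x$k, x$a, x$r_squared, x$n, x$method))
  invisible(x)
}

#' Mean perceived distance under a power fit
#'
#' @param fit an `av_powerfit`, or any list with fields `k` and `a`.
#' @param x physical distance(s) (m), positive.
#' @return `k * x^a` (m).
#' @examples
#' perceived_mean(list(k = 2, a = 0.5), 4)  # 4
#' @export
perceived_mean <- function(fit, x) {
  if (any(x <= 0)) stop("distance must be positive")
  fit$k * x^fit$a
}

#' Power fits from an absolute-judgment table
#'
#' Group fits (default) follow the standard group analysis: judgments are
#' reduced to geometric means across subjects at each target distance per
#' modality, and the power function is fit to those means. Per-subject fits
#' use each subject's raw judgments and feed the individual-subject model
#' fits.
#'
#' @param judgments data.frame with columns `subject_id`, `modality`
#'   (`"aud"`/`"vis"`), `target_m`, `judged_m`, e.g. from
#'   [simulate_absolute_judgments()].
#' @param per_subject fit each subject separately?
#' @param method passed to [fit_power()].
#' @return data.frame with columns (`subject_id`,) `modality`, `k`, `a`,
#'   `r_squared`, `n`.
#' @examples
#' j <- simulate_absolute_judgments(default_design(), observer_params())
#' fit_power_table(j)
#' @export
fit_power_table <- function(judgments, per_subject = FALSE,
                            method = c("log", "linear")) {
  method <- match.arg(method)
  validate_judgments(judgments)
  if (per_subject) {
    parts <- split(judgments, judgments[c("subject_id", "modality")],
                   drop = TRUE)
    out <- lapply(parts, function(p) {
      f <- fit_power(p$target_m, p$judged_m, method = method)
      data.frame(subject_id = p$subject_id[1], modality = p$modality[1],
                 k = f$k, a = f$a, r_squared = f$r_squared, n = f$n)
    })
  } else {
    parts <- split(judgments, judgments$modality, drop = TRUE)
    out <- lapply(parts, function(p) {
      gm <- stats::aggregate(judged_m ~ target_m, data = p,
                             FUN = geometric_mean)
      f <- fit_power(gm$target_m, gm$judged_m, method = method)
      data.frame(modality = p$modality[1], k = f$k, a = f$a,
                 r_squared = f$r_squared, n = f$n)
    })
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
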
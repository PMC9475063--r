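# Model fitting: bound-constrained nonlinear least squares of predicted d'
# curves to empirical d' data, 1-, 2-, and 3-parameter variants, and RMS
# model comparison.

#' Root-mean-squared error
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @examples
#' rms_error(c(0, 0), c(3, 4))  # sqrt(12.5)
#' @export
rms_error <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 1) stop("need at least one value")
  sqrt(mean((observed - predicted)^2))
}

# parameter bounds shared by all fits
FIT_LOWER <- c(k_aud = 0.05, r = 0, factor = 1 + 1e-8)
FIT_UPPER <- c(k_aud = 20, r = 1, factor = 10)

# deterministic multi-start grid
START_GRID <- list(k_aud = c(0.5, 1, 2), r = c(0, 0.5, 0.9),
                   factor = c(1.3, 1.7, 2.5))

#' Fit a coincidence model to an empirical d' curve
#'
#' Minimizes the sum of squared differences between observed d' and the
#' model prediction over a block's auditory distances, by bound-constrained
#' quasi-Newton least squares (`optim(method = "L-BFGS-B")`) from a
#' deterministic multi-start grid (the objective is non-convex in `k_aud`).
#' Free parameters by `n_params`:
#' \describe{
#'   \item{1}{`k_aud` (auditory power-law constant), bounds \[0.05, 20\].}
#'   \item{2}{plus `r` (percept correlation), bounds \[0, 1\].}
#'   \item{3}{plus the auditory variability factor, bounds (1, 10\]; for M3
#'     this is the factor whose natural log is the log-space spread.}
#' }
#' Parameters not freed stay at their values in `spec`. For `n_params > 1`
#' the solution of the next-simpler fit (padded with the fixed default of
#' the extra parameter) is added to the start list, so reported RMS error is
#' non-increasing in `n_params` on the same data.
#'
#' @param curve data.frame for one visual-target block with columns
#'   `auditory_m` and `dprime` (e.g. one block of [empirical_dprime()]).
#' @param spec an `av_model` supplying the variant, the power-law
#'   parameters estimated from absolute-judgment data, and fixed defaults.
#' @param n_params 1, 2, or 3.
#' @param scope label recorded in the result (`"pooled"` or
#'   `"subject:<id>"`).
#' @return list of class `av_fit`: `variant`, `n_params`, `k_aud`, `r`,
#'   `sigma_factor_aud` (NA unless `n_params = 3`), `rms_error`,
#'   `visual_m`, `scope`, `converged`, `objective`, and
#'   `start_objectives` (the objective at each start, for auditing the
#'   multi-start refinement).
#' @examples
#' spec <- model_spec("M3", aud_fit = list(k = 1.32, a = 0.54),
#'                    vis_fit = list(k = 1, a = 0.98))
#' x <- seq(1.75, 4.25, by = 0.25)
#' truth <- model_spec("M3", aud_fit = list(k = 1.32, a = 0.54),
#'                     vis_fit = list(k = 1, a = 0.98), r = 0.3, k_aud = 1.2)
#' curve <- data.frame(auditory_m = x,
#'                     dprime = predict_dprime(truth, 3, x))
#' fit_model(curve, spec, n_params = 2)
#' @export
fit_model <- function(curve, spec, n_params = 2, scope = "pooled") {
  if (!inherits(spec, "av_model")) stop("spec must come from model_spec()")
  if (!all(c("auditory_m", "dprime") %in% names(curve)))
    stop("curve needs auditory_m and dprime columns")
  if (!n_params %in% 1:3) stop("n_params must be 1, 2, or 3")
  if (nrow(curve) < n_params + 1)
    stop("curve must have more points than free parameters")
  visual_m <- if ("visual_m" %in% names(curve)) curve$visual_m[1] else
    spec$reference_distance_m
  obs <- curve$dprime
  x <- curve$auditory_m

  defaults <- c(k_aud = if (is.null(spec$k_aud)) spec$aud_fit$k else spec$k_aud,
                r = spec$r, factor = spec$aud_factor)
  free <- c("k_aud", "r", "factor")[seq_len(n_params)]

  objective <- function(theta) {
    s <- spec
    s$k_aud <- theta[["k_aud"]]
    s$r <- theta[["r"]]
    s$aud_factor <- theta[["factor"]]
    tryCatch(sum((obs - predict_dprime(s, visual_m, x))^2),
             error = function(e) 1e10)
  }

  starts <- expand.grid(START_GRID[free])
  # append the fixed defaults as a start so rms(fit) <= rms(spec defaults)
  starts <- rbind(starts, as.list(pmin(pmax(defaults[free], FIT_LOWER[free]),
                                       FIT_UPPER[free])))
  if (n_params > 1) {
    sub <- fit_model(curve, spec, n_params = n_params - 1, scope = scope)
    prev <- c(k_aud = sub$k_aud, r = sub$r, factor = sub$sigma_factor_aud)
    prev[is.na(prev)] <- defaults[is.na(prev)]
    starts <- rbind(starts, as.list(pmin(pmax(prev[free], FIT_LOWER[free]),
                                         FIT_UPPER[free])))
  }

  best <- NULL
  start_obj <- numeric(nrow(starts))
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    par0 <- unlist(starts[i, , drop = FALSE])
    names(par0) <- free
    full0 <- defaults
    full0[free] <- par0
    start_obj[i] <- objective(full0)
    opt <- stats::optim(par0, function(p) {
      full <- defaults
      full[free] <- p
      objective(full)
    }, method = "L-BFGS-B",
    lower = FIT_LOWER[free], upper = FIT_UPPER[free],
    control = list(maxit = 500, factr = 1e2, pgtol = 1e-10))
    if (opt$convergence == 0) any_conv <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  theta <- defaults
  theta[free] <- best$par
  structure(list(
    variant = spec$variant, n_params = as.integer(n_params),
    k_aud = unname(theta[["k_aud"]]),
    r = if (n_params >= 2) unname(theta[["r"]]) else NA_real_,
    sigma_factor_aud = if (n_params >= 3) unname(theta[["factor"]]) else NA_real_,
    rms_error = sqrt(best$value / length(obs)),
    visual_m = visual_m, scope = scope,
    converged = any_conv, objective = best$value,
    start_objectives = start_obj), class = "av_fit")
}

#' @export
print.av_fit <- function(x, ...) {
  cat(sprintf(
    "%s fit (%d-parameter, %s, visual %.2f m): k_aud = %.4f%s%s, RMS = %.4f%s\n",
    x$variant, x$n_params, x$scope, x$visual_m, x$k_aud,
    if (!is.na(x$r)) sprintf(", r = %.4f", x$r) else "",
    if (!is.na(x$sigma_factor_aud))
      sprintf(", factor = %.4f", x$sigma_factor_aud) else "",
    x$rms_error, if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' Fit all model variants to every d' curve and tabulate RMS errors
#'
#' Fits each requested variant per visual-target block (and per subject if
#' the curves carry a `subject_id` column), holding the power-law
#' parameters at the supplied absolute-judgment fits.
#'
#' @param curves output of [empirical_dprime()] (pooled or per-subject).
#' @param aud_fit,vis_fit power-law parameters; either a single list with
#'   `k`/`a` (pooled curves) or a per-subject data.frame from
#'   [fit_power_table()] with `subject_id`, `modality`, `k`, `a`.
#' @param n_params number of free parameters (1, 2, or 3).
#' @param variants model variants to fit.
#' @param ... further arguments to [model_spec()] (e.g. `r`, factors).
#' @return data.frame with one row per (variant, block\[, subject\]):
#'   `visual_m`, `model`, `n_params`, `scope`, `k_aud`, `r`,
#'   `sigma_factor_aud`, `rms_error`, `converged`.
#' @seealso [rms_summary()] for the mean +/- SE summary across subjects.
#' @export
compare_models <- function(curves, aud_fit, vis_fit, n_params = 2,
                           variants = c("M1", "M2", "M3"), ...) {
  per_subject <- "subject_id" %in% names(curves)
  lookup_fit <- function(tab, sid, mod) {
    if (!is.data.frame(tab)) return(list(k = tab$k, a = tab$a))
    row <- tab[tab$subject_id == sid & tab$modality == mod, ]
    if (nrow(row) != 1) stop("missing power fit for subject ", sid)
    list(k = row$k, a = row$a)
  }
  keys <- if (per_subject) list(curves$subject_id, curves$visual_m) else
    list(curves$visual_m)
  parts <- split(curves, keys, drop = TRUE)
  rows <- lapply(parts, function(blk) {
    if (per_subject) {
      sid <- blk$subject_id[1]
      af <- lookup_fit(aud_fit, sid, "aud")
      vf <- lookup_fit(vis_fit, sid, "vis")
      scope <- paste0("subject:", sid)
    } else {
      af <- aud_fit
      vf <- vis_fit
      scope <- "pooled"
    }
    do.call(rbind, lapply(variants, function(vn) {
      spec <- model_spec(vn, aud_fit = af, vis_fit = vf, ...)
      f <- fit_model(blk, spec, n_params = n_params, scope = scope)
      data.frame(visual_m = f$visual_m, model = vn,
                 n_params = f$n_params, scope = scope,
                 k_aud = f$k_aud, r = f$r,
                 sigma_factor_aud = f$sigma_factor_aud,
                 rms_error = f$rms_error, converged = f$converged)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$model, out$visual_m, out$scope), ]
  rownames(out) <- NULL
  out
}

#' Mean and standard error of RMS fit error across subjects
#'
#' Condenses a per-subject [compare_models()] table into the descriptive
#' summary used for model comparison: mean RMS error and its standard error
#' across subjects, per model and visual-target distance.
#'
#' @param comparison data.frame from [compare_models()] with per-subject
#'   scopes.
#' @return data.frame with columns `model`, `visual_m`, `mean_rms`,
#'   `se_rms`, `n_subjects`.
#' @export
rms_summary <- function(comparison) {
  if (!all(c("model", "visual_m", "rms_error") %in% names(comparison)))
    stop("comparison must come from compare_models()")
  parts <- split(comparison, list(comparison$model, comparison$visual_m),
                 drop = TRUE)
  out <- lapply(parts, function(p) data.frame(
    model = p$model[1], visual_m = p$visual_m[1],
    mean_rms = mean(p$rms_error),
    se_rms = stats::sd(p$rms_error) / sqrt(nrow(p)),
    n_subjects = nrow(p)))
  out <- do.call(rbind, out)
  out <- out[order(out$model, out$visual_m), ]
  rownames(out) <- NULL
  out
}
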
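# Synthetic observer: generative model for absolute judgments and yes/no
# coincidence responses. Percepts are bivariate normal in natural-log
# distance; the decision rule is a symmetric difference criterion in log
# space, so the implied proportion-coincident has the closed form given by
# predict_pc().

# Deterministic substream seed for one (subject, block) pair. Keeps subject
# subsets reproducible: simulating subjects 1..k reproduces the full run's
# rows for those subjects. 2^31 - 1 keeps the value a valid R integer seed.
substream_seed <- function(root, subject, block) {
  as.integer((as.double(root) + 97561 * subject + 7919 * block) %% 2147483647)
}

# block indices >= 1000 are reserved for the absolute-judgment phases
ABS_AUD_BLOCK <- 1001L
ABS_VIS_BLOCK <- 1002L

#' Simulate absolute distance judgments
#'
#' Draws one absolute judgment per subject x modality x target distance from
#' the observer's marginal log-normal percept: `judged = exp(N(ln(k x^a), s))`,
#' mirroring a single-judgment magnitude-estimation protocol.
#'
#' @param design an `av_design`.
#' @param params an `av_observer`.
#' @return data.frame with columns `subject_id`, `modality` (`"aud"` or
#'   `"vis"`), `target_m`, `judged_m`.
#' @examples
#' j <- simulate_absolute_judgments(default_design(), observer_params())
#' head(j)
#' @export
simulate_absolute_judgments <- function(design, params) {
  check_design(design)
  check_observer(params)
  out <- vector("list", design$n_subjects)
  for (s in seq_len(design$n_subjects)) {
    set.seed(substream_seed(params$seed, s, ABS_AUD_BLOCK))
    xa <- design$absolute_auditory
    ja <- exp(stats::rnorm(length(xa),
                           mean = log(params$k_aud * xa^params$a_aud),
                           sd = params$s_aud))
    set.seed(substream_seed(params$seed, s, ABS_VIS_BLOCK))
    xv <- design$absolute_visual
    jv <- exp(stats::rnorm(length(xv),
                           mean = log(params$k_vis * xv^params$a_vis),
                           sd = params$s_vis))
    out[[s]] <- data.frame(
      subject_id = s,
      modality = rep(c("aud", "vis"), c(length(xa), length(xv))),
      target_m = c(xa, xv),
      judged_m = c(ja, jv))
  }
  do.call(rbind, out)
}

#' Simulate yes/no coincidence responses
#'
#' For every trial, draws correlated bivariate-normal log percepts
#' `(A, V)` with means `ln(k_aud x_aud^a_aud)` and `ln(k_vis x_vis^a_vis)`,
#' standard deviations `s_aud`, `s_vis`, and correlation `r`; the simulated
#' observer responds "coincident" (1) iff `|A - V| <= criterion_c`.
#'
#' @inheritParams simulate_absolute_judgments
#' @return data.frame with columns `subject_id`, `visual_m`, `auditory_m`,
#'   `trial_idx`, `response` (0/1), one row per trial.
#' @examples
#' r <- simulate_coincidence_responses(default_design(), observer_params())
#' nrow(r)  # subjects x blocks x grid x trials
#' @export
simulate_coincidence_responses <- function(design, params) {
  check_design(design)
  check_observer(params)
  nt <- design$trials_per_stimulus
  out <- list()
  k <- 0L
  for (s in seq_len(design$n_subjects)) {
    for (b in seq_along(design$visual_targets)) {
      v <- design$visual_targets[b]
      grid <- design$auditory_grids[[b]]
      nd <- length(grid)
      m_a <- log(params$k_aud * grid^params$a_aud)
      m_v <- log(params$k_vis * v^params$a_vis)
      set.seed(substream_seed(params$seed, s, b))
      z1 <- matrix(stats::rnorm(nt * nd), nt, nd)
      z2 <- matrix(stats::rnorm(nt * nd), nt, nd)
      A <- sweep(params$s_aud * z1, 2, m_a, "+")
      V <- m_v + params$s_vis * (params$r * z1 + sqrt(1 - params$r^2) * z2)
      resp <- abs(A - V) <= params$criterion_c
      k <- k + 1L
      out[[k]] <- data.frame(
        subject_id = s,
        visual_m = v,
        auditory_m = rep(grid, each = nt),
        trial_idx = rep(seq_len(nt), nd),
        response = as.integer(resp))
    }
  }
  do.call(rbind, out)
}

check_design <- function(design) {
  if (!inherits(design, "av_design"))
    stop("design must be created by experiment_design()")
  if (any(lengths(design$auditory_grids) == 0))
    stop("degenerate design: empty auditory grid")
  invisible(design)
}

check_observer <- function(params) {
  if (!inherits(params, "av_observer"))
    stop("params must be created by observer_params()")
  invisible(params)
}
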
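#' Construct an audio-visual coincidence experiment design
#'
#' Describes the layout of a distance-coincidence experiment: the fixed
#' visual-target distance of each block, the auditory distances probed within
#' each block, trial counts, and the target distances used for the absolute
#' (unimodal) distance-judgment phases.
#'
#' When `auditory_grids` is `NULL`, each block's grid is built as
#' `grid_points` distances in `grid_step` increments centered on the block's
#' visual target, then shifted inward so the whole grid lies within
#' `grid_range` (the range of distances for which virtual sources can be
#' rendered). The shift reproduces the practical constraint that a room
#' offers little space beyond a far visual target.
#'
#' @param visual_targets numeric vector of visual-target distances (m), one
#'   per block.
#' @param auditory_grids optional list (one numeric vector per visual target)
#'   of auditory distances per block; overrides the constructed grids.
#' @param trials_per_stimulus trials per (visual, auditory) cell per subject.
#' @param n_subjects number of subjects.
#' @param absolute_auditory distances (m) probed in the auditory absolute
#'   judgment phase.
#' @param absolute_visual distances (m) probed in the visual absolute
#'   judgment phase.
#' @param grid_points number of auditory distances per block.
#' @param grid_step spacing (m) of the per-block auditory grid.
#' @param grid_range length-2 numeric, renderable distance range (m).
#'
#' @return An object of class `av_design`: a list with fields
#'   `visual_targets`, `auditory_grids`, `trials_per_stimulus`,
#'   `n_subjects`, `absolute_auditory`, `absolute_visual`,
#'   `measurement_grid` (the union of renderable distances implied by
#'   `grid_range` and `grid_step`).
#' @seealso [default_design()] for the standard 11-subject layout.
#' @examples
#' d <- experiment_design(visual_targets = 3, trials_per_stimulus = 10,
#'                        n_subjects = 4)
#' d$auditory_grids[["3"]]
#' @export
experiment_design <- function(visual_targets = c(1.5, 3.0, 4.5),
                              auditory_grids = NULL,
                              trials_per_stimulus = 30L,
                              n_subjects = 11L,
                              absolute_auditory = seq(1, 5, by = 0.5),
                              absolute_visual = c(1, 2, 3),
                              grid_points = 11L,
                              grid_step = 0.25,
                              grid_range = c(1, 5)) {
  stopifnot(is.numeric(visual_targets), length(visual_targets) >= 1)
  if (any(visual_targets <= 0)) stop("visual targets must be positive")
  if (trials_per_stimulus < 1) stop("trials_per_stimulus must be >= 1")
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (any(absolute_auditory <= 0) || any(absolute_visual <= 0))
    stop("absolute-judgment distances must be positive")

  if (is.null(auditory_grids)) {
    auditory_grids <- lapply(visual_targets, function(v)
      centered_grid(v, grid_points, grid_step, grid_range))
  } else {
    if (length(auditory_grids) != length(visual_targets))
      stop("auditory_grids must supply one grid per visual target")
    auditory_grids <- lapply(auditory_grids, as.numeric)
  }
  names(auditory_grids) <- as.character(visual_targets)
  for (g in auditory_grids) {
    if (length(g) < 1 || any(g <= 0)) stop("auditory grids must be positive and non-empty")
    if (is.unsorted(g, strictly = TRUE)) stop("auditory grids must be sorted ascending and unique")
  }

  structure(list(
    visual_targets = as.numeric(visual_targets),
    auditory_grids = auditory_grids,
    trials_per_stimulus = as.integer(trials_per_stimulus),
    n_subjects = as.integer(n_subjects),
    absolute_auditory = as.numeric(absolute_auditory),
    absolute_visual = as.numeric(absolute_visual),
    measurement_grid = seq(grid_range[1], grid_range[2], by = grid_step)
  ), class = "av_design")
}

# grid of n points spaced by step, centered on v, shifted inward to fit range
centered_grid <- function(v, n, step, range) {
  half <- (n - 1) / 2
  g <- v + step * seq(-half, half)
  if (diff(range) < (n - 1) * step)
    stop("grid span exceeds renderable range")
  if (min(g) < range[1]) g <- g + (range[1] - min(g))
  if (max(g) > range[2]) g <- g - (max(g) - range[2])
  round(g, 10)
}

#' Standard design of the distance-coincidence experiment
#'
#' Eleven subjects; visual targets at 1.5, 3.0, and 4.5 m; per block, 11
#' auditory distances in 0.25 m steps centered on the visual target and
#' shifted to stay within the 1--5 m renderable range; 30 trials per
#' stimulus; auditory absolute judgments at 1--5 m in 0.5 m steps; visual
#' absolute judgments at 1, 2, and 3 m.
#'
#' @return An `av_design` object.
#' @examples
#' d <- default_design()
#' length(d$measurement_grid)                # 17 renderable distances
#' lengths(d$auditory_grids)                 # 11 per block
#' d$trials_per_stimulus * d$n_subjects      # 330 pooled trials per point
#' @export
default_design <- function() experiment_design()

#' @export
print.av_design <- function(x, ...) {
  cat("Audio-visual coincidence design:",
      length(x$visual_targets), "blocks,",
      x$n_subjects, "subjects,",
      x$trials_per_stimulus, "trials/stimulus\n")
  for (i in seq_along(x$visual_targets))
    cat(sprintf("  visual %.2f m: auditory %s m\n", x$visual_targets[i],
                paste(format(x$auditory_grids[[i]]), collapse = ", ")))
  invisible(x)
}

#' Observer parameters for the correlated log-normal percept model
#'
#' Parameterizes a simulated observer whose perceived auditory and visual
#' distances are jointly log-normal: in natural-log space the percepts are
#' bivariate normal with means `ln(k * x^a)` per modality, standard
#' deviations `s_aud`/`s_vis`, and correlation `r`. The observer reports
#' "coincident" when the two log percepts differ by at most `criterion_c`.
#'
#' Defaults describe a typical listener: compressive, underestimating
#' auditory distance perception (`k_aud = 1.32`, `a_aud = 0.54`), nearly
#' veridical vision (`k_vis = 1`, `a_vis = 0.98`), log-space spreads equal to
#' the natural logs of the variability ratios 1.6982 (auditory) and 1.4125
#' (visual), a mid-range percept correlation of 0.5, and an acceptance
#' half-width of 0.6 log-units (a ~1.8x distance ratio), which yields a
#' peak coincidence proportion near 0.8.
#'
#' @param k_aud,a_aud auditory power-law constant (m^(1-a)) and exponent.
#' @param k_vis,a_vis visual power-law constant and exponent.
#' @param s_aud,s_vis natural-log-space percept standard deviations (>= 0).
#' @param r correlation between the two log percepts, in \[0, 1\].
#' @param criterion_c half-width of the coincidence acceptance region in
#'   natural-log-distance units (> 0).
#' @param seed root integer seed; per-(subject, block) substreams are
#'   derived from it deterministically.
#' @return An object of class `av_observer` (a validated list).
#' @examples
#' observer_params(r = 0.8)
#' @export
observer_params <- function(k_aud = 1.32, a_aud = 0.54,
                            k_vis = 1.00, a_vis = 0.98,
                            s_aud = log(1.6982), s_vis = log(1.4125),
                            r = 0.5, criterion_c = 0.6, seed = 1L) {
  if (k_aud <= 0 || k_vis <= 0) stop("power-law constants k must be positive")
  if (s_aud < 0 || s_vis < 0) stop("log-space standard deviations must be >= 0")
  if (r < 0 || r > 1) stop("correlation r must lie in [0, 1]")
  if (criterion_c <= 0) stop("criterion_c must be positive")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(k_aud = k_aud, a_aud = a_aud, k_vis = k_vis, a_vis = a_vis,
                 s_aud = s_aud, s_vis = s_vis, r = r,
                 criterion_c = criterion_c, seed = seed),
            class = "av_observer")
}

#' @export
print.av_observer <- function(x, ...) {
  cat(sprintf(
    "Observer: aud %.3g x^%.3g (s=%.3f), vis %.3g x^%.3g (s=%.3f), r=%.2f, c=%.2f, seed=%d\n",
    x$k_aud, x$a_aud, x$s_aud, x$k_vis, x$a_vis, x$s_vis, x$r,
    x$criterion_c, x$seed))
  invisible(x)
}
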
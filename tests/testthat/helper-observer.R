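# Shared builders for small test designs and observers.

# one-block design with an explicit auditory grid
one_block_design <- function(visual = 3, grid = c(2, 2.5, 3, 3.5, 4),
                             trials = 30, subjects = 11) {
  experiment_design(visual_targets = visual, auditory_grids = list(grid),
                    trials_per_stimulus = trials, n_subjects = subjects,
                    absolute_auditory = c(1, 2), absolute_visual = c(1, 2))
}

# observer with veridical, matched power laws (k = a = 1 in both modalities)
matched_observer <- function(...) {
  observer_params(k_aud = 1, a_aud = 1, k_vis = 1, a_vis = 1, ...)
}

# analytic pc for an observer at auditory distances x, visual target v
analytic_pc <- function(params, x, v) {
  sd_diff <- sqrt(params$s_aud^2 + params$s_vis^2 -
                    2 * params$r * params$s_aud * params$s_vis)
  mu_diff <- log(params$k_aud * x^params$a_aud) -
    log(params$k_vis * v^params$a_vis)
  predict_pc(mu_diff, sd_diff, params$criterion_c)
}
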
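test_that("RMS error matches hand-computed values", {
  expect_equal(rms_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rms_error(c(0, 0), c(3, 4)), sqrt(12.5), tolerance = 1e-12)
  expect_equal(rms_error(2, 5), 3)
  expect_error(rms_error(1:3, 1:2), "mismatch")
})

af <- list(k = 1.32, a = 0.54)
vf <- list(k = 1, a = 0.98)
x_grid <- seq(1.75, 4.25, 0.25)

test_that("fits recover parameters from noiseless model curves", {
  truth <- model_spec("M3", af, vf, r = 0.3, k_aud = 1.2)
  curve <- data.frame(visual_m = 3, auditory_m = x_grid,
                      dprime = predict_dprime(truth, 3, x_grid))
  f <- fit_model(curve, model_spec("M3", af, vf), n_params = 2)
  expect_lt(abs(f$k_aud - 1.2), 1e-3)
  expect_lt(abs(f$r - 0.3), 1e-3)
  expect_lt(f$rms_error, 1e-6)
  expect_true(f$converged)
})

test_that("a curve at spec defaults fits with zero error at the defaults", {
  spec <- model_spec("M2", af, vf, r = 0.4)
  curve <- data.frame(visual_m = 3, auditory_m = x_grid,
                      dprime = predict_dprime(spec, 3, x_grid))
  f <- fit_model(curve, spec, n_params = 2)
  expect_lt(f$rms_error, 1e-6)
  expect_lt(abs(f$k_aud - af$k), 1e-3)
  expect_lt(abs(f$r - 0.4), 1e-3)
})

test_that("fitted parameters respect their bounds", {
  set.seed(31)
  curve <- data.frame(visual_m = 3, auditory_m = x_grid,
                      dprime = runif(length(x_grid), 0, 3))
  for (np in 1:3) {
    f <- fit_model(curve, model_spec("M3", af, vf), n_params = np)
    expect_gte(f$k_aud, 0.05)
    expect_lte(f$k_aud, 20)
    if (np >= 2) {
      expect_gte(f$r, 0)
      expect_lte(f$r, 1)
    }
    if (np == 3) {
      expect_gt(f$sigma_factor_aud, 1)
      expect_lte(f$sigma_factor_aud, 10)
    }
  }
})

test_that("multi-start refinement never loses to its starts and RMS nests", {
  set.seed(77)
  for (variant in c("M1", "M2", "M3")) {
    spec <- model_spec(variant, af, vf, r = 0.35)
    curve <- data.frame(
      visual_m = 3, auditory_m = x_grid,
      dprime = pmax(0, predict_dprime(spec, 3, x_grid) +
                      rnorm(length(x_grid), 0, 0.15)))
    rms <- numeric(3)
    for (np in 1:3) {
      f <- fit_model(curve, spec, n_params = np)
      expect_true(all(f$start_objectives >= f$objective - 1e-8))
      rms[np] <- f$rms_error
    }
    expect_lte(rms[2], rms[1] + 1e-8)
    expect_lte(rms[3], rms[2] + 1e-8)
  }
})

test_that("fit input contracts hold", {
  spec <- model_spec("M3", af, vf)
  short <- data.frame(visual_m = 3, auditory_m = c(2, 3), dprime = c(1, 0))
  expect_error(fit_model(short, spec, n_params = 2), "more points")
  expect_error(fit_model(short, list(), n_params = 1), "model_spec")
})

test_that("the generating model attains the lowest RMS on its own data", {
  for (gen in c("M1", "M3")) {
    truth <- model_spec(gen, af, vf, r = 0.3, k_aud = 1.1)
    curve <- data.frame(visual_m = 3, auditory_m = x_grid,
                        dprime = predict_dprime(truth, 3, x_grid))
    cmp <- compare_models(curve, af, vf, n_params = 2)
    best <- cmp$model[which.min(cmp$rms_error)]
    expect_equal(best, gen)
    expect_lt(min(cmp$rms_error), 1e-6)
  }
})

test_that("per-subject comparison produces the bookkeeping summary", {
  d <- experiment_design(visual_targets = c(1.5, 3),
                         trials_per_stimulus = 30, n_subjects = 4)
  p <- observer_params(seed = 6)
  resp <- simulate_coincidence_responses(d, p)
  jud <- simulate_absolute_judgments(d, p)
  per_fits <- fit_power_table(jud, per_subject = TRUE)
  curves <- empirical_dprime(resp, pooled = FALSE)
  cmp <- compare_models(curves, aud_fit = per_fits, vis_fit = per_fits,
                        n_params = 2)
  # one row per model x block x subject
  expect_equal(nrow(cmp), 3 * 2 * 4)
  expect_true(all(table(cmp$model, cmp$visual_m) == 4))
  s <- rms_summary(cmp)
  expect_equal(nrow(s), 6)
  expect_true(all(s$n_subjects == 4))
  expect_true(all(s$se_rms >= 0))
})

test_that("the generating model wins the per-subject RMS summary", {
  # curves drawn around M3's own predictions for several synthetic subjects:
  # the mean-RMS summary across subjects must rank M3 first
  af2 <- list(k = 1.1, a = 0.6)
  vf2 <- list(k = 1, a = 0.95)
  truth <- model_spec("M3", af2, vf2, r = 0.45, k_aud = 0.9)
  set.seed(19)
  curves <- do.call(rbind, lapply(1:6, function(s) {
    do.call(rbind, lapply(c(1.5, 3), function(v) {
      x <- seq(max(0.5, v - 1.25), v + 1.25, 0.25)
      data.frame(subject_id = s, visual_m = v, auditory_m = x,
                 dprime = pmax(0, predict_dprime(truth, v, x) +
                                 rnorm(length(x), 0, 0.05)))
    }))
  }))
  cmp <- compare_models(curves, af2, vf2, n_params = 2,
                        variants = c("M1", "M2", "M3"))
  s <- rms_summary(cmp)
  agg <- tapply(s$mean_rms, s$model, mean)
  expect_equal(names(which.min(agg)), "M3")
})
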
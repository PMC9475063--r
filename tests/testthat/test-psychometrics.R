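test_that("proportion coincident counts trials per cell", {
  r <- expand.grid(subject_id = 1:11, visual_m = 3, auditory_m = c(2, 3),
                   trial_idx = 1:30)
  r$response <- 0
  r$response[r$auditory_m == 3] <- 1
  # half the trials coincident at 2 m
  r$response[r$auditory_m == 2 & r$trial_idx <= 15] <- 1
  pc <- proportion_coincident(r)
  expect_equal(pc$n, c(330, 330))
  expect_equal(pc$pc, c(0.5, 1))
  per <- proportion_coincident(r, pooled = FALSE)
  expect_equal(nrow(per), 22)
  expect_true(all(per$n == 30))
})

test_that("d' is z(pc_max) - z(pc), zero at the reference", {
  cur <- dprime_curve(c(2, 3), pc = c(0.5, 0.975), n = 1e6, visual_m = 3)
  expect_equal(cur$dprime, c(qnorm(0.975), 0), tolerance = 1e-6)
  expect_equal(attr(cur, "ref_distance_m"), 3)
  # all proportions equal: flat zero curve
  flat <- dprime_curve(c(2, 3, 4), pc = rep(0.7, 3), n = 330, visual_m = 3)
  expect_equal(flat$dprime, rep(0, 3))
})

test_that("pc_max ties resolve toward the visual target, then nearer", {
  cur <- dprime_curve(c(2, 3.5, 4), pc = c(0.9, 0.9, 0.2), n = 330,
                      visual_m = 3)
  expect_equal(attr(cur, "ref_distance_m"), 3.5)
  sym <- dprime_curve(c(2.5, 3.5), pc = c(0.9, 0.9), n = 330, visual_m = 3)
  expect_equal(attr(sym, "ref_distance_m"), 2.5)
})

test_that("clamping keeps z finite and bounds attainable d'", {
  cur <- dprime_curve(c(2, 3), pc = c(0, 1), n = 330, visual_m = 3)
  expect_true(all(is.finite(cur$dprime)))
  dmax <- qnorm(1 - 1 / 660) - qnorm(1 / 660)
  expect_equal(max(cur$dprime), dmax)
})

test_that("d' curves are equivariant under distance relabeling", {
  set.seed(1)
  pc <- runif(6, 0.2, 0.9)
  x <- c(1.5, 2, 2.5, 3, 3.5, 4)
  perm <- sample(6)
  a <- dprime_curve(x, pc, 330, visual_m = 3)
  b <- dprime_curve(x[perm], pc[perm], 330, visual_m = 3)
  expect_equal(b$dprime[order(perm)], a$dprime)
})

test_that("closed-form pc behaves as the decision rule dictates", {
  expect_equal(predict_pc(0, 1, qnorm(0.975)), 0.95, tolerance = 1e-9)
  expect_equal(predict_pc(0.3, 0.5, 1e6), 1)
  expect_lt(predict_pc(0, 1, 1e-8), 1e-7)
  expect_error(predict_pc(0, 0, 1), "sd_diff")
  expect_error(predict_pc(0, 1, -1), "criterion")
})

test_that("empirical d' matches the analytic oracle at large n", {
  grid <- c(2, 2.5, 3, 3.5, 4)
  d <- one_block_design(grid = grid, trials = 100000, subjects = 1)
  p <- observer_params(seed = 4)
  cur <- empirical_dprime(simulate_coincidence_responses(d, p))
  pc_an <- analytic_pc(p, cur$auditory_m, 3)
  z <- qnorm(pc_an)
  d_an <- max(z) - z
  expect_true(all(abs(cur$dprime - d_an) < 0.05))
})

test_that("asymmetric capture shows up in simulated d' at high resolution", {
  # matched power laws: farther-than-target sources are harder to reject
  deltas <- c(0.5, 1, 1.5)
  grid <- sort(c(3 - deltas, 3, 3 + deltas))
  d <- one_block_design(grid = grid, trials = 100000, subjects = 1)
  cur <- empirical_dprime(simulate_coincidence_responses(d, matched_observer()))
  near <- cur$dprime[match(3 - deltas, cur$auditory_m)]
  far <- cur$dprime[match(3 + deltas, cur$auditory_m)]
  expect_true(all(near > far))
})

test_that("bootstrap intervals are seeded, ordered, and degenerate correctly", {
  d <- one_block_design(trials = 10, subjects = 5)
  r <- simulate_coincidence_responses(d, observer_params(seed = 2))
  b1 <- bootstrap_dprime(r, B = 200, seed = 7)
  b2 <- bootstrap_dprime(r, B = 200, seed = 7)
  expect_identical(b1, b2)
  expect_true(all(b1$ci_low <= b1$ci_high))
  # identical subjects: resampling cannot move the curve
  rep1 <- r[r$subject_id == 1, ]
  clones <- do.call(rbind, lapply(1:5, function(s) {
    x <- rep1
    x$subject_id <- s
    x
  }))
  bc <- bootstrap_dprime(clones, B = 50, seed = 3)
  expect_equal(bc$ci_low, bc$dprime)
  expect_equal(bc$ci_high, bc$dprime)
  # single-subject tables cannot be resampled at the subject level
  expect_error(bootstrap_dprime(rep1, B = 10), "2 subjects")
})
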
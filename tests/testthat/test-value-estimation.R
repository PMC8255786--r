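test_that("psychometric fit recovers the generative indifference point", {
  stim <- factorial_stim()
  ag <- example_agent()
  ses <- simulate_session(ag, stim, c("LFLS", "HFLS"), 500, seed = 2)
  fit <- psychometric_fit(ses, stim, "LFLS", "HFLS", n_bootstrap = 300,
                          seed = 1)
  # generative rho-ratio 1.52; recovery band from the bootstrap SD at n=500
  expect_gt(fit$indifference_point, 1.37)
  expect_lt(fit$indifference_point, 1.67)
  expect_lte(fit$ci_low, fit$indifference_point)
  expect_gte(fit$ci_high, fit$indifference_point)
  expect_gt(fit$goodness, 0.8)
  # ratio invariance: doubling all magnitudes leaves the fit unchanged
  ses2 <- ses
  ses2$mag_left <- 2 * ses2$mag_left
  ses2$mag_right <- 2 * ses2$mag_right
  fit2 <- psychometric_fit(ses2, stim, "LFLS", "HFLS", n_bootstrap = 0)
  expect_equal(fit2$indifference_point, psychometric_fit(
    ses, stim, "LFLS", "HFLS", n_bootstrap = 0)$indifference_point,
    tolerance = 1e-10)
})

test_that("an indifferent agent yields an indifference point near 1", {
  stim <- factorial_stim()
  blind <- nutrient_value_fn("blind", temperature = 3)
  ses <- simulate_session(blind, stim, c("LFLS", "HFLS"), 800, seed = 5)
  fit <- psychometric_fit(ses, stim, "LFLS", "HFLS", n_bootstrap = 300,
                          seed = 2)
  expect_lte(fit$ci_low, 1)
  expect_gte(fit$ci_high, 1)
})

test_that("degenerate psychometric inputs are refused", {
  t1 <- toy_trials("a", "b", 1, 1, rep("left", 20))
  stim <- stimulus_table(c("a", "b"), c(1, 2), c(1, 2))
  expect_error(psychometric_fit(t1, stim, "a", "b"), "distinct magnitude")
  t2 <- toy_trials("a", "b", c(1, 2), c(2, 1), rep("left", 20))
  expect_error(psychometric_fit(t2, stim, "a", "b"), "no inflection")
  expect_error(psychometric_fit(t2, stim, "a", "c"), "no trials")
})

test_that("choice-bias tests detect persistence and its absence", {
  stim <- stimulus_table(c("a", "b"), c(1, 2), c(1, 2))
  # perfectly alternating sequence: unbiased frequency, strong anti-persistence
  alt <- toy_trials("a", "b", 1, 1, rep(c("left", "right"), 50))
  bt <- choice_bias_tests(alt)
  expect_gt(bt$binomial_p, 0.9)
  expect_lt(bt$runlength_lr_p, 0.001)
  # 100 identical choices: binomial p = 2 * 0.5^100
  same <- toy_trials("a", "b", 1, 1, rep("left", 100))
  expect_lt(choice_bias_tests(same)$binomial_p, 1e-20)
  expect_error(choice_bias_tests(toy_trials("a", "b", 1, 1, rep("left", 5))),
               "10 trials")
})

test_that("choice-bias tests hold their type-I error on fair-coin data", {
  set.seed(42)
  reps <- 2000
  rej <- matrix(FALSE, reps, 2)
  stim <- stimulus_table(c("a", "b"), c(1, 2), c(1, 2))
  for (r in seq_len(reps)) {
    tr <- toy_trials("a", "b", 1, 1,
                     sample(c("left", "right"), 100, replace = TRUE))
    bt <- choice_bias_tests(tr)
    rej[r, ] <- c(bt$binomial_p, bt$runlength_lr_p) < 0.05
  }
  rates <- colMeans(rej)
  expect_gte(min(rates), 0.03)
  expect_lte(max(rates), 0.07)
})

test_that("trade-off quantification matches hand-computed totals", {
  stim <- factorial_stim()
  # always-choose-HFLS agent on a fixed 4-trial toy session
  tr <- toy_trials("HFLS", "LFLS", c(1, 2, 1, 2), c(2, 1, 2, 1),
                   rep("left", 4))
  tq <- tradeoff_quantification(tr, stim)
  # realized: 6 mL of HFLS; the magnitude oracle takes the larger offer each
  # trial: 2 mL HFLS twice + 2 mL LFLS twice = 8 mL
  expect_equal(unname(tq$pct_magnitude_forgone), 100 * (8 - 6) / 8)
  fat_realized <- 6 * 3.6 / 100
  fat_oracle <- 4 * 3.6 / 100 + 4 * 0.1 / 100
  expect_equal(unname(tq$pct_gained[["fat"]]),
               100 * (fat_realized - fat_oracle) / fat_oracle)
  # magnitude maximizer: nothing forgone, nothing gained
  tq0 <- tradeoff_quantification(
    reference_agent(tr, stim, "magnitude", seed = 1), stim)
  expect_equal(unname(tq0$pct_magnitude_forgone), 0)
  expect_equal(max(abs(tq0$pct_gained)), 0)
  # scale invariance
  tr2 <- tr
  tr2$mag_left <- 3 * tr2$mag_left
  tr2$mag_right <- 3 * tr2$mag_right
  tq2 <- tradeoff_quantification(tr2, stim)
  expect_equal(tq2$pct_gained, tq$pct_gained)
  expect_equal(tq2$pct_magnitude_forgone, tq$pct_magnitude_forgone)
})

test_that("nutrient model recovers strong generative weights", {
  stim <- factorial_stim()
  # tau * w_fat = 0.8, tau * w_sugar = 1.6 (per level); concentrations scale
  ag <- nutrient_value_fn("s", w_fat = 0.4 / 3.5, w_sugar = 0.8 / 7.875,
                          temperature = 2)
  dat <- make_dataset(list(ag), pair_schedule(stim, n_trials = 850), stim,
                      seed = 3)
  fit <- fit_nutrient_model(dat, stim)
  expect_lt(abs(coef(fit)[["dfat"]] - 0.8 / 3.5), 3 * fit$se[["dfat"]])
  expect_lt(abs(coef(fit)[["dsugar"]] - 1.6 / 7.875), 3 * fit$se[["dsugar"]])
  expect_gt(coef(fit)[["dsugar"]] * 7.875, coef(fit)[["dfat"]] * 3.5)
})

test_that("nutrient-blind agents rarely show significant nutrient effects", {
  stim <- factorial_stim()
  blind <- nutrient_value_fn("b", temperature = 2)
  sched <- pair_schedule(stim, n_trials = 120)
  seeds <- 1000 + seq_len(200)
  sig <- vapply(seeds, function(s) {
    dat <- make_dataset(list(blind), sched, stim, seed = s)
    fit <- fit_nutrient_model(dat, stim)
    z <- abs(coef(fit)[c("dfat", "dsugar")] / fit$se[c("dfat", "dsugar")])
    any(z > stats::qnorm(0.995))
  }, logical(1))
  expect_gte(mean(!sig), 0.95)
})

test_that("pseudo-R2 is zero for a null model and positive for real fits", {
  stim <- factorial_stim()
  blind <- nutrient_value_fn("b", temperature = 1)
  ses <- simulate_session(blind, stim, c("LFLS", "LFLS"), 400,
                          magnitude_grid = 0.5, seed = 9)
  fit <- fit_nutrient_model(ses, stim)
  # magnitude/nutrient regressors carry no signal here: LL equals null LL
  expect_equal(fit$pseudo_r2, 0, tolerance = 0.02)
})

test_that("session random intercepts absorb per-session bias", {
  stim <- factorial_stim()
  set.seed(31)
  pairs <- list(c("LFLS", "HFLS"), c("LFLS", "LFHS"), c("LFLS", "HFHS"))
  sessions <- lapply(1:6, function(i) {
    ag <- nutrient_value_fn(
      "v", w_fat = 0.12, w_sugar = 0.12, temperature = 3,
      side_bias = stats::rnorm(1, 0, 0.8))
    s <- simulate_session(ag, stim, pairs[[1 + (i %% 3)]], 200, seed = 40 + i,
                          session_id = paste0("s", i))
    as.data.frame(s)
  })
  dat <- choice_trials(do.call(rbind, sessions))
  fr <- fit_nutrient_model(dat, stim, session_effects = "random")
  ff <- fit_nutrient_model(dat, stim, session_effects = "fixed")
  expect_equal(coef(fr)[["dlogmag"]], 3, tolerance = 0.25)
  expect_equal(coef(ff)[["dlogmag"]], 3, tolerance = 0.25)
  expect_error(fit_nutrient_model(sessions[[1]], stim,
                                  session_effects = "fixed"), "2 sessions")
})

test_that("value-transformed offers predict choices out of sample", {
  stim <- factorial_stim()
  ag <- example_agent()
  dat <- make_dataset(list(ag), pair_schedule(stim, n_trials = 850), stim,
                      seed = 8)
  fits <- lapply(stats::setNames(nm = c("HFLS", "LFHS", "HFHS")), function(tg) {
    psychometric_fit(dat, stim, "LFLS", tg, n_bootstrap = 0)
  })
  val <- value_transform_validate(dat, stim, fits, "LFLS", k_folds = 10,
                                  seed = 4)
  expect_gt(val$adjusted_R2, 0.9)
  # destroying the signal destroys the fit; a bin-level R2 on a flat signal
  # is noisy, so the check is for collapse relative to the intact data
  shuf <- dat
  set.seed(99)
  shuf$choice <- sample(shuf$choice)
  val0 <- value_transform_validate(shuf, stim, fits, "LFLS", seed = 4)
  expect_lt(val0$adjusted_R2, 0.4)
  expect_lt(abs(mean(val0$bins$observed) - 0.5), 0.05)
  expect_error(value_transform_validate(dat[1:5, ], stim, fits, "LFLS"),
               "fewer trials")
})

test_that("reference-vs-reference trials reduce to magnitude alone", {
  stim <- factorial_stim()
  blind <- nutrient_value_fn("b", temperature = 2)
  ses <- simulate_session(blind, stim, c("LFLS", "LFLS"), 600, seed = 3)
  val <- value_transform_validate(ses, stim, list(), "LFLS", seed = 1)
  x_val <- log(ses$mag_left) - log(ses$mag_right)
  expect_equal(val$bins$value_diff,
               as.numeric(tapply(x_val, cut(x_val,
                 unique(stats::quantile(x_val, seq(0, 1, length.out = 11))),
                 include.lowest = TRUE, labels = FALSE), mean)))
})

test_that("relative values are multiplicative (transitivity)", {
  fits <- data.frame(reference = c("A", "B"), target = c("B", "C"),
                     value = c(2, 3))
  fits <- rbind(fits, data.frame(reference = "A", target = "C", value = 6.2,
                                 stringsAsFactors = FALSE))
  fits$ci_low <- fits$value * 0.8
  fits$ci_high <- fits$value * 1.25
  out <- transitivity_check(fits)
  expect_equal(out$implied, 6)
  expect_equal(out$ratio, 6 / 6.2)
  expect_true(out$within_ci)
  expect_error(transitivity_check(fits[1:2, ]), "triple")
})

test_that("measured transitivity holds for a generative agent", {
  stim <- factorial_stim()
  ag <- example_agent()
  # short edges estimated precisely so the implied value's own error stays
  # small relative to the measured CI of the long edge
  hits <- vapply(1:60, function(r) {
    seeds <- 300 + 3 * r + 0:2
    fit_pair <- function(ref, tgt, seed, n) {
      ses <- simulate_session(ag, stim, c(ref, tgt), n, seed = seed)
      f <- psychometric_fit(ses, stim, ref, tgt, n_bootstrap = 150, seed = seed)
      data.frame(reference = ref, target = tgt, value = f$indifference_point,
                 ci_low = f$ci_low, ci_high = f$ci_high,
                 stringsAsFactors = FALSE)
    }
    fits <- rbind(fit_pair("LFLS", "HFLS", seeds[1], 1200),
                  fit_pair("HFLS", "HFHS", seeds[2], 1200),
                  fit_pair("LFLS", "HFHS", seeds[3], 150))
    out <- transitivity_check(fits)
    out$within_ci[1]
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("psychometric and regression estimators agree on one truth", {
  stim <- factorial_stim()
  ag <- example_agent()
  dat <- make_dataset(list(ag), pair_schedule(stim, n_trials = 850), stim,
                      seed = 12)
  psy <- psychometric_fit(dat, stim, "LFLS", "HFLS", n_bootstrap = 0)
  reg <- fit_nutrient_model(dat, stim)
  implied <- implied_relative_value(reg, stim, "LFLS", "HFLS")
  expect_lt(abs(implied / psy$indifference_point - 1), 0.1)
})
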
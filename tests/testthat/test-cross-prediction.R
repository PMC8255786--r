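# two-flavor / two-agent fixtures for transfer prediction
cross_fixture <- function(w_sugar_j = 0.05, seed = 1, n_trials = 300,
                          sugar_levels = c(4.7, 6.7)) {
  stim <- make_factorial_stimuli(sugar_levels = sugar_levels)
  agent_i <- nutrient_value_fn("i", w_fat = 0.1, w_sugar = 0.05,
                               temperature = 1)
  agent_j <- nutrient_value_fn("j", w_fat = 0.1, w_sugar = w_sugar_j,
                               temperature = 1)
  sched <- pair_schedule(stim, n_trials = n_trials)
  list(stim = stim,
       trials_i = make_dataset(list(agent_i), sched, stim, seed = seed),
       trials_j = make_dataset(list(agent_j), sched, stim, seed = seed + 1))
}

test_that("cross-context pseudo-R2 behaves at its fixed points", {
  fx <- cross_fixture(seed = 5)
  fit_b <- fit_nutrient_model(fx$trials_j, fx$stim)
  # predicting B with a model fitted on B equals the in-sample pseudo-R2
  expect_equal(cross_context_predict(fit_b, fx$trials_j, fx$stim),
               fit_b$pseudo_r2, tolerance = 1e-10)
  # a sign-flipped model predicts worse than the null
  flipped <- fit_b
  flipped$coefficients <- -flipped$coefficients
  expect_lt(cross_context_predict(flipped, fx$trials_j, fx$stim), 0)
})

test_that("shared generative truth transfers across flavors", {
  stim_p <- make_factorial_stimuli(flavor = "peach", prefix = "P_")
  stim_b <- make_factorial_stimuli(flavor = "blackcurrant", prefix = "B_")
  both <- stimulus_table(c(stim_p$id, stim_b$id), c(stim_p$fat, stim_b$fat),
                         c(stim_p$sugar, stim_b$sugar), protein = 3.4,
                         flavor = rep(c("peach", "blackcurrant"), each = 4))
  ag <- example_agent(temperature = 2)
  dat_p <- make_dataset(list(ag), pair_schedule(stim_p, n_trials = 600),
                        both, seed = 2)
  dat_b <- make_dataset(list(ag), pair_schedule(stim_b, n_trials = 600),
                        both, seed = 3)
  fit_p <- fit_nutrient_model(dat_p, both)
  cross <- cross_context_predict(fit_p, dat_b, both)
  within <- fit_nutrient_model(dat_b, both)$pseudo_r2
  expect_lt(abs(cross - within), 0.05)
})

test_that("PDI is zero on itself, symmetric, and grows with dissimilarity", {
  fx <- cross_fixture(seed = 9)
  fit_i <- fit_nutrient_model(fx$trials_i, fx$stim)
  fit_j <- fit_nutrient_model(fx$trials_j, fx$stim)
  expect_identical(pdi(fit_i, fx$trials_i, fit_i, fx$trials_i, fx$stim)$pdi, 0)
  a <- pdi(fit_i, fx$trials_i, fit_j, fx$trials_j, fx$stim)
  b <- pdi(fit_j, fx$trials_j, fit_i, fx$trials_i, fx$stim)
  expect_equal(a$pdi, b$pdi, tolerance = 1e-15)
  # strictly increasing in the sugar-weight gap
  pdis <- vapply(c(0.2, 0.4, 0.8), function(delta) {
    fx2 <- cross_fixture(w_sugar_j = 0.05 + delta, seed = 31, n_trials = 400)
    pdi(fit_nutrient_model(fx2$trials_i, fx2$stim), fx2$trials_i,
        fit_nutrient_model(fx2$trials_j, fx2$stim), fx2$trials_j,
        fx2$stim)$pdi
  }, numeric(1))
  expect_true(all(diff(pdis) > 0))
})

test_that("expected PDI is non-negative across simulated agent pairs", {
  pdis <- vapply(1:20, function(r) {
    set.seed(r)
    w <- stats::runif(4, 0, 0.15)
    stim <- make_factorial_stimuli()
    ai <- nutrient_value_fn("i", w_fat = w[1], w_sugar = w[2], temperature = 1)
    aj <- nutrient_value_fn("j", w_fat = w[3], w_sugar = w[4], temperature = 1)
    sched <- pair_schedule(stim, n_trials = 150)
    ti <- make_dataset(list(ai), sched, stim, seed = 100 + r)
    tj <- make_dataset(list(aj), sched, stim, seed = 200 + r)
    pdi(fit_nutrient_model(ti, stim), ti,
        fit_nutrient_model(tj, stim), tj, stim)$pdi
  }, numeric(1))
  expect_gte(mean(pdis >= 0), 0.95)
  expect_gt(mean(pdis), 0)
})

test_that("PDI is invariant to session order and consistent side relabeling", {
  fx <- cross_fixture(seed = 13)
  fit_i <- fit_nutrient_model(fx$trials_i, fx$stim)
  fit_j <- fit_nutrient_model(fx$trials_j, fx$stim)
  ref <- pdi(fit_i, fx$trials_i, fit_j, fx$trials_j, fx$stim)$pdi
  # session order shuffled
  shuffled <- choice_trials(do.call(rbind, rev(split_sessions(fx$trials_i))))
  expect_equal(pdi(fit_i, shuffled, fit_j, fx$trials_j, fx$stim)$pdi, ref,
               tolerance = 1e-12)
  # left/right relabeled consistently (models refitted on relabeled data)
  flip <- function(tr) {
    out <- as.data.frame(tr)
    out[c("stim_left", "stim_right", "mag_left", "mag_right")] <-
      out[c("stim_right", "stim_left", "mag_right", "mag_left")]
    out$choice <- ifelse(out$choice == "left", "right", "left")
    choice_trials(out)
  }
  ti_f <- flip(fx$trials_i)
  tj_f <- flip(fx$trials_j)
  ref_f <- pdi(fit_nutrient_model(ti_f, fx$stim), ti_f,
               fit_nutrient_model(tj_f, fx$stim), tj_f, fx$stim)$pdi
  expect_equal(ref_f, ref, tolerance = 1e-9)
})

test_that("nutrient regressors explain preference dissimilarity", {
  # agents differing only in sugar weight: sugar contribution dominates
  stim <- make_factorial_stimuli(sugar_levels = c(4.7, 8.7))
  ai <- nutrient_value_fn("i", w_fat = 0.10, w_sugar = 0.05, temperature = 1)
  aj <- nutrient_value_fn("j", w_fat = 0.15, w_sugar = 0.25, temperature = 1)
  sched <- pair_schedule(stim, n_trials = 800)
  ti <- make_dataset(list(ai), sched, stim, seed = 51)
  tj <- make_dataset(list(aj), sched, stim, seed = 52)
  contrib <- pdi_contribution(ti, tj, stim)
  expect_gt(contrib[["sugar"]], 3 * contrib[["fat"]])
  expect_gte(contrib[["both"]], max(contrib[c("fat", "sugar")]) - 1e-9)
  # identical value functions: nothing to explain
  ti2 <- make_dataset(list(ai), sched, stim, seed = 61)
  tj2 <- make_dataset(list(ai), sched, stim, seed = 62)
  contrib0 <- pdi_contribution(ti2, tj2, stim)
  pdis0 <- attr(contrib0, "pdis")
  expect_lt(abs(pdis0[["both"]] - pdis0[["base"]]), 0.01)
})

test_that("triangle layout realizes embeddable side lengths", {
  tl <- triangle_layout(3, 4, 5)
  expect_false(tl$degenerate)
  d <- as.matrix(stats::dist(tl$coordinates))
  expect_equal(d["A", "B"], 3)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 5)
  # 3-4-5 is right-angled at A
  v1 <- tl$coordinates["B", ] - tl$coordinates["A", ]
  v2 <- tl$coordinates["C", ] - tl$coordinates["A", ]
  expect_equal(unname(sum(v1 * v2)), 0, tolerance = 1e-12)
  # violated triangle inequality is flagged, not silently drawn
  expect_true(triangle_layout(1, 1, 5)$degenerate)
  eq <- triangle_layout(2, 2, 2)
  expect_equal(unname(as.matrix(stats::dist(eq$coordinates))[c(2, 3, 6)]),
               c(2, 2, 2))
})
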
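test_that("cumulative trajectories sum intake correctly", {
  stim <- factorial_stim()
  # 2-trial toy session, hand-summed: 1 mL HFLS then 2 mL LFHS
  tr <- toy_trials("HFLS", "LFHS", c(1, 1), c(2, 2), c("left", "right"))
  traj <- cumulative_trajectory(tr, stim)
  expect_equal(traj$fat_g, c(0.036, 0.036 + 2 * 0.001))
  expect_equal(traj$sugar_g, c(0.047, 0.047 + 2 * 0.12575))
  expect_equal(traj$mag_HFLS, c(1, 1))
  expect_equal(traj$mag_LFHS, c(0, 2))
  # energy identity at every step
  expect_equal(traj$energy_kcal,
               9 * traj$fat_g + 4 * traj$sugar_g + 4 * traj$protein_g)
  # degenerate: an always-A agent never accumulates B
  trA <- toy_trials("HFLS", "LFHS", 1, 2, rep("left", 5))
  expect_equal(cumulative_trajectory(trA, stim)$mag_LFHS, rep(0, 5))
  # all cumulative series are non-decreasing
  dat <- simulate_session(example_agent(), stim, c("LFLS", "HFHS"), 200,
                          seed = 3)
  tj <- cumulative_trajectory(dat, stim)
  for (cl in setdiff(names(tj), "trial")) expect_true(all(diff(tj[[cl]]) >= -1e-12))
})

test_that("reference agents maximize their target quantity", {
  stim <- factorial_stim()
  ag <- example_agent()
  ses <- simulate_session(ag, stim, c("HFLS", "LFHS"), 1000, seed = 6)
  # calories strategy on isocaloric offers with equal magnitudes: all ties
  eq <- ses
  eq$mag_left <- eq$mag_right <- 0.5
  cal <- reference_agent(eq, stim, "calories", seed = 2)
  n_left <- sum(cal$choice == "left")
  band <- stats::qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(n_left, band[1])
  expect_lte(n_left, band[2])
  # sugar strategy never takes the low-sugar option at equal magnitudes
  sug <- reference_agent(eq, stim, "sugar", seed = 2)
  chosen <- ifelse(sug$choice == "left", sug$stim_left, sug$stim_right)
  expect_true(all(chosen == "LFHS"))
  # fat strategy against an exhaustive per-trial argmax oracle
  fat <- reference_agent(ses, stim, "fat", seed = 2)
  fl <- stim$fat[match(ses$stim_left, stim$id)] * ses$mag_left
  fr <- stim$fat[match(ses$stim_right, stim$id)] * ses$mag_right
  clear <- fl != fr
  expect_identical(fat$choice[clear], ifelse(fl > fr, "left", "right")[clear])
  # no agent can beat the per-strategy maximizer's cumulative target
  for (st in c("calories", "fat", "sugar", "magnitude")) {
    ref <- cumulative_trajectory(reference_agent(ses, stim, st, seed = 1),
                                 stim)
    act <- cumulative_trajectory(ses, stim)
    col <- switch(st, calories = "energy_kcal", fat = "fat_g",
                  sugar = "sugar_g", magnitude = NULL)
    if (!is.null(col)) {
      expect_lte(utils::tail(act[[col]], 1), utils::tail(ref[[col]], 1) + 1e-12)
    }
  }
})

test_that("polar nutrient-space transform has the right geometry", {
  stim <- factorial_stim()
  # pure sugar intake: 90 degrees; LFLS has nonzero sugar but ~zero fat
  sugar_only <- stimulus_table(c("S0", "SS"), fat = c(0, 0),
                               sugar = c(1, 5), protein = 0)
  tr <- toy_trials("S0", "SS", 1, 1, rep("right", 3))
  pol <- to_nutrient_polar(cumulative_trajectory(tr, sugar_only))
  expect_equal(pol$angle_deg, rep(90, 3))
  # equal fat and sugar kcal: 45 degrees
  eqk <- stimulus_table("E", fat = 4, sugar = 9, protein = 0)
  tr2 <- toy_trials("E", "E", 1, 1, rep("left", 2))
  pol2 <- to_nutrient_polar(cumulative_trajectory(tr2, eqk))
  expect_equal(pol2$angle_deg, rep(45, 2))
  # angle invariant to uniform magnitude rescaling
  tr3 <- toy_trials("S0", "SS", c(1, 2), c(2, 1), c("left", "right"))
  p1 <- to_nutrient_polar(cumulative_trajectory(tr3, sugar_only))
  tr3b <- tr3
  tr3b$mag_left <- 10 * tr3b$mag_left
  tr3b$mag_right <- 10 * tr3b$mag_right
  p2 <- to_nutrient_polar(cumulative_trajectory(tr3b, sugar_only))
  expect_equal(p1$angle_deg, p2$angle_deg)
})

test_that("calorie-maximizer angle converges to the expected kcal ratio", {
  stim <- factorial_stim()
  ag <- example_agent()
  ses <- simulate_session(ag, stim, c("HFLS", "LFHS"), 4000, seed = 17)
  cal <- reference_agent(ses, stim, "calories", seed = 3)
  pol <- to_nutrient_polar(cumulative_trajectory(cal, stim))
  # isocaloric offers: ties broken 50/50, so expected intake is the average
  # of the two stimuli's fat and sugar kcal per mL (equal expected mL each)
  fk <- 9 * stim$fat / 100
  sk <- 4 * stim$sugar / 100
  i <- match(c("HFLS", "LFHS"), stim$id)
  expected_angle <- atan2(mean(sk[i]), mean(fk[i])) * 180 / pi
  expect_equal(utils::tail(pol$angle_deg, 1), expected_angle, tolerance = 0.05)
})

test_that("AIC model comparison separates nutrient and energy agents", {
  stim <- factorial_stim()
  # sugar-weighted agent: nutrient model wins decisively
  ag <- nutrient_value_fn("s", w_fat = 0.03, w_sugar = 0.15, temperature = 2)
  dat <- make_dataset(list(ag), pair_schedule(stim, n_trials = 850), stim,
                      seed = 21)
  cmp <- compare_energy_vs_nutrient(dat, stim)
  expect_gt(cmp$delta_AIC, 10)
  # AIC identity 2k - 2LL
  expect_equal(cmp$AIC_nutrient,
               2 * cmp$nutrient_fit$k - 2 * cmp$nutrient_fit$loglik)
  expect_equal(cmp$AIC_energy,
               2 * cmp$energy_fit$k - 2 * cmp$energy_fit$loglik)
  # soft energy maximizer: nutrient model's extra parameters buy <= chance
  en <- energy_value_fn("e", beta_energy = 5)
  dat_e <- make_dataset(list(en), pair_schedule(stim, n_trials = 850), stim,
                        seed = 22)
  cmp_e <- compare_energy_vs_nutrient(dat_e, stim)
  expect_lte(cmp_e$delta_AIC, 4)
})

test_that("isocaloric sessions reveal sugar-over-fat weighting", {
  stim <- factorial_stim()
  iso_sessions <- function(w_fat, w_sugar, n_sessions, seed) {
    ag <- nutrient_value_fn("w", w_fat = w_fat, w_sugar = w_sugar,
                            temperature = 2)
    sched <- data.frame(stim_a = "HFLS", stim_b = "LFHS", n_trials = 100)
    make_dataset(list(ag), sched[rep(1, n_sessions), ], stim, seed = seed)
  }
  # w_sugar (per kcal) twice w_fat: detected in most replications
  p_vals <- vapply(1:30, function(r) {
    dat <- iso_sessions(0.2 / 3.5, 0.4 / 7.875, 12, seed = 400 + r)
    isocaloric_coefficient_test(dat, stim)$wilcoxon_p
  }, numeric(1))
  expect_gte(mean(p_vals < 0.05), 0.8)
  # matched weights: near-nominal rejection
  p0 <- vapply(1:40, function(r) {
    dat <- iso_sessions(0.3 / 3.5, 0.3 / 7.875, 12, seed = 900 + r)
    isocaloric_coefficient_test(dat, stim)$wilcoxon_p
  }, numeric(1))
  expect_lte(mean(p0 < 0.05), 0.15)
  # sign of the median contrast tracks sign of (w_sugar - w_fat)
  dat_s <- iso_sessions(0.1 / 3.5, 0.6 / 7.875, 12, seed = 7)
  expect_gt(isocaloric_coefficient_test(dat_s, stim)$median_dcoef, 0)
  dat_f <- iso_sessions(0.6 / 3.5, 0.1 / 7.875, 12, seed = 8)
  expect_lt(isocaloric_coefficient_test(dat_f, stim)$median_dcoef, 0)
  expect_error(isocaloric_coefficient_test(dat_f[dat_f$session_id ==
    dat_f$session_id[1], ], stim), "6 sessions")
})

test_that("trajectory averaging interpolates onto a common grid", {
  stim <- factorial_stim()
  ag <- example_agent()
  trajs <- lapply(1:3, function(i) {
    cumulative_trajectory(
      simulate_session(ag, stim, c("LFLS", "HFHS"), 100 + 30 * i,
                       seed = 70 + i), stim)
  })
  avg <- average_trajectories(trajs)
  expect_equal(nrow(avg), 130)
  expect_true(all(diff(avg$energy_kcal) >= -1e-12))
})
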
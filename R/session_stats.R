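#' Session-level choice-bias tests
#'
#' Two complementary tests on a single session's choice sequence (by
#' stimulus, not side): a two-sided binomial test of the option-choice
#' frequency against 0.5, and a run-length test comparing a first-order
#' Markov (stay/switch) model of the sequence against an iid Bernoulli
#' model by likelihood ratio (chi-squared, 1 df). Persistent, streaky
#' choices inflate the Markov stay probabilities and reject the iid model.
#'
#' @param trials A single-session [choice_trials()] table.
#' @return List with `binomial_p`, `runlength_lr_p`, `run_length_summary`
#'   (number of runs, mean and max run length) and the estimated stay
#'   probabilities.
#' @export
choice_bias_tests <- function(trials) {
  chosen <- ifelse(trials$choice == "left", trials$stim_left,
                   trials$stim_right)
  n <- length(chosen)
  if (n < 10) stop("need at least 10 trials")
  opts <- unique(c(trials$stim_left, trials$stim_right))
  s <- as.integer(chosen == opts[1])
  binom_p <- stats::binom.test(sum(s), n, 0.5)$p.value

  # first-order Markov (2 params) vs iid Bernoulli (1 param), both
  # conditioned on the first observation
  prev <- s[-n]
  cur <- s[-1]
  ll_term <- function(k, m) {
    if (m == 0) return(0)
    ph <- k / m
    k * log(max(ph, 1e-300)) + (m - k) * log(max(1 - ph, 1e-300))
  }
  ll_markov <- ll_term(sum(cur[prev == 1]), sum(prev == 1)) +
    ll_term(sum(cur[prev == 0]), sum(prev == 0))
  ll_bern <- ll_term(sum(cur), length(cur))
  lr <- 2 * (ll_markov - ll_bern)
  runs <- rle(s)
  list(
    binomial_p = binom_p,
    runlength_lr_p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
    run_length_summary = c(n_runs = length(runs$lengths),
                           mean_run = mean(runs$lengths),
                           max_run = max(runs$lengths)),
    stay_prob = c(
      after_1 = if (any(prev == 1)) mean(cur[prev == 1]) else NA_real_,
      after_0 = if (any(prev == 0)) 1 - mean(cur[prev == 0]) else NA_real_
    ),
    lr_statistic = lr
  )
}

#' Nutrient-for-magnitude trade-off quantification
#'
#' Compares the agent's realized liquid and nutrient intake against a
#' per-trial magnitude-maximizing oracle on the same offers, expressing the
#' magnitude given up and the nutrients gained as percentages of the
#' oracle's totals. A monkey that "gave up 8% of offered reward magnitudes
#' to obtain an additional 33% of fat" shows exactly this pattern.
#'
#' @param trials A single-session [choice_trials()] table.
#' @param stimuli A [stimulus_table()].
#' @return List with `pct_magnitude_forgone` and `pct_gained` (named vector:
#'   fat, sugar, energy) plus the underlying realized/oracle totals.
#' @export
tradeoff_quantification <- function(trials, stimuli) {
  if (length(unique(c(trials$stim_left, trials$stim_right))) < 2) {
    stop("need two distinct stimuli in the session")
  }
  sl <- match(trials$stim_left, stimuli$id)
  sr <- match(trials$stim_right, stimuli$id)
  left <- trials$choice == "left"
  intake <- function(take_left) {
    idx <- ifelse(take_left, sl, sr)
    mag <- ifelse(take_left, trials$mag_left, trials$mag_right)
    c(magnitude = sum(mag),
      fat = sum(mag * stimuli$fat[idx] / 100),
      sugar = sum(mag * stimuli$sugar[idx] / 100),
      energy = sum(mag * stimuli$energy_density[idx]))
  }
  realized <- intake(left)
  oracle <- intake(trials$mag_left >= trials$mag_right)
  list(
    pct_magnitude_forgone =
      100 * (oracle["magnitude"] - realized["magnitude"]) / oracle["magnitude"],
    pct_gained = 100 * (realized[c("fat", "sugar", "energy")] -
                          oracle[c("fat", "sugar", "energy")]) /
      oracle[c("fat", "sugar", "energy")],
    realized = realized, oracle = oracle
  )
}
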
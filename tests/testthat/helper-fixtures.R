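# Shared fixtures, all generated in code.

factorial_stim <- function(...) make_factorial_stimuli(...)

# the printed-example agent: one unit of HFLS worth 1.52 units of LFLS,
# a stronger sugar preference, temperature 3
example_agent <- function(temperature = 3, ...) {
  stim <- make_factorial_stimuli()
  nutrient_value_fn("m1",
                    w_fat = log(1.52) / diff(range(stim$fat)),
                    w_sugar = log(2.5) / diff(range(stim$sugar)),
                    temperature = temperature, ...)
}

# 13-stimulus texture-measurement set: factorial-like points plus cream-,
# juice- and water-like extremes; noise sd = 10% of the texture range
texture_stim_set <- function(seed = 11, visc_noise_sd = 0.27,
                             csf_noise_sd = 0.054) {
  fat <- c(0, 0, 0.1, 0.1, 3.6, 3.6, 9, 9, 1.5, 5, 7, 2.5, 0.5)
  sugar <- c(0, 10, 4.7, 12.6, 4.7, 12.6, 3, 6, 8, 5, 2, 10, 6)
  apply_texture(
    stimulus_table(paste0("S", seq_along(fat)), fat, sugar, protein = 3.4),
    texture_model(visc_noise_sd = visc_noise_sd, csf_noise_sd = csf_noise_sd),
    seed = seed
  )
}

# multi-session dataset of random stimulus pairs for one agent
random_pair_dataset <- function(agent, stim, n_sessions = 16, n_trials = 150,
                                seed = 3) {
  set.seed(seed)
  pairs <- t(replicate(n_sessions, sample(stim$id, 2)))
  sched <- data.frame(stim_a = pairs[, 1], stim_b = pairs[, 2],
                      n_trials = n_trials, stringsAsFactors = FALSE)
  make_dataset(list(agent), sched, stim, seed = seed + 1)
}

# hand-built trial table (no simulation) for exact-arithmetic checks
toy_trials <- function(stim_left, stim_right, mag_left, mag_right, choice,
                       session_id = "toy") {
  n <- length(choice)
  choice_trials(data.frame(
    session_id = session_id, trial = seq_len(n) - 1L,
    stim_left = rep_len(stim_left, n), stim_right = rep_len(stim_right, n),
    mag_left = rep_len(mag_left, n), mag_right = rep_len(mag_right, n),
    choice = choice, stringsAsFactors = FALSE
  ))
}
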
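#' Define a nutrient- or texture-driven value function
#'
#' An agent's subjective (relative) value of a stimulus is
#' \eqn{\log\rho = w_{fat} fat + w_{sugar} sugar (+ w_{int} fat\,sugar)} in
#' nutrient mode, or \eqn{\log\rho = w_{visc} visc + w_{csf} csf + w_{sugar}
#' sugar} in texture mode (texture mode engages as soon as a texture weight
#' is supplied). The subjective value of an offer is magnitude times
#' \eqn{\rho}; choices are logistic in the log-value difference scaled by the
#' temperature, plus a side bias, plus optional decaying choice-history
#' feedback.
#'
#' @param agent_id Agent label.
#' @param w_fat,w_sugar Log-value per g/100 mL of fat and sugar.
#' @param w_interaction Log-value per squared unit of the fat-by-sugar
#'   product (nutrient mode only).
#' @param w_visc,w_csf Log-value per texture unit; supplying either switches
#'   the agent to texture mode.
#' @param temperature Inverse choice noise (> 0); multiplies the log-value
#'   difference on the logit scale.
#' @param side_bias Logit offset toward the left side.
#' @param h_fat,h_sugar Optional choice-history weights (see
#'   [history_regressors()]).
#' @param h_window,h_decay History window length and per-trial decay.
#' @return A list of class `"value_fn"`.
#' @examples
#' # printed-example agent: one unit of HFLS worth 1.52 units of LFLS
#' a <- nutrient_value_fn("m1", w_fat = log(1.52) / 3.5, w_sugar = 0.116,
#'                        temperature = 3)
#' @export
nutrient_value_fn <- function(agent_id, w_fat = 0, w_sugar = 0,
                              w_interaction = 0, w_visc = NULL, w_csf = NULL,
                              temperature = 1, side_bias = 0,
                              h_fat = 0, h_sugar = 0, h_window = 5,
                              h_decay = 0.7) {
  if (temperature <= 0) stop("temperature must be > 0")
  mode <- if (!is.null(w_visc) || !is.null(w_csf)) "texture" else "nutrient"
  structure(list(agent_id = agent_id, mode = mode,
                 w_fat = w_fat, w_sugar = w_sugar,
                 w_interaction = w_interaction,
                 w_visc = if (is.null(w_visc)) 0 else w_visc,
                 w_csf = if (is.null(w_csf)) 0 else w_csf,
                 temperature = temperature, side_bias = side_bias,
                 h_fat = h_fat, h_sugar = h_sugar,
                 h_window = h_window, h_decay = h_decay),
            class = "value_fn")
}

#' Define an energy-maximizing stochastic agent
#'
#' The agent's choice logit is linear in the difference of offered energy
#' (magnitude times energy density, kcal), the soft version of a strict
#' calorie maximizer. Used as the generative counterpart of the energy
#' model in [compare_energy_vs_nutrient()].
#'
#' @param agent_id Agent label.
#' @param beta_energy Logit slope per kcal of offered-energy difference.
#' @param side_bias Logit offset toward the left side.
#' @return A list of class `"value_fn"` with mode `"energy"`.
#' @export
energy_value_fn <- function(agent_id, beta_energy = 5, side_bias = 0) {
  structure(list(agent_id = agent_id, mode = "energy",
                 beta_energy = beta_energy, side_bias = side_bias,
                 temperature = 1, h_fat = 0, h_sugar = 0,
                 h_window = 0, h_decay = 1),
            class = "value_fn")
}

# log rho for each row of a stimulus table under a value function
log_rho <- function(value_fn, stimuli) {
  switch(value_fn$mode,
    nutrient = value_fn$w_fat * stimuli$fat +
      value_fn$w_sugar * stimuli$sugar +
      value_fn$w_interaction * stimuli$fat * stimuli$sugar,
    texture = {
      if (anyNA(stimuli$viscosity) && value_fn$w_visc != 0 ||
          anyNA(stimuli$csf) && value_fn$w_csf != 0) {
        stop("texture-driven agent requires viscosity/csf on all stimuli")
      }
      value_fn$w_visc * ifelse(is.na(stimuli$viscosity), 0, stimuli$viscosity) +
        value_fn$w_csf * ifelse(is.na(stimuli$csf), 0, stimuli$csf) +
        value_fn$w_sugar * stimuli$sugar
    },
    stop("log_rho undefined for mode '", value_fn$mode, "'")
  )
}

#' Closed-form relative value of one stimulus in units of another
#'
#' The generative indifference point for a (reference, target) pair:
#' \eqn{\rho_{target}/\rho_{reference}}, i.e. how many units of reference
#' one unit of target is worth to the agent.
#'
#' @param value_fn A [nutrient_value_fn()].
#' @param stimuli A [stimulus_table()].
#' @param reference,target Stimulus ids.
#' @return The magnitude-ratio scalar.
#' @export
true_relative_value <- function(value_fn, stimuli, reference, target) {
  lr <- log_rho(value_fn, stimuli)
  exp(lr[match(target, stimuli$id)] - lr[match(reference, stimuli$id)])
}

#' Simulate one choice session
#'
#' Per trial the two stimuli are assigned to sides in a counterbalanced
#' pseudorandom order, magnitudes are drawn uniformly from a discrete grid,
#' and the agent chooses left with probability
#' \eqn{P = \mathrm{logistic}(\tau(\log v_L - \log v_R) + bias + history)}
#' where \eqn{v = magnitude \times \rho}. Deterministic for a fixed seed.
#'
#' @param value_fn A [nutrient_value_fn()] or [energy_value_fn()].
#' @param stimuli A [stimulus_table()] containing the offered pair.
#' @param stim_pair Character vector of two stimulus ids.
#' @param n_trials Number of trials.
#' @param magnitude_grid Discrete set of offer magnitudes (mL, positive).
#' @param seed Integer seed.
#' @param session_id Session label.
#' @return A [choice_trials()] table with `agent_id` and `flavor` columns.
#' @export
simulate_session <- function(value_fn, stimuli, stim_pair, n_trials = 200,
                             magnitude_grid = seq(0.2, 1.2, by = 0.2),
                             seed = 1, session_id = NULL) {
  stopifnot(inherits(value_fn, "value_fn"), length(stim_pair) == 2)
  if (!length(magnitude_grid)) stop("magnitude_grid is empty")
  if (any(magnitude_grid <= 0)) stop("magnitudes must be strictly positive")
  rows <- match(stim_pair, stimuli$id)
  if (anyNA(rows)) stop("stim_pair not found in stimulus table")
  if (is.null(session_id)) {
    session_id <- paste(value_fn$agent_id, paste(stim_pair, collapse = "-"),
                        seed, sep = "_")
  }
  set.seed(seed)
  # counterbalanced pseudorandom side assignment of the pair
  a_left <- sample(rep(c(TRUE, FALSE), length.out = n_trials))
  mag_left <- sample(magnitude_grid, n_trials, replace = TRUE)
  mag_right <- sample(magnitude_grid, n_trials, replace = TRUE)
  stim_left <- ifelse(a_left, stim_pair[1], stim_pair[2])
  stim_right <- ifelse(a_left, stim_pair[2], stim_pair[1])
  sl <- match(stim_left, stimuli$id)
  sr <- match(stim_right, stimuli$id)
  u <- stats::runif(n_trials)

  if (value_fn$mode == "energy") {
    dE <- mag_left * stimuli$energy_density[sl] -
      mag_right * stimuli$energy_density[sr]
    p_left <- stats::plogis(value_fn$beta_energy * dE + value_fn$side_bias)
    choice <- ifelse(u < p_left, "left", "right")
  } else {
    lr <- log_rho(value_fn, stimuli)
    base_logit <- value_fn$temperature *
      (log(mag_left) + lr[sl] - log(mag_right) - lr[sr]) + value_fn$side_bias
    use_history <- value_fn$h_fat != 0 || value_fn$h_sugar != 0
    if (!use_history) {
      choice <- ifelse(u < stats::plogis(base_logit), "left", "right")
    } else {
      choice <- character(n_trials)
      dfat <- stimuli$fat[sl] - stimuli$fat[sr]
      dsug <- stimuli$sugar[sl] - stimuli$sugar[sr]
      chose_fat <- chose_sug <- numeric(n_trials)
      w <- value_fn$h_decay^(seq_len(value_fn$h_window) - 1)
      for (t in seq_len(n_trials)) {
        back <- t - seq_len(min(value_fn$h_window, t - 1))
        hf <- hs <- 0
        if (length(back)) {
          hf <- sign(dfat[t]) * sum(w[seq_along(back)] * chose_fat[back])
          hs <- sign(dsug[t]) * sum(w[seq_along(back)] * chose_sug[back])
        }
        logit <- base_logit[t] + value_fn$h_fat * hf + value_fn$h_sugar * hs
        left <- u[t] < stats::plogis(logit)
        choice[t] <- if (left) "left" else "right"
        chose_fat[t] <- sign(if (left) dfat[t] else -dfat[t])
        chose_sug[t] <- sign(if (left) dsug[t] else -dsug[t])
      }
    }
  }
  choice_trials(data.frame(
    session_id = session_id, trial = seq_len(n_trials) - 1L,
    stim_left = stim_left, stim_right = stim_right,
    mag_left = mag_left, mag_right = mag_right, choice = choice,
    agent_id = value_fn$agent_id, flavor = stimuli$flavor[rows[1]],
    stringsAsFactors = FALSE
  ))
}

#' Simulate a full multi-agent, multi-session dataset
#'
#' One session per schedule entry per agent, with per-session seeds derived
#' deterministically from the master seed, so the whole dataset is
#' reproducible and sessions are mutually independent.
#'
#' @param agents List of value functions (see [nutrient_value_fn()]).
#' @param schedule Data frame with columns `stim_a`, `stim_b` and optional
#'   `n_trials` (default 200).
#' @param stimuli A [stimulus_table()].
#' @param seed Master integer seed.
#' @param magnitude_grid Offer magnitude grid passed to [simulate_session()].
#' @return A [choice_trials()] table covering all sessions.
#' @export
make_dataset <- function(agents, schedule, stimuli, seed = 1,
                         magnitude_grid = seq(0.2, 1.2, by = 0.2)) {
  if (inherits(agents, "value_fn")) agents <- list(agents)
  if (!nrow(schedule)) stop("schedule is empty")
  if (is.null(schedule$n_trials)) schedule$n_trials <- 200L
  n_sessions <- length(agents) * nrow(schedule)
  seeds <- derive_seeds(seed, n_sessions)
  out <- vector("list", n_sessions)
  k <- 0L
  for (agent in agents) {
    for (i in seq_len(nrow(schedule))) {
      k <- k + 1L
      out[[k]] <- simulate_session(
        agent, stimuli, c(schedule$stim_a[i], schedule$stim_b[i]),
        n_trials = schedule$n_trials[i], magnitude_grid = magnitude_grid,
        seed = seeds[k],
        session_id = sprintf("%s_s%02d", agent$agent_id, i)
      )
    }
  }
  df <- do.call(rbind, lapply(out, as.data.frame))
  choice_trials(df)
}

#' Default session schedule over the factorial stimulus set
#'
#' All six unordered pairs of the four factorial stimuli, repeated.
#'
#' @param stimuli A [stimulus_table()] (first four rows used).
#' @param n_trials Trials per session.
#' @param repeats Sessions per pair.
#' @return Schedule data frame for [make_dataset()].
#' @export
pair_schedule <- function(stimuli, n_trials = 200, repeats = 1) {
  ids <- stimuli$id[seq_len(min(4, nrow(stimuli)))]
  idx <- utils::combn(length(ids), 2)
  data.frame(
    stim_a = rep(ids[idx[1, ]], repeats),
    stim_b = rep(ids[idx[2, ]], repeats),
    n_trials = n_trials, stringsAsFactors = FALSE
  )
}
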
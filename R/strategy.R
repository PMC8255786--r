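#' Cumulative intake trajectory of a session
#'
#' Running sums, over chosen options only, of liquid magnitude per stimulus
#' and of fat, sugar and protein intake (g) and energy intake (kcal). The
#' energy column satisfies the Atwater identity
#' \eqn{E = 9 fat + 4 sugar + 4 protein} at every trial.
#'
#' @param trials A single-session [choice_trials()] table.
#' @param stimuli A [stimulus_table()].
#' @return Data frame of class `"choice_trajectory"` with one row per trial.
#' @export
cumulative_trajectory <- function(trials, stimuli) {
  idx <- ifelse(trials$choice == "left",
                match(trials$stim_left, stimuli$id),
                match(trials$stim_right, stimuli$id))
  mag <- ifelse(trials$choice == "left", trials$mag_left, trials$mag_right)
  ids <- unique(c(trials$stim_left, trials$stim_right))
  out <- data.frame(trial = trials$trial)
  for (id in ids) {
    out[[paste0("mag_", id)]] <- cumsum(mag * (stimuli$id[idx] == id))
  }
  out$fat_g <- cumsum(mag * stimuli$fat[idx] / 100)
  out$sugar_g <- cumsum(mag * stimuli$sugar[idx] / 100)
  out$protein_g <- cumsum(mag * stimuli$protein[idx] / 100)
  out$energy_kcal <- cumsum(mag * stimuli$energy_density[idx])
  attr(out, "stim_ids") <- ids
  class(out) <- c("choice_trajectory", "data.frame")
  out
}

#' @export
plot.choice_trajectory <- function(x, ...) {
  ids <- attr(x, "stim_ids")[1:2]
  graphics::plot(x[[paste0("mag_", ids[1])]], x[[paste0("mag_", ids[2])]],
                 type = "l", xlab = paste("cumulative", ids[1], "(mL)"),
                 ylab = paste("cumulative", ids[2], "(mL)"), ...)
  invisible(x)
}

#' Reference-strategy agent on the same offers
#'
#' Replays a session's offers through a deterministic maximizer of calories,
#' fat, sugar or magnitude: per trial it chooses the side with the larger
#' magnitude-times-target-content, breaking exact ties uniformly at random
#' under the seed.
#'
#' @param trials A [choice_trials()] table (the offers to replay).
#' @param stimuli A [stimulus_table()].
#' @param strategy One of `"calories"`, `"fat"`, `"sugar"`, `"magnitude"`.
#' @param seed Tie-breaking seed.
#' @return The trial table with `choice` replaced by the strategy's choices.
#' @export
reference_agent <- function(trials, stimuli,
                            strategy = c("calories", "fat", "sugar",
                                         "magnitude"),
                            seed = 1) {
  strategy <- match.arg(strategy)
  sl <- match(trials$stim_left, stimuli$id)
  sr <- match(trials$stim_right, stimuli$id)
  content <- switch(strategy,
                    calories = stimuli$energy_density,
                    fat = stimuli$fat / 100,
                    sugar = stimuli$sugar / 100,
                    magnitude = rep(1, nrow(stimuli)))
  vl <- trials$mag_left * content[sl]
  vr <- trials$mag_right * content[sr]
  set.seed(seed)
  tie <- stats::runif(nrow(trials)) < 0.5
  out <- as.data.frame(trials)
  out$choice <- ifelse(vl > vr, "left",
                       ifelse(vl < vr, "right", ifelse(tie, "left", "right")))
  choice_trials(out)
}

#' Polar nutrient-space transform of a trajectory
#'
#' Maps cumulative intake to nutrient space: Cartesian coordinates are
#' cumulative fat and sugar energy (kcal, so isocaloric designs put the
#' calorie-maximizer on the 45-degree diagonal); the angle against the fat
#' (horizontal) axis measures the fat-sugar trade-off and the radius tracks
#' trial progression.
#'
#' @param trajectory A [cumulative_trajectory()].
#' @return Data frame with per-trial `fat_kcal`, `sugar_kcal`, `radius` and
#'   `angle_deg` (NA while intake is zero).
#' @export
to_nutrient_polar <- function(trajectory) {
  fk <- 9 * trajectory$fat_g
  sk <- 4 * trajectory$sugar_g
  r <- sqrt(fk^2 + sk^2)
  ang <- ifelse(r > 0, atan2(sk, fk) * 180 / pi, NA_real_)
  data.frame(trial = trajectory$trial, fat_kcal = fk, sugar_kcal = sk,
             radius = r, angle_deg = ang)
}

#' Average trajectories across sessions on a common trial grid
#'
#' Linearly interpolates each session's cumulative series onto the trial
#' grid of the shortest session, then averages pointwise.
#'
#' @param trajectories List of [cumulative_trajectory()] objects.
#' @param columns Columns to average (default: all shared numeric columns).
#' @return Data frame of the averaged series.
#' @export
average_trajectories <- function(trajectories, columns = NULL) {
  n_min <- min(vapply(trajectories, nrow, integer(1)))
  grid <- seq_len(n_min) - 1
  if (is.null(columns)) {
    columns <- Reduce(intersect, lapply(trajectories, names))
    columns <- setdiff(columns, "trial")
  }
  out <- data.frame(trial = grid)
  for (cl in columns) {
    mat <- vapply(trajectories, function(tr) {
      stats::approx(tr$trial, tr[[cl]], xout = grid, rule = 2)$y
    }, numeric(n_min))
    out[[cl]] <- rowMeans(mat)
  }
  out
}

#' Energy-model versus nutrient-model AIC comparison
#'
#' Fits the energy-maximization choice model (logit linear in the
#' difference of offered energy, magnitude times energy density) and the
#' nutrient model (separate magnitude, fat and sugar terms) on the same
#' trials and compares them by AIC. Positive
#' \eqn{\Delta AIC = AIC_{energy} - AIC_{nutrient}} favors the nutrient
#' model.
#'
#' @param trials A [choice_trials()] table.
#' @param stimuli A [stimulus_table()].
#' @return List with `AIC_energy`, `AIC_nutrient`, `delta_AIC`, and both
#'   fits.
#' @export
compare_energy_vs_nutrient <- function(trials, stimuli) {
  des <- choice_design(trials, stimuli)
  energy <- fit_logit(cbind(`(side bias)` = 1, denergy = des$denergy), des$y)
  nutrient <- fit_nutrient_model(trials, stimuli)
  list(AIC_energy = energy$aic, AIC_nutrient = nutrient$aic,
       delta_AIC = energy$aic - nutrient$aic,
       energy_fit = energy, nutrient_fit = nutrient)
}

#' Isocaloric sugar-versus-fat coefficient test
#'
#' In sessions offering the complementary isocaloric pair (high-fat/low-sugar
#' vs low-fat/high-sugar), the dichotomous fat and sugar level regressors
#' are exactly anti-collinear within a session, so only their contrast is
#' identified: per session the model
#' \eqn{logit = \beta_0 + \beta_m z(\Delta\log mag) + \theta\, z(\Delta
#' sugar_{level})} is fitted, where \eqn{\theta} estimates the standardized
#' sugar-minus-fat coefficient difference. Energy maximization predicts
#' \eqn{\theta = 0}; the one-sample Wilcoxon signed-rank across sessions
#' (exact for n <= 25, normal approximation with continuity correction
#' above) tests that prediction.
#'
#' @param trials A [choice_trials()] table of isocaloric-pair sessions.
#' @param stimuli A [stimulus_table()].
#' @return List with `median_dcoef`, `wilcoxon_p`, and the per-session
#'   contrast estimates.
#' @export
isocaloric_coefficient_test <- function(trials, stimuli) {
  des <- choice_design(trials, stimuli)
  sessions <- unique(des$session_id)
  if (length(sessions) < 6) stop("need >= 6 sessions")
  theta <- vapply(sessions, function(sid) {
    d <- des[des$session_id == sid, ]
    contrast <- (d$dsugar_level - d$dfat_level) / 2  # +1 high-sugar side left
    zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v
    f <- fit_logit(cbind(1, zmag = zs(d$dlogmag), zcontrast = zs(contrast)),
                   d$y)
    unname(f$coefficients["zcontrast"])
  }, numeric(1))
  n <- length(theta)
  wt <- stats::wilcox.test(theta, mu = 0, exact = n <= 25, correct = TRUE)
  list(median_dcoef = stats::median(theta), wilcoxon_p = wt$p.value,
       per_session = stats::setNames(theta, sessions))
}
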
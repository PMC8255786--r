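#' Psychometric indifference-point estimation
#'
#' Fits a logistic psychometric curve to the probability of choosing the
#' low-nutrient reference as a function of the log offered-magnitude ratio
#' (reference / target), by maximum likelihood on raw trials. The
#' indifference point — the magnitude ratio at which both options are chosen
#' with probability 0.5 — measures the target's value on the common scale of
#' the reference: an indifference point of 1.52 means one unit of target is
#' worth 1.52 units of reference. Confidence intervals come from a
#' case-resampling bootstrap over trials; binning is used only for the
#' display-level adjusted R-squared.
#'
#' @param trials A [choice_trials()] table (trials on other pairs are
#'   ignored).
#' @param stimuli A [stimulus_table()].
#' @param reference,target Stimulus ids of the reference and target rewards.
#' @param n_bootstrap Bootstrap iterations for the 95% CI.
#' @param seed Seed for the bootstrap resampling.
#' @param n_bins Frequency bins for the descriptive adjusted R-squared.
#' @return Object of class `"psychometric_fit"` with elements
#'   `indifference_point`, `slope` (per log-ratio), `ci_low`, `ci_high`,
#'   `n_trials`, `goodness` (adjusted R-squared on binned frequencies) and
#'   the bootstrap draws.
#' @examples
#' stim <- make_factorial_stimuli()
#' ag <- nutrient_value_fn("a", w_fat = log(1.52) / diff(range(stim$fat)),
#'                         temperature = 3)
#' ses <- simulate_session(ag, stim, c("LFLS", "HFLS"), 500, seed = 2)
#' fit <- psychometric_fit(ses, stim, "LFLS", "HFLS", n_bootstrap = 200)
#' coef(fit)
#' @export
psychometric_fit <- function(trials, stimuli, reference, target,
                             n_bootstrap = 1000, seed = 1, n_bins = 8) {
  dat <- pair_trials(trials, reference, target)
  if (!nrow(dat)) stop("no trials offering the requested pair")
  y <- as.integer(dat$stim_ref_side == dat$choice)  # chose reference
  x <- dat$log_ratio                                # log(mag_ref / mag_target)
  if (length(unique(round(x, 12))) < 2) {
    stop("need at least 2 distinct magnitude ratios")
  }
  if (length(unique(y)) < 2) stop("no inflection identifiable: all choices identical")
  fit <- fit_logit(cbind(intercept = 1, log_ratio = x), y)
  ip <- ip_from_coef(fit$coefficients)
  boot <- numeric(0)
  if (n_bootstrap > 0) {
    set.seed(seed)
    boot <- vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(length(y), replace = TRUE)
      if (length(unique(y[idx])) < 2 ||
          length(unique(round(x[idx], 12))) < 2) return(NA_real_)
      f <- fit_logit(cbind(1, x[idx]), y[idx])
      ip_from_coef(f$coefficients)
    }, numeric(1))
    boot <- boot[is.finite(boot)]
  }
  ci <- if (length(boot)) unname(stats::quantile(boot, c(0.025, 0.975))) else
    c(NA_real_, NA_real_)
  structure(list(
    indifference_point = ip, slope = unname(fit$coefficients[2]),
    ci_low = ci[1], ci_high = ci[2], n_trials = length(y),
    goodness = binned_adj_r2(x, y, fit$fitted, n_bins),
    reference = reference, target = target,
    coefficients = fit$coefficients, loglik = fit$loglik,
    bootstrap = boot
  ), class = "psychometric_fit")
}

# ratio at which P(choose reference) = 0.5
ip_from_coef <- function(beta) {
  if (abs(beta[2]) < 1e-12) return(NA_real_)
  exp(-beta[1] / beta[2])
}

# trials offering exactly {reference, target}, with the reference side and
# the log magnitude ratio reference/target
pair_trials <- function(trials, reference, target) {
  ref_left <- trials$stim_left == reference & trials$stim_right == target
  ref_right <- trials$stim_left == target & trials$stim_right == reference
  dat <- as.data.frame(trials)[ref_left | ref_right, , drop = FALSE]
  rl <- dat$stim_left == reference
  dat$stim_ref_side <- ifelse(rl, "left", "right")
  dat$log_ratio <- ifelse(rl, log(dat$mag_left) - log(dat$mag_right),
                          log(dat$mag_right) - log(dat$mag_left))
  dat
}

# adjusted R^2 of model-fitted choice probabilities against binned observed
# frequencies (descriptive goodness-of-fit; the fit itself is trial-level ML)
binned_adj_r2 <- function(x, y, fitted, n_bins = 8, n_params = 2) {
  ux <- sort(unique(x))
  if (length(ux) <= n_bins) {
    bin <- match(x, ux)
  } else {
    br <- unique(stats::quantile(x, seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(x, br, include.lowest = TRUE, labels = FALSE)
  }
  obs <- tapply(y, bin, mean)
  pred <- tapply(fitted, bin, mean)
  nb <- length(obs)
  if (nb <= n_params + 1) return(NA_real_)
  r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  1 - (1 - r2) * (nb - 1) / (nb - n_params - 1)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Psychometric fit:", x$reference, "(reference) vs", x$target, "\n")
  cat(sprintf("  indifference point %.3f [%.3f, %.3f] (95%% bootstrap CI)\n",
              x$indifference_point, x$ci_low, x$ci_high))
  cat(sprintf("  slope %.2f per log-ratio, n = %d trials, adj R2 = %.3f\n",
              x$slope, x$n_trials, x$goodness))
  invisible(x)
}

#' @export
coef.psychometric_fit <- function(object, ...) {
  c(indifference_point = object$indifference_point, slope = object$slope)
}

#' Predicted probability of choosing the reference at given magnitude ratios
#'
#' @param object A [psychometric_fit()].
#' @param ratio Offered magnitude ratios (reference / target).
#' @param ... Unused.
#' @return Vector of choice probabilities.
#' @export
predict.psychometric_fit <- function(object, ratio, ...) {
  b <- object$coefficients
  stats::plogis(b[1] + b[2] * log(ratio))
}

#' @export
plot.psychometric_fit <- function(x, ...) {
  r <- exp(seq(log(0.15), log(8), length.out = 200))
  graphics::plot(r, predict(x, r), type = "l", log = "x",
                 xlab = "magnitude ratio (reference/target)",
                 ylab = "P(choose reference)", ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 3)
  graphics::abline(v = x$indifference_point, lty = 2)
  invisible(x)
}
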
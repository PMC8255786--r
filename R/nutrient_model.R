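#' Fit the trial-level nutrient choice model
#'
#' Logistic regression of the chosen side on the left-minus-right
#' differences of log magnitude and of fat and sugar concentration, with an
#' intercept capturing side bias, optionally a fat-by-sugar interaction,
#' choice-history regressors, and session intercepts as fixed dummies or
#' random intercepts (Laplace approximation via \pkg{lme4}). This is the
#' estimation-side inverse of the generative model in [simulate_session()]:
#' on simulated data the fitted magnitude, fat and sugar coefficients
#' recover \eqn{\tau}, \eqn{\tau w_{fat}} and \eqn{\tau w_{sugar}}.
#'
#' @param trials A [choice_trials()] table.
#' @param stimuli A [stimulus_table()].
#' @param include_interaction Add the fat-by-sugar product difference.
#' @param include_history Add [history_regressors()] terms.
#' @param session_effects `"none"`, `"fixed"` (per-session dummy
#'   intercepts) or `"random"` (random intercepts, Laplace-approximated
#'   marginal likelihood).
#' @param coding `"concentration"` uses g/100 mL differences;
#'   `"level"` uses dichotomous high/low level differences.
#' @param extra_terms Additional design columns to include (e.g. `"dvisc"`,
#'   `"dcsf"`, `"denergy"`).
#' @return Object of class `"nutrient_model"`: coefficients with SEs,
#'   log-likelihood, AIC (\eqn{2k - 2LL}), McFadden pseudo-R-squared against
#'   an intercept-only null, and a separation flag (a ridge-stabilized
#'   refit is reported when the MLE is unbounded).
#' @examples
#' stim <- make_factorial_stimuli()
#' ag <- nutrient_value_fn("a", w_fat = 0.12, w_sugar = 0.12, temperature = 3)
#' dat <- make_dataset(ag, pair_schedule(stim, n_trials = 100), stim, seed = 1)
#' fit <- fit_nutrient_model(dat, stim)
#' coef(fit)
#' @export
fit_nutrient_model <- function(trials, stimuli, include_interaction = FALSE,
                               include_history = FALSE,
                               session_effects = c("none", "fixed", "random"),
                               coding = c("concentration", "level"),
                               extra_terms = NULL) {
  session_effects <- match.arg(session_effects)
  coding <- match.arg(coding)
  des <- choice_design(trials, stimuli)
  if (session_effects != "none" && length(unique(des$session_id)) < 2) {
    stop("need >= 2 sessions to estimate session effects")
  }
  terms <- if (coding == "concentration") c("dlogmag", "dfat", "dsugar") else
    c("dlogmag", "dfat_level", "dsugar_level")
  if (include_interaction) terms <- c(terms, "dfatsugar")
  if (!is.null(extra_terms)) terms <- unique(c(terms, extra_terms))
  if (include_history) {
    des <- cbind(des, history_regressors(trials, stimuli))
    terms <- c(terms, "hist_fat", "hist_sugar")
  }
  X <- as.matrix(des[terms])
  y <- des$y
  ll0 <- null_loglik(y)

  if (session_effects == "random") {
    dat <- data.frame(y = y, X, session_id = des$session_id,
                      check.names = FALSE)
    form <- stats::reformulate(c(sprintf("`%s`", terms), "(1 | session_id)"),
                               response = "y")
    fit <- lme4::glmer(form, data = dat, family = stats::binomial(),
                       nAGQ = 1L,
                       control = lme4::glmerControl(calc.derivs = FALSE))
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    ll <- as.numeric(stats::logLik(fit))
    k <- attr(stats::logLik(fit), "df")
    out <- list(coefficients = beta, se = se, loglik = ll,
                aic = 2 * k - 2 * ll, k = k, separated = FALSE,
                session_intercepts = NULL, glmer_fit = fit)
  } else {
    Xfull <- cbind(`(side bias)` = 1, X)
    if (session_effects == "fixed") {
      sess <- factor(des$session_id)
      if (nlevels(sess) > 1) {
        D <- stats::model.matrix(~sess)[, -1, drop = FALSE]
        colnames(D) <- paste0("session:", levels(sess)[-1])
        Xfull <- cbind(Xfull, D)
      }
    }
    f <- fit_logit(Xfull, y)
    sess_int <- NULL
    if (session_effects == "fixed") {
      sess_cols <- grep("^session:", names(f$coefficients))
      sess_int <- c(f$coefficients[1],
                    f$coefficients[1] + f$coefficients[sess_cols])
    }
    out <- list(coefficients = f$coefficients, se = f$se, loglik = f$loglik,
                aic = f$aic, k = f$k, separated = f$separated,
                session_intercepts = sess_int, glmer_fit = NULL)
  }
  out$pseudo_r2 <- mcfadden_r2(out$loglik, ll0)
  out$null_loglik <- ll0
  out$terms <- terms
  out$coding <- coding
  out$include_history <- include_history
  out$session_effects <- session_effects
  out$n <- length(y)
  class(out) <- "nutrient_model"
  out
}

#' @export
print.nutrient_model <- function(x, ...) {
  cat(sprintf(
    "Nutrient choice model (%s coding, session effects: %s)\n",
    x$coding, x$session_effects))
  keep <- !grepl("^session:", names(x$coefficients))
  tab <- cbind(estimate = x$coefficients[keep], se = x$se[keep])
  print(round(tab, 4))
  cat(sprintf("n = %d trials, logLik = %.2f, AIC = %.2f, McFadden R2 = %.3f\n",
              x$n, x$loglik, x$aic, x$pseudo_r2))
  if (x$separated) cat("note: separation detected; ridge-stabilized fit reported\n")
  invisible(x)
}

#' @export
coef.nutrient_model <- function(object, ...) object$coefficients

#' @export
logLik.nutrient_model <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
summary.nutrient_model <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- data.frame(estimate = object$coefficients, se = object$se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  structure(list(table = tab, model = object), class = "summary.nutrient_model")
}

#' @export
print.summary.nutrient_model <- function(x, ...) {
  print(x$model)
  invisible(x)
}

# population-level linear predictor on new trials; unseen sessions get the
# average session intercept
model_logit <- function(object, trials, stimuli) {
  des <- choice_design(trials, stimuli)
  if (object$include_history) {
    des <- cbind(des, history_regressors(trials, stimuli))
  }
  X <- as.matrix(des[object$terms])
  beta <- object$coefficients
  if (object$session_effects == "random") {
    intercept <- unname(beta["(Intercept)"])
    slopes <- beta[setdiff(names(beta), "(Intercept)")]
  } else {
    intercept <- if (is.null(object$session_intercepts)) {
      unname(beta[1])
    } else mean(object$session_intercepts)
    slopes <- beta[!grepl("^session:", names(beta))][-1]
  }
  drop(X %*% slopes[object$terms]) + intercept
}

#' Predicted leftward-choice probabilities on (new) trials
#'
#' Uses the population-level model: fixed-effect slopes with the average
#' session intercept, so predictions transfer to sessions the model never
#' saw (the basis of cross-flavor and cross-animal prediction).
#'
#' @param object A [fit_nutrient_model()] fit.
#' @param trials,stimuli Data to predict on.
#' @param type `"response"` for probabilities, `"link"` for logits.
#' @param ... Unused.
#' @export
predict.nutrient_model <- function(object, trials, stimuli,
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- model_logit(object, trials, stimuli)
  if (type == "link") eta else stats::plogis(eta)
}

# total log-likelihood of trials under a (possibly foreign) fitted model
model_loglik <- function(object, trials, stimuli) {
  p <- predict.nutrient_model(object, trials, stimuli)
  y <- as.integer(trials$choice == "left")
  bernoulli_loglik(y, p)
}

#' Regression-implied relative value of a stimulus pair
#'
#' Converts fitted nutrient coefficients into the magnitude-ratio scale of
#' the psychometric indifference point:
#' \eqn{\exp\{(\beta \cdot \Delta nutrients) / \beta_{mag}\}} for the
#' (reference, target) pair, the second estimator of the same quantity.
#'
#' @param object A [fit_nutrient_model()] fit with concentration coding.
#' @param stimuli A [stimulus_table()].
#' @param reference,target Stimulus ids.
#' @return Implied indifference-point scalar.
#' @export
implied_relative_value <- function(object, stimuli, reference, target) {
  stopifnot(object$coding == "concentration")
  beta <- object$coefficients
  rt <- match(c(reference, target), stimuli$id)
  dfat <- stimuli$fat[rt[2]] - stimuli$fat[rt[1]]
  dsug <- stimuli$sugar[rt[2]] - stimuli$sugar[rt[1]]
  num <- beta[["dfat"]] * dfat + beta[["dsugar"]] * dsug
  if ("dfatsugar" %in% names(beta)) {
    num <- num + beta[["dfatsugar"]] *
      (stimuli$fat[rt[2]] * stimuli$sugar[rt[2]] -
         stimuli$fat[rt[1]] * stimuli$sugar[rt[1]])
  }
  exp(num / beta[["dlogmag"]])
}
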
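#' Cross-context predictive pseudo-R-squared
#'
#' Evaluates a nutrient model fitted in one context (flavor, animal) on the
#' trials of another: held-out McFadden pseudo-R-squared
#' \eqn{1 - LL(B\mid fit)/LL(B\mid null)}, where the intercept-only null is
#' fitted on the target data (or, optionally, transferred from the source
#' fit's side bias).
#'
#' @param fit A [fit_nutrient_model()] fit from context A.
#' @param trials,stimuli Context-B data.
#' @param null Either `"target"` (default; null fitted on B) or
#'   `"transferred"` (source model's intercept only).
#' @return Pseudo-R-squared scalar (negative when the transferred model is
#'   worse than the null).
#' @export
cross_context_predict <- function(fit, trials, stimuli,
                                  null = c("target", "transferred")) {
  null <- match.arg(null)
  ll <- model_loglik(fit, trials, stimuli)
  y <- as.integer(trials$choice == "left")
  ll0 <- if (null == "target") {
    null_loglik(y)
  } else {
    # source model's side-bias intercept only, transferred to B
    intercept <- if (is.null(fit$session_intercepts)) {
      unname(fit$coefficients[1])
    } else mean(fit$session_intercepts)
    bernoulli_loglik(y, stats::plogis(rep(intercept, length(y))))
  }
  mcfadden_r2(ll, ll0)
}

#' Preference dissimilarity index (PDI)
#'
#' Symmetric per-trial log-likelihood-ratio measure of how badly one
#' agent's fitted value function predicts another agent's choices:
#' \deqn{PDI = \tfrac12\left[\frac{LL(i|i)-LL(i|j)}{n_i} +
#'   \frac{LL(j|j)-LL(j|i)}{n_j}\right]}
#' in nats per trial. Zero when the two models are identical; non-negative
#' in expectation (Gibbs inequality).
#'
#' @param model_i,model_j Fitted [fit_nutrient_model()] objects.
#' @param trials_i,trials_j The two agents' trial tables.
#' @param stimuli A [stimulus_table()] covering both datasets.
#' @return Object of class `"pdi_result"`: `pdi`, per-direction components,
#'   and the trial counts.
#' @export
pdi <- function(model_i, trials_i, model_j, trials_j, stimuli) {
  n_i <- nrow(trials_i)
  n_j <- nrow(trials_j)
  ll_ii <- model_loglik(model_i, trials_i, stimuli)
  ll_ij <- model_loglik(model_j, trials_i, stimuli)
  ll_jj <- model_loglik(model_j, trials_j, stimuli)
  ll_ji <- model_loglik(model_i, trials_j, stimuli)
  comp <- c(i_given_j = (ll_ii - ll_ij) / n_i,
            j_given_i = (ll_jj - ll_ji) / n_j)
  structure(list(pdi = mean(comp), components = comp, n_i = n_i, n_j = n_j),
            class = "pdi_result")
}

#' @export
print.pdi_result <- function(x, ...) {
  cat(sprintf("PDI = %.4f nats/trial (components: %.4f, %.4f; n = %d, %d)\n",
              x$pdi, x$components[1], x$components[2], x$n_i, x$n_j))
  invisible(x)
}

#' Nutrient contributions to preference dissimilarity
#'
#' Refits both agents' choice models from a nutrient-free base (magnitude
#' and side bias only) and with fat, sugar or both added, and reports the
#' percentage increase in PDI attributable to each added regressor set. A
#' large sugar contribution means the agents' sugar valuations are what
#' distinguishes them.
#'
#' @param trials_i,trials_j The two agents' trial tables.
#' @param stimuli A [stimulus_table()].
#' @param added Character vector among `"fat"`, `"sugar"`, `"both"`.
#' @return Named numeric vector of percentage PDI increases (NA with a
#'   `"note"` attribute when the base PDI is zero), with the underlying PDIs
#'   as attribute `"pdis"`.
#' @export
pdi_contribution <- function(trials_i, trials_j, stimuli,
                             added = c("fat", "sugar", "both")) {
  added <- match.arg(added, several.ok = TRUE)
  fit_with <- function(trials, terms) {
    des <- choice_design(trials, stimuli)
    X <- cbind(`(side bias)` = 1, as.matrix(des[terms]))
    f <- fit_logit(X, des$y)
    structure(list(coefficients = f$coefficients, terms = terms,
                   session_effects = "none", include_history = FALSE,
                   session_intercepts = NULL, coding = "concentration"),
              class = "nutrient_model")
  }
  sets <- list(base = "dlogmag")
  if ("fat" %in% added) sets$fat <- c("dlogmag", "dfat")
  if ("sugar" %in% added) sets$sugar <- c("dlogmag", "dsugar")
  if ("both" %in% added) sets$both <- c("dlogmag", "dfat", "dsugar")
  pdis <- vapply(sets, function(terms) {
    pdi(fit_with(trials_i, terms), trials_i,
        fit_with(trials_j, terms), trials_j, stimuli)$pdi
  }, numeric(1))
  base <- pdis["base"]
  out <- 100 * (pdis[-1] - base) / base
  if (!is.finite(base) || abs(base) < 1e-12) {
    out[] <- NA_real_
    attr(out, "note") <- "base PDI is zero; contribution undefined"
  }
  attr(out, "pdis") <- pdis
  out
}

#' Planar triangle layout from three pairwise dissimilarities
#'
#' Places three agents in the plane so that pairwise distances equal the
#' pairwise PDIs, when the triangle inequality allows an embedding.
#'
#' @param d_ab,d_ac,d_bc The three pairwise dissimilarities (>= 0).
#' @param labels Vertex labels.
#' @return List with `coordinates` (3 x 2 matrix), `sides`, and a
#'   `degenerate` flag (TRUE when the sides violate the triangle
#'   inequality, in which case coordinates are NA).
#' @export
triangle_layout <- function(d_ab, d_ac, d_bc, labels = c("A", "B", "C")) {
  sides <- c(ab = d_ab, ac = d_ac, bc = d_bc)
  if (any(sides < 0)) stop("dissimilarities must be non-negative")
  coords <- matrix(NA_real_, 3, 2, dimnames = list(labels, c("x", "y")))
  x <- (d_ab^2 + d_ac^2 - d_bc^2) / (2 * d_ab)
  y2 <- d_ac^2 - x^2
  degenerate <- !is.finite(x) || y2 < -1e-9 * max(sides)^2
  if (!degenerate) {
    coords[1, ] <- c(0, 0)
    coords[2, ] <- c(d_ab, 0)
    coords[3, ] <- c(x, sqrt(max(y2, 0)))
  }
  list(coordinates = coords, sides = sides, degenerate = degenerate)
}
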
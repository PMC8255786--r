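# Internal logistic-regression engine shared by all choice models.
# Plain IRLS via stats::glm.fit with a ridge-penalized fallback when the
# likelihood is unbounded (complete or quasi-complete separation).

fit_logit <- function(X, y, ridge = 1e-2) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  stopifnot(nrow(X) == length(y))
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta <- fit$coefficients
  separated <- !isTRUE(fit$converged) || anyNA(beta) || max(abs(beta)) > 15
  if (separated) beta <- ridge_logit(X, y, lambda = ridge)
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  ll <- bernoulli_loglik(y, p)
  w <- p * (1 - p)
  H <- crossprod(X * w, X)
  if (separated) diag(H) <- diag(H) + ridge
  V <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(pmax(diag(V), 0))
  names(beta) <- names(se) <- colnames(X)
  k <- ncol(X)
  list(coefficients = beta, se = se, loglik = ll, aic = 2 * k - 2 * ll,
       fitted = p, vcov = V, separated = separated, n = length(y), k = k)
}

# Ridge-penalized IRLS; small uniform penalty keeps estimates finite under
# separation while leaving well-identified coefficients essentially unchanged.
ridge_logit <- function(X, y, lambda = 1e-2, maxit = 200, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + lambda
    beta_new <- drop(solve(H, crossprod(X * w, z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

# coefficient-only refit for bootstrap loops: warm-started glm.fit with the
# same ridge fallback, skipping the information-matrix work
fit_logit_coef <- function(X, y, start = NULL, ridge = 1e-2) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                         start = start))
  beta <- fit$coefficients
  if (!isTRUE(fit$converged) || anyNA(beta) || max(abs(beta)) > 15) {
    beta <- ridge_logit(X, y, lambda = ridge)
  }
  beta
}

bernoulli_loglik <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# Log-likelihood of an intercept-only Bernoulli model fitted to y.
null_loglik <- function(y) {
  bernoulli_loglik(y, mean(y))
}

mcfadden_r2 <- function(ll, ll0) {
  if (ll0 == 0) return(NA_real_)
  1 - ll / ll0
}

# Deterministic stream of sub-seeds below 2^31, derived from one master seed.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
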
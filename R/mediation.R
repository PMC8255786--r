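#' Stimulus-level texture-on-nutrient regressions (path a)
#'
#' Ordinary least squares of viscosity and CSF on fat concentration (and,
#' separately, on sugar) across the stimulus set. A positive viscosity
#' slope and a negative CSF slope reproduce the physical signature of fat:
#' thicker and more slippery liquids.
#'
#' @param stimuli A [stimulus_table()] with texture columns filled.
#' @return Data frame with one row per (response, predictor) pair:
#'   slope, SE, 95% CI, R-squared and n.
#' @export
texture_on_nutrients <- function(stimuli) {
  if (anyNA(stimuli$viscosity) || anyNA(stimuli$csf)) {
    stop("stimuli must carry viscosity and csf measurements")
  }
  if (length(unique(stimuli$fat)) < 3) {
    stop("texture and fat collinear; mediation unidentifiable ",
         "(need >= 3 distinct fat concentrations)")
  }
  one <- function(response, predictor) {
    f <- stats::lm(stimuli[[response]] ~ stimuli[[predictor]])
    s <- summary(f)
    ci <- stats::confint(f)[2, ]
    data.frame(response = response, predictor = predictor,
               intercept = unname(stats::coef(f)[1]),
               slope = unname(stats::coef(f)[2]),
               se = s$coefficients[2, 2],
               ci_low = ci[1], ci_high = ci[2],
               r_squared = s$r.squared, n = nrow(stimuli),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  rbind(one("viscosity", "fat"), one("csf", "fat"),
        one("viscosity", "sugar"), one("csf", "sugar"))
}

#' Texture mediation of nutrient effects on choice (path model)
#'
#' Tests whether viscosity and sliding friction mediate the effect of fat on
#' choices via a regression-based path model. The total-effect logistic
#' regression (choice on standardized magnitude, fat and sugar differences)
#' gives the c paths; adding standardized texture differences gives the
#' direct effects c' and the texture paths b; the stimulus-level
#' regressions of texture on fat give the a paths. All regressors are
#' z-scored before fitting so coefficients are comparable across models,
#' and the indirect effect is measured as the standardized-coefficient drop
#' c - c'. CIs for b, c, c' and c - c' come from a session-level (cluster)
#' bootstrap; path-a CIs come from the stimulus-level OLS. Mediation is
#' "complete" for a nutrient when its total effect is significant, its
#' direct effect is not, and the indirect-effect CI excludes zero;
#' "partial" when total, direct and indirect are all significant; "none"
#' otherwise.
#'
#' @param trials A [choice_trials()] table.
#' @param stimuli A [stimulus_table()] with texture values.
#' @param textures Which texture channels to include: subset of
#'   `c("visc", "csf")`.
#' @param n_bootstrap Cluster-bootstrap iterations.
#' @param seed Bootstrap seed.
#' @param conf Confidence level for percentile intervals.
#' @return Object of class `"path_model"`: the a/b/c/c' coefficient tables
#'   with CIs, the bootstrap draws, and a mediation verdict per nutrient.
#' @export
mediation_fit <- function(trials, stimuli, textures = c("visc", "csf"),
                          n_bootstrap = 1000, seed = 1, conf = 0.95) {
  textures <- match.arg(textures, several.ok = TRUE)
  tex_terms <- paste0("d", textures)
  a_table <- texture_on_nutrients(stimuli)  # also validates identifiability
  des <- choice_design(trials, stimuli)
  base_terms <- c("dlogmag", "dfat", "dsugar")
  all_terms <- c(base_terms, tex_terms)
  Z <- as.matrix(des[all_terms])
  sds <- apply(Z, 2, stats::sd)
  if (any(sds < 1e-12)) {
    stop("constant regressor(s) after standardization: ",
         paste(all_terms[sds < 1e-12], collapse = ", "))
  }
  Z <- scale(Z)
  qr_rank <- qr(cbind(1, Z))$rank
  if (qr_rank < ncol(Z) + 1) {
    stop("perfect collinearity among standardized regressors: ",
         paste(all_terms, collapse = ", "))
  }
  y <- des$y
  sess <- factor(des$session_id)
  sess_rows <- split(seq_along(y), sess)

  path_summary <- function(ct, ca) {
    c(c_fat = unname(ct["dfat"]), c_sugar = unname(ct["dsugar"]),
      cp_fat = unname(ca["dfat"]), cp_sugar = unname(ca["dsugar"]),
      stats::setNames(unname(ca[tex_terms]), paste0("b_", textures)),
      ind_fat = unname(ct["dfat"] - ca["dfat"]),
      ind_sugar = unname(ct["dsugar"] - ca["dsugar"]))
  }
  fit_paths <- function(rows, start_t = NULL, start_a = NULL) {
    Xt <- cbind(1, Z[rows, base_terms, drop = FALSE])
    Xa <- cbind(1, Z[rows, all_terms, drop = FALSE])
    bt <- fit_logit_coef(Xt, y[rows], start = start_t)
    ba <- fit_logit_coef(Xa, y[rows], start = start_a)
    list(t = bt, a = ba,
         summary = path_summary(stats::setNames(bt[-1], base_terms),
                                stats::setNames(ba[-1], all_terms)))
  }
  full <- fit_paths(seq_along(y))
  point <- full$summary
  set.seed(seed)
  n_sess <- length(sess_rows)
  boot <- matrix(NA_real_, n_bootstrap, length(point),
                 dimnames = list(NULL, names(point)))
  for (b in seq_len(n_bootstrap)) {
    take <- sample.int(n_sess, replace = TRUE)
    rows <- unlist(sess_rows[take], use.names = FALSE)
    # full-data estimates warm-start the bootstrap refits
    boot[b, ] <- tryCatch(fit_paths(rows, full$t, full$a)$summary,
                          error = function(e) rep(NA_real_, length(point)))
  }
  alpha <- (1 - conf) / 2
  ci <- t(apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE))
  sig <- ci[, 1] > 0 | ci[, 2] < 0
  verdict <- vapply(c("fat", "sugar"), function(nu) {
    tot <- sig[paste0("c_", nu)]
    dir <- sig[paste0("cp_", nu)]
    ind <- sig[paste0("ind_", nu)]
    if (tot && !dir && ind) "complete" else
      if (tot && dir && ind) "partial" else "none"
  }, character(1))
  structure(list(
    paths = data.frame(path = names(point), estimate = unname(point),
                       ci_low = ci[, 1], ci_high = ci[, 2],
                       significant = unname(sig), row.names = NULL),
    a_table = a_table, verdict = verdict, textures = textures,
    n_bootstrap = n_bootstrap, conf = conf, n_sessions = n_sess,
    n_trials = length(y), bootstrap = boot
  ), class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf(
    "Texture mediation path model (%d trials, %d sessions, %d bootstrap)\n",
    x$n_trials, x$n_sessions, x$n_bootstrap))
  print(transform(x$paths, estimate = round(estimate, 3),
                  ci_low = round(ci_low, 3), ci_high = round(ci_high, 3)),
        row.names = FALSE)
  cat("Stimulus-level texture-on-fat slopes (path a):\n")
  af <- x$a_table[x$a_table$predictor == "fat", ]
  for (i in seq_len(nrow(af))) {
    cat(sprintf("  %s ~ fat: %.3f [%.3f, %.3f]\n", af$response[i],
                af$slope[i], af$ci_low[i], af$ci_high[i]))
  }
  cat("Mediation verdict: fat =", x$verdict["fat"],
      "| sugar =", x$verdict["sugar"], "\n")
  invisible(x)
}

#' @export
summary.path_model <- function(object, ...) object$paths
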
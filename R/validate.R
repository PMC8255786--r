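#' Out-of-sample validation of psychometric value estimates
#'
#' Expresses every offer in value equivalents of the low-nutrient reference
#' (magnitude times the stimulus's relative value, taken from its
#' psychometric indifference point), then checks by k-fold cross-validation
#' whether the log value difference predicts choices: a sigmoid is fitted on
#' the training folds and the adjusted R-squared is computed on held-out
#' choice frequencies over equal-count bins of the value difference.
#'
#' @param trials A [choice_trials()] table.
#' @param stimuli A [stimulus_table()].
#' @param fits Named list mapping non-reference stimulus ids to
#'   [psychometric_fit()] objects (or bare relative-value numbers).
#' @param reference Reference stimulus id (relative value 1).
#' @param k_folds Number of cross-validation folds (trials are assigned to
#'   folds at random under `seed`).
#' @param n_bins Equal-count bins of the value difference for the R-squared.
#' @param seed Fold-assignment seed.
#' @return List with `adjusted_R2`, the per-bin table (`bins`), and the
#'   per-fold sigmoid coefficients (`fold_curves`).
#' @export
value_transform_validate <- function(trials, stimuli, fits, reference,
                                     k_folds = 10, n_bins = 10, seed = 1) {
  n <- nrow(trials)
  if (n < k_folds) stop("fewer trials than folds")
  rho <- stats::setNames(rep(1, nrow(stimuli)), stimuli$id)
  for (id in names(fits)) {
    v <- fits[[id]]
    rho[id] <- if (inherits(v, "psychometric_fit")) v$indifference_point else v
  }
  if (!reference %in% stimuli$id) stop("unknown reference stimulus")
  x <- log(trials$mag_left * rho[trials$stim_left]) -
    log(trials$mag_right * rho[trials$stim_right])
  y <- as.integer(trials$choice == "left")
  set.seed(seed)
  fold <- sample(rep(seq_len(k_folds), length.out = n))
  pred <- numeric(n)
  curves <- matrix(NA_real_, k_folds, 2,
                   dimnames = list(NULL, c("intercept", "slope")))
  for (k in seq_len(k_folds)) {
    tr <- fold != k
    f <- fit_logit(cbind(1, x[tr]), y[tr])
    curves[k, ] <- f$coefficients
    pred[!tr] <- stats::plogis(f$coefficients[1] + f$coefficients[2] * x[!tr])
  }
  br <- unique(stats::quantile(x, seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(x, br, include.lowest = TRUE, labels = FALSE)
  bins <- data.frame(
    value_diff = as.numeric(tapply(x, bin, mean)),
    observed = as.numeric(tapply(y, bin, mean)),
    predicted = as.numeric(tapply(pred, bin, mean)),
    n = as.integer(tapply(y, bin, length))
  )
  nb <- nrow(bins)
  r2 <- 1 - sum((bins$observed - bins$predicted)^2) /
    sum((bins$observed - mean(bins$observed))^2)
  adj <- 1 - (1 - r2) * (nb - 1) / (nb - 3)
  list(adjusted_R2 = adj, bins = bins, fold_curves = curves)
}

#' Transitivity check of pairwise relative values
#'
#' For every stimulus triple with measured pairwise values, compares the
#' implied value of the long edge (product of the two short-edge values,
#' since relative values are multiplicative under consistent preferences)
#' with its measured value and CI.
#'
#' @param fits Data frame with one row per measured pair: columns
#'   `reference`, `target`, `value` and optionally `ci_low`, `ci_high`
#'   (e.g. assembled from [psychometric_fit()] objects).
#' @return Data frame with one row per connected triple: implied and
#'   measured values, their ratio, and whether the measured CI contains the
#'   implied value.
#' @export
transitivity_check <- function(fits) {
  if (inherits(fits, "psychometric_fit")) fits <- list(fits)
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- do.call(rbind, lapply(fits, function(f) {
      data.frame(reference = f$reference, target = f$target,
                 value = f$indifference_point,
                 ci_low = f$ci_low, ci_high = f$ci_high,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(fits$ci_low)) fits$ci_low <- NA_real_
  if (is.null(fits$ci_high)) fits$ci_high <- NA_real_
  # value of target measured in units of reference; invert for the reverse
  lookup <- function(ref, tgt) {
    i <- which(fits$reference == ref & fits$target == tgt)
    if (length(i)) return(c(v = fits$value[i[1]], row = i[1], inv = 0))
    i <- which(fits$reference == tgt & fits$target == ref)
    if (length(i)) return(c(v = 1 / fits$value[i[1]], row = i[1], inv = 1))
    NULL
  }
  ids <- unique(c(fits$reference, fits$target))
  if (length(ids) < 3) stop("transitivity needs a connected triple; missing pairs")
  triples <- utils::combn(sort(ids), 3)
  out <- NULL
  for (j in seq_len(ncol(triples))) {
    a <- triples[1, j]; b <- triples[2, j]; c3 <- triples[3, j]
    vab <- lookup(a, b); vbc <- lookup(b, c3); vac <- lookup(a, c3)
    if (is.null(vab) || is.null(vbc) || is.null(vac)) next
    implied <- unname(vab["v"] * vbc["v"])
    measured <- unname(vac["v"])
    row <- vac["row"]
    ci <- c(fits$ci_low[row], fits$ci_high[row])
    if (vac["inv"] == 1) ci <- sort(1 / ci)
    out <- rbind(out, data.frame(
      a = a, b = b, c = c3, implied = implied, measured = measured,
      ratio = implied / measured,
      within_ci = if (anyNA(ci)) NA else ci[1] <= implied & implied <= ci[2],
      stringsAsFactors = FALSE
    ))
  }
  if (is.null(out)) {
    stop("transitivity needs a connected triple; missing pairs among: ",
         paste(sort(ids), collapse = ", "))
  }
  out
}
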
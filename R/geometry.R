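#' Mixture-triangle coordinates of stimuli
#'
#' Geometric Framework for Nutrition coordinates: the percentage of total
#' energy contributed by fat, sugar and protein (Atwater factors 9/4/4).
#' The three percentages sum to 100; because protein is constant by design
#' in the factorial stimulus set, downstream geometry works in the
#' (fat%, sugar%) plane with protein implicit.
#'
#' @param stimuli A [stimulus_table()] (zero-energy stimuli are an error).
#' @return Data frame with columns `id`, `pct_fat`, `pct_sugar`,
#'   `pct_protein`.
#' @export
mixture_coordinates <- function(stimuli) {
  fk <- 9 * stimuli$fat
  sk <- 4 * stimuli$sugar
  pk <- 4 * stimuli$protein
  tot <- fk + sk + pk
  if (any(tot <= 0)) {
    stop("zero-energy stimulus: mixture coordinates undefined for ",
         paste(stimuli$id[tot <= 0], collapse = ", "))
  }
  data.frame(id = stimuli$id, pct_fat = 100 * fk / tot,
             pct_sugar = 100 * sk / tot, pct_protein = 100 * pk / tot,
             stringsAsFactors = FALSE)
}

#' Nutrient balance of a session's aggregated choices
#'
#' The energy-weighted composition of realized intake: a convex combination
#' of the offered stimuli's mixture coordinates with weights equal to each
#' stimulus's share of total energy intake. Computed both as the weighted
#' combination and directly from summed nutrient intakes; the two routes
#' are verified to agree.
#'
#' @param trials A single-session [choice_trials()] table.
#' @param stimuli A [stimulus_table()].
#' @return Named numeric vector (`pct_fat`, `pct_sugar`, `pct_protein`)
#'   with the per-stimulus energy-intake weights as attribute `"weights"`.
#' @export
choice_balance <- function(trials, stimuli) {
  idx <- ifelse(trials$choice == "left",
                match(trials$stim_left, stimuli$id),
                match(trials$stim_right, stimuli$id))
  mag <- ifelse(trials$choice == "left", trials$mag_left, trials$mag_right)
  energy <- mag * stimuli$energy_density[idx]
  if (sum(energy) <= 0) stop("zero energy intake: balance undefined")
  # route 1: summed nutrient intakes
  fat_k <- 9 * sum(mag * stimuli$fat[idx] / 100)
  sug_k <- 4 * sum(mag * stimuli$sugar[idx] / 100)
  pro_k <- 4 * sum(mag * stimuli$protein[idx] / 100)
  tot <- fat_k + sug_k + pro_k
  direct <- c(pct_fat = 100 * fat_k / tot, pct_sugar = 100 * sug_k / tot,
              pct_protein = 100 * pro_k / tot)
  # route 2: energy-weighted convex combination of stimulus compositions
  w <- tapply(energy, stimuli$id[idx], sum) / sum(energy)
  mix <- mixture_coordinates(stimuli[match(names(w), stimuli$id), ,
                                     drop = FALSE])
  combo <- colSums(as.numeric(w) *
                     as.matrix(mix[c("pct_fat", "pct_sugar", "pct_protein")]))
  if (max(abs(direct - combo)) > 1e-9) {
    stop("internal inconsistency between balance computation routes")
  }
  attr(direct, "weights") <- w
  direct
}

#' Project a dietary reference point onto the offer segment
#'
#' Orthogonal projection, in the (fat%, sugar%) energy plane, of a reference
#' composition onto the segment connecting the two offered stimuli —
#' the closest nutrient balance achievable by distributing choices between
#' the offers. The projection parameter is clamped to the segment.
#'
#' @param ref Named vector or list with `pct_fat`, `pct_sugar` (a reference
#'   composition, e.g. a recommended diet or milk).
#' @param stim_pair A two-row [stimulus_table()] (or its
#'   [mixture_coordinates()]).
#' @return List with `projected` (pct_fat/pct_sugar), `t` (position along
#'   the segment, 0 at the first stimulus), and `distance` (Euclidean
#'   residual in percentage-energy units).
#' @export
project_reference <- function(ref, stim_pair) {
  mp <- if (!is.null(stim_pair$pct_fat)) stim_pair else
    mixture_coordinates(stim_pair)
  if (nrow(mp) != 2) stop("stim_pair must contain exactly two stimuli")
  p1 <- c(mp$pct_fat[1], mp$pct_sugar[1])
  p2 <- c(mp$pct_fat[2], mp$pct_sugar[2])
  d <- p2 - p1
  if (sum(d^2) < 1e-12) stop("identical stimulus compositions: segment degenerate")
  r <- c(ref[["pct_fat"]], ref[["pct_sugar"]])
  t_raw <- sum((r - p1) * d) / sum(d^2)
  t <- min(max(t_raw, 0), 1)
  proj <- p1 + t * d
  list(projected = c(pct_fat = proj[1], pct_sugar = proj[2]), t = t,
       distance = sqrt(sum((r - proj)^2)))
}

#' 95% confidence ellipse of session nutrient balances
#'
#' Bivariate normal confidence ellipse for the mean balance in the
#' (fat%, sugar%) plane, at the chi-squared (2 df) quantile of the mean's
#' covariance (sample covariance divided by n).
#'
#' @param balances Data frame or matrix of session balances with columns
#'   `pct_fat`, `pct_sugar` (>= 3 rows).
#' @param level Coverage level.
#' @return Object of class `"balance_ellipse"`: `center`, semi-`axes`
#'   lengths, `orientation_deg` of the major axis, the mean-covariance
#'   matrix, and a `degenerate` flag for singular covariance.
#' @export
balance_ellipse <- function(balances, level = 0.95) {
  B <- as.matrix(as.data.frame(balances)[c("pct_fat", "pct_sugar")])
  n <- nrow(B)
  if (n < 3) stop("need >= 3 session balances")
  center <- colMeans(B)
  S <- stats::cov(B) / n
  e <- eigen(S, symmetric = TRUE)
  q <- stats::qchisq(level, df = 2)
  degenerate <- any(e$values < 1e-12 * max(e$values, 1e-300))
  structure(list(center = center, axes = sqrt(pmax(e$values, 0) * q),
                 orientation_deg = atan2(e$vectors[2, 1], e$vectors[1, 1]) *
                   180 / pi,
                 cov_mean = S, level = level, n = n,
                 degenerate = degenerate),
            class = "balance_ellipse")
}

#' @export
print.balance_ellipse <- function(x, ...) {
  cat(sprintf(
    "%.0f%% balance ellipse: center (%.2f, %.2f), semi-axes %.3f x %.3f, %s%.1f deg\n",
    100 * x$level, x$center[1], x$center[2], x$axes[1], x$axes[2],
    if (x$degenerate) "[degenerate] " else "", x$orientation_deg))
  invisible(x)
}

#' Does a balance ellipse contain a point?
#'
#' @param ellipse A [balance_ellipse()].
#' @param point Named vector with `pct_fat`, `pct_sugar`.
#' @return Logical.
#' @export
ellipse_contains <- function(ellipse, point) {
  p <- c(point[["pct_fat"]], point[["pct_sugar"]])
  d <- p - ellipse$center
  stats::mahalanobis(rbind(p), ellipse$center, ellipse$cov_mean) <=
    stats::qchisq(ellipse$level, df = 2)
}

#' Boundary points of a balance ellipse (for plotting)
#'
#' @param ellipse A [balance_ellipse()].
#' @param n Number of boundary points.
#' @return Matrix with columns `pct_fat`, `pct_sugar`.
#' @export
ellipse_points <- function(ellipse, n = 180) {
  th <- seq(0, 2 * pi, length.out = n)
  e <- eigen(ellipse$cov_mean, symmetric = TRUE)
  q <- sqrt(stats::qchisq(ellipse$level, 2))
  circ <- rbind(cos(th), sin(th)) * (q * sqrt(pmax(e$values, 0)))
  pts <- t(e$vectors %*% circ + ellipse$center)
  colnames(pts) <- c("pct_fat", "pct_sugar")
  pts
}

#' Signed deviation of nutrient balances from a projected reference
#'
#' Positions each balance and the projected reference along the offer
#' segment and reports the difference in percentage-energy units of the
#' varying nutrient (the nutrient whose energy share changes most along the
#' segment), with positive values toward the segment end richer in that
#' nutrient. A value of +20 means the agent obtained 20 percentage points
#' more energy from that nutrient than the closest achievable approximation
#' of the reference.
#'
#' @param balances Data frame of session balances (`pct_fat`, `pct_sugar`).
#' @param ref Reference composition (named `pct_fat`, `pct_sugar`).
#' @param stim_pair Two-row [stimulus_table()] or mixture coordinates.
#' @return Numeric vector of signed deviations; attributes `"nutrient"`
#'   (which axis varies) and `"t_ref"`.
#' @export
deviation_from_reference <- function(balances, ref, stim_pair) {
  mp <- if (!is.null(stim_pair$pct_fat)) stim_pair else
    mixture_coordinates(stim_pair)
  pr <- project_reference(ref, mp)
  d <- c(mp$pct_fat[2] - mp$pct_fat[1], mp$pct_sugar[2] - mp$pct_sugar[1])
  axis <- if (abs(d[1]) >= abs(d[2])) "pct_fat" else "pct_sugar"
  span <- if (axis == "pct_fat") d[1] else d[2]  # signed toward stimulus 2
  B <- as.data.frame(balances)
  t_bal <- vapply(seq_len(nrow(B)), function(i) {
    project_reference(B[i, ], mp)$t
  }, numeric(1))
  # multiplying by the signed span orients positive toward the segment end
  # richer in the varying nutrient, whichever stimulus that is
  dev <- (t_bal - pr$t) * span
  structure(dev, nutrient = axis, t_ref = pr$t)
}
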
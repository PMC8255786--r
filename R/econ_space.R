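#' Nutrient-composition matrix
#'
#' A 2 x 2 matrix whose columns give the fat and sugar content per unit of
#' each of two rewards; it maps bundles of rewards (goods space) into the
#' common fat-sugar nutrient space.
#'
#' @param m A 2 x 2 non-negative matrix (rows: fat, sugar; columns:
#'   rewards), or four values in column-major order.
#' @return Matrix of class `"composition_matrix"`.
#' @export
composition_matrix <- function(m) {
  m <- matrix(as.numeric(m), 2, 2)
  if (any(m < 0)) stop("composition entries must be non-negative")
  dimnames(m) <- list(c("fat", "sugar"), c("reward_1", "reward_2"))
  class(m) <- c("composition_matrix", "matrix", "array")
  m
}

#' Transform a reward bundle into nutrient space
#'
#' @param bundle Non-negative amounts of the two rewards (length-2 vector
#'   or a 2-column matrix of bundles).
#' @param m A [composition_matrix()].
#' @return Fat-sugar vector (or matrix, one row per bundle).
#' @export
bundle_to_nutrients <- function(bundle, m) {
  if (is.matrix(bundle)) {
    out <- bundle %*% t(unclass(m))
    colnames(out) <- c("fat", "sugar")
    out
  } else {
    stats::setNames(drop(unclass(m) %*% bundle), c("fat", "sugar"))
  }
}

#' Transform a nutrient profile into a (possibly new) reward space
#'
#' Inverts the target space's composition matrix. Profiles requiring a
#' negative amount of some reward are unreachable with non-negative bundles
#' and flagged.
#'
#' @param nutrients Fat-sugar vector.
#' @param m A [composition_matrix()] for the target reward space; must be
#'   invertible (collinear reward compositions are an error).
#' @param tol Tolerance below zero treated as reachable.
#' @return Bundle vector with attribute `"reachable"`.
#' @export
nutrients_to_bundle <- function(nutrients, m, tol = 1e-9) {
  if (abs(det(unclass(m))) < 1e-12) {
    stop("rewards nutritionally indistinguishable: composition matrix singular")
  }
  a <- drop(solve(unclass(m), nutrients))
  names(a) <- colnames(m)
  structure(a, reachable = all(a >= -tol))
}

#' Utility function over nutrient space
#'
#' Linear (\eqn{u = w_f f + w_s s}) or Cobb-Douglas
#' (\eqn{u = f^{w_f} s^{w_s}}) utility, both monotone increasing in both
#' nutrients.
#'
#' @param form `"linear"` or `"cobb_douglas"`.
#' @param w_fat,w_sugar Positive weights.
#' @return Function of class `"utility_fn"` taking (fat, sugar) or a
#'   2-column matrix.
#' @export
utility_fn <- function(form = c("linear", "cobb_douglas"), w_fat = 1,
                       w_sugar = 1) {
  form <- match.arg(form)
  if (w_fat <= 0 || w_sugar <= 0) stop("utility weights must be positive")
  f <- function(fat, sugar = NULL) {
    if (is.null(sugar)) {
      sugar <- fat[, 2]
      fat <- fat[, 1]
    }
    if (form == "linear") w_fat * fat + w_sugar * sugar else
      fat^w_fat * sugar^w_sugar
  }
  structure(f, form = form, w_fat = w_fat, w_sugar = w_sugar,
            class = c("utility_fn", "function"))
}

#' Preference-ranking preservation under reward-space transforms
#'
#' Maps bundles from reward space A-B through nutrient space into a second
#' reward space C-D and back, computing utilities in nutrient space at each
#' stage. Because utility is a function of the nutrient profile alone and
#' the transforms are exact inverses, the preference ranking is preserved;
#' this verifies it numerically and returns the ranking.
#'
#' @param bundles Matrix of bundles in the source space (one row each).
#' @param m Source-space [composition_matrix()].
#' @param m_new Target-space [composition_matrix()] (invertible).
#' @param u A [utility_fn()].
#' @return List with `preserved` (logical), `utilities` (source/target, one
#'   per bundle), `ranking` (order indices, best first) and the transformed
#'   bundles.
#' @export
ranking_preserved <- function(bundles, m, m_new, u) {
  bundles <- as.matrix(bundles)
  n <- bundle_to_nutrients(bundles, m)
  u_src <- u(n)
  new_bundles <- t(apply(n, 1, nutrients_to_bundle, m = m_new))
  n_back <- bundle_to_nutrients(new_bundles, m_new)
  u_tgt <- u(n_back)
  list(preserved = isTRUE(all.equal(rank(-u_src), rank(-u_tgt))) &&
         max(abs(u_src - u_tgt)) < 1e-8,
       utilities = cbind(source = u_src, target = u_tgt),
       ranking = order(u_src, decreasing = TRUE),
       transformed_bundles = new_bundles)
}

#' Indifference curves in nutrient or reward space
#'
#' Traces level sets of a nutrient-space utility function. Linear utilities
#' give straight parallel lines of slope \eqn{-w_f/w_s}; Cobb-Douglas
#' utilities give convex curves. Reward-space curves are the pullback of
#' the nutrient-space curves through the inverse composition matrix, and
#' points requiring negative reward amounts are dropped.
#'
#' @param u A [utility_fn()].
#' @param levels Positive utility levels, one curve each.
#' @param space `"nutrient"` or `"reward"`.
#' @param m Required [composition_matrix()] when `space = "reward"`.
#' @param fat_range Range of the fat coordinate to trace over.
#' @param n_points Points per curve.
#' @return Named list of data frames (one per level) with the curve
#'   coordinates (`fat`/`sugar`, plus `reward_1`/`reward_2` in reward
#'   space).
#' @export
indifference_curves <- function(u, levels, space = c("nutrient", "reward"),
                                m = NULL, fat_range = c(0.05, 10),
                                n_points = 200) {
  space <- match.arg(space)
  if (space == "reward") {
    if (is.null(m)) stop("reward-space curves need a composition matrix")
    if (abs(det(unclass(m))) < 1e-12) stop("composition matrix singular")
  }
  if (any(levels <= 0)) stop("utility levels must be positive")
  w_f <- attr(u, "w_fat")
  w_s <- attr(u, "w_sugar")
  form <- attr(u, "form")
  fat <- seq(fat_range[1], fat_range[2], length.out = n_points)
  out <- lapply(levels, function(lv) {
    sugar <- if (form == "linear") (lv - w_f * fat) / w_s else
      (lv / fat^w_f)^(1 / w_s)
    keep <- is.finite(sugar) & sugar >= 0
    df <- data.frame(fat = fat[keep], sugar = sugar[keep], level = lv)
    if (space == "reward" && nrow(df)) {
      a <- t(solve(unclass(m), t(as.matrix(df[c("fat", "sugar")]))))
      df$reward_1 <- a[, 1]
      df$reward_2 <- a[, 2]
      df <- df[df$reward_1 >= 0 & df$reward_2 >= 0, , drop = FALSE]
    }
    df
  })
  names(out) <- paste0("level_", signif(levels, 6))
  out
}
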
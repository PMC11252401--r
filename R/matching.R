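#' Rank-based gaussianization of a spatial map
#'
#' Maps the empirical distribution of a map onto standard-normal quantiles:
#' value `i` with (average, tie-shared) rank `r_i` among `n` becomes
#' `qnorm((r_i - 0.5) / n)`. Monotone in the input and idempotent up to tie
#' handling.
#'
#' @param map Numeric vector (>= 3 values, non-constant).
#' @return Gaussianized vector of the same length.
#' @export
quantile_gaussianize <- function(map) {
  if (length(map) < 3L) stop_invalid("need at least 3 values")
  if (stats::sd(map) == 0) stop_invalid("constant map cannot be gaussianized")
  r <- rank(map, ties.method = "average")
  stats::qnorm((r - 0.5) / length(map))
}

#' LASSO feature selection among candidate gradient maps
#'
#' L1-penalized least squares of a target map on a set of candidate maps
#' (coordinate descent via glmnet), with standardized inputs and an
#' intercept. The penalty is on the scale of scikit-learn's `Lasso(alpha)`:
#' the objective is `(1/2n) RSS + penalty * ||b||_1`.
#'
#' @param target Numeric target map (gaussianize first; see
#'   [quantile_gaussianize()]).
#' @param candidates Matrix (items x candidates) or list of candidate maps.
#' @param penalty L1 penalty (default 0.1).
#' @return Named numeric vector of per-candidate coefficients (sparse:
#'   most are exactly zero at the default penalty).
#' @export
lasso_select <- function(target, candidates, penalty = 0.1) {
  X <- if (is.list(candidates)) do.call(cbind, candidates) else candidates
  stopifnot(is.matrix(X), nrow(X) == length(target))
  if (ncol(X) < 1L) stop_invalid("need at least one candidate")
  penalty <- check_scalar(penalty, "penalty", lower = 0)
  if (is.null(colnames(X))) colnames(X) <- paste0("candidate", seq_len(ncol(X)))
  # fit along a short decreasing path ending at the requested penalty;
  # warm starts make coordinate descent reliable at small penalties
  lam <- sort(unique(penalty * c(64, 16, 4, 1)), decreasing = TRUE)
  if (penalty == 0) lam <- c(lam[lam > 0], 1e-10)
  fit <- glmnet::glmnet(X, target, family = "gaussian", alpha = 1,
                        lambda = lam, standardize = TRUE, intercept = TRUE,
                        thresh = 1e-12, maxit = 1e6)
  co <- as.numeric(stats::coef(fit, s = min(lam)))[-1L]
  names(co) <- colnames(X)
  co
}

#' Univariate OLS goodness of fit between two maps
#'
#' @param target,candidate Numeric maps of equal length; the candidate must
#'   not be constant.
#' @return List with `coefficient` (slope with intercept) and `r2`
#'   (squared Pearson correlation).
#' @export
ols_fit <- function(target, candidate) {
  stopifnot(length(target) == length(candidate))
  if (stats::sd(candidate) == 0) stop_invalid("constant candidate map")
  fit <- stats::lm.fit(cbind(1, candidate), target)
  list(coefficient = unname(fit$coefficients[2L]),
       r2 = stats::cor(target, candidate)^2)
}

# A uniform random proper rotation in SO(3): QR of a Gaussian matrix with
# the sign of R's diagonal fixed, then determinant forced to +1.
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

#' Spin test for the correlation of two spherical maps
#'
#' Builds a spatial-autocorrelation-preserving null by applying uniform
#' random 3D rotations to the sphere coordinates of `map_b`, re-assigning
#' values by nearest rotated neighbour, and recomputing the Pearson
#' correlation with `map_a`. Two-sided p-value
#' `(1 + #{|r_null| >= |r_obs|}) / (n_perm + 1)`.
#'
#' @param map_a,map_b Aligned numeric maps.
#' @param sphere_coords Unit-sphere coordinates (items x 3) shared by both
#'   maps.
#' @param n_perm Number of rotations (>= 1; 1000 is conventional).
#' @param seed Integer seed for the rotation sample.
#' @return List with `p`, `r_obs`, `r_null` (length `n_perm`).
#' @export
spin_test <- function(map_a, map_b, sphere_coords, n_perm = 1000, seed = 1L) {
  stopifnot(length(map_a) == length(map_b),
            is.matrix(sphere_coords),
            nrow(sphere_coords) == length(map_a), ncol(sphere_coords) == 3L)
  n_perm <- check_count(n_perm, "n_perm")
  if (nrow(unique(round(sphere_coords, 12))) < 2L) {
    stop_invalid("degenerate sphere coordinates (all coincident)")
  }
  r_obs <- stats::cor(map_a, map_b)
  r_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      rot <- sphere_coords %*% t(random_rotation())
      # nearest rotated point = largest dot product on the unit sphere
      idx <- max.col(tcrossprod(sphere_coords, rot), ties.method = "first")
      stats::cor(map_a, map_b[idx])
    }, numeric(1L))
  })
  list(p = (1 + sum(abs(r_null) >= abs(r_obs))) / (n_perm + 1),
       r_obs = r_obs, r_null = r_null)
}

suprathreshold_mask <- function(map, q) {
  map > stats::quantile(map, q)   # ties at the quantile excluded
}

#' Dice overlap of two maps binarized at a common quantile
#'
#' Each map is binarized at its own `q`-quantile (strictly greater-than);
#' Dice = `2 |A & B| / (|A| + |B|)`.
#'
#' @param map_a,map_b Numeric maps of equal length.
#' @param q Quantile in `[0, 1)`.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_at_quantile <- function(map_a, map_b, q) {
  stopifnot(length(map_a) == length(map_b))
  q <- check_scalar(q, "q", lower = 0, upper = 1 - 1e-12)
  A <- suprathreshold_mask(map_a, q)
  B <- suprathreshold_mask(map_b, q)
  if (!any(A) || !any(B)) {
    warning("empty suprathreshold set; dice = 0", call. = FALSE)
    return(0)
  }
  2 * sum(A & B) / (sum(A) + sum(B))
}

#' Threshold-Dice combination analysis of candidate maps
#'
#' For every singleton, pair, and triplet of candidate maps, combines the
#' candidates' suprathreshold masks by union and computes the Dice overlap
#' with the target's suprathreshold mask, over a grid of quantile
#' thresholds. Reports the arg-max set, threshold, and Dice.
#'
#' @param target Numeric target map.
#' @param candidates Matrix (items x candidates, >= 2) or list of maps.
#' @param q_grid Quantile thresholds (default 0.70 to 0.95 by 0.05).
#' @return List with `table` (data frame: set, q, dice) and `best`
#'   (set, q, dice of the maximum).
#' @export
best_map_combination <- function(target, candidates,
                                 q_grid = seq(0.70, 0.95, by = 0.05)) {
  X <- if (is.list(candidates)) do.call(cbind, candidates) else candidates
  stopifnot(is.matrix(X), nrow(X) == length(target))
  if (ncol(X) < 2L) stop_invalid("need at least 2 candidates")
  if (is.null(colnames(X))) colnames(X) <- paste0("candidate", seq_len(ncol(X)))
  p <- ncol(X)
  sets <- list()
  for (size in 1:min(3L, p)) {
    sets <- c(sets, utils::combn(p, size, simplify = FALSE))
  }
  rows <- vector("list", length(sets) * length(q_grid))
  k <- 0L
  for (q in q_grid) {
    tmask <- suprathreshold_mask(target, q)
    cmasks <- apply(X, 2L, suprathreshold_mask, q = q)
    for (s in sets) {
      union_mask <- rowSums(cmasks[, s, drop = FALSE]) > 0
      dice <- if (!any(tmask) || !any(union_mask)) 0 else {
        2 * sum(tmask & union_mask) / (sum(tmask) + sum(union_mask))
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        set = paste(colnames(X)[s], collapse = "+"),
        size = length(s), q = q, dice = dice,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  best <- tab[which.max(tab$dice), ]
  list(table = tab,
       best = list(set = best$set, q = best$q, dice = best$dice))
}

#' Match a target gradient map against candidate cortical gradients
#'
#' The full matching report: gaussianize target and candidates, LASSO
#' feature selection, per-candidate univariate OLS fits, spin-test
#' significance with Bonferroni correction across candidates, and the
#' threshold-Dice combination analysis.
#'
#' @param target Target map (e.g. one species' side of the joint
#'   cross-species gradient).
#' @param candidates Matrix (items x candidates) of cortical gradient maps.
#' @param sphere_coords Unit-sphere parcel coordinates for the spin test,
#'   or `NULL` to skip significance testing.
#' @param penalty LASSO penalty (default 0.1).
#' @param n_perm Spin-test permutations (default 1000).
#' @param q_grid Dice threshold grid.
#' @param seed Seed for the spin test.
#' @return A `match_report`: `candidates` (data frame with lasso_coef,
#'   ols_coef, r2, p_spin, p_corrected), `dice` table, `best_set`.
#' @export
match_gradient_maps <- function(target, candidates, sphere_coords = NULL,
                                penalty = 0.1, n_perm = 1000,
                                q_grid = seq(0.70, 0.95, by = 0.05),
                                seed = 1L) {
  X <- if (is.list(candidates)) do.call(cbind, candidates) else candidates
  stopifnot(is.matrix(X), nrow(X) == length(target))
  if (is.null(colnames(X))) colnames(X) <- paste0("candidate", seq_len(ncol(X)))
  tg <- quantile_gaussianize(target)
  Xg <- apply(X, 2L, quantile_gaussianize)
  lasso <- lasso_select(tg, Xg, penalty = penalty)
  ols <- lapply(seq_len(ncol(Xg)), function(j) ols_fit(tg, Xg[, j]))
  p_spin <- rep(NA_real_, ncol(Xg))
  if (!is.null(sphere_coords)) {
    p_spin <- vapply(seq_len(ncol(Xg)), function(j) {
      spin_test(tg, Xg[, j], sphere_coords, n_perm = n_perm,
                seed = seed + j)$p
    }, numeric(1L))
  }
  cand <- data.frame(
    candidate = colnames(X),
    lasso_coef = unname(lasso),
    ols_coef = vapply(ols, `[[`, numeric(1L), "coefficient"),
    r2 = vapply(ols, `[[`, numeric(1L), "r2"),
    p_spin = p_spin,
    p_corrected = pmin(1, p_spin * ncol(Xg)),   # Bonferroni
    stringsAsFactors = FALSE
  )
  combo <- best_map_combination(tg, Xg, q_grid = q_grid)
  structure(
    list(candidates = cand, dice = combo$table, best_set = combo$best,
         settings = list(penalty = penalty, n_perm = n_perm, q_grid = q_grid,
                         correction = "bonferroni",
                         combination_rule = "mask-union")),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat("<match_report>\n")
  ord <- order(-x$candidates$r2)
  print(x$candidates[ord, ], row.names = FALSE, digits = 3)
  cat(sprintf("best combination: %s at q = %.2f (Dice = %.3f)\n",
              x$best_set$set, x$best_set$q, x$best_set$dice))
  invisible(x)
}
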
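test_that("quantile gaussianization is monotone, idempotent and normalizing", {
  set.seed(16)
  x <- rnorm(50)^3
  g <- quantile_gaussianize(x)
  expect_equal(rank(g), rank(x))
  expect_equal(quantile_gaussianize(g), g, tolerance = 1e-12)

  big <- quantile_gaussianize(rexp(10000))
  ks <- suppressWarnings(ks.test(big, pnorm))
  expect_lt(unname(ks$statistic), 0.01)

  expect_error(quantile_gaussianize(rep(1, 10)),
               class = "hippograd_invalid_argument")
  expect_error(quantile_gaussianize(c(1, 2)),
               class = "hippograd_invalid_argument")
})

test_that("lasso selects an exactly matching candidate and kills noise", {
  set.seed(17)
  X <- scale(matrix(rnorm(1000 * 10), 1000, 10))
  y <- X[, 3]
  co <- lasso_select(y, X, penalty = 0.1)
  expect_true(co[3] != 0)
  expect_true(all(co[-3] == 0))

  y_noise <- rnorm(1000)
  co0 <- lasso_select(y_noise, X, penalty = 0.1)
  expect_true(all(co0 == 0))
})

test_that("lasso approaches multivariate OLS as the penalty vanishes", {
  set.seed(18)
  X <- scale(matrix(rnorm(500 * 4), 500, 4))
  y <- drop(X %*% c(0.5, -0.3, 0, 0.8)) + rnorm(500, sd = 0.3)
  co <- lasso_select(y, X, penalty = 1e-6)
  ols <- unname(coef(lm(y ~ X))[-1])
  expect_equal(unname(co), ols, tolerance = 1e-4)
})

test_that("lasso coefficients shrink monotonically with the penalty", {
  set.seed(19)
  X <- scale(matrix(rnorm(400 * 5), 400, 5))
  y <- drop(X %*% c(1, 0.5, 0.2, 0, 0)) + rnorm(400, sd = 0.5)
  pens <- c(0.01, 0.05, 0.1, 0.3)
  norms <- vapply(pens, function(p) sum(abs(lasso_select(y, X, p))),
                  numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("univariate OLS returns slope and squared correlation", {
  set.seed(20)
  x <- rnorm(100)
  f <- ols_fit(2 * x + 1, x)
  expect_equal(f$coefficient, 2)
  expect_equal(f$r2, 1)

  f2 <- ols_fit(-x, x)
  expect_equal(f2$coefficient, -1)
  expect_equal(f2$r2, 1)

  big <- ols_fit(rnorm(1e5), rnorm(1e5))
  expect_lt(big$r2, 0.001)

  expect_error(ols_fit(x, rep(1, 100)), class = "hippograd_invalid_argument")
})

test_that("spin test counts rotated nulls with the add-one formula", {
  set.seed(21)
  cx <- make_cortex(80, 4, "a")
  m <- random_smooth_sphere_map(cx$sphere_coords)
  st <- spin_test(m, m, cx$sphere_coords, n_perm = 19, seed = 1)
  # a self-match beats every rotated null: p = 1/20
  expect_equal(st$p, 1 / 20)
  expect_equal(st$r_obs, 1)

  st2 <- spin_test(m, m, cx$sphere_coords, n_perm = 200, seed = 2)
  expect_lte(st2$p, 0.05)

  expect_error(spin_test(m, m, matrix(1, 80, 3), n_perm = 5),
               class = "hippograd_invalid_argument")
})

test_that("dice at quantile matches hand enumeration", {
  a <- c(1, 2, 3, 4)
  b <- c(4, 3, 2, 1)
  expect_equal(dice_at_quantile(a, b, 0.5), 0)
  expect_equal(dice_at_quantile(a, a, 0.5), 1)

  set.seed(22)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(dice_at_quantile(x, y, 0.7), dice_at_quantile(y, x, 0.7))

  expect_warning(d0 <- dice_at_quantile(rep(1, 5), rep(1, 5), 0.5), "empty")
  expect_equal(d0, 0)
})

test_that("map-combination search equals a brute-force subset loop", {
  set.seed(23)
  n <- 200
  X <- matrix(rnorm(n * 4), n, 4)
  target <- rnorm(n)
  q_grid <- c(0.7, 0.8)
  got <- best_map_combination(target, X, q_grid = q_grid)

  brute_best <- -Inf
  masks <- apply(X, 2, function(col) col)
  for (q in q_grid) {
    tm <- target > quantile(target, q)
    cm <- apply(X, 2, function(col) col > quantile(col, q))
    for (size in 1:3) {
      for (s in combn(4, size, simplify = FALSE)) {
        um <- rowSums(cm[, s, drop = FALSE]) > 0
        d <- 2 * sum(tm & um) / (sum(tm) + sum(um))
        brute_best <- max(brute_best, d)
      }
    }
  }
  expect_equal(got$best$dice, brute_best)
  expect_equal(nrow(got$table), length(q_grid) * (4 + 6 + 4))
})

test_that("a union-structured target is matched by the generating pair", {
  set.seed(24)
  n <- 400
  X <- matrix(rnorm(n * 4), n, 4)
  # target whose suprathreshold support is the union of candidates 2 and 3
  target <- pmax(X[, 2], X[, 3])
  got <- best_map_combination(target, X, q_grid = 0.75)
  expect_equal(got$best$set, "candidate2+candidate3")

  self <- best_map_combination(X[, 1], X, q_grid = c(0.7, 0.9))
  expect_equal(self$best$set, "candidate1")
  expect_equal(self$best$dice, 1)
})

test_that("the full match report ranks the true generating candidate first", {
  set.seed(25)
  cx <- make_cortex(150, 5, "a")
  cands <- sapply(1:5, function(i) random_smooth_sphere_map(cx$sphere_coords))
  target <- cands[, 2] + rnorm(150, sd = 0.1)
  rep <- match_gradient_maps(target, cands, sphere_coords = cx$sphere_coords,
                             n_perm = 99, seed = 3)
  expect_equal(which.max(rep$candidates$r2), 2L)
  expect_true(rep$candidates$lasso_coef[2] > 0)
  expect_lt(rep$candidates$p_corrected[2], 0.2)
  expect_true(all(rep$candidates$p_spin > 0 & rep$candidates$p_spin <= 1))
})
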
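test_that("global-mean regression removes the mean series exactly", {
  m <- matrix(rep(rnorm(20), each = 5), 5, 20, byrow = FALSE)
  m_same <- matrix(rnorm(20), 5, 20, byrow = TRUE)  # identical rows
  expect_lt(max(abs(regress_global_mean(m_same))), 1e-12)

  set.seed(42)
  r <- matrix(rnorm(100), 5, 20)
  res <- regress_global_mean(r)
  g <- colMeans(r)
  expect_true(all(abs(apply(res, 1, function(row) cor(row, g))) < 1e-10))

  # idempotence (the residual mean series is numerically null, so the
  # second pass reduces to the intercept-only branch)
  expect_lt(max(abs(suppressWarnings(regress_global_mean(res)) - res)), 1e-10)

  # a zero-mean row already orthogonal to the mean series is untouched
  orth <- res[1, ] - mean(res[1, ])
  m2 <- rbind(orth, r[2:5, ])
  expect_lt(max(abs(regress_global_mean(m2)[1, ] - orth)), 1e-12)

  expect_warning(regress_global_mean(matrix(1, 3, 5)), "constant")
})

test_that("parcellation averages member vertices in ascending label order", {
  m <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  expect_equal(parcellate_timeseries(m, c(1L, 1L)), matrix(c(2, 3), 1))

  set.seed(1)
  v <- matrix(rnorm(40), 4, 10)
  perm <- parcellate_timeseries(v, c(3L, 1L, 4L, 2L))
  expect_equal(perm, v[c(2L, 4L, 1L, 3L), ], ignore_attr = TRUE)

  dup <- parcellate_timeseries(v[c(1, 1), ], c(5L, 5L))
  expect_equal(dup, v[1, , drop = FALSE], ignore_attr = TRUE)

  expect_error(parcellate_timeseries(v, c(1L, 1L, 3L, 3L)), "empty parcel.*2")
})

test_that("fisher z is the clipped arctanh", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_true(is.finite(fisher_z(1)))
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1.2), class = "hippograd_invalid_argument")
})

test_that("connectivity matrices are Fisher-z correlations", {
  a <- matrix(c(1, 2, 3, 2, 4, 6), 2, 3, byrow = TRUE)
  cm <- connectivity_matrix(a[1, , drop = FALSE], a[2, , drop = FALSE])
  expect_equal(cm$values[1, 1], atanh(1 - 1e-7))

  b <- matrix(c(1, 2, 3, 3, 2, 1), 2, 3, byrow = TRUE)
  cm2 <- connectivity_matrix(b[1, , drop = FALSE], b[2, , drop = FALSE])
  expect_equal(cm2$values[1, 1], atanh(-1 + 1e-7))

  set.seed(2)
  m <- matrix(rnorm(30), 3, 10)
  sq <- connectivity_matrix(m, m)
  expect_equal(sq$values, t(sq$values))
  expect_equal(sq$values[1, 2], fisher_z(cor(m[1, ], m[2, ])))

  # permutation equivariance
  p <- c(3L, 1L, 2L)
  sq_p <- connectivity_matrix(m[p, ], m[p, ])
  expect_equal(sq_p$values, sq$values[p, p])

  degenerate <- rbind(m[1:2, ], 0)
  expect_warning(cm3 <- connectivity_matrix(degenerate, degenerate),
                 "zero-variance")
  expect_true(all(cm3$values[3, ] == 0) && all(cm3$values[, 3] == 0))
})

test_that("group averaging is the element-wise mean after Fisher z", {
  set.seed(3)
  mats <- lapply(1:3, function(i) {
    connectivity_matrix(matrix(rnorm(40), 4, 10), matrix(rnorm(50), 5, 10))
  })
  avg <- group_average(mats)
  brute <- (mats[[1]]$values + mats[[2]]$values + mats[[3]]$values) / 3
  expect_equal(avg$values, brute)
  expect_equal(avg$averaged_over, 3L)

  expect_equal(group_average(mats[1])$values, mats[[1]]$values)

  neg <- mats[[1]]
  neg$values <- -neg$values
  expect_true(all(group_average(list(mats[[1]], neg))$values == 0))

  expect_error(group_average(list()), class = "hippograd_invalid_argument")
})

test_that("max connectivity map is the column-wise maximum", {
  set.seed(4)
  v <- matrix(rnorm(20 * 50), 20, 50)
  dense <- hippograd:::new_connectivity_matrix(v, "hippocampal-vertex", "cortical-vertex")
  expect_equal(max_connectivity_map(dense), apply(v, 2, max))

  single <- hippograd:::new_connectivity_matrix(v[1, , drop = FALSE],
                                                "hippocampal-vertex", "cortical-vertex")
  expect_equal(max_connectivity_map(single), v[1, ])

  col <- hippograd:::new_connectivity_matrix(matrix(c(0.1, -0.5, 0.3), 3, 1),
                                             "hippocampal-vertex", "cortical-vertex")
  expect_equal(max_connectivity_map(col), 0.3)

  wrong <- hippograd:::new_connectivity_matrix(v, "cortical-parcel", "cortical-parcel")
  expect_error(max_connectivity_map(wrong), class = "hippograd_invalid_argument")
})

test_that("sector connectivity splits the flatmap into quadrants", {
  g <- make_flatmap_grid(2, 2)
  set.seed(5)
  h <- matrix(rnorm(4 * 30), 4, 30)
  x <- matrix(rnorm(6 * 30), 6, 30)
  sec <- sector_connectivity(h, x, g)
  # each sector is a single vertex: rows equal per-vertex connectivity
  per_vertex <- connectivity_matrix(h, x)$values
  expect_equal(unname(sec["anterior-distal", ]), per_vertex[3, ])
  expect_equal(unname(sec["posterior-proximal", ]), per_vertex[2, ])

  h_same <- matrix(rep(rnorm(30), each = 4), 4, 30)
  sec2 <- sector_connectivity(h_same, x, g)
  expect_true(all(apply(sec2, 2, function(col) max(col) - min(col)) < 1e-12))
})

test_that("anterior sectors track the anterior-coupled network", {
  sim <- small_sim(seed = 6, n_subjects = 2)
  grid <- sim$a$grid
  sub <- sim$a$subjects[[1]]
  sec <- sector_connectivity(sub$hippo$values, sub$cortex$values, grid)
  # the divergent network is the most anterior-coupled by construction
  ant_net <- sim$a$ground_truth$divergent_network
  parcels <- which(sim$a$cortex$network_label == ant_net)
  ant <- mean(sec[c("anterior-distal", "anterior-proximal"), parcels])
  post <- mean(sec[c("posterior-distal", "posterior-proximal"), parcels])
  expect_gt(ant, post)
})

test_that("tSNR is mean over sample SD with invalid flagging", {
  r <- tsnr_map(matrix(c(9, 11), 1, 2))
  expect_equal(r$tsnr, 10 / sqrt(2))

  flat <- tsnr_map(matrix(5, 1, 3))
  expect_false(flat$valid)

  set.seed(6)
  row <- matrix(rnorm(20, mean = 4), 1, 20)
  expect_equal(tsnr_map(3 * row)$tsnr, tsnr_map(row)$tsnr)
})
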
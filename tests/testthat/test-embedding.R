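test_that("normalized-angle affinity matches its closed forms", {
  M <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0))
  S <- normalized_angle_affinity(M, sparsity = 0)$values
  expect_equal(S[1, 2], 1)            # identical rows
  expect_identical(S[1, 3], 0.5)      # orthogonal rows, exact
  expect_equal(S[1, 4], 0)            # opposite rows
  expect_true(all(S >= 0 & S <= 1))
  expect_equal(S, t(S))
  expect_equal(diag(S), rep(1, 4))
})

test_that("affinity sparsification keeps the top fraction per row", {
  set.seed(7)
  M <- matrix(runif(5 * 20), 5, 20)
  S0 <- normalized_angle_affinity(M, sparsity = 0)$values
  S9 <- normalized_angle_affinity(M, sparsity = 0.9)$values
  expect_false(isTRUE(all.equal(S0, S9)))
  expect_error(normalized_angle_affinity(rbind(M, 0), sparsity = 0),
               "zero row")
})

test_that("diffusion embedding matches an independent dense oracle", {
  set.seed(8)
  for (n in c(12, 25, 50)) {
    S <- random_affinity(n)
    g <- diffusion_map_embed(S, n_components = 3)
    o <- oracle_diffusion(S, 3)
    expect_equal(g$eigenvalues, o$values, tolerance = 1e-8)
    for (j in 1:3) {
      expect_gt(abs(cor(g$components[, j], o$vectors[, j])), 0.999)
    }
  }
})

test_that("first component separates a two-block affinity", {
  blocks <- matrix(0.01, 20, 20)
  blocks[1:10, 1:10] <- 1
  blocks[11:20, 11:20] <- 1
  diag(blocks) <- 1
  g <- diffusion_map_embed(blocks, n_components = 2)
  signs <- sign(g$components[, 1])
  expect_true(all(signs[1:10] == signs[1]) && all(signs[11:20] == -signs[1]))
})

test_that("embedding is equivariant under item permutation", {
  set.seed(9)
  S <- random_affinity(15)
  p <- sample(15)
  g <- diffusion_map_embed(S, n_components = 3)
  gp <- diffusion_map_embed(S[p, p], n_components = 3)
  expect_equal(gp$components, g$components[p, ], tolerance = 1e-8)
})

test_that("embedding eigenvalues are below 1 and components pi-orthogonal", {
  set.seed(10)
  S <- random_affinity(30)
  g <- diffusion_map_embed(S, n_components = 4, alpha = 0.5)
  expect_true(all(g$eigenvalues < 1))
  expect_true(all(diff(g$eigenvalues) <= 1e-12))
  # orthogonality under the stationary measure of the transition matrix
  d <- rowSums(S)
  W <- S / outer(sqrt(d), sqrt(d))
  dw <- rowSums(W)
  G <- t(g$components) %*% diag(dw) %*% g$components
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(abs(diag(G))), 1e-6)
})

test_that("disconnected affinity graphs are rejected with component sizes", {
  S <- diag(6)
  S[1:3, 1:3] <- 0.9
  S[4:6, 4:6] <- 0.9
  diag(S) <- 1
  expect_error(diffusion_map_embed(S, 2), "component sizes: 3, 3")
})

test_that("dense and iterative eigensolver routes agree", {
  set.seed(11)
  S <- random_affinity(120)
  dense <- diffusion_map_embed(S, n_components = 3, dense_cutoff = 2000L)
  iter <- diffusion_map_embed(S, n_components = 3, dense_cutoff = 50L)
  expect_equal(iter$eigenvalues, dense$eigenvalues, tolerance = 1e-8)
  expect_equal(iter$components, dense$components, tolerance = 1e-6)
})

test_that("hippocampal gradients are scale invariant and reject degenerate input", {
  set.seed(12)
  C <- matrix(rnorm(40 * 15), 40, 15)
  g1 <- hippocampal_gradients(C, 3, sparsity = 0)
  g2 <- hippocampal_gradients(2 * C, 3, sparsity = 0)
  expect_equal(g1$components, g2$components, tolerance = 1e-9)

  same_rows <- matrix(rep(rnorm(15), each = 40), 40, 15)
  expect_error(hippocampal_gradients(same_rows, 3), "degenerate affinity")
})

test_that("joint embedding satisfies the species-duplication identity", {
  set.seed(13)
  C <- matrix(rnorm(30 * 25), 30, 25)
  j <- joint_cross_species_embed(C, C, n_components = 3, sparsity = 0)
  expect_equal(j$a, j$b, tolerance = 1e-8)

  expect_error(joint_cross_species_embed(C, C[-1, ], 3),
               class = "hippograd_invalid_argument")
})

test_that("joint embedding aligns exchangeable species and flags divergence", {
  sim0 <- small_sim(seed = 14, divergence = 0, n_subjects = 4,
                    n_timepoints = 300, n_parcels = 80)
  C_a <- species_connectivity(sim0$a)
  C_b <- species_connectivity(sim0$b)
  j0 <- joint_cross_species_embed(C_a, C_b, n_components = 3)
  expect_gt(abs(cor(j0$a[, 1], j0$b[, 1])), 0.95)

  sim8 <- small_sim(seed = 14, divergence = 0.8, n_subjects = 4,
                    n_timepoints = 300, n_parcels = 80)
  C_a8 <- species_connectivity(sim8$a)
  C_b8 <- species_connectivity(sim8$b)
  j8 <- joint_cross_species_embed(C_a8, C_b8, n_components = 3)
  gap <- tapply(abs(j8$a[, 1] - j8$b[, 1]),
                sim8$a$cortex$network_label, mean)
  expect_equal(unname(which.max(gap)),
               sim8$a$ground_truth$divergent_network)
})

test_that("cortico-cortical gradients separate planted networks", {
  sim <- small_sim(seed = 15, noise_sd = 0.05, n_subjects = 2,
                   n_timepoints = 200, n_parcels = 40, n_networks = 3)
  ts_list <- lapply(sim$a$subjects, `[[`, "cortex")
  g <- corticocortical_gradients(ts_list, n_components = 3)
  labs <- sim$a$cortex$network_label
  # between-network separation on the leading components exceeds the
  # within-network spread
  spread <- mean(tapply(g$components[, 1], labs, sd))
  separation <- sd(tapply(g$components[, 1], labs, mean))
  expect_gt(separation, spread)

  single <- corticocortical_gradients(ts_list[1], n_components = 3)
  duplicated_group <- corticocortical_gradients(ts_list[c(1, 1, 1)],
                                                n_components = 3)
  expect_equal(single$components, duplicated_group$components,
               tolerance = 1e-10)
})
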
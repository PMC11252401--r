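# Shared fixtures and independent oracles used across test files.

# A random symmetric affinity with unit diagonal, entries in (0, 1); always
# connected because all entries are strictly positive.
random_affinity <- function(n) {
  R <- matrix(stats::runif(n * n, 0.01, 1), n, n)
  S <- (R + t(R)) / 2
  diag(S) <- 1
  S
}

# Independent diffusion-map oracle: build the alpha-normalized transition
# matrix explicitly and take the (non-symmetric) dense eigendecomposition.
# This is a separate route from the package's symmetric-conjugate solver.
oracle_diffusion <- function(S, k, alpha = 0.5) {
  d <- rowSums(S)
  W <- S / outer(d^alpha, d^alpha)
  P <- W / rowSums(W)
  e <- eigen(P)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values)[ord]
  vecs <- Re(e$vectors)[, ord, drop = FALSE]
  list(values = vals[2:(k + 1)], vectors = vecs[, 2:(k + 1), drop = FALSE])
}

# A smooth random map on the sphere: mixture of Gaussian kernels around
# random centres (spatially autocorrelated, as a cortical map would be).
random_smooth_sphere_map <- function(coords, n_centers = 6, bw = 0.8) {
  centers <- matrix(stats::rnorm(n_centers * 3), n_centers)
  centers <- centers / sqrt(rowSums(centers^2))
  w <- stats::rnorm(n_centers)
  D <- acos(pmin(pmax(tcrossprod(coords, centers), -1), 1))
  drop(exp(-D^2 / (2 * bw^2)) %*% w)
}

# Small default-structure two-species simulation for fast tests.
small_sim <- function(seed = 1L, divergence = 0.8, n_subjects = 3,
                      n_timepoints = 150, n_parcels = 60, n_networks = 4,
                      grid = make_flatmap_grid(8L, 4L), ...) {
  ca <- make_cortex(n_parcels, n_networks, "speciesA")
  cb <- make_cortex(n_parcels, n_networks, "speciesB")
  simulate_two_species(grid, ca, cb, n_subjects = n_subjects,
                       n_timepoints = n_timepoints,
                       divergent_network = n_networks,
                       divergence = divergence, seed = seed, ...)
}

# Species-mean hippocampus x cortex Fisher-z connectivity after global-mean
# regression, mirroring the pipeline's preprocessing.
species_connectivity <- function(dataset) {
  group_average(lapply(dataset$subjects, function(s) {
    connectivity_matrix(regress_global_mean(s$hippo),
                        regress_global_mean(s$cortex))
  }))
}
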
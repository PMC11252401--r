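#' Build a synthetic cortical model on the unit sphere
#'
#' Parcels are placed on a deterministic Fibonacci lattice covering the unit
#' sphere and grouped into networks by contiguous runs in lattice order, so
#' that networks are spatially coherent patches (a stand-in for a functional
#' network parcellation such as the seven canonical resting-state networks).
#'
#' @param n_parcels Number of cortical parcels (>= `n_networks`).
#' @param n_networks Number of functional networks (>= 1).
#' @param species_tag Identifier stored with the model (e.g. `"human"`).
#' @param seed Integer seed recorded in the model; the lattice itself is
#'   deterministic, so two calls with equal arguments are identical.
#' @return A `cortex_model` with `sphere_coords` (n_parcels x 3, unit rows),
#'   `network_label` (integer in `1..n_networks`), `n_parcels`,
#'   `n_networks`, `species_tag`.
#' @examples
#' cx <- make_cortex(200, 7, "human")
#' table(cx$network_label)
#' @export
make_cortex <- function(n_parcels, n_networks, species_tag = "species", seed = 1L) {
  n_parcels <- check_count(n_parcels, "n_parcels")
  n_networks <- check_count(n_networks, "n_networks")
  if (n_networks > n_parcels) {
    stop_invalid("n_networks must not exceed n_parcels")
  }
  i <- seq_len(n_parcels) - 1L
  z <- 1 - 2 * (i + 0.5) / n_parcels
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  r <- sqrt(pmax(0, 1 - z^2))
  coords <- cbind(x = cos(phi) * r, y = sin(phi) * r, z = z)
  coords <- coords / sqrt(rowSums(coords^2))
  # contiguous near-equal blocks in lattice order -> spatially coherent
  labels <- as.integer(cut(i, breaks = n_networks, labels = FALSE))
  structure(
    list(
      n_parcels = n_parcels,
      n_networks = n_networks,
      sphere_coords = coords,
      network_label = labels,
      species_tag = as.character(species_tag),
      seed = as.integer(seed)
    ),
    class = "cortex_model"
  )
}

#' @export
print.cortex_model <- function(x, ...) {
  cat(sprintf("<cortex_model> '%s': %d parcels, %d networks\n",
              x$species_tag, x$n_parcels, x$n_networks))
  invisible(x)
}

new_timeseries <- function(values, space_kind, subject_id, species_tag) {
  stopifnot(is.matrix(values), ncol(values) >= 2, !anyNA(values))
  structure(
    list(values = values, space_kind = space_kind,
         subject_id = subject_id, species_tag = species_tag),
    class = "timeseries"
  )
}

# T x F latent scores: AR(1) innovations, then empirically centred and
# whitened (sample covariance exactly identity) so that planted second
# moments hold exactly at finite T.
latent_scores <- function(n_time, n_factors, ar = 0) {
  u <- matrix(stats::rnorm(n_time * n_factors), n_time, n_factors)
  if (ar > 0) {
    u <- apply(u, 2L, function(col) as.numeric(stats::filter(col, ar, "recursive")))
  }
  u <- scale(u, center = TRUE, scale = FALSE)
  u %*% backsolve(chol(stats::cov(u)), diag(n_factors))
}

#' Simulate paired two-species hippocampus + cortex resting-state datasets
#'
#' Generates per-subject multivariate time series for hippocampal flatmap
#' vertices and cortical parcels in two species, from a shared latent-factor
#' model with known (stored) ground truth. The model has one latent factor
#' per cortical network plus two hippocampal axis factors:
#'
#' * Axis factors: hippocampal loadings are `2*ap_coord - 1`
#'   (anterior-posterior) and `2*pd_coord - 1` (distal-proximal); cortical
#'   parcels carry smooth sphere-map loadings on the same factors
#'   (`axis_coupling_sd` times the parcel's `z` and `x` coordinate,
#'   respectively), so each axis has a planted cortical coupling map.
#' * Network factors: each network `k` couples to the hippocampus with a
#'   Gaussian bump profile along the anterior-posterior axis,
#'   `network_coupling * exp(-(ap - mu_k)^2 / (2 bump_width^2))`, whose
#'   centre `mu_k` is the network's mean polar angle divided by `pi` — so
#'   networks tile the cortex from one pole to the other and their
#'   preferred hippocampal positions sweep the long axis in step. Cortical
#'   parcels load on network factors through a soft spatial membership
#'   kernel in polar angle (width `membership_sigma`), dominated by the
#'   parcel's own network but mixing smoothly into neighbouring networks,
#'   as real connectivity transitions do. Couplings are identical across
#'   species except for `divergent_network`, whose hippocampal coupling is
#'   attenuated by `(1 - divergence)` in the second species.
#'
#' Observed series are `loadings %*% t(latents) + noise_sd * noise`. Latent
#' scores are drawn independently per subject and species (different
#' individuals), optionally AR(1)-correlated in time, and empirically
#' whitened within subject so the planted covariance structure holds exactly
#' at finite length.
#'
#' @param grid A `flatmap_grid` shared by both species.
#' @param cortex_a,cortex_b `cortex_model`s for the two species; must have
#'   the same number of networks.
#' @param n_subjects Subjects per species (>= 1).
#' @param n_timepoints Time points per run; must exceed the number of latent
#'   factors (`n_networks + 2`).
#' @param noise_sd Observation noise standard deviation.
#' @param divergent_network Network label whose hippocampal coupling is
#'   attenuated in species B; defaults to the last (most anterior-coupled)
#'   network, the stand-in for the default-mode network.
#' @param divergence Attenuation in `[0, 1]`; 0 means identical coupling.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @param ar AR(1) coefficient of the latent factors (default 0, white).
#' @param axis_coupling_sd Amplitude of the planted cortical axis-coupling
#'   maps (default 0.5).
#' @param network_coupling Amplitude of the hippocampal network-coupling
#'   bumps (default 2).
#' @param bump_width Width of the hippocampal coupling bumps on the
#'   normalized anterior-posterior axis (default 0.25).
#' @param membership_sigma Width (radians of polar angle) of the soft
#'   network-membership kernel of cortical parcels (default 0.25).
#' @return A list of two `species_dataset`s (`$a`, `$b`). Each holds `grid`,
#'   `cortex`, `subjects` (list of `hippo`/`cortex` `timeseries` pairs) and
#'   `ground_truth` (hippocampal and cortical factor loadings, the species
#'   coupling vector, and the analytic `ap_coupling`/`pd_coupling` cortical
#'   maps implied by the model).
#' @examples
#' g <- make_flatmap_grid(8, 4)
#' cx <- make_cortex(40, 4, "human"); cm <- make_cortex(40, 4, "macaque")
#' sim <- simulate_two_species(g, cx, cm, n_subjects = 2, n_timepoints = 80,
#'                             seed = 1)
#' dim(sim$a$subjects[[1]]$hippo$values)
#' @export
simulate_two_species <- function(grid, cortex_a, cortex_b,
                                 n_subjects = 10, n_timepoints = 600,
                                 noise_sd = 1, divergent_network = NULL,
                                 divergence = 0.8, seed = 7L, ar = 0,
                                 axis_coupling_sd = 0.5,
                                 network_coupling = 2,
                                 bump_width = 0.25,
                                 membership_sigma = 0.25) {
  stopifnot(inherits(grid, "flatmap_grid"),
            inherits(cortex_a, "cortex_model"),
            inherits(cortex_b, "cortex_model"))
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 2L)
  noise_sd <- check_scalar(noise_sd, "noise_sd", lower = 0)
  divergence <- check_scalar(divergence, "divergence", lower = 0, upper = 1)
  ar <- check_scalar(ar, "ar", lower = 0, upper = 0.99)
  if (cortex_a$n_networks != cortex_b$n_networks) {
    stop_invalid("the two cortex models must share the network count")
  }
  K <- cortex_a$n_networks
  if (is.null(divergent_network)) divergent_network <- K
  divergent_network <- check_count(divergent_network, "divergent_network")
  if (divergent_network > K) {
    stop_invalid("unknown divergent_network label: ", divergent_network)
  }
  n_factors <- K + 2L
  if (n_timepoints <= n_factors) {
    stop_invalid("n_timepoints must exceed the number of latent factors (",
                 n_factors, ")")
  }

  ap <- 2 * grid$ap_coord - 1
  pd <- 2 * grid$pd_coord - 1

  coupling_a <- rep(1, K)
  coupling_b <- rep(1, K)
  coupling_b[divergent_network] <- 1 - divergence

  factor_names <- c(paste0("network", seq_len(K)), "ap_axis", "pd_axis")

  network_theta <- function(cortex) {
    theta <- acos(clip(cortex$sphere_coords[, 3L], -1, 1))
    as.numeric(tapply(theta, cortex$network_label, mean))
  }

  cortex_loadings <- function(cortex) {
    theta <- acos(clip(cortex$sphere_coords[, 3L], -1, 1))
    centers <- network_theta(cortex)
    omega <- sapply(seq_len(K), function(k) {
      exp(-(theta - centers[k])^2 / (2 * membership_sigma^2))
    })
    omega <- omega / rowSums(omega)            # soft network membership
    co <- cortex$sphere_coords
    ap_map <- axis_coupling_sd * co[, 3L]      # smooth planted axis couplings
    pd_map <- axis_coupling_sd * co[, 1L]
    cbind(omega, ap_map, pd_map)
  }

  hippo_loadings <- function(cortex, coupling) {
    mu <- network_theta(cortex) / pi           # preferred AP position per network
    bumps <- sapply(seq_len(K), function(k) {
      network_coupling * exp(-(grid$ap_coord - mu[k])^2 / (2 * bump_width^2))
    })
    cbind(sweep(bumps, 2L, coupling, `*`), ap, pd)
  }

  build_species <- function(cortex, coupling) {
    lh <- hippo_loadings(cortex, coupling)
    lc <- cortex_loadings(cortex)
    colnames(lh) <- colnames(lc) <- factor_names
    subjects <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      u <- latent_scores(n_timepoints, n_factors, ar = ar)   # T x F, cov = I
      h <- tcrossprod(lh, u)
      x <- tcrossprod(lc, u)
      if (noise_sd > 0) {
        h <- h + noise_sd * matrix(stats::rnorm(length(h)), nrow(h))
        x <- x + noise_sd * matrix(stats::rnorm(length(x)), nrow(x))
      }
      sid <- sprintf("%s_sub%02d", cortex$species_tag, s)
      subjects[[s]] <- list(
        hippo = new_timeseries(h, "hippocampal-vertex", sid, cortex$species_tag),
        cortex = new_timeseries(x, "cortical-parcel", sid, cortex$species_tag)
      )
    }
    # analytic cortical coupling to the centred hippocampal axis contrasts
    ap_contrast <- ap - mean(ap)
    pd_contrast <- pd - mean(pd)
    alpha_ap <- drop(crossprod(lh, ap_contrast))
    alpha_pd <- drop(crossprod(lh, pd_contrast))
    structure(
      list(
        grid = grid,
        cortex = cortex,
        subjects = subjects,
        ground_truth = list(
          hippo_loadings = lh,
          cortex_loadings = lc,
          coupling = stats::setNames(coupling, paste0("network", seq_len(K))),
          ap_loading = ap,
          pd_loading = pd,
          ap_coupling = drop(lc %*% alpha_ap),
          pd_coupling = drop(lc %*% alpha_pd),
          divergent_network = divergent_network,
          params = list(n_subjects = n_subjects, n_timepoints = n_timepoints,
                        noise_sd = noise_sd, divergence = divergence,
                        ar = ar, seed = as.integer(seed),
                        axis_coupling_sd = axis_coupling_sd,
                        network_coupling = network_coupling,
                        bump_width = bump_width,
                        membership_sigma = membership_sigma)
        )
      ),
      class = "species_dataset"
    )
  }

  with_seed(seed, {
    a <- build_species(cortex_a, coupling_a)
    b <- build_species(cortex_b, coupling_b)
    list(a = a, b = b)
  })
}

#' @export
print.species_dataset <- function(x, ...) {
  cat(sprintf(
    "<species_dataset> '%s': %d subjects, %d hippocampal vertices, %d parcels, T = %d\n",
    x$cortex$species_tag, length(x$subjects), x$grid$n_vertices,
    x$cortex$n_parcels, ncol(x$subjects[[1]]$hippo$values)))
  invisible(x)
}

#' Subfield label set used throughout the package
#' @export
SUBFIELD_LEVELS <- c("subicular complex", "CA1", "CA2", "CA3/4")

#' Generate a striped categorical subfield flatmap
#'
#' The hippocampal subfields appear as near-vertical stripes along the
#' distal-proximal axis of the flatmap. This generator lays down four
#' stripes (subicular complex, CA1, CA2, CA3/4, in distal-to-proximal
#' order) at the requested boundary fractions, with optional per-row
#' Gaussian jitter of the boundaries (clipped and re-ordered so the stripe
#' sequence is preserved).
#'
#' @param grid A `flatmap_grid`.
#' @param boundaries Three strictly increasing fractions in `(0, 1)`: the
#'   distal-proximal positions of the subiculum/CA1, CA1/CA2 and CA2/CA3-4
#'   boundaries.
#' @param jitter_sd Standard deviation of per-row boundary jitter.
#' @param seed Integer seed (the map is deterministic given the seed).
#' @return A `subfield_flatmap` with integer `labels` (1..4 in grid vertex
#'   order), the label `levels`, and the `grid`.
#' @examples
#' g <- make_flatmap_grid(16, 16)
#' sf <- make_subfield_map(g, c(0.25, 0.5, 0.75))
#' table(SUBFIELD_LEVELS[sf$labels])
#' @export
make_subfield_map <- function(grid, boundaries = c(0.25, 0.5, 0.75),
                              jitter_sd = 0, seed = 1L) {
  stopifnot(inherits(grid, "flatmap_grid"))
  if (length(boundaries) != 3L || any(diff(boundaries) <= 0) ||
      any(boundaries <= 0) || any(boundaries >= 1)) {
    stop_invalid("boundaries must be 3 strictly increasing fractions in (0,1)")
  }
  jitter_sd <- check_scalar(jitter_sd, "jitter_sd", lower = 0)
  labels <- with_seed(seed, {
    out <- integer(grid$n_vertices)
    for (row in seq_len(grid$n_ap)) {
      b <- boundaries
      if (jitter_sd > 0) {
        b <- sort(clip(b + stats::rnorm(3L, sd = jitter_sd), 1e-6, 1 - 1e-6))
      }
      idx <- ((row - 1L) * grid$n_pd + 1L):(row * grid$n_pd)
      out[idx] <- 1L + findInterval(grid$pd_coord[idx], b)
    }
    out
  })
  structure(
    list(labels = labels, levels = SUBFIELD_LEVELS, grid = grid),
    class = "subfield_flatmap"
  )
}

#' @export
print.subfield_flatmap <- function(x, ...) {
  cat("<subfield_flatmap>", x$grid$n_ap, "x", x$grid$n_pd, "vertices;",
      "labels:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated dataset bundle to disk
#'
#' Writes per-subject TSV time-series tables (rows = vertices/parcels,
#' columns = time points), ground-truth loading maps, and a JSON manifest
#' with grid dimensions, the parcel table (sphere coordinates, network
#' labels) and the generative parameters.
#'
#' @param dataset A `species_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_dataset_bundle <- function(dataset, dir) {
  stopifnot(inherits(dataset, "species_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tag <- dataset$cortex$species_tag
  for (sub in dataset$subjects) {
    for (kind in c("hippo", "cortex")) {
      ts <- sub[[kind]]
      write_matrix_table(
        ts$values,
        file.path(dir, sprintf("%s_%s.tsv", ts$subject_id, kind)),
        row_names = sprintf("%s%04d", substr(kind, 1, 1), seq_len(nrow(ts$values))),
        col_names = sprintf("t%04d", seq_len(ncol(ts$values)))
      )
    }
  }
  gt <- dataset$ground_truth
  write_matrix_table(gt$hippo_loadings,
                     file.path(dir, sprintf("%s_hippo_loadings.tsv", tag)),
                     row_names = sprintf("v%04d", seq_len(nrow(gt$hippo_loadings))),
                     col_names = colnames(gt$hippo_loadings))
  write_matrix_table(gt$cortex_loadings,
                     file.path(dir, sprintf("%s_cortex_loadings.tsv", tag)),
                     row_names = sprintf("p%04d", seq_len(nrow(gt$cortex_loadings))),
                     col_names = colnames(gt$cortex_loadings))
  manifest <- list(
    species_tag = tag,
    grid = list(n_ap = dataset$grid$n_ap, n_pd = dataset$grid$n_pd),
    parcels = data.frame(
      parcel = seq_len(dataset$cortex$n_parcels),
      x = dataset$cortex$sphere_coords[, 1L],
      y = dataset$cortex$sphere_coords[, 2L],
      z = dataset$cortex$sphere_coords[, 3L],
      network = dataset$cortex$network_label
    ),
    params = gt$params,
    coupling = as.list(gt$coupling),
    divergent_network = gt$divergent_network
  )
  path <- file.path(dir, sprintf("%s_manifest.json", tag))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
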
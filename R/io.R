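#' Write a numeric matrix as a headed TSV table
#'
#' One header row (corner cell + column names) and one header column.
#' Values are printed at 17 significant digits, so finite doubles
#' round-trip bit-exactly through [read_matrix_table()].
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @param row_names,col_names Header labels (defaults `r1..`, `c1..`).
#' @return Invisibly, `path`.
#' @export
write_matrix_table <- function(m, path, row_names = NULL, col_names = NULL) {
  stopifnot(is.matrix(m))
  if (is.null(row_names)) row_names <- paste0("r", seq_len(nrow(m)))
  if (is.null(col_names)) col_names <- paste0("c", seq_len(ncol(m)))
  stopifnot(length(row_names) == nrow(m), length(col_names) == ncol(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", col_names), collapse = "\t"), con)
  body <- apply(m, 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = "\t")
  })
  writeLines(paste(row_names, body, sep = "\t"), con)
  invisible(path)
}

#' Read a headed TSV matrix table
#'
#' Inverse of [write_matrix_table()]; errors (with the offending line
#' number) on ragged rows or non-numeric cells.
#'
#' @param path Input path.
#' @return List with `values` (numeric matrix), `row_names`, `col_names`.
#' @export
read_matrix_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop_invalid("empty input file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) stop_invalid("missing column header in ", path)
  col_names <- header[-1L]
  n_col <- length(col_names)
  body <- lines[-1L]
  if (!length(body)) stop_invalid("no data rows in ", path)
  row_names <- character(length(body))
  values <- matrix(NA_real_, length(body), n_col)
  for (i in seq_along(body)) {
    cells <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(cells) != n_col + 1L) {
      stop_invalid("ragged row at line ", i + 1L, ": expected ",
                   n_col + 1L, " cells, got ", length(cells))
    }
    row_names[i] <- cells[1L]
    nums <- suppressWarnings(as.numeric(cells[-1L]))
    if (anyNA(nums)) {
      stop_invalid("non-numeric cell at line ", i + 1L)
    }
    values[i, ] <- nums
  }
  list(values = values, row_names = row_names, col_names = col_names)
}

write_sidecar <- function(path, info) {
  jsonlite::write_json(info, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export a flatmap map as a PNG heat map
#'
#' Writes an `n_ap` x `n_pd` pixel grayscale image (anterior-posterior
#' rows, distal-proximal columns) of a per-vertex map.
#'
#' @param values Per-vertex values in grid row-major order.
#' @param grid A `flatmap_grid`.
#' @param path Output `.png` path.
#' @return Invisibly, `path`.
#' @export
export_flatmap_png <- function(values, grid, path) {
  stopifnot(inherits(grid, "flatmap_grid"))
  if (length(values) != grid$n_vertices) {
    stop_invalid("map length does not match the grid")
  }
  rng <- range(values)
  scaled <- if (diff(rng) == 0) rep(0.5, length(values)) else {
    (values - rng[1L]) / diff(rng)
  }
  img <- t(matrix(scaled, nrow = grid$n_pd, ncol = grid$n_ap))
  png::writePNG(img, target = path)
  invisible(path)
}

pipeline_defaults <- function() {
  list(
    seed = 7L,
    n_parcels = 200L, n_networks = 7L,
    grid_ap = 32L, grid_pd = 16L,
    n_subjects = 10L, n_timepoints = 600L,
    noise_sd = 1, divergence = 0.8, divergent_network = NULL, ar = 0,
    sparsity = 0.9, alpha = 0.5, n_components = 10L,
    penalty = 0.1, n_perm = 200L, q_grid = seq(0.70, 0.95, by = 0.05),
    ap_bins = 16L, pd_bins = 8L, exclude = 0.10,
    homology_radius = 0.45, sphere_radius = 1,
    subfield_boundaries_a = c(0.25, 0.50, 0.75),
    subfield_boundaries_b = c(0.30, 0.55, 0.78),
    subfield_jitter_sd = 0.02,
    out_dir = NULL
  )
}

#' Build and validate a pipeline run configuration
#'
#' Named overrides of the default synthetic-study configuration; unknown
#' keys are rejected before any computation.
#'
#' @param ... Named settings overriding the defaults (see
#'   `hippograd:::pipeline_defaults()` for the full key set: simulation
#'   sizes, embedding settings, matching settings, dual-regression bins,
#'   homology radius, output directory).
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- pipeline_defaults()
  override <- list(...)
  if (length(override)) {
    nm <- names(override)
    if (is.null(nm) || any(nm == "")) stop_invalid("all settings must be named")
    unknown <- setdiff(nm, names(cfg))
    if (length(unknown)) {
      stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[nm] <- override
  }
  cfg$seed <- check_count(cfg$seed, "seed", min = 0L)
  cfg$n_parcels <- check_count(cfg$n_parcels, "n_parcels")
  cfg$n_subjects <- check_count(cfg$n_subjects, "n_subjects")
  cfg$divergence <- check_scalar(cfg$divergence, "divergence", 0, 1)
  structure(cfg, class = "run_config")
}

#' Run the full synthetic cross-species pipeline
#'
#' Executes simulate, preprocess (global-mean regression), per-species
#' hippocampal gradients, joint cross-species embedding, cortico-cortical
#' gradients with gradient matching, dual regression and reprojection with
#' cross-species KS comparisons, searchlight homology with network means,
#' and subfield flatmap metrics. Deterministic given `config$seed`; when
#' `config$out_dir` is set, key artifacts are written as TSV tables with
#' JSON provenance sidecars.
#'
#' @param config A `run_config` (see [run_config()]).
#' @return A result bundle (list) with elements `sim`, `conn`, `gradients`,
#'   `joint`, `match`, `dualreg`, `reprojection`, `ks`, `homology`,
#'   `subfields`, and `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  grid <- make_flatmap_grid(cfg$grid_ap, cfg$grid_pd)
  cortex_a <- make_cortex(cfg$n_parcels, cfg$n_networks, "speciesA", cfg$seed)
  cortex_b <- make_cortex(cfg$n_parcels, cfg$n_networks, "speciesB", cfg$seed)
  sim <- simulate_two_species(
    grid, cortex_a, cortex_b,
    n_subjects = cfg$n_subjects, n_timepoints = cfg$n_timepoints,
    noise_sd = cfg$noise_sd, divergent_network = cfg$divergent_network,
    divergence = cfg$divergence, seed = cfg$seed, ar = cfg$ar
  )

  preprocess <- function(ds) {
    lapply(ds$subjects, function(sub) {
      list(hippo = regress_global_mean(sub$hippo),
           cortex = regress_global_mean(sub$cortex))
    })
  }
  subj_a <- preprocess(sim$a)
  subj_b <- preprocess(sim$b)

  species_conn <- function(subjects) {
    group_average(lapply(subjects, function(s) {
      connectivity_matrix(s$hippo, s$cortex)
    }))
  }
  C_a <- species_conn(subj_a)
  C_b <- species_conn(subj_b)

  grad_a <- hippocampal_gradients(C_a, cfg$n_components, cfg$sparsity, cfg$alpha)
  grad_b <- hippocampal_gradients(C_b, cfg$n_components, cfg$sparsity, cfg$alpha)
  joint <- joint_cross_species_embed(C_a, C_b, cfg$n_components,
                                     cfg$sparsity, cfg$alpha)

  cc_a <- corticocortical_gradients(lapply(subj_a, `[[`, "cortex"),
                                    cfg$n_components, cfg$sparsity, cfg$alpha)
  match <- match_gradient_maps(
    joint$a[, 1L], cc_a$components[, seq_len(min(6L, cfg$n_components))],
    sphere_coords = cortex_a$sphere_coords,
    penalty = cfg$penalty, n_perm = cfg$n_perm, q_grid = cfg$q_grid,
    seed = cfg$seed
  )

  design <- build_axis_design(grid, cfg$n_parcels, cfg$ap_bins, cfg$pd_bins)
  dr_fit <- function(subjects) {
    lapply(subjects, function(s) {
      dual_regress(rbind(s$cortex$values, s$hippo$values), design)
    })
  }
  fits_a <- dr_fit(subj_a)
  fits_b <- dr_fit(subj_b)
  maps_a <- group_axis_maps(fits_a)
  maps_b <- group_axis_maps(fits_b)

  embed_subjects <- function(fits) {
    lapply(fits, function(f) {
      reproject_to_flatmap_space(f$ap_map, f$pd_map, grid, cfg$exclude)
    })
  }
  emb_a <- embed_subjects(fits_a)
  emb_b <- embed_subjects(fits_b)
  rois <- split(seq_len(cfg$n_parcels), cortex_a$network_label)
  n_comp <- length(rois) * 2L
  ks <- lapply(names(rois), function(k) {
    list(
      network = as.integer(k),
      AP = ks_region_comparison(emb_a, emb_b, rois[[k]], "AP", n_comp),
      PD = ks_region_comparison(emb_a, emb_b, rois[[k]], "PD", n_comp)
    )
  })

  # fingerprints: parcels x hippocampal vertices
  nb <- searchlight_neighbors(cortex_a$sphere_coords, cortex_b$sphere_coords,
                              radius = cfg$homology_radius,
                              sphere_radius = cfg$sphere_radius)
  hmap <- homology_index(t(C_a$values), t(C_b$values), nb)
  net_hom <- network_mean_homology(hmap, cortex_a$network_label)

  sf_a <- make_subfield_map(grid, cfg$subfield_boundaries_a,
                            cfg$subfield_jitter_sd, cfg$seed)
  sf_b <- make_subfield_map(grid, cfg$subfield_boundaries_b,
                            cfg$subfield_jitter_sd, cfg$seed + 1L)
  prof_a <- subfield_extent_profile(sf_a)
  prof_b <- subfield_extent_profile(sf_b)
  subfields <- list(
    similarity = flatmap_similarity(prof_a, prof_b),
    relative_a = relative_subfield_size(prof_a),
    relative_b = relative_subfield_size(prof_b),
    percent_change = percent_change(relative_subfield_size(prof_a),
                                    relative_subfield_size(prof_b))
  )

  result <- list(
    sim = sim,
    conn = list(a = C_a, b = C_b),
    gradients = list(a = grad_a, b = grad_b),
    joint = joint,
    match = match,
    dualreg = list(a = maps_a, b = maps_b, design = design),
    reprojection = list(a = emb_a, b = emb_b),
    ks = ks,
    homology = list(map = hmap, network = net_hom),
    subfields = subfields,
    config = cfg
  )
  if (!is.null(cfg$out_dir)) {
    write_pipeline_outputs(result, cfg$out_dir)
  }
  result
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  prov <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("hippograd")),
    config = unclass(cfg)[setdiff(names(cfg), "out_dir")]
  )
  save_map <- function(values, name, cols = NULL) {
    m <- as.matrix(values)
    p <- file.path(dir, paste0(name, ".tsv"))
    write_matrix_table(m, p, col_names = cols %||% colnames(m))
    write_sidecar(p, c(list(artifact = name), prov))
  }
  save_map(result$gradients$a$components, "hippocampal_gradients_speciesA")
  save_map(result$gradients$b$components, "hippocampal_gradients_speciesB")
  save_map(result$joint$a, "joint_gradient_speciesA")
  save_map(result$joint$b, "joint_gradient_speciesB")
  save_map(cbind(ap = result$dualreg$a$ap_map, pd = result$dualreg$a$pd_map),
           "axis_maps_speciesA")
  save_map(cbind(ap = result$dualreg$b$ap_map, pd = result$dualreg$b$pd_map),
           "axis_maps_speciesB")
  save_map(cbind(homology = result$homology$map$values), "homology_map")
  utils::write.table(result$homology$network,
              file.path(dir, "network_homology.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(similarity = result$subfields$similarity,
         best_match = result$match$best_set, provenance = prov),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
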
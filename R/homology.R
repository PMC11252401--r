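#' Searchlight neighbourhoods on the registration sphere
#'
#' For every parcel of species A, finds the species-B parcels whose
#' great-circle (geodesic) distance from the parcel's registered location
#' is at most `radius`. Locations and target coordinates are unit-sphere
#' 3-vectors; distances are measured on a sphere of physical radius
#' `sphere_radius` (default 1, i.e. radii in radians).
#'
#' @param corr_coords Registered locations of species-A parcels in species
#'   B's coordinate frame (n_A x 3, unit rows). The identity
#'   correspondence simply passes species A's own coordinates.
#' @param target_coords Species-B parcel coordinates (n_B x 3, unit rows).
#' @param radius Searchlight radius (> 0), in units of `sphere_radius`.
#' @param sphere_radius Physical radius of the registration sphere.
#' @return List of integer neighbour index vectors, one per species-A
#'   parcel; parcels with no neighbour get `integer(0)` (flagged
#'   downstream, not fatal).
#' @export
searchlight_neighbors <- function(corr_coords, target_coords, radius,
                                  sphere_radius = 1) {
  stopifnot(is.matrix(corr_coords), is.matrix(target_coords),
            ncol(corr_coords) == 3L, ncol(target_coords) == 3L)
  radius <- check_scalar(radius, "radius")
  if (radius <= 0) stop_invalid("radius must be > 0")
  sphere_radius <- check_scalar(sphere_radius, "sphere_radius")
  norms <- sqrt(rowSums(corr_coords^2))
  if (any(abs(norms - 1) > 1e-6)) stop_invalid("corr_coords must be unit vectors")
  D <- acos(clip(tcrossprod(corr_coords, target_coords), -1, 1)) * sphere_radius
  lapply(seq_len(nrow(D)), function(i) which(D[i, ] <= radius))
}

#' Searchlight homology index from hippocampal connectivity fingerprints
#'
#' For each species-A parcel: the Pearson correlation between its
#' hippocampal connectivity fingerprint and the fingerprint of every
#' species-B parcel inside its searchlight, summarized by the median. High
#' values mean the parcel's hippocampal coupling profile is preserved at
#' the registered location; low values mean cross-species reconfiguration.
#'
#' @param C_a,C_b Parcels x hippocampal-vertices connectivity matrices
#'   (`connectivity_matrix` or plain; identical hippocampal vertex order,
#'   i.e. the matched flatmap).
#' @param neighbors Neighbour lists from [searchlight_neighbors()].
#' @return A `homology_map`: `values` (per-parcel median correlation, NA
#'   where flagged missing), `neighbor_counts`, `missing` (logical).
#' @export
homology_index <- function(C_a, C_b, neighbors) {
  A <- if (inherits(C_a, "connectivity_matrix")) C_a$values else C_a
  B <- if (inherits(C_b, "connectivity_matrix")) C_b$values else C_b
  if (ncol(A) != ncol(B)) {
    stop_invalid("hippocampal fingerprint dimensions differ")
  }
  stopifnot(length(neighbors) == nrow(A))
  sd_a <- apply(A, 1L, stats::sd)
  sd_b <- apply(B, 1L, stats::sd)
  R <- suppressWarnings(stats::cor(t(A), t(B)))
  values <- rep(NA_real_, nrow(A))
  counts <- lengths(neighbors)
  for (i in seq_len(nrow(A))) {
    nb <- neighbors[[i]]
    nb <- nb[sd_b[nb] > 0]
    if (sd_a[i] == 0 || !length(nb)) next     # flagged missing
    values[i] <- stats::median(R[i, nb])
  }
  if (anyNA(values)) {
    warning("parcel(s) flagged missing (zero-variance fingerprint or no ",
            "neighbours): ", paste(which(is.na(values)), collapse = ", "),
            call. = FALSE)
  }
  structure(
    list(values = values, neighbor_counts = counts,
         missing = is.na(values)),
    class = "homology_map"
  )
}

#' @export
print.homology_map <- function(x, ...) {
  cat(sprintf("<homology_map> %d parcels (%d missing); median = %.3f\n",
              length(x$values), sum(x$missing),
              stats::median(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Mean homology per cortical network
#'
#' @param hmap A `homology_map`.
#' @param network_label Integer network label per parcel.
#' @return Data frame with `network`, `mean_homology` (NA with a warning
#'   for networks whose parcels are all missing), `n_parcels` (non-missing
#'   count).
#' @export
network_mean_homology <- function(hmap, network_label) {
  stopifnot(inherits(hmap, "homology_map"),
            length(network_label) == length(hmap$values))
  nets <- sort(unique(network_label))
  means <- vapply(nets, function(k) {
    v <- hmap$values[network_label == k]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1L))
  if (anyNA(means)) {
    warning("network(s) with all parcels missing: ",
            paste(nets[is.na(means)], collapse = ", "), call. = FALSE)
  }
  data.frame(
    network = nets,
    mean_homology = means,
    n_parcels = vapply(nets, function(k) {
      sum(network_label == k & !hmap$missing)
    }, integer(1L))
  )
}
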
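#' Build the binned hippocampal-axis design matrix
#'
#' One regressor per intrinsic hippocampal axis, plus an intercept, over
#' the concatenated brain space (cortical block first, then the
#' hippocampal block). The flatmap is stratified into `ap_bins` bins along
#' the anterior-posterior axis and `pd_bins` bins along the
#' distal-proximal axis; hippocampal vertices in bin `i` of `B` get value
#' `-1 + 2 i / (B - 1)` (-1 = most posterior / most distal, +1 = most
#' anterior / most proximal). Cortical elements are 0 on both axis
#' regressors. Axis columns are mean-centred within the hippocampal block
#' (a no-op for balanced bins), making the three columns mutually
#' orthogonal.
#'
#' @param grid A `flatmap_grid`.
#' @param n_cortex Number of cortical elements preceding the hippocampal
#'   block.
#' @param ap_bins,pd_bins Bin counts (defaults 16 and 8).
#' @return An `axis_design`: `matrix` ((n_cortex + n_hippo) x 3, columns
#'   `ap`, `pd`, `intercept`), bin counts, block sizes.
#' @export
build_axis_design <- function(grid, n_cortex, ap_bins = 16, pd_bins = 8) {
  stopifnot(inherits(grid, "flatmap_grid"))
  n_cortex <- check_count(n_cortex, "n_cortex")
  ap_bins <- check_count(ap_bins, "ap_bins", min = 2L)
  pd_bins <- check_count(pd_bins, "pd_bins", min = 2L)
  bin_values <- function(coord, B) {
    i <- pmin(floor(coord * B), B - 1L)       # nearest-assignment by coordinate
    v <- -1 + 2 * i / (B - 1)
    v - mean(v)                               # centred within hippocampal block
  }
  ap <- bin_values(grid$ap_coord, ap_bins)
  pd <- bin_values(grid$pd_coord, pd_bins)
  X <- cbind(
    ap = c(rep(0, n_cortex), ap),
    pd = c(rep(0, n_cortex), pd),
    intercept = rep(1, n_cortex + grid$n_vertices)
  )
  structure(
    list(matrix = X, ap_bins = ap_bins, pd_bins = pd_bins,
         n_cortex = n_cortex, n_hippo = grid$n_vertices),
    class = "axis_design"
  )
}

#' Dual regression of the hippocampal axes into the cortex
#'
#' Stage 1 multiplies the pseudo-inverse of the design matrix with the
#' concatenated data matrix, yielding one time series per regressor (the
#' "axis time series"). Stage 2 regresses that set of time series back
#' into the data, yielding per-element coupling coefficients. The cortical
#' block of the anterior-posterior and distal-proximal coefficient columns
#' are the cortical axis maps.
#'
#' @param data Concatenated (n_cortex + n_hippo) x T matrix (cortical rows
#'   first) or `timeseries`.
#' @param design An `axis_design` with matching row count.
#' @return List with `axis_series` (3 x T), `coefficients` (all elements x
#'   3), `ap_map`, `pd_map` (cortical block only).
#' @export
dual_regress <- function(data, design) {
  D <- if (inherits(data, "timeseries")) data$values else data
  stopifnot(inherits(design, "axis_design"), is.matrix(D))
  X <- design$matrix
  if (nrow(D) != nrow(X)) {
    stop_invalid("data rows (", nrow(D), ") do not match the design (",
                 nrow(X), ")")
  }
  if (ncol(D) < 3L) stop_invalid("need at least 3 time points")
  if (qr(X)$rank < ncol(X)) stop_invalid("rank-deficient design matrix")
  Ts <- MASS::ginv(X) %*% D                    # stage 1: 3 x T
  B <- D %*% MASS::ginv(Ts)                    # stage 2: elements x 3
  colnames(B) <- colnames(X)
  rownames(Ts) <- colnames(X)
  cort <- seq_len(design$n_cortex)
  list(axis_series = Ts, coefficients = B,
       ap_map = B[cort, "ap"], pd_map = B[cort, "pd"])
}

#' Group-mean axis maps over subjects
#'
#' @param fits List of per-subject [dual_regress()] results.
#' @return List with `ap_map` and `pd_map` group means plus the per-subject
#'   map matrices (`ap_subject`, `pd_subject`, subjects in columns).
#' @export
group_axis_maps <- function(fits) {
  if (!length(fits)) stop_invalid("empty fit list")
  ap <- vapply(fits, `[[`, numeric(length(fits[[1L]]$ap_map)), "ap_map")
  pd <- vapply(fits, `[[`, numeric(length(fits[[1L]]$pd_map)), "pd_map")
  list(ap_map = rowMeans(ap), pd_map = rowMeans(pd),
       ap_subject = ap, pd_subject = pd)
}

#' Reproject cortical elements into the 2D hippocampal flatmap space
#'
#' Uses the two axis maps as coordinates of a 2D space that reflects the
#' intrinsic hippocampal coordinate system. Each axis is linearly rescaled
#' so that its `exclude` and `1 - exclude` percentiles map to 0 and 1,
#' with values outside clipped (winsorized rescaling: the most extreme
#' vertices at either end are excluded from determining the bounds).
#'
#' @param ap_map,pd_map Per-cortical-element axis coupling maps.
#' @param grid A `flatmap_grid` (fixes the aspect ratio).
#' @param exclude Percentile excluded at each end (default 0.10).
#' @return An `embedding2d`: `x` (AP coordinate), `y` (PD coordinate),
#'   `aspect_ratio` (= n_ap / n_pd), `bounds`.
#' @export
reproject_to_flatmap_space <- function(ap_map, pd_map, grid, exclude = 0.10) {
  stopifnot(length(ap_map) == length(pd_map), inherits(grid, "flatmap_grid"))
  exclude <- check_scalar(exclude, "exclude", lower = 0, upper = 0.49)
  rescale <- function(v) {
    b <- stats::quantile(v, c(exclude, 1 - exclude), names = FALSE)
    if (diff(b) == 0) stop_invalid("constant axis map cannot be rescaled")
    list(coord = clip((v - b[1L]) / (b[2L] - b[1L]), 0, 1), bounds = b)
  }
  rx <- rescale(ap_map)
  ry <- rescale(pd_map)
  structure(
    list(x = rx$coord, y = ry$coord,
         aspect_ratio = grid$n_ap / grid$n_pd,
         bounds = list(ap = rx$bounds, pd = ry$bounds)),
    class = "embedding2d"
  )
}

#' Cross-species Kolmogorov-Smirnov comparison of reprojected regions
#'
#' For each subject, the region summary is the mean coordinate of the ROI
#' elements along the chosen axis; species are then compared with a
#' two-sample two-sided KS test on the subject-level summaries (exact
#' small-sample p-value), Bonferroni-corrected by the number of
#' comparisons performed.
#'
#' @param emb_a,emb_b Lists of per-subject `embedding2d` objects, one list
#'   per species (>= 2 subjects each).
#' @param roi Integer vector of cortical element indices (non-empty).
#' @param axis `"AP"` or `"PD"`.
#' @param n_comparisons Bonferroni correction count (default 1).
#' @return List with `D`, `p`, `p_corrected`, and the per-species subject
#'   summaries.
#' @export
ks_region_comparison <- function(emb_a, emb_b, roi, axis = c("AP", "PD"),
                                 n_comparisons = 1) {
  axis <- match.arg(axis)
  if (!length(roi)) stop_invalid("empty ROI")
  if (length(emb_a) < 2L || length(emb_b) < 2L) {
    stop_invalid("need >= 2 subjects per species")
  }
  field <- if (axis == "AP") "x" else "y"
  summarize <- function(embs) {
    vapply(embs, function(e) mean(e[[field]][roi]), numeric(1L))
  }
  sa <- summarize(emb_a)
  sb <- summarize(emb_b)
  kt <- suppressWarnings(stats::ks.test(sa, sb, alternative = "two.sided"))
  list(D = unname(kt$statistic), p = kt$p.value,
       p_corrected = min(1, kt$p.value * n_comparisons),
       summary_a = sa, summary_b = sb)
}
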
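#' Regress the global mean signal out of a time series
#'
#' Each spatial row is replaced by its least-squares residual after
#' regression on the spatial-mean time series plus an intercept. Residual
#' rows are exactly orthogonal to the mean series, and the operation is
#' idempotent.
#'
#' @param ts A `timeseries` (space x time) or a plain numeric matrix.
#' @return Object of the same type with residual values.
#' @examples
#' m <- matrix(rnorm(100), 5, 20)
#' r <- regress_global_mean(m)
#' max(abs(r %*% colMeans(m)))  # ~0
#' @export
regress_global_mean <- function(ts) {
  m <- if (inherits(ts, "timeseries")) ts$values else ts
  stopifnot(is.matrix(m), ncol(m) >= 2)
  g <- colMeans(m)
  # treat a numerically null mean series as constant (keeps the operation
  # idempotent: residual means are exact zeros up to float noise)
  if (stats::sd(g) <= 1e-10 * max(stats::sd(as.vector(m)), .Machine$double.eps)) {
    warning("global mean series is constant; regressing intercept only",
            call. = FALSE)
    res <- m - rowMeans(m)
  } else {
    X <- cbind(1, g)                         # T x 2
    # residual = D - D X (X'X)^-1 X'  applied over rows of D
    beta <- t(qr.solve(X, t(m)))             # rows x 2
    res <- m - tcrossprod(beta, X)
  }
  if (inherits(ts, "timeseries")) {
    ts$values <- res
    ts
  } else {
    res
  }
}

#' Average vertex time series within parcels
#'
#' @param ts A `timeseries` over vertices or a matrix (vertices x time).
#' @param labels Integer parcel id per vertex; every parcel id between its
#'   observed values must be non-empty.
#' @return Parcellated series (parcels x time), parcel order = ascending id.
#' @export
parcellate_timeseries <- function(ts, labels) {
  m <- if (inherits(ts, "timeseries")) ts$values else ts
  stopifnot(is.matrix(m), length(labels) == nrow(m))
  ids <- sort(unique(labels))
  expected <- seq(min(ids), max(ids))
  if (length(setdiff(expected, ids))) {
    stop_invalid("empty parcel(s): ",
                 paste(setdiff(expected, ids), collapse = ", "))
  }
  counts <- as.numeric(table(factor(labels, levels = ids)))
  out <- rowsum(m, group = labels, reorder = TRUE) / counts
  dimnames(out) <- NULL
  if (inherits(ts, "timeseries")) {
    new_timeseries(out, "cortical-parcel", ts$subject_id, ts$species_tag)
  } else {
    out
  }
}

#' Fisher r-to-z transform with clipping
#'
#' `atanh(r)` after clipping `|r|` to `1 - 1e-7`, keeping self-correlations
#' finite.
#'
#' @param r Correlations in `[-1, 1]` (vectorised).
#' @return Fisher-z values.
#' @examples
#' fisher_z(0.5)  # 0.5493
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop_invalid("correlations must lie in [-1, 1]")
  }
  atanh(clip(r, -(1 - 1e-7), 1 - 1e-7))
}

new_connectivity_matrix <- function(values, row_kind, col_kind,
                                    species_tag = NA_character_,
                                    averaged_over = 1L) {
  structure(
    list(values = values, row_kind = row_kind, col_kind = col_kind,
         species_tag = species_tag, averaged_over = as.integer(averaged_over)),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d (%s) x %d (%s), averaged over %d\n",
              nrow(x$values), x$row_kind, ncol(x$values), x$col_kind,
              x$averaged_over))
  invisible(x)
}

#' Fisher-z connectivity matrix between two sets of time series
#'
#' Entry `(i, j)` is the Fisher-z transformed Pearson correlation between
#' row `i` of `a` and row `j` of `b`. With `b` missing or identical to `a`
#' the result is the square (cortico-cortical) matrix, symmetric with a
#' clipped-maximum diagonal. Zero-variance rows produce zero entries with a
#' warning.
#'
#' @param a,b `timeseries` objects or space x time matrices with equal T.
#' @return A `connectivity_matrix`.
#' @export
connectivity_matrix <- function(a, b = NULL) {
  ats <- inherits(a, "timeseries")
  ma <- if (ats) a$values else a
  if (is.null(b)) b <- a
  bts <- inherits(b, "timeseries")
  mb <- if (bts) b$values else b
  stopifnot(is.matrix(ma), is.matrix(mb))
  if (ncol(ma) != ncol(mb)) stop_invalid("time dimensions differ")
  z <- fisher_z(row_cor(ma, mb))
  new_connectivity_matrix(
    z,
    row_kind = if (ats) a$space_kind else "rows",
    col_kind = if (bts) b$space_kind else "cols",
    species_tag = if (ats) a$species_tag else NA_character_
  )
}

#' Element-wise group average of connectivity matrices
#'
#' Fixed order of operations: Fisher z per subject first, then average.
#'
#' @param matrices Non-empty list of `connectivity_matrix` objects with
#'   identical shapes and kinds.
#' @return A `connectivity_matrix` with `averaged_over` set.
#' @export
group_average <- function(matrices) {
  if (!length(matrices)) stop_invalid("empty matrix list")
  stopifnot(all(vapply(matrices, inherits, TRUE, "connectivity_matrix")))
  ref <- matrices[[1L]]
  for (m in matrices[-1L]) {
    if (!identical(dim(m$values), dim(ref$values)) ||
        !identical(c(m$row_kind, m$col_kind), c(ref$row_kind, ref$col_kind))) {
      stop_invalid("matrices have mismatched shapes or kinds")
    }
  }
  avg <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  new_connectivity_matrix(avg, ref$row_kind, ref$col_kind, ref$species_tag,
                          averaged_over = length(matrices))
}

#' Maximum hippocampal connectivity per cortical element
#'
#' Assigns to each cortical column the maximal connectivity value across all
#' hippocampal vertices, capturing coupling with any part of the
#' hippocampus.
#'
#' @param dense A `connectivity_matrix` with hippocampal rows.
#' @return Numeric vector, one value per cortical column.
#' @export
max_connectivity_map <- function(dense) {
  stopifnot(inherits(dense, "connectivity_matrix"))
  if (!startsWith(dense$row_kind, "hippocampal")) {
    stop_invalid("row_kind must be hippocampal, got '", dense$row_kind, "'")
  }
  apply(dense$values, 2L, max)
}

#' Connectivity of four hippocampal flatmap sectors with the cortex
#'
#' Sectors are the flatmap quadrants split at `ap_coord = 0.5` and
#' `pd_coord = 0.5` (anterior/posterior x distal/proximal); each sector map
#' is the Fisher-z correlation of the sector's mean time series with every
#' cortical series.
#'
#' @param hippo_ts Hippocampal `timeseries`/matrix (vertices x time).
#' @param cortex_ts Cortical `timeseries`/matrix with equal T.
#' @param grid The `flatmap_grid` matching the hippocampal rows.
#' @return A 4 x n_cortex matrix with rows `anterior-distal`,
#'   `anterior-proximal`, `posterior-distal`, `posterior-proximal`.
#' @export
sector_connectivity <- function(hippo_ts, cortex_ts, grid) {
  stopifnot(inherits(grid, "flatmap_grid"))
  h <- if (inherits(hippo_ts, "timeseries")) hippo_ts$values else hippo_ts
  x <- if (inherits(cortex_ts, "timeseries")) cortex_ts$values else cortex_ts
  if (nrow(h) != grid$n_vertices) stop_invalid("grid does not match hippocampal rows")
  ant <- grid$ap_coord > 0.5
  prox <- grid$pd_coord > 0.5
  sectors <- list(
    `anterior-distal` = ant & !prox,
    `anterior-proximal` = ant & prox,
    `posterior-distal` = !ant & !prox,
    `posterior-proximal` = !ant & prox
  )
  if (any(!vapply(sectors, any, TRUE))) {
    stop_invalid("degenerate grid: an empty flatmap sector")
  }
  means <- t(vapply(sectors, function(ix) colMeans(h[ix, , drop = FALSE]),
                    numeric(ncol(h))))
  fisher_z(row_cor(means, x))
}

#' Temporal signal-to-noise ratio per row
#'
#' Temporal mean divided by temporal sample standard deviation (n - 1).
#' Rows with zero variance get `Inf` and are flagged invalid.
#'
#' @param ts A `timeseries` or space x time matrix (T >= 2).
#' @return Data frame with columns `tsnr` and logical `valid`.
#' @export
tsnr_map <- function(ts) {
  m <- if (inherits(ts, "timeseries")) ts$values else ts
  stopifnot(is.matrix(m), ncol(m) >= 2)
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  valid <- sdv > 0
  tsnr <- ifelse(valid, mu / sdv, Inf)
  data.frame(tsnr = tsnr, valid = valid)
}
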
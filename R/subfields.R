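#' Per-row subfield extent profile of a flatmap
#'
#' For each anterior-posterior row of the flatmap, the fraction of the
#' distal-proximal extent occupied by each of the four subfields.
#'
#' @param map A `subfield_flatmap`.
#' @return n_ap x 4 matrix (columns named by subfield); every row sums
#'   to 1.
#' @export
subfield_extent_profile <- function(map) {
  stopifnot(inherits(map, "subfield_flatmap"))
  g <- map$grid
  prof <- matrix(0, g$n_ap, 4L, dimnames = list(NULL, map$levels))
  for (row in seq_len(g$n_ap)) {
    idx <- ((row - 1L) * g$n_pd + 1L):(row * g$n_pd)
    prof[row, ] <- tabulate(map$labels[idx], nbins = 4L) / g$n_pd
  }
  prof
}

# Linear interpolation of an extent profile onto n_target rows at matched
# normalized anterior-posterior positions.
resample_profile <- function(profile, n_target) {
  n <- nrow(profile)
  if (n == n_target) return(profile)
  xi <- (seq_len(n) - 0.5) / n
  xo <- (seq_len(n_target) - 0.5) / n_target
  out <- apply(profile, 2L, function(col) {
    stats::approx(xi, col, xout = xo, rule = 2)$y
  })
  out / rowSums(out)   # renormalize rows after interpolation
}

#' Similarity of two subfield flatmaps from their extent profiles
#'
#' Each anterior-posterior row is a point in the 4-dimensional space of
#' subfield extents; rows are compared by cosine distance
#' `d_i = 1 - cos(a_i, b_i)` and the similarity is `1 - mean(d_i)`
#' (equivalently, the mean row-wise cosine). Profiles with unequal row
#' counts are aligned by linear interpolation onto the smaller count
#' (logged via message).
#'
#' @param a,b Extent profiles (n_ap x 4 matrices, e.g. from
#'   [subfield_extent_profile()]).
#' @return Similarity in `[0, 1]`; 1 iff the profiles are row-wise
#'   proportional.
#' @export
flatmap_similarity <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), ncol(a) == 4L, ncol(b) == 4L)
  if (nrow(a) != nrow(b)) {
    n <- min(nrow(a), nrow(b))
    message("resampling extent profiles to ", n, " rows for comparison")
    a <- resample_profile(a, n)
    b <- resample_profile(b, n)
  }
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  if (any(na == 0) || any(nb == 0)) stop_invalid("zero extent row vector")
  cosines <- rowSums(a * b) / (na * nb)
  mean(cosines)   # = 1 - mean(1 - cos)
}

#' Relative size of each subfield compared with each other subfield
#'
#' Entry `(s, t)` is the total extent of subfield `s` divided by the total
#' extent of subfield `t` across the whole flatmap.
#'
#' @param profile An extent profile (n_ap x 4).
#' @return 4 x 4 reciprocal-symmetric ratio table; rows/columns of
#'   zero-extent subfields are NA with a warning.
#' @export
relative_subfield_size <- function(profile) {
  stopifnot(is.matrix(profile), ncol(profile) == 4L)
  totals <- colSums(profile)
  lv <- colnames(profile)
  if (is.null(lv)) lv <- SUBFIELD_LEVELS
  if (any(totals == 0)) {
    warning("zero-extent subfield(s): ",
            paste(lv[totals == 0], collapse = ", "), call. = FALSE)
    totals[totals == 0] <- NA_real_
  }
  ratios <- outer(totals, totals, `/`)
  dimnames(ratios) <- list(lv, lv)
  ratios
}

#' Percentage change between two relative-size tables
#'
#' `100 * (a - b) / b` element-wise; NA entries propagate.
#'
#' @param ratio_a,ratio_b Matching ratio tables from
#'   [relative_subfield_size()].
#' @return Table of percentage changes.
#' @export
percent_change <- function(ratio_a, ratio_b) {
  stopifnot(identical(dim(ratio_a), dim(ratio_b)))
  100 * (ratio_a - ratio_b) / ratio_b
}
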
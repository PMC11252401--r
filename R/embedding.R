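#' Normalized-angle affinity matrix
#'
#' Computes the similarity `1 - acos(cosine(row_i, row_j)) / pi` between
#' every pair of rows of a feature matrix (items x features), after
#' optionally zeroing the smallest fraction of entries in each row
#' (row-wise sparsification, mirroring the usual gradient-embedding
#' preprocessing of connectivity fingerprints). The result is symmetrized
#' as `(S + t(S)) / 2`, has unit diagonal and entries in `[0, 1]`.
#'
#' @param M Feature matrix, one item per row (e.g. connectivity
#'   fingerprints).
#' @param sparsity Fraction of smallest entries to zero per row before the
#'   kernel (default 0.9 keeps the top 10%).
#' @return An `affinity_matrix` (list with `values`, `kernel`, `sparsity`).
#' @examples
#' normalized_angle_affinity(diag(3), sparsity = 0)$values
#' @export
normalized_angle_affinity <- function(M, sparsity = 0.9) {
  stopifnot(is.matrix(M))
  sparsity <- check_scalar(sparsity, "sparsity", lower = 0, upper = 1 - 1e-12)
  n_zero <- floor(sparsity * ncol(M))
  if (n_zero > 0) {
    for (i in seq_len(nrow(M))) {
      ord <- order(M[i, ])[seq_len(n_zero)]
      M[i, ord] <- 0
    }
  }
  norms <- sqrt(rowSums(M^2))
  if (any(norms == 0)) {
    stop_invalid("zero row(s) after sparsification: ",
                 paste(which(norms == 0), collapse = ", "))
  }
  U <- M / norms
  C <- clip(tcrossprod(U), -1, 1)
  S <- 1 - acos(C) / pi
  S <- (S + t(S)) / 2
  diag(S) <- 1
  structure(
    list(values = S, kernel = "normalized-angle", sparsity = sparsity),
    class = "affinity_matrix"
  )
}

# Connected components of the affinity graph (edge where S > 0 off the
# diagonal); returns component sizes.
affinity_components <- function(S) {
  n <- nrow(S)
  adj <- S > 0
  diag(adj) <- FALSE
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    comp[start] <- cur
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  tabulate(comp)
}

# Leading k eigenpairs of a dense symmetric matrix. Dense solve up to
# `dense_cutoff` items; subspace (orthogonal) iteration with Rayleigh-Ritz
# above it. Contract: both routes agree within 1e-8.
sym_top_eigs <- function(M, k, dense_cutoff = 2000L, tol = 1e-10,
                         maxit = 20000L) {
  n <- nrow(M)
  if (n <= dense_cutoff) {
    e <- eigen(M, symmetric = TRUE)
    return(list(values = e$values[seq_len(k)],
                vectors = e$vectors[, seq_len(k), drop = FALSE]))
  }
  p <- min(n, k + 8L)
  V <- with_seed(20240716L, matrix(stats::rnorm(n * p), n, p))
  V <- qr.Q(qr(V))
  for (it in seq_len(maxit)) {
    V <- qr.Q(qr(M %*% V))
    MV <- M %*% V
    B <- crossprod(V, MV)
    eb <- eigen((B + t(B)) / 2, symmetric = TRUE)
    V <- V %*% eb$vectors
    vals <- eb$values
    # converge on the Ritz-pair residuals of the wanted eigenvectors
    MV <- MV %*% eb$vectors
    resid <- MV[, seq_len(k), drop = FALSE] -
      sweep(V[, seq_len(k), drop = FALSE], 2L, vals[seq_len(k)], `*`)
    if (max(sqrt(colSums(resid^2))) < tol) break
    if (it == maxit) {
      stop("eigensolver did not converge after ", maxit, " iterations")
    }
  }
  list(values = vals[seq_len(k)], vectors = V[, seq_len(k), drop = FALSE])
}

#' Diffusion-map embedding of an affinity matrix
#'
#' The standard diffusion-map recipe: degree-normalize the affinity by
#' `d^-alpha` on both sides, row-normalize to a Markov transition matrix,
#' take its leading eigenpairs, drop the trivial constant eigenvector
#' (eigenvalue 1), and return the next `n_components` right eigenvectors
#' scaled by `lambda / (1 - lambda)` (the automatic-diffusion-time
#' convention), sorted by eigenvalue. Each component's sign is fixed so
#' that its element of largest absolute value is positive.
#'
#' @param S An `affinity_matrix` or symmetric non-negative matrix.
#' @param n_components Number of non-trivial components to return.
#' @param alpha Diffusion normalization exponent in `[0, 1]` (default 0.5).
#' @param dense_cutoff Use a dense eigensolver up to this many items,
#'   subspace iteration above.
#' @return A `gradient_set`: `components` (items x k), `eigenvalues` (k,
#'   descending, in `[0, 1]` for connected graphs), `alpha`,
#'   `n_components`, `source`.
#' @export
diffusion_map_embed <- function(S, n_components = 10, alpha = 0.5,
                                dense_cutoff = 2000L) {
  A <- if (inherits(S, "affinity_matrix")) S$values else S
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (max(abs(A - t(A))) > 1e-8) stop_invalid("affinity matrix must be symmetric")
  if (min(A) < 0) stop_invalid("affinity entries must be non-negative")
  n <- nrow(A)
  n_components <- check_count(n_components, "n_components")
  if (n_components >= n) stop_invalid("n_components must be < number of items")
  alpha <- check_scalar(alpha, "alpha", lower = 0, upper = 1)
  sizes <- affinity_components(A)
  if (length(sizes) > 1L) {
    stop("disconnected affinity graph; component sizes: ",
         paste(sizes, collapse = ", "))
  }

  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  dw <- rowSums(W)
  # symmetric conjugate of the transition matrix D^-1 W
  Ms <- W / outer(sqrt(dw), sqrt(dw))
  e <- sym_top_eigs((Ms + t(Ms)) / 2, n_components + 1L,
                    dense_cutoff = dense_cutoff)
  lambdas <- clip(e$values[-1L], -1, 1 - 1e-12)
  # right eigenvectors of the transition matrix
  V <- e$vectors[, -1L, drop = FALSE] / sqrt(dw)
  V <- sweep(V, 2L, sqrt(colSums(V^2)), `/`)
  scale <- lambdas / (1 - lambdas)
  comps <- sweep(V, 2L, scale, `*`)
  for (j in seq_len(ncol(comps))) {
    if (comps[which.max(abs(comps[, j])), j] < 0) comps[, j] <- -comps[, j]
  }
  colnames(comps) <- paste0("G", seq_len(ncol(comps)))
  structure(
    list(components = comps, eigenvalues = lambdas, alpha = alpha,
         n_components = n_components, source = "diffusion-map"),
    class = "gradient_set"
  )
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("<gradient_set> %d items x %d components (%s); eigenvalues: %s\n",
              nrow(x$components), ncol(x$components), x$source,
              paste(signif(x$eigenvalues, 3), collapse = ", ")))
  invisible(x)
}

check_degenerate_affinity <- function(S) {
  if (min(S$values) > 1 - 1e-10) {
    stop_invalid("degenerate affinity: all items identical (affinity ",
                 "uniformly 1); embedding is undefined")
  }
  S
}

#' Hippocampal connectivity gradients
#'
#' Embeds the hippocampal vertices based on their cortical connectivity
#' fingerprints: normalized-angle affinity over the rows of a
#' hippocampus x cortex connectivity matrix, followed by diffusion-map
#' embedding. The first component typically recovers the
#' anterior-posterior functional axis.
#'
#' @param C A `connectivity_matrix` (hippocampal rows x cortical columns)
#'   or a plain matrix.
#' @param n_components Components to return (default 10).
#' @param sparsity,alpha Affinity/embedding settings.
#' @return A `gradient_set` over hippocampal vertices.
#' @export
hippocampal_gradients <- function(C, n_components = 10, sparsity = 0.9,
                                  alpha = 0.5) {
  M <- if (inherits(C, "connectivity_matrix")) C$values else C
  S <- check_degenerate_affinity(normalized_angle_affinity(M, sparsity))
  g <- diffusion_map_embed(S, n_components = n_components, alpha = alpha)
  g$source <- "hippocampal-gradients"
  g
}

#' Joint cross-species embedding of cortico-hippocampal connectivity
#'
#' Stacks the cortical parcels of both species as items (features = their
#' hippocampal connectivity fingerprints, which live on the shared matched
#' flatmap), embeds them together, and splits the component values back
#' into the two species' parcel sets. Homologous parcels land close in the
#' joint gradient space to the extent their hippocampal fingerprints agree.
#'
#' @param C_a,C_b Hippocampus x parcels `connectivity_matrix` (or plain
#'   matrix) for each species; hippocampal vertex sets must be identical in
#'   size and order.
#' @param n_components,sparsity,alpha Embedding settings.
#' @return List with `a`, `b` (items x k component matrices per species),
#'   `eigenvalues`, and the full joint `gradient_set`.
#' @export
joint_cross_species_embed <- function(C_a, C_b, n_components = 10,
                                      sparsity = 0.9, alpha = 0.5) {
  Ma <- if (inherits(C_a, "connectivity_matrix")) C_a$values else C_a
  Mb <- if (inherits(C_b, "connectivity_matrix")) C_b$values else C_b
  if (nrow(Ma) != nrow(Mb)) {
    stop_invalid("hippocampal dimensions differ (", nrow(Ma), " vs ",
                 nrow(Mb), "); a matched flatmap is required")
  }
  X <- rbind(t(Ma), t(Mb))   # items = parcels of species a then b
  S <- check_degenerate_affinity(normalized_angle_affinity(X, sparsity))
  g <- diffusion_map_embed(S, n_components = n_components, alpha = alpha)
  g$source <- "joint-cross-species"
  pa <- ncol(Ma)
  list(
    a = g$components[seq_len(pa), , drop = FALSE],
    b = g$components[pa + seq_len(ncol(Mb)), , drop = FALSE],
    eigenvalues = g$eigenvalues,
    joint = g
  )
}

#' Cortico-cortical connectivity gradients
#'
#' Square parcel x parcel Fisher-z connectivity per subject, group
#' averaged, then affinity + diffusion-map embedding. The leading
#' components are the canonical macroscale cortical gradients used as
#' candidates in gradient matching.
#'
#' @param cortex_ts_list List of per-subject cortical `timeseries` (or
#'   matrices, parcels x time).
#' @param n_components,sparsity,alpha Embedding settings.
#' @return A `gradient_set` over parcels.
#' @export
corticocortical_gradients <- function(cortex_ts_list, n_components = 10,
                                      sparsity = 0.9, alpha = 0.5) {
  if (!length(cortex_ts_list)) stop_invalid("empty subject list")
  mats <- lapply(cortex_ts_list, function(ts) connectivity_matrix(ts, ts))
  avg <- group_average(mats)
  S <- check_degenerate_affinity(normalized_angle_affinity(avg$values, sparsity))
  g <- diffusion_map_embed(S, n_components = n_components, alpha = alpha)
  g$source <- "cortico-cortical"
  g
}
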
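# ---- validation helpers ------------------------------------------------

check_square_symmetric <- function(A, name = deparse(substitute(A)),
                                   tol = 1e-10) {
  if (!is.matrix(A) || !is.numeric(A))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (nrow(A) != ncol(A))
    stop(sprintf("'%s' must be square (got %d x %d)", name,
                 nrow(A), ncol(A)), call. = FALSE)
  if (anyNA(A))
    stop(sprintf("'%s' contains missing values", name), call. = FALSE)
  dev <- abs(A - t(A))
  if (max(dev) > tol) {
    idx <- which(dev == max(dev), arr.ind = TRUE)[1, ]
    stop(sprintf("'%s' is not symmetric: entry (%d, %d) differs from (%d, %d) by %.3g",
                 name, idx[1], idx[2], idx[2], idx[1], max(dev)),
         call. = FALSE)
  }
  invisible(A)
}

check_adjacency <- function(A, name = deparse(substitute(A))) {
  check_square_symmetric(A, name)
  if (any(A < 0))
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
  if (any(diag(A) != 0))
    stop(sprintf("'%s' must have a zero diagonal", name), call. = FALSE)
  invisible(A)
}

# ---- distances and proximities -----------------------------------------

#' Normalize a distance matrix to the unit interval
#'
#' Rescales a symmetric pairwise-distance matrix so that all entries lie in
#' \eqn{[0, 1]}, dividing every entry by the largest distance in the matrix.
#' This removes the overall size scale (for example differences in head size
#' between subjects) while preserving the relative geometry of the regions.
#'
#' @param D symmetric \eqn{p \times p} numeric matrix of non-negative
#'   pairwise distances with a zero diagonal (Euclidean or geodesic units).
#' @return A \eqn{p \times p} matrix of unitless normalized distances; the
#'   maximum entry equals 1. Dimnames of `D` are preserved.
#' @examples
#' D <- rbind(c(0, 10, 20), c(10, 0, 40), c(20, 40, 0))
#' normalize_distances(D)
#' @export
normalize_distances <- function(D) {
  check_adjacency(D, "D")
  if (nrow(D) < 2) stop("'D' must have at least 2 rows", call. = FALSE)
  mx <- max(D)
  if (mx <= 0)
    stop("degenerate distance matrix: all entries are zero, cannot normalize",
         call. = FALSE)
  D / mx
}

#' Convert normalized distances to a proximity (adjacency) matrix
#'
#' Applies the Gaussian similarity kernel \eqn{a_{ij} = \exp(-h \tilde d_{ij}^2)}
#' to the off-diagonal entries of a normalized distance matrix. Larger `h`
#' sharpens the contrast between nearby and distant regions; the diagonal is
#' kept at zero so the result is a true adjacency matrix.
#'
#' @param Dn normalized distance matrix (entries in \eqn{[0, 1]}, zero
#'   diagonal), as produced by [normalize_distances()].
#' @param h positive kernel bandwidth controlling how fast proximity decays
#'   with distance.
#' @return Symmetric \eqn{p \times p} proximity matrix with zero diagonal and
#'   off-diagonal entries in \eqn{(0, 1]}.
#' @export
proximity_from_distance <- function(Dn, h) {
  check_adjacency(Dn, "Dn")
  if (max(Dn) > 1)
    stop("'Dn' must be normalized to [0, 1]; call normalize_distances() first",
         call. = FALSE)
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0)
    stop("'h' must be a single positive number", call. = FALSE)
  A <- exp(-h * Dn^2)
  diag(A) <- 0
  A
}

#' Node degrees of a weighted adjacency matrix
#'
#' @param A symmetric non-negative adjacency matrix (connectivity or
#'   proximity).
#' @return Numeric vector of row sums \eqn{s_i = \sum_j a_{ij}}.
#' @export
degrees <- function(A) {
  check_adjacency(A, "A")
  rowSums(A)
}

#' Graph Laplacians of an adjacency matrix
#'
#' `unnormalized_laplacian()` returns \eqn{Q = S - A} with
#' \eqn{S = \mathrm{diag}(s_1, \dots, s_p)} the degree matrix; its quadratic
#' form satisfies \eqn{b^\top Q b = \sum_{i<j} a_{ij} (b_i - b_j)^2}, so it
#' penalizes differences between coefficients of strongly connected regions.
#' `normalized_laplacian()` returns the degree-normalized version with unit
#' diagonal and off-diagonal entries \eqn{-a_{ij} / \sqrt{s_i s_j}}; its
#' eigenvalues lie in \eqn{[0, 2]}, which puts connectivity- and
#' proximity-based penalties on a comparable scale.
#'
#' Isolated nodes (degree zero, possible in sparse connectivity matrices) get
#' an identity row in the normalized Laplacian: diagonal 1, off-diagonals 0.
#' The penalty then degenerates to a pure ridge penalty for that coefficient
#' and the matrix remains positive semi-definite.
#'
#' @param A symmetric non-negative adjacency matrix with zero diagonal.
#' @return A \eqn{p \times p} symmetric positive semi-definite matrix.
#' @export
normalized_laplacian <- function(A) {
  check_adjacency(A, "A")
  s <- rowSums(A)
  pos <- s > 0
  inv_sqrt <- ifelse(pos, 1 / sqrt(s), 0)
  Q <- -A * tcrossprod(inv_sqrt)
  diag(Q) <- 1            # identity row for isolated nodes as well
  # symmetrize against rounding in the outer product
  (Q + t(Q)) / 2
}

#' @rdname normalized_laplacian
#' @export
unnormalized_laplacian <- function(A) {
  check_adjacency(A, "A")
  Q <- -A
  diag(Q) <- rowSums(A)
  Q
}

# ---- connectivity dissimilarity and perturbation -----------------------

#' Dissimilarity between two connectivity matrices
#'
#' Counts the entries at which an observed connectivity matrix differs from a
#' reference ("true") matrix and normalizes by twice the number of positive
#' entries of the reference:
#' \deqn{\mathrm{diss}(A_{obs}, A_{true}) =
#'   \frac{\#\{(i,j): |A_{obs,ij} - A_{true,ij}| > 0\}}
#'        {2\,\#\{(i,j): A_{true,ij} > 0\}}.}
#' The comparison is exact (strict inequality at machine precision): the
#' matrices are stored values, not computed quantities.
#'
#' @param A_obs,A_true symmetric non-negative connectivity matrices of the
#'   same dimension; `A_true` must have at least one positive entry.
#' @return Non-negative scalar; 0 iff the matrices are identical.
#' @export
dissimilarity <- function(A_obs, A_true) {
  check_adjacency(A_obs, "A_obs")
  check_adjacency(A_true, "A_true")
  if (!all(dim(A_obs) == dim(A_true)))
    stop("'A_obs' and 'A_true' must have the same dimensions", call. = FALSE)
  n_pos <- sum(A_true > 0)
  if (n_pos == 0)
    stop("'A_true' has no positive entries; dissimilarity is undefined",
         call. = FALSE)
  sum(abs(A_obs - A_true) > 0) / (2 * n_pos)
}

#' Perturb a connectivity matrix to a target dissimilarity
#'
#' Produces an "observed" connectivity matrix that only partially contains
#' the information of the true matrix, at a prescribed [dissimilarity()]
#' level. The required number of symmetric entry pairs
#' \eqn{k = \mathrm{round}(t \cdot E)} (with \eqn{E} the number of positive
#' entries of `A_true`) is chosen uniformly at random among all off-diagonal
#' pairs; each chosen pair is toggled — a positive entry is zeroed, a zero
#' entry receives a weight resampled uniformly from the positive entries of
#' `A_true`. Achievable dissimilarities are therefore multiples of
#' \eqn{1/E}; the value nearest `target_diss` is hit exactly.
#'
#' @param A_true symmetric non-negative connectivity matrix with at least one
#'   positive entry.
#' @param target_diss requested dissimilarity in \eqn{[0, 1]}.
#' @param rng_seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return A perturbed connectivity matrix, symmetric, non-negative, zero
#'   diagonal, with `dissimilarity(out, A_true)` equal to the achievable value
#'   nearest `target_diss`.
#' @export
perturb_connectivity <- function(A_true, target_diss, rng_seed = NULL) {
  check_adjacency(A_true, "A_true")
  if (!is.numeric(target_diss) || length(target_diss) != 1 ||
      target_diss < 0 || target_diss > 1)
    stop("'target_diss' must be a single number in [0, 1]", call. = FALSE)
  pos_weights <- A_true[upper.tri(A_true) & A_true > 0]
  E <- 2 * length(pos_weights)
  if (E == 0)
    stop("'A_true' has no positive entries; cannot perturb", call. = FALSE)
  k <- round(target_diss * E)
  if (k == 0) return(A_true)
  p <- nrow(A_true)
  n_pairs <- p * (p - 1) / 2
  if (k > n_pairs)
    stop(sprintf(paste("target dissimilarity %.3g needs %d entry-pair toggles",
                       "but only %d off-diagonal pairs exist"),
                 target_diss, k, n_pairs), call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ut <- which(upper.tri(A_true), arr.ind = TRUE)
  chosen <- ut[sample.int(n_pairs, k), , drop = FALSE]
  A <- A_true
  for (r in seq_len(k)) {
    i <- chosen[r, 1]; j <- chosen[r, 2]
    if (A[i, j] > 0) {
      A[i, j] <- A[j, i] <- 0
    } else {
      w <- pos_weights[sample.int(length(pos_weights), 1)]
      A[i, j] <- A[j, i] <- w
    }
  }
  A
}
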
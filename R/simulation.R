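# Synthetic-data framework: block-structured connectivity, cortex-like
# coordinates, the generative model for b, and the rMSE / bias-variance
# comparison of ridge, connectivity-penalized and distance-penalized fits.

#' Configuration for synthetic brain-like structure
#'
#' Describes the sparse block-structured connectivity graph and the region
#' coordinates from which pairwise distances are computed. Connected blocks
#' of fewer than four regions carry too little graph information to be
#' useful, so block sizes below 4 are rejected.
#'
#' @param p number of regions.
#' @param block_sizes integer vector summing to `p`, each entry at least 4;
#'   if `NULL`, `p` is split into blocks of about 6 regions.
#' @param edge_density_within probability in (0, 1] of each within-block
#'   edge beyond the connected ring backbone every block receives.
#' @param weight_range positive range from which edge weights are drawn
#'   uniformly (connection-strength units).
#' @param coordinate_model `"cube"` draws region centroids uniformly in a
#'   60 mm cube (Euclidean distances); `"sphere_patch"` draws them on a
#'   spherical cap of radius 80 mm and uses great-circle distances, a
#'   surrogate for geodesic distances along the cortical surface (it
#'   preserves geodesic >= Euclidean-chord ordering).
#' @param seed integer seed making the generated structure reproducible.
#' @return A list of class `"structure_config"`.
#' @export
structure_config <- function(p, block_sizes = NULL,
                             edge_density_within = 0.5,
                             weight_range = c(0.5, 1.5),
                             coordinate_model = c("cube", "sphere_patch"),
                             seed = 1) {
  coordinate_model <- match.arg(coordinate_model)
  if (is.null(block_sizes)) {
    n_blocks <- max(1, round(p / 6))
    base <- p %/% n_blocks
    block_sizes <- rep(base, n_blocks)
    extra <- p - sum(block_sizes)
    if (extra > 0) block_sizes[seq_len(extra)] <- block_sizes[seq_len(extra)] + 1
  }
  if (sum(block_sizes) != p)
    stop("block_sizes must sum to p", call. = FALSE)
  if (any(block_sizes < 4))
    stop("every block must contain at least 4 regions", call. = FALSE)
  if (!is.numeric(edge_density_within) || edge_density_within <= 0 ||
      edge_density_within > 1)
    stop("edge_density_within must lie in (0, 1]", call. = FALSE)
  if (length(weight_range) != 2 || any(weight_range <= 0) ||
      weight_range[1] > weight_range[2])
    stop("weight_range must be a positive increasing interval", call. = FALSE)
  structure(list(p = p, block_sizes = block_sizes,
                 edge_density_within = edge_density_within,
                 weight_range = weight_range,
                 coordinate_model = coordinate_model,
                 seed = as.integer(seed)),
            class = "structure_config")
}

#' Pairwise distances from region coordinates
#'
#' @param coords `p x k` coordinate matrix (mm).
#' @param metric `"euclidean"` for straight-line distances;
#'   `"great_circle"` treats rows as points on a common sphere centred at
#'   the origin and returns arc lengths.
#' @return Symmetric `p x p` distance matrix with zero diagonal.
#' @export
distances_from_coords <- function(coords,
                                  metric = c("euclidean", "great_circle")) {
  metric <- match.arg(metric)
  coords <- as.matrix(coords)
  if (metric == "euclidean") {
    D <- as.matrix(stats::dist(coords))
  } else {
    r <- sqrt(rowSums(coords^2))
    if (any(r == 0)) stop("great-circle metric needs nonzero radii",
                          call. = FALSE)
    unit <- coords / r
    cosang <- pmin(pmax(tcrossprod(unit), -1), 1)
    D <- mean(r) * acos(cosang)
  }
  dimnames(D) <- NULL
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Generate a synthetic connectivity matrix and distance matrix
#'
#' Emulates the two structural inputs of a cortical-hemisphere analysis: a
#' sparse block-diagonal structural-connectivity adjacency (regions connect
#' only within anatomical blocks; each block gets a connected ring backbone
#' plus random extra edges) and a dense matrix of pairwise distances between
#' random region centroids.
#'
#' @param cfg a [structure_config()] object.
#' @return A list with elements `connectivity` (`p x p` weighted adjacency),
#'   `distance` (`p x p` distance matrix), `coords`, `blocks` (block index
#'   per region) and `region_labels`.
#' @export
generate_structure <- function(cfg) {
  stopifnot(inherits(cfg, "structure_config"))
  set.seed(cfg$seed)
  p <- cfg$p
  A <- matrix(0, p, p)
  blocks <- rep(seq_along(cfg$block_sizes), cfg$block_sizes)
  draw_w <- function(k) runif(k, cfg$weight_range[1], cfg$weight_range[2])
  for (bl in seq_along(cfg$block_sizes)) {
    idx <- which(blocks == bl)
    # ring backbone keeps each block connected
    ring <- cbind(idx, idx[c(seq_along(idx)[-1], 1)])
    for (r in seq_len(nrow(ring))) {
      w <- draw_w(1)
      A[ring[r, 1], ring[r, 2]] <- A[ring[r, 2], ring[r, 1]] <- w
    }
    pairs <- which(upper.tri(matrix(0, length(idx), length(idx))),
                   arr.ind = TRUE)
    for (r in seq_len(nrow(pairs))) {
      i <- idx[pairs[r, 1]]; j <- idx[pairs[r, 2]]
      if (A[i, j] == 0 && runif(1) < cfg$edge_density_within) {
        w <- draw_w(1)
        A[i, j] <- A[j, i] <- w
      }
    }
  }
  if (cfg$coordinate_model == "cube") {
    coords <- matrix(runif(p * 3, 0, 60), p, 3)
    D <- distances_from_coords(coords, "euclidean")
  } else {
    theta <- runif(p, 0, pi / 3)          # polar angle within the cap
    phi <- runif(p, 0, 2 * pi)
    R <- 80
    coords <- R * cbind(sin(theta) * cos(phi), sin(theta) * sin(phi),
                        cos(theta))
    D <- distances_from_coords(coords, "great_circle")
  }
  labels <- sprintf("region_%02d", seq_len(p))
  dimnames(A) <- list(labels, labels)
  dimnames(D) <- list(labels, labels)
  list(connectivity = A, distance = D, coords = coords, blocks = blocks,
       region_labels = labels)
}

#' Covariance of the true penalized coefficients
#'
#' The generative model draws \eqn{b \sim N(0, \sigma_b^2 B_{true}^{-1})}
#' with \eqn{B_{true} = r_C Q_{C,true} + r_D Q_{D,true} + r_R I} and
#' \eqn{r_D = 1 - r_C}, so `r_C` controls how much of the coefficient
#' structure comes from connectivity versus spatial proximity.
#'
#' @param QC_true,QD_true normalized Laplacians of the true connectivity and
#'   proximity graphs.
#' @param r_C fraction in \eqn{[0, 1]} of structure attributed to
#'   connectivity.
#' @param r_R small positive ridge weight keeping \eqn{B_{true}} invertible.
#' @param sigma2_b marginal signal-strength variance.
#' @return Symmetric positive-definite `p x p` covariance matrix
#'   \eqn{\sigma_b^2 B_{true}^{-1}}.
#' @export
build_btrue_covariance <- function(QC_true, QD_true, r_C, r_R, sigma2_b) {
  stopifnot(r_C >= 0, r_C <= 1, sigma2_b > 0)
  B <- r_C * QC_true + (1 - r_C) * QD_true + diag(r_R, nrow(QC_true))
  R <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(R))
    stop("B_true is singular; use a positive r_R", call. = FALSE)
  sigma2_b * chol2inv(R)
}

#' Simulation configuration
#'
#' Collects the generative settings of the estimator-comparison study:
#' Gaussian designs, structured coefficients and Gaussian noise. Defaults
#' are the study conditions — `n = 400` observations, `m = 2` unpenalized
#' covariates with true coefficients zero, dissimilarity 0.25 between the
#' true and the observed connectivity, proximity bandwidth `h = 5`
#' (Euclidean; 100 for the great-circle surrogate of geodesic distances)
#' and 100 replicates.
#'
#' @param p number of penalized regions (must match the structure).
#' @param n observations per replicate.
#' @param m number of unpenalized covariates.
#' @param sigma2_b,sigma2_eps signal and noise variances.
#' @param r_C fraction of coefficient structure from connectivity
#'   (`r_D = 1 - r_C` comes from proximity).
#' @param r_R ridge weight in \eqn{B_{true}} (kept small so the two graph
#'   terms dominate while \eqn{B_{true}} stays invertible).
#' @param diss_target dissimilarity between observed and true connectivity.
#' @param h proximity bandwidth used to generate the data.
#' @param h_fit bandwidth used when fitting (defaults to `h`; set off `h`
#'   for sensitivity analyses).
#' @param n_reps number of Monte-Carlo replicates.
#' @param seed master seed; every replicate derives its own stream from it.
#' @param methods subset of `c("ridge", "ripeer", "dispeer")` to compare.
#' @param control optimizer control passed to [fit_dispeer()].
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(p, n = 400, m = 2, sigma2_b = 0.01,
                              sigma2_eps = 1, r_C = 0.1, r_R = 0.01,
                              diss_target = 0.25, h = 5, h_fit = h,
                              n_reps = 100, seed = 1,
                              methods = c("ridge", "ripeer", "dispeer"),
                              control = dispeer_control()) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(n_reps >= 1, r_C >= 0, r_C <= 1, h > 0, h_fit > 0,
            sigma2_b > 0, sigma2_eps >= 0, r_R >= 0,
            diss_target >= 0, diss_target <= 1)
  structure(list(p = p, n = n, m = m, sigma2_b = sigma2_b,
                 sigma2_eps = sigma2_eps, r_C = r_C, r_D = 1 - r_C,
                 r_R = r_R, diss_target = diss_target, h = h, h_fit = h_fit,
                 n_reps = n_reps, seed = as.integer(seed), methods = methods,
                 control = control),
            class = "simulation_config")
}

#' Generate one synthetic data replicate
#'
#' Draws `Z` with iid \eqn{N(0, I_p)} rows, `X` with iid \eqn{N(0, I_m)}
#' rows, coefficients \eqn{b \sim N(0, \sigma_b^2 B_{true}^{-1})}, sets
#' \eqn{\beta = 0}, and returns
#' \eqn{y = X\beta + Zb + \varepsilon}, \eqn{\varepsilon \sim N(0,
#' \sigma_\varepsilon^2 I_n)}. Uses the current RNG stream; seed it (or let
#' [run_experiment()] do so) for reproducibility.
#'
#' @param cfg a [simulation_config()] object.
#' @param QC_true,QD_true true normalized Laplacians defining
#'   \eqn{B_{true}}.
#' @return A list with `data` (a [regression_data()] object), `b_true` and
#'   `beta_true`.
#' @export
generate_replicate <- function(cfg, QC_true, QD_true) {
  stopifnot(inherits(cfg, "simulation_config"))
  Sigma_b <- build_btrue_covariance(QC_true, QD_true, cfg$r_C, cfg$r_R,
                                    cfg$sigma2_b)
  Z <- matrix(rnorm(cfg$n * cfg$p), cfg$n, cfg$p)
  X <- matrix(rnorm(cfg$n * cfg$m), cfg$n, cfg$m)
  b <- drop(MASS::mvrnorm(1, rep(0, cfg$p), Sigma_b))
  beta <- rep(0, cfg$m)
  eps <- rnorm(cfg$n, 0, sqrt(cfg$sigma2_eps))
  y <- drop(X %*% beta + Z %*% b + eps)
  list(data = regression_data(y, X, Z), b_true = b, beta_true = beta)
}

#' Relative mean squared error of a coefficient estimate
#'
#' \deqn{\mathrm{rMSE}(\hat b) = \|\hat b - b\|_2^2 / \|b\|_2^2.}
#' A value of 1 corresponds to the trivial all-zero estimator.
#'
#' @param b_hat,b_true numeric vectors of equal length; `b_true` must be
#'   nonzero.
#' @return Non-negative scalar.
#' @export
rmse <- function(b_hat, b_true) {
  if (length(b_hat) != length(b_true))
    stop("b_hat and b_true must have equal length", call. = FALSE)
  denom <- sum(b_true^2)
  if (denom == 0)
    stop("b_true is the zero vector; relative MSE is undefined",
         call. = FALSE)
  sum((b_hat - b_true)^2) / denom
}

#' Empirical bias-variance decomposition of estimation errors
#'
#' Works on the per-replicate errors \eqn{e_r = \hat b_r - b_r}. For every
#' coefficient the empirical mean squared error splits exactly into the
#' (population-divisor) variance of the errors plus the squared mean error,
#' so `mse = variance + squared_bias` holds by construction. Both the
#' per-coefficient table and the totals (summed over coefficients) are
#' returned.
#'
#' @param estimates replicates-by-coefficients matrix (or list of vectors)
#'   of estimates.
#' @param b_true_list matching matrix/list of true coefficient vectors, or a
#'   single vector reused for all replicates.
#' @return A list with `per_coef` (data frame with columns `variance`,
#'   `squared_bias`, `mse`) and `total` (named vector of their sums).
#' @export
bias_variance <- function(estimates, b_true_list) {
  if (is.list(estimates)) estimates <- do.call(rbind, estimates)
  estimates <- as.matrix(estimates)
  if (is.list(b_true_list)) b_true_list <- do.call(rbind, b_true_list)
  if (is.vector(b_true_list))
    b_true_list <- matrix(b_true_list, nrow(estimates), length(b_true_list),
                          byrow = TRUE)
  if (!all(dim(estimates) == dim(b_true_list)))
    stop("estimates and truths must have matching dimensions", call. = FALSE)
  if (nrow(estimates) < 2)
    stop("need at least 2 replicates for a bias-variance decomposition",
         call. = FALSE)
  err <- estimates - b_true_list
  mean_err <- colMeans(err)
  mse <- colMeans(err^2)
  squared_bias <- mean_err^2
  variance <- mse - squared_bias
  per_coef <- data.frame(variance = variance, squared_bias = squared_bias,
                         mse = mse)
  list(per_coef = per_coef,
       total = c(variance = sum(variance), squared_bias = sum(squared_bias),
                 mse = sum(mse)))
}

#' Run the seeded estimator-comparison experiment
#'
#' For each replicate: perturb the true connectivity to the configured
#' dissimilarity, generate data from the structured coefficient model, fit
#' the selected methods (ridge; connectivity-penalized; connectivity- plus
#' proximity-penalized), and record the relative MSE of \eqn{\hat b}. Fits
#' use the observed (perturbed) connectivity Laplacian and the proximity
#' Laplacian built with bandwidth `h_fit`, while data generation uses the
#' true connectivity and bandwidth `h`. The run is fully deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [simulation_config()] object.
#' @param structure a [generate_structure()] result (or any list with
#'   `connectivity` and `distance` matrices over `cfg$p` regions).
#' @return An object of class `"dispeer_experiment"`: per-replicate rMSE
#'   matrix, per-method median rMSE, the percentage rMSE decrease of the
#'   distance-informed fit relative to the connectivity-only fit,
#'   bias-variance decompositions, fitted penalty weights, and the config.
#' @export
run_experiment <- function(cfg, structure) {
  stopifnot(inherits(cfg, "simulation_config"))
  A_C_true <- structure$connectivity
  if (nrow(A_C_true) != cfg$p)
    stop("structure and config disagree on the number of regions",
         call. = FALSE)
  Dn <- normalize_distances(structure$distance)
  QC_true <- normalized_laplacian(A_C_true)
  QD_true <- normalized_laplacian(proximity_from_distance(Dn, cfg$h))
  QD_fit <- normalized_laplacian(proximity_from_distance(Dn, cfg$h_fit))

  methods <- cfg$methods
  rmse_mat <- matrix(NA_real_, cfg$n_reps, length(methods),
                     dimnames = list(NULL, methods))
  est <- lapply(methods, function(m) matrix(NA_real_, cfg$n_reps, cfg$p))
  names(est) <- methods
  truths <- matrix(NA_real_, cfg$n_reps, cfg$p)
  lambda_arr <- lapply(methods, function(m)
    matrix(NA_real_, cfg$n_reps, 3,
           dimnames = list(NULL, c("lambda_C", "lambda_D", "lambda_R"))))
  names(lambda_arr) <- methods

  set.seed(cfg$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, cfg$n_reps)
  for (r in seq_len(cfg$n_reps)) {
    set.seed(rep_seeds[r])
    A_C_obs <- perturb_connectivity(A_C_true, cfg$diss_target)
    QC_obs <- normalized_laplacian(A_C_obs)
    repl <- generate_replicate(cfg, QC_true, QD_true)
    truths[r, ] <- repl$b_true
    for (m in methods) {
      f <- switch(m,
        ridge   = fit_dispeer(repl$data, method = "ridge",
                              control = cfg$control),
        ripeer  = fit_dispeer(repl$data, QC = QC_obs, method = "ripeer",
                              control = cfg$control),
        dispeer = fit_dispeer(repl$data, QC = QC_obs, QD = QD_fit,
                              method = "dispeer", control = cfg$control))
      est[[m]][r, ] <- f$b_hat
      rmse_mat[r, m] <- rmse(f$b_hat, repl$b_true)
      lambda_arr[[m]][r, ] <- f$lambdas
    }
  }

  medians <- apply(rmse_mat, 2, median)
  decrease_pct <- if (all(c("ripeer", "dispeer") %in% methods))
    100 * (medians[["ripeer"]] - medians[["dispeer"]]) / medians[["ripeer"]]
  else NA_real_
  bv <- if (cfg$n_reps >= 2)
    lapply(est, bias_variance, b_true_list = truths)
  else NULL
  structure(list(rmse = rmse_mat, medians = medians,
                 decrease_pct = decrease_pct, bias_variance = bv,
                 lambdas = lambda_arr, config = cfg),
            class = "dispeer_experiment")
}

#' @export
print.dispeer_experiment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Estimator comparison: %d replicates, n = %d, p = %d\n",
              cfg$n_reps, cfg$n, cfg$p))
  cat(sprintf("  r_C = %.2f, sigma2_b/sigma2_eps = %.3g, h = %g (fit h = %g)\n",
              cfg$r_C, cfg$sigma2_b / cfg$sigma2_eps, cfg$h, cfg$h_fit))
  cat("  median rMSE:\n")
  for (m in names(x$medians))
    cat(sprintf("    %-8s %.4f\n", m, x$medians[[m]]))
  if (is.finite(x$decrease_pct))
    cat(sprintf("  rMSE decrease (distance-informed vs connectivity-only): %.1f%%\n",
                x$decrease_pct))
  invisible(x)
}
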
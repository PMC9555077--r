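# Estimation core: linear model y = X beta + Z b + eps with the penalized
# coefficients b shrunk through a quadratic penalty
#   b' (lambda_C Qc + lambda_D Qd + lambda_R I) b.
# Penalty weights are tuned by maximizing the marginal likelihood of the
# equivalent mixed model with prior b ~ N(0, sigma_eps^2 B_lambda^{-1}).

#' Bundle a response and design matrices for penalized fitting
#'
#' @param y numeric response vector of length `n`.
#' @param X `n x m` design matrix of unpenalized covariates (demographics
#'   such as gender and age in the cortical application); must have full
#'   column rank with `n > m`.
#' @param Z `n x p` design matrix of penalized covariates (for example
#'   standardized region-level cortical volumes).
#' @return An object of class `"regression_data"` (a validated list with
#'   elements `y`, `X`, `Z`).
#' @export
regression_data <- function(y, X, Z) {
  y <- as.numeric(y)
  X <- as.matrix(X); Z <- as.matrix(Z)
  n <- length(y)
  if (nrow(X) != n || nrow(Z) != n)
    stop(sprintf("row mismatch: length(y) = %d, nrow(X) = %d, nrow(Z) = %d",
                 n, nrow(X), nrow(Z)), call. = FALSE)
  if (anyNA(y) || anyNA(X) || anyNA(Z))
    stop("missing values are not allowed in y, X or Z", call. = FALSE)
  if (n <= ncol(X))
    stop("need more observations than unpenalized covariates", call. = FALSE)
  rk <- qr(X)$rank
  if (rk < ncol(X))
    stop(sprintf("X is rank deficient: rank %d < %d columns", rk, ncol(X)),
         call. = FALSE)
  structure(list(y = y, X = X, Z = Z), class = "regression_data")
}

#' Project the response and penalized design onto the complement of X
#'
#' Removes the unpenalized covariates by applying the residual-maker
#' projection \eqn{P = I - X (X^\top X)^{-1} X^\top} to both `y` and the
#' columns of `Z`. The penalty-weight estimation then works entirely in the
#' projected model \eqn{y_P = \tilde Z b + \tilde\varepsilon}.
#'
#' @param data a [regression_data()] object.
#' @return A list of class `"projected_data"` with elements `y_P` (projected
#'   response), `Z_tilde` (projected penalized design) and `n`, `p`.
#' @export
project_out_fixed <- function(data) {
  stopifnot(inherits(data, "regression_data"))
  qx <- qr(data$X)
  if (qx$rank < ncol(data$X))
    stop(sprintf("X is rank deficient: rank %d < %d columns",
                 qx$rank, ncol(data$X)), call. = FALSE)
  y_P <- qr.resid(qx, data$y)
  Z_tilde <- qr.resid(qx, data$Z)
  structure(list(y_P = y_P, Z_tilde = Z_tilde,
                 n = length(y_P), p = ncol(Z_tilde)),
            class = "projected_data")
}

#' Combined penalty matrix
#'
#' Forms \eqn{B_\lambda = \lambda_C \tilde Q_C + \lambda_D \tilde Q_D +
#' \lambda_R I}. Laplacians that are not part of the model may be `NULL`;
#' their weights are then ignored.
#'
#' @param w named numeric vector of penalty weights with elements
#'   `lambda_C`, `lambda_D`, `lambda_R` (all non-negative).
#' @param QC,QD normalized Laplacian penalty matrices, or `NULL`.
#' @param p number of penalized coefficients; inferred from `QC`/`QD` when
#'   either is supplied.
#' @return Symmetric `p x p` penalty matrix; positive definite whenever
#'   `lambda_R > 0`.
#' @export
penalty_matrix <- function(w, QC = NULL, QD = NULL,
                           p = if (!is.null(QC)) nrow(QC) else nrow(QD)) {
  w <- as_penalty_weights(w)
  if (is.null(p)) stop("'p' is required when both QC and QD are NULL",
                       call. = FALSE)
  B <- diag(w[["lambda_R"]], p)
  if (!is.null(QC)) B <- B + w[["lambda_C"]] * QC
  if (!is.null(QD)) B <- B + w[["lambda_D"]] * QD
  B
}

as_penalty_weights <- function(w) {
  if (is.list(w)) w <- unlist(w)
  full <- c(lambda_C = 0, lambda_D = 0, lambda_R = 0)
  if (is.null(names(w))) {
    if (length(w) != 3)
      stop("unnamed penalty weights must have length 3 (C, D, R)",
           call. = FALSE)
    names(w) <- names(full)
  }
  unknown <- setdiff(names(w), names(full))
  if (length(unknown))
    stop("unknown penalty weight(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  full[names(w)] <- w
  if (any(!is.finite(full)) || any(full < 0))
    stop("penalty weights must be finite and non-negative", call. = FALSE)
  full
}

# Shared Woodbury-style workspace: everything the likelihood needs reduces
# to p x p algebra through ZtZ and Zty (n enters only through yty and the
# profiled variance).
proj_crossprods <- function(proj) {
  list(ZtZ = crossprod(proj$Z_tilde),
       Zty = drop(crossprod(proj$Z_tilde, proj$y_P)),
       yty = sum(proj$y_P^2),
       n = proj$n, p = proj$p)
}

# Core evaluation for a crossprod workspace; returns the -2 profile
# log-likelihood together with the profiled variance.
negloglik_core <- function(w, cp, QC, QD) {
  B <- penalty_matrix(w, QC, QD, p = cp$p)
  RB <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(RB))
    stop(paste("singular penalty matrix B_lambda; a positive ridge weight",
               "lambda_R (AIM) is required"), call. = FALSE)
  RM <- chol(B + cp$ZtZ)
  u <- backsolve(RM, cp$Zty, transpose = TRUE)
  quad <- cp$yty - sum(u^2)              # y' V^{-1} y with V = Z B^{-1} Z' + I
  quad <- max(quad, .Machine$double.eps)
  sigma2 <- quad / cp$n
  logdetV <- 2 * sum(log(diag(RM))) - 2 * sum(log(diag(RB)))
  val <- cp$n * log(2 * pi) + cp$n * log(sigma2) + logdetV + cp$n
  list(value = val, sigma2 = sigma2)
}

#' Marginal negative log-likelihood of the penalty weights
#'
#' Evaluates \eqn{-2} times the profile log-likelihood of the Gaussian model
#' \eqn{y_P \sim N(0, \sigma_\varepsilon^2 (\tilde Z B_\lambda^{-1}
#' \tilde Z^\top + I_n))}, with the error variance profiled out analytically.
#' The random-effect covariance \eqn{\sigma_\varepsilon^2 B_\lambda^{-1}} is
#' the mixed-model counterpart of the quadratic penalty, so minimizing this
#' function over the weights is maximum-likelihood tuning of the penalty.
#' Evaluation uses determinant and quadratic-form identities that only
#' involve `p x p` factorizations, never the `n x n` covariance.
#'
#' @inheritParams penalty_matrix
#' @param proj a [project_out_fixed()] result.
#' @return A single finite number (smaller is better).
#' @export
marginal_negloglik <- function(w, proj, QC = NULL, QD = NULL) {
  stopifnot(inherits(proj, "projected_data"))
  negloglik_core(as_penalty_weights(w), proj_crossprods(proj), QC, QD)$value
}

#' Profile maximum-likelihood estimate of the error variance
#'
#' @inheritParams marginal_negloglik
#' @return \eqn{\hat\sigma_\varepsilon^2 = \frac{1}{n} y_P^\top (\tilde Z
#'   B_\lambda^{-1} \tilde Z^\top + I_n)^{-1} y_P}.
#' @export
estimate_sigma2 <- function(w, proj, QC = NULL, QD = NULL) {
  stopifnot(inherits(proj, "projected_data"))
  negloglik_core(as_penalty_weights(w), proj_crossprods(proj), QC, QD)$sigma2
}

#' Control parameters for penalty-weight estimation
#'
#' @param n_starts number of deterministic multi-start points; starts are
#'   log-spaced over `start_range` and every free weight is initialized at
#'   the same start value.
#' @param start_range range (on the lambda scale) spanned by the starts.
#' @param lambda_floor lower bound kept on `lambda_R` so the combined
#'   penalty stays invertible and the likelihood well defined (the
#'   "add-identity" device for possibly singular Laplacians).
#' @param lambda_max upper box constraint on every weight.
#' @param log_eps offset of the `log(lambda + eps)` search scale; lets the
#'   optimizer reach exact zeros for the Laplacian weights.
#' @param obj_tol objective tolerance used both for optimizer convergence
#'   and for the smallest-total-penalty tie-break among equal optima.
#' @return A list of class `"dispeer_control"`.
#' @export
dispeer_control <- function(n_starts = 5, start_range = c(1e-4, 1e2),
                            lambda_floor = 1e-6, lambda_max = 1e6,
                            log_eps = 1e-8, obj_tol = 1e-8) {
  stopifnot(n_starts >= 1, lambda_floor >= 0, lambda_max > lambda_floor,
            log_eps > 0, obj_tol > 0, length(start_range) == 2,
            all(start_range > 0))
  structure(list(n_starts = n_starts, start_range = sort(start_range),
                 lambda_floor = lambda_floor, lambda_max = lambda_max,
                 log_eps = log_eps, obj_tol = obj_tol),
            class = "dispeer_control")
}

#' Estimate penalty weights by marginal maximum likelihood
#'
#' Minimizes [marginal_negloglik()] over the active penalty weights with a
#' box-constrained quasi-Newton search (`L-BFGS-B`) on the
#' \eqn{\log(\lambda + \epsilon)} scale, restarted from a fixed log-spaced
#' grid of starting values. The objective is not convex in the weights, so
#' the deterministic multi-start keeps fits reproducible; among starts whose
#' objectives tie within `obj_tol`, the solution with the smallest total
#' penalty \eqn{\sum \lambda} is returned. `lambda_C` is active only when
#' `QC` is supplied and `lambda_D` only when `QD` is; `lambda_R` is always
#' active and bounded below by `control$lambda_floor`.
#'
#' @inheritParams marginal_negloglik
#' @param control a [dispeer_control()] list.
#' @return Named weight vector (`lambda_C`, `lambda_D`, `lambda_R`) with
#'   attributes `objective`, `converged` and `diagnostics` (per-start
#'   objectives and optimizer convergence codes).
#' @export
estimate_lambdas <- function(proj, QC = NULL, QD = NULL,
                             control = dispeer_control()) {
  stopifnot(inherits(proj, "projected_data"))
  cp <- proj_crossprods(proj)
  eps <- control$log_eps
  active <- c(lambda_C = !is.null(QC), lambda_D = !is.null(QD),
              lambda_R = TRUE)
  nm <- names(active)[active]
  lower <- ifelse(nm == "lambda_R", log(control$lambda_floor + eps), log(eps))
  upper <- rep(log(control$lambda_max + eps), length(nm))

  to_lambda <- function(u) pmax(exp(u) - eps, 0)
  obj <- function(u) {
    w <- c(lambda_C = 0, lambda_D = 0, lambda_R = 0)
    w[nm] <- to_lambda(u)
    negloglik_core(w, cp, QC, QD)$value
  }

  starts <- 10^seq(log10(control$start_range[1]),
                   log10(control$start_range[2]),
                   length.out = control$n_starts)
  runs <- lapply(starts, function(s) {
    u0 <- pmin(pmax(rep(log(s + eps), length(nm)), lower), upper)
    stats::optim(u0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(factr = control$obj_tol / .Machine$double.eps,
                                maxit = 500))
  })
  objs <- vapply(runs, `[[`, numeric(1), "value")
  totals <- vapply(runs, function(r) sum(to_lambda(r$par)), numeric(1))
  near <- which(objs <= min(objs) + control$obj_tol)
  best <- near[which.min(totals[near])]

  w <- c(lambda_C = 0, lambda_D = 0, lambda_R = 0)
  w[nm] <- to_lambda(runs[[best]]$par)
  structure(w,
            objective = objs[best],
            converged = runs[[best]]$convergence == 0,
            diagnostics = list(start = starts, objective = objs,
                               total_penalty = totals,
                               convergence = vapply(runs, `[[`, integer(1),
                                                    "convergence"),
                               selected = best))
}

#' Penalized coefficient estimates for fixed penalty weights
#'
#' Solves the quadratic program
#' \eqn{\min_b \|y_P - \tilde Z b\|_2^2 + b^\top B_\lambda b} exactly via its
#' normal equations \eqn{(\tilde Z^\top \tilde Z + B_\lambda) \hat b =
#' \tilde Z^\top y_P}.
#'
#' @inheritParams marginal_negloglik
#' @return The `p`-vector of penalized coefficient estimates.
#' @export
solve_b <- function(proj, w, QC = NULL, QD = NULL) {
  stopifnot(inherits(proj, "projected_data"))
  w <- as_penalty_weights(w)
  B <- penalty_matrix(w, QC, QD, p = proj$p)
  M <- crossprod(proj$Z_tilde) + B
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R))
    stop(paste("singular penalized normal matrix; with lambda_R = 0 the",
               "system can be rank deficient - use a positive ridge floor"),
         call. = FALSE)
  drop(backsolve(R, backsolve(R, crossprod(proj$Z_tilde, proj$y_P),
                              transpose = TRUE)))
}

#' Unpenalized coefficient estimates given the penalized fit
#'
#' Ordinary least squares of the partial residual \eqn{y - Z \hat b} on `X`.
#'
#' @param data a [regression_data()] object.
#' @param b_hat penalized coefficient vector of length `ncol(Z)`.
#' @return The `m`-vector of unpenalized coefficient estimates.
#' @export
solve_beta <- function(data, b_hat) {
  stopifnot(inherits(data, "regression_data"))
  if (length(b_hat) != ncol(data$Z))
    stop("length(b_hat) must equal ncol(Z)", call. = FALSE)
  qx <- qr(data$X)
  if (qx$rank < ncol(data$X))
    stop(sprintf("X is rank deficient: rank %d < %d columns",
                 qx$rank, ncol(data$X)), call. = FALSE)
  drop(qr.coef(qx, data$y - data$Z %*% b_hat))
}
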
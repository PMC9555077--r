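# Independent oracles and small random-input generators shared across the
# suite. Oracles deliberately take different computational routes than the
# package (dense n x n algebra, QR on augmented systems, double loops).

# random symmetric non-negative adjacency with zero diagonal
rand_adjacency <- function(p, density = 0.5) {
  A <- matrix(0, p, p)
  ut <- upper.tri(A)
  vals <- ifelse(runif(sum(ut)) < density, runif(sum(ut), 0.2, 2), 0)
  A[ut] <- vals
  A + t(A)
}

# random regression_data with intercept + one covariate in X
rand_data <- function(n, p, m = 2, sigma = 1) {
  X <- cbind(1, matrix(rnorm(n * (m - 1)), n))
  Z <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n, sd = sigma)
  regression_data(y, X, Z)
}

# quadratic-minimizer oracle for ||y - Z b||^2 + b' B b via the augmented
# least-squares system [Z; chol(B)] b ~ [y; 0], solved by QR
oracle_quadmin <- function(yP, Zt, B) {
  R <- chol(B)
  Zaug <- rbind(Zt, R)
  yaug <- c(yP, rep(0, nrow(R)))
  drop(qr.solve(Zaug, yaug))
}

# dense multivariate-normal -2 log-density oracle at the profiled variance,
# built from the full n x n covariance
oracle_mvn_negloglik <- function(yP, Zt, B) {
  n <- length(yP)
  V <- Zt %*% solve(B) %*% t(Zt) + diag(n)
  sigma2 <- drop(crossprod(yP, solve(V, yP))) / n
  Sig <- sigma2 * V
  as.numeric(n * log(2 * pi) + determinant(Sig, logarithm = TRUE)$modulus +
               drop(crossprod(yP, solve(Sig, yP))))
}

# pairwise-difference quadratic form sum_{i<j} a_ij (b_i - b_j)^2 by loop
oracle_pairwise_quadform <- function(A, b) {
  p <- length(b)
  total <- 0
  for (i in seq_len(p - 1))
    for (j in (i + 1):p)
      total <- total + A[i, j] * (b[i] - b[j])^2
  total
}
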
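test_that("projection removes the fixed-effect column space", {
  set.seed(101)
  # intercept-only X: projection is mean-centering
  d <- regression_data(rnorm(10), matrix(1, 10, 1), matrix(rnorm(30), 10))
  pr <- project_out_fixed(d)
  expect_equal(pr$y_P, d$y - mean(d$y))
  expect_equal(pr$Z_tilde, sweep(d$Z, 2, colMeans(d$Z)))
  # orthogonality on random inputs
  for (rep in 1:10) {
    d <- rand_data(n = 25, p = 6, m = 3)
    pr <- project_out_fixed(d)
    expect_lt(max(abs(crossprod(d$X, pr$Z_tilde))), 1e-8)
    expect_lt(max(abs(crossprod(d$X, pr$y_P))), 1e-8)
  }
  # X orthogonal to y and Z: projection changes nothing
  X <- cbind(c(1, 1, 0, 0)); y <- c(0, 0, 1, -1)
  Z <- cbind(c(0, 0, 2, 2), c(0, 0, -1, 1))
  pr <- project_out_fixed(regression_data(y, X, Z))
  expect_equal(pr$y_P, y)
  expect_equal(pr$Z_tilde, Z)
})

test_that("rank-deficient X is rejected with a rank report", {
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_error(regression_data(rnorm(4), X, matrix(rnorm(8), 4)),
               "rank deficient: rank 2 < 3")
})

test_that("penalty matrix combines the weighted Laplacians plus ridge", {
  set.seed(111)
  A1 <- rand_adjacency(5); A2 <- rand_adjacency(5, density = 1)
  QC <- normalized_laplacian(A1); QD <- normalized_laplacian(A2)
  expect_equal(penalty_matrix(c(0, 0, 1), QC, QD), diag(5))
  expect_equal(penalty_matrix(c(1, 0, 0), QC, QD), QC)
  expect_equal(penalty_matrix(c(lambda_D = 2), QD = QD, p = 5), 2 * QD)
  for (rep in 1:10) {
    w <- c(runif(1, 0, 3), runif(1, 0, 3), runif(1, 0.01, 2))
    B <- penalty_matrix(w, QC, QD)
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), w[3] - 1e-10)   # ridge weight shifts the spectrum
  }
  expect_error(penalty_matrix(c(-1, 0, 0), QC, QD), "non-negative")
})

test_that("marginal likelihood matches a dense Gaussian-density oracle", {
  set.seed(121)
  d <- rand_data(n = 20, p = 3)
  pr <- project_out_fixed(d)
  QC <- normalized_laplacian(rand_adjacency(3, 1))
  QD <- normalized_laplacian(rand_adjacency(3, 1))
  for (rep in 1:5) {
    w <- c(runif(1, 0, 4), runif(1, 0, 4), runif(1, 0.05, 4))
    B <- penalty_matrix(w, QC, QD)
    got <- marginal_negloglik(w, pr, QC, QD)
    want <- oracle_mvn_negloglik(pr$y_P, pr$Z_tilde, B)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("zero penalized design reduces to the iid Gaussian likelihood", {
  set.seed(122)
  d <- regression_data(rnorm(15), matrix(1, 15, 1), matrix(0, 15, 4))
  pr <- project_out_fixed(d)
  n <- 15
  s2 <- mean(pr$y_P^2)
  iid <- n * log(2 * pi * s2) + n
  for (lr in c(0.01, 1, 100))
    expect_equal(marginal_negloglik(c(0, 0, lr), pr), iid)
  expect_equal(estimate_sigma2(c(0, 0, 1), pr), s2)
})

test_that("infinite shrinkage drives the likelihood to the Z-free model", {
  set.seed(123)
  d <- rand_data(n = 30, p = 4)
  pr <- project_out_fixed(d)
  iid <- 30 * log(2 * pi * mean(pr$y_P^2)) + 30
  expect_equal(marginal_negloglik(c(0, 0, 1e10), pr), iid, tolerance = 1e-5)
  expect_equal(estimate_sigma2(c(0, 0, 1e12), pr), mean(pr$y_P^2),
               tolerance = 1e-6)
  # and b_hat -> 0
  expect_lt(sqrt(sum(solve_b(pr, c(0, 0, 1e12))^2)), 1e-9)
})

test_that("singular penalty without ridge is rejected pointing to AIM", {
  set.seed(124)
  d <- rand_data(n = 20, p = 4)
  pr <- project_out_fixed(d)
  Q <- normalized_laplacian(rand_adjacency(4, 1))   # singular (PSD)
  expect_error(marginal_negloglik(c(1, 0, 0), pr, QC = Q), "lambda_R")
})

test_that("solve_b solves the penalized quadratic program exactly", {
  set.seed(131)
  # ridge reduction
  d <- rand_data(n = 30, p = 5)
  pr <- project_out_fixed(d)
  lam <- 2.5
  ridge <- solve(crossprod(pr$Z_tilde) + lam * diag(5),
                 crossprod(pr$Z_tilde, pr$y_P))
  expect_equal(solve_b(pr, c(0, 0, lam)), drop(ridge), tolerance = 1e-12)
  # oracle equivalence on random instances
  for (rep in 1:10) {
    p <- sample(3:8, 1)
    d <- rand_data(n = sample(15:40, 1), p = p)
    pr <- project_out_fixed(d)
    QC <- normalized_laplacian(rand_adjacency(p, 1))
    QD <- normalized_laplacian(rand_adjacency(p, 1))
    w <- c(runif(1, 0, 5), runif(1, 0, 5), runif(1, 0.01, 5))
    b <- solve_b(pr, w, QC, QD)
    b_or <- oracle_quadmin(pr$y_P, pr$Z_tilde, penalty_matrix(w, QC, QD))
    expect_equal(b, b_or, tolerance = 1e-8)
  }
})

test_that("shrinkage is monotone in the ridge weight", {
  set.seed(141)
  d <- rand_data(n = 40, p = 6)
  pr <- project_out_fixed(d)
  QC <- normalized_laplacian(rand_adjacency(6))
  norms <- sapply(10^seq(-3, 4, length.out = 15), function(lr)
    sqrt(sum(solve_b(pr, c(lambda_C = 0.5, lambda_D = 0, lambda_R = lr),
                     QC = QC)^2)))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("solve_beta is OLS on the partial residual", {
  set.seed(151)
  d <- rand_data(n = 30, p = 4, m = 3)
  # b_hat = 0: plain OLS of y on X
  expect_equal(solve_beta(d, rep(0, 4)),
               drop(qr.solve(d$X, d$y)))
  # exact recovery when y = X beta* and Z b_hat = 0 contribution removed
  beta_star <- c(2, -1, 0.5)
  b_any <- rnorm(4)
  d2 <- regression_data(drop(d$X %*% beta_star + d$Z %*% b_any), d$X, d$Z)
  expect_equal(solve_beta(d2, b_any), beta_star, tolerance = 1e-10)
})

test_that("lambda estimation dominates a dense grid on a small instance", {
  set.seed(161)
  p <- 5
  QC <- normalized_laplacian(rand_adjacency(p, 1))
  QD <- normalized_laplacian(rand_adjacency(p, 1))
  Sigma <- build_btrue_covariance(QC, QD, r_C = 0.5, r_R = 0.05,
                                  sigma2_b = 0.5)
  Z <- matrix(rnorm(30 * p), 30)
  b <- drop(MASS::mvrnorm(1, rep(0, p), Sigma))
  d <- regression_data(drop(Z %*% b + rnorm(30, 0, 0.5)),
                       matrix(1, 30, 1), Z)
  pr <- project_out_fixed(d)
  w <- estimate_lambdas(pr, QC, QD)
  grid <- 10^seq(-3, 2, length.out = 10)
  grid_min <- min(apply(expand.grid(grid, grid, grid), 1, function(g)
    marginal_negloglik(as.numeric(g), pr, QC, QD)))
  expect_lte(attr(w, "objective"), grid_min + 1e-6)
})

test_that("pure-noise data are shrunk toward zero", {
  set.seed(171)
  d <- rand_data(n = 100, p = 5)        # y independent of Z
  pr <- project_out_fixed(d)
  QC <- normalized_laplacian(rand_adjacency(5))
  w <- estimate_lambdas(pr, QC = QC)
  b <- solve_b(pr, w, QC = QC)
  expect_lt(sqrt(sum(b^2)), 0.15)
})

test_that("excluding the distance penalty reduces to a two-weight fit", {
  set.seed(181)
  d <- rand_data(n = 40, p = 5)
  pr <- project_out_fixed(d)
  QC <- normalized_laplacian(rand_adjacency(5, 1))
  w2 <- estimate_lambdas(pr, QC = QC)
  expect_identical(w2[["lambda_D"]], 0)
  # likelihood agrees with the three-weight surface at lambda_D = 0
  QD <- normalized_laplacian(rand_adjacency(5, 1))
  expect_equal(marginal_negloglik(w2, pr, QC = QC),
               marginal_negloglik(w2, pr, QC = QC, QD = QD))
})

test_that("profiled error variance is recovered on generated data", {
  set.seed(191)
  p <- 8; n <- 400
  QC <- normalized_laplacian(rand_adjacency(p))
  QD <- normalized_laplacian(rand_adjacency(p, 1))
  Sigma <- build_btrue_covariance(QC, QD, 0.5, 0.01, sigma2_b = 0.05)
  ests <- replicate(50, {
    Z <- matrix(rnorm(n * p), n)
    X <- cbind(1, rnorm(n))
    b <- drop(MASS::mvrnorm(1, rep(0, p), Sigma))
    d <- regression_data(drop(Z %*% b + rnorm(n, 0, 1)), X, Z)
    f <- fit_dispeer(d, QC = QC, QD = QD, method = "dispeer")
    f$sigma2_eps
  })
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 1), 3 * mc_se + 0.02)
})
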
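test_that("generated structure satisfies the matrix invariants across seeds", {
  for (s in 1:20) {
    st <- generate_structure(structure_config(13, seed = s))
    A <- st$connectivity; D <- st$distance
    expect_equal(A, t(A))
    expect_true(all(A >= 0) && all(diag(A) == 0))
    expect_gt(sum(A > 0), 0)
    expect_equal(D, t(D))
    expect_true(all(D[upper.tri(D)] > 0) && all(diag(D) == 0))
    # no edges across blocks
    cross <- outer(st$blocks, st$blocks, "!=")
    expect_true(all(A[cross] == 0))
  }
  # determinism
  expect_identical(generate_structure(structure_config(13, seed = 4)),
                   generate_structure(structure_config(13, seed = 4)))
})

test_that("single full-density block yields a complete weighted graph", {
  st <- generate_structure(structure_config(8, block_sizes = 8,
                                            edge_density_within = 1,
                                            seed = 2))
  A <- st$connectivity
  expect_true(all(A[upper.tri(A)] > 0))
})

test_that("great-circle distances exceed chords and degenerate coords fail", {
  theta <- c(0.1, 0.5, 1.0); phi <- c(0, 2, 4)
  coords <- 80 * cbind(sin(theta) * cos(phi), sin(theta) * sin(phi),
                       cos(theta))
  Dg <- distances_from_coords(coords, "great_circle")
  De <- distances_from_coords(coords, "euclidean")
  expect_true(all(Dg[upper.tri(Dg)] >= De[upper.tri(De)]))
  # identical coordinates: zero distances, which normalization then rejects
  same <- matrix(1, 4, 3)
  D0 <- distances_from_coords(same, "euclidean")
  expect_true(all(D0 == 0))
  expect_error(normalize_distances(D0), "all entries are zero")
})

test_that("structure config rejects infeasible settings", {
  expect_error(structure_config(10, block_sizes = c(4, 4)), "sum to p")
  expect_error(structure_config(10, block_sizes = c(3, 7)), "at least 4")
  expect_error(structure_config(10, edge_density_within = 0), "\\(0, 1\\]")
})

test_that("true-coefficient covariance inverts the structure matrix", {
  set.seed(301)
  p <- 6
  QC <- normalized_laplacian(rand_adjacency(p))
  QD <- normalized_laplacian(rand_adjacency(p, 1))
  # no graph structure: pure scaled identity
  Z0 <- matrix(0, p, p)
  expect_equal(build_btrue_covariance(Z0, Z0, r_C = 0, r_R = 1,
                                      sigma2_b = 0.3),
               0.3 * diag(p))
  for (rep in 1:10) {
    r_C <- runif(1)
    Sigma <- build_btrue_covariance(QC, QD, r_C, 0.01, 0.1)
    B <- r_C * QC + (1 - r_C) * QD + 0.01 * diag(p)
    expect_equal(Sigma %*% B, 0.1 * diag(p), tolerance = 1e-10)
    expect_gt(min(eigen(Sigma, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("replicates follow the declared generative model", {
  set.seed(311)
  p <- 5
  QC <- normalized_laplacian(rand_adjacency(p, 1))
  QD <- normalized_laplacian(rand_adjacency(p, 1))
  # noiseless: y is exactly X beta + Z b (beta = 0)
  cfg0 <- simulation_config(p = p, n = 50, sigma2_eps = 0, n_reps = 1)
  r <- generate_replicate(cfg0, QC, QD)
  expect_equal(r$data$y, drop(r$data$Z %*% r$b_true))
  expect_equal(r$beta_true, c(0, 0))
  # rows of Z are approximately iid N(0, I_p) at large n
  cfgL <- simulation_config(p = p, n = 4000, n_reps = 1)
  rL <- generate_replicate(cfgL, QC, QD)
  expect_lt(max(abs(crossprod(rL$data$Z) / 4000 - diag(p))), 0.1)
  # empirical covariance of b across many draws matches sigma2_b B_true^-1
  cfgB <- simulation_config(p = p, n = 10, sigma2_b = 0.5, r_C = 0.3,
                            n_reps = 1)
  bs <- t(replicate(2000, generate_replicate(cfgB, QC, QD)$b_true))
  Sigma <- build_btrue_covariance(QC, QD, 0.3, cfgB$r_R, 0.5)
  expect_lt(max(abs(cov(bs) - Sigma)), 6 * max(diag(Sigma)) / sqrt(2000))
})

test_that("relative MSE identities hold exactly", {
  b <- c(1, -2, 0.5)
  expect_equal(rmse(b, b), 0)
  expect_equal(rmse(rep(0, 3), b), 1)
  expect_equal(rmse(2 * b, b), 1)
  expect_error(rmse(b, rep(0, 3)), "zero vector")
  expect_error(rmse(b, c(1, 2)), "equal length")
})

test_that("bias-variance decomposition is exact by construction", {
  truth <- c(1, 2, 3)
  ident <- matrix(truth, 5, 3, byrow = TRUE)
  bv0 <- bias_variance(ident, truth)
  expect_equal(unname(bv0$total), c(0, 0, 0))
  # constant offset: zero variance, bias fully determined by the offset
  off <- sweep(ident, 2, c(0.5, -1, 0), "+")
  bv1 <- bias_variance(off, truth)
  expect_equal(bv1$per_coef$variance, rep(0, 3))
  expect_equal(bv1$per_coef$squared_bias, c(0.25, 1, 0))
  expect_equal(bv1$total[["mse"]], 1.25)
  # identity on random inputs
  set.seed(321)
  for (rep in 1:10) {
    est <- matrix(rnorm(40), 8, 5)
    tru <- matrix(rnorm(40), 8, 5)
    bv <- bias_variance(est, tru)
    expect_lt(max(abs(bv$per_coef$mse - bv$per_coef$variance -
                        bv$per_coef$squared_bias)), 1e-12)
  }
})

test_that("experiments are reproducible and summarized consistently", {
  st <- generate_structure(structure_config(8, block_sizes = 8, seed = 6))
  cfg <- simulation_config(p = 8, n = 80, n_reps = 3, seed = 9)
  ex1 <- run_experiment(cfg, st)
  ex2 <- run_experiment(cfg, st)
  expect_identical(ex1$rmse, ex2$rmse)
  expect_identical(ex1$medians, ex2$medians)
  # median of a single replicate is that replicate
  cfg1 <- simulation_config(p = 8, n = 80, n_reps = 1, seed = 9,
                            methods = "ridge")
  ex3 <- run_experiment(cfg1, st)
  expect_equal(ex3$medians[["ridge"]], unname(ex3$rmse[1, "ridge"]))
  # percentage decrease recomputes from the medians
  expect_equal(ex1$decrease_pct,
               100 * (ex1$medians[["ripeer"]] - ex1$medians[["dispeer"]]) /
                 ex1$medians[["ripeer"]])
})

test_that("estimation degrades gracefully when the bandwidth is misspecified", {
  st <- generate_structure(structure_config(12, seed = 1))
  base <- simulation_config(p = 12, n = 200, n_reps = 30, r_C = 0.1,
                            sigma2_b = 0.01, sigma2_eps = 1, seed = 17,
                            methods = "dispeer")
  off <- simulation_config(p = 12, n = 200, n_reps = 30, r_C = 0.1,
                           sigma2_b = 0.01, sigma2_eps = 1, seed = 17,
                           h_fit = 10, methods = "dispeer")
  m_base <- run_experiment(base, st)$medians[["dispeer"]]
  m_off <- run_experiment(off, st)$medians[["dispeer"]]
  expect_lt(m_off, 1.2 * m_base)
})
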
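test_that("trajectories honor closed-form special cases", {
  times <- c(3, 24, 72, 75, 96)
  # null dynamics: state frozen
  m0 <- influence_model(matrix(0, 2, 2), c(1, 1))
  tr0 <- simulate_trajectory(m0, c(1, 2), times)
  expect_equal(unname(tr0$values), matrix(c(1, 2), 2, 5))
  # uncoupled exponential decay
  m1 <- influence_model(diag(-1, 2), c(1, 1))
  tr1 <- simulate_trajectory(m1, c(1, 2), times)
  expect_equal(unname(tr1$values),
               rbind(exp(-(times - 3)), 2 * exp(-(times - 3))),
               tolerance = 1e-12)
  # nilpotent coupling: exact linear growth c1(t) = t - t0, c2 = 1
  m2 <- influence_model(matrix(c(0, 0, 1, 0), 2, 2), c(1, 1))
  tr2 <- simulate_trajectory(m2, c(0, 1), times)
  expect_equal(unname(tr2$values), rbind(times - 3, rep(1, 5)),
               tolerance = 1e-12)
  # and against a fixed-step RK4 oracle
  rk <- rk4_solve(m2$A, c(0, 1), times)
  expect_equal(unname(tr2$values), rk, tolerance = 1e-8)
})

test_that("matrix exponential agrees with adaptive ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  times <- c(3, 24, 72, 75, 96)
  for (rep in 1:10) {
    A <- random_stable_matrix(10)
    c0 <- rnorm(10)
    model <- influence_model(A, rep(1, 10))
    sim <- simulate_trajectory(model, c0, times)$values
    ode <- deSolve::lsoda(c0, times, function(t, y, p) list(A %*% y),
                          rtol = 1e-11, atol = 1e-12)
    ref <- t(unname(ode[, -1]))
    expect_lt(max(abs(sim - ref)) / max(abs(ref)), 1e-8)
  }
})

test_that("the linear system superposes initial states", {
  set.seed(8)
  A <- random_stable_matrix(6)
  m <- influence_model(A, rep(1, 6))
  times <- c(3, 24, 72, 75, 96)
  a <- rnorm(6); b <- rnorm(6)
  sab <- simulate_trajectory(m, a + b, times)$values
  sa <- simulate_trajectory(m, a, times)$values
  sb <- simulate_trajectory(m, b, times)$values
  expect_equal(sab, sa + sb, tolerance = 1e-10)
})

test_that("weighted correlation reproduces its defining identities", {
  obs <- matrix(c(1, 2, 3, 4, 5,
                  1, -1, 1, -1, 0), 2, 5, byrow = TRUE)
  g <- c(3, 1)
  expect_equal(weighted_correlation_performance(obs, obs, g), 1.0)
  expect_equal(weighted_correlation_performance(-obs, obs, g), -1.0)
  # (3,1)-weighted correlations (1, 0): 0.75
  sim <- obs
  sim[2, ] <- c(1, 1, -1, -1, 0)          # orthogonal to obs row 2
  stopifnot(abs(cor(sim[2, ], obs[2, ])) < 1e-12)
  expect_equal(weighted_correlation_performance(sim, obs, g), 0.75)
  # constant simulated row contributes zero, not NA
  sim[2, ] <- 7
  expect_equal(weighted_correlation_performance(sim, obs, g), 0.75)
  expect_error(weighted_correlation_performance(obs[, 1:4], obs, g), "shapes")
  expect_error(weighted_correlation_performance(obs[, 1:2], obs[, 1:2], g),
               "time points")
})

test_that("weighted correlation ignores positive affine rescaling", {
  set.seed(9)
  obs <- matrix(rnorm(15), 3, 5)
  sim <- obs + matrix(rnorm(15, sd = 0.3), 3, 5)
  g <- c(5, 2, 1)
  base <- weighted_correlation_performance(sim, obs, g)
  rescaled <- sim * c(2, 10, 0.3) + c(-1, 5, 0.2)
  expect_equal(weighted_correlation_performance(rescaled, obs, g), base,
               tolerance = 1e-12)
})

test_that("normalized RMSD follows its definition", {
  obs <- matrix(c(0, 0.5, 1, 0.2, 0.4,
                  0, 1, 2, 0.4, 0.8), 2, 5, byrow = TRUE)
  expect_equal(rmsd_performance(obs, obs), 0)
  # offsets of 20% and 40% of each range average to 0.3
  sim <- obs + c(0.2, 0.4) * c(1, 2)
  expect_equal(rmsd_performance(sim, obs), 0.3, tolerance = 1e-12)
  # offset by one full range: normalized RMSD 1 for that cluster
  one <- obs[1, , drop = FALSE]
  expect_equal(rmsd_performance(one + 1, one), 1)
  # zero-range cluster excluded with a warning
  obs2 <- rbind(obs, 3)
  sim2 <- rbind(sim, 9)
  expect_warning(v <- rmsd_performance(sim2, obs2), "zero observed range")
  expect_equal(v, 0.3, tolerance = 1e-12)
})

test_that("model matrices survive a TSV round trip", {
  tm <- generate_truth_model(6, 0.3, gene_counts = 4, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model_tsv(tm, path)
  back <- read_model_tsv(path, gene_counts = tm$gene_counts)
  expect_equal(back$A, tm$A, tolerance = 1e-9)
  expect_equal(back$cluster_ids, tm$cluster_ids)
})

test_that("constructors validate their invariants", {
  expect_error(influence_model(matrix(1, 2, 3), c(1, 1)), "square")
  expect_error(influence_model(matrix(NA_real_, 2, 2), c(1, 1)), "finite")
  expect_error(influence_model(matrix(0, 2, 2), c(1, 0)), "gene_counts")
  expect_error(build_influence_model(matrix(0, 2, 2), c(1, -5), c(1, 1)),
               "tau")
  expect_error(time_course("x", c(3, 3, 24), matrix(0, 1, 3)), "increasing")
  # decay folds into the diagonal
  m <- build_influence_model(matrix(0, 2, 2), c(10, 20), c(1, 1))
  expect_equal(unname(diag(m$A)), c(-0.1, -0.05))
})
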
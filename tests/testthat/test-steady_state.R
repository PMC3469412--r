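test_that("lasso fit matches a naive coordinate-descent oracle", {
  set.seed(31)
  n <- 25
  X <- matrix(rnorm(4 * n), n, 4)
  X <- scale(X, center = TRUE, scale = FALSE)
  y <- 1.0 * X[, 1] + rnorm(n, sd = 0.01)
  y <- y - mean(y)
  regs <- t(X)
  rownames(regs) <- paste0("r", 1:4)
  for (lam in c(0.005, 0.05, 0.2, 0.8)) {
    got <- fit_target_lasso(y, regs, lam)
    want <- cd_lasso(X, y, lam)
    expect_equal(unname(got), as.numeric(want), tolerance = 1e-6)
  }
  # target tracking regulator 1: weight near 1, noise regulators exactly 0
  got <- fit_target_lasso(y, regs, 0.02)
  expect_lt(abs(got[["r1"]] - 1), 0.05)
  expect_identical(unname(got[-1]), rep(0, 3))
})

test_that("extreme penalties behave as the objective dictates", {
  set.seed(32)
  n <- 20
  X <- matrix(rnorm(3 * n), n, 3)
  y <- X[, 2] * 0.7 + rnorm(n, 0.05)
  regs <- t(X); rownames(regs) <- paste0("r", 1:3)
  # full shrinkage at huge lambda
  expect_identical(unname(fit_target_lasso(y, regs, 100)), rep(0, 3))
  # orthogonal target: zero at any positive penalty
  ortho <- qr.Q(qr(cbind(X, rnorm(n))))[, 4] # orthogonal to col span of X
  expect_identical(unname(fit_target_lasso(ortho, regs, 0.01)), rep(0, 3))
  expect_error(fit_target_lasso(y, regs, -1), "penalty")
  expect_error(fit_target_lasso(y[1], regs[, 1, drop = FALSE], 0.1), "samples")
})

test_that("raising the penalty never grows the active set", {
  set.seed(33)
  n <- 25
  X <- matrix(rnorm(6 * n), n, 6)
  y <- X %*% c(1, -0.8, 0.5, 0, 0, 0) + rnorm(n, sd = 0.1)
  regs <- t(X); rownames(regs) <- paste0("r", 1:6)
  grid <- c(0.001, 0.01, 0.05, 0.1, 0.3, 0.6, 1)
  sizes <- vapply(grid, function(l) sum(fit_target_lasso(y, regs, l) != 0),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("cross-validation builds one fold per treatment excluding its course", {
  tm <- generate_truth_model(5, 0.2, gene_counts = 10, seed = 3)
  tr <- synthetic_truth(tm, sigma_obs = 0.05, sigma_gene = 0.1, seed = 3)
  ds <- generate_expression_dataset(tr)
  folds <- infer_cv_models(ds$profiles)
  expect_length(folds, 5)
  expect_setequal(vapply(folds, `[[`, character(1), "held_out_treatment"),
                  unique(ds$profiles$samples$treatment))
  for (f in folds) {
    expect_true(all(diag(f$coefficients) == 0))
    expect_true(all(is.finite(f$coefficients)))
  }
  # single-treatment data cannot be cross-validated
  one <- ds$profiles
  keep <- one$samples$treatment == "lps"
  one$values <- one$values[, keep, drop = FALSE]
  one$samples <- one$samples[keep, , drop = FALSE]
  expect_error(infer_cv_models(one), "treatments")
})

test_that("identical treatments give identical folds", {
  set.seed(35)
  K <- 4
  block <- matrix(rnorm(K * 5), K, 5)
  vals <- cbind(block, block, block)
  rownames(vals) <- paste0("cluster_", 1:K)
  colnames(vals) <- paste0("s", 1:15)
  prof <- structure(list(
    values = vals, gene_counts = rep(5L, K),
    cluster_ids = rownames(vals),
    samples = data.frame(sample = colnames(vals),
                         treatment = rep(c("a", "b", "c"), each = 5),
                         time_h = rep(c(3, 24, 72, 75, 96), 3))),
    class = "cluster_profiles")
  folds <- infer_cv_models(prof)
  expect_equal(folds[[1]]$coefficients, folds[[2]]$coefficients)
  expect_equal(folds[[2]]$coefficients, folds[[3]]$coefficients)
})

test_that("noise-free planted targets are recovered along the penalty path", {
  # five exogenous clusters drive targets with 2 regulators each and an
  # exact linear relation; as the penalty relaxes the fit converges on
  # the planted weights, with any spurious weight vanishing
  set.seed(36)
  n <- 25
  exo <- matrix(rnorm(5 * n), 5, n)
  grid <- exp(seq(log(1), log(1e-3), length.out = 12))
  for (i in 1:5) {
    regs_true <- sample(1:5, 2)
    w_full <- rep(0, 5)
    w_full[regs_true] <- sample(c(-1, 1), 2, TRUE) * runif(2, 0.5, 1)
    y <- as.numeric(w_full %*% exo)
    clean_hit <- FALSE
    for (lam in grid) {
      b <- fit_target_lasso(y, exo, lam)
      if (all(regs_true %in% which(b != 0)) &&
          max(abs(b[-regs_true])) < 0.05) {
        clean_hit <- TRUE
      }
    }
    expect_true(clean_hit)
    # near-OLS end of the path reproduces the planted weights
    b_end <- fit_target_lasso(y, exo, 1e-3)
    expect_lt(max(abs(b_end - w_full)), 0.05)
  }
})

test_that("consensus filtering follows the support and magnitude rules", {
  K <- 3
  base <- matrix(0, K, K)
  mk_fold <- function(m) {
    structure(list(held_out_treatment = "x", coefficients = m,
                   penalties = rep(0.1, K), heldout_performance = 0.5),
              class = "steady_state_fold")
  }
  m_list <- lapply(1:5, function(i) {
    m <- base
    m[1, 2] <- 0.5                      # in all 5 folds
    if (i <= 2) m[1, 3] <- 0.9          # only 2 of 5 folds
    m[2, 1] <- 0.05                     # all folds but tiny mean
    m[3, 1] <- c(0.3, -0.3, 0.3, -0.3, 0.3)[i] # support 5, mean 0.06
    mk_fold(m)
  })
  rep0 <- consensus_initial_model(m_list)
  expect_equal(rep0$consensus[1, 2], 0.5)  # retained at its mean
  expect_equal(rep0$consensus[1, 3], 0)    # support 2 < 3
  expect_equal(rep0$consensus[2, 1], 0)    # |mean| 0.05 < 0.1
  expect_equal(rep0$consensus[3, 1], 0)    # cancellation below the floor
  expect_equal(rep0$support_counts[1, 3], 2)
  # consensus support is a subset of the union of fold supports
  union_support <- Reduce(`|`, lapply(m_list, function(f) f$coefficients != 0))
  expect_true(all(!(rep0$consensus != 0) | union_support))
  expect_error(consensus_initial_model(list()), "folds")
  expect_error(consensus_initial_model(m_list, min_support = 9), "min_support")
})

test_that("support recovery succeeds when the steady-state relation holds", {
  # data generated from the model class the regression assumes: strong
  # planted influences, weak exogenous drive on regulated clusters
  set.seed(42)
  K <- 10
  W <- matrix(0, K, K)
  for (i in 6:10) {
    regs <- sample(1:5, 2)
    W[i, regs] <- sample(c(-1, 1), 2, TRUE) * runif(2, 0.5, 1)
  }
  n <- 25
  eps <- matrix(rnorm(K * n), K, n)
  eps[6:10, ] <- eps[6:10, ] * 0.05
  Cm <- solve(diag(K) - W, eps)
  rownames(Cm) <- paste0("cluster_", 1:K)
  colnames(Cm) <- paste0("s", 1:n)
  prof <- structure(list(
    values = Cm, gene_counts = rep(20L, K), cluster_ids = rownames(Cm),
    samples = data.frame(sample = colnames(Cm),
                         treatment = rep(letters[1:5], each = 5),
                         time_h = rep(c(3, 24, 72, 75, 96), 5))),
    class = "cluster_profiles")
  rep0 <- consensus_initial_model(infer_cv_models(prof))
  tp <- sum(rep0$consensus != 0 & W != 0)
  fn <- sum(rep0$consensus == 0 & W != 0)
  expect_gte(tp / (tp + fn), 0.8) # recall: true influences survive filtering
})
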
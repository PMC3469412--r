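# Independent oracles and small fixture builders used across the suite.

# Cyclic coordinate descent for the lasso objective
# (1/2n) ||y - X b||^2 + lambda ||b||_1 on pre-centered data, no
# intercept. Deliberately naive; the reference for fit_target_lasso.
cd_lasso <- function(X, y, lambda, n_iter = 5000, tol = 1e-12) {
  n <- nrow(X)
  p <- ncol(X)
  b <- rep(0, p)
  xs <- colSums(X^2) / n
  for (it in seq_len(n_iter)) {
    b_old <- b
    for (j in seq_len(p)) {
      r <- y - X[, -j, drop = FALSE] %*% b[-j]
      rho <- sum(X[, j] * r) / n
      b[j] <- if (xs[j] == 0) 0 else sign(rho) * max(abs(rho) - lambda, 0) / xs[j]
    }
    if (max(abs(b - b_old)) < tol) break
  }
  b
}

# Exact hypergeometric upper tail P(X >= k) by direct enumeration of the
# probability mass, independent of phyper.
hyper_tail_enum <- function(k, n_term, n_universe, n_cluster) {
  kk <- k:min(n_term, n_cluster)
  sum(choose(n_term, kk) * choose(n_universe - n_term, n_cluster - kk)) /
    choose(n_universe, n_cluster)
}

# All permutations of a vector (Heap-free simple recursion; fine for n <= 6).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Classic RK4 with a fixed fine step: the integration oracle for the
# matrix-exponential solver when deSolve is not wanted.
rk4_solve <- function(A, c0, times, dt = 0.01) {
  f <- function(x) A %*% x
  out <- matrix(NA_real_, length(c0), length(times))
  out[, 1] <- c0
  x <- c0
  t <- times[1]
  for (j in 2:length(times)) {
    while (t < times[j] - 1e-12) {
      h <- min(dt, times[j] - t)
      k1 <- f(x); k2 <- f(x + h / 2 * k1)
      k3 <- f(x + h / 2 * k2); k4 <- f(x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[, j] <- x
  }
  out
}

# Weighted-correlation fitness of a model on a course, via the public
# simulate/score surface (the annealer computes this internally).
fitness_of <- function(model, course) {
  sim <- simulate_trajectory(model, course$observed[, 1], course$times)
  weighted_correlation_performance(sim, course, model$gene_counts)
}

# A tiny two-treatment expression table used by IO and clustering tests.
tiny_table <- function() {
  vals <- matrix(c(1, 2, 3, 4), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expression_table(vals, data.frame(sample = c("s1", "s2"),
                                    treatment = c("a", "b"),
                                    time_h = c(3, 3)))
}

# Random stable matrix: spectral abscissa forced below -margin by
# shifting the diagonal.
random_stable_matrix <- function(K, margin = 0.05) {
  A <- matrix(rnorm(K * K, sd = 0.3), K, K)
  shift <- max(Re(eigen(A, only.values = TRUE)$values))
  A - (shift + margin) * diag(K)
}

# Planted small-cluster scenario where functional coherence has a strict
# maximum at the planted division (clusters small relative to the
# universe; see the methods vignette for why size matters here).
small_coherence_scenario <- function(seed = 11) {
  tm <- generate_truth_model(4, 0.5, gene_counts = 3, seed = seed)
  tr <- synthetic_truth(tm, sigma_obs = 0, sigma_gene = 0.05, purity = 1,
                        seed = seed)
  ds <- generate_expression_dataset(tr)
  vd <- generate_validation_data(tr, ds$assignment)
  list(truth = tr, data = ds, annotations = vd$annotations, planted_k = 4)
}
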
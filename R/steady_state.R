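#' Fit one target cluster by L1-penalized regression
#'
#' Minimizes `(1/2n) * sum(residual^2) + penalty * sum(|w|)` over linear
#' weights, with the target and regulator profiles centered and no
#' intercept (values are fold changes relative to baseline). Each sample
#' is treated as an independent steady-state observation. The fit is the
#' parsimonious set of regulatory influences explaining the target.
#'
#' @param target_profile numeric vector of the target cluster's values
#'   over samples.
#' @param regulator_profiles matrix with rows = regulator clusters,
#'   columns = samples (the target itself must not be among them).
#' @param penalty lasso penalty `lambda >= 0`.
#' @return Named numeric coefficient vector, one weight per regulator.
#' @export
fit_target_lasso <- function(target_profile, regulator_profiles, penalty) {
  if (penalty < 0) stop("penalty must be >= 0", call. = FALSE)
  n <- length(target_profile)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (ncol(regulator_profiles) != n) {
    stop("regulator profiles must share the target's samples", call. = FALSE)
  }
  x <- t(regulator_profiles)            # samples x regulators
  y <- as.numeric(target_profile)
  x <- scale(x, center = TRUE, scale = FALSE)
  y <- y - mean(y)
  p <- ncol(x)
  beta <- if (p == 1) {
    # closed-form soft threshold for the single-regulator case
    num <- sum(x[, 1] * y) / n
    den <- sum(x[, 1]^2) / n
    if (den == 0) 0 else sign(num) * max(abs(num) - penalty, 0) / den
  } else {
    lam_data <- max(abs(crossprod(x, y)) / n)
    if (penalty >= lam_data) {
      # KKT: the all-zero solution is exact once lambda >= max|X'y|/n
      rep(0, p)
    } else if (penalty == 0) {
      b <- as.numeric(stats::lm.fit(x, y)$coefficients)
      b[is.na(b)] <- 0
      b
    } else {
      # descending path ending exactly at the requested penalty (glmnet
      # is more reliable warm-started along a path than at one value)
      path <- exp(seq(log(lam_data), log(penalty), length.out = 30))
      path[length(path)] <- penalty
      fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                            lambda = path, standardize = FALSE,
                            intercept = FALSE, thresh = 1e-9, maxit = 1e6)
      if (length(fit$lambda) < length(path)) {
        # path truncated before the requested penalty: solve there directly
        return(setNames(cd_lasso_exact(x, y, penalty),
                        rownames(regulator_profiles)))
      }
      as.numeric(fit$beta[, ncol(fit$beta)])
    }
  }
  names(beta) <- rownames(regulator_profiles)
  beta
}

# Cyclic coordinate descent on the lasso objective; backstop for the
# rare penalties where the warm-started path solver gives up early.
cd_lasso_exact <- function(x, y, lambda, n_iter = 10000, tol = 1e-10) {
  n <- nrow(x)
  p <- ncol(x)
  b <- rep(0, p)
  xs <- colSums(x^2) / n
  xty <- crossprod(x, y) / n
  xtx <- crossprod(x) / n
  for (it in seq_len(n_iter)) {
    b_old <- b
    for (j in seq_len(p)) {
      rho <- xty[j] - sum(xtx[j, -j] * b[-j])
      b[j] <- if (xs[j] == 0) 0 else sign(rho) * max(abs(rho) - lambda, 0) / xs[j]
    }
    if (max(abs(b - b_old)) < tol) break
  }
  b
}

#' Leave-one-time-course-out steady-state model inference
#'
#' One cross-validation fold per treatment. Within a fold, each cluster
#' is fit by [fit_target_lasso()] on all samples of the remaining
#' treatments (each time point an independent steady-state observation),
#' with the target cluster excluded from its own regulator set. The
#' penalty is chosen per target as the grid value minimizing mean squared
#' prediction error under an inner leave-one-treatment-out loop over the
#' training treatments. Held-out performance is the gene-count-weighted
#' correlation between steady-state predictions and observations on the
#' excluded treatment's samples.
#'
#' @param profiles a `cluster_profiles` object (see
#'   [cluster_mean_profiles()]) carrying sample metadata.
#' @param penalty_grid candidate penalties; default a geometric grid from
#'   1 down to 1e-3.
#' @return List of folds (class `steady_state_fold`): each has
#'   `held_out_treatment`, `coefficients` (K x K, rows = target, diagonal
#'   zero), `penalties` (chosen per target), `heldout_performance`.
#' @export
infer_cv_models <- function(profiles, penalty_grid = NULL) {
  stopifnot(inherits(profiles, "cluster_profiles"))
  meta <- profiles$samples
  treatments <- unique(meta$treatment)
  if (length(treatments) < 2) stop("need at least 2 treatments", call. = FALSE)
  if (is.null(penalty_grid)) {
    penalty_grid <- exp(seq(log(1), log(1e-3), length.out = 12))
  }
  K <- nrow(profiles$values)
  vals <- profiles$values
  lapply(treatments, function(heldout) {
    train_tr <- setdiff(treatments, heldout)
    train_cols <- meta$treatment != heldout
    coefs <- matrix(0, K, K,
                    dimnames = list(profiles$cluster_ids, profiles$cluster_ids))
    penalties <- numeric(K)
    for (i in seq_len(K)) {
      regs <- setdiff(seq_len(K), i)
      # inner leave-one-treatment-out over the training treatments
      mse <- matrix(NA_real_, length(train_tr), length(penalty_grid))
      for (v in seq_along(train_tr)) {
        inner_train <- train_cols & meta$treatment != train_tr[v]
        inner_test <- meta$treatment == train_tr[v]
        xtr <- vals[regs, inner_train, drop = FALSE]
        ytr <- vals[i, inner_train]
        for (j in seq_along(penalty_grid)) {
          w <- fit_target_lasso(ytr, xtr, penalty_grid[j])
          mu_x <- rowMeans(xtr)
          mu_y <- mean(ytr)
          pred <- mu_y + as.numeric(
            crossprod(w, vals[regs, inner_test, drop = FALSE] - mu_x))
          mse[v, j] <- mean((vals[i, inner_test] - pred)^2)
        }
      }
      best_j <- which.min(colMeans(mse))
      penalties[i] <- penalty_grid[best_j]
      coefs[i, regs] <- fit_target_lasso(vals[i, train_cols],
                                         vals[regs, train_cols, drop = FALSE],
                                         penalties[i])
    }
    # steady-state prediction on the held-out treatment
    test_cols <- which(meta$treatment == heldout)
    mu_x <- rowMeans(vals[, train_cols, drop = FALSE])
    pred <- matrix(0, K, length(test_cols))
    for (i in seq_len(K)) {
      pred[i, ] <- mu_x[i] + as.numeric(
        coefs[i, , drop = FALSE] %*% (vals[, test_cols, drop = FALSE] - mu_x))
    }
    perf <- if (length(test_cols) >= 3) {
      .weighted_cor(pred, vals[, test_cols, drop = FALSE],
                    as.numeric(profiles$gene_counts))
    } else NA_real_
    structure(list(held_out_treatment = heldout, coefficients = coefs,
                   penalties = penalties, heldout_performance = perf),
              class = "steady_state_fold")
  })
}

#' Average cross-validation folds into the initial influence model
#'
#' Coefficients are averaged entrywise over the folds; an influence is
#' retained only if it is nonzero in at least `min_support` folds
#' (default 3 of 5) and its mean absolute value reaches `weight_floor`
#' (default 0.1). This removes influences with low support or low impact
#' and yields the starting matrix for dynamic calibration.
#'
#' @param folds list of `steady_state_fold` objects from
#'   [infer_cv_models()].
#' @param min_support minimum number of folds an influence must appear in.
#' @param weight_floor minimum absolute mean coefficient.
#' @return An object of class `initial_model_report`: list with
#'   `consensus` (K x K filtered mean matrix), `support_counts`,
#'   `mean_performance`, `per_treatment_performance`.
#' @export
consensus_initial_model <- function(folds, min_support = 3, weight_floor = 0.1) {
  if (length(folds) == 0) stop("no folds supplied", call. = FALSE)
  if (min_support < 1 || min_support > length(folds)) {
    stop("min_support must be in [1, n_folds]", call. = FALSE)
  }
  if (weight_floor < 0) stop("weight_floor must be >= 0", call. = FALSE)
  mats <- lapply(folds, `[[`, "coefficients")
  mean_mat <- Reduce(`+`, mats) / length(mats)
  support <- Reduce(`+`, lapply(mats, function(m) (m != 0) * 1L))
  consensus <- mean_mat
  consensus[support < min_support | abs(mean_mat) < weight_floor] <- 0
  perf <- vapply(folds, `[[`, numeric(1), "heldout_performance")
  names(perf) <- vapply(folds, `[[`, character(1), "held_out_treatment")
  structure(list(consensus = consensus, support_counts = support,
                 mean_performance = mean(perf, na.rm = TRUE),
                 per_treatment_performance = perf),
            class = "initial_model_report")
}
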
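#' Construct an influence model
#'
#' The influence model is the coefficient matrix of a coupled linear ODE
#' system `dc/dt = A c` over cluster mean log2 fold changes `c`. The
#' off-diagonal entry `A[i, l]` is the regulatory influence of cluster
#' `l` on the rate of change of cluster `i` (per hour per unit log2FC).
#' The diagonal absorbs the per-cluster expression decay: when built from
#' raw influences `w` and decay constants `tau`, `A[i, i] = w[i, i] -
#' 1/tau[i]`. The effective matrix `A` is the authoritative object — a
#' randomized model may carry a diagonal whose implied decay constant is
#' non-positive, which is permitted for null models.
#'
#' @param A numeric K x K matrix, rows = target cluster, columns =
#'   regulator cluster; all entries finite.
#' @param gene_counts positive integer vector of genes per cluster,
#'   length K (weights of the performance metric).
#' @param tau optional per-cluster decay constants in hours (> 0),
#'   retained for provenance when the model was built from `w` and `tau`.
#' @param cluster_ids optional cluster labels; default `cluster_<i>`.
#' @return An object of class `influence_model`.
#' @export
influence_model <- function(A, gene_counts, tau = NULL, cluster_ids = NULL) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("A must be square", call. = FALSE)
  if (!all(is.finite(A))) stop("non-finite entries in A", call. = FALSE)
  K <- nrow(A)
  gene_counts <- as.integer(gene_counts)
  if (length(gene_counts) != K || any(gene_counts < 1)) {
    stop("gene_counts must be positive, one per cluster", call. = FALSE)
  }
  if (!is.null(tau)) {
    if (length(tau) != K || any(!is.finite(tau)) || any(tau <= 0)) {
      stop("tau must be positive and finite", call. = FALSE)
    }
  }
  if (is.null(cluster_ids)) cluster_ids <- paste0("cluster_", seq_len(K))
  dimnames(A) <- list(cluster_ids, cluster_ids)
  structure(list(n_clusters = K, A = A, tau = tau,
                 gene_counts = gene_counts, cluster_ids = cluster_ids),
            class = "influence_model")
}

#' Assemble an influence model from raw influences and decay constants
#'
#' Folds the per-cluster decay `-1/tau[i]` into the diagonal of the raw
#' influence matrix `w` to produce the effective ODE matrix.
#'
#' @param w numeric K x K raw influence matrix (rows = target).
#' @param tau per-cluster decay constants (hours, > 0).
#' @inheritParams influence_model
#' @return An [influence_model()].
#' @export
build_influence_model <- function(w, tau, gene_counts, cluster_ids = NULL) {
  if (!is.matrix(w) || nrow(w) != ncol(w)) stop("w must be square", call. = FALSE)
  if (length(tau) != nrow(w) || any(tau <= 0)) {
    stop("tau must be positive, one per cluster", call. = FALSE)
  }
  A <- w
  diag(A) <- diag(w) - 1 / tau
  influence_model(A, gene_counts, tau = tau, cluster_ids = cluster_ids)
}

#' Construct an observed time course
#'
#' Ordered observation times with cluster-mean log2 fold-change profiles
#' for one treatment. The first time point doubles as the initial state
#' of dynamic simulations.
#'
#' @param treatment treatment label.
#' @param times strictly increasing observation times in hours
#'   (default 3, 24, 72, 75, 96: three times post-pretreatment plus 3 h
#'   and 24 h after the ischemic challenge at 72 h).
#' @param observed K x length(times) matrix of observed cluster means.
#' @param cluster_ids optional cluster labels.
#' @return An object of class `time_course`.
#' @export
time_course <- function(treatment, times, observed, cluster_ids = NULL) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (!is.matrix(observed) || ncol(observed) != length(times)) {
    stop("observed must be clusters x times", call. = FALSE)
  }
  if (!all(is.finite(observed))) stop("non-finite observed values", call. = FALSE)
  if (is.null(cluster_ids)) cluster_ids <- paste0("cluster_", seq_len(nrow(observed)))
  dimnames(observed) <- list(cluster_ids, as.character(times))
  structure(list(treatment = treatment, times = times, observed = observed,
                 cluster_ids = cluster_ids),
            class = "time_course")
}

#' Simulate cluster trajectories from an initial state
#'
#' Solves `dc/dt = A c` in closed form, `c(t) = expm(A (t - t0)) c(t0)`,
#' at each requested time. The first requested time is `t0` and the
#' returned values there equal the supplied initial state exactly.
#'
#' @param model an [influence_model()].
#' @param initial numeric initial state `c(t0)`, length K.
#' @param times ordered observation times (hours); `times[1] = t0`.
#' @return An object of class `trajectory`: list with `times` and
#'   `values` (K x length(times) matrix).
#' @export
simulate_trajectory <- function(model, initial, times) {
  stopifnot(inherits(model, "influence_model"))
  if (length(initial) != model$n_clusters) {
    stop("initial state length must equal the number of clusters", call. = FALSE)
  }
  if (!all(is.finite(initial))) stop("non-finite initial state", call. = FALSE)
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  vals <- .sim_expm(model$A, as.numeric(initial), times)
  dimnames(vals) <- list(model$cluster_ids, as.character(times))
  structure(list(times = times, values = vals), class = "trajectory")
}

#' Gene-count-weighted correlation performance
#'
#' Per cluster, the Pearson correlation `r_i` between simulated and
#' observed values across all observation times (including the anchored
#' initial point); the score is `sum(g_i r_i) / sum(g_i)` with `g_i` the
#' cluster gene count. A constant vector on either side contributes
#' `r_i = 0` (neutral). This is the fitness used for annealing, chosen
#' over error metrics because the modeling goal is to capture the pattern
#' of expression rather than its magnitude.
#'
#' @param sim a `trajectory` (or bare K x T matrix).
#' @param obs a [time_course()] (or bare K x T matrix).
#' @param gene_counts positive weights, one per cluster.
#' @return Score in `[-1, 1]`.
#' @export
weighted_correlation_performance <- function(sim, obs, gene_counts) {
  sim_m <- if (inherits(sim, "trajectory")) sim$values else sim
  obs_m <- if (inherits(obs, "time_course")) obs$observed else obs
  if (!all(dim(sim_m) == dim(obs_m))) stop("mismatched shapes", call. = FALSE)
  if (ncol(sim_m) < 3) stop("need at least 3 time points", call. = FALSE)
  if (length(gene_counts) != nrow(sim_m)) {
    stop("one gene count per cluster required", call. = FALSE)
  }
  .weighted_cor(sim_m, obs_m, as.numeric(gene_counts))
}

#' Range-normalized RMSD performance (alternative metric)
#'
#' Per-cluster root-mean-square deviation between simulated and observed
#' values divided by that cluster's observed range, averaged over
#' clusters. Provided as a secondary error metric only; clusters with
#' zero observed range are excluded with a warning.
#'
#' @inheritParams weighted_correlation_performance
#' @return Mean normalized RMSD (0 = perfect).
#' @export
rmsd_performance <- function(sim, obs) {
  sim_m <- if (inherits(sim, "trajectory")) sim$values else sim
  obs_m <- if (inherits(obs, "time_course")) obs$observed else obs
  if (!all(dim(sim_m) == dim(obs_m))) stop("mismatched shapes", call. = FALSE)
  rng <- apply(obs_m, 1, function(x) diff(range(x)))
  keep <- rng > 0
  if (!all(keep)) {
    warning(sprintf("%d cluster(s) with zero observed range excluded", sum(!keep)))
  }
  if (!any(keep)) stop("no cluster with nonzero observed range", call. = FALSE)
  rmsd <- sqrt(rowMeans((sim_m - obs_m)^2))
  mean(rmsd[keep] / rng[keep])
}

#' Read / write influence model matrices as TSV
#'
#' The matrix is written K rows x K columns with row = target cluster and
#' column = regulator cluster, with cluster ids as row and column names.
#'
#' @param model an [influence_model()].
#' @param path TSV path.
#' @param digits decimal digits (fixed precision).
#' @return `path` (write) or an `influence_model` (read).
#' @export
write_model_tsv <- function(model, path, digits = 10) {
  stopifnot(inherits(model, "influence_model"))
  df <- data.frame(cluster = model$cluster_ids,
                   formatC(model$A, format = "g", digits = digits),
                   check.names = FALSE)
  names(df)[-1] <- model$cluster_ids
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param gene_counts gene counts to attach on read (the TSV stores only
#'   the matrix).
#' @rdname write_model_tsv
#' @export
read_model_tsv <- function(path, gene_counts = NULL) {
  df <- read.delim(path, check.names = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df[[1]]
  storage.mode(A) <- "double"
  if (is.null(gene_counts)) gene_counts <- rep(1L, nrow(A))
  influence_model(A, gene_counts, cluster_ids = df[[1]])
}
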
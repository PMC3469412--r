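#' Generate a planted ground-truth influence model
#'
#' Off-diagonal influences are drawn independently with probability
#' `edge_density`; their weights have random sign and magnitude
#' `U(0.1, 1)`. Per-cluster decay constants are `tau ~ U(5, 50)` hours,
#' folded into the diagonal as `-1/tau`. The off-diagonal block is then
#' shrunk uniformly (factor 0.9 per iteration) until the spectral
#' abscissa of `A` is at most `-0.005` per hour, so every trajectory is
#' bounded over the ~100 h study horizon while still allowing transient
#' rises.
#'
#' @param n_clusters number of clusters K (>= 2).
#' @param edge_density probability of each off-diagonal influence, in
#'   (0, 1].
#' @param gene_counts genes per cluster (recycled to length K); default
#'   20.
#' @param seed integer seed.
#' @param stability_margin required upper bound on eigenvalue real parts
#'   (per hour).
#' @return An [influence_model()] with attribute `"w"` (the raw
#'   off-diagonal influence matrix before decay folding).
#' @export
generate_truth_model <- function(n_clusters, edge_density, gene_counts = 20L,
                                 seed = 1L, stability_margin = -0.005) {
  if (n_clusters < 2) stop("need at least 2 clusters", call. = FALSE)
  if (edge_density <= 0 || edge_density > 1) {
    stop("edge_density must be in (0,1]", call. = FALSE)
  }
  set.seed(seed)
  K <- n_clusters
  w <- matrix(0, K, K)
  off <- which(!diag(TRUE, K))
  present <- off[runif(length(off)) < edge_density]
  w[present] <- sample(c(-1, 1), length(present), replace = TRUE) *
    runif(length(present), 0.1, 1.0)
  tau <- runif(K, 5, 50)
  shrink <- function(wm) {
    A <- wm
    diag(A) <- -1 / tau
    for (it in 1:200) {
      if (max(Re(eigen(A, only.values = TRUE)$values)) <= stability_margin) {
        return(A)
      }
      A[!diag(TRUE, K)] <- A[!diag(TRUE, K)] * 0.9
    }
    stop("could not stabilize the truth model", call. = FALSE)
  }
  A <- shrink(w)
  gene_counts <- rep_len(as.integer(gene_counts), K)
  model <- influence_model(A, gene_counts, tau = tau)
  w_final <- A
  diag(w_final) <- 0
  attr(model, "w") <- w_final
  model
}

#' Bundle of parameters describing a synthetic ground truth
#'
#' @param model a planted [influence_model()] (see
#'   [generate_truth_model()]).
#' @param sigma_obs cluster-level observation noise sd (log2FC units).
#' @param sigma_gene gene-level noise sd around the cluster value.
#' @param purity probability that a gene is annotated with its own
#'   cluster's term rather than a random other term, in [0,1].
#' @param concordance fraction of interaction mass placed on true model
#'   edges rather than random background, in [0,1].
#' @param seed integer seed for all downstream draws.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(model, sigma_obs = 0.1, sigma_gene = 0.3,
                            purity = 0.9, concordance = 0.9, seed = 1L) {
  stopifnot(inherits(model, "influence_model"))
  if (purity < 0 || purity > 1) stop("purity must be in [0,1]", call. = FALSE)
  if (concordance < 0 || concordance > 1) {
    stop("concordance must be in [0,1]", call. = FALSE)
  }
  if (sigma_obs < 0 || sigma_gene < 0) stop("noise sds must be >= 0", call. = FALSE)
  structure(list(model = model, sigma_obs = sigma_obs, sigma_gene = sigma_gene,
                 purity = purity, concordance = concordance,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Generate a synthetic expression dataset from a planted model
#'
#' Emulates parallel pretreatment condition courses: per treatment, a
#' cluster initial state is drawn `N(0, 1)`, the cluster trajectory is
#' the closed-form solution of the planted ODE system at the requested
#' times, the observed cluster value adds `N(0, sigma_obs^2)`, and each
#' member gene adds `N(0, sigma_gene^2)` around its cluster's observed
#' value. All draws derive from the truth seed.
#'
#' @param truth a [synthetic_truth()].
#' @param treatments character vector of treatment labels (default five
#'   pretreatments).
#' @param times observation times in hours (default 3, 24, 72, 75, 96).
#' @return List with `table` ([expression_table()]), `assignment` (named
#'   integer vector), `profiles` (observed [cluster_mean_profiles()]),
#'   `courses` (list of [time_course()] of observed cluster values), and
#'   `true_trajectories` (noise-free cluster trajectories per treatment).
#' @export
generate_expression_dataset <- function(truth,
                                        treatments = c("lps", "cpg", "ip",
                                                       "saline", "sham"),
                                        times = c(3, 24, 72, 75, 96)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  model <- truth$model
  K <- model$n_clusters
  gene_counts <- model$gene_counts
  gene_ids <- unlist(lapply(seq_len(K), function(k) {
    sprintf("g%02d_%03d", k, seq_len(gene_counts[k]))
  }))
  assignment <- rep(seq_len(K), gene_counts)
  names(assignment) <- gene_ids
  set.seed(derive_seed(truth$seed, "expression"))
  courses <- list()
  true_traj <- list()
  blocks <- list()
  meta <- list()
  for (tr in treatments) {
    c0 <- rnorm(K)
    traj <- simulate_trajectory(model, c0, times)
    obs <- traj$values + matrix(rnorm(K * length(times), 0, truth$sigma_obs),
                                K, length(times))
    true_traj[[tr]] <- traj
    courses[[tr]] <- time_course(tr, times, obs, model$cluster_ids)
    gene_vals <- obs[assignment, , drop = FALSE] +
      matrix(rnorm(length(gene_ids) * length(times), 0, truth$sigma_gene),
             length(gene_ids), length(times))
    colnames(gene_vals) <- sprintf("%s_t%g", tr, times)
    blocks[[tr]] <- gene_vals
    meta[[tr]] <- data.frame(sample = colnames(gene_vals), treatment = tr,
                             time_h = times)
  }
  values <- do.call(cbind, blocks)
  rownames(values) <- gene_ids
  table <- expression_table(values, do.call(rbind, meta))
  profiles <- cluster_mean_profiles(table, assignment)
  list(table = table, assignment = assignment, profiles = profiles,
       courses = courses, true_trajectories = true_traj)
}

#' Generate synthetic annotations and interaction sets
#'
#' Annotations: one private functional term per planted cluster; each
#' gene receives its own cluster's term with probability `purity`, else
#' the term of a uniformly chosen other cluster. Interactions: for each
#' true influence (l -> i), gene pairs (g in l, h in i) are included so
#' that the expected count per true edge is `10 * concordance`; random
#' background pairs are added so the expected background total is
#' `10 * (1 - concordance) * n_true_edges`.
#'
#' @param truth a [synthetic_truth()].
#' @param assignment named integer assignment as produced by
#'   [generate_expression_dataset()] (defaults to the truth model's
#'   block assignment).
#' @return List with `annotations` (named list gene -> terms) and
#'   `interactions` (list of one directed [interaction_set()]).
#' @export
generate_validation_data <- function(truth, assignment = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  model <- truth$model
  K <- model$n_clusters
  if (is.null(assignment)) {
    gene_counts <- model$gene_counts
    gene_ids <- unlist(lapply(seq_len(K), function(k) {
      sprintf("g%02d_%03d", k, seq_len(gene_counts[k]))
    }))
    assignment <- rep(seq_len(K), gene_counts)
    names(assignment) <- gene_ids
  }
  assignment <- validate_assignment(assignment)
  genes <- names(assignment)
  set.seed(derive_seed(truth$seed, "validation"))
  terms <- paste0("TERM", seq_len(K))
  annot <- lapply(seq_along(genes), function(gi) {
    own <- assignment[gi]
    if (runif(1) < truth$purity) terms[own]
    else terms[sample(setdiff(seq_len(K), own), 1)]
  })
  names(annot) <- genes
  # interactions concentrated on true edges, diluted by background
  w <- model$A
  diag(w) <- 0
  true_edges <- which(w != 0, arr.ind = TRUE) # (target, regulator)
  n_true <- nrow(true_edges)
  edge_rows <- list()
  per_edge <- 10 * truth$concordance
  if (n_true > 0 && per_edge > 0) {
    for (r in seq_len(n_true)) {
      src_genes <- genes[assignment == true_edges[r, 2]]
      dst_genes <- genes[assignment == true_edges[r, 1]]
      n_pairs <- length(src_genes) * length(dst_genes)
      p_inc <- min(per_edge / n_pairs, 1)
      pick <- which(runif(n_pairs) < p_inc)
      if (length(pick) > 0) {
        ij <- arrayInd(pick, c(length(src_genes), length(dst_genes)))
        edge_rows[[length(edge_rows) + 1]] <- data.frame(
          gene_a = src_genes[ij[, 1]], gene_b = dst_genes[ij[, 2]])
      }
    }
  }
  n_bg <- stats::rpois(1, 10 * (1 - truth$concordance) * max(n_true, 1))
  if (n_bg > 0) {
    edge_rows[[length(edge_rows) + 1]] <- data.frame(
      gene_a = sample(genes, n_bg, replace = TRUE),
      gene_b = sample(genes, n_bg, replace = TRUE))
  }
  edges <- if (length(edge_rows) > 0) do.call(rbind, edge_rows)
           else data.frame(gene_a = character(0), gene_b = character(0))
  list(annotations = annot,
       interactions = list(synthetic = interaction_set("synthetic", edges,
                                                       directed = TRUE)))
}
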
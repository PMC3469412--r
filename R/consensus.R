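#' Summarize an ensemble of influence models edge-wise
#'
#' For every cell of the influence matrix: the number of ensemble models
#' in which it is nonzero, and the mean, median, and range of its values
#' over the whole ensemble (absent treated as 0, matching the combined
#' mean/median model construction).
#'
#' @param models list of [influence_model()]s over the same clusters.
#' @return An object of class `edge_summary`: list with `count`, `mean`,
#'   `median`, `min`, `max` matrices and `n_models`.
#' @export
ensemble_summary <- function(models) {
  if (length(models) == 0) stop("empty ensemble", call. = FALSE)
  K <- models[[1]]$n_clusters
  for (m in models) {
    if (m$n_clusters != K) stop("shape mismatch in ensemble", call. = FALSE)
  }
  arr <- vapply(models, function(m) m$A, matrix(0, K, K))
  structure(list(
    count = apply(arr != 0, c(1, 2), sum),
    mean = apply(arr, c(1, 2), mean),
    median = apply(arr, c(1, 2), median),
    min = apply(arr, c(1, 2), min),
    max = apply(arr, c(1, 2), max),
    n_models = length(models)
  ), class = "edge_summary")
}

#' Group-consensus model over member condition models
#'
#' An edge enters the consensus when it is nonzero in at least
#' `ceiling(presence_fraction * n_members)` member models (default: half,
#' so 1 of 2 or 2 of 3); its consensus weight is the mean of its values
#' over the members in which it is present. Edges whose present-member
#' mean is exactly zero are treated as absent.
#'
#' @param best_models named list of [influence_model()]s, one per member
#'   condition (e.g. the saline and sham models for the injurious group).
#' @param presence_fraction required fraction of members (default 0.5).
#' @param label group label (e.g. "injurious").
#' @return An object of class `group_consensus`: list with `label`,
#'   `members`, `consensus` (K x K matrix), `presence_fraction`,
#'   `presence_counts`.
#' @export
group_consensus <- function(best_models, presence_fraction = 0.5,
                            label = "group") {
  if (length(best_models) == 0) stop("empty group", call. = FALSE)
  K <- best_models[[1]]$n_clusters
  for (m in best_models) {
    if (m$n_clusters != K) stop("shape mismatch in group", call. = FALSE)
  }
  arr <- vapply(best_models, function(m) m$A, matrix(0, K, K))
  counts <- apply(arr != 0, c(1, 2), sum)
  need <- ceiling(presence_fraction * length(best_models))
  present_sum <- apply(arr, c(1, 2), sum)
  consensus <- ifelse(counts >= need & counts > 0, present_sum / pmax(counts, 1), 0)
  consensus[!is.finite(consensus)] <- 0
  structure(list(label = label, members = names(best_models),
                 consensus = consensus, presence_fraction = presence_fraction,
                 presence_counts = counts, n_members = length(best_models)),
            class = "group_consensus")
}

#' Edge-wise comparison of two group-consensus models
#'
#' Every edge present in at least one group is classified: present in
#' both with the same sign is `conserved`; present in exactly one group
#' is `differential`; present in both with opposite signs is `opposite`.
#' Differential and opposite edges are the candidates for regulatory
#' differences between the two condition groups.
#'
#' @param a,b `group_consensus` objects over the same clusters.
#' @return Data.frame with columns `source`, `target`, `weight_a`,
#'   `weight_b`, `status`.
#' @export
compare_groups <- function(a, b) {
  stopifnot(inherits(a, "group_consensus"), inherits(b, "group_consensus"))
  if (!all(dim(a$consensus) == dim(b$consensus))) {
    stop("shape mismatch between groups", call. = FALSE)
  }
  wa <- a$consensus
  wb <- b$consensus
  idx <- which(wa != 0 | wb != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(source = integer(0), target = integer(0),
                      weight_a = numeric(0), weight_b = numeric(0),
                      status = character(0)))
  }
  va <- wa[idx]
  vb <- wb[idx]
  status <- ifelse(va != 0 & vb != 0 & sign(va) == sign(vb), "conserved",
            ifelse(va != 0 & vb != 0, "opposite", "differential"))
  # influence matrix rows are targets, columns regulators (sources)
  out <- data.frame(source = idx[, 2], target = idx[, 1],
                    weight_a = va, weight_b = vb, status = status)
  out[order(out$source, out$target), , drop = FALSE]
}
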
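#' Build one hierarchical tree and cut it at several divisions
#'
#' Genes are clustered by agglomerative hierarchical clustering with
#' Ward's minimum-variance linkage on Euclidean distances between their
#' log2 fold-change profiles (`hclust` method `ward.D2`, which applies
#' Ward's criterion to unsquared Euclidean distances). All requested
#' divisions are cuts of this single tree, so partitions at increasing K
#' are nested refinements.
#'
#' @param table an [expression_table()].
#' @param divisions integer vector of cluster counts K to extract; each
#'   must lie in `[1, n_genes]`.
#' @return Named list mapping each K (as character) to a named integer
#'   assignment vector (gene id -> cluster index 1..K).
#' @export
build_tree_and_cut <- function(table, divisions) {
  stopifnot(inherits(table, "expression_table"))
  n <- nrow(table$values)
  if (n < 2) stop("need at least 2 genes to cluster", call. = FALSE)
  divisions <- as.integer(divisions)
  if (any(divisions < 1) || any(divisions > n)) {
    stop("each division K must be in [1, n_genes]", call. = FALSE)
  }
  tree <- hclust(dist(table$values, method = "euclidean"), method = "ward.D2")
  out <- lapply(divisions, function(K) {
    ct <- cutree(tree, k = K)
    # relabel clusters to contiguous 1..K in order of first appearance
    ct <- match(ct, unique(ct))
    names(ct) <- rownames(table$values)
    ct
  })
  names(out) <- as.character(divisions)
  out
}

#' Hypergeometric enrichment of a functional term in a cluster
#'
#' One-sided hypergeometric tail probability of drawing at least the
#' observed number of term-annotated genes in a cluster of this size,
#' when sampling without replacement from the universe of differentially
#' expressed genes (the cluster is tested against all other genes).
#'
#' @param cluster_genes character vector of gene ids in the cluster.
#' @param universe character vector of all clustered gene ids; must
#'   contain `cluster_genes`.
#' @param annot named list mapping gene id to a character vector of term
#'   ids (possibly empty).
#' @param term term id to test.
#' @return The enrichment p-value, `P(X >= observed)`.
#' @export
enrich_cluster <- function(cluster_genes, universe, annot, term) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (!all(cluster_genes %in% universe)) {
    stop("cluster genes must be a subset of the universe", call. = FALSE)
  }
  has_term <- vapply(universe, function(g) term %in% annot[[g]], logical(1))
  m <- sum(has_term)                           # term genes in universe
  k <- sum(cluster_genes %in% universe[has_term])
  n_draw <- length(cluster_genes)
  if (k == 0) return(1)
  # P(X >= k), X ~ Hypergeom(universe = N, white = m, draws = n_draw)
  phyper(k - 1, m, length(universe) - m, n_draw, lower.tail = FALSE)
}

#' Functional-coherence curve over clustering divisions
#'
#' For each division K and each p-value threshold, every (cluster, term)
#' pair with at least one annotated member is tested with
#' [enrich_cluster()]; a term is enriched in a cluster when its p-value
#' is strictly below the threshold. The coherence score of a division is
#' the number of genes annotated with at least one term enriched in their
#' own cluster. The best division per threshold maximizes this score,
#' with ties broken toward the smallest K (parsimony).
#'
#' @param assignments named list of assignment vectors as returned by
#'   [build_tree_and_cut()].
#' @param annot named list mapping gene id to character vector of terms.
#' @param thresholds numeric vector of enrichment cutoffs in (0,1).
#' @return An object of class `coherence_curve`: list with `divisions`,
#'   `thresholds`, `scores` (divisions x thresholds gene counts),
#'   `normalized` (scores divided by the number of annotated genes), and
#'   `best_division` (one K per threshold).
#' @export
coherence_curve <- function(assignments, annot, thresholds = c(0.05, 0.01, 0.001)) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie in (0,1)", call. = FALSE)
  }
  divisions <- as.integer(names(assignments))
  scores <- matrix(0L, length(divisions), length(thresholds),
                   dimnames = list(names(assignments), as.character(thresholds)))
  for (d in seq_along(divisions)) {
    assign <- validate_assignment(assignments[[d]])
    universe <- names(assign)
    for (k in seq_len(attr(assign, "K"))) {
      members <- universe[assign == k]
      terms <- unique(unlist(annot[members], use.names = FALSE))
      if (length(terms) == 0) next
      pvals <- vapply(terms, function(tm) {
        enrich_cluster(members, universe, annot, tm)
      }, numeric(1))
      for (j in seq_along(thresholds)) {
        enriched <- terms[pvals < thresholds[j]]
        if (length(enriched) == 0) next
        covered <- vapply(members, function(g) {
          any(annot[[g]] %in% enriched)
        }, logical(1))
        scores[d, j] <- scores[d, j] + sum(covered)
      }
    }
  }
  universe0 <- names(assignments[[1]])
  total_annot <- sum(vapply(universe0, function(g) length(annot[[g]]) > 0, logical(1)))
  ord <- order(divisions) # smallest K wins ties regardless of input order
  best <- apply(scores, 2, function(s) divisions[ord][which.max(s[ord])])
  structure(list(divisions = divisions, thresholds = thresholds,
                 scores = scores,
                 normalized = scores / max(total_annot, 1L),
                 n_annotated = total_annot,
                 best_division = best),
            class = "coherence_curve")
}

#' Diagnostic: within- versus between-cluster expression correlation
#'
#' Mean Pearson correlation between gene profiles within the same cluster
#' versus genes in different clusters; a descriptive check of expression
#' coherence, not a selection criterion.
#'
#' @param table an [expression_table()].
#' @param assign named integer assignment vector.
#' @return List with `within` and `between` mean correlations.
#' @export
cluster_correlation_diagnostic <- function(table, assign) {
  assign <- validate_assignment(assign)
  cm <- cor(t(table$values[names(assign), , drop = FALSE]))
  same <- outer(assign, assign, "==")
  ut <- upper.tri(cm)
  list(within = mean(cm[ut & same]), between = mean(cm[ut & !same]))
}
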
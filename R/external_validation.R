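#' Construct a gene-gene interaction set
#'
#' @param name dataset label (e.g. ChIP, PPI, regulatory, functional).
#' @param edges data.frame (or 2-column matrix) with columns `gene_a`,
#'   `gene_b`; duplicate rows are collapsed; self-edges are permitted.
#' @param directed whether edges are directed (`gene_a` -> `gene_b`).
#'   Undirected edges are counted in both directions downstream.
#' @return An object of class `interaction_set`.
#' @export
interaction_set <- function(name, edges, directed = TRUE) {
  edges <- as.data.frame(edges)
  names(edges)[1:2] <- c("gene_a", "gene_b")
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  edges <- unique(edges[, c("gene_a", "gene_b")])
  rownames(edges) <- NULL
  structure(list(name = name, edges = edges, directed = isTRUE(directed)),
            class = "interaction_set")
}

#' Read an interaction set from TSV
#'
#' Columns `gene_a`, `gene_b`; an optional first-line directive
#' `#directed=true|false` overrides the `directed` argument.
#'
#' @param path TSV path.
#' @param name dataset label; default the file name.
#' @param directed default directedness when no directive is present.
#' @return An [interaction_set()].
#' @export
read_interaction_set <- function(path, name = basename(path), directed = TRUE) {
  first <- readLines(path, n = 1)
  if (grepl("^#directed=", first)) {
    directed <- tolower(sub("^#directed=", "", first)) == "true"
  }
  df <- read.delim(path, comment.char = "#")
  interaction_set(name, df, directed)
}

#' Count interactions between every ordered cluster pair
#'
#' `count[s, t]` is the number of interaction edges whose source gene
#' lies in cluster `s` and target gene in cluster `t`; for undirected
#' sets each edge contributes to both `(s, t)` and `(t, s)`. The diagonal
#' holds within-cluster counts. Edges with an endpoint outside the
#' clustered genes are dropped (their number is attached as attribute
#' `n_dropped`).
#'
#' @param assign named integer assignment vector (gene -> cluster).
#' @param iset an [interaction_set()].
#' @return K x K integer count matrix.
#' @export
pair_interaction_counts <- function(assign, iset) {
  assign <- validate_assignment(assign)
  K <- attr(assign, "K")
  e <- iset$edges
  keep <- e$gene_a %in% names(assign) & e$gene_b %in% names(assign)
  dropped <- sum(!keep)
  e <- e[keep, , drop = FALSE]
  counts <- matrix(0L, K, K)
  if (nrow(e) > 0) {
    ca <- assign[e$gene_a]
    cb <- assign[e$gene_b]
    for (r in seq_along(ca)) {
      counts[ca[r], cb[r]] <- counts[ca[r], cb[r]] + 1L
      if (!iset$directed && (ca[r] != cb[r] || e$gene_a[r] != e$gene_b[r])) {
        counts[cb[r], ca[r]] <- counts[cb[r], ca[r]] + 1L
      }
    }
  }
  attr(counts, "n_dropped") <- dropped
  counts
}

#' Permutation p-values for cluster-pair interaction counts
#'
#' Null replicates randomize gene labels: a uniformly random permutation
#' of the clustered-gene identities is applied to all edge endpoints, so
#' each replicate has the same genes, the same number of edges, and the
#' same topology. `p[s, t]` is the smoothed upper-tail rank
#' `(1 + #\{null count >= observed\}) / (n_reps + 1)`.
#'
#' @param assign named integer assignment vector.
#' @param iset an [interaction_set()].
#' @param n_reps permutation replicates (default 1000).
#' @param seed integer seed.
#' @return K x K matrix of p-values (attribute `observed` carries the
#'   observed count matrix).
#' @export
rewire_pvalues <- function(assign, iset, n_reps = 1000, seed = 1L) {
  assign <- validate_assignment(assign)
  if (length(assign) < 2) stop("need at least 2 clustered genes", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  observed <- pair_interaction_counts(assign, iset)
  K <- attr(assign, "K")
  genes <- names(assign)
  ge <- sum_tail <- matrix(0L, K, K)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    relabel <- setNames(sample(genes), genes) # permute gene identities
    perm <- iset
    perm$edges$gene_a <- unname(relabel[perm$edges$gene_a])
    perm$edges$gene_b <- unname(relabel[perm$edges$gene_b])
    cnt <- pair_interaction_counts(assign, perm)
    ge <- ge + (cnt >= observed)
  }
  p <- (1 + ge) / (n_reps + 1)
  attr(p, "observed") <- observed
  p
}

#' Label cluster pairs against a model and compute validation accuracy
#'
#' For each interaction dataset and each ordered off-diagonal cluster
#' pair: a model influence with a significant interaction count
#' (`p < alpha`) is a true positive (TP); a model influence without
#' support is labeled a false negative (FN); no influence with no
#' support is a true negative (TN); no influence but a significant count
#' is a false positive (FP). (The TP/FN/FP/TN naming follows the
#' validation convention of treating the external data as ground truth
#' for present influences.) Accuracy is `(TP + TN) / (TP + TN + FP +
#' FN)`. The combined "any" accuracy counts a pair correct if it is TP
#' or TN under at least one dataset. Within-cluster counts never enter
#' accuracy; they are reported as a separate diagnostic.
#'
#' @param model an [influence_model()].
#' @param pvals named list of K x K p-value matrices, one per dataset
#'   (from [rewire_pvalues()]).
#' @param alpha significance threshold in (0,1); default 0.05.
#' @return An object of class `validation_table`: `pairs` (long
#'   data.frame with dataset, source, target, p_value, model_edge,
#'   label), `accuracy` (per dataset), `any_accuracy`,
#'   `within_cluster` (data.frame of diagonal p-values per dataset).
#' @export
validation_accuracy <- function(model, pvals, alpha = 0.05) {
  stopifnot(inherits(model, "influence_model"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  K <- model$n_clusters
  for (p in pvals) {
    if (!all(dim(p) == c(K, K))) stop("mismatched cluster sets", call. = FALSE)
  }
  if (is.null(names(pvals))) names(pvals) <- paste0("dataset_", seq_along(pvals))
  # p/count matrices are source x target; the model matrix is target x
  # source (rows = target cluster)
  idx <- which(!diag(TRUE, K), arr.ind = TRUE) # (source, target) pairs
  edge <- model$A[cbind(idx[, 2], idx[, 1])] != 0
  rows <- lapply(names(pvals), function(nm) {
    pv <- pvals[[nm]][idx]
    sig <- pv < alpha
    label <- ifelse(edge & sig, "TP",
             ifelse(edge & !sig, "FN",
             ifelse(!edge & !sig, "TN", "FP")))
    data.frame(dataset = nm, source = idx[, 1], target = idx[, 2],
               p_value = pv, model_edge = edge, label = label)
  })
  pairs <- do.call(rbind, rows)
  acc <- vapply(split(pairs$label, pairs$dataset), function(l) {
    mean(l %in% c("TP", "TN"))
  }, numeric(1))[names(pvals)]
  # combined: a pair is correct if TP or TN under at least one dataset
  key <- paste(pairs$source, pairs$target)
  correct_any <- tapply(pairs$label %in% c("TP", "TN"), key, any)
  within <- data.frame(
    cluster = seq_len(K),
    vapply(pvals, function(p) diag(p), numeric(K))
  )
  structure(list(pairs = pairs, accuracy = acc,
                 any_accuracy = mean(correct_any),
                 within_cluster = within, alpha = alpha),
            class = "validation_table")
}
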
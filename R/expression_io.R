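#' Construct an expression table
#'
#' An expression table holds a genes x samples matrix of log2 fold-change
#' values (relative to an untreated baseline) together with per-sample
#' metadata: the treatment label and the time in hours post-pretreatment.
#' Samples are reordered internally by (treatment, time_h) so downstream
#' behavior does not depend on file column order.
#'
#' @param values numeric matrix, rows = genes (rownames = gene ids),
#'   columns = samples (colnames = sample names); all values finite.
#' @param samples data.frame with columns `sample`, `treatment`, `time_h`;
#'   one row per column of `values`, matched by name.
#' @return An object of class `expression_table` with elements `values`
#'   and `samples`.
#' @export
expression_table <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values))) stop("`values` needs gene ids as rownames", call. = FALSE)
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids in expression table", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("non-finite expression values", call. = FALSE)
  req <- c("sample", "treatment", "time_h")
  if (!all(req %in% names(samples))) {
    stop("sample metadata needs columns sample, treatment, time_h", call. = FALSE)
  }
  samples$time_h <- as.numeric(samples$time_h)
  if (any(!is.finite(samples$time_h)) || any(samples$time_h < 0)) {
    stop("time_h must be finite and non-negative", call. = FALSE)
  }
  if (nrow(samples) != ncol(values)) {
    stop("metadata row count does not match sample columns", call. = FALSE)
  }
  if (is.null(colnames(values)) || !setequal(colnames(values), samples$sample)) {
    stop("sample names in metadata do not match expression columns", call. = FALSE)
  }
  if (anyDuplicated(samples[, c("treatment", "time_h")])) {
    stop("duplicate (treatment, time_h) pairs in metadata", call. = FALSE)
  }
  ord <- order(samples$treatment, samples$time_h)
  samples <- samples[ord, req, drop = FALSE]
  rownames(samples) <- NULL
  values <- values[, samples$sample, drop = FALSE]
  structure(list(values = values, samples = samples), class = "expression_table")
}

#' Read an expression table and its sample metadata from TSV files
#'
#' The expression file has a header row of sample names and a first column
#' `gene_id`; remaining cells are decimal log2 fold changes. The metadata
#' file has columns `sample`, `treatment`, `time_h`.
#'
#' @param path expression TSV path.
#' @param meta_path metadata TSV path.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path, meta_path) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (names(raw)[1] != "gene_id") stop("first column must be `gene_id`", call. = FALSE)
  ids <- raw$gene_id
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate gene id '%s' in %s", ids[duplicated(ids)][1], path),
         call. = FALSE)
  }
  num <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(ids, names(raw)[-1]))
  if (anyNA(num)) stop("non-numeric expression cell", call. = FALSE)
  meta <- read.delim(meta_path, check.names = FALSE)
  if (!all(meta$sample %in% colnames(num))) {
    missing <- setdiff(meta$sample, colnames(num))
    stop(sprintf("metadata sample '%s' absent from expression header", missing[1]),
         call. = FALSE)
  }
  expression_table(num, meta)
}

#' Write an expression table (and optionally its metadata) to TSV
#'
#' @param table an [expression_table()].
#' @param path expression TSV output path.
#' @param meta_path optional metadata TSV output path.
#' @param digits decimal digits for values (fixed precision so a
#'   write/read round trip is exact as text).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path, meta_path = NULL, digits = 6) {
  stopifnot(inherits(table, "expression_table"))
  df <- data.frame(gene_id = rownames(table$values),
                   formatC(table$values, format = "f", digits = digits),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    write.table(table$samples, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Filter probes by differential-expression significance and fold change
#'
#' Keeps genes with p-value strictly below `p_max` and maximum absolute
#' linear fold change strictly above `fc_min`, the probe filter applied
#' before clustering. Fold change is interpreted on the linear scale; if
#' the statistics carry absolute log2 fold changes use
#' `max_abs_fc = 2^max|log2FC|` upstream.
#'
#' @param stats data.frame with columns `gene_id`, `p_value`, `max_abs_fc`.
#' @param p_max significance cutoff in (0,1); default 0.05.
#' @param fc_min linear fold-change cutoff (> 1); default 2.0.
#' @return Character vector of kept gene ids (possibly empty).
#' @export
filter_probes <- function(stats, p_max = 0.05, fc_min = 2.0) {
  if (p_max <= 0 || p_max >= 1) stop("p_max must be in (0,1)", call. = FALSE)
  if (fc_min <= 1) stop("fc_min must exceed 1 (linear scale)", call. = FALSE)
  if (NROW(stats) == 0) return(character(0))
  req <- c("gene_id", "p_value", "max_abs_fc")
  if (!all(req %in% names(stats))) {
    stop("stats needs columns gene_id, p_value, max_abs_fc", call. = FALSE)
  }
  if (any(stats$p_value < 0 | stats$p_value > 1)) {
    stop("p_value outside [0,1]", call. = FALSE)
  }
  keep <- stats$p_value < p_max & stats$max_abs_fc > fc_min
  as.character(stats$gene_id[keep])
}

#' Cluster mean expression profiles
#'
#' Row `i` of the result is the unweighted arithmetic mean over the rows
#' of the genes assigned to cluster `i`; these mean profiles are the
#' dynamic variables of the influence model.
#'
#' @param table an [expression_table()].
#' @param assign named integer vector mapping gene id to cluster index
#'   (1..K, contiguous).
#' @return An object of class `cluster_profiles`: list with `values`
#'   (K x samples matrix), `gene_counts`, `cluster_ids`, and the sample
#'   metadata carried over.
#' @export
cluster_mean_profiles <- function(table, assign) {
  stopifnot(inherits(table, "expression_table"))
  assign <- validate_assignment(assign)
  K <- attr(assign, "K")
  missing <- setdiff(names(assign), rownames(table$values))
  if (length(missing) > 0) {
    stop(sprintf("gene '%s' in assignment missing from table", missing[1]),
         call. = FALSE)
  }
  counts <- tabulate(assign, nbins = K)
  if (any(counts == 0)) stop("cluster with zero members", call. = FALSE)
  vals <- matrix(0, K, ncol(table$values),
                 dimnames = list(paste0("cluster_", seq_len(K)),
                                 colnames(table$values)))
  for (k in seq_len(K)) {
    rows <- table$values[names(assign)[assign == k], , drop = FALSE]
    vals[k, ] <- colMeans(rows)
  }
  structure(list(values = vals, gene_counts = counts,
                 cluster_ids = rownames(vals), samples = table$samples),
            class = "cluster_profiles")
}

# Validate a gene -> cluster assignment: named, contiguous indices 1..K.
validate_assignment <- function(assign) {
  if (is.null(names(assign)) || anyDuplicated(names(assign))) {
    stop("assignment must be a named vector with unique gene ids", call. = FALSE)
  }
  nm <- names(assign)
  assign <- as.integer(assign)
  names(assign) <- nm
  K <- max(assign)
  if (min(assign) < 1 || !all(seq_len(K) %in% assign)) {
    stop("cluster indices must be contiguous 1..K", call. = FALSE)
  }
  attr(assign, "K") <- K
  assign
}
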
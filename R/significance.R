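#' Randomize an influence matrix
#'
#' Three null constructions over the effective matrix `A` (diagonal
#' included):
#' \describe{
#'   \item{resample}{permute the multiset of nonzero values among the
#'     existing nonzero positions — structure preserved, values shuffled.}
#'   \item{uniform}{replace each nonzero value with an independent draw
#'     from `U(-2, 2)` — structure preserved, values discarded.}
#'   \item{scramble}{permute all entries (zeros included) over all
#'     positions — structure destroyed, value multiset preserved.}
#' }
#' A randomized diagonal may imply a non-positive decay constant; that is
#' permitted for null models, where `A` is taken at face value.
#'
#' @param model an [influence_model()].
#' @param mode one of `"resample"`, `"uniform"`, `"scramble"`.
#' @return A randomized `influence_model`. Consumes the R RNG stream.
#' @export
randomize_matrix <- function(model, mode = c("resample", "uniform", "scramble")) {
  mode <- match.arg(mode)
  A <- model$A
  nz <- which(A != 0)
  if (mode == "resample") {
    A[nz] <- A[nz][sample.int(length(nz))]
  } else if (mode == "uniform") {
    A[nz] <- runif(length(nz), -2, 2)
  } else {
    A[] <- A[sample.int(length(A))]
  }
  out <- model
  out$A <- A
  out$tau <- NULL
  out
}

#' Significance of dynamic performance against a randomization null
#'
#' Simulates the model from the course's initial state and scores it with
#' the gene-count-weighted correlation; repeats for `n_reps` randomized
#' matrices to form the null distribution. The empirical p-value is the
#' smoothed rank `(1 + #\{null >= observed\}) / (n_reps + 1)`; the
#' parametric p-value is the one-sided upper tail of a normal with the
#' null sample mean and standard deviation (reported because very small
#' tail probabilities are unreachable from a finite number of replicates;
#' the empirical rank is the defensible default).
#'
#' @param model an [influence_model()].
#' @param course a [time_course()].
#' @param mode randomization mode, see [randomize_matrix()].
#' @param n_reps number of null replicates (>= 1; default 100).
#' @param seed integer seed.
#' @return An object of class `null_result`: `mode`, `n_reps`,
#'   `null_scores`, `observed`, `empirical_p`, `parametric_p` (NA when
#'   the null sd is 0), `null_mean`, `null_sd`.
#' @export
significance_test <- function(model, course, mode = "scramble",
                              n_reps = 100, seed = 1L) {
  stopifnot(inherits(model, "influence_model"), inherits(course, "time_course"))
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  observed <- sa_fitness(model$A, course, model$gene_counts)
  set.seed(seed)
  null_scores <- vapply(seq_len(n_reps), function(r) {
    rnd <- randomize_matrix(model, mode)
    sa_fitness(rnd$A, course, model$gene_counts)
  }, numeric(1))
  mu <- mean(null_scores)
  sdv <- sd(null_scores)
  structure(list(mode = mode, n_reps = as.integer(n_reps),
                 null_scores = null_scores, observed = observed,
                 empirical_p = (1 + sum(null_scores >= observed)) / (n_reps + 1),
                 parametric_p = parametric_null_p(observed, mu, sdv),
                 null_mean = mu, null_sd = sdv),
            class = "null_result")
}

#' One-sided normal tail p-value for an observed score against null
#' summary statistics
#'
#' `P(Z >= (observed - mean) / sd)` under a normal null; `NA` when the
#' null standard deviation is zero (degenerate null).
#'
#' @param observed observed performance score.
#' @param null_mean,null_sd null-distribution mean and standard deviation.
#' @return Upper-tail probability, or `NA`.
#' @export
parametric_null_p <- function(observed, null_mean, null_sd) {
  if (!is.finite(null_sd) || null_sd == 0) return(NA_real_)
  pnorm(observed, mean = null_mean, sd = null_sd, lower.tail = FALSE)
}
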
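two_cluster_assign <- c(a = 1L, b = 1L, c = 2L, d = 2L)

test_that("pair counts enumerate directed and undirected edges correctly", {
  # empty set: zero matrix
  empty <- interaction_set("e", data.frame(gene_a = character(0),
                                           gene_b = character(0)))
  expect_true(all(pair_interaction_counts(two_cluster_assign, empty) == 0))
  # directed a->c, b->d: both flow cluster 1 -> cluster 2
  dir <- interaction_set("d", data.frame(gene_a = c("a", "b"),
                                         gene_b = c("c", "d")), directed = TRUE)
  cnt <- pair_interaction_counts(two_cluster_assign, dir)
  expect_equal(cnt[1, 2], 2L)
  expect_equal(cnt[2, 1], 0L)
  # the same edges undirected count in both directions
  und <- interaction_set("u", dir$edges, directed = FALSE)
  cnt_u <- pair_interaction_counts(two_cluster_assign, und)
  expect_equal(cnt_u[1, 2], 2L)
  expect_equal(cnt_u[2, 1], 2L)
  # within-cluster edge on the diagonal; unclustered endpoints dropped
  mixed <- interaction_set("m", data.frame(gene_a = c("a", "a", "z"),
                                           gene_b = c("b", "c", "a")))
  cnt_m <- pair_interaction_counts(two_cluster_assign, mixed)
  expect_equal(cnt_m[1, 1], 1L)
  expect_equal(cnt_m[1, 2], 1L)
  expect_equal(attr(cnt_m, "n_dropped"), 1L)
})

test_that("total counted interactions equal usable edges (doubled if undirected)", {
  set.seed(41)
  genes <- paste0("g", 1:20)
  assign <- setNames(sample(rep(1:4, 5)), genes)
  edges <- data.frame(gene_a = sample(genes, 30, TRUE),
                      gene_b = sample(genes, 30, TRUE))
  edges <- unique(edges)
  n_self <- sum(edges$gene_a == edges$gene_b)
  dir <- interaction_set("d", edges, directed = TRUE)
  expect_equal(sum(pair_interaction_counts(assign, dir)), nrow(edges))
  und <- interaction_set("u", edges, directed = FALSE)
  expect_equal(sum(pair_interaction_counts(assign, und)),
               2L * (nrow(edges) - n_self) + n_self)
})

test_that("rewiring p-values converge to the exhaustive permutation answer", {
  iset <- interaction_set("t", data.frame(gene_a = c("a", "a", "b"),
                                          gene_b = c("c", "d", "c")))
  obs <- pair_interaction_counts(two_cluster_assign, iset)
  expect_equal(obs[1, 2], 3L)
  # exact null: all 24 relabelings of the four genes
  genes <- names(two_cluster_assign)
  tail_ge <- vapply(all_perms(genes), function(perm) {
    relabel <- setNames(perm, genes)
    pi <- iset
    pi$edges$gene_a <- unname(relabel[pi$edges$gene_a])
    pi$edges$gene_b <- unname(relabel[pi$edges$gene_b])
    pair_interaction_counts(two_cluster_assign, pi)[1, 2] >= obs[1, 2]
  }, logical(1))
  exact_p <- mean(tail_ge)
  est <- rewire_pvalues(two_cluster_assign, iset, n_reps = 4000, seed = 8)
  expect_equal(est[1, 2], exact_p, tolerance = 0.02)
  # a pair with zero observed count can never be exceeded
  expect_equal(est[2, 1], 1, tolerance = 1e-12)
  expect_error(rewire_pvalues(c(a = 1L), iset), "2 clustered genes")
})

test_that("one-cluster assignments make every count permutation-invariant", {
  assign <- c(a = 1L, b = 1L, c = 1L)
  iset <- interaction_set("t", data.frame(gene_a = c("a", "b"),
                                          gene_b = c("b", "c")))
  p <- rewire_pvalues(assign, iset, n_reps = 50, seed = 2)
  expect_equal(p[1, 1], 1)
})

test_that("validation labels and accuracies follow the quoted rules", {
  # hand-built scenario over K = 4: 12 ordered off-diagonal pairs
  K <- 4
  A <- matrix(0, K, K)
  # model influences source -> target: A[target, source]
  A[2, 1] <- 1; A[3, 1] <- 1; A[4, 1] <- -1; A[1, 2] <- 0.5 # 4 influences
  model <- influence_model(A, rep(1, K))
  p <- matrix(1, K, K)
  p[1, 2] <- 0.01; p[1, 3] <- 0.01; p[1, 4] <- 0.01 # support for 3 of them
  # p[2, 1] stays 1 -> the (2 -> 1) influence is unsupported: FN
  p[3, 4] <- 0.01                                   # spurious support: FP
  vt <- validation_accuracy(model, list(chip = p), alpha = 0.05)
  tab <- table(vt$pairs$label)
  expect_equal(as.vector(tab[c("TP", "FN", "FP", "TN")]), c(3L, 1L, 1L, 7L))
  expect_equal(unname(vt$accuracy["chip"]), 10 / 12)
  # all influences present and all pairs significant: accuracy 1
  dense <- influence_model(matrix(1, K, K), rep(1, K))
  p_all <- matrix(0.001, K, K)
  expect_equal(unname(validation_accuracy(dense, list(x = p_all))$accuracy), 1)
  # combined "any": a pair wrong in one dataset but right in another counts
  p2 <- matrix(1, K, K)  # dataset 2 supports nothing
  vt2 <- validation_accuracy(model, list(chip = p, none = p2), alpha = 0.05)
  # under `none` alone accuracy is (0 TP + 8 TN) / 12; combined recovers
  # every pair that chip validated
  expect_equal(unname(vt2$accuracy["none"]), 8 / 12)
  expect_equal(vt2$any_accuracy, 11 / 12)
  expect_error(validation_accuracy(model, list(bad = p[1:3, 1:3])),
               "mismatched")
})

test_that("relabeling clusters permutes p-values consistently", {
  set.seed(43)
  genes <- paste0("g", 1:12)
  assign <- setNames(rep(1:3, each = 4), genes)
  edges <- data.frame(gene_a = sample(genes, 20, TRUE),
                      gene_b = sample(genes, 20, TRUE))
  iset <- interaction_set("t", edges)
  p1 <- rewire_pvalues(assign, iset, n_reps = 300, seed = 6)
  # relabel clusters 1<->2 everywhere
  relab <- c(2L, 1L, 3L)[assign]
  names(relab) <- genes
  p2 <- rewire_pvalues(relab, iset, n_reps = 300, seed = 6)
  perm <- c(2, 1, 3)
  expect_equal(p2[perm, perm], p1, tolerance = 1e-12, ignore_attr = TRUE)
})
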
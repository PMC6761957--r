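star_tree <- function(taxa) {
  ape::read.tree(text = paste0("(", paste(taxa, ":1", collapse = ","), ");"))
}

test_that("both permutation schemes preserve per-column state multisets", {
  cm <- random_matrix(8, 6, 3, missing_rate = 0.15, seed = 3)
  w <- patristic_weights(star_tree(cm$taxa), cm$taxa)
  set.seed(1)
  for (i in 1:20) {
    for (pm in list(permute_equiprobable(cm), permute_phylogenetic(cm, w))) {
      for (j in seq_len(ncol(cm$cells))) {
        expect_identical(unname(sort(pm$cells[, j], na.last = TRUE)),
                         unname(sort(cm$cells[, j], na.last = TRUE)))
      }
    }
  }
  # constant column is a fixed point
  cc <- parse_table(text = "t,c1\nA,0\nB,0\nC,0", sep = ",")
  set.seed(2)
  expect_identical(unname(permute_equiprobable(cc)$cells),
                   unname(cc$cells))
})

test_that("patristic weights follow w = k - d with normalised distances", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  w <- patristic_weights(tr, c("A", "B"), k = 1.01)
  expect_equal(w$W["A", "B"], 0.01)
  expect_equal(w$W["A", "A"], 1.01)
  # star tree: all off-diagonal weights equal
  st <- star_tree(c("A", "B", "C", "D"))
  ws <- patristic_weights(st, c("A", "B", "C", "D"))
  off <- ws$W[upper.tri(ws$W)]
  expect_true(all(off == off[1]))
  # large k: near-uniform weights (ratio bounded by k/(k-1))
  tr2 <- ape::rtree(8)
  wk <- patristic_weights(tr2, tr2$tip.label, k = 1000)
  expect_lt(max(wk$W) / min(wk$W), 1000 / 999 + 1e-9)
  wk2 <- patristic_weights(tr2, tr2$tip.label, k = 1e6)
  expect_lt(max(wk2$W) / min(wk2$W), 1 + 2e-6)
  expect_error(patristic_weights(tr, c("A", "Z")), "Z")
})

test_that("empirical p-values follow the (b+1)/(M+1) convention", {
  # plant a matrix whose type II layer is maximal: permutations can only tie
  # or reduce it is not guaranteed, so check the formula directly instead
  cm <- random_matrix(6, 5, 2, seed = 8)
  nd <- null_distribution(cm, list(k3 = function(net) nrow(net$edges$III)),
                          M = 99, seed = 4)
  x <- nd$k3
  b_hi <- sum(x$replicates >= x$observed)
  b_lo <- sum(x$replicates <= x$observed)
  expect_equal(x$p_high, (b_hi + 1) / (99 + 1))
  expect_equal(x$p_low, (b_lo + 1) / (99 + 1))
  expect_gte(x$p_high, 1 / (99 + 1))
  # permutation-invariant statistic ties with every replicate: p = 1
  ndN <- null_distribution(cm, list(N = function(net) net$N), M = 19,
                           seed = 4)
  expect_equal(ndN$N$p_high, 1)
  expect_equal(ndN$N$p_low, 1)
})

test_that("empirical p matches exhaustive enumeration on a tiny matrix", {
  cells <- matrix(c("0", "0", "1", "1",
                    "0", "1", "1", "0",
                    "1", "0", "0", "1"), nrow = 4,
                  dimnames = list(LETTERS[1:4], paste0("c", 1:3)))
  cm <- character_matrix(cells)
  stat <- function(net) nrow(net$edges$IV)
  tm <- recode_traits(cm)
  obs <- stat(build_network(tm))
  # exact null: uniform over all 24^3 per-column index permutations
  perm4 <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perm4 <- perm4[apply(perm4, 1, function(r) length(unique(r)) == 4), ,
                 drop = FALSE]
  combos <- as.matrix(expand.grid(1:24, 1:24, 1:24))
  vals <- apply(combos, 1, function(co) {
    pc <- cells
    for (j in 1:3) pc[, j] <- cells[perm4[co[j], ], j]
    stat(build_network(recode_traits(character_matrix(pc))))
  })
  exact_p <- mean(vals >= obs)
  nd <- null_distribution(cm, list(s = stat), M = 2000, seed = 6)
  se <- sqrt(exact_p * (1 - exact_p) / 2000)
  expect_lt(abs(nd$s$p_high - exact_p), 3 * se + 1 / 2001)
})

test_that("star-tree phylogenetic permutations match the equiprobable null", {
  cm <- random_matrix(7, 8, 2, seed = 10)
  tr <- star_tree(cm$taxa)
  stat <- list(k3 = function(net) nrow(net$edges$III))
  nd_e <- null_distribution(cm, stat, model = "equiprobable", M = 2000,
                            seed = 11)
  nd_p <- null_distribution(cm, stat, model = "phylogenetic", M = 2000,
                            tree = tr, seed = 12)
  p <- suppressWarnings(stats::wilcox.test(nd_e$k3$replicates[, 1],
                                           nd_p$k3$replicates[, 1]))$p.value
  expect_gt(p, 0.01)
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(1 / 5001, 213), 213 / 5001)
  expect_error(bonferroni(0, 3))
})

test_that("identical seeds reproduce identical replicate streams", {
  cm <- random_matrix(6, 6, 3, seed = 14)
  st <- trait_network_statistics(per_node = TRUE)
  a <- null_distribution(cm, st, M = 25, seed = 99)
  b <- null_distribution(cm, st, M = 25, seed = 99)
  expect_identical(a, b)
  tr <- ape::rtree(6, tip.label = cm$taxa)
  ap <- null_distribution(cm, st, model = "phylogenetic", M = 10, tree = tr,
                          seed = 5)
  bp <- null_distribution(cm, st, model = "phylogenetic", M = 10, tree = tr,
                          seed = 5)
  expect_identical(ap, bp)
})

test_that("phylogenetic null without a tree is an error", {
  cm <- random_matrix(4, 3, 2, seed = 1)
  expect_error(null_distribution(cm, list(n = function(net) net$N),
                                 model = "phylogenetic", M = 5),
               "without a tree")
})

test_that("stable/pivotal flagging is a Bonferroni conjunction of both nulls", {
  # ladder structure: broad traits accumulate in-degree; star tree makes the
  # phylogenetic null agree with the equiprobable one
  set.seed(17)
  cm <- ladder_matrix(10, 30)
  tr <- star_tree(cm$taxa)
  st <- list(in_degree = function(net) type2_degrees(net)$in_degree,
             d_centrality = function(net)
               count_d_triplets(net)$records$d_centrality)
  nd_e <- null_distribution(cm, st, M = 999, seed = 21)
  nd_p <- null_distribution(cm, st, model = "phylogenetic", M = 999,
                            tree = tr, seed = 22)
  stable <- significant_stable_traits(nd_e$in_degree, nd_p$in_degree)
  deg <- type2_degrees(build_network(recode_traits(cm)))
  # flagged traits must have positive in-degree
  expect_true(all(deg$in_degree[stable] > 0))
  # a node with in-degree 0 can never be flagged
  expect_false(any(deg$in_degree[stable] == 0))
  pivotal <- significant_pivotal_traits(nd_e$d_centrality,
                                        nd_p$d_centrality)
  cent <- count_d_triplets(build_network(recode_traits(cm)))$records
  expect_true(all(cent$d_centrality[pivotal] > 0))
  # all-identical columns: permutation-invariant, nothing flagged
  cc <- parse_table(text = "t,c1,c2\nA,0,0\nB,0,0\nC,0,0", sep = ",")
  nd0 <- null_distribution(cc, st["in_degree"], M = 99, seed = 1)
  expect_length(suppressWarnings(
    significant_stable_traits(nd0$in_degree, nd0$in_degree)), 0)
})
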
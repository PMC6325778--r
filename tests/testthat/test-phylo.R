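test_that("single-region tumors give a germline-to-region trunk", {
  mat <- matrix(1L, 12, 1, dimnames = list(paste0("m", 1:12), "R1"))
  tr <- build_phylogenetic_tree(mat)
  expect_equal(tr$parsimony_score, 12)
  expect_equal(tr$trunk_len, 12)
  expect_equal(tr$newick, "(R1:12)germline;")
})

test_that("the 3-region worked example resolves exactly", {
  mat <- matrix(0L, 10, 3,
                dimnames = list(paste0("m", 1:10), c("R1", "R2", "R3")))
  mat[1:5, ] <- 1L          # trunk
  mat[6:8, c(1, 2)] <- 1L   # shared R1+R2
  mat[9:10, 3] <- 1L        # private R3
  tr <- build_phylogenetic_tree(mat)
  expect_equal(tr$parsimony_score, 10)
  expect_equal(tr$trunk_len, 5)
  expect_setequal(tr$edges$length, c(5, 3, 2, 0, 0))
  expect_equal(path_lengths(tr)[c("R1", "R2", "R3")],
               c(R1 = 8, R2 = 8, R3 = 7))
  # trunk mutations all on the edge leaving the germline root
  trunk_edge <- which(tr$edges$parent_label == "germline")
  expect_setequal(tr$edge_mutations[[trunk_edge]], paste0("m", 1:5))
  expect_equal(trunk_fraction_from_tree(tr), 0.5)
  expect_equal(trunk_fraction_from_tree(tr),
               1 - compute_ithi(classify_trunk_branch(mat))$ithi)
})

test_that("incompatible characters incur homoplasy scored by Fitch", {
  mat <- matrix(c(1, 1, 0,
                  0, 1, 1), 2, 3, byrow = TRUE,
                dimnames = list(c("a", "b"), c("R1", "R2", "R3")))
  tr <- build_phylogenetic_tree(mat)
  expect_equal(tr$parsimony_score, oracle_parsimony(mat))
  # one of the two mutations must occupy two edges
  occupancy <- table(unlist(tr$edge_mutations))
  expect_true(any(occupancy == 2))
  expect_equal(sum(occupancy), tr$parsimony_score)
})

test_that("exact search matches brute-force Fitch over all topologies", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (rep in 1:15) {
    n_reg <- sample(2:5, 1)
    mat <- random_presence_matrix(sample(3:8, 1), n_reg)
    tr <- build_phylogenetic_tree(mat)
    expect_equal(tr$parsimony_score, oracle_parsimony(mat),
                 info = sprintf("rep %d", rep))
    expect_equal(sum(tr$edges$length), tr$parsimony_score)
  }
})

test_that("perfect-phylogeny matrices score one change per mutation", {
  # nested/disjoint rows: compatible by construction
  mat <- rbind(t1 = c(1, 1, 1, 1), t2 = c(1, 1, 1, 1),
               s1 = c(1, 1, 0, 0), s2 = c(1, 0, 0, 0),
               p1 = c(0, 0, 1, 0), p2 = c(0, 0, 0, 1))
  colnames(mat) <- paste0("R", 1:4)
  tr <- build_phylogenetic_tree(mat)
  expect_equal(tr$parsimony_score, nrow(mat))
  expect_equal(tr$trunk_len, 2)
  expect_true(all(table(unlist(tr$edge_mutations)) == 1))
})

test_that("branch-and-bound at 7+ regions agrees with the plain search", {
  # 8 distinct region profiles exercises the branch-and-bound path;
  # a compatible caterpillar makes the optimum known exactly
  n <- 8
  mat <- matrix(0L, n, n, dimnames = list(paste0("m", 1:n), paste0("R", 1:n)))
  for (i in 1:n) mat[i, i:n] <- 1L  # nested chain
  tr <- build_phylogenetic_tree(mat)
  expect_equal(tr$parsimony_score, n)
  expect_equal(tr$pattern, "LINEAR")
  # small incompatible 7-region case against the exhaustive scorer
  set.seed(3)
  mat2 <- random_presence_matrix(6, 7)
  # oracle by scoring every rooted topology with the package's own Fitch
  # is circular; instead check the fundamental bounds and determinism
  tr2 <- build_phylogenetic_tree(mat2)
  expect_gte(tr2$parsimony_score, nrow(mat2))
  expect_lte(tr2$parsimony_score, sum(mat2))
  expect_identical(build_phylogenetic_tree(mat2)$newick, tr2$newick)
})

test_that("region relabeling permutes leaves but preserves the tree", {
  set.seed(21)
  for (rep in 1:8) {
    mat <- random_presence_matrix(6, 4)
    tr <- build_phylogenetic_tree(mat)
    perm <- sample(ncol(mat))
    mat2 <- mat[, perm, drop = FALSE]
    tr2 <- build_phylogenetic_tree(mat2)
    expect_equal(tr2$parsimony_score, tr$parsimony_score)
    expect_equal(sort(tr2$edges$length), sort(tr$edges$length))
    # the trunk never carries fewer mutations than the clonal count, and
    # carries exactly that count whenever the tree needs no homoplasy
    n_trunk <- compute_ithi(classify_trunk_branch(mat))$n_trunk
    expect_gte(tr$trunk_len, n_trunk)
    if (tr$parsimony_score == nrow(mat)) {
      expect_equal(tr$trunk_len, n_trunk)
    }
  }
})

test_that("evolution pattern distinguishes nested chains from divergence", {
  chain <- rbind(c(1, 1, 0), c(1, 0, 0))
  colnames(chain) <- paste0("R", 1:3)
  expect_equal(classify_evolution_pattern(chain), "LINEAR")

  split <- rbind(c(1, 0, 0), c(0, 1, 0))
  colnames(split) <- paste0("R", 1:3)
  expect_equal(classify_evolution_pattern(split), "BRANCHED")

  all_trunk <- matrix(1L, 4, 3, dimnames = list(NULL, paste0("R", 1:3)))
  expect_equal(classify_evolution_pattern(all_trunk), "LINEAR")
})

test_that("degenerate and oversized inputs are rejected", {
  expect_error(build_phylogenetic_tree(matrix(0L, 0, 3)), "empty")
  big <- matrix(1L, 2, 11, dimnames = list(c("a", "b"), paste0("R", 1:11)))
  expect_error(build_phylogenetic_tree(big), "10 regions")
})
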
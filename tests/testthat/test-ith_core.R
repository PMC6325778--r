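test_that("presence matrix follows the read-support rule and drops empty rows", {
  obs <- data.frame(
    variant_key = c("A", "A", "A", "B", "C"),
    region_id = c("R1", "R2", "R3", "R2", "R1"),
    alt_reads = c(10L, 5L, 8L, 3L, 0L),
    stringsAsFactors = FALSE)
  mat <- build_mutation_matrix(obs, c("R1", "R2", "R3"))
  expect_equal(mat["A", ], c(R1 = 1L, R2 = 1L, R3 = 1L))
  expect_equal(mat["B", ], c(R1 = 0L, R2 = 1L, R3 = 0L))
  expect_false("C" %in% rownames(mat))  # zero supporting reads

  # NA read counts (CNV/FUSION rows) count as present by existence
  obs$alt_reads[5] <- NA_integer_
  mat <- build_mutation_matrix(obs, c("R1", "R2", "R3"))
  expect_equal(unname(mat["C", "R1"]), 1L)

  # observation order never matters
  mat2 <- build_mutation_matrix(obs[sample(nrow(obs)), ], c("R1", "R2", "R3"))
  expect_identical(mat, mat2)

  expect_error(build_mutation_matrix(obs, c("R1", "R2")), "unknown region")
})

test_that("trunk means shared by all regions, branch otherwise", {
  mat <- rbind(a = c(1L, 1L, 1L, 1L), b = c(1L, 1L, 0L, 1L))
  colnames(mat) <- paste0("R", 1:4)
  labs <- classify_trunk_branch(mat)
  expect_equal(unname(labs["a"]), "TRUNK")
  expect_equal(unname(labs["b"]), "BRANCH")

  single <- matrix(1L, 3, 1, dimnames = list(c("a", "b", "c"), "R1"))
  expect_true(all(classify_trunk_branch(single) == "TRUNK"))
})

test_that("ITH index is the branch fraction with documented limits", {
  expect_equal(compute_ithi(rep("TRUNK", 10))$ithi, 0)
  expect_equal(compute_ithi(rep("BRANCH", 5))$ithi, 1)
  res <- compute_ithi(c(rep("TRUNK", 6), rep("BRANCH", 4)))
  expect_equal(res$ithi, 0.4)
  expect_equal(res$n_trunk, 6)
  expect_error(compute_ithi(character(0)), "zero")
  expect_equal(compute_ithi(c(rep("TRUNK", 2), rep("BRANCH", 4)),
                            formula = "branch_trunk_ratio")$ithi, 2)
})

test_that("adding regions moves labels monotonically under the all-regions rule", {
  set.seed(11)
  for (rep in 1:10) {
    mat <- random_presence_matrix(6, 4)
    labs <- classify_trunk_branch(mat)
    # a region carrying every mutation changes nothing
    expect_identical(classify_trunk_branch(cbind(mat, R5 = 1L)), labs)
    # a region carrying none turns every trunk mutation into branch
    labs2 <- classify_trunk_branch(cbind(mat, R5 = 0L))
    expect_true(all(labs2 == "BRANCH"))
    # ITHi invariant under region and mutation reordering
    perm <- mat[sample(nrow(mat)), sample(ncol(mat))]
    expect_equal(compute_ithi(classify_trunk_branch(perm))$ithi,
                 compute_ithi(labs)$ithi)
  }
})

test_that("subtype ITHi comparison uses the exact Mann-Whitney null", {
  ith <- data.frame(
    subtype = c(rep("EGFR_LUAD", 3), rep("KRAS_LUAD", 2)),
    n_regions = 3,
    ithi = c(0.9, 0.8, 0.7, 0.1, 0.2))
  res <- compare_ithi_by_subtype(ith, "EGFR_LUAD", "KRAS_LUAD")
  expect_true(res$exact)
  expect_equal(res$p.value, 0.2)  # 2 / C(5,3) tail doubling
  expect_equal(res$median1, 0.8)
  expect_equal(res$n2, 2)

  # symmetric interleaved configuration: p = 1
  ith2 <- data.frame(subtype = rep(c("A", "B"), each = 4), n_regions = 2,
                     ithi = c(0.1, 0.4, 0.5, 0.8, 0.2, 0.3, 0.6, 0.7))
  expect_equal(compare_ithi_by_subtype(ith2, "A", "B")$p.value, 1)

  # identical multisets force the tie-corrected approximation, still p = 1
  ith3 <- data.frame(subtype = rep(c("A", "B"), each = 3), n_regions = 2,
                     ithi = rep(c(0.1, 0.5, 0.9), 2))
  res3 <- compare_ithi_by_subtype(ith3, "A", "B")
  expect_false(res3$exact)
  expect_equal(res3$p.value, 1)

  # complete separation at n = 6 vs 6: minimal attainable exact p
  ith4 <- data.frame(subtype = rep(c("A", "B"), each = 6), n_regions = 2,
                     ithi = c(7:12, 1:6) / 100)
  expect_equal(compare_ithi_by_subtype(ith4, "A", "B")$p.value,
               2 / choose(12, 6))

  # single-region patients are excluded
  ith5 <- rbind(ith, data.frame(subtype = "EGFR_LUAD", n_regions = 1,
                                ithi = 0))
  expect_equal(compare_ithi_by_subtype(ith5, "EGFR_LUAD", "KRAS_LUAD")$n1, 3)
  expect_error(compare_ithi_by_subtype(ith, "EGFR_LUAD", "LELC"), "empty")
})

test_that("Mann-Whitney agrees with exhaustive enumeration for small n", {
  set.seed(42)
  for (rep in 1:20) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    vals <- sample(100, nx + ny)  # tie-free
    x <- vals[1:nx]; y <- vals[-(1:nx)]
    expect_equal(mrith:::.mann_whitney(x, y)$p.value, oracle_mw_p(x, y))
  }
})

test_that("gene frequency counts patients once and thresholds strictly", {
  rows <- unlist(lapply(1:10, function(i) {
    tissue_row(sprintf("P%02d", i), "R1", "chr1", i, "A", "T",
               if (i == 1) "G1" else sprintf("OTHER%d", i))
  }))
  # G1 also in a second region of P01: still one patient
  rows <- c(rows, tissue_row("P01", "R2", "chr1", 1, "A", "T", "G1"),
            tissue_row("P01", "R1", "chr9", 99, "G", "C", "G2"),
            tissue_row("P02", "R1", "chr9", 99, "G", "C", "G2"))
  gf <- gene_frequency_table(read_tissue_table(write_tissue_fixture(rows)))
  expect_equal(gf$n_patients[gf$gene == "G1"], 1)
  expect_equal(gf$fraction[gf$gene == "G1"], 0.10)
  expect_false(gf$above_threshold[gf$gene == "G1"])  # strictly more than 10%
  expect_equal(gf$fraction[gf$gene == "G2"], 0.20)
  expect_true(gf$above_threshold[gf$gene == "G2"])
})
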
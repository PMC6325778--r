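test_that("tissue rows deduplicate to variants with per-region observations", {
  rows <- c(
    tissue_row("P1", "R1", "chr1", 100, "A", "T", "GENE1"),
    tissue_row("P1", "R2", "chr1", 100, "A", "T", "GENE1"),
    tissue_row("P1", "R3", "chr1", 100, "A", "T", "GENE1"),
    tissue_row("P1", "R1", "chr2", 200, "G", "C", "GENE2"),
    tissue_row("P1", "R2", "chr2", 200, "G", "C", "GENE2"),
    tissue_row("P1", "R3", "chr2", 200, "G", "C", "GENE2"))
  cohort <- read_tissue_table(write_tissue_fixture(rows))
  expect_equal(nrow(cohort$variants), 2)
  expect_equal(nrow(cohort$observations), 6)
  expect_equal(cohort$patients$n_regions, 3)
  # row order never matters
  cohort2 <- read_tissue_table(write_tissue_fixture(rev(rows)))
  expect_identical(cohort, cohort2)
})

test_that("an empty tissue table yields an empty cohort without error", {
  cohort <- read_tissue_table(write_tissue_fixture(character(0)))
  expect_s3_class(cohort, "mrith_cohort")
  expect_equal(nrow(cohort$patients), 0)
  expect_equal(nrow(cohort$observations), 0)
})

test_that("schema and row-level errors carry the offending column/line", {
  path <- tempfile()
  writeLines(c("patient_id\tregion_id\tchrom\tpos\tref\talt\tgene",
               "P1\tR1\tchr1\t100\tA\tT\tG1"), path)
  expect_error(read_tissue_table(path), "vclass")

  bad <- write_tissue_fixture(
    tissue_row("P1", "R1", "chr1", 100, "A", "T", "G1", vclass = "SV"))
  expect_error(read_tissue_table(bad), "SV.*line 2")

  dup <- write_tissue_fixture(c(
    tissue_row("P1", "R1", "chr1", 100, "A", "T", "G1"),
    tissue_row("P1", "R1", "chr1", 100, "A", "T", "G1")))
  expect_error(read_tissue_table(dup), "duplicate")

  inconsistent <- write_tissue_fixture(
    tissue_row("P1", "R1", "chr1", 100, "A", "T", "G1",
               vaf = 0.5, alt_reads = 10, depth = 100))
  expect_error(read_tissue_table(inconsistent), "vaf")
})

test_that("variant keys are canonical and shared between tissue and plasma", {
  expect_equal(variant_key("chr7", 55249071L, "C", "T", "EGFR", "SNV"),
               "chr7:55249071:C:T")
  expect_equal(variant_key("chrX", 0L, ".", "AMP", "MYC", "CNV"),
               "MYC:CNV:AMP")
  ct <- read_ctdna_table(write_ctdna_fixture(
    ctdna_row("P1", "chr1", 100, "A", "T", "G1", mutant_reads = 0,
              depth = 1200)))
  expect_equal(nrow(ct), 1)  # zero mutant reads retained
  tissue <- read_tissue_table(write_tissue_fixture(
    tissue_row("P1", "R1", "chr1", 100, "A", "T", "G1")))
  expect_equal(ct$variant_key, tissue$variants$variant_key)
})

test_that("malformed ctDNA counts are rejected with their line number", {
  expect_error(read_ctdna_table(write_ctdna_fixture(
    ctdna_row("P1", "chr1", 100, "A", "T", "G1", mutant_reads = "many"))),
    "line 2")
  expect_error(read_ctdna_table(write_ctdna_fixture(
    ctdna_row("P1", "chr1", 100, "A", "T", "G1", mutant_reads = 5,
              depth = 3))), "mutant_reads > depth")
})

test_that("driver catalog parsing is idempotent and role-checked", {
  path <- tempfile()
  writeLines(c("gene\trole", "EGFR\toncogene", "TP53\tTSG", "TP53\tTSG"),
             path)
  catalog <- read_driver_catalog(path)
  expect_equal(length(catalog), 2)
  expect_equal(unname(catalog["EGFR"]), "ONCOGENE")

  writeLines(c("gene\trole", "TP53\ttumor_suppressor"), path)
  expect_error(read_driver_catalog(path), "role")
  writeLines(c("gene\trole", "TP53\tTSG", "TP53\tONCOGENE"), path)
  expect_error(read_driver_catalog(path), "conflicting")
})

test_that("panel filtering follows BED half-open convention and is idempotent", {
  cohort <- read_tissue_table(write_tissue_fixture(c(
    tissue_row("P1", "R1", "chr1", 100, "A", "T", "G1"),
    tissue_row("P1", "R1", "chr1", 150, "G", "C", "G2"),
    tissue_row("P1", "R1", ".", 0, ".", "AMP", "MYC", vclass = "CNV"))))
  bed <- tempfile()
  writeLines("chr1\t99\t100\tG1", bed)  # 1-based pos 100 is inside (99,100]
  f <- filter_to_panel(cohort, bed)
  expect_equal(f$variants$variant_key, "chr1:100:A:T")

  writeLines("chr1\t100\t200\tMYC", bed)  # pos 100 now outside; MYC by gene
  f <- filter_to_panel(cohort, bed)
  expect_setequal(f$variants$variant_key, c("chr1:150:G:C", "MYC:CNV:AMP"))
  expect_identical(filter_to_panel(f, bed)$variants, f$variants)

  empty <- tempfile(); writeLines(character(0), empty)
  expect_equal(nrow(filter_to_panel(cohort, empty)$variants), 0)
  writeLines("chr1\tx\t100", bed)
  expect_error(read_panel_bed(bed), "line 1")
})

test_that("Newick output is exact and round-trips through ape", {
  m1 <- matrix(1L, 10, 1, dimnames = list(paste0("m", 1:10), "R1"))
  tr1 <- build_phylogenetic_tree(m1)
  path <- tempfile(fileext = ".nwk")
  write_newick(tr1, path)
  expect_equal(readLines(path), "(R1:10)germline;")

  mat <- matrix(0L, 10, 3,
                dimnames = list(paste0("m", 1:10), c("R1", "R2", "R3")))
  mat[1:5, ] <- 1L; mat[6:8, c(1, 2)] <- 1L; mat[9:10, 3] <- 1L
  tr <- build_phylogenetic_tree(mat)
  write_newick(tr, path)
  ape_tree <- ape::read.tree(path)
  expect_setequal(ape_tree$tip.label, colnames(mat))
  expect_equal(sort(ape_tree$edge.length), sort(tr$edges$length))
  # leaf-to-root path length equals each region's mutation count
  depths <- ape::node.depth.edgelength(ape_tree)[seq_along(ape_tree$tip.label)]
  names(depths) <- ape_tree$tip.label
  expect_equal(depths[colnames(mat)], colSums(mat)[colnames(mat)])
})

test_that("result tables round-trip through write_tsv", {
  cohort <- toy_cohort()
  ith <- ithi_table(cohort)
  path <- tempfile()
  write_tsv(ith, path)
  back <- utils::read.delim(path, sep = "\t", na.strings = ".")
  expect_equal(back$ithi, ith$ithi)
  expect_equal(back$patient_id, ith$patient_id)
})
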
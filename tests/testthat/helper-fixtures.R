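# In-code fixtures: tiny cohorts written as the TSV formats the readers
# consume.

tissue_header <- paste("patient_id", "region_id", "subtype", "chrom", "pos",
                       "ref", "alt", "gene", "vclass", "vaf", "alt_reads",
                       "depth", sep = "\t")

tissue_row <- function(patient, region, chrom, pos, ref, alt, gene,
                       vclass = "SNV", subtype = "WT_LUAD", vaf = ".",
                       alt_reads = ".", depth = ".") {
  paste(patient, region, subtype, chrom, pos, ref, alt, gene, vclass, vaf,
        alt_reads, depth, sep = "\t")
}

write_tissue_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c(tissue_header, rows), path)
  path
}

ctdna_header <- paste("patient_id", "chrom", "pos", "ref", "alt", "gene",
                      "vclass", "mutant_reads", "depth", sep = "\t")

ctdna_row <- function(patient, chrom, pos, ref, alt, gene, vclass = "SNV",
                      mutant_reads = 0, depth = 1000) {
  paste(patient, chrom, pos, ref, alt, gene, vclass, mutant_reads, depth,
        sep = "\t")
}

write_ctdna_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c(ctdna_header, rows), path)
  path
}

# A 2-patient toy cohort: P1 has 3 regions with one trunk (EGFR) and two
# branch mutations; P2 has 2 regions, all trunk.
toy_cohort <- function() {
  rows <- c(
    tissue_row("P1", "R1", "chr7", 100, "C", "T", "EGFR",
               subtype = "EGFR_LUAD"),
    tissue_row("P1", "R2", "chr7", 100, "C", "T", "EGFR",
               subtype = "EGFR_LUAD"),
    tissue_row("P1", "R3", "chr7", 100, "C", "T", "EGFR",
               subtype = "EGFR_LUAD"),
    tissue_row("P1", "R1", "chr1", 200, "G", "A", "PNL0001",
               subtype = "EGFR_LUAD"),
    tissue_row("P1", "R2", "chr1", 200, "G", "A", "PNL0001",
               subtype = "EGFR_LUAD"),
    tissue_row("P1", "R3", "chr2", 300, "T", "C", "TP53",
               subtype = "EGFR_LUAD"),
    tissue_row("P2", "R1", "chr12", 400, "C", "A", "KRAS",
               subtype = "KRAS_LUAD"),
    tissue_row("P2", "R2", "chr12", 400, "C", "A", "KRAS",
               subtype = "KRAS_LUAD"))
  read_tissue_table(write_tissue_fixture(rows))
}

# Build a detection table realizing given trunk/branch detected counts,
# for driving summarize_detection with arbitrary 2x2 tables.
detection_fixture <- function(trunk_detected, trunk_total, branch_detected,
                              branch_total) {
  mk <- function(clon, det, n, offset) {
    if (n == 0) return(NULL)
    data.frame(patient_id = "P1",
               variant_key = paste0("chrS:", offset + seq_len(n), ":A:T"),
               clonality = clon,
               mutant_reads = if (det) 3L else 0L,
               detected = det, stringsAsFactors = FALSE)
  }
  out <- rbind(mk("TRUNK", TRUE, trunk_detected, 0),
               mk("TRUNK", FALSE, trunk_total - trunk_detected, 1000),
               mk("BRANCH", TRUE, branch_detected, 2000),
               mk("BRANCH", FALSE, branch_total - branch_detected, 3000))
  out
}

toy_patients <- data.frame(patient_id = "P1", subtype = "WT_LUAD",
                           stringsAsFactors = FALSE)
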
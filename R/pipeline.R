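#' Run the full multi-region ITH analysis pipeline
#'
#' End-to-end orchestration: reads the tissue table (and optionally ctDNA
#' table, driver catalog and panel BED), classifies trunk/branch
#' mutations, computes per-patient ITH indices, reconstructs
#' maximum-parsimony phylogenies, tabulates driver/passenger and
#' oncogene/TSG composition, scores driver dominance, quantifies ctDNA
#' detection concordance, and writes all result tables to `out_dir`:
#' `ithi.tsv`, `gene_freq.tsv`, `trees.tsv` plus one Newick per patient
#' under `trees/`, `composition.tsv`, `dominance.tsv`, `detection.tsv`,
#' `detection_summary.tsv`, and an aggregate `report.tsv`. Stages whose
#' inputs are absent (no ctDNA table, no driver catalog) are skipped and
#' their outputs not written. The run is deterministic given inputs and
#' options; on failure, partial outputs are removed.
#'
#' @param tissue Path to the tissue TSV, or an `mrith_cohort`.
#' @param out_dir Output directory (created if needed).
#' @param ctdna Optional path to the ctDNA TSV, or a data frame from
#'   [read_ctdna_table()].
#' @param drivers Optional path to the driver TSV, or a named role vector.
#' @param panel Optional path to a panel BED, or a data frame from
#'   [read_panel_bed()].
#' @param min_alt_reads Presence-rule threshold (reads needed to call a
#'   variant present in a region).
#' @param ithi_formula ITH index formula, see [compute_ithi()].
#' @param detect_threshold Mutant reads needed to call plasma detection.
#' @param detection_test `"fisher"` or `"chisq"` for the trunk-vs-branch
#'   detection contrast.
#' @param gene_freq_threshold Strict patient-fraction threshold for the
#'   recurrently mutated gene list.
#' @return Invisibly, a list with all in-memory results (`cohort`, `ithi`,
#'   `trees`, `tree_summary`, `gene_freq`, `annotations`, `composition`,
#'   `dominance`, `detection`, `detection_summary`, `report`).
#' @export
run_pipeline <- function(tissue, out_dir, ctdna = NULL, drivers = NULL,
                         panel = NULL, min_alt_reads = 1L,
                         ithi_formula = "branch_fraction",
                         detect_threshold = 1L,
                         detection_test = "fisher",
                         gene_freq_threshold = 0.10) {
  cohort <- if (inherits(tissue, "mrith_cohort")) tissue else
    read_tissue_table(tissue)
  if (!is.null(panel)) cohort <- filter_to_panel(cohort, panel)
  if (nrow(cohort$variants) == 0) stop("no variants to analyze")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  created <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(created, recursive = TRUE))
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    created <<- c(created, p)
  }

  mats <- mutation_matrices(cohort, min_alt_reads = min_alt_reads)
  labels <- lapply(mats, classify_trunk_branch)
  ith <- ithi_table(cohort, min_alt_reads = min_alt_reads,
                    formula = ithi_formula)
  emit(.round_cols(ith, "ithi"), "ithi.tsv")
  gf <- gene_frequency_table(cohort, threshold = gene_freq_threshold)
  emit(.round_cols(gf, "fraction"), "gene_freq.tsv")

  tree_dir <- file.path(out_dir, "trees")
  dir.create(tree_dir, showWarnings = FALSE)
  created <- c(created, tree_dir)
  trees <- list()
  tsum <- list()
  for (p in names(mats)) {
    if (nrow(mats[[p]]) == 0) next
    tr <- build_phylogenetic_tree(mats[[p]], patient_id = p)
    trees[[p]] <- tr
    write_newick(tr, file.path(tree_dir, paste0(p, ".nwk")))
    tsum[[p]] <- data.frame(patient_id = p,
                            n_regions = length(tr$region_ids),
                            parsimony_score = tr$parsimony_score,
                            trunk_len = tr$trunk_len, pattern = tr$pattern,
                            stringsAsFactors = FALSE)
  }
  tree_summary <- do.call(rbind, c(tsum, list(make.row.names = FALSE)))
  emit(tree_summary, "trees.tsv")

  annotations <- composition <- dominance <- NULL
  if (!is.null(drivers)) {
    catalog <- if (is.character(drivers) && length(drivers) == 1 &&
                   is.null(names(drivers))) {
      read_driver_catalog(drivers)
    } else drivers
    annotations <- annotate_mutations(cohort, catalog, labels = labels)
    composition <- composition_table(annotations, cohort$patients)
    emit(.round_cols(composition, c("pct_driver", "pct_oncogene")),
         "composition.tsv")
    dominance <- compute_dominance(annotations, nrow(cohort$patients))
    emit(.round_cols(dominance, c("carrier_fraction", "score")),
         "dominance.tsv")
  }

  detection <- detection_summary <- NULL
  if (!is.null(ctdna)) {
    ct <- if (is.character(ctdna)) read_ctdna_table(ctdna) else ctdna
    detection <- match_tumor_to_plasma(cohort, ct, labels = labels,
                                       detect_threshold = detect_threshold)
    emit(detection, "detection.tsv")
    detection_summary <- summarize_detection(detection, cohort$patients,
                                             method = detection_test)
    flat <- detection_summary$strata
    flat$p_fisher <- detection_summary$tests$p_value[
      match(flat$group, detection_summary$tests$group)]
    flat$stratum <- paste(flat$group, tolower(flat$clonality), sep = ".")
    emit(.round_cols(flat[c("stratum", "n_total", "n_detected", "rate",
                            "p_fisher")], "rate"),
         "detection_summary.tsv")
  }

  report <- .assemble_report(ith, tree_summary, composition, dominance,
                             detection_summary)
  emit(report, "report.tsv")
  ok <- TRUE
  invisible(list(cohort = cohort, ithi = ith, trees = trees,
                 tree_summary = tree_summary, gene_freq = gf,
                 annotations = annotations, composition = composition,
                 dominance = dominance, detection = detection,
                 detection_summary = detection_summary, report = report))
}

.round_cols <- function(df, cols, digits = 6) {
  for (col in intersect(cols, names(df))) df[[col]] <- round(df[[col]], digits)
  df
}

# One-row-per-metric summary pulling numbers straight from the per-module
# results (no recomputation).
.assemble_report <- function(ith, tree_summary, composition, dominance,
                             detection_summary) {
  rows <- list()
  add <- function(metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric,
                                             value = signif(value, 6),
                                             stringsAsFactors = FALSE)
  }
  add("n_patients", nrow(ith))
  informative <- ith$n_regions > 1
  for (s in sort(unique(ith$subtype[!is.na(ith$subtype)]))) {
    sel <- informative & ith$subtype == s
    if (any(sel)) add(paste0("median_ithi.", s),
                      stats::median(ith$ithi[sel]))
  }
  if (any(informative)) add("median_ithi.overall",
                            stats::median(ith$ithi[informative]))
  add("pct_linear_evolution", mean(tree_summary$pattern == "LINEAR"))
  if (!is.null(composition)) {
    for (i in which(composition$group == "overall")) {
      comp <- tolower(composition$compartment[i])
      add(paste0("pct_driver.", comp), composition$pct_driver[i])
      add(paste0("p_driver_vs_passenger.", comp), composition$p_binomial[i])
    }
  }
  if (!is.null(dominance)) {
    for (g in intersect(c("EGFR", "KRAS"), dominance$gene)) {
      add(paste0("dominance_score.", g),
          dominance$score[dominance$gene == g])
    }
  }
  if (!is.null(detection_summary)) {
    st <- detection_summary$strata
    for (i in which(st$group == "overall")) {
      add(paste0("ctdna_detection_rate.", tolower(st$clonality[i])),
          st$rate[i])
    }
    ov <- detection_summary$tests$p_value[
      detection_summary$tests$group == "overall"]
    if (length(ov)) add("ctdna_trunk_vs_branch_p", ov)
    add("pct_patients_ctdna_positive", detection_summary$patients$fraction)
  }
  do.call(rbind, rows)
}
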
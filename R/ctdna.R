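#' Match tumor-derived mutations to plasma read counts
#'
#' Builds the ctDNA detection table: one row per (patient, tissue mutation)
#' assayed in plasma, with its mutant read count and trunk/branch
#' clonality. A mutation is called detected when it has at least
#' `detect_threshold` (default one) high-quality mutant reads; read counts
#' are assumed quality-filtered upstream.
#'
#' Tissue mutations absent from the ctDNA table are counted as assayed but
#' undetected (mutant_reads = 0) when the patient has a plasma sample, and
#' excluded when the patient has none (`missing_as_undetected = FALSE`
#' instead excludes all tissue mutations without an explicit plasma row).
#' Plasma records with no matching tissue mutation are plasma-private and
#' out of scope for tumor-derived analysis; they are dropped with a
#' message and returned in the `"unmatched"` attribute.
#'
#' @param cohort An `mrith_cohort`.
#' @param ctdna Data frame from [read_ctdna_table()].
#' @param labels Named list (by patient) of trunk/branch vectors; computed
#'   from the cohort if `NULL`.
#' @param plasma_patients Patients with a plasma sample; defaults to the
#'   patients appearing in `ctdna`.
#' @param detect_threshold Minimum mutant reads to call detection.
#' @param missing_as_undetected Count uncovered tissue mutations as
#'   undetected (default) or exclude them.
#' @return Data frame `patient_id`, `variant_key`, `clonality`,
#'   `mutant_reads`, `detected`.
#' @export
match_tumor_to_plasma <- function(cohort, ctdna, labels = NULL,
                                  plasma_patients = unique(ctdna$patient_id),
                                  detect_threshold = 1L,
                                  missing_as_undetected = TRUE) {
  stopifnot(inherits(cohort, "mrith_cohort"))
  if (is.null(labels)) {
    labels <- lapply(mutation_matrices(cohort), classify_trunk_branch)
  }
  tissue_keys <- unlist(lapply(names(labels), function(p) {
    paste(p, names(labels[[p]]), sep = "\r")
  }))
  ct_id <- paste(ctdna$patient_id, ctdna$variant_key, sep = "\r")
  unmatched <- ctdna[!ct_id %in% tissue_keys, , drop = FALSE]
  if (nrow(unmatched)) {
    message(nrow(unmatched),
            " plasma record(s) without a matching tissue mutation; excluded")
  }
  reads <- structure(ctdna$mutant_reads, names = ct_id)

  rows <- lapply(intersect(names(labels), plasma_patients), function(p) {
    lab <- labels[[p]]
    if (length(lab) == 0) return(NULL)
    ids <- paste(p, names(lab), sep = "\r")
    mr <- unname(reads[ids])
    if (!missing_as_undetected) {
      keep <- !is.na(mr)
      lab <- lab[keep]; mr <- mr[keep]
      if (length(lab) == 0) return(NULL)
    } else {
      mr[is.na(mr)] <- 0L
    }
    data.frame(patient_id = p, variant_key = names(lab),
               clonality = unname(lab), mutant_reads = mr,
               detected = mr >= detect_threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), variant_key = character(0),
                      clonality = character(0), mutant_reads = integer(0),
                      detected = logical(0), stringsAsFactors = FALSE)
  }
  attr(out, "unmatched") <- unmatched
  out
}

# Fisher exact two-sided p for a 2x2 matrix.
.fisher_p <- function(tab) {
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Summarize ctDNA detection of trunk and branch mutations
#'
#' Detection rates are pooled over mutations within each stratum (overall
#' and subtype, split by trunk/branch clonality), not averaged over
#' patients. The trunk-vs-branch contrast in each stratum is a two-sided
#' Fisher exact test on the 2x2 detected/undetected table (a chi-square
#' test with continuity correction is available via `method`). Also
#' reports the number and fraction of patients with at least one detected
#' tumor-derived mutation.
#'
#' @param detection Data frame from [match_tumor_to_plasma()].
#' @param patients Data frame with `patient_id`, `subtype`.
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return List with `strata` (data frame `group`, `clonality`, `n_total`,
#'   `n_detected`, `rate`), `tests` (data frame `group`, `p_value`),
#'   `patients` (list `n_positive`, `n_assayed`, `fraction`).
#' @export
summarize_detection <- function(detection, patients,
                                method = c("fisher", "chisq")) {
  method <- match.arg(method)
  if (nrow(detection) == 0) stop("empty detection table")
  det <- merge(detection, patients[c("patient_id", "subtype")],
               by = "patient_id", all.x = TRUE)
  det$group <- det$subtype
  groups <- c("overall", sort(unique(det$group[!is.na(det$group)])))

  strata <- list(); tests <- list()
  for (g in groups) {
    d <- if (g == "overall") det else det[!is.na(det$group) & det$group == g, ]
    for (cl in c("TRUNK", "BRANCH")) {
      dd <- d[d$clonality == cl, , drop = FALSE]
      if (nrow(dd) == 0) next
      strata[[length(strata) + 1L]] <- data.frame(
        group = g, clonality = cl, n_total = nrow(dd),
        n_detected = sum(dd$detected), rate = mean(dd$detected),
        stringsAsFactors = FALSE)
    }
    tab <- table(factor(d$clonality, levels = c("TRUNK", "BRANCH")),
                 factor(d$detected, levels = c(TRUE, FALSE)))
    if (all(rowSums(tab) > 0)) {
      p <- if (method == "fisher") .fisher_p(tab) else {
        suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
      }
      tests[[length(tests) + 1L]] <- data.frame(group = g, p_value = p,
                                                stringsAsFactors = FALSE)
    }
  }
  pat_pos <- tapply(detection$detected, detection$patient_id, any)
  list(strata = do.call(rbind, strata),
       tests = do.call(rbind, tests),
       patients = list(n_positive = sum(pat_pos),
                       n_assayed = length(pat_pos),
                       fraction = mean(pat_pos)))
}
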
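#' Build a patient's binary mutation-by-region presence matrix
#'
#' A variant is scored present in a region when it has an observation there
#' with at least one supporting read; observations without read counts
#' (CNV/FUSION rows, or tables without count columns) count as present by
#' their existence, since the calls are assumed quality-filtered upstream.
#' Variants left with an all-zero row are dropped.
#'
#' @param observations Data frame with columns `variant_key`, `region_id`
#'   and optionally `alt_reads` (as in the `observations` slot of an
#'   `mrith_cohort`, already restricted to one patient).
#' @param region_ids Character vector of the patient's region identifiers
#'   (columns of the matrix, in this order).
#' @param min_alt_reads Presence rule threshold (default 1 supporting read).
#' @return Integer 0/1 matrix, rows named by variant key, columns by region.
#' @export
build_mutation_matrix <- function(observations, region_ids,
                                  min_alt_reads = 1L) {
  if (anyDuplicated(region_ids)) stop("duplicate region_ids")
  if (length(region_ids) < 1) stop("at least one region required")
  unknown <- setdiff(unique(observations$region_id), region_ids)
  if (length(unknown)) {
    stop("observation in unknown region: ", paste(unknown, collapse = ", "))
  }
  keys <- sort(unique(observations$variant_key))
  mat <- matrix(0L, nrow = length(keys), ncol = length(region_ids),
                dimnames = list(keys, region_ids))
  if (nrow(observations)) {
    alt <- if ("alt_reads" %in% names(observations)) {
      observations$alt_reads
    } else rep(NA_integer_, nrow(observations))
    present <- is.na(alt) | alt >= min_alt_reads
    idx <- cbind(match(observations$variant_key, keys),
                 match(observations$region_id, region_ids))
    mat[idx[present, , drop = FALSE]] <- 1L
  }
  mat[rowSums(mat) > 0, , drop = FALSE]
}

# Per-patient matrices for a whole cohort, as a named list.
#' Build presence matrices for every patient in a cohort
#'
#' @param cohort An `mrith_cohort`.
#' @param min_alt_reads Presence rule threshold, see [build_mutation_matrix()].
#' @return Named list of 0/1 matrices, one per patient.
#' @export
mutation_matrices <- function(cohort, min_alt_reads = 1L) {
  stopifnot(inherits(cohort, "mrith_cohort"))
  pats <- cohort$patients$patient_id
  out <- lapply(pats, function(p) {
    obs <- cohort$observations[cohort$observations$patient_id == p, ,
                               drop = FALSE]
    regs <- cohort$regions$region_id[cohort$regions$patient_id == p]
    build_mutation_matrix(obs, regs, min_alt_reads = min_alt_reads)
  })
  names(out) <- pats
  out
}

#' Classify mutations as trunk or branch
#'
#' A mutation is a trunk mutation when it is present in every sampled
#' region of the tumor, and a branch mutation otherwise. For a patient with
#' a single sampled region every mutation is trunk by this rule.
#'
#' @param mat Binary presence matrix from [build_mutation_matrix()].
#' @return Named character vector (`"TRUNK"`/`"BRANCH"`) over variant keys.
#' @export
classify_trunk_branch <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 1)
  labels <- ifelse(rowSums(mat == 1L) == ncol(mat), "TRUNK", "BRANCH")
  names(labels) <- rownames(mat)
  labels
}

#' Compute the intratumor heterogeneity index (ITHi)
#'
#' The default index is the branch fraction, `n_branch / (n_trunk +
#' n_branch)`: 0 for a fully clonal tumor, 1 when no mutation is shared by
#' all regions, increasing as the trunk fraction falls. A branch-to-trunk
#' ratio variant (`n_branch / n_trunk`, unbounded) is available.
#'
#' @param labels Named trunk/branch vector from [classify_trunk_branch()].
#' @param formula `"branch_fraction"` (default) or `"branch_trunk_ratio"`.
#' @return List with `n_trunk`, `n_branch`, `ithi`.
#' @export
compute_ithi <- function(labels, formula = c("branch_fraction",
                                             "branch_trunk_ratio")) {
  formula <- match.arg(formula)
  if (length(labels) == 0) stop("ITH index undefined for zero mutations")
  n_trunk <- sum(labels == "TRUNK")
  n_branch <- sum(labels == "BRANCH")
  ithi <- switch(formula,
                 branch_fraction = n_branch / (n_trunk + n_branch),
                 branch_trunk_ratio = n_branch / n_trunk)
  list(n_trunk = n_trunk, n_branch = n_branch, ithi = ithi)
}

#' Per-patient ITH table for a cohort
#'
#' @param cohort An `mrith_cohort`.
#' @param min_alt_reads Presence rule threshold.
#' @param formula ITH index formula, see [compute_ithi()].
#' @return Data frame with columns `patient_id`, `subtype`, `n_regions`,
#'   `n_trunk`, `n_branch`, `ithi`. Patients with a single region carry no
#'   ITH information; they are retained here (ithi 0 by the trunk rule) and
#'   excluded from subtype comparisons by [compare_ithi_by_subtype()].
#' @export
ithi_table <- function(cohort, min_alt_reads = 1L,
                       formula = "branch_fraction") {
  mats <- mutation_matrices(cohort, min_alt_reads = min_alt_reads)
  rows <- lapply(cohort$patients$patient_id, function(p) {
    if (nrow(mats[[p]]) == 0) {
      warning("patient ", p, " has no mutations passing the presence rule; ",
              "excluded from ITH table")
      return(NULL)
    }
    res <- compute_ithi(classify_trunk_branch(mats[[p]]), formula = formula)
    data.frame(patient_id = p, n_trunk = res$n_trunk,
               n_branch = res$n_branch, ithi = res$ithi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- merge(cohort$patients[c("patient_id", "subtype", "n_regions")], out,
               by = "patient_id", sort = TRUE)
  out[order(out$patient_id), c("patient_id", "subtype", "n_regions",
                               "n_trunk", "n_branch", "ithi")]
}

#' Compare ITHi between two subtype groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test: the exact no-tie null
#' distribution is used when the pooled sample size is at most 20 and the
#' values are tie-free, the normal approximation with tie correction
#' otherwise. Patients with a single sampled region are excluded (their
#' ITHi is uninformative).
#'
#' @param ith Data frame from [ithi_table()] (columns `subtype`,
#'   `n_regions`, `ithi`), or any data frame with those columns.
#' @param group1,group2 Character vectors of subtype labels defining the two
#'   groups.
#' @return List with `statistic` (Mann-Whitney U for group1), `p.value`,
#'   `median1`, `median2`, `n1`, `n2`, `exact`.
#' @export
compare_ithi_by_subtype <- function(ith, group1, group2) {
  informative <- ith$n_regions > 1
  x <- ith$ithi[informative & ith$subtype %in% group1]
  y <- ith$ithi[informative & ith$subtype %in% group2]
  if (length(x) == 0 || length(y) == 0) stop("empty subtype group")
  res <- .mann_whitney(x, y)
  c(res, list(median1 = stats::median(x), median2 = stats::median(y),
              n1 = length(x), n2 = length(y)))
}

# Exact Mann-Whitney for small tie-free samples, normal approximation
# (with tie correction, no continuity correction in the exact regime)
# otherwise. Returns U statistic for x.
.mann_whitney <- function(x, y, exact_max_n = 20L) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_max_n && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value, exact = exact)
}

#' Per-gene mutation frequency across patients
#'
#' A patient counts once per gene no matter how many distinct variants or
#' regions carry it. The reported subset uses a strict threshold: genes
#' mutated in more than `threshold` of patients.
#'
#' @param cohort An `mrith_cohort`.
#' @param threshold Strict lower bound on the patient fraction (default 0.10).
#' @return Data frame `gene`, `n_patients`, `fraction`, `above_threshold`,
#'   sorted by decreasing frequency then gene name.
#' @export
gene_frequency_table <- function(cohort, threshold = 0.10) {
  stopifnot(inherits(cohort, "mrith_cohort"))
  n_pat <- nrow(cohort$patients)
  if (n_pat == 0) stop("empty cohort")
  pg <- unique(cohort$variants[c("patient_id", "gene")])
  counts <- table(pg$gene)
  out <- data.frame(gene = names(counts), n_patients = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$fraction <- out$n_patients / n_pat
  out$above_threshold <- out$fraction > threshold
  out[order(-out$n_patients, out$gene), , drop = FALSE]
}
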
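#' Annotate a cohort's mutations with driver role and clonality
#'
#' A mutation is a driver when its gene appears in the driver catalog; the
#' oncogene/TSG role is copied from the catalog and genes absent from it
#' are passengers. Clonality (trunk/branch) is taken from the per-patient
#' classification.
#'
#' @param cohort An `mrith_cohort`.
#' @param catalog Named role vector from [read_driver_catalog()].
#' @param labels Named list (by patient) of trunk/branch label vectors from
#'   [classify_trunk_branch()]; if `NULL` they are computed from the cohort
#'   with the default presence rule.
#' @return Data frame with one row per (patient, variant): `patient_id`,
#'   `variant_key`, `gene`, `is_driver`, `role`
#'   (`ONCOGENE`/`TSG`/`PASSENGER`), `clonality`.
#' @export
annotate_mutations <- function(cohort, catalog, labels = NULL) {
  stopifnot(inherits(cohort, "mrith_cohort"))
  if (is.null(labels)) {
    labels <- lapply(mutation_matrices(cohort), classify_trunk_branch)
  }
  v <- cohort$variants
  role <- unname(catalog[v$gene])
  role[is.na(role)] <- "PASSENGER"
  clon <- mapply(function(p, k) {
    lab <- labels[[p]][k]
    if (is.null(lab) || is.na(lab)) NA_character_ else unname(lab)
  }, v$patient_id, v$variant_key)
  out <- data.frame(patient_id = v$patient_id, variant_key = v$variant_key,
                    gene = v$gene, is_driver = role != "PASSENGER",
                    role = role, clonality = unname(clon),
                    stringsAsFactors = FALSE)
  # variants dropped by the presence rule carry no clonality
  out[!is.na(out$clonality), , drop = FALSE]
}

# Exact two-sided binomial test against an even split.
.binom_p <- function(x, n, p0 = 0.5) {
  stats::binom.test(x, n, p = p0, alternative = "two.sided")$p.value
}

#' Trunk/branch driver-passenger and oncogene-TSG composition
#'
#' For each patient group and tree compartment (trunk, branch), counts
#' driver vs passenger mutations pooled over the group's patients, and
#' among drivers oncogene vs TSG mutations, each dichotomy with an exact
#' two-sided binomial test against an even (50/50) split. Compartments
#' with no mutations in a group are omitted; the role test is reported
#' only where the compartment has at least one driver mutation.
#'
#' @param annotations Data frame from [annotate_mutations()].
#' @param patients Data frame with `patient_id`, `subtype` (the `patients`
#'   slot of a cohort).
#' @param grouping Named list of subtype vectors. Default: `overall` plus
#'   one group per subtype present.
#' @return Data frame: `group`, `compartment`, `n_driver`, `n_passenger`,
#'   `pct_driver`, `p_binomial`, `n_oncogene`, `n_tsg`, `pct_oncogene`,
#'   `p_binomial_role`.
#' @export
composition_table <- function(annotations, patients, grouping = NULL) {
  if (is.null(grouping)) {
    subtypes <- unique(patients$subtype[!is.na(patients$subtype)])
    grouping <- c(list(overall = subtypes),
                  stats::setNames(as.list(subtypes), subtypes))
  }
  rows <- list()
  for (gname in names(grouping)) {
    pats <- patients$patient_id[patients$subtype %in% grouping[[gname]]]
    ann <- annotations[annotations$patient_id %in% pats, , drop = FALSE]
    for (comp in c("TRUNK", "BRANCH")) {
      a <- ann[ann$clonality == comp, , drop = FALSE]
      n_total <- nrow(a)
      if (n_total == 0) next
      n_driver <- sum(a$is_driver)
      n_pass <- n_total - n_driver
      n_onco <- sum(a$role == "ONCOGENE")
      n_tsg <- sum(a$role == "TSG")
      rows[[length(rows) + 1L]] <- data.frame(
        group = gname, compartment = comp,
        n_driver = n_driver, n_passenger = n_pass,
        pct_driver = n_driver / n_total,
        p_binomial = .binom_p(n_driver, n_total),
        n_oncogene = n_onco, n_tsg = n_tsg,
        pct_oncogene = if (n_driver > 0) n_onco / n_driver else NA_real_,
        p_binomial_role = if (n_driver > 0) .binom_p(n_onco, n_driver)
                          else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Driver-dominance score per driver gene
#'
#' Measures driver self-sufficiency: for gene g, carriers are the patients
#' with at least one mutation in g, and the score is the mean over carriers
#' of `1 / (number of distinct mutated driver genes in that patient)`. The
#' score is 1 exactly when g is the sole mutated driver in every carrier
#' and decreases as carriers accumulate co-drivers. Reported alongside the
#' fraction of patients carrying the mutated driver.
#'
#' @param annotations Data frame from [annotate_mutations()].
#' @param n_patients Total number of patients in the cohort (denominator of
#'   the carrier fraction).
#' @return Data frame `gene`, `role`, `n_carriers`, `carrier_fraction`,
#'   `score`, restricted to driver genes with at least one carrier, sorted
#'   by decreasing score then gene.
#' @export
compute_dominance <- function(annotations, n_patients) {
  drv <- annotations[annotations$is_driver, , drop = FALSE]
  if (nrow(drv) == 0) {
    return(data.frame(gene = character(0), role = character(0),
                      n_carriers = integer(0), carrier_fraction = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  pg <- unique(drv[c("patient_id", "gene", "role")])
  n_drivers_per_patient <- table(pg$patient_id)
  genes <- sort(unique(pg$gene))
  rows <- lapply(genes, function(g) {
    carriers <- pg$patient_id[pg$gene == g]
    data.frame(gene = g, role = pg$role[pg$gene == g][1],
               n_carriers = length(carriers),
               carrier_fraction = length(carriers) / n_patients,
               score = mean(1 / as.numeric(n_drivers_per_patient[carriers])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$score, out$gene), , drop = FALSE]
}
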
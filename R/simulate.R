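# Clonal-evolution + ctDNA-detection simulator. Each patient gets a random
# rooted bifurcating region tree with a germline root; mutations are placed
# on the trunk with a subtype-specific probability and uniformly on the
# remaining edges otherwise, so presence matrices are perfect-phylogeny
# compatible by construction (an optional dropout rate introduces
# homoplasy). A calibrated binomial read model turns configured per-stratum
# ctDNA detection probabilities into mutant read counts.

# Built-in synthetic driver catalog: familiar lung-cancer driver genes with
# oncogene/TSG roles.
.DRIVER_ONCOGENES <- c("EGFR", "KRAS", "BRAF", "PIK3CA", "MET", "ERBB2",
                       "ALK", "RET", "ROS1", "NRAS", "MYC", "CCND1",
                       "FGFR1", "AKT1", "HRAS")
.DRIVER_TSGS <- c("TP53", "RB1", "PTEN", "STK11", "KEAP1", "CDKN2A", "NF1",
                  "SMAD4", "ARID1A", "BRCA2", "ATM", "APC", "SETD2",
                  "SMARCA4", "NOTCH1")

#' Built-in synthetic driver catalog
#'
#' Thirty lung-cancer driver genes with oncogene/TSG roles, used as the
#' simulator's default catalog. Also shipped as a TSV at
#' `system.file("extdata", "driver_catalog_synthetic.tsv", package = "mrith")`.
#'
#' @return Named character vector gene -> role.
#' @export
default_driver_catalog <- function() {
  stats::setNames(c(rep("ONCOGENE", length(.DRIVER_ONCOGENES)),
                    rep("TSG", length(.DRIVER_TSGS))),
                  c(.DRIVER_ONCOGENES, .DRIVER_TSGS))
}

# 1021-symbol panel-like gene universe: the 30 drivers plus synthetic
# passenger symbols.
.panel_genes <- function() {
  c(.DRIVER_ONCOGENES, .DRIVER_TSGS, sprintf("PNL%04d", seq_len(991)))
}

# Expand a scalar or partially named per-subtype parameter to all subtypes.
.per_subtype <- function(x, subtypes, what) {
  if (length(x) == 1 && is.null(names(x))) {
    return(stats::setNames(rep(x, length(subtypes)), subtypes))
  }
  if (!all(subtypes %in% names(x))) {
    stop(what, " must be a scalar or named for every subtype")
  }
  x[subtypes]
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a 32-patient multi-region
#' NSCLC cohort: subtype composition 9 EGFR-mutant LUAD / 6 KRAS-mutant
#' LUAD / 11 EGFR&KRAS-wild-type LUAD / 5 LUSC / 1 LELC; 3-7 regions per
#' patient; mean mutation burden 14 per patient (Poisson); the lowest
#' trunk fraction in EGFR-mutant LUAD; and per-subtype ctDNA detection
#' probabilities with trunk mutations detected more readily than branch
#' mutations (trunk: LUSC 0.81, WT-LUAD 0.53, EGFR-LUAD 0.30, KRAS-LUAD
#' 0.22; branch rates in the 0.13-0.25 band).
#'
#' @param n_patients Named integer vector of patients per subtype.
#' @param regions_range Integer interval for the per-patient region count.
#' @param mutation_burden Mean somatic mutation count per patient
#'   (Poisson), scalar or per-subtype.
#' @param trunk_fraction Probability theta that a mutation is placed on
#'   the trunk, per subtype or scalar.
#' @param driver_prob Probability a mutation hits a driver-catalog gene.
#' @param oncogene_share Among driver mutations, probability of an oncogene
#'   (vs TSG), per subtype or scalar.
#' @param p_detect_trunk,p_detect_branch Per-subtype (or scalar) ctDNA
#'   detection probabilities for trunk and branch mutations.
#' @param plasma_depth Constant plasma depth per assayed mutation.
#' @param tissue_depth Constant tissue depth per observation.
#' @param vclass_probs Probabilities of SNV/INDEL/CNV/FUSION per mutation.
#' @param dropout Per-(mutation, region) probability that a truly present
#'   call is missed in one region (0 = noiseless presence; positive values
#'   create homoplasy).
#' @param force_driver Force the subtype's canonical driver (EGFR/KRAS) as
#'   a trunk oncogene mutation in EGFR_LUAD/KRAS_LUAD patients.
#' @param seed Integer random seed.
#' @return Object of class `mrith_sim_config`.
#' @export
simulation_config <- function(n_patients = c(EGFR_LUAD = 9, KRAS_LUAD = 6,
                                             WT_LUAD = 11, LUSC = 5,
                                             LELC = 1),
                              regions_range = c(3L, 7L),
                              mutation_burden = 14,
                              trunk_fraction = c(EGFR_LUAD = 0.30,
                                                 KRAS_LUAD = 0.55,
                                                 WT_LUAD = 0.55, LUSC = 0.60,
                                                 LELC = 0.55),
                              driver_prob = 0.5,
                              oncogene_share = c(EGFR_LUAD = 0.75,
                                                 KRAS_LUAD = 0.55,
                                                 WT_LUAD = 0.55, LUSC = 0.30,
                                                 LELC = 0.50),
                              p_detect_trunk = c(EGFR_LUAD = 0.30,
                                                 KRAS_LUAD = 0.22,
                                                 WT_LUAD = 0.53, LUSC = 0.81,
                                                 LELC = 0.45),
                              p_detect_branch = c(EGFR_LUAD = 0.25,
                                                  KRAS_LUAD = 0.13,
                                                  WT_LUAD = 0.23,
                                                  LUSC = 0.15, LELC = 0.20),
                              plasma_depth = 1000L,
                              tissue_depth = 500L,
                              vclass_probs = c(SNV = 0.92, INDEL = 0.04,
                                               CNV = 0.03, FUSION = 0.01),
                              dropout = 0,
                              force_driver = TRUE,
                              seed = 1L) {
  subtypes <- names(n_patients)
  if (is.null(subtypes) || !all(subtypes %in% SUBTYPE_LEVELS)) {
    stop("n_patients must be named with subtypes among: ",
         paste(SUBTYPE_LEVELS, collapse = ", "))
  }
  cfg <- list(
    n_patients = n_patients,
    regions_range = as.integer(regions_range),
    mutation_burden = .per_subtype(mutation_burden, subtypes,
                                   "mutation_burden"),
    trunk_fraction = .per_subtype(trunk_fraction, subtypes, "trunk_fraction"),
    driver_prob = driver_prob,
    oncogene_share = .per_subtype(oncogene_share, subtypes, "oncogene_share"),
    p_detect_trunk = .per_subtype(p_detect_trunk, subtypes, "p_detect_trunk"),
    p_detect_branch = .per_subtype(p_detect_branch, subtypes,
                                   "p_detect_branch"),
    plasma_depth = as.integer(plasma_depth),
    tissue_depth = as.integer(tissue_depth),
    vclass_probs = vclass_probs,
    dropout = dropout,
    force_driver = isTRUE(force_driver),
    seed = as.integer(seed))
  probs <- c(cfg$trunk_fraction, cfg$p_detect_trunk, cfg$p_detect_branch,
             cfg$driver_prob, cfg$oncogene_share, cfg$dropout,
             cfg$vclass_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (abs(sum(cfg$vclass_probs) - 1) > 1e-9) {
    stop("vclass_probs must sum to 1")
  }
  if (length(cfg$regions_range) != 2 || cfg$regions_range[1] < 1 ||
      cfg$regions_range[2] > 10 ||
      cfg$regions_range[1] > cfg$regions_range[2]) {
    stop("regions_range must be an integer interval within [1, 10]")
  }
  class(cfg) <- "mrith_sim_config"
  cfg
}

# Random rooted bifurcating topology by stepwise random insertion; returns
# the list of leaf sets below each non-root edge (proper subtrees).
.random_topology_edges <- function(n_regions) {
  if (n_regions == 1) return(list())
  tree <- 1L
  for (leaf in 2:n_regions) {
    options <- .insert_leaf_everywhere(tree, leaf)
    tree <- options[[sample.int(length(options), 1)]]
  }
  subtrees <- list()
  collect <- function(t, is_root) {
    if (!is_root) subtrees[[length(subtrees) + 1L]] <<- sort(.leaves_of(t))
    if (is.list(t)) {
      collect(t[[1]], FALSE)
      collect(t[[2]], FALSE)
    }
  }
  collect(tree, TRUE)
  subtrees
}

.leaves_of <- function(t) {
  if (!is.list(t)) return(t)
  c(.leaves_of(t[[1]]), .leaves_of(t[[2]]))
}

# Per-read mutant probability q such that 1 - (1 - q)^depth equals the
# target detection probability.
.calibrate_q <- function(p_detect, depth) {
  1 - (1 - p_detect)^(1 / depth)
}

#' Simulate a multi-region cohort with matched ctDNA
#'
#' Generates tissue, ctDNA and driver-catalog tables in exactly the
#' formats read by [read_tissue_table()], [read_ctdna_table()] and
#' [read_driver_catalog()], together with the full ground truth. See
#' [simulation_config()] for the generative model. With the same config
#' (including seed) the output is identical.
#'
#' @param config An `mrith_sim_config`.
#' @return Object of class `mrith_sim`: list with data frames `tissue`,
#'   `ctdna`, `drivers` (gene/role), and `truth` (one row per mutation:
#'   `patient_id`, `variant_key`, `subtype`, `clonality`, `gene`, `role`,
#'   `vclass`, `n_regions_present`, `p_detect`), plus `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "mrith_sim_config"))
  set.seed(config$seed)
  genes <- .panel_genes()
  catalog <- default_driver_catalog()
  passengers <- setdiff(genes, names(catalog))

  tissue <- list(); ctdna <- list(); truth <- list()
  pos_counter <- 0L
  bases <- c("A", "C", "G", "T")
  pid_n <- 0L

  for (subtype in names(config$n_patients)) {
    for (k in seq_len(config$n_patients[[subtype]])) {
      pid_n <- pid_n + 1L
      pid <- sprintf("P%03d", pid_n)
      n_reg <- sample(seq(config$regions_range[1], config$regions_range[2]),
                      1)
      regions <- sprintf("%s_R%d", pid, seq_len(n_reg))
      branch_edges <- .random_topology_edges(n_reg)

      n_base <- max(1L, stats::rpois(1, config$mutation_burden[[subtype]]))
      # canonical subtype driver forced as an extra trunk oncogene SNV
      forced <- config$force_driver && subtype %in% c("EGFR_LUAD",
                                                      "KRAS_LUAD")

      # Draw clonality and placement until every sampled region carries at
      # least one mutation: a region with no somatic call would be
      # invisible in the per-observation output table. Rare at realistic
      # burdens; the burden is enlarged if coverage proves infeasible.
      tries <- 0L
      repeat {
        tries <- tries + 1L
        is_trunk <- stats::rbinom(n_base, 1,
                                  config$trunk_fraction[[subtype]]) == 1
        if (forced) is_trunk <- c(TRUE, is_trunk)
        n_mut <- length(is_trunk)
        if (n_reg == 1) is_trunk[] <- TRUE

        # trunk mutations sit in all regions, branch mutations in the
        # regions below a uniformly chosen non-root edge
        presence <- matrix(0L, nrow = n_mut, ncol = n_reg)
        presence[is_trunk, ] <- 1L
        for (i in which(!is_trunk)) {
          below <- branch_edges[[sample.int(length(branch_edges), 1)]]
          presence[i, below] <- 1L
        }
        if (config$dropout > 0) {
          for (i in seq_len(n_mut)) {
            on <- which(presence[i, ] == 1L)
            drop <- on[stats::runif(length(on)) < config$dropout]
            if (length(drop) == length(on)) {
              drop <- drop[-sample.int(length(drop), 1)]
            }
            presence[i, drop] <- 0L
          }
        }
        if (all(colSums(presence) > 0L)) break
        if (tries %% 25L == 0L) n_base <- n_base + 1L
      }

      is_driver <- stats::runif(n_mut) < config$driver_prob
      is_onco <- stats::runif(n_mut) < config$oncogene_share[[subtype]]
      gene <- character(n_mut)
      gene[is_driver & is_onco] <- sample(.DRIVER_ONCOGENES,
                                          sum(is_driver & is_onco),
                                          replace = TRUE)
      gene[is_driver & !is_onco] <- sample(.DRIVER_TSGS,
                                           sum(is_driver & !is_onco),
                                           replace = TRUE)
      gene[!is_driver] <- sample(passengers, sum(!is_driver), replace = TRUE)
      vclass <- sample(names(config$vclass_probs), n_mut, replace = TRUE,
                       prob = config$vclass_probs)
      if (forced) {
        is_driver[1] <- TRUE
        gene[1] <- if (subtype == "EGFR_LUAD") "EGFR" else "KRAS"
        vclass[1] <- "SNV"
      }

      # synthetic coordinates; CNV/FUSION carry gene-level events
      pos <- integer(n_mut); ref <- character(n_mut); alt <- character(n_mut)
      for (i in seq_len(n_mut)) {
        if (vclass[i] %in% c("SNV", "INDEL")) {
          pos_counter <- pos_counter + 1L
          pos[i] <- pos_counter
          if (vclass[i] == "SNV") {
            ra <- sample(bases, 2)
            ref[i] <- ra[1]; alt[i] <- ra[2]
          } else {
            ref[i] <- paste(sample(bases, 3, replace = TRUE), collapse = "")
            alt[i] <- substr(ref[i], 1, 1)
          }
        } else {
          pos[i] <- 0L
          ref[i] <- "."
          alt[i] <- if (vclass[i] == "CNV") {
            sample(c("AMP", "DEL"), 1)
          } else {
            sample(genes, 1)
          }
        }
      }
      key <- variant_key("chrS", pos, ref, alt, gene, vclass)
      tries <- 0L
      while (anyDuplicated(key)) {  # regenerate clashing gene-level keys
        i <- which(duplicated(key))[1]
        tries <- tries + 1L
        if (tries > 5L) {  # same gene hit repeatedly: move the event
          gene[i] <- sample(if (gene[i] %in% names(catalog)) {
            names(catalog)
          } else passengers, 1)
        }
        alt[i] <- if (vclass[i] == "CNV") {
          sample(c("AMP", "DEL"), 1)
        } else sample(genes, 1)
        key <- variant_key("chrS", pos, ref, alt, gene, vclass)
      }

      counts <- vclass %in% c("SNV", "INDEL")
      vaf_base <- ifelse(is_trunk, stats::runif(n_mut, 0.20, 0.50),
                         stats::runif(n_mut, 0.05, 0.30))
      idx <- which(presence == 1L, arr.ind = TRUE)
      mi <- idx[, 1]; ri <- idx[, 2]
      has_counts <- counts[mi]
      ar <- rep(NA_integer_, length(mi))
      ar[has_counts] <- pmax(1L, stats::rbinom(sum(has_counts),
                                               config$tissue_depth,
                                               vaf_base[mi[has_counts]]))
      tissue[[length(tissue) + 1L]] <- data.frame(
        patient_id = pid, region_id = regions[ri], subtype = subtype,
        chrom = "chrS", pos = pos[mi], ref = ref[mi], alt = alt[mi],
        gene = gene[mi], vclass = vclass[mi],
        vaf = round(ar / config$tissue_depth, 4), alt_reads = ar,
        depth = ifelse(has_counts, config$tissue_depth, NA_integer_),
        stringsAsFactors = FALSE)

      p_det <- ifelse(is_trunk, config$p_detect_trunk[[subtype]],
                      config$p_detect_branch[[subtype]])
      q <- .calibrate_q(p_det, config$plasma_depth)
      mreads <- stats::rbinom(n_mut, config$plasma_depth, q)
      ctdna[[length(ctdna) + 1L]] <- data.frame(
        patient_id = pid, chrom = "chrS", pos = pos, ref = ref, alt = alt,
        gene = gene, vclass = vclass, mutant_reads = mreads,
        depth = config$plasma_depth, stringsAsFactors = FALSE)

      truth[[length(truth) + 1L]] <- data.frame(
        patient_id = pid, variant_key = key, subtype = subtype,
        clonality = ifelse(is_trunk, "TRUNK", "BRANCH"), gene = gene,
        role = ifelse(gene %in% names(catalog), unname(catalog[gene]),
                      "PASSENGER"),
        vclass = vclass, n_regions_present = rowSums(presence),
        p_detect = p_det, stringsAsFactors = FALSE)
    }
  }

  out <- list(
    tissue = do.call(rbind, c(tissue, list(make.row.names = FALSE))),
    ctdna = do.call(rbind, c(ctdna, list(make.row.names = FALSE))),
    drivers = data.frame(gene = names(catalog), role = unname(catalog),
                         stringsAsFactors = FALSE),
    truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
    config = config)
  class(out) <- "mrith_sim"
  out
}

#' @export
print.mrith_sim <- function(x, ...) {
  cat(sprintf("mrith_sim: %d patients, %d mutations, %d tissue rows, seed %d\n",
              length(unique(x$truth$patient_id)), nrow(x$truth),
              nrow(x$tissue), x$config$seed))
  invisible(x)
}

#' Write a simulated cohort's tables to a directory
#'
#' Emits `tissue.tsv`, `ctdna.tsv`, `drivers.tsv` in the formats consumed
#' by the readers, plus `truth.tsv`.
#'
#' @param sim An `mrith_sim`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulated_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "mrith_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(sim$tissue, file.path(dir, "tissue.tsv"))
  write_tsv(sim$ctdna, file.path(dir, "ctdna.tsv"))
  write_tsv(sim$drivers, file.path(dir, "drivers.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Check pipeline recovery of simulated ground truth
#'
#' Runs the classification, phylogeny and ctDNA stages on a simulated
#' cohort and compares against the generator's truth: trunk/branch call
#' accuracy (exact under noiseless presence), the fraction of patients
#' whose parsimony score equals their mutation count (1 when presence is
#' perfect-phylogeny compatible), and the recovered pooled detection rate
#' per clonality stratum next to the configured probability.
#'
#' @param sim An `mrith_sim`.
#' @return List with `trunk_branch_accuracy`, `n_mutations`,
#'   `parsimony_equals_mutation_count` (fraction of patients),
#'   `detection` (data frame `clonality`, `n`, `rate_recovered`,
#'   `rate_configured`).
#' @export
truth_check <- function(sim) {
  stopifnot(inherits(sim, "mrith_sim"))
  dir <- tempfile("simcheck")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  write_simulated_cohort(sim, dir)
  cohort <- read_tissue_table(file.path(dir, "tissue.tsv"))
  if (!setequal(cohort$patients$patient_id, unique(sim$truth$patient_id))) {
    stop("patient sets of pipeline input and truth differ")
  }
  mats <- mutation_matrices(cohort)
  labels <- lapply(mats, classify_trunk_branch)

  called <- unlist(lapply(names(labels), function(p) {
    stats::setNames(unname(labels[[p]]),
                    paste(p, names(labels[[p]]), sep = "\r"))
  }))
  truth_id <- paste(sim$truth$patient_id, sim$truth$variant_key, sep = "\r")
  acc <- mean(called[truth_id] == sim$truth$clonality)

  score_ok <- vapply(names(mats), function(p) {
    tr <- build_phylogenetic_tree(mats[[p]], patient_id = p)
    tr$parsimony_score == nrow(mats[[p]])
  }, logical(1))

  ctdna <- read_ctdna_table(file.path(dir, "ctdna.tsv"))
  det <- match_tumor_to_plasma(cohort, ctdna, labels = labels)
  det_id <- paste(det$patient_id, det$variant_key, sep = "\r")
  truth_p <- structure(sim$truth$p_detect, names = truth_id)
  detection <- do.call(rbind, lapply(c("TRUNK", "BRANCH"), function(cl) {
    sel <- det$clonality == cl
    if (!any(sel)) return(NULL)
    data.frame(clonality = cl, n = sum(sel),
               rate_recovered = mean(det$detected[sel]),
               rate_configured = mean(truth_p[det_id[sel]]),
               stringsAsFactors = FALSE)
  }))
  list(trunk_branch_accuracy = acc,
       n_mutations = nrow(sim$truth),
       parsimony_equals_mutation_count = mean(score_ok),
       detection = detection)
}
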
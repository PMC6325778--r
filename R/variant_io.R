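# Controlled vocabularies shared across the package.
VCLASS_LEVELS <- c("SNV", "INDEL", "CNV", "FUSION")
SUBTYPE_LEVELS <- c("EGFR_LUAD", "KRAS_LUAD", "WT_LUAD", "LUSC", "LELC")
ROLE_LEVELS <- c("ONCOGENE", "TSG")

#' Canonical variant identity key
#'
#' Builds the identity string under which the same somatic alteration is
#' matched across tumor regions and in plasma. Positional classes (SNV,
#' INDEL) are keyed by genomic coordinate and alleles, `chrom:pos:ref:alt`;
#' non-positional classes (CNV, FUSION) are keyed at the gene level,
#' `gene:vclass:alt`, where `alt` carries the event (e.g. `"AMP"`, `"DEL"`,
#' or the fusion partner symbol).
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position (ignored for CNV/FUSION).
#' @param ref,alt Allele strings (for CNV/FUSION, `alt` is the event label).
#' @param gene Gene symbol.
#' @param vclass Variant class, one of `"SNV"`, `"INDEL"`, `"CNV"`, `"FUSION"`.
#' @return Character vector of canonical keys.
#' @export
#' @examples
#' variant_key("chr7", 55249071, "C", "T", "EGFR", "SNV")
#' variant_key("chr2", 0, ".", "ALK", "EML4", "FUSION")
variant_key <- function(chrom, pos, ref, alt, gene, vclass) {
  if (!all(vclass %in% VCLASS_LEVELS)) {
    bad <- unique(vclass[!vclass %in% VCLASS_LEVELS])
    stop("unknown variant class: ", paste(bad, collapse = ", "))
  }
  positional <- vclass %in% c("SNV", "INDEL")
  ifelse(positional,
         paste(chrom, pos, ref, alt, sep = ":"),
         paste(gene, vclass, alt, sep = ":"))
}

.parse_num <- function(x) {
  x[x == "." | x == ""] <- NA_character_
  suppressWarnings(as.numeric(x))
}

.parse_int <- function(x, what, lines) {
  x[x == "." | x == ""] <- NA_character_
  out <- suppressWarnings(as.integer(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("non-integer %s '%s' at line %d", what, x[bad[1]], lines[bad[1]]))
  }
  out
}

.read_tsv_raw <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "", comment.char = "")
  df
}

#' Read a multi-region tissue variant table
#'
#' Parses a tab-separated table of pre-called somatic variants, one row per
#' observation of a variant in one tumor region, into a cohort object. The
#' same alteration seen in several regions (or patients) collapses to a
#' single variant record via [variant_key()]; per-region evidence is kept as
#' observations.
#'
#' Required columns: `patient_id`, `region_id`, `chrom`, `pos`, `ref`,
#' `alt`, `gene`, `vclass`. Recognized optional columns: `subtype`,
#' `stage`, `vaf`, `alt_reads`, `depth` (missing values written `"."`).
#' Extra columns are ignored.
#'
#' @param path Path to the tab-separated file (header required).
#' @return An object of class `mrith_cohort`: a list with data frames
#'   `patients` (patient_id, subtype, stage, n_regions), `regions`
#'   (patient_id, region_id), `variants` (patient_id, variant_key, chrom,
#'   pos, ref, alt, gene, vclass) and `observations` (patient_id,
#'   variant_key, region_id, vaf, alt_reads, depth).
#' @export
read_tissue_table <- function(path) {
  df <- .read_tsv_raw(path)
  required <- c("patient_id", "region_id", "chrom", "pos", "ref", "alt",
                "gene", "vclass")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(df)
  lines <- seq_len(n) + 1L  # header is line 1
  if (n == 0) {
    return(.new_cohort(df[required], subtype = character(0),
                       stage = character(0)))
  }
  bad <- which(!df$vclass %in% VCLASS_LEVELS)
  if (length(bad)) {
    stop(sprintf("invalid vclass '%s' at line %d", df$vclass[bad[1]],
                 lines[bad[1]]))
  }
  pos <- .parse_int(df$pos, "pos", lines)
  pos[is.na(pos)] <- 0L
  positional <- df$vclass %in% c("SNV", "INDEL")
  if (any(positional & pos < 1L)) {
    i <- which(positional & pos < 1L)[1]
    stop(sprintf("SNV/INDEL with pos < 1 at line %d", lines[i]))
  }
  df$pos <- pos
  key <- variant_key(df$chrom, df$pos, df$ref, df$alt, df$gene, df$vclass)

  dup <- duplicated(paste(df$patient_id, df$region_id, key, sep = "\r"))
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf(
      "duplicate observation of variant '%s' in patient %s region %s (line %d)",
      key[i], df$patient_id[i], df$region_id[i], lines[i]))
  }

  vaf <- if ("vaf" %in% names(df)) .parse_num(df$vaf) else rep(NA_real_, n)
  alt_reads <- if ("alt_reads" %in% names(df)) {
    .parse_int(df$alt_reads, "alt_reads", lines)
  } else rep(NA_integer_, n)
  depth <- if ("depth" %in% names(df)) {
    .parse_int(df$depth, "depth", lines)
  } else rep(NA_integer_, n)
  bad <- which(!is.na(alt_reads) & !is.na(depth) & alt_reads > depth)
  if (length(bad)) {
    stop(sprintf("alt_reads > depth at line %d", lines[bad[1]]))
  }
  bad <- which((!is.na(alt_reads) & alt_reads < 0) | (!is.na(depth) & depth < 0))
  if (length(bad)) {
    stop(sprintf("negative read count at line %d", lines[bad[1]]))
  }
  bad <- which(!is.na(vaf) & !is.na(alt_reads) & !is.na(depth) & depth > 0 &
                 abs(vaf - alt_reads / depth) > 0.01)
  if (length(bad)) {
    stop(sprintf("vaf inconsistent with alt_reads/depth at line %d",
                 lines[bad[1]]))
  }

  subtype <- if ("subtype" %in% names(df)) df$subtype else rep(NA_character_, n)
  subtype[subtype %in% c(".", "")] <- NA_character_
  bad <- which(!is.na(subtype) & !subtype %in% SUBTYPE_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown subtype '%s' at line %d", subtype[bad[1]],
                 lines[bad[1]]))
  }
  stage <- if ("stage" %in% names(df)) df$stage else rep(NA_character_, n)
  stage[stage %in% c(".", "")] <- NA_character_

  tab <- data.frame(patient_id = df$patient_id, region_id = df$region_id,
                    chrom = df$chrom, pos = df$pos, ref = df$ref,
                    alt = df$alt, gene = df$gene, vclass = df$vclass,
                    variant_key = key, vaf = vaf, alt_reads = alt_reads,
                    depth = depth, stringsAsFactors = FALSE)
  .new_cohort(tab, subtype = subtype, stage = stage)
}

# Assemble a cohort object from a validated long-format observation table.
.new_cohort <- function(tab, subtype, stage) {
  if (nrow(tab) == 0) {
    cohort <- list(
      patients = data.frame(patient_id = character(0),
                            subtype = character(0), stage = character(0),
                            n_regions = integer(0), stringsAsFactors = FALSE),
      regions = data.frame(patient_id = character(0),
                           region_id = character(0), stringsAsFactors = FALSE),
      variants = data.frame(patient_id = character(0),
                            variant_key = character(0), chrom = character(0),
                            pos = integer(0), ref = character(0),
                            alt = character(0), gene = character(0),
                            vclass = character(0), stringsAsFactors = FALSE),
      observations = data.frame(patient_id = character(0),
                                variant_key = character(0),
                                region_id = character(0), vaf = numeric(0),
                                alt_reads = integer(0), depth = integer(0),
                                stringsAsFactors = FALSE))
    class(cohort) <- "mrith_cohort"
    return(cohort)
  }
  ord <- order(tab$patient_id, tab$region_id, tab$variant_key)
  tab <- tab[ord, , drop = FALSE]
  subtype <- subtype[ord]
  stage <- stage[ord]

  regions <- unique(tab[c("patient_id", "region_id")])
  rownames(regions) <- NULL

  pat_ids <- unique(tab$patient_id)
  pstype <- vapply(pat_ids, function(p) {
    s <- unique(subtype[tab$patient_id == p & !is.na(subtype)])
    if (length(s) > 1) stop("conflicting subtype labels for patient ", p)
    if (length(s) == 0) NA_character_ else s
  }, character(1))
  pstage <- vapply(pat_ids, function(p) {
    s <- unique(stage[tab$patient_id == p & !is.na(stage)])
    if (length(s) == 0) NA_character_ else s[1]
  }, character(1))
  patients <- data.frame(patient_id = pat_ids, subtype = unname(pstype),
                         stage = unname(pstage),
                         n_regions = as.integer(table(regions$patient_id)[pat_ids]),
                         stringsAsFactors = FALSE)
  rownames(patients) <- NULL

  vkeep <- !duplicated(paste(tab$patient_id, tab$variant_key, sep = "\r"))
  variants <- tab[vkeep, c("patient_id", "variant_key", "chrom", "pos",
                           "ref", "alt", "gene", "vclass")]
  rownames(variants) <- NULL

  observations <- tab[c("patient_id", "variant_key", "region_id", "vaf",
                        "alt_reads", "depth")]
  rownames(observations) <- NULL

  cohort <- list(patients = patients, regions = regions, variants = variants,
                 observations = observations)
  class(cohort) <- "mrith_cohort"
  cohort
}

#' @export
print.mrith_cohort <- function(x, ...) {
  cat(sprintf("mrith_cohort: %d patients, %d regions, %d distinct variants, %d observations\n",
              nrow(x$patients), nrow(x$regions), nrow(x$variants),
              nrow(x$observations)))
  st <- table(x$patients$subtype, useNA = "ifany")
  if (length(st)) {
    cat("  subtypes:", paste(sprintf("%s=%d", names(st), st), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Read a ctDNA (plasma) variant read-count table
#'
#' Columns: `patient_id`, `chrom`, `pos`, `ref`, `alt`, `gene`, `vclass`,
#' `mutant_reads`, `depth`. Keys are canonicalized exactly as in
#' [read_tissue_table()], so plasma and tissue records for the same
#' alteration compare equal. `mutant_reads` is taken to be the
#' post-quality-filter count; rows with zero mutant reads are retained
#' (the detection call is made downstream).
#'
#' @param path Path to the tab-separated file.
#' @return Data frame with columns `patient_id`, `variant_key`,
#'   `mutant_reads`, `depth`.
#' @export
read_ctdna_table <- function(path) {
  df <- .read_tsv_raw(path)
  required <- c("patient_id", "chrom", "pos", "ref", "alt", "gene", "vclass",
                "mutant_reads", "depth")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(df)
  lines <- seq_len(n) + 1L
  if (n == 0) {
    return(data.frame(patient_id = character(0), variant_key = character(0),
                      mutant_reads = integer(0), depth = integer(0),
                      stringsAsFactors = FALSE))
  }
  bad <- which(!df$vclass %in% VCLASS_LEVELS)
  if (length(bad)) {
    stop(sprintf("invalid vclass '%s' at line %d", df$vclass[bad[1]],
                 lines[bad[1]]))
  }
  pos <- .parse_int(df$pos, "pos", lines)
  pos[is.na(pos)] <- 0L
  mutant_reads <- .parse_int(df$mutant_reads, "mutant_reads", lines)
  depth <- .parse_int(df$depth, "depth", lines)
  bad <- which(is.na(mutant_reads) | is.na(depth))
  if (length(bad)) {
    stop(sprintf("missing read counts at line %d", lines[bad[1]]))
  }
  bad <- which(mutant_reads < 0 | depth < 0)
  if (length(bad)) {
    stop(sprintf("negative read count at line %d", lines[bad[1]]))
  }
  bad <- which(mutant_reads > depth)
  if (length(bad)) {
    stop(sprintf("mutant_reads > depth at line %d", lines[bad[1]]))
  }
  key <- variant_key(df$chrom, pos, df$ref, df$alt, df$gene, df$vclass)
  data.frame(patient_id = df$patient_id, variant_key = key,
             mutant_reads = mutant_reads, depth = depth,
             stringsAsFactors = FALSE)
}

#' Read a driver-gene catalog
#'
#' Two-column tab-separated file `gene`, `role` with role `"ONCOGENE"` or
#' `"TSG"` (case-insensitive). Genes absent from the catalog are treated as
#' passengers everywhere in the pipeline.
#'
#' @param path Path to the file.
#' @return Named character vector mapping gene symbol to role.
#' @export
read_driver_catalog <- function(path) {
  df <- .read_tsv_raw(path)
  if (!all(c("gene", "role") %in% names(df))) {
    stop("driver catalog must have columns 'gene' and 'role'")
  }
  role <- toupper(df$role)
  bad <- which(!role %in% ROLE_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown driver role '%s' at line %d (expected ONCOGENE or TSG)",
                 df$role[bad[1]], bad[1] + 1L))
  }
  catalog <- character(0)
  for (i in seq_len(nrow(df))) {
    g <- df$gene[i]
    if (g %in% names(catalog)) {
      if (catalog[[g]] != role[i]) {
        stop(sprintf("conflicting roles for gene %s: %s vs %s", g,
                     catalog[[g]], role[i]))
      }
    } else {
      catalog[[g]] <- role[i]
    }
  }
  catalog
}

#' Read a panel BED file
#'
#' Four columns: chrom, start, end, gene name; 0-based half-open intervals.
#'
#' @param path Path to the BED file (no header).
#' @return Data frame with columns `chrom`, `start`, `end`, `gene`.
#' @export
read_panel_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  bad <- which(n_fields < 3)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields", bad[1]))
  }
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end < start)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: bad interval", bad[1]))
  }
  gene <- vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_,
                 "")
  data.frame(chrom = vapply(parts, `[`, "", 1), start = start, end = end,
             gene = gene, stringsAsFactors = FALSE)
}

#' Restrict a cohort to a capture panel
#'
#' Keeps SNV/INDEL variants whose 1-based position falls inside a panel
#' interval (BED is 0-based half-open, so position p is inside (start, end]
#' when `start < p <= end` on the same chromosome), and CNV/FUSION records
#' whose gene matches a panel gene name. All observations of dropped
#' variants are dropped. Idempotent.
#'
#' @param cohort An `mrith_cohort`.
#' @param panel Data frame from [read_panel_bed()] (or a path to a BED file).
#' @return Filtered `mrith_cohort`.
#' @export
filter_to_panel <- function(cohort, panel) {
  stopifnot(inherits(cohort, "mrith_cohort"))
  if (is.character(panel)) panel <- read_panel_bed(panel)
  v <- cohort$variants
  if (nrow(v) == 0) return(cohort)
  keep <- logical(nrow(v))
  positional <- v$vclass %in% c("SNV", "INDEL")
  for (i in which(positional)) {
    keep[i] <- any(panel$chrom == v$chrom[i] & panel$start < v$pos[i] &
                     v$pos[i] <= panel$end)
  }
  panel_genes <- unique(panel$gene[!is.na(panel$gene)])
  keep[!positional] <- v$gene[!positional] %in% panel_genes
  kept_keys <- paste(v$patient_id, v$variant_key, sep = "\r")[keep]
  cohort$variants <- v[keep, , drop = FALSE]
  rownames(cohort$variants) <- NULL
  ok <- paste(cohort$observations$patient_id,
              cohort$observations$variant_key, sep = "\r") %in% kept_keys
  cohort$observations <- cohort$observations[ok, , drop = FALSE]
  rownames(cohort$observations) <- NULL
  cohort
}

#' Write a data frame as a UTF-8, LF, tab-separated file with header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param na String used for missing values (default `"."`).
#' @export
write_tsv <- function(df, path, na = ".") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = na, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}
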
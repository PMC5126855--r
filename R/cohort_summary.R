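## Cohort-level aggregation of curation outcomes: diagnostic yield by
## karyotype / phenotype category / recruitment, per-gene variant tallies,
## and oligogenic patient lists.

.roundHalfUp <- function(x) floor(x + 0.5)

#' Summarise curation outcomes across a cohort
#'
#' Stratifies patients by karyotype class, phenotype category and
#' (optionally) recruitment mode, counting per stratum the patients, those
#' with at least one curated (non-filtered) variant, and the best
#' classification per patient (pathogenic > likely pathogenic > VUS; the
#' VUS tiers collapse to one rank).  A genetic diagnosis is a best
#' classification of pathogenic or likely pathogenic.  Percentages are
#' recomputed from the counts with half-up rounding.
#'
#' @param curatedPatients the `patients` table returned by [curateCohort()]
#'   (or [table2Fixture()]): needs columns `karyotype`, `category`,
#'   `recruitment`, `best_classification`.
#' @param by stratification columns (subset of karyotype, category,
#'   recruitment).
#' @return data.frame with per-stratum counts `n_patients`,
#'   `n_with_curated_variant`, `n_pathogenic`, `n_likely_pathogenic`,
#'   `n_vus`, `n_diagnosed` and `diagnostic_rate` (integer percent, NA for
#'   empty strata), plus one `TOTAL` row per karyotype class.
#' @export
summarizeCohort <- function(curatedPatients,
                            by = c("karyotype", "category")) {
  p <- curatedPatients
  need <- c(by, "best_classification")
  if (!all(need %in% colnames(p)))
    stop("curated patient table must have columns: ",
         paste(need, collapse = ", "))
  if (anyNA(p$best_classification))
    stop("patient without curation record: ",
         p$id[which(is.na(p$best_classification))[1L]])

  strat <- function(rows, label) {
    best <- rows$best_classification
    np <- nrow(rows)
    nPath <- sum(best == "pathogenic")
    nLp <- sum(best == "likely_pathogenic")
    nVus <- sum(best %in% c("VUS1", "VUS2", "VUS3"))
    nCur <- nPath + nLp + nVus
    nDiag <- nPath + nLp
    cbind(label, data.frame(
      n_patients = np, n_with_curated_variant = nCur,
      n_pathogenic = nPath, n_likely_pathogenic = nLp, n_vus = nVus,
      n_diagnosed = nDiag,
      diagnostic_rate = if (np) .roundHalfUp(100 * nDiag / np) else NA_real_))
  }

  groups <- split(p, p[by], drop = TRUE)
  rows <- lapply(names(groups), function(g) {
    lab <- as.data.frame(as.list(groups[[g]][1L, by, drop = FALSE]),
                         stringsAsFactors = FALSE)
    rownames(lab) <- NULL
    strat(groups[[g]], lab)
  })
  out <- do.call(rbind, rows)

  ## totals per karyotype class
  if ("karyotype" %in% by) {
    tot <- lapply(unique(p$karyotype), function(k) {
      lab <- data.frame(karyotype = k, stringsAsFactors = FALSE)
      for (cn in setdiff(by, "karyotype")) lab[[cn]] <- "TOTAL"
      lab <- lab[, by, drop = FALSE]
      strat(p[p$karyotype == k, , drop = FALSE], lab)
    })
    out <- rbind(out, do.call(rbind, tot))
  }
  rownames(out) <- NULL
  out
}

#' Diagnostic count and rate for one stratum
#'
#' @param summary output of [summarizeCohort()].
#' @param karyotype,category,recruitment stratum selectors; use "TOTAL" for
#'   a karyotype totals row, NULL to ignore a key.
#' @return list with `count` (pathogenic + likely pathogenic) and `percent`
#'   (half-up rounded integer; NULL when the stratum has no patients).
#' @export
diagnosticRate <- function(summary, karyotype = NULL, category = NULL,
                           recruitment = NULL) {
  sel <- rep(TRUE, nrow(summary))
  if (!is.null(karyotype)) sel <- sel & summary$karyotype == karyotype
  if (!is.null(category)) sel <- sel & summary$category == category
  if (!is.null(recruitment) && "recruitment" %in% colnames(summary))
    sel <- sel & summary$recruitment == recruitment
  row <- summary[sel, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("stratum selection matched ", nrow(row), " rows")
  if (row$n_patients == 0)
    return(list(count = 0L, percent = NULL))
  list(count = as.integer(row$n_diagnosed),
       percent = as.integer(.roundHalfUp(100 * row$n_diagnosed /
                                           row$n_patients)))
}

#' Per-gene variant tally
#'
#' Deduplicates curated variants by normalized key across the cohort and
#' tallies, per gene: unique variants, previously reported vs unreported,
#' missense vs null (frameshift / stop gain / splice site) counts, and
#' unique protein-changing variants per kilobase of coding target.
#'
#' @param curatedVariants per-variant curation results joined with the
#'   variant annotations; needs `key`, `gene`, `consequence`,
#'   `reported_status`, `classification` (filtered_out rows are dropped).
#' @param codingKb named numeric vector: kilobases of coding target per
#'   gene.  Genes with variants but no entry get `variants_per_kb` NA with
#'   a warning.
#' @return data.frame per gene: `unique_variants`, `reported_count`,
#'   `unreported_count`, `missense_count`, `null_count`, `variants_per_kb`.
#' @export
geneTally <- function(curatedVariants, codingKb = NULL) {
  cv <- curatedVariants
  if (!is.null(cv$classification))
    cv <- cv[cv$classification != "filtered_out", , drop = FALSE]
  cv <- cv[!duplicated(cv$key), , drop = FALSE]
  if (!nrow(cv))
    return(data.frame(gene = character(0), unique_variants = integer(0),
                      reported_count = integer(0),
                      unreported_count = integer(0),
                      missense_count = integer(0), null_count = integer(0),
                      variants_per_kb = numeric(0)))
  proteinChanging <- c(.NULL_CONSEQUENCES, "missense", "inframe_indel")
  rows <- lapply(split(cv, cv$gene), function(g) {
    gene <- g$gene[1L]
    kb <- if (!is.null(codingKb) && gene %in% names(codingKb))
      codingKb[[gene]] else NA_real_
    npc <- sum(g$consequence %in% proteinChanging)
    if (is.na(kb) && !is.null(codingKb))
      warning("no coding_kb for gene ", gene, "; variants_per_kb set to NA")
    data.frame(
      gene = gene,
      unique_variants = nrow(g),
      reported_count = sum(g$reported_status != "unreported"),
      unreported_count = sum(g$reported_status == "unreported"),
      missense_count = sum(g$consequence == "missense"),
      null_count = sum(g$consequence %in% .NULL_CONSEQUENCES),
      variants_per_kb = if (is.na(kb)) NA_real_ else npc / kb)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Patients with curated variants in two or more genes
#'
#' Lists possible oligogenic cases: patients whose curated (non-filtered)
#' variants hit at least two distinct diagnostic genes.  Two variants in
#' the same gene only (a possible compound heterozygote) do not qualify.
#'
#' @param curationResults per-variant results from [curateCohort()].
#' @return data.frame with `patient_id`, `genes` (comma-joined, sorted) and
#'   `classifications` (per-gene best classification, matching order).
#' @export
oligogenicReport <- function(curationResults) {
  cr <- curationResults[curationResults$classification != "filtered_out", ,
                        drop = FALSE]
  if (!nrow(cr))
    return(data.frame(patient_id = character(0), genes = character(0),
                      classifications = character(0)))
  rows <- lapply(split(cr, cr$patient_id), function(p) {
    genes <- sort(unique(p$gene))
    if (length(genes) < 2L) return(NULL)
    cls <- vapply(genes, function(g)
      bestClassification(p$classification[p$gene == g]), character(1))
    data.frame(patient_id = p$patient_id[1L],
               genes = paste(genes, collapse = ","),
               classifications = paste(cls, collapse = ","))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(patient_id = character(0), genes = character(0),
                      classifications = character(0))
  rownames(out) <- NULL
  out
}
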
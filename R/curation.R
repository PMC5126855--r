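## Variant filtering, inheritance checking and rule-based classification.
##
## Variants are rows of a data.frame with (at least) the columns:
##   patient_id, chrom, pos, ref, alt, gene, consequence,
##   af_kg1000, af_esp, af_exac_subpop_max        (NA = unobserved),
##   pred_sift, pred_polyphen2, pred_lrt, pred_mutationtaster
##                                               (damaging/benign/missing),
##   reported_status (reported_same_phenotype / reported_other_disease /
##                    unreported),
##   genotype (het/hom/hemi), qual, depth, in_repeat_tract (logical),
## optionally father_gt / mother_gt (het/hom/absent/NA) and run_id.
##
## Patients are rows of a data.frame with columns:
##   id, karyotype (46XY/46XX), category (gonadal_development /
##   androgen_synthesis_action / other / unknown), subtype (free text),
##   recruitment (singleton / trio).

.variantKey <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Index cohort-internal variant recurrence
#'
#' Tracks how often each normalized variant key is observed across the
#' cohort database and within each sequencing run, so that likely
#' amplification/sequencing artifacts and locally common polymorphisms can
#' be discounted.
#'
#' @param variants cohort variant table (one row per observation, i.e. per
#'   patient carrying the variant); optional `run_id` column.
#' @return data.frame keyed by variant `key` with `count_in_database` and
#'   `max_count_in_run`.
#' @export
buildCohortIndex <- function(variants) {
  key <- .variantKey(variants)
  run <- if (!is.null(variants$run_id)) variants$run_id else "run1"
  db <- table(key)
  perRun <- tapply(run, key, function(r) max(table(r)))
  data.frame(key = names(db),
             count_in_database = as.integer(db),
             max_count_in_run = as.integer(perRun[names(db)]),
             stringsAsFactors = FALSE)
}

.predCols <- c("pred_sift", "pred_polyphen2", "pred_lrt",
               "pred_mutationtaster")

.damagingCount <- function(v) {
  sum(vapply(.predCols, function(cn)
    identical(as.character(v[[cn]]), "damaging"), logical(1)))
}

#' Filter one annotated variant
#'
#' Applies the panel's conjunctive filter rules in order, recording every
#' rule evaluated: population frequency (each of 1000 Genomes, ESP and the
#' maximum ExAC subpopulation frequency must be <= `mafMax`; absent = pass),
#' functional consequence (synonymous/other fail), cohort recurrence (more
#' than `cohortRecurrenceMax` observations in one run or in the database
#' fail), and gene panel membership.  Low call quality or depth does not
#' fail a variant but flags it for manual review.
#'
#' @param v one-row data.frame (or list) with the annotated variant fields.
#' @param cohortIndex output of [buildCohortIndex()] (NULL: counts of 1).
#' @param registry a \linkS4class{GeneRegistry}.
#' @param thresholds a \linkS4class{PanelThresholds}.
#' @return list with `pass` (logical) and `trail`, a data.frame of
#'   (rule, outcome, reason) rows in evaluation order.
#' @export
filterVariant <- function(v, cohortIndex = NULL, registry,
                          thresholds = panelThresholds()) {
  trail <- list()
  note <- function(rule, outcome, reason)
    trail[[length(trail) + 1L]] <<- data.frame(rule = rule,
                                               outcome = outcome,
                                               reason = reason)
  mafMax <- thresholds@mafMax

  freqRule <- function(rule, val) {
    if (!is.null(val) && !is.na(val) && val > mafMax)
      note(rule, "fail", sprintf("AF %.4g > %.4g", val, mafMax))
    else note(rule, "pass", if (is.null(val) || is.na(val)) "unobserved"
              else sprintf("AF %.4g <= %.4g", val, mafMax))
  }
  freqRule("frequency_1000genomes", v$af_kg1000)
  freqRule("frequency_esp", v$af_esp)
  freqRule("frequency_exac_subpop", v$af_exac_subpop_max)

  cons <- as.character(v$consequence)
  if (!cons %in% .CONSEQUENCES)
    stop("unknown consequence '", cons, "'; allowed: ",
         paste(.CONSEQUENCES, collapse = ", "))
  if (cons %in% c("synonymous", "other"))
    note("consequence", "fail", paste("non-functional consequence:", cons))
  else note("consequence", "pass", cons)

  key <- .variantKey(v)
  cdb <- crun <- 1L
  if (!is.null(cohortIndex)) {
    m <- match(key, cohortIndex$key)
    if (!is.na(m)) {
      cdb <- cohortIndex$count_in_database[m]
      crun <- cohortIndex$max_count_in_run[m]
    }
  }
  rmax <- thresholds@cohortRecurrenceMax
  if (crun > rmax)
    note("recurrence_run", "fail",
         sprintf("seen in %d samples in one run (> %d)", crun, rmax))
  else note("recurrence_run", "pass", sprintf("%d sample(s) in run", crun))
  if (cdb > rmax)
    note("recurrence_database", "fail",
         sprintf("seen in %d samples in the database (> %d)", cdb, rmax))
  else note("recurrence_database", "pass",
            sprintf("%d sample(s) in database", cdb))

  if (!as.character(v$gene) %in% geneSymbols(registry))
    note("gene_panel", "fail",
         paste0("gene ", v$gene, " is not a diagnostic panel gene"))
  else note("gene_panel", "pass", as.character(v$gene))

  lowq <- (!is.null(v$qual) && !is.na(v$qual) && v$qual < thresholds@minQual) ||
    (!is.null(v$depth) && !is.na(v$depth) && v$depth < thresholds@minDepth)
  if (lowq)
    note("quality_depth", "flag",
         "low quality or depth: flagged for manual review")
  else note("quality_depth", "pass", "quality and depth adequate")

  trail <- do.call(rbind, trail)
  list(pass = !any(trail$outcome == "fail"), trail = trail)
}

#' Inheritance-model check for a variant
#'
#' For singletons the supported models are inferred from the genotype alone
#' (hom/hemi supports recessive and X-linked models, het supports dominant)
#' and the variant is never discarded for inheritance.  With parental
#' genotypes (`father_gt`/`mother_gt`: het, hom, absent) the model set is
#' derived -- de novo (absent in both parents), recessive homozygous (both
#' parents carriers), inherited dominant, X-linked, and compound
#' heterozygous (two heterozygous variants in the same gene on opposite
#' parental origins, supplied via `gene_het_origins`) -- and consistency
#' requires a non-empty intersection with the gene's inheritance modes.
#'
#' @param v one-row variant data.frame (genotype and, for trios,
#'   father_gt/mother_gt).
#' @param patient one-row patient data.frame (`recruitment`).
#' @param gene a gene record from [geneRecord()].
#' @param gene_het_origins for trios: parental origins ("father"/"mother")
#'   of all heterozygous passing variants in the same gene for this patient,
#'   used to detect compound heterozygotes.
#' @return list with `consistent` (logical) and `models` (character subset
#'   of de_novo, AD_inherited, AR_hom, AR_compound_het, XL).
#' @export
checkInheritance <- function(v, patient, gene, gene_het_origins = NULL) {
  gt <- as.character(v$genotype)
  trio <- identical(as.character(patient$recruitment), "trio") &&
    !is.null(v$father_gt) && !is.null(v$mother_gt) &&
    !is.na(v$father_gt) && !is.na(v$mother_gt)

  if (!trio) {
    models <- switch(gt,
                     hom = c("AR_hom", "XL"),
                     hemi = c("XL", "AR_hom"),
                     het = c("AD_inherited", "de_novo"),
                     stop("malformed genotype '", gt, "'"))
    return(list(consistent = TRUE, models = models))
  }

  f <- as.character(v$father_gt); m <- as.character(v$mother_gt)
  ok <- c("het", "hom", "absent")
  if (!f %in% ok || !m %in% ok)
    stop("malformed trio genotypes: father '", f, "', mother '", m, "'")
  models <- character(0)
  if (f == "absent" && m == "absent") models <- c(models, "de_novo")
  if (gt == "hom" && f != "absent" && m != "absent")
    models <- c(models, "AR_hom")
  if (gt == "hemi" && m != "absent") models <- c(models, "XL")
  if (gt == "hemi" && f == "absent" && m == "absent")
    models <- c(models, "XL")  # de novo hemizygous
  if (gt == "het" && xor(f == "absent", m == "absent"))
    models <- c(models, "AD_inherited")
  if (gt == "het" && !is.null(gene_het_origins) &&
      all(c("father", "mother") %in% gene_het_origins))
    models <- c(models, "AR_compound_het")
  models <- unique(models)

  modeOf <- c(de_novo = "AD", AD_inherited = "AD", AR_hom = "AR",
              AR_compound_het = "AR", XL = "XL")
  supported <- unique(unlist(lapply(models, function(mo) {
    base <- modeOf[[mo]]
    if (mo == "de_novo") c("AD", "XL") else base
  })))
  geneModes <- sub("_dup$", "", gene$inheritance)  # XL_dup supports XL etc.
  list(consistent = length(intersect(supported, geneModes)) > 0,
       models = models)
}

#' Phenotype fit between a patient and a gene
#'
#' A patient's phenotype category fits a gene when it intersects the gene's
#' registry categories; patients of unknown category fit every gene.
#'
#' @param patientCategory one of gonadal_development,
#'   androgen_synthesis_action, other, unknown.
#' @param gene a record from [geneRecord()].
#' @return logical.
#' @export
phenotypeFit <- function(patientCategory, gene) {
  patientCategory <- as.character(patientCategory)
  if (!patientCategory %in% .PATIENT_CATEGORIES)
    stop("unknown patient category '", patientCategory, "'")
  if (patientCategory == "unknown") return(TRUE)
  patientCategory %in% gene$category
}

#' Classify a filtered variant
#'
#' Decision procedure (first match wins):
#' \enumerate{
#'   \item variant in the AR CAG/GGN repeat tract: VUS-3;
#'   \item null variant (frameshift, stop gain, splice site) in a gene
#'     where loss of function is a known disease mechanism and the
#'     phenotype fits: pathogenic;
#'   \item missense previously reported in a patient with a similar
#'     phenotype: pathogenic;
#'   \item unreported missense fitting the phenotype, with a consistent
#'     inheritance pattern and at least `minDamagingPredictors` of the four
#'     in-silico predictors damaging: likely pathogenic;
#'   \item phenotype fits but the damaging support is below threshold:
#'     VUS-1;
#'   \item damaging support at/above threshold but the phenotype does not
#'     fit: VUS-2;
#'   \item otherwise VUS-1.
#' }
#' Missing predictions count as non-damaging.
#'
#' @param v one-row variant data.frame.
#' @param gene record from [geneRecord()].
#' @param patient one-row patient data.frame (`category`).
#' @param inheritanceOk from [checkInheritance()].
#' @param thresholds a \linkS4class{PanelThresholds}.
#' @return one of "pathogenic", "likely_pathogenic", "VUS1", "VUS2", "VUS3".
#' @export
classifyVariant <- function(v, gene, patient, inheritanceOk = TRUE,
                            thresholds = panelThresholds()) {
  if (isTRUE(as.logical(v$in_repeat_tract))) return("VUS3")
  fit <- phenotypeFit(patient$category, gene)
  cons <- as.character(v$consequence)
  dmg <- .damagingCount(v)
  reported <- as.character(v$reported_status)

  if (cons %in% .NULL_CONSEQUENCES && isTRUE(gene$lof_mechanism) && fit)
    return("pathogenic")
  if (cons == "missense" && reported == "reported_same_phenotype")
    return("pathogenic")
  if (cons == "missense" && reported == "unreported" && fit &&
      inheritanceOk && dmg >= thresholds@minDamagingPredictors)
    return("likely_pathogenic")
  if (fit && dmg < thresholds@minDamagingPredictors) return("VUS1")
  if (!fit && dmg >= thresholds@minDamagingPredictors) return("VUS2")
  "VUS1"
}

.CLASS_RANK <- c(pathogenic = 1, likely_pathogenic = 2, VUS1 = 3, VUS2 = 3,
                 VUS3 = 3, filtered_out = 4)

#' Best classification by clinical precedence
#'
#' pathogenic > likely pathogenic > VUS (the three VUS tiers tie); returns
#' "none" when nothing survives filtering.
#'
#' @param classifications character vector.
#' @return the single highest-precedence classification.
#' @export
bestClassification <- function(classifications) {
  cl <- classifications[classifications != "filtered_out"]
  if (!length(cl)) return("none")
  cl[which.min(.CLASS_RANK[cl])]
}

#' Curate all variants of one patient
#'
#' Runs each variant through the filter, the inheritance check (variants
#' whose inheritance is inconsistent with the gene in a trio are removed
#' from curation), and the classifier, then summarises the patient: the
#' best classification by precedence, whether it constitutes a genetic
#' diagnosis (pathogenic or likely pathogenic), and whether the patient is
#' oligogenic (curated variants in two or more distinct panel genes).
#'
#' @param patient one-row patient data.frame.
#' @param variants variant table rows belonging to this patient.
#' @param cohortIndex from [buildCohortIndex()] (may be NULL).
#' @param registry a \linkS4class{GeneRegistry}.
#' @param thresholds a \linkS4class{PanelThresholds}.
#' @return list with `results` (per-variant data.frame: key, gene,
#'   classification, inheritance models, trail as a compact string),
#'   `best_classification`, `genetic_diagnosis`, `oligogenic`.
#' @export
curatePatient <- function(patient, variants, cohortIndex = NULL, registry,
                          thresholds = panelThresholds()) {
  n <- if (is.null(variants)) 0L else nrow(variants)
  if (!n) {
    return(list(results = data.frame(), best_classification = "none",
                genetic_diagnosis = FALSE, oligogenic = FALSE))
  }
  classification <- character(n)
  trailStr <- character(n)
  models <- character(n)

  ## parental origins of het variants per gene (for compound-het detection)
  hetOrigins <- list()
  if (identical(as.character(patient$recruitment), "trio") &&
      all(c("father_gt", "mother_gt") %in% colnames(variants))) {
    for (i in seq_len(n)) {
      if (identical(as.character(variants$genotype[i]), "het") &&
          !is.na(variants$father_gt[i]) && !is.na(variants$mother_gt[i])) {
        org <- if (variants$father_gt[i] != "absent" &&
                   variants$mother_gt[i] == "absent") "father"
        else if (variants$mother_gt[i] != "absent" &&
                 variants$father_gt[i] == "absent") "mother"
        else NA_character_
        g <- as.character(variants$gene[i])
        hetOrigins[[g]] <- c(hetOrigins[[g]], org)
      }
    }
  }

  for (i in seq_len(n)) {
    v <- variants[i, , drop = FALSE]
    flt <- filterVariant(v, cohortIndex, registry, thresholds)
    trailStr[i] <- paste(sprintf("%s=%s", flt$trail$rule, flt$trail$outcome),
                         collapse = ";")
    if (!flt$pass) {
      classification[i] <- "filtered_out"
      next
    }
    gene <- geneRecord(registry, as.character(v$gene))
    inh <- checkInheritance(v, patient, gene,
                            gene_het_origins =
                              hetOrigins[[as.character(v$gene)]])
    models[i] <- paste(inh$models, collapse = ",")
    if (!inh$consistent) {
      classification[i] <- "filtered_out"
      trailStr[i] <- paste0(trailStr[i], ";inheritance=fail")
      next
    }
    trailStr[i] <- paste0(trailStr[i], ";inheritance=pass")
    classification[i] <- classifyVariant(v, gene, patient,
                                         inheritanceOk = inh$consistent,
                                         thresholds = thresholds)
  }

  results <- data.frame(
    patient_id = as.character(patient$id),
    key = .variantKey(variants),
    gene = as.character(variants$gene),
    classification = classification,
    inheritance_models = models,
    filter_trail = trailStr,
    stringsAsFactors = FALSE)
  curated <- results[results$classification != "filtered_out", , drop = FALSE]
  best <- bestClassification(classification)
  list(results = results,
       best_classification = best,
       genetic_diagnosis = best %in% c("pathogenic", "likely_pathogenic"),
       oligogenic = length(unique(curated$gene)) >= 2)
}

#' Curate a whole cohort
#'
#' @param patients patient table (one row per patient).
#' @param variants cohort variant table (`patient_id` links to patients).
#' @param registry a \linkS4class{GeneRegistry}.
#' @param thresholds a \linkS4class{PanelThresholds}.
#' @param cohortIndex recurrence index; computed from `variants` when NULL.
#' @return list with `results` (row-bound per-variant curation) and
#'   `patients` (the patient table plus `best_classification`,
#'   `genetic_diagnosis`, `oligogenic`, `n_curated_variants`).
#' @export
curateCohort <- function(patients, variants, registry,
                         thresholds = panelThresholds(),
                         cohortIndex = NULL) {
  if (is.null(cohortIndex) && nrow(variants))
    cohortIndex <- buildCohortIndex(variants)
  res <- vector("list", nrow(patients))
  best <- character(nrow(patients))
  diag <- logical(nrow(patients))
  olig <- logical(nrow(patients))
  ncur <- integer(nrow(patients))
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, , drop = FALSE]
    pv <- variants[variants$patient_id == p$id, , drop = FALSE]
    cur <- curatePatient(p, pv, cohortIndex, registry, thresholds)
    res[[i]] <- cur$results
    best[i] <- cur$best_classification
    diag[i] <- cur$genetic_diagnosis
    olig[i] <- cur$oligogenic
    ncur[i] <- if (nrow(cur$results))
      sum(cur$results$classification != "filtered_out") else 0L
  }
  out <- patients
  out$best_classification <- best
  out$genetic_diagnosis <- diag
  out$oligogenic <- olig
  out$n_curated_variants <- ncur
  list(results = do.call(rbind, res[lengths(res) > 0]), patients = out)
}
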
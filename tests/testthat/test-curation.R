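## Filtering rules, inheritance models and the classification procedure.

reg <- loadGeneRegistry()
th <- panelThresholds()

test_that("frequency filters remove common variants in any population database", {
  idx <- NULL
  f <- filterVariant(makeVariant(af_kg1000 = 0.05), idx, reg, th)
  expect_false(f$pass)
  expect_equal(f$trail$outcome[f$trail$rule == "frequency_1000genomes"],
               "fail")
  expect_false(filterVariant(makeVariant(af_esp = 0.02), idx, reg, th)$pass)
  expect_false(filterVariant(makeVariant(af_exac_subpop_max = 0.3),
                             idx, reg, th)$pass)
  ## boundary: exactly 0.01 is rare (<= threshold passes)
  expect_true(filterVariant(makeVariant(af_kg1000 = 0.01), idx, reg, th)$pass)
  ## absent frequencies pass (unobserved = novel)
  expect_true(filterVariant(makeVariant(), idx, reg, th)$pass)
})

test_that("cohort recurrence above 15 samples is discounted", {
  v <- makeVariant()
  ## 16 observations of the same variant in the database
  obs <- do.call(rbind, lapply(1:16, function(i)
    makeVariant(patient_id = paste0("P", i))))
  idx <- buildCohortIndex(obs)
  f <- filterVariant(v, idx, reg, th)
  expect_false(f$pass)
  expect_equal(f$trail$outcome[f$trail$rule == "recurrence_database"], "fail")

  ## 15 observations pass
  idx15 <- buildCohortIndex(obs[1:15, ])
  expect_true(filterVariant(v, idx15, reg, th)$pass)

  ## per-run recurrence: 16 in one run fails even if spread thin elsewhere
  obs$run_id <- "runA"
  fr <- filterVariant(v, buildCohortIndex(obs), reg, th)
  expect_equal(fr$trail$outcome[fr$trail$rule == "recurrence_run"], "fail")
})

test_that("consequence and panel-membership gates work and trails record all rules", {
  expect_false(filterVariant(makeVariant(consequence = "synonymous"),
                             NULL, reg, th)$pass)
  expect_false(filterVariant(makeVariant(gene = "NOTAGENE"),
                             NULL, reg, th)$pass)
  f <- filterVariant(makeVariant(consequence = "frameshift"), NULL, reg, th)
  expect_true(f$pass)
  expect_equal(f$trail$rule,
               c("frequency_1000genomes", "frequency_esp",
                 "frequency_exac_subpop", "consequence", "recurrence_run",
                 "recurrence_database", "gene_panel", "quality_depth"))
  ## low quality flags for review without failing
  fl <- filterVariant(makeVariant(qual = 10), NULL, reg, th)
  expect_true(fl$pass)
  expect_equal(fl$trail$outcome[fl$trail$rule == "quality_depth"], "flag")
})

test_that("filter outcome is invariant to rule order (conjunctive rules)", {
  ## a variant failing several rules fails regardless of which is first;
  ## verified by comparing against the conjunction of individual gates
  set.seed(41)
  for (i in 1:20) {
    v <- makeVariant(
      af_kg1000 = sample(c(NA, 0.001, 0.05), 1),
      consequence = sample(c("missense", "synonymous", "frameshift"), 1),
      gene = sample(c("NR5A1", "NOPE"), 1))
    f <- filterVariant(v, NULL, reg, th)
    expected <- (is.na(v$af_kg1000) || v$af_kg1000 <= 0.01) &&
      !v$consequence %in% c("synonymous", "other") &&
      v$gene %in% geneSymbols(reg)
    expect_equal(f$pass, expected)
  }
})

test_that("raising mafMax is monotone: variants only move out of filtered_out", {
  afs <- c(0.001, 0.008, 0.02, 0.04, NA)
  strict <- vapply(afs, function(a)
    filterVariant(makeVariant(af_kg1000 = a), NULL, reg,
                  panelThresholds(mafMax = 0.01))$pass, logical(1))
  loose <- vapply(afs, function(a)
    filterVariant(makeVariant(af_kg1000 = a), NULL, reg,
                  panelThresholds(mafMax = 0.05))$pass, logical(1))
  expect_true(all(loose[strict]))   # nothing passing strict fails loose
  expect_gt(sum(loose), sum(strict))
})

test_that("singleton inheritance is permissive, trios constrain models", {
  nr5a1 <- geneRecord(reg, "NR5A1")      # AD
  hsd <- geneRecord(reg, "HSD17B3")      # AR only

  ## singleton het in AD gene
  s <- checkInheritance(makeVariant(), makePatient(), nr5a1)
  expect_true(s$consistent)
  expect_true("AD_inherited" %in% s$models)

  ## trio de novo het in AD gene: consistent
  p <- makePatient(recruitment = "trio")
  dn <- checkInheritance(makeVariant(father_gt = "absent",
                                     mother_gt = "absent"), p, nr5a1)
  expect_true(dn$consistent)
  expect_true("de_novo" %in% dn$models)

  ## single het in an AR-only gene inherited from one healthy parent, no
  ## second variant: inconsistent
  inh <- checkInheritance(makeVariant(gene = "HSD17B3", father_gt = "het",
                                      mother_gt = "absent"), p, hsd)
  expect_false(inh$consistent)

  ## homozygote with both parents carriers: consistent AR
  hom <- checkInheritance(makeVariant(gene = "HSD17B3", genotype = "hom",
                                      father_gt = "het", mother_gt = "het"),
                          p, hsd)
  expect_true(hom$consistent)
  expect_true("AR_hom" %in% hom$models)

  ## compound het: two variants on opposite parental origins
  ch <- checkInheritance(makeVariant(gene = "DHH", father_gt = "het",
                                     mother_gt = "absent"), p,
                         geneRecord(reg, "DHH"),
                         gene_het_origins = c("father", "mother"))
  expect_true(ch$consistent)
  expect_true("AR_compound_het" %in% ch$models)

  expect_error(checkInheritance(makeVariant(father_gt = "maybe",
                                            mother_gt = "het"), p, nr5a1),
               "malformed")
})

test_that("classification follows the decision procedure", {
  p <- makePatient(category = "gonadal_development")
  nr5a1 <- geneRecord(reg, "NR5A1")

  ## novel frameshift in LoF-mechanism gene fitting phenotype -> pathogenic
  expect_equal(classifyVariant(makeVariant(consequence = "frameshift"),
                               nr5a1, p, TRUE, th), "pathogenic")

  ## reported missense with same phenotype -> pathogenic
  expect_equal(classifyVariant(
    makeVariant(reported_status = "reported_same_phenotype"),
    nr5a1, p, TRUE, th), "pathogenic")

  ## novel missense, fit, inheritance ok, 4/4 damaging -> likely pathogenic
  lp <- withPredictions(makeVariant(), damaging = 4)
  expect_equal(classifyVariant(lp, nr5a1, p, TRUE, th), "likely_pathogenic")
  ## 3/4 damaging meets the default >=3 threshold
  expect_equal(classifyVariant(withPredictions(makeVariant(), 3),
                               nr5a1, p, TRUE, th), "likely_pathogenic")
  ## 2/4 does not: phenotype fits but support is weak -> VUS1
  expect_equal(classifyVariant(withPredictions(makeVariant(), 2),
                               nr5a1, p, TRUE, th), "VUS1")
  ## inconsistent inheritance blocks the upgrade -> VUS1
  expect_equal(classifyVariant(lp, nr5a1, p, FALSE, th), "VUS1")

  ## damaging but phenotype mismatch -> VUS2 (e.g. DHH variant in a
  ## suspected androgen-action patient)
  pai <- makePatient(category = "androgen_synthesis_action")
  dhh <- geneRecord(reg, "DHH")
  vus2 <- withPredictions(makeVariant(gene = "DHH"), 4)
  expect_equal(classifyVariant(vus2, dhh, pai, TRUE, th), "VUS2")

  ## AR repeat-tract change -> VUS3 regardless of anything else
  ar <- geneRecord(reg, "AR")
  vus3 <- makeVariant(gene = "AR", consequence = "inframe_indel",
                      in_repeat_tract = TRUE)
  expect_equal(classifyVariant(vus3, ar, pai, TRUE, th), "VUS3")

  ## the stricter 4-of-4 reading is configurable
  th4 <- panelThresholds(minDamagingPredictors = 4)
  expect_equal(classifyVariant(withPredictions(makeVariant(), 3),
                               nr5a1, p, TRUE, th4), "VUS1")
  expect_equal(classifyVariant(withPredictions(makeVariant(), 4),
                               nr5a1, p, TRUE, th4), "likely_pathogenic")
})

test_that("unknown-category patients fit every gene; missing predictions are benign", {
  pu <- makePatient(category = "unknown")
  chd7 <- geneRecord(reg, "CHD7")
  expect_true(phenotypeFit("unknown", chd7))
  expect_false(phenotypeFit("other", chd7))
  ## all predictions missing -> damaging count 0 -> VUS1 under fit
  expect_equal(classifyVariant(makeVariant(gene = "CHD7"), chd7, pu, TRUE, th),
               "VUS1")
})

test_that("patient curation aggregates best classification, diagnosis and oligogenicity", {
  p <- makePatient(category = "gonadal_development")
  v1 <- makeVariant(consequence = "frameshift")            # pathogenic
  v2 <- withPredictions(makeVariant(gene = "CHD7", pos = 2000L), 4)  # VUS2
  out <- curatePatient(p, rbind(v1, v2), NULL, reg, th)
  expect_equal(out$best_classification, "pathogenic")
  expect_true(out$genetic_diagnosis)
  expect_true(out$oligogenic)   # two distinct genes curated

  ## only a VUS: no diagnosis
  out2 <- curatePatient(p, withPredictions(makeVariant(), 1), NULL, reg, th)
  expect_equal(out2$best_classification, "VUS1")
  expect_false(out2$genetic_diagnosis)

  ## nothing passing: best none
  out3 <- curatePatient(p, makeVariant(af_kg1000 = 0.2), NULL, reg, th)
  expect_equal(out3$best_classification, "none")
  expect_false(out3$genetic_diagnosis)
  expect_false(out3$oligogenic)

  ## two variants in the same gene only: not oligogenic
  out4 <- curatePatient(p, rbind(v1, makeVariant(consequence = "frameshift",
                                                 pos = 3000L)),
                        NULL, reg, th)
  expect_false(out4$oligogenic)

  ## determinism: identical input, identical trails
  again <- curatePatient(p, rbind(v1, v2), NULL, reg, th)
  expect_identical(again$results, out$results)
})

test_that("trio-inconsistent variants are removed from curation", {
  p <- makePatient(recruitment = "trio",
                   category = "androgen_synthesis_action")
  ## het HSD17B3 (AR-only) inherited from the father, no second variant
  v <- makeVariant(gene = "HSD17B3", consequence = "frameshift",
                   father_gt = "het", mother_gt = "absent")
  out <- curatePatient(p, v, NULL, reg, th)
  expect_equal(out$results$classification, "filtered_out")
  expect_match(out$results$filter_trail, "inheritance=fail")
})
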
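## Seeded synthetic-data generators: panel reads with planted adapter
## read-through and amplicon dropout, truth/query callset pairs with planted
## sensitivity/FPR, annotated cohorts with known classification outcomes,
## and the published-cohort count fixture.  All generators are deterministic
## given the seed (Mersenne-Twister, explicitly pinned).

#' Default adapter used by the simulators (an arbitrary 33-mer; real
#' platform adapters are not required for correctness testing).
#' @export
defaultAdapter <- function() "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

.setSeed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

.randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## substitute bases at `rate`, never into the same base; N never introduced
.mutate <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate an amplicon panel with reads and planted adapter read-through
#'
#' Builds a random reference, a non-overlapping amplicon design on it, and
#' paired-end reads drawn from the amplicons.  A configurable fraction of
#' read pairs comes from reads longer than their amplicon and therefore
#' runs through into adapter sequence at the amplicon boundary (both
#' mates); the true junction offset is recorded per read.  A fraction of
#' amplicons can be dropped out (zero reads).  Amplicon terminal k-mers are
#' kept unique unless collision testing is requested.
#'
#' @param nAmplicons number of amplicons.
#' @param ampliconLenRange min/max amplicon length (bp); keep the maximum
#'   below `readLen` if read-through must be expressible.
#' @param readLen read length (bp).
#' @param nReadPairs total read pairs.
#' @param readthroughFraction fraction of pairs with adapter read-through.
#' @param substitutionRate per-base substitution error rate.
#' @param dropoutFraction fraction of amplicons emitting zero reads.
#' @param adapter adapter sequence appended after the boundary.
#' @param k terminal k-mer length kept collision-free.
#' @param seed integer seed; fixed seed gives byte-identical outputs.
#' @param outDir directory for reference.fa, design.bed, reads_R1/R2.fastq.
#' @return list with `reference` (DNAStringSet), `design`
#'   (\linkS4class{AmpliconDesign}), file paths, `truth` (read_id, mate,
#'   amplicon, trim_pos -- NA where no read-through), and `dropout` (amplicon
#'   ids planted with zero reads).
#' @export
simulatePanelReads <- function(nAmplicons = 40, ampliconLenRange = c(90, 140),
                               readLen = 150, nReadPairs = 1000,
                               readthroughFraction = 0.5,
                               substitutionRate = 0, dropoutFraction = 0,
                               adapter = defaultAdapter(), k = 12,
                               seed = 1, outDir = tempfile("simreads")) {
  .setSeed(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (readthroughFraction > 0 && min(ampliconLenRange) >= readLen)
    stop("read-through requested but every amplicon is at least as long ",
         "as the reads; shorten the amplicons or lengthen the reads")

  lens <- sample(seq(ampliconLenRange[1L], ampliconLenRange[2L]),
                 nAmplicons, replace = TRUE)
  spacer <- 20L
  ## draw amplicon sequences with unique terminal k-mers
  seen <- character(0)
  seqs <- character(nAmplicons)
  for (i in seq_len(nAmplicons)) {
    repeat {
      s <- .randSeq(lens[i])
      k5 <- substr(s, 1L, k)
      k3 <- as.character(reverseComplement(DNAStringSet(
        substr(s, nchar(s) - k + 1L, nchar(s)))))
      if (!k5 %in% seen && !k3 %in% seen && k5 != k3) {
        seen <- c(seen, k5, k3)
        seqs[i] <- s
        break
      }
    }
  }
  starts <- cumsum(c(1L, head(lens, -1L) + spacer))  # 1-based
  ends <- starts + lens - 1L
  gap <- vapply(seq_len(nAmplicons), function(i) .randSeq(spacer),
                character(1))
  chromSeq <- paste0(paste0(seqs, gap, collapse = ""), collapse = "")
  reference <- DNAStringSet(c(chr1 = chromSeq))

  refPath <- file.path(outDir, "reference.fa")
  writeXStringSet(reference, refPath)
  bedPath <- file.path(outDir, "design.bed")
  ids <- sprintf("amp%03d", seq_len(nAmplicons))
  utils::write.table(
    data.frame("chr1", starts - 1L, ends, ids),
    bedPath, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  design <- loadAmpliconDesign(bedPath)

  nDrop <- round(dropoutFraction * nAmplicons)
  dropped <- if (nDrop) sample(ids, nDrop) else character(0)
  alive <- setdiff(ids, dropped)
  aliveIdx <- match(alive, ids)

  pick <- sample(aliveIdx, nReadPairs, replace = TRUE)
  canRt <- lens[pick] < readLen
  rt <- stats::runif(nReadPairs) < readthroughFraction & canRt

  makeRead <- function(core) {
    if (nchar(core) >= readLen) return(substr(core, 1L, readLen))
    fill <- readLen - nchar(core) - nchar(adapter)
    out <- if (fill > 0)
      paste0(core, adapter, .randSeq(fill))
    else paste0(core, substr(adapter, 1L, readLen - nchar(core)))
    substr(out, 1L, readLen)
  }

  r1 <- character(nReadPairs); r2 <- character(nReadPairs)
  trim1 <- rep(NA_integer_, nReadPairs); trim2 <- trim1
  for (j in seq_len(nReadPairs)) {
    a <- seqs[pick[j]]
    arc <- as.character(reverseComplement(DNAStringSet(a)))
    if (rt[j]) {
      r1[j] <- makeRead(a)
      r2[j] <- makeRead(arc)
      trim1[j] <- nchar(a); trim2[j] <- nchar(a)
    } else {
      r1[j] <- substr(a, 1L, min(readLen, nchar(a)))
      r2[j] <- substr(arc, 1L, min(readLen, nchar(arc)))
    }
  }
  r1 <- .mutate(r1, substitutionRate)
  r2 <- .mutate(r2, substitutionRate)

  readIds <- sprintf("read%05d", seq_len(nReadPairs))
  writeFq <- function(seqsv, path) {
    x <- DNAStringSet(seqsv)
    names(x) <- readIds
    writeXStringSet(x, path, format = "fastq",
                    qualities = BStringSet(strrep("I", nchar(seqsv))))
  }
  fq1 <- file.path(outDir, "reads_R1.fastq")
  fq2 <- file.path(outDir, "reads_R2.fastq")
  writeFq(r1, fq1)
  writeFq(r2, fq2)

  truth <- data.frame(
    read_id = rep(readIds, 2L),
    mate = rep(1:2, each = nReadPairs),
    amplicon = rep(ids[pick], 2L),
    trim_pos = c(trim1, trim2),
    stringsAsFactors = FALSE)

  list(reference = reference, design = design,
       reference_path = refPath, design_path = bedPath,
       fastq_r1 = fq1, fastq_r2 = fq2,
       truth = truth, dropout = dropped)
}

#' Simulate per-sample read starts with planted amplicon dropout
#'
#' Emits, for each sample, a table of read start positions assignable to
#' amplicons, with a planted fraction of amplicon failures.  In
#' "consistent" mode the same amplicons fail in every sample; in "sporadic"
#' mode each failing amplicon fails in exactly one sample.
#'
#' @param design an \linkS4class{AmpliconDesign}.
#' @param nSamples number of samples.
#' @param dropoutFraction fraction of amplicons failing.
#' @param mode "consistent" or "sporadic".
#' @param readsPerAmplicon reads emitted per non-failed amplicon.
#' @param seed integer seed.
#' @return list with `samples` (named list of data.frames chrom/pos) and
#'   `dropout` (data.frame amplicon x sample logical truth).
#' @export
simulateReadStarts <- function(design, nSamples = 3, dropoutFraction = 0.08,
                               mode = c("consistent", "sporadic"),
                               readsPerAmplicon = 20, seed = 1) {
  mode <- match.arg(mode)
  .setSeed(seed)
  amp <- amplicons(design)
  ids <- amp$id
  nDrop <- round(dropoutFraction * length(ids))
  failing <- sample(ids, nDrop)
  failMat <- matrix(FALSE, length(ids), nSamples,
                    dimnames = list(ids, paste0("sample", seq_len(nSamples))))
  if (nDrop) {
    if (mode == "consistent") failMat[failing, ] <- TRUE
    else for (f in failing) failMat[f, sample(nSamples, 1L)] <- TRUE
  }
  samples <- lapply(seq_len(nSamples), function(s) {
    keep <- !failMat[, s]
    idx <- rep(which(keep), each = readsPerAmplicon)
    data.frame(chrom = as.character(seqnames(amp))[idx],
               pos = start(amp)[idx],
               stringsAsFactors = FALSE)
  })
  names(samples) <- colnames(failMat)
  list(samples = samples, dropout = failMat)
}

.writeVcf <- function(df, path, contigLen) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>",
                       unique(df$chrom), contigLen),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(df)) {
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.1f\tPASS\t.",
                       df$chrom, df$pos, df$ref, df$alt, df$qual), con)
  }
  invisible(path)
}

#' Simulate a truth/query callset pair with planted accuracy
#'
#' Generates `nTruth` SNVs as the truth set and a query set containing
#' `round(sensitivity * nTruth)` matching calls plus false positives such
#' that FP / (TP + FP) equals the planted false positive rate after
#' rounding.  Query qualities are drawn so true positives stochastically
#' dominate false positives (TP ~ Normal(100, 10), FP ~ Normal(30, 10)).
#' Optionally both sets carry matching long deletions (>= 10 bp) that a
#' concordance comparison restricted to small INDELs must ignore.
#'
#' @param nTruth number of truth SNVs.
#' @param sensitivity planted sensitivity.
#' @param fpr planted false positive rate (1 - precision).
#' @param nLongIndels number of >= 10 bp deletions added to both sets.
#' @param seed integer seed.
#' @param outDir directory for truth.vcf / query.vcf.
#' @return list with `truth_vcf`, `query_vcf`, `truth`, `query` (call
#'   tables) and `planted` (tp/fp/fn counts).
#' @export
simulateCallsets <- function(nTruth = 1000, sensitivity = 0.97, fpr = 0.02,
                             nLongIndels = 0, seed = 1,
                             outDir = tempfile("simcalls")) {
  .setSeed(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tp <- round(sensitivity * nTruth)
  fp <- if (fpr >= 1) stop("fpr must be < 1") else round(tp * fpr / (1 - fpr))
  if (fpr > 0 && fp == 0)
    stop("planted fpr ", fpr, " is not representable with ", nTruth,
         " truth variants; increase nTruth")

  contigLen <- (nTruth + fp + nLongIndels) * 50L + 1000L
  bases <- c("A", "C", "G", "T")
  allPos <- sample(seq(100L, contigLen - 100L), nTruth + fp + nLongIndels)
  posT <- allPos[seq_len(nTruth)]
  posF <- allPos[nTruth + seq_len(fp)]
  posL <- allPos[nTruth + fp + seq_len(nLongIndels)]

  mkSnv <- function(pos) {
    if (!length(pos))
      return(data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        qual = numeric(0), stringsAsFactors = FALSE))
    ref <- sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                  character(1))
    data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
               qual = NA_real_, stringsAsFactors = FALSE)
  }
  truth <- mkSnv(posT)
  truth$qual <- 100
  matched <- truth[sample(nTruth, tp), , drop = FALSE]
  matched$qual <- pmax(1, round(stats::rnorm(tp, 100, 10), 1))
  false <- mkSnv(posF)
  false$qual <- pmax(1, round(stats::rnorm(fp, 30, 10), 1))
  query <- rbind(matched, false)

  if (nLongIndels > 0) {
    longdel <- data.frame(
      chrom = "chr1", pos = posL,
      ref = vapply(posL, function(p) .randSeq(13L), character(1)),
      alt = NA_character_, qual = 90, stringsAsFactors = FALSE)
    longdel$alt <- substr(longdel$ref, 1L, 1L)
    truth <- rbind(truth, longdel)
    query <- rbind(query, longdel)
  }

  tv <- file.path(outDir, "truth.vcf")
  qv <- file.path(outDir, "query.vcf")
  .writeVcf(truth, tv, contigLen)
  .writeVcf(query, qv, contigLen)
  list(truth_vcf = tv, query_vcf = qv, truth = truth, query = query,
       planted = list(tp = tp, fp = fp, fn = nTruth - tp,
                      sensitivity = tp / nTruth, fpr = fp / (tp + fp)))
}

## gene choices per planted classification, by patient category
.geneForPlant <- function(category, classification) {
  fitGene <- switch(category,
                    gonadal_development = "NR5A1",
                    androgen_synthesis_action = "HSD17B3",
                    other = "ATF3",
                    unknown = "NR5A1")
  switch(classification,
         pathogenic = fitGene,
         likely_pathogenic = switch(category,
                                    gonadal_development = "MAP3K1",
                                    androgen_synthesis_action = "SRD5A2",
                                    other = "RXFP2",
                                    unknown = "MAP3K1"),
         VUS1 = fitGene,
         VUS2 = "CHD7",   # central hypogonadism: fits no patient category
         VUS3 = "AR",
         stop("no gene rule for classification ", classification))
}

#' Simulate an annotated cohort with planted classification outcomes
#'
#' For every row of the plan, generates patients of the given karyotype,
#' phenotype category and recruitment, each carrying one variant engineered
#' so the curation rules classify it exactly as planted: pathogenic (novel
#' frameshift in a loss-of-function gene matching the category), likely
#' pathogenic (novel missense, phenotype fit, 4/4 damaging, consistent
#' inheritance), VUS1 (fit but predicted benign), VUS2 (damaging but in a
#' central-hypogonadism gene outside the patient's phenotype spectrum),
#' VUS3 (androgen-receptor repeat-tract change), or none (only a common
#' distractor variant that the frequency filter removes).  Trio patients
#' carry parental genotypes consistent with the planted model.
#'
#' @param plan data.frame with columns `karyotype` (46XY/46XX), `category`,
#'   `recruitment` (singleton/trio), `classification` (pathogenic,
#'   likely_pathogenic, VUS1, VUS2, VUS3, VUS, none) and `n`.
#' @param registry a \linkS4class{GeneRegistry}.
#' @param seed integer seed.
#' @param distractors add a common (AF 0.30) missense distractor variant to
#'   every patient to exercise the frequency filter.
#' @return list with `patients`, `variants` and `truth` (patient_id,
#'   planted classification).
#' @export
simulateCohort <- function(plan, registry = loadGeneRegistry(), seed = 1,
                           distractors = TRUE) {
  .setSeed(seed)
  need <- c("karyotype", "category", "recruitment", "classification", "n")
  if (!all(need %in% colnames(plan)))
    stop("plan needs columns: ", paste(need, collapse = ", "))
  plan$classification[plan$classification == "VUS"] <- "VUS1"
  badCls <- setdiff(plan$classification,
                    c(.CLASSIFICATIONS[.CLASSIFICATIONS != "filtered_out"],
                      "none"))
  if (length(badCls))
    stop("plan requests unknown classification: ", badCls[1L])
  badCat <- setdiff(plan$category, .PATIENT_CATEGORIES)
  if (length(badCat))
    stop("plan requests unknown category: ", badCat[1L])
  if (any(plan$classification == "VUS2" & plan$category == "unknown"))
    stop("a VUS2 outcome cannot be planted for an unknown-category ",
         "patient: unknown phenotype fits every gene, but VUS2 requires ",
         "a phenotype mismatch")

  patients <- list(); variants <- list(); truth <- list()
  pid <- 0L; vpos <- 1000L
  for (r in seq_len(nrow(plan))) {
    row <- plan[r, ]
    for (j in seq_len(row$n)) {
      pid <- pid + 1L
      id <- sprintf("P%04d", pid)
      patients[[pid]] <- data.frame(
        id = id, karyotype = row$karyotype, category = row$category,
        subtype = row$category, recruitment = row$recruitment,
        stringsAsFactors = FALSE)
      cls <- row$classification
      trio <- identical(row$recruitment, "trio")
      if (cls != "none") {
        vpos <- vpos + 17L
        gene <- .geneForPlant(row$category, cls)
        modes <- sub("_dup$", "", geneRecord(registry, gene)$inheritance)
        gt <- if ("XL" %in% modes && row$karyotype == "46XY") "hemi" else "het"
        fgt <- NA_character_; mgt <- NA_character_
        if (trio) {
          if (gt == "hemi") {              # maternally inherited X-linked
            fgt <- "absent"; mgt <- "het"
          } else if (any(c("AD", "XL") %in% modes)) {
            fgt <- "absent"; mgt <- "absent"   # de novo
          } else {                         # recessive-only gene: homozygote
            gt <- "hom"; fgt <- "het"; mgt <- "het"
          }
        }
        v <- data.frame(
          patient_id = id, chrom = "chr7", pos = vpos,
          ref = "G", alt = "A", gene = gene,
          consequence = switch(cls, pathogenic = "frameshift",
                               VUS3 = "inframe_indel", "missense"),
          af_kg1000 = NA_real_, af_esp = NA_real_,
          af_exac_subpop_max = NA_real_,
          pred_sift = "missing", pred_polyphen2 = "missing",
          pred_lrt = "missing", pred_mutationtaster = "missing",
          reported_status = "unreported",
          genotype = gt, qual = 99, depth = 60,
          in_repeat_tract = cls == "VUS3",
          father_gt = fgt, mother_gt = mgt,
          run_id = "run1", stringsAsFactors = FALSE)
        if (cls %in% c("likely_pathogenic", "VUS2")) {
          v$pred_sift <- v$pred_polyphen2 <- v$pred_lrt <-
            v$pred_mutationtaster <- "damaging"
        } else if (cls == "VUS1") {
          v$pred_sift <- "damaging"
          v$pred_polyphen2 <- v$pred_lrt <- v$pred_mutationtaster <- "benign"
        }
        variants[[length(variants) + 1L]] <- v
      }
      if (distractors) {
        variants[[length(variants) + 1L]] <- data.frame(
          patient_id = id, chrom = "chr7", pos = 500L,
          ref = "T", alt = "C", gene = "WT1",
          consequence = "missense",
          af_kg1000 = 0.30, af_esp = 0.28, af_exac_subpop_max = 0.31,
          pred_sift = "benign", pred_polyphen2 = "benign",
          pred_lrt = "benign", pred_mutationtaster = "benign",
          reported_status = "unreported",
          genotype = "het", qual = 99, depth = 80,
          in_repeat_tract = FALSE,
          father_gt = NA_character_, mother_gt = NA_character_,
          run_id = "run1", stringsAsFactors = FALSE)
      }
      truth[[pid]] <- data.frame(patient_id = id, planted = cls,
                                 stringsAsFactors = FALSE)
    }
  }
  list(patients = do.call(rbind, patients),
       variants = if (length(variants)) do.call(rbind, variants)
       else data.frame(),
       truth = do.call(rbind, truth))
}

## Published cohort arithmetic: per-subtype counts
## (trios, singletons, total, no variant, curated, pathogenic, likely
## pathogenic, VUS) for each karyotype class and phenotype category.
.TABLE2_ROWS <- local({
  r <- function(kar, cat, sub, t, s, tot, none, cur, p, lp, v)
    data.frame(karyotype = kar, category = cat, subtype = sub, trios = t,
               singletons = s, total = tot, no_variant = none, curated = cur,
               pathogenic = p, likely_pathogenic = lp, vus = v,
               stringsAsFactors = FALSE)
  rbind(
    r("46XY", "gonadal_development", "CGD", 3, 21, 24, 11, 13, 6, 7, 0),
    r("46XY", "gonadal_development", "PGD", 2, 19, 21, 13, 8, 2, 4, 2),
    r("46XY", "gonadal_development", "OT", 3, 3, 6, 4, 2, 1, 1, 0),
    r("46XY", "gonadal_development", "GR", 0, 1, 1, 1, 0, 0, 0, 0),
    r("46XY", "androgen_synthesis_action", "DASA", 12, 23, 35, 11, 24, 18, 2, 4),
    r("46XY", "androgen_synthesis_action", "LCH", 0, 1, 1, 0, 1, 0, 1, 0),
    r("46XY", "androgen_synthesis_action", "PMDS", 1, 0, 1, 0, 1, 1, 0, 0),
    r("46XY", "other", "hypospadias", 12, 34, 46, 20, 26, 6, 10, 10),
    r("46XY", "other", "syndromic", 5, 4, 9, 6, 3, 1, 1, 1),
    r("46XY", "other", "diphallus", 0, 1, 1, 1, 0, 0, 0, 0),
    r("46XY", "unknown", "unknown", 25, 108, 133, 52, 81, 41, 16, 24),
    r("46XX", "gonadal_development", "testicular", 2, 14, 16, 8, 8, 8, 0, 0),
    r("46XX", "gonadal_development", "ovotesticular", 2, 5, 7, 6, 1, 0, 0, 1),
    r("46XX", "gonadal_development", "GD", 2, 1, 3, 3, 0, 0, 0, 0),
    r("46XX", "other", "MRKH", 0, 9, 9, 9, 0, 0, 0, 0),
    r("46XX", "other", "dysplastic_ovaries", 1, 0, 1, 1, 0, 0, 0, 0),
    r("46XX", "other", "syndromic", 1, 1, 2, 2, 0, 0, 0, 0),
    r("46XX", "unknown", "unknown", 4, 6, 10, 10, 0, 0, 0, 0))
})

#' Reference-cohort fixture
#'
#' Deterministically encodes the published DSD cohort arithmetic: one
#' patient row per individual (278 with 46,XY DSD, 48 with 46,XX DSD) with
#' karyotype class, phenotype category, clinical subtype and recruitment
#' mode, and a best classification per patient reproducing the printed
#' per-subtype counts of pathogenic, likely pathogenic and VUS outcomes.
#'
#' @param outDir optional directory; when given, `patients.tsv` and
#'   `curation.tsv` are written.
#' @return list with `patients` (including `best_classification`, ready for
#'   [summarizeCohort()]) and `rows` (the encoded per-subtype counts).
#' @export
table2Fixture <- function(outDir = NULL) {
  rows <- .TABLE2_ROWS
  patients <- list()
  pid <- 0L
  for (r in seq_len(nrow(rows))) {
    x <- rows[r, ]
    stopifnot(x$trios + x$singletons == x$total,
              x$no_variant + x$curated == x$total,
              x$pathogenic + x$likely_pathogenic + x$vus == x$curated)
    cls <- c(rep("pathogenic", x$pathogenic),
             rep("likely_pathogenic", x$likely_pathogenic),
             rep("VUS1", x$vus),
             rep("none", x$no_variant))
    recruit <- c(rep("trio", x$trios), rep("singleton", x$singletons))
    for (j in seq_len(x$total)) {
      pid <- pid + 1L
      patients[[pid]] <- data.frame(
        id = sprintf("T2_%04d", pid), karyotype = x$karyotype,
        category = x$category, subtype = x$subtype,
        recruitment = recruit[j], best_classification = cls[j],
        stringsAsFactors = FALSE)
    }
  }
  patients <- do.call(rbind, patients)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(patients[, setdiff(colnames(patients),
                                          "best_classification")],
                       file.path(outDir, "patients.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(patients[, c("id", "best_classification")],
                       file.path(outDir, "curation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(patients = patients, rows = rows)
}

#' Simulate a deduplicatable cohort variant-observation table
#'
#' Synthetic stand-in for a cohort-wide list of curated variant
#' observations: `nUnique` distinct variants spread over `nGenes` genes, of
#' which `nRecurrent` recur in more than one patient, padding the table to
#' `nObservations` rows.  Used to exercise the unique-variant tally.
#'
#' @param nUnique distinct variants.
#' @param nGenes distinct genes (sampled from the registry).
#' @param nRecurrent variants observed in more than one patient.
#' @param nObservations total observation rows (>= nUnique + nRecurrent).
#' @param registry a \linkS4class{GeneRegistry}.
#' @param seed integer seed.
#' @return data.frame with one row per observation: `key`, `gene`,
#'   `consequence`, `reported_status`, `classification`.
#' @export
simulateVariantObservations <- function(nUnique = 151, nGenes = 28,
                                        nRecurrent = 22,
                                        nObservations = 187,
                                        registry = loadGeneRegistry(),
                                        seed = 1) {
  .setSeed(seed)
  stopifnot(nObservations >= nUnique + nRecurrent,
            nUnique >= nGenes, nRecurrent <= nUnique)
  genes <- sample(geneSymbols(registry), nGenes)
  ## every gene gets at least one variant
  geneOf <- c(genes, sample(genes, nUnique - nGenes, replace = TRUE))
  key <- sprintf("chr1:%d:G:A", seq(1000L, by = 29L, length.out = nUnique))
  cons <- sample(c("missense", "frameshift", "stop_gain", "splice_site",
                   "inframe_indel"), nUnique, replace = TRUE,
                 prob = c(0.6, 0.15, 0.1, 0.1, 0.05))
  rep_status <- sample(c("reported_same_phenotype", "unreported"),
                       nUnique, replace = TRUE, prob = c(0.38, 0.62))
  uniq <- data.frame(key = key, gene = geneOf, consequence = cons,
                     reported_status = rep_status,
                     classification = "VUS1", stringsAsFactors = FALSE)
  recIdx <- sample(nUnique, nRecurrent)
  nExtra <- nObservations - nUnique
  extra <- uniq[c(recIdx, sample(recIdx, nExtra - nRecurrent,
                                 replace = TRUE)), , drop = FALSE]
  out <- rbind(uniq, extra)
  rownames(out) <- NULL
  out
}
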
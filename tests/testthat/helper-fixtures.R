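## Shared fixture builders: everything is generated in code at test time.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## Write a BED file from vectors; returns the path.
makeBed <- function(chrom, start, end, name = NULL, path = tempfile(fileext = ".bed")) {
  df <- if (is.null(name)) data.frame(chrom, start, end)
  else data.frame(chrom, start, end, name)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

## Minimal coordinate-sorted SAM with simple fully-aligned reads.
## reads: data.frame(id, chrom, pos, len) -- cigar is <len>M.
makeSam <- function(reads, chromLens = c(chr1 = 100000L),
                    path = tempfile(fileext = ".sam"),
                    unmapped = 0L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chromLens), chromLens))
  body <- character(0)
  if (nrow(reads)) {
    reads <- reads[order(reads$chrom, reads$pos), ]
    body <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                    reads$id, reads$chrom, reads$pos, reads$len,
                    strrep("A", reads$len), strrep("I", reads$len))
  }
  if (unmapped > 0L)
    body <- c(body, sprintf("u%d\t4\t*\t0\t0\t*\t*\t0\t0\tAAAA\tIIII",
                            seq_len(unmapped)))
  writeLines(c(hdr, body), path)
  path
}

## A small panel: reference + design with ampliconLen < readLen so that
## read-through is expressible.
makeToyPanel <- function(nAmplicons = 10, seed = 42) {
  simulatePanelReads(nAmplicons = nAmplicons, ampliconLenRange = c(90, 120),
                     readLen = 150, nReadPairs = 50,
                     readthroughFraction = 0.5, seed = seed)
}

## One-row annotated variant with sane defaults, overridable by name.
makeVariant <- function(...) {
  v <- data.frame(
    patient_id = "P1", chrom = "chr9", pos = 1000L, ref = "G", alt = "A",
    gene = "NR5A1", consequence = "missense",
    af_kg1000 = NA_real_, af_esp = NA_real_, af_exac_subpop_max = NA_real_,
    pred_sift = "missing", pred_polyphen2 = "missing", pred_lrt = "missing",
    pred_mutationtaster = "missing",
    reported_status = "unreported", genotype = "het",
    qual = 99, depth = 50, in_repeat_tract = FALSE,
    father_gt = NA_character_, mother_gt = NA_character_,
    run_id = "run1", stringsAsFactors = FALSE)
  ov <- list(...)
  for (nm in names(ov)) v[[nm]] <- ov[[nm]]
  v
}

makePatient <- function(id = "P1", karyotype = "46XY",
                        category = "gonadal_development",
                        recruitment = "singleton") {
  data.frame(id = id, karyotype = karyotype, category = category,
             subtype = category, recruitment = recruitment,
             stringsAsFactors = FALSE)
}

## Set all four predictor columns at once.
withPredictions <- function(v, damaging = 0L) {
  cols <- c("pred_sift", "pred_polyphen2", "pred_lrt", "pred_mutationtaster")
  v[cols] <- "benign"
  if (damaging > 0) v[cols[seq_len(damaging)]] <- "damaging"
  v
}
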
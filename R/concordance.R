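#' Read a VCF into a plain call table
#'
#' Light front-end over the VCF text format returning the columns the
#' concordance comparison needs.  Multi-allelic records are split into one
#' row per alternate allele.
#'
#' @param path VCF path (plain or bgzip).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `qual`.
#' @export
readVcfCalls <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (!length(rr))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      qual = numeric(0)))
  data.frame(
    chrom = as.character(seqnames(rr)),
    pos = start(rr),
    ref = toupper(as.character(rr$REF)),
    alt = toupper(as.character(rr$ALT)),
    qual = if (is.null(rr$QUAL)) NA_real_ else as.numeric(rr$QUAL),
    stringsAsFactors = FALSE)
}

#' Normalize variant representations
#'
#' Splits multi-allelic rows, removes ref==alt no-ops, trims shared
#' leading/trailing context (keeping at least one base of each allele), and
#' left-aligns INDELs against the reference when one is supplied.  The
#' result carries the variant type and INDEL length change.
#'
#' @param calls data.frame with `chrom`, `pos` (1-based), `ref`, `alt` and
#'   optionally `qual`.
#' @param reference optional named `DNAStringSet` used for left alignment
#'   and reference-consistency checking.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `qual`, `type`
#'   (SNV/INDEL), `indel_len`, and `key` (chrom:pos:ref:alt).
#' @examples
#' normalizeVariants(data.frame(chrom = "chr1", pos = 100,
#'                              ref = "CT", alt = "CA"))  # SNV at 101 T>A
#' @export
normalizeVariants <- function(calls, reference = NULL) {
  if (!nrow(calls)) {
    calls$type <- character(0); calls$indel_len <- integer(0)
    calls$key <- character(0)
    return(calls)
  }
  if (is.null(calls$qual)) calls$qual <- NA_real_
  alts <- strsplit(as.character(calls$alt), ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(calls)), lengths(alts))
  calls <- calls[idx, , drop = FALSE]
  calls$alt <- unlist(alts)
  calls$ref <- toupper(calls$ref); calls$alt <- toupper(calls$alt)
  calls <- calls[calls$ref != calls$alt, , drop = FALSE]

  n <- nrow(calls)
  pos <- as.integer(calls$pos); ref <- calls$ref; alt <- calls$alt
  lastChar <- function(x) substr(x, nchar(x), nchar(x))
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    chromSeq <- if (!is.null(reference))
      reference[[as.character(calls$chrom[i])]]
    if (!is.null(chromSeq) &&
        as.character(Biostrings::subseq(chromSeq, p, p + nchar(r) - 1L)) != r)
      stop("REF allele inconsistent with reference at ",
           calls$chrom[i], ":", p)
    ## canonical normalization: strip shared trailing bases, extending left
    ## from the reference when an allele would empty; then strip shared
    ## leading bases
    repeat {
      if (lastChar(r) == lastChar(a)) {
        if (nchar(r) > 1L && nchar(a) > 1L) {
          r <- substr(r, 1L, nchar(r) - 1L)
          a <- substr(a, 1L, nchar(a) - 1L)
        } else if (!is.null(chromSeq) && p > 1L) {
          ## stripping would empty an allele: extend left from the reference
          prev <- as.character(Biostrings::subseq(chromSeq, p - 1L, p - 1L))
          r <- paste0(prev, substr(r, 1L, nchar(r) - 1L))
          a <- paste0(prev, substr(a, 1L, nchar(a) - 1L))
          p <- p - 1L
        } else break
      } else if (nchar(r) > 1L && nchar(a) > 1L &&
                 substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
        r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
        p <- p + 1L
      } else break
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  out <- data.frame(chrom = as.character(calls$chrom), pos = pos,
                    ref = ref, alt = alt, qual = calls$qual,
                    stringsAsFactors = FALSE)
  out$indel_len <- abs(nchar(out$alt) - nchar(out$ref))
  out$type <- ifelse(out$indel_len == 0L & nchar(out$ref) == 1L, "SNV",
                     ifelse(out$indel_len > 0L, "INDEL", "MNV"))
  out$key <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
  rownames(out) <- NULL
  out
}

#' Compare a query callset against a truth set
#'
#' Allele-level concordance of normalized variants: a query call is a true
#' positive iff an identical (chrom, pos, ref, alt) record exists in the
#' truth set.  INDELs with a length change of `indelMaxLen` (default 10 bp)
#' or more are excluded from both sides before counting, and the comparison
#' can be restricted to confident regions.  Genotype agreement is not
#' required.
#'
#' @param truth,query VCF paths or call data.frames (see [readVcfCalls()]).
#' @param regions optional GRanges restricting the comparison.
#' @param thresholds a \linkS4class{PanelThresholds} (uses `indelMaxLen`).
#' @param reference optional reference for normalization.
#' @return a \linkS4class{ConcordanceResult} with TP/FN/FP counts,
#'   sensitivity, false positive rate (1 - precision) and a quality-swept
#'   ROC table.
#' @export
matchCallsets <- function(truth, query, regions = NULL,
                          thresholds = panelThresholds(), reference = NULL) {
  toCalls <- function(x) {
    if (is.character(x)) x <- readVcfCalls(x)
    normalizeVariants(x, reference)
  }
  tr <- toCalls(truth)
  qr <- toCalls(query)
  tr <- tr[tr$indel_len < thresholds@indelMaxLen, , drop = FALSE]
  qr <- qr[qr$indel_len < thresholds@indelMaxLen, , drop = FALSE]
  if (!is.null(regions)) {
    inRegions <- function(df) {
      gr <- GenomicRanges::GRanges(df$chrom, IRanges(df$pos, df$pos))
      IRanges::overlapsAny(gr, regions, ignore.strand = TRUE)
    }
    tr <- tr[inRegions(tr), , drop = FALSE]
    qr <- qr[inRegions(qr), , drop = FALSE]
  }
  if (anyDuplicated(tr$key))
    stop("truth set contains duplicate variants after normalization: ",
         tr$key[duplicated(tr$key)][1L])
  qr <- qr[!duplicated(qr$key), , drop = FALSE]

  isTp <- qr$key %in% tr$key
  tp <- sum(isTp)
  fp <- sum(!isTp)
  fn <- nrow(tr) - tp
  roc <- rocPoints(isTp, qr$qual, nTruth = nrow(tr))
  new("ConcordanceResult", tp = as.integer(tp), fn = as.integer(fn),
      fp = as.integer(fp),
      sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
      falsePositiveRate = if (tp + fp) fp / (tp + fp) else NA_real_,
      roc = roc)
}

#' ROC points from matched calls
#'
#' Sweeps the observed query quality scores (descending) and recomputes
#' sensitivity and false positive rate over the query calls at or above
#' each threshold.
#'
#' @param isTp logical vector: query call matches truth.
#' @param qual query quality scores (same length).
#' @param nTruth number of truth variants (fixes the sensitivity
#'   denominator).
#' @return data.frame with `threshold`, `tp`, `fp`, `sensitivity`, `fpr`.
#'   With no usable quality scores a single point over all calls is
#'   returned (threshold NA).
#' @export
rocPoints <- function(isTp, qual, nTruth) {
  if (length(isTp) == 0L)
    return(data.frame(threshold = NA_real_, tp = 0L, fp = 0L,
                      sensitivity = 0, fpr = NA_real_))
  if (all(is.na(qual))) {
    tp <- sum(isTp); fp <- sum(!isTp)
    return(data.frame(threshold = NA_real_, tp = tp, fp = fp,
                      sensitivity = if (nTruth) tp / nTruth else NA_real_,
                      fpr = if (tp + fp) fp / (tp + fp) else NA_real_))
  }
  qual[is.na(qual)] <- -Inf   # calls without qual only enter at the bottom
  th <- sort(unique(qual), decreasing = TRUE)
  rows <- lapply(th, function(t) {
    sel <- qual >= t
    tp <- sum(isTp & sel); fp <- sum(!isTp & sel)
    data.frame(threshold = t, tp = tp, fp = fp,
               sensitivity = if (nTruth) tp / nTruth else NA_real_,
               fpr = if (tp + fp) fp / (tp + fp) else NA_real_)
  })
  do.call(rbind, rows)
}
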
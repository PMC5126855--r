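#' @importFrom Rsamtools BamFile ScanBamParam scanBamFlag PileupParam pileup
#'   asBam countBam
#' @importFrom GenomicAlignments readGAlignments grglist
#' @importFrom IRanges IRanges
NULL

## Accept a BAM path, a SAM path (converted on the fly), or a BamFile.
.asBamFile <- function(x) {
  if (is(x, "BamFile")) return(x)
  stopifnot(is.character(x), file.exists(x))
  if (grepl("\\.sam$", x, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- asBam(x, dest, overwrite = TRUE, indexDestination = TRUE)
    return(BamFile(bam))
  }
  bf <- BamFile(x)
  if (!file.exists(paste0(x, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", x))) {
    sorted <- tryCatch(
      Rsamtools::sortBam(x, tempfile()),
      error = function(e) stop("BAM must be coordinate-sorted ",
                               "(samtools sort): ", conditionMessage(e)))
    Rsamtools::indexBam(sorted)
    bf <- BamFile(sorted)
  }
  bf
}

#' Per-base depth over target regions
#'
#' Computes the depth of every targeted base from a coordinate-sorted
#' SAM/BAM (via a pileup; every primary aligned base counts once, no
#' deduplication and no quality filtering) or from a 3-column per-base
#' depth table.  Targeted bases with no aligned reads get depth 0.
#'
#' @param alignments SAM/BAM path, `BamFile`, a data.frame with columns
#'   `chrom`, `pos` (1-based), `depth`, or a TSV path to such a table.
#' @param targets GRanges of target regions (or an
#'   \linkS4class{AmpliconDesign}, whose targets are used).
#' @return a \linkS4class{DepthTrack}.
#' @export
depthFromAlignments <- function(alignments, targets) {
  if (is(targets, "AmpliconDesign")) targets <- targetRegions(targets)
  if (!length(targets)) stop("no target regions supplied")
  targets <- GenomicRanges::reduce(GenomicRanges::sort(targets),
                                   ignore.strand = TRUE)
  tpos <- .targetPositions(targets)

  if (is.character(alignments) && length(alignments) == 1L &&
      grepl("\\.(tsv|txt|bed\\.depth|depth)$", alignments, ignore.case = TRUE)) {
    alignments <- utils::read.delim(alignments, header = TRUE,
                                    stringsAsFactors = FALSE)
  }
  if (is.data.frame(alignments)) {
    need <- c("chrom", "pos", "depth")
    if (!all(need %in% colnames(alignments)))
      stop("depth table needs columns chrom, pos, depth")
    key <- paste(alignments$chrom, alignments$pos)
    m <- match(key, paste(tpos$chrom, tpos$pos))
    if (anyNA(m)) {
      warning(sum(is.na(m)), " depth-table position(s) outside the targets ",
              "were ignored")
    }
    depth <- integer(nrow(tpos))
    depth[m[!is.na(m)]] <- as.integer(alignments$depth[!is.na(m)])
  } else {
    bf <- .asBamFile(alignments)
    pp <- PileupParam(max_depth = 10000000L, min_base_quality = 0L,
                      min_mapq = 0L, min_nucleotide_depth = 1L,
                      distinguish_strands = FALSE,
                      distinguish_nucleotides = FALSE,
                      include_deletions = FALSE, include_insertions = FALSE)
    res <- pileup(bf, scanBamParam = ScanBamParam(which = targets),
                  pileupParam = pp)
    depth <- integer(nrow(tpos))
    if (nrow(res)) {
      ## `which` labels can duplicate positions if targets overlapped;
      ## targets were reduced above so each position appears once.
      m <- match(paste(res$seqnames, res$pos), paste(tpos$chrom, tpos$pos))
      keep <- !is.na(m)
      depth[m[keep]] <- depth[m[keep]] + res$count[keep]
    }
  }
  pos <- GenomicRanges::GRanges(tpos$chrom, IRanges(tpos$pos, tpos$pos))
  new("DepthTrack", positions = pos, depth = depth, targets = targets)
}

.targetPositions <- function(targets) {
  chrom <- rep(as.character(seqnames(targets)), width(targets))
  pos <- unlist(mapply(seq, start(targets), end(targets), SIMPLIFY = FALSE),
                use.names = FALSE)
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Cumulative coverage distribution
#'
#' Fraction of targeted bases covered at or above each threshold, as in the
#' usual panel coverage plot (the vertical axis of a cumulative depth
#' distribution).
#'
#' @param track a \linkS4class{DepthTrack}.
#' @param thresholds ascending coverage thresholds.
#' @return list with `thresholds`, `fraction_at_least` (monotone
#'   non-increasing), `mean` and `median` depth.  The median over an even
#'   number of bases is the lower of the two central values.
#' @export
coverageCdf <- function(track, thresholds = c(0, 1, 10, 20, 30, 50, 100, 200)) {
  d <- depthValues(track)
  if (!length(d)) stop("empty depth track")
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  frac <- vapply(thresholds, function(t) mean(d >= t), numeric(1))
  s <- sort(d)
  med <- s[floor((length(s) + 1) / 2)]
  list(thresholds = thresholds, fraction_at_least = frac,
       mean = mean(d), median = med)
}

#' Coverage uniformity
#'
#' Fraction of targeted bases with depth at least `factor` times the mean
#' depth -- the standard evenness measure used to compare capture
#' technologies (at `factor = 0.5`: fraction of bases with at least half
#' the mean coverage).
#'
#' @param track a \linkS4class{DepthTrack}.
#' @param factor fraction of the mean depth (default 0.5).
#' @return a fraction in \\[0, 1].
#' @export
uniformity <- function(track, factor = 0.5) {
  d <- depthValues(track)
  if (!length(d) || mean(d) <= 0) stop("uniformity undefined on an all-zero track")
  mean(d >= factor * mean(d))
}

#' Targeting efficiency at read and base level
#'
#' Read-level: fraction of all reads (unmapped reads count in the
#' denominator) overlapping any target by at least 1 bp.  Base-level:
#' fraction of aligned (M/=/X) bases falling inside the targets; soft-clipped
#' bases are not counted as aligned.
#'
#' @param alignments SAM/BAM path or `BamFile`.
#' @param targets GRanges of target regions or an
#'   \linkS4class{AmpliconDesign}.
#' @return list with `read_level` and `base_level` fractions.
#' @export
targetingEfficiency <- function(alignments, targets) {
  if (is(targets, "AmpliconDesign")) targets <- targetRegions(targets)
  targets <- GenomicRanges::reduce(targets, ignore.strand = TRUE)
  bf <- .asBamFile(alignments)
  total <- countBam(bf, param = ScanBamParam(
    flag = scanBamFlag(isSecondaryAlignment = FALSE,
                       isSupplementaryAlignment = FALSE)))$records
  galn <- readGAlignments(bf)
  nOverlap <- sum(GenomicRanges::countOverlaps(
    galn, targets, minoverlap = 1L, ignore.strand = TRUE) > 0)
  blocks <- unlist(grglist(galn, drop.D.ranges = TRUE), use.names = FALSE)
  alignedBases <- sum(width(blocks))
  ov <- GenomicRanges::findOverlaps(blocks, targets, ignore.strand = TRUE)
  inTarget <- sum(width(GenomicRanges::pintersect(
    blocks[S4Vectors::queryHits(ov)], targets[S4Vectors::subjectHits(ov)])))
  list(read_level = if (total) nOverlap / total else NA_real_,
       base_level = if (alignedBases) inTarget / alignedBases else NA_real_)
}

#' Amplicon failure report across samples
#'
#' Assigns each read to the amplicon whose interval contains the read start
#' (leftmost aligned position; ties broken by the leftmost amplicon), counts
#' reads per amplicon per sample, and classifies every amplicon's failure
#' consistency: `consistent` (zero reads in all samples), `sporadic` (zero
#' reads in exactly one sample), `intermediate` (otherwise), or `none`.
#'
#' @param alignmentsPerSample named list; each element a SAM/BAM path, a
#'   `BamFile`, or a data.frame of read starts with columns `chrom`, `pos`.
#' @param design an \linkS4class{AmpliconDesign}.
#' @return list with `counts` (amplicon x sample matrix), `failed`
#'   (logical matrix), and `consistency` (named character vector).
#' @export
ampliconFailureReport <- function(alignmentsPerSample, design) {
  amp <- amplicons(design)
  amp <- amp[order(as.character(seqnames(amp)), start(amp))]
  if (!length(amp)) stop("design contains no amplicons")
  if (!length(alignmentsPerSample)) stop("at least one sample is required")
  if (is.null(names(alignmentsPerSample)))
    names(alignmentsPerSample) <- paste0("sample", seq_along(alignmentsPerSample))

  assignCounts <- function(x) {
    if (is.data.frame(x)) {
      starts <- GenomicRanges::GRanges(x$chrom, IRanges(x$pos, x$pos))
    } else {
      galn <- readGAlignments(.asBamFile(x))
      starts <- GenomicRanges::GRanges(seqnames(galn),
                                       IRanges(start(galn), start(galn)))
    }
    ov <- GenomicRanges::findOverlaps(starts, amp, ignore.strand = TRUE,
                                      select = "first")  # amplicons sorted
    tabulate(ov[!is.na(ov)], nbins = length(amp))
  }

  counts <- vapply(alignmentsPerSample, assignCounts,
                   integer(length(amp)))
  counts <- matrix(counts, nrow = length(amp),
                   dimnames = list(amp$id, names(alignmentsPerSample)))
  failed <- counts == 0L
  nFail <- rowSums(failed)
  nSamp <- ncol(failed)
  consistency <- ifelse(nFail == 0L, "none",
                 ifelse(nFail == nSamp, "consistent",
                 ifelse(nFail == 1L, "sporadic", "intermediate")))
  names(consistency) <- amp$id
  list(counts = counts, failed = failed, consistency = consistency)
}

#' Per-gene diagnostic coverage report
#'
#' For each registry gene with targeted bases inside its locus, the fraction
#' of those bases covered at or above `depthThreshold`.  Genes without
#' targeted bases are flagged (`no_target = TRUE`, fraction NA) rather than
#' silently reported as 0.
#'
#' @param track a \linkS4class{DepthTrack}.
#' @param registry a \linkS4class{GeneRegistry}.
#' @param locusMap GRanges named by gene symbol.
#' @param depthThreshold coverage threshold (default 20x).
#' @param lowCoverageCutoff genes with fraction below this are flagged low.
#' @return data.frame with one row per registry gene present in `locusMap`:
#'   `gene`, `targeted_bases`, `fraction_at_threshold`, `no_target`,
#'   `flagged_low`.
#' @export
geneCoverageReport <- function(track, registry, locusMap,
                               depthThreshold = 20, lowCoverageCutoff = 0.9) {
  genes <- intersect(geneSymbols(registry), names(locusMap))
  pos <- track@positions
  d <- depthValues(track)
  res <- lapply(genes, function(g) {
    ov <- suppressWarnings(
      IRanges::overlapsAny(pos, locusMap[names(locusMap) == g],
                           ignore.strand = TRUE))
    nb <- sum(ov)
    frac <- if (nb) mean(d[ov] >= depthThreshold) else NA_real_
    data.frame(gene = g, targeted_bases = nb,
               fraction_at_threshold = frac,
               no_target = nb == 0L,
               flagged_low = !is.na(frac) && frac < lowCoverageCutoff)
  })
  do.call(rbind, res)
}
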
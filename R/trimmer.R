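#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   BStringSet subseq reverseComplement
NULL

## Hamming distance between equal-length strings, vectorised over pairs.
## N (or any non-matching byte) counts as a mismatch.
.mismatches <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

#' Build a boundary index for adapter read-through trimming
#'
#' Amplicon-based (circularisation) libraries produce reads that always
#' start exactly at an amplicon terminus.  When the read is longer than the
#' amplicon it runs through into adapter sequence at a predictable offset:
#' the amplicon length.  This indexes, for every amplicon, the k-mer a read
#' will start with in read-1 orientation (the first k reference bases) and
#' in read-2 orientation (reverse complement of the last k bases), together
#' with the amplicon length, so the expected adapter junction is computable
#' from a read prefix match alone.
#'
#' @param design an \linkS4class{AmpliconDesign}.
#' @param reference a named `DNAStringSet` or path to a FASTA file covering
#'   every amplicon.
#' @param adapter adapter sequence expected after the boundary.
#' @param k junction key length in bp (>= 8).
#' @return a \linkS4class{BoundaryIndex}.  k-mers shared by several amplicon
#'   termini keep all candidates.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 50),
#'                                                collapse = "")))
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t120\tamp1", bed)
#' idx <- buildBoundaryIndex(loadAmpliconDesign(bed), ref,
#'                           adapter = "CTGTCTCTTATACACATCT")
#' @export
buildBoundaryIndex <- function(design, reference, adapter, k = 12L) {
  stopifnot(nzchar(adapter))
  k <- as.integer(k)
  if (is.character(reference))
    reference <- readDNAStringSet(reference)
  names(reference) <- sub("\\s.*", "", names(reference))
  amp <- amplicons(design)
  if (!length(amp)) stop("design contains no amplicons")
  if (any(width(amp) < k))
    stop("k (", k, ") exceeds the shortest amplicon length (",
         min(width(amp)), ")")
  chr <- as.character(seqnames(amp))
  missing <- setdiff(chr, names(reference))
  if (length(missing))
    stop("amplicon chromosome(s) absent from reference: ",
         paste(missing, collapse = ", "))
  outside <- end(amp) > Biostrings::width(reference)[match(chr, names(reference))]
  if (any(outside))
    stop("amplicon(s) outside the reference: ",
         paste(amp$id[outside], collapse = ", "))
  seqs <- as.character(subseq(reference[chr], start = start(amp),
                              end = end(amp)))
  five <- substr(seqs, 1L, k)
  three <- as.character(reverseComplement(
    DNAStringSet(substr(seqs, nchar(seqs) - k + 1L, nchar(seqs)))))
  entries <- data.frame(
    kmer = c(five, three),
    amplicon = rep(amp$id, 2L),
    terminus = rep(c("5p", "3p"), each = length(amp)),
    len = rep(width(amp), 2L),
    stringsAsFactors = FALSE)
  new("BoundaryIndex", k = k, adapter = toupper(adapter), entries = entries)
}

## Core matcher: for a character vector of read sequences, decide per read.
## Returns data.frame(action, trim_pos, amplicon).  trim_pos is the 0-based
## offset where adapter begins (== number of bases kept).
.trimDecisions <- function(seqs, index, maxMismatch = 1L,
                           adapterSpan = 10L) {
  k <- index@k
  entries <- index@entries
  adapter <- index@adapter
  n <- length(seqs)
  action <- rep("unassigned", n)
  trim_pos <- rep(NA_integer_, n)
  amplicon <- rep(NA_character_, n)

  long_enough <- nchar(seqs) >= k
  prefix <- substr(seqs, 1L, k)

  ## candidate lists: exact hash hit first, mismatch scan as fallback
  exact <- match(prefix, entries$kmer)   # first hit; collisions handled below
  kmerGroups <- split(seq_len(nrow(entries)), entries$kmer)

  adapterOk <- function(seq, L) {
    overhang <- nchar(seq) - L
    span <- min(adapterSpan, overhang, nchar(adapter))
    obs <- substr(seq, L + 1L, L + span)
    .mismatches(obs, substr(adapter, 1L, span)) <= maxMismatch
  }

  for (i in seq_len(n)) {
    if (!long_enough[i]) next
    cand <- integer(0)
    if (!is.na(exact[i])) {
      cand <- kmerGroups[[prefix[i]]]
    } else if (maxMismatch > 0L) {
      mm <- .mismatches(rep(prefix[i], nrow(entries)), entries$kmer)
      cand <- which(mm <= maxMismatch)
    }
    if (!length(cand)) next
    lens <- unique(entries$len[cand])
    rl <- nchar(seqs[i])
    ## lengths at which an adapter-consistent junction is observed
    consistent <- lens[lens < rl & vapply(lens, function(L)
      adapterOk(seqs[i], L), logical(1))]
    if (length(consistent) == 1L) {
      L <- consistent
      action[i] <- "trimmed"
      trim_pos[i] <- L
      amplicon[i] <- entries$amplicon[cand[match(L, entries$len[cand])]]
    } else if (length(consistent) > 1L) {
      ## ambiguous junction evidence: never trim on ambiguity
      action[i] <- "unassigned"
    } else {
      action[i] <- "untrimmed"
      amplicon[i] <- entries$amplicon[cand[1L]]
    }
  }
  data.frame(action = action, trim_pos = trim_pos, amplicon = amplicon,
             stringsAsFactors = FALSE)
}

#' Trim a single read at its amplicon boundary
#'
#' @param seq read sequence (character).
#' @param qual quality string of the same length (optional).
#' @param index a \linkS4class{BoundaryIndex}.
#' @param maxMismatch mismatches tolerated in the boundary k-mer and in the
#'   adapter comparison (N counts as a mismatch).
#' @param adapterSpan maximum number of adapter bases compared beyond the
#'   junction (the comparison uses `min(adapterSpan, overhang)` bases).
#' @return list with `seq`, `qual` (trimmed in lockstep) and `decision`, a
#'   one-row data.frame with `action` (trimmed / untrimmed / unassigned),
#'   `trim_pos` (0-based offset where adapter began; NA unless trimmed) and
#'   `amplicon`.
#' @export
trimRead <- function(seq, qual = NULL, index, maxMismatch = 1L,
                     adapterSpan = 10L) {
  dec <- .trimDecisions(seq, index, maxMismatch, adapterSpan)
  if (dec$action == "trimmed") {
    seq <- substr(seq, 1L, dec$trim_pos)
    if (!is.null(qual)) qual <- substr(qual, 1L, dec$trim_pos)
  }
  list(seq = seq, qual = qual, decision = dec)
}

#' Trim paired FASTQ files of adapter read-through
#'
#' Each mate is matched independently against the boundary index (read 1
#' against 5' termini, read 2 against 3' termini -- both orientations are in
#' the same index).  Output reads are always prefixes of the input reads;
#' qualities are trimmed in lockstep.
#'
#' @param r1,r2 input FASTQ paths (gzip-aware; `r2` may be NULL for
#'   single-end input).
#' @param index a \linkS4class{BoundaryIndex}.
#' @param out1,out2 output FASTQ paths.
#' @param maxMismatch,adapterSpan see [trimRead()].
#' @param truth optional data.frame(`read_id`, `trim_pos`) of planted
#'   junction offsets (NA = no read-through); when supplied the fraction of
#'   reads trimmed at exactly the true position is reported.
#' @return a list (`TrimStats`): `reads_total`, `reads_trimmed`,
#'   `reads_unassigned`, `correctly_trimmed_fraction` (NA without truth),
#'   and `decisions`, the per-read decision table.
#' @export
trimFastq <- function(r1, r2 = NULL, index, out1, out2 = NULL,
                      maxMismatch = 1L, adapterSpan = 10L, truth = NULL) {
  s1 <- readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  s2 <- if (!is.null(r2))
    readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (!is.null(s2)) {
    id1 <- sub("\\s.*", "", names(s1))
    id2 <- sub("\\s.*", "", names(s2))
    if (length(id1) != length(id2) || any(id1 != id2)) {
      bad <- if (length(id1) != length(id2)) min(length(id1), length(id2)) + 1L
             else which(id1 != id2)[1L]
      stop("mate id mismatch at record ", bad)
    }
  }

  processOne <- function(ss, out, mate) {
    seqs <- as.character(ss)
    quals <- as.character(S4Vectors::mcols(ss)$qualities)
    dec <- .trimDecisions(seqs, index, maxMismatch, adapterSpan)
    tr <- dec$action == "trimmed"
    seqs[tr] <- substr(seqs[tr], 1L, dec$trim_pos[tr])
    quals[tr] <- substr(quals[tr], 1L, dec$trim_pos[tr])
    outset <- DNAStringSet(seqs)
    names(outset) <- names(ss)
    writeXStringSet(outset, out, format = "fastq",
                    qualities = BStringSet(quals))
    dec$read_id <- sub("\\s.*", "", names(ss))
    dec$mate <- mate
    dec
  }

  dec1 <- processOne(s1, out1, 1L)
  decisions <- dec1
  if (!is.null(s2)) {
    dec2 <- processOne(s2, out2, 2L)
    decisions <- rbind(dec1, dec2)
  }

  stats <- list(
    reads_total = nrow(decisions),
    reads_trimmed = sum(decisions$action == "trimmed"),
    reads_unassigned = sum(decisions$action == "unassigned"),
    correctly_trimmed_fraction = NA_real_,
    decisions = decisions)

  if (!is.null(truth)) {
    key <- paste(decisions$read_id, decisions$mate, sep = "/")
    tkey <- if ("mate" %in% colnames(truth))
      paste(truth$read_id, truth$mate, sep = "/") else truth$read_id
    m <- match(key, tkey)
    have <- !is.na(m)
    expected <- truth$trim_pos[m[have]]
    observed <- decisions$trim_pos[have]
    correct <- (is.na(expected) & is.na(observed)) |
      (!is.na(expected) & !is.na(observed) & expected == observed)
    stats$correctly_trimmed_fraction <- sum(correct) / sum(have)
  }
  stats
}
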
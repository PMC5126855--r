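#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom utils head
#' @importFrom stats runif rnorm
NULL

## Enumerations shared across the package ------------------------------------

.PHENOTYPE_CATEGORIES <- c("gonadal_development", "androgen_synthesis_action",
                           "central_hypogonadism", "other")

.PATIENT_CATEGORIES <- c("gonadal_development", "androgen_synthesis_action",
                         "other", "unknown")

.INHERITANCE_MODES <- c("AR", "AD", "XL", "XL_dup", "AD_dup")

.CONSEQUENCES <- c("frameshift", "stop_gain", "splice_site", "inframe_indel",
                   "missense", "synonymous", "other")

.NULL_CONSEQUENCES <- c("frameshift", "stop_gain", "splice_site")

.PREDICTORS <- c("SIFT", "PolyPhen2", "LRT", "MutationTaster")

.REPORTED_STATUS <- c("reported_same_phenotype", "reported_other_disease",
                      "unreported")

.CLASSIFICATIONS <- c("pathogenic", "likely_pathogenic", "VUS1", "VUS2",
                      "VUS3", "filtered_out")

## PanelThresholds ------------------------------------------------------------

#' Shared filtering and QC thresholds
#'
#' Container for the numeric cut-offs used by the variant filter, the
#' concordance comparison and the coverage reports.  Defaults follow common
#' diagnostic panel practice: rare means minor allele frequency at most 1\%
#' in each population database, cohort-recurrent artifacts are discounted
#' above 15 observations per run or database, diagnostic coverage is 20x,
#' only INDELs shorter than 10 bp enter the concordance comparison, and a
#' missense call needs at least 3 of the 4 in-silico predictors to be
#' "damaging" before it can be upgraded.
#'
#' @slot mafMax maximum population minor allele frequency for a variant to
#'   be considered rare (fraction).
#' @slot cohortRecurrenceMax variants seen in more than this many samples in
#'   one sequencing run or in the whole cohort database are discounted.
#' @slot diagnosticDepth depth (x) used for per-gene diagnostic coverage.
#' @slot indelMaxLen INDELs with length change >= this many bp are excluded
#'   from concordance.
#' @slot minDamagingPredictors minimum number (of 4) of damaging in-silico
#'   calls supporting an upgrade.
#' @slot uniformityFactor fraction of mean depth used by [uniformity()].
#' @slot minQual,minDepth variant call quality/depth below which a variant
#'   is flagged for manual review.
#' @export
setClass("PanelThresholds", representation(
  mafMax = "numeric",
  cohortRecurrenceMax = "numeric",
  diagnosticDepth = "numeric",
  indelMaxLen = "numeric",
  minDamagingPredictors = "numeric",
  uniformityFactor = "numeric",
  minQual = "numeric",
  minDepth = "numeric"
))

setValidity("PanelThresholds", function(object) {
  v <- c(mafMax = object@mafMax,
         cohortRecurrenceMax = object@cohortRecurrenceMax,
         diagnosticDepth = object@diagnosticDepth,
         indelMaxLen = object@indelMaxLen,
         minDamagingPredictors = object@minDamagingPredictors,
         uniformityFactor = object@uniformityFactor,
         minQual = object@minQual,
         minDepth = object@minDepth)
  if (any(is.na(v)) || any(v < 0))
    return("all thresholds must be non-negative and non-missing")
  if (object@mafMax > 1)
    return("mafMax must be a fraction <= 1")
  if (object@minDamagingPredictors > 4)
    return("minDamagingPredictors cannot exceed the 4 predictors used")
  TRUE
})

#' Construct a PanelThresholds object
#'
#' @param mafMax,cohortRecurrenceMax,diagnosticDepth,indelMaxLen,
#'   minDamagingPredictors,uniformityFactor,minQual,minDepth see
#'   \linkS4class{PanelThresholds}.
#' @return a \linkS4class{PanelThresholds} object.
#' @examples
#' panelThresholds()
#' panelThresholds(mafMax = 0.005)
#' @export
panelThresholds <- function(mafMax = 0.01, cohortRecurrenceMax = 15,
                            diagnosticDepth = 20, indelMaxLen = 10,
                            minDamagingPredictors = 3,
                            uniformityFactor = 0.5,
                            minQual = 30, minDepth = 10) {
  new("PanelThresholds", mafMax = mafMax,
      cohortRecurrenceMax = cohortRecurrenceMax,
      diagnosticDepth = diagnosticDepth, indelMaxLen = indelMaxLen,
      minDamagingPredictors = minDamagingPredictors,
      uniformityFactor = uniformityFactor,
      minQual = minQual, minDepth = minDepth)
}

setMethod("show", "PanelThresholds", function(object) {
  cat("PanelThresholds\n")
  cat("  mafMax:                ", object@mafMax, "\n")
  cat("  cohortRecurrenceMax:   ", object@cohortRecurrenceMax, "\n")
  cat("  diagnosticDepth:       ", object@diagnosticDepth, "x\n", sep = "")
  cat("  indelMaxLen:           <", object@indelMaxLen, "bp\n")
  cat("  minDamagingPredictors: ", object@minDamagingPredictors, "of 4\n")
  cat("  uniformityFactor:      ", object@uniformityFactor, "\n")
  cat("  minQual/minDepth:      ", object@minQual, "/", object@minDepth, "\n")
})

## AmpliconDesign -------------------------------------------------------------

#' Amplicon design: amplicons plus target regions
#'
#' Holds the amplicons of a targeted capture design and the target regions
#' the panel is meant to cover.  Both are stored as \linkS4class{GRanges}
#' (1-based, closed intervals, the Bioconductor convention); BED input and
#' output are 0-based half-open and converted at the I/O boundary only.
#'
#' @slot amplicons GRanges with a unique `id` metadata column.
#' @slot targets GRanges, optionally carrying a `gene` metadata column.
#' @export
setClass("AmpliconDesign", representation(
  amplicons = "GRanges",
  targets = "GRanges"
))

setValidity("AmpliconDesign", function(object) {
  amp <- object@amplicons
  if (length(amp)) {
    if (is.null(amp$id)) return("amplicons must carry an 'id' column")
    if (anyDuplicated(amp$id)) return("amplicon ids must be unique")
    if (any(width(amp) < 1)) return("amplicons must have positive length")
  }
  if (length(object@targets) && any(width(object@targets) < 1))
    return("target regions must have positive length")
  TRUE
})

#' @describeIn AmpliconDesign-class number of amplicons.
#' @param x,object an AmpliconDesign.
#' @export
setMethod("length", "AmpliconDesign", function(x) length(x@amplicons))

setMethod("show", "AmpliconDesign", function(object) {
  cat("AmpliconDesign with", length(object@amplicons), "amplicons and",
      length(object@targets), "target regions\n")
  if (length(object@amplicons)) {
    w <- width(object@amplicons)
    cat("  amplicon length: ", min(w), "-", max(w), " bp\n", sep = "")
  }
})

#' Accessors for AmpliconDesign
#'
#' @param design an \linkS4class{AmpliconDesign}.
#' @return `amplicons()` and `targetRegions()` return GRanges.
#' @export
amplicons <- function(design) design@amplicons

#' @rdname amplicons
#' @export
targetRegions <- function(design) design@targets

## GeneRegistry ---------------------------------------------------------------

#' Registry of diagnostic panel genes
#'
#' The diagnostic gene set of the panel with, per gene, its locus, OMIM id,
#' phenotype category (the four groups used to test phenotype fit during
#' curation), inheritance modes, and whether loss of function is a known
#' disease mechanism.  The packaged default encodes the 64 diagnostic genes
#' of the DSD panel.
#'
#' @slot genes a \linkS4class{DataFrame} keyed (rownames) by gene symbol
#'   with columns `locus`, `omim`, `category` (list of phenotype
#'   categories), `inheritance` (list of modes), `lof_mechanism` (logical),
#'   `coverage20x` (integer percent or NA) and `associated_dsd`.
#' @export
setClass("GeneRegistry", representation(genes = "DataFrame"))

setValidity("GeneRegistry", function(object) {
  g <- object@genes
  need <- c("locus", "omim", "category", "inheritance", "lof_mechanism")
  if (!all(need %in% colnames(g)))
    return(paste("registry must have columns:", paste(need, collapse = ", ")))
  if (nrow(g)) {
    if (is.null(rownames(g)) || anyDuplicated(rownames(g)))
      return("gene symbols (rownames) must be present and unique")
    cats <- unlist(g$category)
    if (any(!cats %in% .PHENOTYPE_CATEGORIES))
      return(paste("unknown phenotype category; allowed:",
                   paste(.PHENOTYPE_CATEGORIES, collapse = ", ")))
    inh <- unlist(g$inheritance)
    if (any(!inh %in% .INHERITANCE_MODES))
      return(paste("unknown inheritance mode; allowed:",
                   paste(.INHERITANCE_MODES, collapse = ", ")))
    if (any(lengths(g$category) == 0) || any(lengths(g$inheritance) == 0))
      return("every gene needs at least one category and inheritance mode")
  }
  TRUE
})

setMethod("show", "GeneRegistry", function(object) {
  g <- object@genes
  cat("GeneRegistry with", nrow(g), "genes\n")
  if (nrow(g)) {
    tab <- table(vapply(g$category, `[`, character(1), 1L))
    for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  }
})

#' @describeIn GeneRegistry-class number of genes.
#' @param x a GeneRegistry.
#' @export
setMethod("length", "GeneRegistry", function(x) nrow(x@genes))

#' Gene symbols in a registry
#' @param registry a \linkS4class{GeneRegistry}.
#' @return character vector of gene symbols.
#' @export
geneSymbols <- function(registry) rownames(registry@genes)

#' Look up one gene record
#' @param registry a \linkS4class{GeneRegistry}.
#' @param symbol gene symbol.
#' @return a list with the record's fields.
#' @export
geneRecord <- function(registry, symbol) {
  g <- registry@genes
  if (!symbol %in% rownames(g))
    stop("gene '", symbol, "' is not in the registry")
  r <- g[symbol, ]
  list(symbol = symbol, locus = r$locus, omim = r$omim,
       category = r$category[[1L]], inheritance = r$inheritance[[1L]],
       lof_mechanism = r$lof_mechanism,
       coverage20x = if ("coverage20x" %in% colnames(g)) r$coverage20x else NA,
       associated_dsd = if ("associated_dsd" %in% colnames(g))
         r$associated_dsd else NA_character_)
}

## BoundaryIndex --------------------------------------------------------------

#' Index of amplicon boundary k-mers for adapter read-through trimming
#'
#' Maps the k-mer observed at the start of a read deriving from either
#' terminus of each amplicon to the amplicon and its length, so the position
#' where adapter sequence is expected (the amplicon length) is known for any
#' read whose prefix matches a boundary.
#'
#' @slot k k-mer length.
#' @slot adapter adapter sequence expected after the amplicon boundary.
#' @slot entries data.frame with columns `kmer`, `amplicon`, `terminus`
#'   ("5p" for read-1 orientation, "3p" for read-2 orientation), `len`.
#' @export
setClass("BoundaryIndex", representation(
  k = "integer",
  adapter = "character",
  entries = "data.frame"
))

setValidity("BoundaryIndex", function(object) {
  if (object@k < 8L) return("k must be >= 8")
  if (!nzchar(object@adapter)) return("adapter must be non-empty")
  need <- c("kmer", "amplicon", "terminus", "len")
  if (!all(need %in% colnames(object@entries)))
    return("entries must have columns kmer, amplicon, terminus, len")
  TRUE
})

setMethod("show", "BoundaryIndex", function(object) {
  cat("BoundaryIndex: k=", object@k, ", ", nrow(object@entries),
      " boundary entries (", length(unique(object@entries$amplicon)),
      " amplicons), adapter ", object@adapter, "\n", sep = "")
})

## DepthTrack -----------------------------------------------------------------

#' Per-base depth over the targeted bases
#'
#' @slot positions GRanges of width-1 targeted positions.
#' @slot depth integer depth per position (same length as `positions`).
#' @slot targets the target regions the track covers.
#' @export
setClass("DepthTrack", representation(
  positions = "GRanges",
  depth = "integer",
  targets = "GRanges"
))

setValidity("DepthTrack", function(object) {
  if (length(object@positions) != length(object@depth))
    return("depth must have one value per targeted position")
  if (length(object@depth) && any(object@depth < 0))
    return("depths must be non-negative")
  TRUE
})

setMethod("show", "DepthTrack", function(object) {
  cat("DepthTrack over", length(object@depth), "targeted bases")
  if (length(object@depth))
    cat("; mean depth", round(mean(object@depth), 1))
  cat("\n")
})

#' Depth values of a DepthTrack
#' @param track a \linkS4class{DepthTrack}.
#' @return integer vector of per-base depths.
#' @export
depthValues <- function(track) track@depth

#' @rdname depthValues
#' @export
totalTargetedBases <- function(track) length(track@depth)

## ConcordanceResult ----------------------------------------------------------

#' Result of a truth-vs-query callset comparison
#'
#' @slot tp,fn,fp counts of true positives, false negatives, false
#'   positives (allele-level matching on normalized variants).
#' @slot sensitivity tp / (tp + fn).
#' @slot falsePositiveRate fp / (tp + fp), i.e. 1 - precision.
#' @slot roc data.frame with columns `threshold`, `tp`, `fp`,
#'   `sensitivity`, `fpr`, one row per quality threshold swept.
#' @export
setClass("ConcordanceResult", representation(
  tp = "integer", fn = "integer", fp = "integer",
  sensitivity = "numeric", falsePositiveRate = "numeric",
  roc = "data.frame"
))

setValidity("ConcordanceResult", function(object) {
  if (object@tp < 0 || object@fn < 0 || object@fp < 0)
    return("counts must be non-negative")
  TRUE
})

setMethod("show", "ConcordanceResult", function(object) {
  cat("ConcordanceResult: TP=", object@tp, " FN=", object@fn,
      " FP=", object@fp, "\n", sep = "")
  cat(sprintf("  sensitivity %.4f, false positive rate %.4f (1 - precision)\n",
              object@sensitivity, object@falsePositiveRate))
  cat("  ROC points:", nrow(object@roc), "\n")
})

#' Accessors for ConcordanceResult
#' @param x a \linkS4class{ConcordanceResult}.
#' @return `sensitivity()` / `falsePositiveRate()` return fractions;
#'   `rocPointsOf()` the swept ROC table.
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @rdname sensitivity
#' @export
setMethod("sensitivity", "ConcordanceResult", function(x) x@sensitivity)

#' @rdname sensitivity
#' @export
setGeneric("falsePositiveRate", function(x) standardGeneric("falsePositiveRate"))

#' @rdname sensitivity
#' @export
setMethod("falsePositiveRate", "ConcordanceResult",
          function(x) x@falsePositiveRate)

#' @rdname sensitivity
#' @export
rocPointsOf <- function(x) x@roc
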
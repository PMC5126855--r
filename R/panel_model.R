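#' Load an amplicon design from BED
#'
#' Reads amplicons and (optionally separate) target regions from BED.  BED
#' coordinates are 0-based half-open; the returned GRanges use the
#' Bioconductor 1-based closed convention.  Column 4, when present, supplies
#' amplicon ids; missing ids are synthesized as `chrom:start-end` (BED
#' coordinates).  Duplicate ids are suffixed `_1`, `_2`, ... in file order,
#' with a warning.
#'
#' @param ampliconBed path to the amplicon BED file.
#' @param targetBed optional path to a target-region BED; when omitted the
#'   amplicon footprint (merged) is used as the target.
#' @return an \linkS4class{AmpliconDesign}; amplicons sorted by
#'   (chrom, start).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t220\tamp1", bed)
#' design <- loadAmpliconDesign(bed)
#' amplicons(design)
#' @export
loadAmpliconDesign <- function(ampliconBed, targetBed = NULL) {
  amp <- .readBed(ampliconBed)
  if (length(amp)) {
    id <- amp$name
    if (is.null(id)) id <- rep(NA_character_, length(amp))
    miss <- is.na(id) | !nzchar(id)
    if (any(miss))
      id[miss] <- paste0(as.character(seqnames(amp))[miss], ":",
                         start(amp)[miss] - 1L, "-", end(amp)[miss])
    if (anyDuplicated(id)) {
      dupset <- unique(id[duplicated(id)])
      warning("duplicate amplicon ids deduplicated with numeric suffixes: ",
              paste(dupset, collapse = ", "))
      for (d in dupset) {
        w <- which(id == d)
        id[w] <- paste0(d, "_", seq_along(w))
      }
    }
    S4Vectors::mcols(amp) <- S4Vectors::DataFrame(id = id)
    amp <- amp[order(as.character(seqnames(amp)), start(amp))]
  } else {
    S4Vectors::mcols(amp) <- S4Vectors::DataFrame(id = character(0))
  }
  targets <- if (is.null(targetBed)) {
    GenomicRanges::reduce(amp, ignore.strand = TRUE)
  } else {
    tg <- .readBed(targetBed)
    if (!is.null(tg$name)) names(S4Vectors::mcols(tg))[
      names(S4Vectors::mcols(tg)) == "name"] <- "gene"
    tg[order(as.character(seqnames(tg)), start(tg))]
  }
  new("AmpliconDesign", amplicons = amp, targets = targets)
}

## BED import with per-line validation so malformed input is reported by line.
.readBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (!length(body))
    return(GenomicRanges::GRanges())
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", lineno[which(nf < 3)[1L]],
         ": fewer than 3 columns")
  s <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  e <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- is.na(s) | is.na(e)
  if (any(bad))
    stop("malformed BED line ", lineno[which(bad)[1L]],
         ": non-numeric coordinates")
  if (any(s >= e))
    stop("invalid interval at BED line ", lineno[which(s >= e)[1L]],
         ": start must be < end (0-based half-open)")
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::granges(gr, use.mcols = TRUE)
}

#' Write an amplicon design back to BED
#'
#' Inverse of [loadAmpliconDesign()]: coordinates round-trip bit-exactly
#' (converted back to 0-based half-open).
#'
#' @param design an \linkS4class{AmpliconDesign}.
#' @param path output BED path.
#' @return invisibly, `path`.
#' @export
writeAmpliconDesign <- function(design, path) {
  amp <- amplicons(design)
  df <- data.frame(chrom = as.character(seqnames(amp)),
                   start = start(amp) - 1L, end = end(amp),
                   name = amp$id,
                   score = 0L,
                   strand = ifelse(as.character(strand(amp)) == "*",
                                   "+", as.character(strand(amp))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load the diagnostic gene registry
#'
#' Reads a gene registry from TSV, or (default) the registry packaged with
#' panelcurate encoding the 64 diagnostic DSD genes with their phenotype
#' category, inheritance modes and loss-of-function mechanism flag.
#'
#' Expected TSV columns: `symbol`, `locus`, `omim`, `category`
#' (comma-separated subset of gonadal_development, androgen_synthesis_action,
#' central_hypogonadism, other), `inheritance` (comma-separated subset of
#' AR, AD, XL, XL_dup, AD_dup), `lof_mechanism` (TRUE/FALSE); optional
#' `coverage20x`, `associated_dsd`.
#'
#' @param path TSV path; `NULL` loads the packaged 64-gene default.
#' @return a \linkS4class{GeneRegistry}.
#' @examples
#' reg <- loadGeneRegistry()
#' length(reg)   # 64
#' geneRecord(reg, "NR5A1")$inheritance
#' @export
loadGeneRegistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dsd_gene_registry.tsv",
                        package = "panelcurate", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("symbol", "locus", "omim", "category", "inheritance",
            "lof_mechanism")
  if (!all(need %in% colnames(df)))
    stop("gene registry TSV must have columns: ",
         paste(need, collapse = ", "))
  if (anyDuplicated(df$symbol))
    stop("duplicate gene symbols in registry: ",
         paste(unique(df$symbol[duplicated(df$symbol)]), collapse = ", "))
  cats <- strsplit(df$category, ",", fixed = TRUE)
  cats <- lapply(cats, trimws)
  badc <- setdiff(unlist(cats), .PHENOTYPE_CATEGORIES)
  if (length(badc))
    stop("unknown phenotype category '", badc[1L], "'; allowed: ",
         paste(.PHENOTYPE_CATEGORIES, collapse = ", "))
  inh <- lapply(strsplit(df$inheritance, ",", fixed = TRUE), trimws)
  badi <- setdiff(unlist(inh), .INHERITANCE_MODES)
  if (length(badi))
    stop("unknown inheritance mode '", badi[1L], "'; allowed: ",
         paste(.INHERITANCE_MODES, collapse = ", "))
  genes <- S4Vectors::DataFrame(
    locus = df$locus, omim = df$omim,
    category = I(cats), inheritance = I(inh),
    lof_mechanism = as.logical(df$lof_mechanism),
    coverage20x = if ("coverage20x" %in% colnames(df))
      suppressWarnings(as.integer(df$coverage20x)) else NA_integer_,
    associated_dsd = if ("associated_dsd" %in% colnames(df))
      df$associated_dsd else NA_character_,
    row.names = df$symbol)
  new("GeneRegistry", genes = genes)
}

#' Genes overlapping a region
#'
#' @param region GRanges of length 1 (or more) to query.
#' @param registry a \linkS4class{GeneRegistry}; only symbols present in the
#'   registry are reported.
#' @param locusMap GRanges named by gene symbol giving each gene's interval
#'   on the same assembly as `region`.
#' @return character vector of overlapping registry symbols (>= 1 bp
#'   overlap), sorted lexicographically.  Chromosomes absent from the map
#'   simply yield no hits.
#' @export
genesOverlapping <- function(region, registry, locusMap) {
  if (is.null(names(locusMap)) || !length(locusMap))
    return(character(0))
  ## disjoint seqlevels are expected (chromosomes absent from the map)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(region, locusMap, minoverlap = 1L,
                                ignore.strand = TRUE))
  sym <- unique(names(locusMap)[S4Vectors::subjectHits(hits)])
  sort(intersect(sym, geneSymbols(registry)))
}
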
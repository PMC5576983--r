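#' @importFrom GenomicRanges GRanges strand seqnames mcols "mcols<-" reduce
#' @importFrom IRanges IRanges IRangesList start end width
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths "seqlengths<-" seqlevels
NULL

# internal constructor. genes: GRanges (1-based internally via IRanges, but
# the public convention is 0-based half-open: accessors convert). We store
# everything as IRanges in 1-based closed coordinates and expose 0-based
# half-open numbers in data.frame outputs.
.newGeneModelSet <- function(genes, cds, introns, flanks, flankWidth) {
  new("GeneModelSet", genes = genes, cds = cds, introns = introns,
      flanks = flanks, flankWidth = flankWidth)
}

#' @describeIn GeneModelSet-class Gene identifiers.
#' @param x A GeneModelSet.
#' @export
setMethod("geneIds", "GeneModelSet", function(x) names(x@genes))

#' @describeIn GeneModelSet-class Transcription-unit GRanges.
#' @export
setMethod("transcriptionUnits", "GeneModelSet", function(x) x@genes)

#' @describeIn GeneModelSet-class CDS intervals per gene.
#' @export
setMethod("cdsIntervals", "GeneModelSet", function(x) x@cds)

#' @describeIn GeneModelSet-class Intron intervals per gene.
#' @export
setMethod("intronIntervals", "GeneModelSet", function(x) x@introns)

#' @describeIn GeneModelSet-class Flank intervals per gene.
#' @export
setMethod("flankIntervals", "GeneModelSet", function(x) x@flanks)

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet:", length(object@genes), "genes on",
      length(unique(as.character(seqnames(object@genes)))), "chromosomes;",
      "flank width", object@flankWidth, "bp\n")
})

#' Per-gene summary table of a model set
#'
#' @param models A [GeneModelSet-class].
#' @return data.frame with 0-based half-open `tss`/`polya` coordinates,
#'   strand, transcription-unit length, CDS length and intron count.
#' @export
geneTable <- function(models) {
  g <- models@genes
  plus <- as.character(strand(g)) == "+"
  s0 <- start(g) - 1L
  e0 <- end(g)
  data.frame(
    gene_id = names(g),
    chrom = as.character(seqnames(g)),
    strand = as.character(strand(g)),
    tss = ifelse(plus, s0, e0),
    polya = ifelse(plus, e0, s0),
    start = s0, end = e0,
    length = e0 - s0,
    cds_length = sum(width(models@cds)),
    n_introns = lengths(models@introns),
    stringsAsFactors = FALSE
  )
}

# flanks: up to `width` bp of contiguous non-genic sequence immediately
# upstream of the TU start and downstream of the TU end, clipped to the
# chromosome and truncated at the nearest annotated transcription unit
# (a gene abutting or inside another gene's span gets an empty flank on
# that side)
.buildFlanks <- function(genes, width, seqlens) {
  n <- length(genes)
  chrom <- as.character(seqnames(genes))
  s <- start(genes); e <- end(genes)
  upS <- integer(n); upE <- integer(n); dnS <- integer(n); dnE <- integer(n)
  red <- reduce(genes, ignore.strand = TRUE)
  redChrom <- as.character(seqnames(red))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    L <- as.numeric(seqlens[[ch]])
    if (length(L) == 0L || is.na(L)) L <- Inf
    rs <- start(red)[redChrom == ch]
    re <- end(red)[redChrom == ch]
    k <- findInterval(s[idx], rs)
    atStart <- s[idx] == rs[k]
    atEnd <- e[idx] == re[k]
    prevEnd <- ifelse(k > 1L, re[pmax(k - 1L, 1L)], 0L)
    nextStart <- ifelse(k < length(rs), rs[pmin(k + 1L, length(rs))], L + 1L)
    upS[idx] <- ifelse(atStart, pmax(s[idx] - width, prevEnd + 1, 1), s[idx])
    upE[idx] <- s[idx] - 1L
    dnS[idx] <- e[idx] + 1L
    dnE[idx] <- ifelse(atEnd, pmin(e[idx] + width, nextStart - 1, L), e[idx])
  }
  gi <- rep(seq_len(n), 2L)
  fs <- c(upS, dnS); fe <- c(upE, dnE)
  keep <- fe >= fs
  ir <- IRanges(fs[keep], fe[keep])
  out <- S4Vectors::split(ir, factor(gi[keep], levels = seq_len(n)))
  names(out) <- names(genes)
  out
}

#' Load canonical gene models from a GFF3 annotation
#'
#' One model is kept per gene (the canonical transcript: longest total CDS,
#' ties broken by lexicographic transcript id). Mitochondrial contigs
#' (`MT`, `chrM`, `chrMT`) are dropped. Genes whose total CDS length is not
#' divisible by 3 are excluded with a logged reason. Coordinates in returned
#' tables follow the package's 0-based half-open convention.
#'
#' @param annotation Path to a GFF3 file, or a `GRanges` as returned by
#'   `rtracklayer::import`.
#' @param genome Optional genome `DNAStringSet` (or FASTA path); when given,
#'   every referenced chromosome must be present and seqlengths are taken
#'   from it.
#' @param flankWidth Width in bp of each flanking region (default 10 kb).
#' @return A [GeneModelSet-class].
#' @export
loadGeneModels <- function(annotation, genome = NULL, flankWidth = 10000) {
  gr <- if (is(annotation, "GRanges")) annotation else
    rtracklayer::import(annotation, format = "gff3")
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))

  mito <- c("MT", "chrM", "chrMT", "mito")
  gr <- gr[!(as.character(seqnames(gr)) %in% mito)]

  type <- as.character(gr$type)
  cdsGr <- gr[type == "CDS"]
  txGr <- gr[type %in% c("mRNA", "transcript")]
  if (length(txGr) == 0L) stop("annotation has no mRNA/transcript records")
  txId <- as.character(txGr$ID)
  txParent <- vapply(txGr$Parent, function(p) as.character(p)[1L], character(1))
  cdsParent <- vapply(cdsGr$Parent, function(p) as.character(p)[1L], character(1))

  if (!is.null(genome)) {
    missing <- setdiff(unique(as.character(seqnames(txGr))), names(genome))
    if (length(missing))
      stop("chromosomes absent from genome: ", paste(missing, collapse = ", "))
  }

  cdsByTx <- S4Vectors::split(cdsGr, factor(cdsParent, levels = txId))
  cdsLen <- sum(width(cdsByTx))

  # canonical transcript per gene: longest CDS, lexicographic tie-break
  ord <- order(txParent, -cdsLen, txId)
  keep <- ord[!duplicated(txParent[ord])]
  keep <- keep[cdsLen[keep] > 0L]

  genesList <- list()
  cdsList <- list()
  intronList <- list()
  for (i in keep) {
    gid <- txParent[i]
    cds <- .sortIR(IRanges::ranges(cdsByTx[[txId[i]]]))
    if (sum(width(cds)) %% 3L != 0L) {
      message("excluding ", gid, ": CDS length ", sum(width(cds)),
              " not divisible by 3")
      next
    }
    genesList[[gid]] <- txGr[i]
    cdsList[[gid]] <- cds
    intronList[[gid]] <- IRanges::gaps(cds,
                                       start = min(start(cds)),
                                       end = max(end(cds)))
  }
  if (length(genesList) == 0L) stop("no usable gene models")
  genes <- unlist(methods::as(genesList, "GRangesList"))
  names(genes) <- names(genesList)
  mcols(genes) <- NULL
  seqlens <- if (!is.null(genome)) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else {
    stats::setNames(rep(NA_integer_, length(seqlevels(genes))),
                    seqlevels(genes))
  }
  sl <- seqlens[seqlevels(genes)]
  names(sl) <- seqlevels(genes)
  suppressWarnings(seqlengths(genes) <- sl)
  .newGeneModelSet(
    genes,
    methods::as(IRangesList(cdsList), "CompressedIRangesList"),
    methods::as(IRangesList(intronList), "CompressedIRangesList"),
    .buildFlanks(genes, flankWidth, as.list(seqlens)),
    flankWidth
  )
}

# extract and concatenate genomic intervals per gene from a DNAStringSet
# genome; irl is a CompressedIRangesList in 1-based closed coordinates
# parallel to `chrom`. Returns a character vector (plus-strand sequence).
.extractConcat <- function(genome, chrom, irl) {
  n <- length(irl)
  out <- character(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- as.character(genome[[ch]])
    for (i in idx) {
      ir <- irl[[i]]
      if (length(ir) == 0L) { out[i] <- ""; next }
      out[i] <- paste(substring(s, start(ir), end(ir)), collapse = "")
    }
  }
  names(out) <- names(irl)
  out
}

#' Coding sequences of a model set
#'
#' Concatenates CDS intervals in genomic order and reverse-complements
#' minus-strand genes, so each returned sequence starts with the initiator
#' codon.
#'
#' @param models A [GeneModelSet-class].
#' @param genome Genome `DNAStringSet` named by chromosome.
#' @return `DNAStringSet` named by gene id.
#' @export
cdsSequences <- function(models, genome) {
  chrom <- as.character(seqnames(models@genes))
  seqs <- .extractConcat(genome, chrom, models@cds)
  dss <- Biostrings::DNAStringSet(seqs)
  minus <- as.character(strand(models@genes)) == "-"
  if (any(minus)) dss[minus] <- Biostrings::reverseComplement(dss[minus])
  names(dss) <- names(models@genes)
  dss
}
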
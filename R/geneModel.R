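#' Build a GeneModel from exon intervals
#'
#' @param exons a `GRanges` of exons with metadata columns `gene` and
#'   `transcript`; an optional logical column `canonical` flags the canonical
#'   transcript of a gene. Strand must be `+` or `-`.
#' @return a [GeneModel-class] object.
#'
#' @details Introns are computed per transcript as the gaps between
#' consecutive exons, then deduplicated across transcripts to form the
#' canonical junction set. When no transcript of a gene is flagged canonical,
#' the transcript with the largest summed exon width is used.
#'
#' @examples
#' ex <- GenomicRanges::GRanges("chrT",
#'   IRanges::IRanges(c(501, 1201, 1901), c(1000, 1700, 2400)),
#'   strand = "+", gene = "GENE1", transcript = "TX1")
#' gm <- makeGeneModel(ex)
#' canonicalJunctions(gm)
#' @export
makeGeneModel <- function(exons) {
  stopifnot(is(exons, "GRanges"))
  mc <- mcols(exons)
  if (!all(c("gene", "transcript") %in% colnames(mc)))
    stop("exons must carry 'gene' and 'transcript' metadata columns")
  mc$gene <- as.character(mc$gene)
  mc$transcript <- as.character(mc$transcript)
  mcols(exons) <- mc

  introns <- .transcriptIntrons(exons)
  canon <- .pickCanonical(exons)
  new("GeneModel", exons = exons, introns = introns, canonicalTx = canon)
}

# gaps between consecutive exons of each transcript, deduplicated
.transcriptIntrons <- function(exons) {
  pieces <- split(exons, mcols(exons)$transcript)
  out <- GRanges()
  mcols(out)$gene <- character(0)
  mcols(out)$transcript <- character(0)
  for (tx in names(pieces)) {
    e <- sort(pieces[[tx]])
    if (length(e) < 2L) next
    istart <- end(e)[-length(e)] + 1L
    iend <- start(e)[-1L] - 1L
    keep <- iend >= istart
    if (!any(keep)) next
    gr <- GRanges(seqnames(e)[1L], IRanges(istart[keep], iend[keep]),
                  strand = strand(e)[1L])
    mcols(gr)$gene <- mcols(e)$gene[1L]
    mcols(gr)$transcript <- tx
    out <- c(out, gr)
  }
  if (length(out)) {
    key <- paste(seqnames(out), start(out), end(out), mcols(out)$gene)
    out <- out[!duplicated(key)]
  }
  out
}

.pickCanonical <- function(exons) {
  mc <- mcols(exons)
  genes <- unique(mc$gene)
  vapply(genes, function(g) {
    sel <- mc$gene == g
    if ("canonical" %in% colnames(mc)) {
      flagged <- unique(mc$transcript[sel & isTRUE_vec(mc$canonical)])
      if (length(flagged) >= 1L) return(flagged[1L])
    }
    spans <- tapply(width(exons)[sel], mc$transcript[sel], sum)
    names(spans)[which.max(spans)]
  }, character(1L))
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Read a gene model from a GTF/GFF file
#'
#' Imports exon features and builds a [GeneModel-class]. Gene symbols are
#' taken from `gene_name` when present, else `gene_id`.
#'
#' @param path GTF or GFF file.
#' @return a [GeneModel-class] object.
#' @export
readGeneModel <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(mcols(gr)$type)) == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  mc <- mcols(gr)
  gene <- if ("gene_name" %in% colnames(mc) && !all(is.na(mc$gene_name)))
    mc$gene_name else mc$gene_id
  ex <- granges(gr)
  mcols(ex)$gene <- as.character(gene)
  mcols(ex)$transcript <- as.character(mc$transcript_id)
  if ("tag" %in% colnames(mc))
    mcols(ex)$canonical <- vapply(mc$tag, function(t) "canonical" %in% t, logical(1))
  makeGeneModel(ex)
}

#' @rdname GeneModel-class
#' @export
setMethod("modelExons", "GeneModel", function(x) x@exons)

#' @rdname GeneModel-class
#' @export
setMethod("canonicalJunctions", "GeneModel", function(x) x@introns)

#' @rdname GeneModel-class
#' @export
setMethod("modelGenes", "GeneModel", function(x) unique(mcols(x@exons)$gene))

#' @rdname GeneModel-class
#' @export
setMethod("geneStrand", "GeneModel", function(x, gene) {
  sel <- mcols(x@exons)$gene == gene
  if (!any(sel)) stop("gene not in model: ", gene)
  as.character(strand(x@exons))[sel][1L]
})

# Splice-site boundary coordinates of the canonical transcript, as the
# genomic position of the boundary *exonic* base: donor = last exonic base
# before an intron (transcript orientation), acceptor = first exonic base
# after an intron.
#' @rdname GeneModel-class
#' @export
setMethod("donorSites", "GeneModel", function(x, gene) {
  ib <- .canonicalIntrons(x, gene)
  if (!length(ib)) return(integer())
  s <- geneStrand(x, gene)
  sort(if (s == "+") start(ib) - 1L else end(ib) + 1L)
})

#' @rdname GeneModel-class
#' @export
setMethod("acceptorSites", "GeneModel", function(x, gene) {
  ib <- .canonicalIntrons(x, gene)
  if (!length(ib)) return(integer())
  s <- geneStrand(x, gene)
  sort(if (s == "+") end(ib) + 1L else start(ib) - 1L)
})

.canonicalIntrons <- function(x, gene) {
  tx <- x@canonicalTx[[gene]]
  x@introns[mcols(x@introns)$gene == gene & mcols(x@introns)$transcript == tx]
}

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel with", length(modelGenes(object)), "gene(s),",
      length(unique(mcols(object@exons)$transcript)), "transcript(s),",
      length(object@exons), "exons,",
      length(object@introns), "junctions\n")
  for (g in modelGenes(object))
    cat("  ", g, " (", geneStrand(object, g), "): canonical tx ",
        object@canonicalTx[[g]], "\n", sep = "")
})
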
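#' Retrieve RNA-seq reads crossing a genomic position
#'
#' Returns primary, non-duplicate alignments whose reference span contains
#' the position, including reads that splice over it (the position falls in
#' an N gap of the CIGAR). Reads below the mapping-quality cutoff are
#' excluded (default MapQ >= 20).
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param contig reference sequence name.
#' @param pos 1-based genomic position.
#' @param minMapq minimum mapping quality (inclusive).
#' @return a `GAlignments` object with `qname`, `flag` and `mapq` metadata.
#' @export
readsCrossing <- function(bam, contig, pos, minMapq = 20L) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!contig %in% names(hdr)) {
    warning("contig '", contig, "' absent from ", bam)
    return(GenomicAlignments::GAlignments())
  }
  param <- Rsamtools::ScanBamParam(
    which = GRanges(contig, IRanges(pos, pos)),
    what = c("qname", "flag", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE),
    mapqFilter = minMapq)
  GenomicAlignments::readGAlignments(bam, param = param)
}

#' Splice junctions of aligned reads
#'
#' One junction per N (skip) CIGAR operation, as the genomic intron
#' interval; deletions do not produce junctions.
#'
#' @param reads a `GAlignments` object.
#' @return a `GRangesList`, one element per read, of intron ranges.
#' @export
junctionsOf <- function(reads) GenomicAlignments::junctions(reads)

# Geometry of one splice event against the gene model, all 1-based genomic:
#   sign     +1 / -1 transcript strand
#   B        boundary exonic base of the nearest canonical donor (D events)
#            or acceptor (A events)
#   Bint     the intronic base adjacent to B
#   s        novel site for gains (NA for losses)
#   sInt     the would-be intronic neighbour of s for gains
#   p        evaluation position: first intronic base of the lost site for
#            DL/AL, the novel site for DG/AG
.eventGeometry <- function(event, gm) {
  type <- event$event_type
  stopifnot(type %in% c("AL", "DL", "AG", "DG"))
  nb <- .nearestBoundary(gm, event$gene, event$site_pos, type)
  if (is.na(nb[1L]))
    stop("gene '", event$gene, "' absent from gene model")
  sign <- as.integer(nb[2L])
  B <- as.integer(nb[1L])
  donorlike <- substr(type, 1L, 1L) == "D"
  Bint <- if (donorlike) B + sign else B - sign
  gain <- substr(type, 2L, 2L) == "G"
  s <- if (gain) as.integer(event$site_pos) else NA_integer_
  sInt <- if (gain) { if (donorlike) s + sign else s - sign } else NA_integer_
  p <- if (gain) s else Bint
  list(type = type, sign = sign, B = B, Bint = Bint, donorlike = donorlike,
       gain = gain, s = s, sInt = sInt, p = p,
       canonical = .geneIntrons(gm, event$gene))
}

.geneIntrons <- function(gm, gene) {
  ib <- canonicalJunctions(gm)
  ib <- ib[mcols(ib)$gene == gene]
  cbind(gs = start(ib), ge = end(ib))
}

# does a junction's splice edge sit exactly at `site` (boundary exonic base)?
# donor-like: intron begins just after the site in transcript orientation
.edgeAt <- function(gs, ge, site, donorlike, sign) {
  if (donorlike) {
    if (sign > 0) gs == site + 1L else ge == site - 1L
  } else {
    if (sign > 0) ge == site - 1L else gs == site + 1L
  }
}

#' Classify reads at a predicted splice event
#'
#' Partitions reads crossing the event's evaluation position into normal,
#' abnormal and uninformative, in one of two modes. `direct` counts as
#' abnormal only the most direct consequence of the event: intron retention
#' through a lost donor/acceptor (DL/AL), or a junction using the novel site
#' (DG/AG); reads showing other non-canonical patterns are uninformative in
#' this mode. `all` counts as abnormal any non-canonical splicing pattern at
#' the exon-intron boundary: the direct consequence, any junction absent
#' from the canonical junction set that overlaps the boundary (cryptic-site
#' usage, exon skipping), or retention across the canonical boundary.
#' Reads soft-clipped within `clipWindow` bases of the decision point are
#' uninformative in both modes.
#'
#' @param reads `GAlignments` from [readsCrossing()] at the event's
#'   evaluation position (see [evaluationPosition()]).
#' @param event one event (one-row data.frame or list) with fields `gene`,
#'   `event_type` and `site_pos`.
#' @param gm a [GeneModel-class].
#' @param mode `"direct"` or `"all"`.
#' @param clipWindow clip-detection window around the decision point (bp).
#' @return data.frame with columns `qname` and `call`
#'   (`normal` / `abnormal` / `uninformative`).
#' @export
classifyReads <- function(reads, event, gm, mode = c("direct", "all"),
                          clipWindow = 3L) {
  mode <- match.arg(mode)
  geo <- .eventGeometry(event, gm)
  n <- length(reads)
  if (!n) return(data.frame(qname = character(), call = character()))
  cig <- GenomicAlignments::cigar(reads)
  starts <- GenomicAlignments::start(reads)
  ends <- GenomicAlignments::end(reads)
  qn <- mcols(reads)$qname
  if (is.null(qn)) qn <- paste0("read", seq_len(n))

  # aligned blocks (D merged, split on N only), flattened with a read index
  blocks <- IRanges::reduce(GenomicAlignments::extractAlignmentRangesOnReference(
    cig, pos = starts, drop.D.ranges = FALSE))
  bread <- rep(seq_len(n), lengths(blocks))
  bflat <- unlist(blocks, use.names = FALSE)
  bs <- IRanges::start(bflat); be <- IRanges::end(bflat)
  # junctions likewise
  juncs <- GenomicAlignments::junctions(reads)
  jread <- rep(seq_len(n), lengths(juncs))
  jflat <- unlist(juncs, use.names = FALSE)
  gs <- GenomicRanges::start(jflat); ge <- GenomicRanges::end(jflat)

  perRead <- function(idx, cond) {
    out <- logical(n)
    out[idx[cond]] <- TRUE
    out
  }
  spans <- function(a, b) perRead(bread, bs <= min(a, b) & be >= max(a, b))

  # soft/hard clips at the alignment edges, located at start-1 / end+1
  clipLead <- grepl("^([0-9]+H)?[0-9]+S", cig)
  clipTrail <- grepl("[0-9]+S([0-9]+H)?$", cig)
  guard <- c(geo$p, geo$B)
  nearGuard <- function(x) {
    Reduce(`|`, lapply(guard, function(g) abs(x - g) <= clipWindow))
  }
  clipped <- (clipLead & nearGuard(starts - 1L)) |
    (clipTrail & nearGuard(ends + 1L))

  isCanon <- paste(gs, ge) %in%
    paste(geo$canonical[, "gs"], geo$canonical[, "ge"])
  canonicalAtB <- perRead(jread,
    isCanon & .edgeAt(gs, ge, geo$B, geo$donorlike, geo$sign))
  retention <- spans(geo$B, geo$Bint)

  if (!geo$gain) {                      # DL / AL
    direct <- retention
    normal <- canonicalAtB
  } else {                              # DG / AG
    direct <- perRead(jread, .edgeAt(gs, ge, geo$s, geo$donorlike, geo$sign))
    normal <- canonicalAtB | spans(geo$s, geo$sInt)
  }

  call <- if (mode == "direct") {
    ifelse(direct, "abnormal", ifelse(normal, "normal", "uninformative"))
  } else {
    # all mode: any non-canonical pattern at the boundary is abnormal
    lo <- min(geo$B, geo$Bint); hi <- max(geo$B, geo$Bint)
    novelAtBoundary <- perRead(jread, !isCanon & gs <= hi & ge >= lo)
    ifelse(direct | novelAtBoundary | retention, "abnormal",
           ifelse(normal, "normal", "uninformative"))
  }
  call[clipped] <- "uninformative"
  data.frame(qname = qn, call = call, stringsAsFactors = FALSE)
}

#' Evaluation position of a splice event
#'
#' The genomic position whose crossing reads are classified: the first
#' intronic base of the lost splice site for donor/acceptor losses, or the
#' novel site itself for donor/acceptor gains.
#'
#' @inheritParams classifyReads
#' @return 1-based genomic position.
#' @export
evaluationPosition <- function(event, gm) .eventGeometry(event, gm)$p

#' Tally read calls into abnormal and normal counts
#'
#' Counts are at fragment level: calls sharing a read name (mate pairs) are
#' merged, a fragment being abnormal if either informative mate is abnormal.
#' Uninformative fragments are excluded from both tallies.
#'
#' @param calls data.frame from [classifyReads()].
#' @return named integer vector `c(n_abnormal, n_normal)`.
#' @export
countCalls <- function(calls) {
  if (!nrow(calls)) return(c(n_abnormal = 0L, n_normal = 0L))
  frag <- tapply(calls$call, calls$qname, function(v) {
    if (any(v == "abnormal")) "abnormal"
    else if (any(v == "normal")) "normal"
    else "uninformative"
  })
  c(n_abnormal = sum(frag == "abnormal"), n_normal = sum(frag == "normal"))
}
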
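#' Toy three-exon gene model for simulations
#'
#' One gene with exons 501-1000, 1201-1700 and 1901-2400 on a 3000 bp
#' contig, on either strand. The middle exon provides donor and acceptor
#' boundaries flanked by full introns, so that intron retention,
#' cryptic-site junctions and exon skipping can all be simulated.
#'
#' @param strand `"+"` or `"-"`.
#' @param contig contig name (default `"chrT"`).
#' @param gene gene symbol (default `"GENE1"`).
#' @return a [GeneModel-class].
#' @export
simGeneModel <- function(strand = "+", contig = "chrT", gene = "GENE1") {
  ex <- GRanges(contig,
                IRanges(c(501L, 1201L, 1901L), c(1000L, 1700L, 2400L)),
                strand = strand)
  mcols(ex)$gene <- gene
  mcols(ex)$transcript <- "TX1"
  makeGeneModel(ex)
}

#' Construct a splice event consistent with a gene model
#'
#' Places the event at the middle exon of the gene so that all abnormal
#' read classes (retention, cryptic junction, exon skip) are constructible.
#' Loss events sit on the middle exon's donor (DL) or acceptor (AL)
#' boundary; gain events create a novel site `crypticOffset` bases inside
#' the exon from that boundary.
#'
#' @param gm a [GeneModel-class].
#' @param event_type one of `"DL"`, `"AL"`, `"DG"`, `"AG"`.
#' @param gene gene symbol (default: first gene of the model).
#' @param ds delta score to record (default 0.9).
#' @param crypticOffset distance of a novel site from the boundary, in
#'   exonic bases (default 20).
#' @return one-row data.frame usable with [classifyReads()] and
#'   [validateCohort()].
#' @export
simSpliceEvent <- function(gm, event_type, gene = modelGenes(gm)[1L],
                           ds = 0.9, crypticOffset = 20L) {
  stopifnot(event_type %in% c("AL", "DL", "AG", "DG"))
  ex <- modelExons(gm)
  ex <- sort(ex[mcols(ex)$gene == gene])
  stopifnot(length(ex) >= 3L)
  mid <- ex[2L]
  sgn <- if (geneStrand(gm, gene) == "+") 1L else -1L
  donorlike <- substr(event_type, 1L, 1L) == "D"
  # middle exon's donor / acceptor boundary exonic base
  B <- if (donorlike) {
    if (sgn > 0) end(mid) else start(mid)
  } else {
    if (sgn > 0) start(mid) else end(mid)
  }
  gain <- substr(event_type, 2L, 2L) == "G"
  intronLeft <- if (donorlike) sgn < 0 else sgn > 0
  site <- if (!gain) B
  else if (intronLeft) B + crypticOffset else B - crypticOffset
  pos <- B   # variant placed on the boundary exonic base
  data.frame(chrom = as.character(seqnames(mid)), pos = pos, ref = "A",
             alt = "G", gene = gene, event_type = event_type, ds = ds,
             site_pos = site, stringsAsFactors = FALSE)
}

# canonical intron (gs, ge) adjacent to the event's boundary
.adjacentIntron <- function(geo) {
  canon <- geo$canonical
  if (geo$Bint < geo$B) {
    row <- which(canon[, "ge"] == geo$B - 1L)
  } else {
    row <- which(canon[, "gs"] == geo$B + 1L)
  }
  stopifnot(length(row) >= 1L)
  canon[row[1L], ]
}

# one simulated alignment: returns list(pos, cigar)
.simJunctionRead <- function(gs, ge, p, readLen) {
  aLmin <- max(10L, gs - p + 1L)
  aLmax <- readLen - max(10L, p - ge + 1L)
  aL <- if (aLmin >= aLmax) aLmin else sample(aLmin:aLmax, 1L)
  aR <- readLen - aL
  list(pos = gs - aL,
       cigar = sprintf("%dM%dN%dM", aL, ge - gs + 1L, aR))
}

.simContiguousRead <- function(reqLo, reqHi, readLen) {
  lo <- reqHi - readLen + 6L
  hi <- reqLo - 5L
  start <- if (lo >= hi) lo else sample(lo:hi, 1L)
  list(pos = start, cigar = sprintf("%dM", readLen))
}

.simClippedRead <- function(p, dirRight, readLen, clipLen = 20L) {
  alen <- readLen - clipLen
  extra <- sample(0:2, 1L)
  if (dirRight) {
    list(pos = p + extra - alen + 1L,
         cigar = sprintf("%dM%dS", alen, clipLen))
  } else {
    list(pos = p - extra, cigar = sprintf("%dS%dM", clipLen, alen))
  }
}

# expected read calls per simulated class, by construction
.TRUTH <- list(
  loss = list(canonical = c("normal", "normal"),
              retention = c("abnormal", "abnormal"),
              cryptic = c("uninformative", "abnormal"),
              skip = c("uninformative", "abnormal"),
              clipped = c("uninformative", "uninformative")),
  gain = list(canonical = c("normal", "normal"),
              retention = c("normal", "abnormal"),
              cryptic = c("abnormal", "abnormal"),
              skip = c("uninformative", "abnormal"),
              clipped = c("uninformative", "uninformative")))

# generate one read of a given class; returns list(pos, cigar)
.simReadOfClass <- function(class, geo, gm, event, readLen) {
  adj <- .adjacentIntron(geo)
  gsC <- adj[["gs"]]; geC <- adj[["ge"]]
  intronLeft <- geo$Bint < geo$B
  switch(class,
    canonical = .simJunctionRead(gsC, geC, geo$p, readLen),
    retention = {
      req <- if (geo$gain) c(geo$s, geo$sInt, geo$B, geo$Bint)
      else c(geo$B, geo$Bint)
      .simContiguousRead(min(req), max(req), readLen)
    },
    cryptic = {
      cs <- if (geo$gain) geo$s
      else if (intronLeft) geo$B + 20L else geo$B - 20L
      if (intronLeft) .simJunctionRead(gsC, cs - 1L, geo$p, readLen)
      else .simJunctionRead(cs + 1L, geC, geo$p, readLen)
    },
    skip = {
      ex <- sort(modelExons(gm)[mcols(modelExons(gm))$gene == event$gene])
      mid <- which(start(ex) <= geo$B & end(ex) >= geo$B)
      stopifnot(length(mid) == 1L, mid > 1L, mid < length(ex))
      .simJunctionRead(end(ex)[mid - 1L] + 1L, start(ex)[mid + 1L] - 1L,
                       geo$p, readLen)
    },
    clipped = {
      dirRight <- if (geo$gain) geo$sInt > geo$s else geo$Bint > geo$B
      .simClippedRead(geo$p, dirRight, readLen)
    },
    stop("unknown read class: ", class))
}

.writeSimBam <- function(reads, contig, contigLen, dest) {
  ord <- order(vapply(reads, `[[`, numeric(1L), "pos"))
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", contig, contigLen),
    vapply(reads[ord], function(r) {
      qlen <- sum(as.integer(
        regmatches(r$cigar, gregexpr("[0-9]+(?=[MIS=X])", r$cigar,
                                     perl = TRUE))[[1L]]))
      paste(r$qname, 0L, contig, r$pos, r$mapq, r$cigar, "*", 0L, 0L,
            strrep("A", qlen), strrep("I", qlen), sep = "\t")
    }, character(1L)))
  sam <- paste0(dest, ".sam")
  writeLines(lines, sam)
  bam <- Rsamtools::asBam(sam, dest, overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

#' Simulate reads of explicit classes at a splice event
#'
#' Generates pre-aligned reads (analytic CIGAR strings, no aligner) of the
#' requested classes around the event's boundary, writes a sorted indexed
#' BAM, and returns per-read truth labels: the constructed class and the
#' expected classification call in direct and all modes.
#'
#' @param gm a [GeneModel-class].
#' @param event one event from [simSpliceEvent()].
#' @param classCounts named integer vector over
#'   `canonical`, `retention`, `cryptic`, `skip`, `clipped` (absent names
#'   mean 0 reads).
#' @param readLen read length in bp (default 100).
#' @param mapq mapping quality to emit (default 60).
#' @param seed integer seed; identical seeds give identical output.
#' @param dest output path prefix (default a tempfile).
#' @return list with `bam` (path) and `truth` (data.frame `qname`, `class`,
#'   `expected_direct`, `expected_all`).
#' @export
simulateClassifiedReads <- function(gm, event, classCounts, readLen = 100L,
                                    mapq = 60L, seed = 1L,
                                    dest = tempfile("simreads")) {
  set.seed(seed)
  geo <- .eventGeometry(event, gm)
  kind <- if (geo$gain) "gain" else "loss"
  if (readLen < 40L) stop("read length too short for junction overhangs")
  classes <- rep(names(classCounts), times = unlist(classCounts))
  reads <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    r <- .simReadOfClass(classes[i], geo, gm, event, readLen)
    r$qname <- sprintf("sim%06d_%s", i, classes[i])
    r$mapq <- mapq
    reads[[i]] <- r
  }
  contig <- event$chrom
  contigLen <- max(end(modelExons(gm))) + 600L
  bam <- .writeSimBam(reads, contig, contigLen, dest)
  exp_ <- do.call(rbind, lapply(classes, function(cl) .TRUTH[[kind]][[cl]]))
  truth <- data.frame(
    qname = vapply(reads, `[[`, character(1L), "qname"),
    class = classes,
    expected_direct = if (length(classes)) exp_[, 1L] else character(),
    expected_all = if (length(classes)) exp_[, 2L] else character(),
    stringsAsFactors = FALSE)
  list(bam = bam, truth = truth)
}

#' Simulate reads crossing a splice event with a given abnormal fraction
#'
#' Each read crossing the evaluation position is, independently,
#' boundary-clipped with probability `clipFraction` (uninformative),
#' otherwise abnormal with probability `f` (intron retention for loss
#' events, a novel-site junction for gain events) and canonically spliced
#' otherwise.
#'
#' @inheritParams simulateClassifiedReads
#' @param depth number of reads crossing the evaluation position.
#' @param f abnormal-splicing fraction in \[0, 1\].
#' @param clipFraction fraction of boundary-clipped reads (default 0).
#' @return list with `bam`, `truth` and `n_abnormal` (realized count).
#' @export
simulateReads <- function(gm, event, depth = 200L, f = 0.3,
                          clipFraction = 0, readLen = 100L, mapq = 60L,
                          seed = 1L, dest = tempfile("simreads")) {
  stopifnot(f >= 0, f <= 1, clipFraction >= 0, clipFraction <= 1, depth > 0)
  set.seed(seed)
  u <- stats::runif(depth)
  v <- stats::runif(depth)
  cls <- ifelse(u < clipFraction, "clipped",
                ifelse(v < f,
                       ifelse(substr(event$event_type, 2L, 2L) == "L",
                              "retention", "cryptic"),
                       "canonical"))
  counts <- table(factor(cls, levels = c("canonical", "retention",
                                         "cryptic", "skip", "clipped")))
  out <- simulateClassifiedReads(gm, event, as.list(counts),
                                 readLen = readLen, mapq = mapq,
                                 seed = seed + 104729L, dest = dest)
  out$n_abnormal <- sum(cls %in% c("retention", "cryptic"))
  out
}

#' Simulate a control panel of samples
#'
#' Generates `nSamples` independent BAMs at the event locus with abnormal
#' fraction `panelF` (0 for clean panels), with per-sample seeds derived
#' from the master seed.
#'
#' @inheritParams simulateReads
#' @param nSamples panel size (default 5).
#' @param panelF abnormal fraction in the panel samples (default 0).
#' @param dir output directory.
#' @return character vector of BAM paths (empty when `nSamples` is 0).
#' @export
simulatePanels <- function(gm, event, nSamples = 5L, panelF = 0,
                           depth = 200L, readLen = 100L, seed = 1L,
                           dir = tempfile("panel")) {
  if (nSamples <= 0L) return(character())
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vapply(seq_len(nSamples), function(i) {
    simulateReads(gm, event, depth = depth, f = panelF, readLen = readLen,
                  seed = (seed + i * 7919L) %% .Machine$integer.max,
                  dest = file.path(dir, sprintf("panel%02d", i)))$bam
  }, character(1L))
}

#' Simulate mutations from a known signature mixture
#'
#' Draws each mutation's signature from the exposure weights and its SBS-96
#' context from that signature's profile, then writes the trinucleotides
#' into a miniature reference so contexts can be recomputed from sequence.
#' Half the mutations (in expectation) are emitted on the purine strand to
#' exercise the reverse-complement convention.
#'
#' @param catalog a [SignatureCatalog-class].
#' @param exposures named numeric vector of signature weights (normalized
#'   internally).
#' @param n number of mutations.
#' @param seed integer seed.
#' @param sample sample identifier (default `"S1"`).
#' @param contig reference contig name (default `"chrS"`).
#' @return list with `mutations` (data.frame `sample`, `chrom`, `pos`,
#'   `ref`, `alt`, `true_context`, `true_signature`) and `refseq` (a
#'   `DNAStringSet` with the matching miniature reference).
#' @export
simulateMutations <- function(catalog, exposures, n, seed = 1L,
                              sample = "S1", contig = "chrS") {
  sigs <- signatureNames(catalog)
  stopifnot(all(names(exposures) %in% sigs), all(exposures >= 0))
  w <- exposures / sum(exposures)
  set.seed(seed)
  if (n == 0L) {
    return(list(mutations = data.frame(
      sample = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), true_context = character(),
      true_signature = character(), stringsAsFactors = FALSE),
      refseq = Biostrings::DNAStringSet(stats::setNames("A", contig))))
  }
  sig <- base::sample(names(w), n, replace = TRUE, prob = w)
  probs <- signatureProbs(catalog)
  ctx <- vapply(sig, function(s)
    base::sample(rownames(probs), 1L, prob = probs[, s]), character(1L))
  flip <- stats::runif(n) < 0.5

  tri <- paste0(substr(ctx, 1L, 1L), substr(ctx, 3L, 3L), substr(ctx, 7L, 7L))
  alt <- substr(ctx, 5L, 5L)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  tri[flip] <- rc(tri[flip])
  alt[flip] <- rc(alt[flip])
  ref <- substr(tri, 2L, 2L)

  # triplets at 4(i-1)+1 .. 4(i-1)+3 with single-base separators
  seqchars <- rep("A", 4L * n)
  starts <- 4L * (seq_len(n) - 1L) + 1L
  for (i in seq_len(n))
    seqchars[starts[i]:(starts[i] + 2L)] <-
      strsplit(tri[i], "")[[1L]]
  refseq <- Biostrings::DNAStringSet(
    stats::setNames(paste(seqchars, collapse = ""), contig))
  list(mutations = data.frame(
    sample = sample, chrom = contig, pos = starts + 1L, ref = ref,
    alt = alt, true_context = unname(ctx), true_signature = unname(sig),
    stringsAsFactors = FALSE),
    refseq = refseq)
}

#' Write a SpliceAI-annotated VCF for simulated events
#'
#' Emits one VCF record per event with the pipe-delimited annotation
#' `ALT|GENE|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL`, offsets
#' consistent with the event's `site_pos`, and the original consequence in
#' a `CONSEQUENCE` INFO field.
#'
#' @param events data.frame from [simSpliceEvent()] (optionally with an
#'   `original_consequence` column, default `"missense"`).
#' @param path output VCF path.
#' @param contigLen contig length for the header (default 3000).
#' @return `path`, invisibly.
#' @export
simulateSpliceAIVcf <- function(events, path, contigLen = 3000L) {
  key2ds <- c(AG = "ds_ag", AL = "ds_al", DG = "ds_dg", DL = "ds_dl")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", unique(events$chrom), contigLen),
    paste0("##INFO=<ID=SpliceAI,Number=.,Type=String,Description=",
           "\"SpliceAI annotation ALT|GENE|DS_AG|DS_AL|DS_DG|DS_DL|",
           "DP_AG|DP_AL|DP_DG|DP_DL\">"),
    paste0("##INFO=<ID=CONSEQUENCE,Number=1,Type=String,",
           "Description=\"Original consequence annotation\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- vapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    ds <- c(AG = 0, AL = 0, DG = 0, DL = 0)
    dp <- c(AG = 0L, AL = 0L, DG = 0L, DL = 0L)
    ds[ev$event_type] <- ev$ds
    dp[ev$event_type] <- ev$site_pos - ev$pos
    csq <- if (!is.null(events$original_consequence))
      ev$original_consequence else "missense"
    info <- sprintf(
      "SpliceAI=%s|%s|%.2f|%.2f|%.2f|%.2f|%d|%d|%d|%d;CONSEQUENCE=%s",
      ev$alt, ev$gene, ds["AG"], ds["AL"], ds["DG"], ds["DL"],
      dp["AG"], dp["AL"], dp["DG"], dp["DL"], csq)
    paste(ev$chrom, ev$pos, ".", ev$ref, ev$alt, ".", "PASS", info,
          sep = "\t")
  }, character(1L))
  writeLines(c(hdr, body), path)
  invisible(path)
}
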
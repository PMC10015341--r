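# Shared fixtures, built in code and cached per session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

toyModel <- function(strand = "+") {
  fixture(paste0("gm", strand), function() simGeneModel(strand))
}

# two disjoint-support signatures: uniform over C>T contexts vs T>A contexts
toyCatalog <- function() {
  fixture("catalog", function() {
    ctx <- sbs96Contexts()
    a <- stats::setNames(rep(0, 96), ctx)
    a[grep("[C>T]", ctx, fixed = TRUE)] <- 1 / 16
    b <- stats::setNames(rep(0, 96), ctx)
    b[grep("[T>A]", ctx, fixed = TRUE)] <- 1 / 16
    SignatureCatalog(cbind(SIGA = a, SIGB = b))
  })
}

# independently coded RUNJ expression, including the documented conventions
# for empty denominators
oracleRunj <- function(m_a, m_n, c_a, c_n) {
  if (m_a + m_n == 0) return(NA_real_)
  cf <- if (c_a + c_n == 0) 0 else c_a / (c_a + c_n)
  m_a / (m_a + m_n) - cf
}

# rank-sum p-value by normal approximation with tie correction, coded
# independently of stats::wilcox.test
oracleRankSum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- (w - mu) / sqrt(sig2)
  2 * stats::pnorm(-abs(z))
}

# build a GAlignments object from explicit positions and cigars
makeAlignments <- function(pos, cigar, contig = "chrT", qname = NULL,
                           mapq = 60L) {
  n <- length(pos)
  ga <- GenomicAlignments::GAlignments(
    seqnames = S4Vectors::Rle(factor(rep(contig, n))),
    pos = as.integer(pos), cigar = cigar,
    strand = S4Vectors::Rle(factor(rep("+", n), levels = c("+", "-", "*"))))
  S4Vectors::mcols(ga)$qname <-
    if (is.null(qname)) paste0("r", seq_len(n)) else qname
  S4Vectors::mcols(ga)$mapq <- rep(as.integer(mapq), length.out = n)
  ga
}

# a classified-read fixture per event type and strand, cached
classifiedFixture <- function(event_type, strand = "+", n_per_class = 50L,
                              seed = 11L) {
  key <- paste("cls", event_type, strand, n_per_class, seed)
  fixture(key, function() {
    gm <- toyModel(strand)
    ev <- simSpliceEvent(gm, event_type)
    counts <- stats::setNames(rep(n_per_class, 5L),
                              c("canonical", "retention", "cryptic",
                                "skip", "clipped"))
    sim <- simulateClassifiedReads(gm, ev, counts, seed = seed)
    p <- evaluationPosition(ev, gm)
    reads <- readsCrossing(sim$bam, ev$chrom, p)
    list(gm = gm, event = ev, sim = sim, reads = reads)
  })
}
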
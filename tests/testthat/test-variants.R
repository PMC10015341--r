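mkVariant <- function(ds_ag = 0, ds_al = 0, ds_dg = 0, ds_dl = 0,
                      dp_ag = 0L, dp_al = 0L, dp_dg = 0L, dp_dl = 0L,
                      pos = 1700L, gene = "GENE1", csq = "missense") {
  data.frame(chrom = "chrT", pos = pos, ref = "A", alt = "G", gene = gene,
             ds_ag = ds_ag, ds_al = ds_al, ds_dg = ds_dg, ds_dl = ds_dl,
             dp_ag = dp_ag, dp_al = dp_al, dp_dg = dp_dg, dp_dl = dp_dl,
             original_consequence = csq, stringsAsFactors = FALSE)
}

test_that("VCF parsing maps annotation fields and skips unannotated records", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr17,length=10000000>",
    paste0("##INFO=<ID=SpliceAI,Number=.,Type=String,Description=\"x\">"),
    paste0("##INFO=<ID=CONSEQUENCE,Number=1,Type=String,Description=\"x\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr17\t7675000\t.\tC\tA\t.\tPASS\tSpliceAI=A|TP53|0.02|0.91|0.00|0.03|12|-1|3|5;CONSEQUENCE=synonymous",
    "chr17\t7675100\t.\tG\tT\t.\tPASS\tCONSEQUENCE=missense",
    "chr17\t7675200\t.\tG\tA,C\t.\tPASS\tSpliceAI=A|TP53|0.10|0|0|0|1|0|0|0,C|TP53|0.20|0|0|0|2|0|0|0"),
    vcf)
  v <- readSpliceAIVcf(vcf)
  expect_equal(nrow(v), 3L)
  expect_equal(attr(v, "n_skipped"), 1L)
  expect_equal(v$ds_al[1], 0.91)
  expect_equal(v$dp_al[1], -1L)
  expect_equal(v$original_consequence[1], "synonymous")
  expect_equal(v$alt[2:3], c("A", "C"))  # multi-allelic -> two rows
  expect_equal(v$ds_ag[3], 0.20)
})

test_that("top-event selection takes the max score with the fixed tie order", {
  v <- rbind(
    mkVariant(ds_ag = 0.10, ds_al = 0.80, ds_dg = 0.05),
    mkVariant(ds_ag = 0.60, ds_al = 0.60, ds_dg = 0.10, ds_dl = 0.10),
    mkVariant(ds_dg = 0.70, ds_dl = 0.70),
    mkVariant())  # all zero -> dropped
  e <- selectTopEvents(v)
  expect_equal(nrow(e), 3L)
  expect_equal(e$event_type, c("AL", "AL", "DL"))
  expect_equal(e$ds, c(0.80, 0.60, 0.70))
})

test_that("site position is variant position plus the matching offset", {
  v <- mkVariant(ds_dg = 0.9, dp_dg = -20L, pos = 1700L)
  e <- selectTopEvents(v)
  expect_equal(e$site_pos, 1680L)
})

test_that("significance filter is boundary-inclusive, idempotent and monotone", {
  v <- rbind(mkVariant(ds_dl = 0.49), mkVariant(ds_dl = 0.50),
             mkVariant(ds_dl = 0.90))
  e <- selectTopEvents(v)
  f5 <- filterSignificant(e, 0.5)
  expect_equal(f5$ds, c(0.50, 0.90))
  expect_equal(filterSignificant(f5, 0.5), f5)
  # monotone: higher threshold gives a subset
  f8 <- filterSignificant(e, 0.8)
  expect_true(all(f8$ds %in% f5$ds))
  expect_equal(nrow(filterSignificant(e[0, ], 0.5)), 0L)
})

test_that("relative positions follow the donor and acceptor conventions", {
  gm <- toyModel("+")
  # donor at 1700 (last exonic base of middle exon)
  dl <- function(pos) {
    e <- selectTopEvents(mkVariant(ds_dl = 0.9, pos = pos))
    relativePosition(e, gm)
  }
  expect_equal(dl(1700L), 0L)   # last exonic base
  expect_equal(dl(1705L), 5L)   # 5th intronic base
  expect_equal(dl(1698L), -2L)  # exonic
  # acceptor at 1201: -k intronic upstream, +k exonic, no 0
  al <- function(pos) {
    e <- selectTopEvents(mkVariant(ds_al = 0.9, pos = pos))
    relativePosition(e, gm)
  }
  expect_equal(al(1198L), -3L)
  expect_equal(al(1201L), 1L)
  expect_equal(al(1203L), 3L)
})

test_that("relative positions are strand-symmetric on the mirrored model", {
  gmp <- toyModel("+"); gmm <- toyModel("-")
  # minus-strand donor of the middle exon sits at genomic 1201
  em <- selectTopEvents(mkVariant(ds_dl = 0.9, pos = 1196L))
  expect_equal(relativePosition(em, gmm), 5L)   # 5th intronic base
  ep <- selectTopEvents(mkVariant(ds_dl = 0.9, pos = 1705L))
  expect_equal(relativePosition(ep, gmp), 5L)
  # minus-strand acceptor of the middle exon at genomic 1700
  am <- selectTopEvents(mkVariant(ds_al = 0.9, pos = 1703L))
  expect_equal(relativePosition(am, gmm), -3L)
})

test_that("unknown genes are flagged unresolvable and excluded from spectra", {
  gm <- toyModel("+")
  e <- selectTopEvents(rbind(mkVariant(ds_dl = 0.9, pos = 1700L),
                             mkVariant(ds_dl = 0.9, gene = "NOPE")))
  expect_equal(relativePosition(e, gm), c(0L, NA))
  sp <- positionSpectrum(e, gm)
  expect_equal(sum(sp$count), 1L)
})

test_that("position spectrum normalizes fractions within event type", {
  gm <- toyModel("+")
  v <- rbind(mkVariant(ds_dl = 0.9, pos = 1700L),
             mkVariant(ds_dl = 0.9, pos = 1700L),
             mkVariant(ds_dl = 0.9, pos = 1705L),
             mkVariant(ds_al = 0.9, pos = 1198L))
  sp <- positionSpectrum(selectTopEvents(v), gm)
  dlrows <- sp[sp$event_type == "DL", ]
  expect_equal(sum(dlrows$fraction), 1)
  expect_equal(dlrows$fraction[dlrows$rel == 0], 2 / 3)
  expect_equal(sp$fraction[sp$event_type == "AL"], 1)
  expect_equal(nrow(positionSpectrum(selectTopEvents(v)[0, ], gm)), 0L)
})

test_that("reclassification converts high-score variants and preserves splice", {
  v <- rbind(mkVariant(ds_dl = 0.91, csq = "synonymous"),
             mkVariant(ds_dl = 0.30, csq = "missense"),
             mkVariant(ds_dl = 0.10, csq = "essential-splice"),
             mkVariant(ds_ag = 0.50, csq = "intronic"))
  rc <- reclassify(v)
  expect_equal(rc, c("splice", "missense", "splice", "splice"))
  # never converts splice away; reclassified count matches ds >= t among
  # not-already-splice
  maxds <- pmax(v$ds_ag, v$ds_al, v$ds_dg, v$ds_dl)
  already <- v$original_consequence %in% c("splice", "essential-splice")
  expect_equal(sum(rc == "splice" & !already), sum(maxds >= 0.5 & !already))
})

test_that("gene splice frequencies count samples once and nest correctly", {
  mut <- data.frame(
    sample = c("s1", "s2", "s3", "s4", "s5", "s5"),
    gene = "G",
    consequence = c("essential-splice", "essential-splice", "essential-splice",
                    "synonymous", "essential-splice", "synonymous"),
    reclassified = c("splice", "splice", "splice", "splice", "splice", "splice"),
    stringsAsFactors = FALSE)
  fr <- geneSpliceFrequency(mut, c("G", "ABSENT"), cohortSize = 100)
  expect_equal(fr$freq_essential, c(0.04, 0))
  expect_equal(fr$freq_with_cryptic, c(0.05, 0))
  expect_true(all(fr$freq_with_cryptic >= fr$freq_essential))
  expect_equal(nrow(geneSpliceFrequency(mut, character(), 100)), 0L)
})
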
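test_that("SBS-96 context lookup follows the pyrimidine-strand convention", {
  refseq <- Biostrings::DNAStringSet(c(chr1 = "AACGTAGCAT"))
  # G at position 4 with flanks C_T: reverse-complemented to A[C>T]G
  expect_equal(contextOf("chr1", 4, "G", "A", refseq), "A[C>T]G")
  # direct pyrimidine case: C>T with flanks A-G
  refseq2 <- Biostrings::DNAStringSet(c(chr1 = "TACGT"))
  expect_equal(contextOf("chr1", 3, "C", "T", refseq2), "A[C>T]G")
  # purine ref: G>A with flanks A_C -> reverse-complemented G[C>T]T
  refseq3 <- Biostrings::DNAStringSet(c(chr1 = "TAGCT"))
  expect_equal(contextOf("chr1", 3, "G", "A", refseq3), "G[C>T]T")
  # rejects non-SNVs and reference mismatches
  expect_error(contextOf("chr1", 3, "T", "T", refseq3), "single-nucleotide")
  expect_error(contextOf("chr1", 3, "GA", "G", refseq3), "single-nucleotide")
  expect_error(contextOf("chr1", 3, "C", "T", refseq3), "mismatch")
})

test_that("catalog constructor validates and normalizes columns", {
  expect_length(sbs96Contexts(), 96L)
  expect_false(anyDuplicated(sbs96Contexts()) > 0)
  cat_ <- toyCatalog()
  expect_equal(unname(colSums(signatureProbs(cat_))), c(1, 1))
  bad <- matrix(1, nrow = 95, ncol = 1)
  expect_error(SignatureCatalog(bad))
})

test_that("catalog TSV round trip", {
  cat_ <- toyCatalog()
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(Type = rownames(signatureProbs(cat_)),
                   signatureProbs(cat_), check.names = FALSE)
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  cat2 <- readSignatureCatalog(tsv)
  expect_equal(signatureProbs(cat2), signatureProbs(cat_))
})

test_that("attribution arithmetic: identity and two-signature cases", {
  ctx <- sbs96Contexts()
  # two signatures with mass 0.2 / 0.1 on the same context
  p1 <- stats::setNames(rep(0, 96), ctx); p1["A[C>T]G"] <- 0.2
  p1[ctx != "A[C>T]G"] <- 0.8 / 95
  p2 <- stats::setNames(rep(0, 96), ctx); p2["A[C>T]G"] <- 0.1
  p2[ctx != "A[C>T]G"] <- 0.9 / 95
  cat_ <- SignatureCatalog(cbind(S1 = p1, S2 = p2))
  mut <- data.frame(sample = "s", chrom = "c", pos = 1L, ref = "C",
                    alt = "T", context = "A[C>T]G", splice = TRUE)
  # equal exposures: posterior proportional to context probabilities
  at <- attributeMutations(mut, data.frame(sample = "s", S1 = 0.5, S2 = 0.5),
                           cat_)
  expect_equal(unname(attributionProbs(at)[1, ]), c(2 / 3, 1 / 3))
  # all exposure on one signature -> P = 1 on it
  at1 <- attributeMutations(mut, data.frame(sample = "s", S1 = 1, S2 = 0),
                            cat_)
  expect_equal(unname(attributionProbs(at1)[1, ]), c(1, 0))
})

test_that("unattributable mutations are excluded with a message", {
  ctx <- sbs96Contexts()
  p1 <- stats::setNames(rep(0, 96), ctx)
  p1[grep("[C>T]", ctx, fixed = TRUE)] <- 1 / 16
  cat_ <- SignatureCatalog(cbind(S1 = p1))
  mut <- data.frame(sample = "s", chrom = "c", pos = 1:2, ref = "C",
                    alt = c("T", "A"),
                    context = c("A[C>T]G", "A[C>A]G"), splice = FALSE)
  expect_message(
    at <- attributeMutations(mut, data.frame(sample = "s", S1 = 1), cat_),
    "unattributable")
  expect_equal(nrow(attributionProbs(at)), 1L)
})

test_that("attribution rows are stochastic and contributions conserve", {
  cat_ <- toyCatalog()
  sim <- simulateMutations(cat_, c(SIGA = 0.6, SIGB = 0.4), n = 400,
                           seed = 21)
  mut <- sim$mutations
  mut$splice <- seq_len(nrow(mut)) %% 3 == 0
  at <- attributeMutations(mut, data.frame(sample = "S1", SIGA = 0.6,
                                           SIGB = 0.4), cat_,
                           refseq = sim$refseq)
  expect_equal(max(abs(rowSums(attributionProbs(at)) - 1)), 0)
  total <- signatureContribution(at)
  expect_equal(unname(sum(total)), nrow(attributionProbs(at)))
  sp <- signatureContribution(at, spliceFlag(at))
  ot <- signatureContribution(at, !spliceFlag(at))
  expect_equal(sp + ot, total)
  expect_equal(unname(signatureContribution(at, integer(0))), c(0, 0))
})

test_that("context recomputation from the simulated reference matches truth", {
  cat_ <- toyCatalog()
  sim <- simulateMutations(cat_, c(SIGA = 0.5, SIGB = 0.5), n = 300,
                           seed = 31)
  got <- vapply(seq_len(nrow(sim$mutations)), function(i)
    contextOf(sim$mutations$chrom[i], sim$mutations$pos[i],
              sim$mutations$ref[i], sim$mutations$alt[i], sim$refseq),
    character(1))
  expect_equal(got, sim$mutations$true_context)
})

test_that("enrichment test agrees with an independent rank-sum computation", {
  set.seed(77)
  n <- 80
  p1 <- c(stats::rbeta(n, 2, 2), stats::rbeta(n, 4, 2))  # shifted groups
  at <- new("MutationAttribution",
            probs = cbind(S1 = p1, S2 = 1 - p1),
            splice = rep(c(TRUE, FALSE), each = n),
            mutations = data.frame(i = seq_len(2 * n)))
  res <- enrichmentTest(at)
  oracle <- oracleRankSum(p1[1:n], p1[(n + 1):(2 * n)])
  expect_lt(res$p_value[res$signature == "S1"], 0.05)
  expect_equal(res$p_value[res$signature == "S1"], oracle,
               tolerance = 0.02)
  expect_equal(res$direction, c(-1, 1))
})

test_that("enrichment test handles single observations and empty groups", {
  at <- new("MutationAttribution",
            probs = cbind(S1 = c(0.3, 0.7), S2 = c(0.7, 0.3)),
            splice = c(TRUE, FALSE),
            mutations = data.frame(i = 1:2))
  res <- enrichmentTest(at)  # closed form on 2 observations: p = 1
  expect_equal(res$p_value, c(1, 1))
  expect_true(all(is.finite(res$p_value)))
  at0 <- new("MutationAttribution",
             probs = cbind(S1 = c(0.5, 0.5), S2 = c(0.5, 0.5)),
             splice = c(TRUE, TRUE), mutations = data.frame(i = 1:2))
  expect_true(all(is.na(enrichmentTest(at0)$p_value)))
})

test_that("mixture recovery: contributions match the generating exposures", {
  cat_ <- toyCatalog()
  n <- 2000
  sim <- simulateMutations(cat_, c(SIGA = 0.7, SIGB = 0.3), n = n, seed = 41)
  mut <- sim$mutations
  mut$splice <- FALSE
  at <- attributeMutations(mut, data.frame(sample = "S1", SIGA = 0.7,
                                           SIGB = 0.3), cat_,
                           refseq = sim$refseq)
  est <- signatureContribution(at)[["SIGA"]] / n
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(est - 0.7), 3 * se)
})
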
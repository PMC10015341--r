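#' Parse SpliceAI-annotated variants from a VCF
#'
#' Reads a VCF and extracts per-variant delta scores and positional offsets
#' from a SpliceAI-style INFO field with pipe-delimited subfields
#' `ALT|GENE|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL`. One row is
#' produced per annotated ALT x gene combination; records lacking the
#' annotation are skipped and counted.
#'
#' @param path VCF file (plain or bgzipped).
#' @param key INFO key holding the annotation (default `"SpliceAI"`).
#' @param consequenceKey optional INFO key with the variant's original
#'   consequence category (e.g. missense, synonymous); `NA` when absent.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   the four delta scores `ds_ag`, `ds_al`, `ds_dg`, `ds_dl`, the four
#'   offsets `dp_ag`, `dp_al`, `dp_dg`, `dp_dl` and
#'   `original_consequence`. The number of records skipped for lack of the
#'   annotation is attached as attribute `"n_skipped"`.
#' @export
readSpliceAIVcf <- function(path, key = "SpliceAI", consequenceKey = "CONSEQUENCE") {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  if (!key %in% colnames(info))
    stop("INFO key '", key, "' not declared in VCF header")
  ann <- info[[key]]
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(seqnames(rr))
  pos <- start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  csq <- if (consequenceKey %in% colnames(info))
    as.character(info[[consequenceKey]]) else rep(NA_character_, length(rr))

  rows <- list()
  n_skipped <- 0L
  for (i in seq_along(rr)) {
    entries <- ann[[i]]
    entries <- entries[!is.na(entries) & nzchar(entries)]
    if (!length(entries)) { n_skipped <- n_skipped + 1L; next }
    for (e in entries) {
      f <- strsplit(e, "|", fixed = TRUE)[[1L]]
      if (length(f) != 10L) {
        warning("malformed ", key, " annotation at ", chrom[i], ":", pos[i],
                " ('", e, "'); record skipped")
        next
      }
      num <- suppressWarnings(as.numeric(f[3:10]))
      if (anyNA(num)) {
        warning("non-numeric ", key, " fields at ", chrom[i], ":", pos[i],
                "; record skipped")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom[i], pos = pos[i], ref = ref[i], alt = f[1L],
        gene = f[2L],
        ds_ag = num[1L], ds_al = num[2L], ds_dg = num[3L], ds_dl = num[4L],
        dp_ag = as.integer(num[5L]), dp_al = as.integer(num[6L]),
        dp_dg = as.integer(num[7L]), dp_dl = as.integer(num[8L]),
        original_consequence = csq[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .emptyVariants()
  rownames(out) <- NULL
  if (n_skipped)
    message(n_skipped, " record(s) without ", key, " annotation skipped")
  attr(out, "n_skipped") <- n_skipped
  out
}

.emptyVariants <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene = character(),
             ds_ag = numeric(), ds_al = numeric(), ds_dg = numeric(),
             ds_dl = numeric(), dp_ag = integer(), dp_al = integer(),
             dp_dg = integer(), dp_dl = integer(),
             original_consequence = character(), stringsAsFactors = FALSE)
}

# fixed tie-break order for equal maximal delta scores
.EVENT_ORDER <- c("AL", "DL", "AG", "DG")

#' Select the strongest predicted splice event per variant
#'
#' For each variant the maximal delta score across the four event types
#' (acceptor loss/gain, donor loss/gain) is retained, together with the
#' genomic position of the affected or created splice site
#' (`site_pos = pos + offset`). Ties on the maximal score are broken by the
#' fixed order AL > DL > AG > DG. Variants whose four scores are all zero
#' yield no event.
#'
#' @param variants data.frame as returned by [readSpliceAIVcf()].
#' @param gm optional [GeneModel-class]; when supplied, each event is
#'   annotated with the transcript strand and the nearest canonical
#'   exon-intron boundary of the matching kind (donor for DL/DG, acceptor
#'   for AL/AG); events whose gene is absent from the model get `NA`.
#' @return data.frame of events: variant columns plus `event_type`, `ds`,
#'   `site_pos`, and (with `gm`) `strand` and `boundary`.
#' @export
selectTopEvents <- function(variants, gm = NULL) {
  ds <- as.matrix(variants[, c("ds_al", "ds_dl", "ds_ag", "ds_dg")])
  dp <- as.matrix(variants[, c("dp_al", "dp_dl", "dp_ag", "dp_dg")])
  keep <- nrow(variants) > 0 & apply(ds, 1L, max) > 0
  idx <- apply(ds, 1L, which.max)  # first max = tie-break order AL>DL>AG>DG
  ev <- variants[keep, , drop = FALSE]
  ev$event_type <- .EVENT_ORDER[idx[keep]]
  ev$ds <- ds[cbind(seq_len(nrow(variants)), idx)][keep]
  ev$site_pos <- ev$pos + dp[cbind(seq_len(nrow(variants)), idx)][keep]
  rownames(ev) <- NULL
  if (!is.null(gm) && nrow(ev)) {
    ann <- t(vapply(seq_len(nrow(ev)), function(i) {
      .nearestBoundary(gm, ev$gene[i], ev$site_pos[i], ev$event_type[i])
    }, c(boundary = NA_real_, strandSign = NA_real_)))
    ev$strand <- ifelse(is.na(ann[, "strandSign"]), NA,
                        ifelse(ann[, "strandSign"] > 0, "+", "-"))
    ev$boundary <- as.integer(ann[, "boundary"])
  }
  ev
}

# nearest canonical donor (D events) or acceptor (A events) boundary to a
# genomic position; returns c(boundary, strandSign) or NAs if unresolvable
.nearestBoundary <- function(gm, gene, pos, event_type) {
  if (!gene %in% modelGenes(gm)) return(c(NA_real_, NA_real_))
  sites <- if (substr(event_type, 1L, 1L) == "D")
    donorSites(gm, gene) else acceptorSites(gm, gene)
  if (!length(sites)) return(c(NA_real_, NA_real_))
  b <- sites[which.min(abs(sites - pos))]
  c(b, if (geneStrand(gm, gene) == "+") 1 else -1)
}

#' Keep events with a significant splicing impact
#'
#' Retains events whose delta score is at least `threshold` (default 0.5,
#' inclusive), preserving order.
#'
#' @param events data.frame from [selectTopEvents()].
#' @param threshold delta-score cutoff in \[0, 1\].
#' @export
filterSignificant <- function(events, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  events[events$ds >= threshold, , drop = FALSE]
}

#' Position of the mutated base relative to the closest essential splice site
#'
#' Donor-relative coordinates (DL/DG events): 0 is the last exonic base and
#' +k the k-th intronic base; negative values are exonic. Acceptor-relative
#' coordinates (AL/AG): -k is the k-th intronic base upstream and +k the
#' k-th exonic base; there is no 0. Both are strand-aware (positions advance
#' in transcript orientation).
#'
#' @param events data.frame from [selectTopEvents()] (needs `gene`, `pos`,
#'   `event_type`).
#' @param gm a [GeneModel-class].
#' @return integer vector of relative positions, `NA` where the gene is
#'   absent from the model (such events are excluded from spectra).
#' @export
relativePosition <- function(events, gm) {
  vapply(seq_len(nrow(events)), function(i) {
    ann <- .nearestBoundary(gm, events$gene[i], events$pos[i],
                            events$event_type[i])
    if (is.na(ann[1L])) return(NA_integer_)
    d <- as.integer(ann[2L] * (events$pos[i] - ann[1L]))
    if (substr(events$event_type[i], 1L, 1L) == "D") d
    else if (d >= 0L) d + 1L else d
  }, integer(1L))
}

#' Tabulate the position spectrum of splice events
#'
#' Counts events by type and position relative to the closest essential
#' splice site; fractions are normalized within each event type over
#' resolvable positions.
#'
#' @inheritParams relativePosition
#' @return data.frame with columns `event_type`, `rel`, `count`, `fraction`.
#' @export
positionSpectrum <- function(events, gm) {
  if (!nrow(events))
    return(data.frame(event_type = character(), rel = integer(),
                      count = integer(), fraction = numeric()))
  rel <- relativePosition(events, gm)
  ok <- !is.na(rel)
  if (!any(ok))
    return(data.frame(event_type = character(), rel = integer(),
                      count = integer(), fraction = numeric()))
  tab <- stats::aggregate(list(count = rep(1L, sum(ok))),
                   by = list(event_type = events$event_type[ok], rel = rel[ok]),
                   FUN = sum)
  tab <- tab[order(tab$event_type, tab$rel), , drop = FALSE]
  totals <- tapply(tab$count, tab$event_type, sum)
  tab$fraction <- tab$count / as.numeric(totals[tab$event_type])
  rownames(tab) <- NULL
  tab
}

.ESSENTIAL_SPLICE <- c("splice", "essential-splice", "essential_splice",
                       "splice_acceptor_variant", "splice_donor_variant")

#' Reclassify variant consequences using predicted splice impact
#'
#' Variants whose maximal delta score reaches `threshold` are converted to
#' the `"splice"` category regardless of their original annotation (e.g. a
#' synonymous variant that disrupts the adjacent donor); essential-splice
#' annotations remain `"splice"` regardless of score. All other variants
#' keep their original category.
#'
#' @param variants data.frame from [readSpliceAIVcf()].
#' @param threshold delta-score cutoff (default 0.5).
#' @return character vector of reclassified consequence categories.
#' @export
reclassify <- function(variants, threshold = 0.5) {
  maxds <- do.call(pmax, variants[c("ds_ag", "ds_al", "ds_dg", "ds_dl")])
  ifelse(maxds >= threshold |
           variants$original_consequence %in% .ESSENTIAL_SPLICE,
         "splice", variants$original_consequence)
}

#' Per-gene splice mutation frequency with and without cryptic events
#'
#' For each gene, the fraction of cohort samples carrying at least one
#' splice mutation, under two definitions: essential splice annotations
#' only, or essential plus cryptic splice mutations (reclassified by
#' predicted impact). A sample carrying both is counted once.
#'
#' @param mutations data.frame with columns `sample`, `gene`,
#'   `consequence` (original annotation) and `reclassified` (output of
#'   [reclassify()]).
#' @param genes character vector of genes to tabulate.
#' @param cohortSize number of samples in the cohort.
#' @return data.frame with columns `gene`, `freq_essential`,
#'   `freq_with_cryptic`; genes absent from the table get frequency 0.
#' @export
geneSpliceFrequency <- function(mutations, genes, cohortSize) {
  stopifnot(cohortSize > 0)
  out <- lapply(genes, function(g) {
    m <- mutations[mutations$gene == g, , drop = FALSE]
    ess <- unique(m$sample[m$consequence %in% .ESSENTIAL_SPLICE])
    all <- unique(m$sample[m$reclassified == "splice"])
    data.frame(gene = g,
               freq_essential = length(ess) / cohortSize,
               freq_with_cryptic = length(union(ess, all)) / cohortSize)
  })
  if (!length(out))
    return(data.frame(gene = character(), freq_essential = numeric(),
                      freq_with_cryptic = numeric()))
  do.call(rbind, out)
}
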
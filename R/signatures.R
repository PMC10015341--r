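#' The 96 SBS trinucleotide-context labels
#'
#' Standard single-base-substitution classes in pyrimidine-strand
#' convention, labelled like `"A[C>T]G"`, ordered by substitution
#' (C>A, C>G, C>T, T>A, T>C, T>G) then alphabetically by flanks.
#'
#' @return character vector of length 96.
#' @export
sbs96Contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  fl <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(fl, fl, function(a, b)
      paste0(a, "[", s, "]", b))))))
}

#' Read a COSMIC-style SBS-96 signature catalog
#'
#' Expects a TSV whose first column holds the 96 bracketed context labels
#' (e.g. `"A[C>T]G"`) and one column per signature. Columns are
#' normalized to sum to 1.
#'
#' @param path TSV file.
#' @return a [SignatureCatalog-class].
#' @export
readSignatureCatalog <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ctx <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- ctx
  SignatureCatalog(m)
}

#' Construct a SignatureCatalog from a matrix
#'
#' @param probs 96 x S matrix of context probabilities; rownames must be
#'   the labels of [sbs96Contexts()]. Columns are renormalized to sum to 1.
#' @return a [SignatureCatalog-class].
#' @export
SignatureCatalog <- function(probs) {
  probs <- probs[sbs96Contexts(), , drop = FALSE]
  probs <- sweep(probs, 2L, colSums(probs), "/")
  new("SignatureCatalog", probs = probs)
}

#' @rdname SignatureCatalog-class
#' @export
setMethod("signatureNames", "SignatureCatalog", function(x) colnames(x@probs))

#' @rdname SignatureCatalog-class
#' @export
setMethod("signatureProbs", "SignatureCatalog", function(x) x@probs)

setMethod("show", "SignatureCatalog", function(object) {
  cat("SignatureCatalog with", ncol(object@probs), "signature(s):",
      paste(colnames(object@probs), collapse = ", "), "\n")
})

#' SBS-96 context of a single-nucleotide substitution
#'
#' Looks up the trinucleotide around the mutated base in the reference and
#' returns the substitution class in pyrimidine-strand convention: when the
#' reference base is a purine, trinucleotide and alternate allele are
#' reverse-complemented.
#'
#' @param chrom,pos,ref,alt the mutation (1-based position; single-base
#'   `ref`/`alt`).
#' @param refseq a named `DNAStringSet` (e.g. from
#'   [Biostrings::readDNAStringSet()]) covering `chrom`.
#' @return context label, e.g. `"A[C>T]G"`; an error if `ref` does not
#'   match the reference sequence; `NA` for non-SNV input is not produced
#'   (indels are rejected with an error).
#' @export
contextOf <- function(chrom, pos, ref, alt, refseq) {
  if (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt)
    stop("only single-nucleotide substitutions have an SBS-96 context")
  seqnames_ <- sub(" .*", "", names(refseq))
  k <- match(chrom, seqnames_)
  if (is.na(k)) stop("contig '", chrom, "' not in reference")
  tri <- as.character(Biostrings::subseq(refseq[[k]], pos - 1L, pos + 1L))
  if (substr(tri, 2L, 2L) != ref)
    stop("reference mismatch at ", chrom, ":", pos, " (expected ", ref,
         ", found ", substr(tri, 2L, 2L), ")")
  if (ref %in% c("A", "G")) {
    tri <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tri)))
    alt <- as.character(Biostrings::complement(Biostrings::DNAString(alt)))
  }
  paste0(substr(tri, 1L, 1L), "[", substr(tri, 2L, 2L), ">", alt, "]",
         substr(tri, 3L, 3L))
}

#' Attribute mutations to signatures given per-sample exposures
#'
#' For each mutation m in context c carried by sample j, the posterior
#' probability that signature s generated it is
#' \deqn{P(s \mid m) = \frac{e_{j,s} f_s(c)}{\sum_{s'} e_{j,s'} f_{s'}(c)}}
#' with `e` the sample's exposures and `f` the catalog context
#' probabilities. Mutations with an all-zero denominator are flagged
#' unattributable and excluded (with a message).
#'
#' @param mutations data.frame with columns `sample`, `chrom`, `pos`,
#'   `ref`, `alt` and a splice indicator: either logical `splice`, or
#'   `consequence`/`reclassified` columns from which splice status is
#'   derived (essential splice or reclassified cryptic splice).
#' @param exposures data.frame of per-sample signature activities: column
#'   `sample` plus one column per signature; rows are renormalized to sum
#'   to 1.
#' @param catalog a [SignatureCatalog-class].
#' @param refseq named `DNAStringSet` reference for context lookup, or
#'   `NULL` if `mutations` already has a `context` column.
#' @return a [MutationAttribution-class].
#' @export
attributeMutations <- function(mutations, exposures, catalog, refseq = NULL) {
  sigs <- signatureNames(catalog)
  if (!all(sigs %in% colnames(exposures)))
    stop("exposures must have one column per catalog signature")
  em <- as.matrix(exposures[, sigs, drop = FALSE])
  rownames(em) <- exposures$sample
  em <- em / rowSums(em)

  if (is.null(mutations$context)) {
    if (is.null(refseq)) stop("need a reference sequence or a context column")
    mutations$context <- vapply(seq_len(nrow(mutations)), function(i)
      contextOf(mutations$chrom[i], mutations$pos[i], mutations$ref[i],
                mutations$alt[i], refseq), character(1L))
  }
  splice <- if (!is.null(mutations$splice)) as.logical(mutations$splice)
  else (mutations$consequence %in% .ESSENTIAL_SPLICE |
          mutations$reclassified == "splice")

  f <- signatureProbs(catalog)[mutations$context, , drop = FALSE]
  e <- em[mutations$sample, , drop = FALSE]
  w <- e * f
  denom <- rowSums(w)
  ok <- denom > 0
  if (any(!ok))
    message(sum(!ok), " mutation(s) unattributable (zero mass on context)")
  probs <- w[ok, , drop = FALSE] / denom[ok]
  dimnames(probs) <- list(NULL, sigs)
  new("MutationAttribution", probs = probs, splice = splice[ok],
      mutations = mutations[ok, , drop = FALSE])
}

#' @rdname MutationAttribution-class
#' @export
setMethod("attributionProbs", "MutationAttribution", function(x) x@probs)

#' @rdname MutationAttribution-class
#' @export
setMethod("spliceFlag", "MutationAttribution", function(x) x@splice)

#' @rdname MutationAttribution-class
#' @export
setMethod("mutationInfo", "MutationAttribution", function(x) x@mutations)

setMethod("show", "MutationAttribution", function(object) {
  cat("MutationAttribution:", nrow(object@probs), "mutation(s) x",
      ncol(object@probs), "signature(s);", sum(object@splice),
      "splice mutation(s)\n")
})

#' Contribution of each signature to a mutation subset
#'
#' The contribution of signature s to a set of mutations is the sum of the
#' per-mutation probabilities \eqn{\sum_{m \in S} P(m, s)}. Contributions
#' over all signatures total the subset size.
#'
#' @param attr a [MutationAttribution-class].
#' @param subset logical or integer index of mutations (default: all).
#' @return named numeric vector, one entry per signature.
#' @export
signatureContribution <- function(attr, subset = NULL) {
  p <- attributionProbs(attr)
  if (!is.null(subset)) p <- p[subset, , drop = FALSE]
  colSums(p)
}

#' Test signatures for enrichment in splice mutations
#'
#' For each signature, compares the distribution of per-mutation
#' probabilities P(m, s) between splice mutations and other mutations with
#' a two-sided Wilcoxon rank-sum test. Direction is the sign of the median
#' difference (splice minus other). Raw p-values are reported; a
#' Benjamini-Hochberg adjusted column is added for convenience.
#'
#' @param attr a [MutationAttribution-class].
#' @return data.frame with columns `signature`, `p_value`, `direction`
#'   (+1/-1/0) and `p_adjust`; all-`NA` rows when either group is empty.
#' @export
enrichmentTest <- function(attr) {
  p <- attributionProbs(attr)
  sp <- spliceFlag(attr)
  sigs <- colnames(p)
  if (!any(sp) || all(sp)) {
    out <- data.frame(signature = sigs, p_value = NA_real_,
                      direction = NA_real_, p_adjust = NA_real_)
    return(out)
  }
  res <- lapply(sigs, function(s) {
    x <- p[sp, s]; y <- p[!sp, s]
    pv <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    data.frame(signature = s, p_value = pv,
               direction = sign(stats::median(x) - stats::median(y)))
  })
  out <- do.call(rbind, res)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
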
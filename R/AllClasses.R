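#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' GeneModel: exon structures and the canonical junction set
#'
#' Holds the exon intervals of one or more transcripts and the intron set
#' derived from them. Introns are the gaps between consecutive exons of a
#' transcript; the unique set of introns across transcripts is the canonical
#' junction set used to decide whether a split read is normally spliced.
#' For each gene one transcript is designated canonical (the flagged one if
#' the annotation carries a `canonical` attribute, otherwise the transcript
#' with the largest summed exon width); splice-site boundaries for
#' position-relative coordinates are taken from that transcript.
#'
#' @slot exons GRanges of exons with metadata columns `gene` and `transcript`.
#' @slot introns GRanges of unique introns with metadata columns `gene` and
#'   `transcript` (the transcript each intron was first seen in).
#' @slot canonicalTx named character vector, canonical transcript per gene.
#'
#' @seealso [makeGeneModel()], [readGeneModel()], [canonicalJunctions()]
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    exons = "GRanges",
    introns = "GRanges",
    canonicalTx = "character"
  )
)

setValidity("GeneModel", function(object) {
  msg <- NULL
  need <- c("gene", "transcript")
  if (!all(need %in% colnames(mcols(object@exons))))
    msg <- c(msg, "exons must carry 'gene' and 'transcript' metadata columns")
  if (!all(need %in% colnames(mcols(object@introns))))
    msg <- c(msg, "introns must carry 'gene' and 'transcript' metadata columns")
  if (length(object@introns) && any(width(object@introns) < 1))
    msg <- c(msg, "introns must have width >= 1")
  if (length(object@exons) && any(strand(object@exons) == "*"))
    msg <- c(msg, "exon strand must be '+' or '-'")
  genes <- unique(mcols(object@exons)$gene)
  if (!all(genes %in% names(object@canonicalTx)))
    msg <- c(msg, "every gene needs a canonical transcript")
  if (is.null(msg)) TRUE else msg
})

#' SignatureCatalog: SBS-96 mutational signature profiles
#'
#' A matrix of 96 trinucleotide-context probabilities per signature,
#' COSMIC-style. Rows are the 96 substitution classes (labels like
#' `"A[C>T]G"`, pyrimidine-strand convention), columns are signatures, and
#' each column sums to 1.
#'
#' @slot probs numeric matrix, 96 x n_signatures; rownames are context
#'   labels, colnames are signature names.
#'
#' @seealso [readSignatureCatalog()], [sbs96Contexts()]
#' @exportClass SignatureCatalog
setClass("SignatureCatalog", representation(probs = "matrix"))

setValidity("SignatureCatalog", function(object) {
  p <- object@probs
  msg <- NULL
  if (nrow(p) != 96L)
    msg <- c(msg, "catalog must have exactly 96 context rows")
  if (is.null(rownames(p)) || !setequal(rownames(p), sbs96Contexts()))
    msg <- c(msg, "rownames must be the 96 SBS context labels")
  if (is.null(colnames(p)) || anyDuplicated(colnames(p)))
    msg <- c(msg, "signatures must have unique names")
  if (any(p < 0))
    msg <- c(msg, "probabilities must be non-negative")
  if (ncol(p) && any(abs(colSums(p) - 1) > 1e-6))
    msg <- c(msg, "each signature must sum to 1 (tolerance 1e-6)")
  if (is.null(msg)) TRUE else msg
})

#' MutationAttribution: per-mutation signature probabilities
#'
#' Row-stochastic matrix of posterior probabilities P(m, s) that mutation m
#' arose from signature s, given the sample's signature exposures, together
#' with a per-mutation splice flag (essential or cryptic splice vs other).
#'
#' @slot probs numeric matrix, mutations x signatures; every row sums to 1.
#' @slot splice logical vector, one entry per mutation.
#' @slot mutations data.frame of the attributed mutations (one row per
#'   matrix row; at least `sample`, `chrom`, `pos`, `ref`, `alt`, `context`).
#'
#' @seealso [attributeMutations()], [signatureContribution()],
#'   [enrichmentTest()]
#' @exportClass MutationAttribution
setClass("MutationAttribution",
  representation(probs = "matrix", splice = "logical", mutations = "data.frame")
)

setValidity("MutationAttribution", function(object) {
  msg <- NULL
  n <- nrow(object@probs)
  if (length(object@splice) != n)
    msg <- c(msg, "splice flag must have one entry per mutation")
  if (nrow(object@mutations) != n)
    msg <- c(msg, "mutation table must have one row per matrix row")
  if (any(object@probs < 0) || any(object@probs > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (n && any(abs(rowSums(object@probs) - 1) > 1e-9))
    msg <- c(msg, "every row must sum to 1 (tolerance 1e-9)")
  if (is.null(msg)) TRUE else msg
})
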
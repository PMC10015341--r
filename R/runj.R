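#' Relative Usage of the Novel Junction (RUNJ)
#'
#' RUNJ contrasts the abnormal-read fraction at a predicted splice event in
#' the mutated sample with the pooled fraction in a control panel:
#' \deqn{RUNJ = \frac{\#M_a}{\#M_a + \#M_n} - \frac{\#C_a}{\#C_a + \#C_n}}
#' where \eqn{M_a}/\eqn{M_n} are abnormal/normal informative reads in the
#' mutated sample and \eqn{C_a}/\eqn{C_n} the pooled counts across the
#' control samples.
#'
#' With no informative tumor coverage (`m_a + m_n == 0`) the score is `NA`.
#' With no control coverage the control fraction is taken as 0 and the
#' result flagged (attribute `"low_control_coverage"`), so sparsely covered
#' loci remain assessable but auditable.
#'
#' @param m_a,m_n abnormal/normal read counts in the mutated sample.
#' @param c_a,c_n pooled abnormal/normal counts in the control panel.
#' @return numeric vector of RUNJ scores in \[-1, 1\] (or `NA`), with the
#'   logical attribute `low_control_coverage`.
#' @examples
#' runj(12, 88, 0, 100)   # 0.12
#' runj(30, 70, 5, 95)    # 0.25
#' @export
runj <- function(m_a, m_n, c_a, c_n) {
  if (any(c(m_a, m_n, c_a, c_n) < 0)) stop("counts must be non-negative")
  md <- m_a + m_n
  cd <- c_a + c_n
  lowc <- cd == 0
  cf <- ifelse(lowc, 0, c_a / ifelse(cd == 0, 1, cd))
  out <- ifelse(md == 0, NA_real_, m_a / ifelse(md == 0, 1, md) - cf)
  attr(out, "low_control_coverage") <- lowc
  out
}

#' Assemble a panel of tumors unmutated at a locus
#'
#' Selects up to `size` tumor samples from the same series that carry no
#' somatic mutation at the event locus, in a seeded deterministic order.
#'
#' @param tumors character vector of candidate tumor sample names.
#' @param locus `c(contig, pos)` of the event's variant.
#' @param mutationTable data.frame with columns `sample`, `chrom`, `pos`
#'   listing somatic mutations per sample.
#' @param size target panel size (default 5).
#' @param seed integer seed fixing the selection order.
#' @return character vector of panel samples with logical attribute
#'   `undersized`, or `NULL` when no tumor is eligible (the panel-of-tumors
#'   criterion is then not applicable).
#' @export
buildPOT <- function(tumors, locus, mutationTable, size = 5L, seed = 1L) {
  mutated <- unique(mutationTable$sample[
    mutationTable$chrom == locus[[1L]] &
      mutationTable$pos == as.integer(locus[[2L]])])
  eligible <- setdiff(tumors, mutated)
  if (!length(eligible)) return(NULL)
  eligible <- sort(eligible)
  set.seed(seed)
  eligible <- sample(eligible)
  panel <- eligible[seq_len(min(size, length(eligible)))]
  attr(panel, "undersized") <- length(panel) < size
  panel
}

#' Apply the validation criteria to one event's scores
#'
#' A prediction is validated if and only if (i) at least `minReads` reads
#' support the abnormal event in the mutated sample, (ii) RUNJ against the
#' panel of normals reaches `minRunj` in direct or all mode, and (iii) RUNJ
#' against the panel of tumors reaches `minRunj` in direct or all mode, or
#' the panel of tumors is not applicable (no eligible/covered tumor).
#'
#' @param m_a abnormal read count in the mutated sample (all mode).
#' @param runj_direct_pon,runj_all_pon,runj_direct_pot,runj_all_pot the four
#'   RUNJ scores (`NA` allowed).
#' @param pot_applicable logical; `FALSE` when no panel of tumors exists or
#'   it has no informative coverage at the event.
#' @param minReads minimum abnormal read support (default 2).
#' @param minRunj minimum RUNJ (default 0.01), applied to the signed value.
#' @return list with `validated` (logical) and `reasons` (named logical
#'   vector of the three criteria).
#' @export
validateDecision <- function(m_a, runj_direct_pon, runj_all_pon,
                             runj_direct_pot, runj_all_pot,
                             pot_applicable = TRUE,
                             minReads = 2L, minRunj = 0.01) {
  ge <- function(x) !is.na(x) && x >= minRunj
  crit_reads <- !is.na(m_a) && m_a >= minReads
  crit_pon <- ge(runj_direct_pon) || ge(runj_all_pon)
  crit_pot <- !pot_applicable || ge(runj_direct_pot) || ge(runj_all_pot)
  list(validated = crit_reads && crit_pon && crit_pot,
       reasons = c(reads = crit_reads, pon = crit_pon, pot = crit_pot))
}

# classify + count one sample's reads at an event, both modes
.sampleCounts <- function(bam, event, gm, p, contig, minMapq) {
  reads <- readsCrossing(bam, contig, p, minMapq = minMapq)
  direct <- countCalls(classifyReads(reads, event, gm, mode = "direct"))
  all <- countCalls(classifyReads(reads, event, gm, mode = "all"))
  list(direct = direct, all = all)
}

.poolCounts <- function(bams, event, gm, p, contig, minMapq) {
  if (inherits(bams, "runjPanelCounts")) return(bams)
  acc <- list(direct = c(n_abnormal = 0L, n_normal = 0L),
              all = c(n_abnormal = 0L, n_normal = 0L))
  for (b in bams) {
    one <- .sampleCounts(b, event, gm, p, contig, minMapq)
    acc$direct <- acc$direct + one$direct
    acc$all <- acc$all + one$all
  }
  acc
}

#' Pool a control panel's read counts at one event
#'
#' Classifies and tallies each panel sample's reads at the event's
#' evaluation position and sums the counts (the pooled `C_a`/`C_n` pair of
#' the RUNJ formula). The result can be passed to [validateCohort()] in
#' place of the BAM paths when the same panel is reused across many
#' mutated samples.
#'
#' @inheritParams validateCohort
#' @param bams character vector of panel BAM paths.
#' @param event one event row.
#' @return a `runjPanelCounts` object (list with `direct` and `all`
#'   count pairs).
#' @export
poolPanelCounts <- function(bams, event, gm, minMapq = 20L) {
  p <- evaluationPosition(event, gm)
  out <- .poolCounts(bams, event, gm, p, event$chrom, minMapq)
  class(out) <- "runjPanelCounts"
  out
}

#' Validate a set of predicted splice events against RNA-seq
#'
#' For each event, retrieves tumor reads crossing the evaluation position,
#' classifies them in direct and all modes, pools the control panels, and
#' computes the four RUNJ scores and the validation decision.
#'
#' @param events data.frame of events from [selectTopEvents()] (columns
#'   `chrom`, `gene`, `event_type`, `site_pos` required).
#' @param tumorBam tumor BAM path.
#' @param ponBams character vector of panel-of-normal BAM paths, or a
#'   precomputed `runjPanelCounts` object from [poolPanelCounts()].
#' @param potBams character vector of panel-of-tumor BAM paths or a
#'   `runjPanelCounts` object; `NULL` when not applicable.
#' @param gm a [GeneModel-class].
#' @param minReads,minRunj,minMapq validation thresholds (defaults 2, 0.01,
#'   20).
#' @return data.frame, one row per event, with the tumor and pooled panel
#'   counts in both modes, the four RUNJ scores, the per-criterion outcomes
#'   and the `validated` flag. The overall validation rate is attached as
#'   attribute `"validation_rate"`.
#' @export
validateCohort <- function(events, tumorBam, ponBams, potBams = NULL, gm,
                           minReads = 2L, minRunj = 0.01, minMapq = 20L) {
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, , drop = FALSE]
    p <- evaluationPosition(ev, gm)
    tum <- .sampleCounts(tumorBam, ev, gm, p, ev$chrom, minMapq)
    pon <- .poolCounts(ponBams, ev, gm, p, ev$chrom, minMapq)
    pot <- if (length(potBams)) .poolCounts(potBams, ev, gm, p, ev$chrom, minMapq)
    rdp <- runj(tum$direct[["n_abnormal"]], tum$direct[["n_normal"]],
                pon$direct[["n_abnormal"]], pon$direct[["n_normal"]])
    rap <- runj(tum$all[["n_abnormal"]], tum$all[["n_normal"]],
                pon$all[["n_abnormal"]], pon$all[["n_normal"]])
    pot_cov <- !is.null(pot) && sum(pot$all) > 0
    rdt <- if (pot_cov)
      runj(tum$direct[["n_abnormal"]], tum$direct[["n_normal"]],
           pot$direct[["n_abnormal"]], pot$direct[["n_normal"]]) else NA_real_
    rat <- if (pot_cov)
      runj(tum$all[["n_abnormal"]], tum$all[["n_normal"]],
           pot$all[["n_abnormal"]], pot$all[["n_normal"]]) else NA_real_
    dec <- validateDecision(tum$all[["n_abnormal"]], as.numeric(rdp),
                            as.numeric(rap), as.numeric(rdt), as.numeric(rat),
                            pot_applicable = pot_cov,
                            minReads = minReads, minRunj = minRunj)
    data.frame(
      chrom = ev$chrom, gene = ev$gene, event_type = ev$event_type,
      site_pos = ev$site_pos, eval_pos = p,
      m_a_direct = tum$direct[["n_abnormal"]],
      m_n_direct = tum$direct[["n_normal"]],
      m_a_all = tum$all[["n_abnormal"]], m_n_all = tum$all[["n_normal"]],
      c_a_direct_pon = pon$direct[["n_abnormal"]],
      c_n_direct_pon = pon$direct[["n_normal"]],
      c_a_all_pon = pon$all[["n_abnormal"]],
      c_n_all_pon = pon$all[["n_normal"]],
      runj_direct_pon = as.numeric(rdp), runj_all_pon = as.numeric(rap),
      runj_direct_pot = as.numeric(rdt), runj_all_pot = as.numeric(rat),
      pot_applicable = pot_cov,
      crit_reads = dec$reasons[["reads"]], crit_pon = dec$reasons[["pon"]],
      crit_pot = dec$reasons[["pot"]], validated = dec$validated,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "validation_rate") <-
    if (nrow(out)) mean(out$validated) else NA_real_
  out
}
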
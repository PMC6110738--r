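#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom GenomicRanges GRanges findOverlaps pintersect tileGenome
#' @importFrom IRanges IRanges width
#' @importFrom GenomeInfoDb seqnames seqlengths Seqinfo
NULL

.GROUP_LEVELS    <- c("ERG_POS", "ERG_NEG", "UNASSIGNED")
.ANCESTRY_LEVELS <- c("CA", "AA", "ASIAN", "UNKNOWN")
.GLEASON_LEVELS  <- c("LE6", "G3p4", "G4p3_8to10", "UNKNOWN")
.STAGE_LEVELS    <- c("pT2ab", "pT2c", "pT3a", "pT3b", "pT4", "UNKNOWN")
.BCR_LEVELS      <- c("yes", "no", "unknown")
.EVENT_CLASSES   <- c("mut", "amp", "del", "fusion")
.PROMOTER_CLASSES <- c("TSS200", "TSS1500", "5UTR", "1stExon")

#' Analysis thresholds
#'
#' Returns the full set of tunable cutoffs used across the pipeline, with
#' defaults equal to the published analysis settings: 10 kb copy-number bins
#' decided by a strict >5 kb base majority, GISTIC-convention log2-ratio cuts
#' at +/-0.3, the 20\% common-SCNA floor, the p < 0.001 / 10\% difference
#' rule for group-specific SCNA genes, candidate-gene recurrence floors
#' (SCNA > 15\%, mutation > 10\%), cytoband significance (p < 0.01 and
#' frequency > 30\%), fusion (p < 0.05) and mutation (p < 0.01) comparison
#' levels, differential-expression calling (p < 0.05, |fold change| > 2),
#' the methylation cascade (p < 0.01, |delta beta| > 0.2), the signature
#' cluster cut (within-cluster correlation >= 0.5), and the expected-count
#' minimum (5) that switches the 2x2 association test from Yates chi-squared
#' to Fisher's exact test.
#'
#' @param ... named overrides for any default, e.g. `amp_cut = 0.2`.
#' @return A named list of thresholds.
#' @examples
#' th <- ergThresholds(de_p = 0.01)
#' th$bin_width
#' @export
ergThresholds <- function(...) {
  th <- list(
    bin_width = 10000L,
    majority_bases = 5000L,
    amp_cut = 0.3,
    del_cut = -0.3,
    common_scna_freq = 0.20,
    specific_p = 0.001,
    specific_delta = 0.10,
    cand_scna_freq = 0.15,
    cand_mut_freq = 0.10,
    cytoband_p = 0.01,
    cytoband_freq = 0.30,
    fusion_p = 0.05,
    mutation_p = 0.01,
    de_p = 0.05,
    de_fc = 2,
    meth_p = 0.01,
    meth_delta_beta = 0.2,
    pathway_p = 0.01,
    meth_na_frac = 0.20,
    cluster_r_cut = 0.5,
    expected_count_min = 5,
    expr_check_p = 0.05,
    priority_p = 0.05,
    corr_p = 0.05,
    region_sample_frac = 0.5,
    gene_overlap_frac = 0.5,
    min_fusion_recurrence = 3L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(th))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  th[names(ov)] <- ov
  for (p in c("specific_p", "cytoband_p", "fusion_p", "mutation_p", "de_p",
              "meth_p", "pathway_p", "expr_check_p", "priority_p", "corr_p")) {
    if (th[[p]] <= 0 || th[[p]] >= 1) stop("threshold ", p, " must lie in (0,1)")
  }
  for (f in c("common_scna_freq", "specific_delta", "cand_scna_freq",
              "cand_mut_freq", "cytoband_freq")) {
    if (th[[f]] <= 0 || th[[f]] >= 1) stop("threshold ", f, " must lie in (0,1)")
  }
  if (th$bin_width <= 0) stop("bin_width must be positive")
  th
}

#' ErgCohort: a stratified multi-omics tumor cohort
#'
#' Container for one cohort: per-sample clinical records with the assigned
#' fusion group, fusion calls from up to two evidence sources, MAF-style
#' somatic mutation records, SEG-style copy-number segments (0-based
#' half-open internally), expression counts, methylation betas with probe
#' annotation, gene/cytoband/arm annotations as `GRanges`, the toy or real
#' genome as named chromosome lengths, and the threshold set.
#'
#' Validity requires unique sample identifiers, every omics sample resolving
#' to a clinical record, betas inside [0,1], and per-sample per-chromosome
#' non-overlapping segments.
#'
#' @slot clinical data.frame of per-sample records (sample_id, group,
#'   ancestry, age, psa, gleason, stage, bcr_event, bcr_time).
#' @slot fusions data.frame (sample_id, gene_5p, gene_3p, source).
#' @slot mutations data.frame (sample_id, gene, variant_class).
#' @slot segments data.frame (sample_id, chrom, start, end, value),
#'   0-based half-open coordinates.
#' @slot expression numeric matrix, genes x samples, non-negative counts.
#' @slot methylation numeric matrix, probes x samples, betas in [0,1] or NA.
#' @slot probeAnno data.frame (probe, chrom, gene, region_class).
#' @slot genes GRanges with mcols symbol, role.
#' @slot regions GRanges with mcols name, level ("cytoband"/"arm").
#' @slot genome named numeric vector of chromosome lengths.
#' @slot thresholds list from [ergThresholds()].
#' @export
setClass("ErgCohort", representation(
  clinical = "data.frame",
  fusions = "data.frame",
  mutations = "data.frame",
  segments = "data.frame",
  expression = "matrix",
  methylation = "matrix",
  probeAnno = "data.frame",
  genes = "GRanges",
  regions = "GRanges",
  genome = "numeric",
  thresholds = "list"
))

.validErgCohort <- function(object) {
  msg <- character()
  cl <- object@clinical
  need <- c("sample_id", "group", "ancestry", "age", "psa", "gleason",
            "stage", "bcr_event", "bcr_time")
  if (!all(need %in% names(cl)))
    msg <- c(msg, paste("clinical table lacks columns:",
                        paste(setdiff(need, names(cl)), collapse = ", ")))
  else {
    if (anyDuplicated(cl$sample_id))
      msg <- c(msg, "duplicated sample_id in clinical table")
    ids <- cl$sample_id
    for (layer in c("fusions", "mutations", "segments")) {
      tab <- slot(object, layer)
      if (nrow(tab)) {
        orphan <- setdiff(unique(tab$sample_id), ids)
        if (length(orphan))
          msg <- c(msg, paste0(layer, " reference unknown sample(s): ",
                               paste(orphan, collapse = ", ")))
      }
    }
    for (layer in c("expression", "methylation")) {
      m <- slot(object, layer)
      if (ncol(m)) {
        orphan <- setdiff(colnames(m), ids)
        if (length(orphan))
          msg <- c(msg, paste0(layer, " matrix references unknown sample(s): ",
                               paste(orphan, collapse = ", ")))
      }
    }
  }
  if (length(object@expression) && any(object@expression < 0, na.rm = TRUE))
    msg <- c(msg, "negative expression counts")
  if (length(object@methylation)) {
    b <- object@methylation
    if (any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "methylation beta outside [0,1]")
  }
  seg <- object@segments
  if (nrow(seg)) {
    if (any(seg$end <= seg$start))
      msg <- c(msg, "segment with end <= start")
    key <- paste(seg$sample_id, seg$chrom)
    for (k in unique(key)) {
      s <- seg[key == k, , drop = FALSE]
      if (nrow(s) > 1L) {
        o <- order(s$start)
        if (any(s$start[o][-1L] < s$end[o][-nrow(s)])) {
          msg <- c(msg, paste("overlapping segments for", k))
          break
        }
      }
    }
    if (length(object@genome)) {
      known <- seg$chrom %in% names(object@genome)
      if (any(known) &&
          any(seg$end[known] > object@genome[seg$chrom[known]]))
        msg <- c(msg, "segment extends beyond chromosome end")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("ErgCohort", .validErgCohort)

#' @describeIn ErgCohort compact cohort summary.
#' @param object an `ErgCohort`.
#' @export
setMethod("show", "ErgCohort", function(object) {
  cl <- object@clinical
  tab <- table(factor(cl$group, levels = .GROUP_LEVELS))
  cat("ErgCohort with", nrow(cl), "samples (",
      paste(names(tab), tab, sep = ":", collapse = " "), ")\n")
  cat("  fusions:", nrow(object@fusions),
      "| mutations:", nrow(object@mutations),
      "| segments:", nrow(object@segments), "\n")
  cat("  expression:", nrow(object@expression), "genes x",
      ncol(object@expression), "samples",
      "| methylation:", nrow(object@methylation), "probes x",
      ncol(object@methylation), "samples\n")
  cat("  annotation:", length(object@genes), "genes,",
      length(object@regions), "regions,",
      length(object@genome), "chromosomes\n")
})

#' AlterationMatrix: multi-class gene x sample alteration calls
#'
#' Boolean gene x sample x class array over the four event classes
#' `mut`, `amp`, `del`, `fusion`. Mutation entries derive only from
#' nonsilent records; amp/del from discretized segments overlapping at
#' least half of the gene body; fusion from calls touching the gene at
#' either end.
#'
#' @slot calls logical array [gene, sample, class].
#' @export
setClass("AlterationMatrix", representation(calls = "array"))

setValidity("AlterationMatrix", function(object) {
  d <- dim(object@calls)
  if (length(d) != 3L || d[3L] != 4L)
    return("calls must be a gene x sample x 4 array")
  if (!identical(dimnames(object@calls)[[3L]], .EVENT_CLASSES))
    return("third dimension must be mut/amp/del/fusion")
  if (!is.logical(object@calls)) return("calls must be logical")
  TRUE
})

#' @describeIn AlterationMatrix summary of call counts per class.
#' @param object an `AlterationMatrix`.
#' @export
setMethod("show", "AlterationMatrix", function(object) {
  d <- dim(object@calls)
  cat("AlterationMatrix:", d[1L], "genes x", d[2L], "samples\n")
  cnt <- apply(object@calls, 3L, sum)
  cat("  events:", paste(names(cnt), cnt, sep = "=", collapse = " "), "\n")
})

#' BinTrack: ternary copy-number status over fixed genome bins
#'
#' Per-sample copy-number status (-1 deletion, 0 neutral, +1 amplification)
#' over consecutive fixed-width genome bins; the bin intervals are carried
#' as a `GRanges`.
#'
#' @slot status integer matrix bins x samples with values -1, 0, 1.
#' @slot bins GRanges of the bin intervals, parallel to the rows.
#' @export
setClass("BinTrack", representation(status = "matrix", bins = "GRanges"))

setValidity("BinTrack", function(object) {
  if (nrow(object@status) != length(object@bins))
    return("status rows must match bins")
  if (!all(object@status %in% c(-1L, 0L, 1L)))
    return("status must be -1/0/1")
  TRUE
})

#' @describeIn BinTrack summary of bin statuses.
#' @param object a `BinTrack`.
#' @export
setMethod("show", "BinTrack", function(object) {
  cat("BinTrack:", nrow(object@status), "bins x", ncol(object@status),
      "samples;", sum(object@status == 1L), "amp /",
      sum(object@status == -1L), "del bin-calls\n")
})
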
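#' Build the gene x sample alteration matrix
#'
#' Combines the four event classes into one boolean gene x sample x
#' class array: nonsilent mutations by symbol; amplification/deletion
#' when a discretized segment of that status overlaps at least
#' `gene_overlap_frac` (default half) of the gene body; fusions credited
#' to both the 5' and 3' partner.
#'
#' @param cohort an `ErgCohort` with gene annotation.
#' @param sample_ids samples to include (default: all clinical samples).
#' @return An [AlterationMatrix-class].
#' @export
buildAlterationMatrix <- function(cohort, sample_ids = NULL) {
  genes <- geneAnno(cohort)
  if (!length(genes)) stop("cohort has no gene annotation")
  th <- thresholds(cohort)
  if (is.null(sample_ids)) sample_ids <- clinical(cohort)$sample_id
  syms <- S4Vectors::mcols(genes)$symbol
  ng <- length(syms); ns <- length(sample_ids)
  calls <- array(FALSE, dim = c(ng, ns, 4L),
                 dimnames = list(syms, sample_ids, .EVENT_CLASSES))
  mut <- mutationCalls(cohort)
  mut <- mut[mut$variant_class == "nonsilent" &
               mut$gene %in% syms & mut$sample_id %in% sample_ids, ,
             drop = FALSE]
  if (nrow(mut))
    calls[cbind(match(mut$gene, syms), match(mut$sample_id, sample_ids),
                1L)] <- TRUE
  seg <- discretizeSegments(segTable(cohort), th)
  seg <- seg[seg$status != 0L & seg$sample_id %in% sample_ids, ,
             drop = FALSE]
  if (nrow(seg)) {
    segGR <- GRanges(seg$chrom, IRanges(seg$start + 1, seg$end))
    hits <- findOverlaps(genes, segGR)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    frac <- width(pintersect(genes[qh], segGR[sh])) / width(genes[qh])
    keep <- frac >= th$gene_overlap_frac
    cls <- ifelse(seg$status[sh][keep] == 1L, 2L, 3L)  # amp / del slice
    calls[cbind(qh[keep], match(seg$sample_id[sh][keep], sample_ids),
                cls)] <- TRUE
  }
  fus <- fusionCalls(cohort)
  fus <- fus[fus$sample_id %in% sample_ids, , drop = FALSE]
  if (nrow(fus)) {
    for (side in c("gene_5p", "gene_3p")) {
      f <- fus[fus[[side]] %in% syms, , drop = FALSE]
      if (nrow(f))
        calls[cbind(match(f[[side]], syms),
                    match(f$sample_id, sample_ids), 4L)] <- TRUE
    }
  }
  new("AlterationMatrix", calls = calls)
}

.groupIds <- function(groups, which, universe = NULL) {
  ids <- names(groups)[groups == which]
  if (!is.null(universe)) ids <- intersect(ids, universe)
  ids
}

#' Compare recurrent fusion-pair frequencies between groups
#'
#' Per fusion pair seen in at least `min_fusion_recurrence` samples
#' (default 3): distinct-sample frequency per group and a Fisher exact
#' test (forced — fusion counts are sparse); significant at `fusion_p`.
#'
#' @param fusions fusion-call data.frame or `ErgCohort`.
#' @param groups named group vector (sample_id -> group).
#' @param thresholds list from [ergThresholds()].
#' @return data.frame: item (gene5:gene3), freq_pos, freq_neg, delta,
#'   test_used, p, significant, n_pos, n_neg.
#' @export
compareFusions <- function(fusions, groups, thresholds = ergThresholds()) {
  if (is(fusions, "ErgCohort")) fusions <- fusionCalls(fusions)
  pos <- .groupIds(groups, "ERG_POS"); neg <- .groupIds(groups, "ERG_NEG")
  np <- length(pos); nn <- length(neg)
  pair <- paste(fusions$gene_5p, fusions$gene_3p, sep = ":")
  rows <- list()
  for (pr in sort(unique(pair))) {
    samp <- unique(fusions$sample_id[pair == pr])
    if (length(samp) < thresholds$min_fusion_recurrence) next
    a <- length(intersect(samp, pos)); cc <- length(intersect(samp, neg))
    res <- assocTest(a, np - a, cc, nn - cc, thresholds,
                     force = "fisher_exact")
    fp <- a / np; fn <- cc / nn
    rows[[length(rows) + 1L]] <- data.frame(
      item = pr, freq_pos = fp, freq_neg = fn, delta = fn - fp,
      test_used = res$test_used, p = res$p,
      significant = res$p < thresholds$fusion_p,
      n_pos = a, n_neg = cc, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(item = character(), freq_pos = numeric(),
                      freq_neg = numeric(), delta = numeric(),
                      test_used = character(), p = numeric(),
                      significant = logical(), n_pos = integer(),
                      n_neg = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Compare nonsilent mutation frequencies between groups
#'
#' Per gene with at least one nonsilent record: distinct mutated-sample
#' frequency per group and the chooser association test; significant at
#' `mutation_p`. Silent records never contribute.
#'
#' @param mutations mutation data.frame or `ErgCohort`.
#' @inheritParams compareFusions
#' @return data.frame as for [compareFusions()].
#' @export
compareMutations <- function(mutations, groups,
                             thresholds = ergThresholds()) {
  if (is(mutations, "ErgCohort")) mutations <- mutationCalls(mutations)
  mutations <- mutations[mutations$variant_class == "nonsilent", ,
                         drop = FALSE]
  pos <- .groupIds(groups, "ERG_POS"); neg <- .groupIds(groups, "ERG_NEG")
  np <- length(pos); nn <- length(neg)
  rows <- list()
  for (g in sort(unique(mutations$gene))) {
    samp <- unique(mutations$sample_id[mutations$gene == g])
    a <- length(intersect(samp, pos)); cc <- length(intersect(samp, neg))
    if (a + cc == 0L) next
    res <- assocTest(a, np - a, cc, nn - cc, thresholds)
    fp <- a / np; fn <- cc / nn
    rows[[length(rows) + 1L]] <- data.frame(
      item = g, freq_pos = fp, freq_neg = fn, delta = fn - fp,
      test_used = res$test_used, p = res$p,
      significant = res$p < thresholds$mutation_p,
      n_pos = a, n_neg = cc, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(item = character(), freq_pos = numeric(),
                      freq_neg = numeric(), delta = numeric(),
                      test_used = character(), p = numeric(),
                      significant = logical(), n_pos = integer(),
                      n_neg = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Classify tumor suppressor / oncogene copy-number alterations
#'
#' Direction-aware frequencies — deletion for tumor suppressors,
#' amplification for oncogenes. A gene is a common SCNA gene when its
#' frequency exceeds `common_scna_freq` (20\%) in both groups, and
#' group-specific when the chooser test gives p < `specific_p` (0.001)
#' with an absolute frequency difference above `specific_delta` (10\%);
#' a gene satisfying both rules is assigned to the specific class.
#' Genes with role `OTHER` (or absent from the annotation) are skipped.
#'
#' @param am an [AlterationMatrix-class].
#' @param genes `GRanges` gene annotation with mcols symbol, role.
#' @param groups named group vector.
#' @param thresholds list from [ergThresholds()].
#' @return list with `common`, `neg_specific`, `pos_specific` (character
#'   vectors) and `table` (per-gene details).
#' @export
classifyScnaGenes <- function(am, genes, groups,
                              thresholds = ergThresholds()) {
  pos <- .groupIds(groups, "ERG_POS", dimnames(am)[[2L]])
  neg <- .groupIds(groups, "ERG_NEG", dimnames(am)[[2L]])
  np <- length(pos); nn <- length(neg)
  roles <- stats::setNames(S4Vectors::mcols(genes)$role,
                           S4Vectors::mcols(genes)$symbol)
  rows <- list()
  for (g in dimnames(am)[[1L]]) {
    role <- roles[g]
    if (is.na(role) || !role %in% c("TSG", "ONCOGENE")) next
    cls <- if (role == "TSG") "del" else "amp"
    altered <- alteredMatrix(am, cls)[g, ]
    a <- sum(altered[pos]); cc <- sum(altered[neg])
    fp <- a / np; fn <- cc / nn
    res <- if (a + cc == 0L)
      list(p = NA_real_, test_used = "untestable")
    else assocTest(a, np - a, cc, nn - cc, thresholds)
    common <- fp > thresholds$common_scna_freq &
      fn > thresholds$common_scna_freq
    specific <- !is.na(res$p) && res$p < thresholds$specific_p &&
      abs(fn - fp) > thresholds$specific_delta
    klass <- if (specific) {
      if (fn > fp) "neg_specific" else "pos_specific"
    } else if (common) "common" else "none"
    rows[[length(rows) + 1L]] <- data.frame(
      item = g, role = unname(role), status = cls, freq_pos = fp,
      freq_neg = fn, delta = fn - fp, test_used = res$test_used,
      p = res$p, class = klass, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(item = character(), role = character(), status = character(),
               freq_pos = numeric(), freq_neg = numeric(), delta = numeric(),
               test_used = character(), p = numeric(), class = character(),
               stringsAsFactors = FALSE)
  list(common = tab$item[tab$class == "common"],
       neg_specific = tab$item[tab$class == "neg_specific"],
       pos_specific = tab$item[tab$class == "pos_specific"],
       table = tab)
}
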
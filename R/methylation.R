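## The promoter-hypermethylation cascade: five nested filters applied in
## order, each recording its survivors, so the trace is auditable and the
## nesting invariant (stage k survivors contained in stage k-1) is asserted
## on every run.

.normChrom <- function(chrom) sub("^chr", "", chrom)

.probeWelch <- function(beta, ids_a, ids_b) {
  ## per-probe Welch with pairwise NA deletion; returns delta (A - B) and p
  t(vapply(seq_len(nrow(beta)), function(i) {
    x <- beta[i, ids_a]; x <- x[!is.na(x)]
    y <- beta[i, ids_b]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L)
      return(c(delta = NA_real_, p = NA_real_))
    if (stats::var(x) == 0 && stats::var(y) == 0)
      return(c(delta = mean(x) - mean(y),
               p = if (mean(x) == mean(y)) 1 else 0))
    tt <- stats::t.test(x, y, var.equal = FALSE)
    c(delta = mean(x) - mean(y), p = tt$p.value)
  }, c(delta = 0, p = 0)))
}

#' Five-step promoter hypermethylation cascade
#'
#' Applies, in order: (1) removal of probes on the X/Y/mitochondrial
#' chromosomes and probes with more than `meth_na_frac` missing betas;
#' (2) differential methylation, |delta beta| > `meth_delta_beta` with
#' Welch p < `meth_p` between `tumor_ids` and `normal_ids`; (3)
#' restriction to promoter probe classes (TSS200, TSS1500, 5'UTR,
#' 1stExon) — probes without a gene mapping are dropped and counted;
#' (4) negative Pearson correlation (p < `corr_p`) between the probe's
#' beta and its gene's log2-CPM expression across tumor samples; (5)
#' restriction to probes whose gene is expressed significantly lower in
#' tumors than normals (one-sided Welch, p < `corr_p` level). The final
#' set keeps the hypermethylated direction (delta beta > 0).
#'
#' @param meth probe x sample beta matrix.
#' @param probe_anno data.frame (probe, chrom, gene, region_class).
#' @param expr gene x sample count matrix.
#' @param tumor_ids,normal_ids sample identifiers for the stage-2 and
#'   stage-5 contrasts.
#' @param thresholds list from [ergThresholds()].
#' @param contrast_ids optional two-element list overriding the stage-2
#'   contrast groups (used for the between-tumor-group comparison).
#' @param direction `"hyper"` (delta > 0 in the first contrast group),
#'   `"hypo"`, or `"both"` for the stage-2 sign filter applied at the
#'   end.
#' @return list with `stages` (data.frame stage/description/n),
#'   `survivors` (list of probe vectors per stage), `final`
#'   (data.frame probe, gene, delta_beta, p).
#' @export
methylationCascade <- function(meth, probe_anno, expr, tumor_ids,
                               normal_ids, thresholds = ergThresholds(),
                               contrast_ids = NULL, direction = "hyper") {
  anno <- probe_anno[match(rownames(meth), probe_anno$probe), , drop = FALSE]
  if (anyNA(anno$probe)) stop("probe(s) missing from annotation")
  ids2 <- if (is.null(contrast_ids)) list(tumor_ids, normal_ids)
  else contrast_ids
  used <- unique(c(ids2[[1L]], ids2[[2L]], tumor_ids))
  ## stage 1: drop sex/mitochondrial chromosomes and high-missingness probes
  chrom <- .normChrom(anno$chrom)
  na_frac <- rowMeans(is.na(meth[, intersect(used, colnames(meth)),
                                 drop = FALSE]))
  s1 <- rownames(meth)[!chrom %in% c("X", "Y", "M", "MT") &
                         na_frac <= thresholds$meth_na_frac]
  ## stage 2: differential methylation
  wt <- .probeWelch(meth[s1, , drop = FALSE], ids2[[1L]], ids2[[2L]])
  ok2 <- !is.na(wt[, "p"]) &
    abs(wt[, "delta"]) > thresholds$meth_delta_beta &
    wt[, "p"] < thresholds$meth_p
  s2 <- s1[ok2]
  stats2 <- data.frame(probe = s2,
                       delta_beta = wt[ok2, "delta"],
                       p = wt[ok2, "p"], stringsAsFactors = FALSE)
  ## stage 3: promoter probes with a gene mapping
  a2 <- anno[match(s2, anno$probe), , drop = FALSE]
  cls <- gsub("'", "", a2$region_class)
  mapped <- !is.na(a2$gene) & nzchar(a2$gene)
  s3 <- s2[mapped & cls %in% .PROMOTER_CLASSES]
  ## stage 4: negative cis correlation with expression
  lexpr <- cpmLog2(expr)
  tum <- intersect(tumor_ids, intersect(colnames(meth), colnames(lexpr)))
  s4 <- character()
  for (pr in s3) {
    g <- anno$gene[match(pr, anno$probe)]
    if (!g %in% rownames(lexpr)) next
    b <- meth[pr, tum]
    keep <- !is.na(b)
    if (sum(keep) < 3L) next
    ct <- tryCatch(pearsonR(b[keep], lexpr[g, tum][keep]),
                   error = function(e) NULL)
    if (!is.null(ct) && ct$r < 0 && ct$p < thresholds$corr_p)
      s4 <- c(s4, pr)
  }
  ## stage 5: gene expressed lower in tumor than normal
  s5 <- character()
  norm_e <- intersect(normal_ids, colnames(lexpr))
  tum_e <- intersect(tumor_ids, colnames(lexpr))
  down_cache <- new.env(parent = emptyenv())
  for (pr in s4) {
    g <- anno$gene[match(pr, anno$probe)]
    down <- if (!is.null(down_cache[[g]])) down_cache[[g]] else {
      d <- tryCatch(
        welchT(lexpr[g, norm_e], lexpr[g, tum_e], tail = "greater")$p <
          thresholds$corr_p,
        error = function(e) FALSE)
      down_cache[[g]] <- d
      d
    }
    if (down) s5 <- c(s5, pr)
  }
  final <- stats2[stats2$probe %in% s5, , drop = FALSE]
  if (direction == "hyper") final <- final[final$delta_beta > 0, , drop = FALSE]
  if (direction == "hypo") final <- final[final$delta_beta < 0, , drop = FALSE]
  final$gene <- anno$gene[match(final$probe, anno$probe)]
  survivors <- list(stage1 = s1, stage2 = s2, stage3 = s3,
                    stage4 = s4, stage5 = s5)
  for (i in 2:5)
    stopifnot(all(survivors[[i]] %in% survivors[[i - 1L]]))
  stages <- data.frame(
    stage = 1:5,
    description = c("autosomal, low missingness", "differentially methylated",
                    "promoter region", "negative cis correlation",
                    "gene down in tumor"),
    n = lengths(survivors), stringsAsFactors = FALSE)
  rownames(stages) <- NULL
  list(stages = stages, survivors = survivors,
       final = final[c("probe", "gene", "delta_beta", "p")])
}

#' Between-group promoter hypermethylation
#'
#' Runs the cascade once per direction with the stage-2 contrast taken
#' between the two tumor groups (ERG-negative vs ERG-positive) at the
#' same thresholds; stages 4-5 are still evaluated against tumor
#' expression and the tumor-vs-normal expression contrast. Reports
#' hypermethylated sites and distinct gene counts per direction.
#'
#' @param meth probe x sample beta matrix.
#' @param probe_anno probe annotation data.frame.
#' @param expr gene x sample count matrix.
#' @param groups named group vector over tumor samples.
#' @param normal_ids normal-sample identifiers (for stage 5).
#' @param thresholds list from [ergThresholds()].
#' @return list with `neg`, `pos` (cascade traces) and `summary`
#'   (direction, n_sites, n_genes).
#' @export
groupHypermethylation <- function(meth, probe_anno, expr, groups,
                                  normal_ids,
                                  thresholds = ergThresholds()) {
  pos <- .groupIds(groups, "ERG_POS", colnames(meth))
  neg <- .groupIds(groups, "ERG_NEG", colnames(meth))
  if (!length(pos) || !length(neg)) stop("both groups must be present")
  tumor <- c(pos, neg)
  tr_neg <- methylationCascade(meth, probe_anno, expr, tumor, normal_ids,
                               thresholds, contrast_ids = list(neg, pos),
                               direction = "hyper")
  tr_pos <- methylationCascade(meth, probe_anno, expr, tumor, normal_ids,
                               thresholds, contrast_ids = list(pos, neg),
                               direction = "hyper")
  summary <- data.frame(
    direction = c("hyper_in_neg", "hyper_in_pos"),
    n_sites = c(nrow(tr_neg$final), nrow(tr_pos$final)),
    n_genes = c(length(unique(tr_neg$final$gene)),
                length(unique(tr_pos$final$gene))),
    stringsAsFactors = FALSE)
  list(neg = tr_neg, pos = tr_pos, summary = summary)
}
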
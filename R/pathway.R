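#' Pathway-level alteration frequency comparison
#'
#' A sample is pathway-altered when at least one member gene carries at
#' least one event of the allowed classes. Per pathway: per-group
#' frequencies and the chooser association test, significant at
#' `pathway_p` (0.01). Pathways with no resolvable member are skipped
#' with a warning; pathways with members but no events anywhere are
#' reported untestable. The union bound (pathway frequency >= max member
#' frequency) is asserted on every run.
#'
#' @param am an [AlterationMatrix-class].
#' @param pathways named list of member-gene vectors (see [readGmt()]).
#' @param groups named group vector.
#' @param thresholds list from [ergThresholds()].
#' @param classes event classes counted (default all four).
#' @return data.frame: item, n_members, freq_pos, freq_neg, delta,
#'   test_used, p, significant; attribute `unresolved` maps pathway ->
#'   unresolved members.
#' @export
pathwayAlteration <- function(am, pathways, groups,
                              thresholds = ergThresholds(),
                              classes = .EVENT_CLASSES) {
  pos <- .groupIds(groups, "ERG_POS", dimnames(am)[[2L]])
  neg <- .groupIds(groups, "ERG_NEG", dimnames(am)[[2L]])
  np <- length(pos); nn <- length(neg)
  altm <- alteredMatrix(am, classes)
  rows <- list(); unresolved <- list()
  for (nm in names(pathways)) {
    members <- intersect(pathways[[nm]], rownames(altm))
    unresolved[[nm]] <- setdiff(pathways[[nm]], rownames(altm))
    if (!length(members)) {
      warning("pathway ", nm, " has no resolvable member; skipped")
      next
    }
    hit <- colSums(altm[members, , drop = FALSE]) > 0L
    a <- sum(hit[pos]); cc <- sum(hit[neg])
    fp <- if (np) a / np else NA_real_
    fn <- if (nn) cc / nn else NA_real_
    if (np)  # union bound over member genes
      stopifnot(fp >= max(rowMeans(altm[members, pos, drop = FALSE])) - 1e-12)
    if (nn)
      stopifnot(fn >= max(rowMeans(altm[members, neg, drop = FALSE])) - 1e-12)
    res <- if (a + cc == 0L || np == 0L || nn == 0L)
      list(statistic = NA_real_, p = NA_real_, test_used = "untestable")
    else assocTest(a, np - a, cc, nn - cc, thresholds)
    rows[[length(rows) + 1L]] <- data.frame(
      item = nm, n_members = length(members), freq_pos = fp,
      freq_neg = fn, delta = fn - fp, test_used = res$test_used,
      p = res$p,
      significant = !is.na(res$p) & res$p < thresholds$pathway_p,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(item = character(), n_members = integer(),
               freq_pos = numeric(), freq_neg = numeric(),
               delta = numeric(), test_used = character(), p = numeric(),
               significant = logical(), stringsAsFactors = FALSE)
  attr(out, "unresolved") <- unresolved
  out
}

#' Gene-level drill-down within one pathway
#'
#' Per member gene: any-event frequency per group and the chooser test,
#' ordered by absolute frequency difference (ties by symbol). Members
#' never altered are reported untestable.
#'
#' @param am an [AlterationMatrix-class].
#' @param members character vector of member genes (or one pathway from
#'   a GMT list).
#' @param groups named group vector.
#' @param thresholds list from [ergThresholds()].
#' @param classes event classes counted.
#' @return data.frame: item, freq_pos, freq_neg, delta, test_used, p,
#'   significant.
#' @export
pathwayGeneBreakdown <- function(am, members, groups,
                                 thresholds = ergThresholds(),
                                 classes = .EVENT_CLASSES) {
  members <- intersect(members, dimnames(am)[[1L]])
  if (!length(members)) stop("no resolvable member gene")
  pos <- .groupIds(groups, "ERG_POS", dimnames(am)[[2L]])
  neg <- .groupIds(groups, "ERG_NEG", dimnames(am)[[2L]])
  np <- length(pos); nn <- length(neg)
  altm <- alteredMatrix(am, classes)
  rows <- lapply(members, function(g) {
    a <- sum(altm[g, pos]); cc <- sum(altm[g, neg])
    res <- if (a + cc == 0L)
      list(statistic = NA_real_, p = NA_real_, test_used = "untestable")
    else assocTest(a, np - a, cc, nn - cc, thresholds)
    fp <- a / np; fn <- cc / nn
    data.frame(item = g, freq_pos = fp, freq_neg = fn, delta = fn - fp,
               test_used = res$test_used, p = res$p,
               significant = !is.na(res$p) & res$p < thresholds$pathway_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$delta), out$item), , drop = FALSE]
}
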
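#' Select candidate feature genes for the fusion-negative group
#'
#' A gene is a candidate when its copy-number alteration frequency in
#' the ERG-negative group exceeds `cand_scna_freq` (15\%) or its
#' nonsilent mutation frequency exceeds `cand_mut_freq` (10\%). Each
#' candidate records its dominant event class and three priority flags:
#' `higher_in_neg` (chooser test p < `priority_p` with the negative
#' group ahead), `druggable` (membership of a user-supplied list), and
#' `cnv_expr_correlated` (positive Pearson correlation, p < `corr_p`,
#' between the per-sample copy status and log2-CPM expression).
#'
#' @param am an [AlterationMatrix-class].
#' @param groups named group vector.
#' @param thresholds list from [ergThresholds()].
#' @param druggable character vector of druggable gene symbols.
#' @param expr optional raw count matrix for the correlation flag.
#' @return data.frame: gene, event_class, freq_neg, freq_pos, the three
#'   flag columns, and n_flags.
#' @export
selectCandidates <- function(am, groups, thresholds = ergThresholds(),
                             druggable = character(), expr = NULL) {
  pos <- .groupIds(groups, "ERG_POS", dimnames(am)[[2L]])
  neg <- .groupIds(groups, "ERG_NEG", dimnames(am)[[2L]])
  np <- length(pos); nn <- length(neg)
  fr <- function(cls, ids) altFrequency(am, ids, cls)
  scna_neg <- pmax(fr("amp", neg), fr("del", neg))
  mut_neg <- fr("mut", neg)
  lexpr <- if (!is.null(expr)) cpmLog2(expr) else NULL
  rows <- list()
  for (g in dimnames(am)[[1L]]) {
    is_scna <- scna_neg[g] > thresholds$cand_scna_freq
    is_mut <- mut_neg[g] > thresholds$cand_mut_freq
    if (!is_scna && !is_mut) next
    cls <- if (is_mut && (!is_scna || mut_neg[g] > scna_neg[g])) "mut"
    else if (fr("amp", neg)[g] >= fr("del", neg)[g]) "amp" else "del"
    altered <- alteredMatrix(am, cls)[g, ]
    a <- sum(altered[pos]); cc <- sum(altered[neg])
    fn <- cc / nn
    fp <- if (np) a / np else NA_real_
    higher <- FALSE
    if (np > 0L && a + cc > 0L) {
      res <- tryCatch(assocTest(a, np - a, cc, nn - cc, thresholds),
                      error = function(e) NULL)
      higher <- !is.null(res) && res$p < thresholds$priority_p && fn > fp
    }
    corr <- FALSE
    if (!is.null(lexpr) && g %in% rownames(lexpr) && cls != "mut") {
      ids <- intersect(c(pos, neg), colnames(lexpr))
      copy <- alteredMatrix(am, "amp")[g, ids] * 1L -
        alteredMatrix(am, "del")[g, ids] * 1L
      if (stats::var(copy) > 0) {
        ct <- pearsonR(copy, lexpr[g, ids])
        corr <- ct$p < thresholds$corr_p && ct$r > 0
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, event_class = cls, freq_neg = unname(fn),
      freq_pos = unname(fp), higher_in_neg = higher,
      druggable = g %in% druggable, cnv_expr_correlated = corr,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), event_class = character(),
               freq_neg = numeric(), freq_pos = numeric(),
               higher_in_neg = logical(), druggable = logical(),
               cnv_expr_correlated = logical(), stringsAsFactors = FALSE)
  out$n_flags <- out$higher_in_neg + out$druggable + out$cnv_expr_correlated
  out
}

#' Cluster candidate genes by alteration-pattern similarity
#'
#' Pearson correlation between the binary per-sample alteration vectors
#' of the candidates over the ERG-negative samples, average-linkage
#' hierarchical clustering of the 1 - r distance, and a flat cut so that
#' genes merged at correlation >= `cluster_r_cut` (0.5) share a cluster;
#' singletons are allowed. Candidates altered in no sample (or all
#' samples — correlation undefined) are excluded with a warning.
#'
#' @param candidates data.frame from [selectCandidates()].
#' @param am an [AlterationMatrix-class].
#' @param groups named group vector.
#' @param thresholds list from [ergThresholds()].
#' @return integer vector of cluster ids named by gene.
#' @export
clusterCandidates <- function(candidates, am, groups,
                              thresholds = ergThresholds()) {
  if (!nrow(candidates)) stop("no candidates to cluster")
  neg <- .groupIds(groups, "ERG_NEG", dimnames(am)[[2L]])
  m <- alteredMatrix(am)[candidates$gene, neg, drop = FALSE] * 1
  keep <- apply(m, 1L, stats::var) > 0
  if (any(!keep)) {
    warning("excluding candidate(s) with constant alteration vector: ",
            paste(rownames(m)[!keep], collapse = ", "))
    m <- m[keep, , drop = FALSE]
  }
  if (!nrow(m)) stop("no clusterable candidates")
  if (nrow(m) == 1L) return(stats::setNames(1L, rownames(m)))
  r <- stats::cor(t(m))
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  cl <- stats::cutree(hc, h = 1 - thresholds$cluster_r_cut)
  cl
}

#' Pick one representative gene per cluster
#'
#' Within each cluster candidates are ranked by number of priority flags
#' (descending), then ERG-negative frequency (descending), then gene
#' symbol (ascending); the top gene represents the cluster. The
#' representative list is ordered by ERG-negative frequency, then
#' symbol. All tie-breaks are total, so the selection is deterministic.
#'
#' @param clusters named cluster vector from [clusterCandidates()].
#' @param candidates data.frame from [selectCandidates()].
#' @param n_max optional cap on the number of representatives (the
#'   ranking is honored; default uncapped).
#' @return list with `representatives` (character) and `table`
#'   (candidates with cluster and representative columns).
#' @export
pickRepresentatives <- function(clusters, candidates, n_max = Inf) {
  tab <- candidates[candidates$gene %in% names(clusters), , drop = FALSE]
  tab$cluster <- clusters[tab$gene]
  tab <- tab[order(tab$cluster, -tab$n_flags, -tab$freq_neg, tab$gene), ,
             drop = FALSE]
  rep_gene <- tapply(tab$gene, tab$cluster, `[`, 1L)
  tab$representative <- tab$gene %in% rep_gene
  reps <- tab[tab$representative, , drop = FALSE]
  reps <- reps[order(-reps$freq_neg, reps$gene), , drop = FALSE]
  out <- reps$gene
  if (is.finite(n_max) && length(out) > n_max) out <- out[seq_len(n_max)]
  list(representatives = out, table = tab)
}

#' Sample coverage of a representative-gene set
#'
#' Fraction of a sample set carrying at least one alteration among the
#' representative genes, with per-sample flags and a text oncoprint:
#' genes ordered by alteration frequency (descending) and samples by
#' the lexicographic order of their alteration pattern, so mutually
#' exclusive alterations form the familiar staircase. Cell codes
#' concatenate M (mutation), A (amplification), D (deletion),
#' F (fusion); "." is unaltered. A frozen representative list can be
#' applied to a second cohort's matrix for cross-cohort coverage.
#'
#' @param representatives character vector of gene symbols.
#' @param am an [AlterationMatrix-class].
#' @param sample_set sample identifiers (default: all in `am`).
#' @return list with `coverage` (fraction), `flags` (named logical),
#'   `oncoprint` (character matrix genes x samples).
#' @export
signatureCoverage <- function(representatives, am, sample_set = NULL) {
  if (is.null(sample_set)) sample_set <- dimnames(am)[[2L]]
  if (!length(sample_set)) stop("empty sample set")
  if (!length(representatives)) {
    warning("empty representative list: coverage 0")
    return(list(coverage = 0,
                flags = stats::setNames(rep(FALSE, length(sample_set)),
                                        sample_set),
                oncoprint = matrix(character(), 0, length(sample_set))))
  }
  missing <- setdiff(representatives, dimnames(am)[[1L]])
  if (length(missing))
    stop("representative(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  sub <- am@calls[representatives, sample_set, , drop = FALSE]
  any_alt <- apply(sub, c(1L, 2L), any)
  flags <- apply(any_alt, 2L, any)
  ord_g <- order(-rowMeans(any_alt), representatives)
  any_alt <- any_alt[ord_g, , drop = FALSE]
  sub <- sub[ord_g, , , drop = FALSE]
  key <- lapply(seq_len(nrow(any_alt)), function(i) -any_alt[i, ])
  ord_s <- do.call(order, c(key, list(colnames(any_alt))))
  code <- matrix(".", nrow(any_alt), ncol(any_alt),
                 dimnames = dimnames(any_alt))
  letters4 <- c(mut = "M", amp = "A", del = "D", fusion = "F")
  for (cls in .EVENT_CLASSES) {
    hitm <- array(sub[, , cls, drop = FALSE], dim = dim(any_alt))
    code[hitm] <- ifelse(code[hitm] == ".", letters4[cls],
                         paste0(code[hitm], letters4[cls]))
  }
  list(coverage = mean(flags),
       flags = flags,
       oncoprint = code[, ord_s, drop = FALSE])
}
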
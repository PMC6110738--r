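#' Counts-per-million normalization on the log2 scale
#'
#' CPM per sample followed by log2(x + 1); a rank-preserving
#' normalization of the count matrix used wherever expression enters a
#' test.
#'
#' @param counts non-negative gene x sample count matrix.
#' @return log2-CPM matrix of the same shape.
#' @export
cpmLog2 <- function(counts) {
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts")
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("sample with zero total counts")
  log2(sweep(counts, 2L, libsize, "/") * 1e6 + 1)
}

## Row-wise Welch t over a matrix split into two column groups; returns
## two-sided p-values (p = 1 for rows constant in both groups with equal
## means, p = 0 with unequal means) and the mean difference.
.rowWelch <- function(m, ia, ib) {
  n1 <- length(ia); n2 <- length(ib)
  x <- m[, ia, drop = FALSE]; y <- m[, ib, drop = FALSE]
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1L)
  v2 <- rowSums((y - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  list(p = unname(p), diff = unname(m1 - m2), t = unname(tstat))
}

#' Differential expression between two sample groups
#'
#' Welch t-test per gene on log2-CPM values; the fold change is the
#' ratio of linear-scale group mean CPMs (group A over group B). A gene
#' is called when p < `de_p` (0.05) and the absolute linear fold change
#' exceeds `de_fc` (2). Genes with zero counts in every sample are
#' skipped (recorded in the `skipped` attribute).
#'
#' @param counts gene x sample count matrix.
#' @param ids_a,ids_b column identifiers of the two groups (>= 2 each).
#' @param thresholds list from [ergThresholds()].
#' @return data.frame: gene, log2fc, p, direction ("up"/"down" in A vs
#'   B), called; attribute `skipped` lists all-zero genes.
#' @export
differentialExpression <- function(counts, ids_a, ids_b,
                                   thresholds = ergThresholds()) {
  stopifnot(length(ids_a) >= 2L, length(ids_b) >= 2L)
  bad <- setdiff(c(ids_a, ids_b), colnames(counts))
  if (length(bad)) stop("unknown sample(s): ", paste(bad, collapse = ", "))
  use <- counts[, c(ids_a, ids_b), drop = FALSE]
  zero <- rowSums(use) == 0
  if (any(zero)) use <- use[!zero, , drop = FALSE]
  lcpm <- cpmLog2(use)
  cpm <- 2^lcpm - 1
  ia <- seq_along(ids_a); ib <- length(ids_a) + seq_along(ids_b)
  w <- .rowWelch(lcpm, ia, ib)
  fc <- rowMeans(cpm[, ia, drop = FALSE]) /
    rowMeans(cpm[, ib, drop = FALSE])
  out <- data.frame(gene = rownames(use), log2fc = unname(log2(fc)),
                    p = w$p,
                    direction = ifelse(w$diff >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out$called <- out$p < thresholds$de_p &
    (fc > thresholds$de_fc | fc < 1 / thresholds$de_fc)
  out$called[!is.finite(out$p)] <- FALSE
  attr(out, "skipped") <- rownames(counts)[zero]
  out
}

#' Direction-aware overlap of two differential-expression runs
#'
#' Intersects the called gene sets of two DE runs on the same gene
#' universe; a gene counts as common only when called in both runs with
#' the same direction.
#'
#' @param de_pos,de_neg data.frames from [differentialExpression()]
#'   (e.g. each tumor group against normals).
#' @return list with `common`, `pos_only`, `neg_only` gene vectors and
#'   `common_fraction` (common over union of called genes).
#' @export
deOverlap <- function(de_pos, de_neg) {
  if (!setequal(de_pos$gene, de_neg$gene))
    stop("DE runs cover different gene universes")
  key <- function(d) paste(d$gene[d$called], d$direction[d$called])
  kp <- key(de_pos); kn <- key(de_neg)
  common_keys <- intersect(kp, kn)
  common <- sub(" .*", "", common_keys)
  called_p <- de_pos$gene[de_pos$called]
  called_n <- de_neg$gene[de_neg$called]
  uni <- union(called_p, called_n)
  list(common = sort(common),
       pos_only = sort(setdiff(called_p, common)),
       neg_only = sort(setdiff(called_n, common)),
       common_fraction = if (length(uni)) length(common) / length(uni)
       else NA_real_)
}
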
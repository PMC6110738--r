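#' Discretize copy-number segments to ternary calls
#'
#' The value column is interpreted per file: when every sample's values
#' lie exactly in \{-2,-1,0,1,2\} they are discrete calls (amp when
#' >= 1, del when <= -1); otherwise they are log2 copy ratios
#' thresholded at `amp_cut` / `del_cut` (GISTIC-convention +/-0.3).
#' A file where some samples carry calls and others carry ratios is
#' rejected.
#'
#' @param segments segment data.frame (internal 0-based half-open).
#' @param thresholds list from [ergThresholds()].
#' @return the segment table with an integer `status` column
#'   (-1 del, 0 neutral, +1 amp).
#' @export
discretizeSegments <- function(segments, thresholds = ergThresholds()) {
  seg <- segments
  if (!nrow(seg)) {
    seg$status <- integer()
    return(seg)
  }
  callset <- c(-2, -1, 0, 1, 2)
  is_call <- tapply(seg$value, seg$sample_id, function(v) all(v %in% callset))
  nonzero <- tapply(seg$value, seg$sample_id, function(v) any(v != 0))
  vote <- is_call[nonzero]           # all-zero samples fit either dialect
  if (length(vote) && !all(vote) && any(vote))
    stop("mixed call/ratio dialect: some samples carry discrete calls, ",
         "others log2 ratios")
  dialect <- if (length(vote) && all(vote)) "calls" else "ratio"
  seg$status <- if (dialect == "calls") {
    ifelse(seg$value >= 1, 1L, ifelse(seg$value <= -1, -1L, 0L))
  } else {
    ifelse(seg$value >= thresholds$amp_cut, 1L,
           ifelse(seg$value <= thresholds$del_cut, -1L, 0L))
  }
  seg
}

.binRangesFor <- function(genome, bin_width) {
  si <- Seqinfo(seqnames = names(genome), seqlengths = as.integer(genome))
  bins <- tileGenome(si, tilewidth = bin_width,
                     cut.last.tile.in.chrom = TRUE)
  bins
}

#' Bin the genome into fixed windows of ternary copy-number status
#'
#' Divides every chromosome into consecutive fixed-width bins (10 kb by
#' default) and assigns each (bin, sample) the status carried by the
#' strict majority of its bases: a status wins only when its base count
#' strictly exceeds `majority_bases` (5 kb — more than half a full bin);
#' uncovered bases count as neutral, and ties fall back to neutral.
#'
#' @param segments discretized segments (with `status`), or raw segments
#'   (discretized on the fly).
#' @param genome named numeric chromosome lengths.
#' @param thresholds list from [ergThresholds()].
#' @param sample_ids samples to track (default: those present in
#'   `segments`); samples without segments are all-neutral.
#' @return A [BinTrack-class].
#' @export
binGenome <- function(segments, genome, thresholds = ergThresholds(),
                      sample_ids = NULL) {
  if (is.null(segments$status))
    segments <- discretizeSegments(segments, thresholds)
  if (!length(genome)) stop("empty genome")
  if (nrow(segments)) {
    unknown <- setdiff(unique(segments$chrom), names(genome))
    if (length(unknown))
      stop("segments on unknown chromosome(s): ",
           paste(unknown, collapse = ", "))
    over <- segments$end > genome[segments$chrom]
    if (any(over)) stop("segment beyond chromosome end")
  }
  if (is.null(sample_ids)) sample_ids <- sort(unique(segments$sample_id))
  bins <- .binRangesFor(genome, thresholds$bin_width)
  nb <- length(bins)
  ns <- length(sample_ids)
  status <- matrix(0L, nb, ns, dimnames = list(NULL, sample_ids))
  ev <- segments[segments$status != 0L &
                   segments$sample_id %in% sample_ids, , drop = FALSE]
  if (nrow(ev)) {
    segGR <- GRanges(ev$chrom, IRanges(ev$start + 1, ev$end))
    hits <- findOverlaps(bins, segGR)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    w <- width(pintersect(bins[qh], segGR[sh]))
    sidx <- match(ev$sample_id[sh], sample_ids)
    st <- ev$status[sh]
    for (code in c(1L, -1L)) {
      sel <- st == code
      if (!any(sel)) next
      key <- (sidx[sel] - 1L) * nb + qh[sel]
      agg <- rowsum(w[sel], key)
      flat <- as.integer(rownames(agg))
      win <- agg[, 1L] > thresholds$majority_bases
      status[flat[win]] <- code
    }
  }
  new("BinTrack", status = status, bins = bins)
}

#' Per-bin or region-level alteration frequency
#'
#' Bin-level frequency of a status is the fraction of the given samples
#' whose bin carries it; a cytoband or arm frequency is the median of
#' its member-bin frequencies.
#'
#' @param bintrack a [BinTrack-class].
#' @param sample_ids samples forming the denominator.
#' @param status `"amp"` or `"del"`.
#' @param region optional `GRanges` (one or more regions); when `NULL`
#'   the per-bin frequency vector is returned.
#' @return numeric vector: per-bin frequencies, or one median frequency
#'   per region.
#' @export
regionFrequency <- function(bintrack, sample_ids, status = c("amp", "del"),
                            region = NULL) {
  status <- match.arg(status)
  code <- if (status == "amp") 1L else -1L
  m <- binStatus(bintrack)
  missing <- setdiff(sample_ids, colnames(m))
  if (length(missing))
    stop("samples absent from bin track: ", paste(missing, collapse = ", "))
  freq <- rowMeans(m[, sample_ids, drop = FALSE] == code)
  if (is.null(region)) return(freq)
  hits <- findOverlaps(binRanges(bintrack), region)
  out <- vapply(seq_along(region), function(i) {
    memb <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]
    if (!length(memb)) stop("region with zero bins")
    stats::median(freq[memb])
  }, numeric(1L))
  names(out) <- S4Vectors::mcols(region)$name
  out
}

#' Compare regional copy-number alteration frequencies between groups
#'
#' For every cytoband and arm and each status (amplification,
#' deletion), a sample counts as altered when more than
#' `region_sample_frac` (default half) of the region's bins carry the
#' status; group counts feed the expected-count chooser test. A region
#' is flagged when p < `cytoband_p` and the larger group frequency
#' exceeds `cytoband_freq`.
#'
#' @param bintrack a [BinTrack-class] over all cohort samples.
#' @param groups named group factor/character (sample_id -> ERG_POS /
#'   ERG_NEG).
#' @param regions `GRanges` with mcols `name`, `level`.
#' @param thresholds list from [ergThresholds()].
#' @return data.frame: item, level, status, freq_pos, freq_neg, delta,
#'   test_used, p, significant.
#' @export
compareRegions <- function(bintrack, groups, regions,
                           thresholds = ergThresholds()) {
  m <- binStatus(bintrack)
  pos_ids <- intersect(names(groups)[groups == "ERG_POS"], colnames(m))
  neg_ids <- intersect(names(groups)[groups == "ERG_NEG"], colnames(m))
  np <- length(pos_ids); nn <- length(neg_ids)
  hits <- findOverlaps(binRanges(bintrack), regions)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  rows <- list()
  for (i in seq_along(regions)) {
    memb <- qh[sh == i]
    if (!length(memb)) next
    for (status in c("amp", "del")) {
      code <- if (status == "amp") 1L else -1L
      altered <- colMeans(m[memb, , drop = FALSE] == code) >
        thresholds$region_sample_frac
      a <- sum(altered[pos_ids]); cc <- sum(altered[neg_ids])
      res <- if (a + cc == 0L)
        list(statistic = NA_real_, p = NA_real_, test_used = "untestable")
      else assocTest(a, np - a, cc, nn - cc, thresholds)
      fp <- a / np; fn <- cc / nn
      rows[[length(rows) + 1L]] <- data.frame(
        item = S4Vectors::mcols(regions)$name[i],
        level = S4Vectors::mcols(regions)$level[i],
        status = status, freq_pos = fp, freq_neg = fn, delta = fn - fp,
        test_used = res$test_used, p = res$p,
        significant = !is.na(res$p) & res$p < thresholds$cytoband_p &
          max(fp, fn) > thresholds$cytoband_freq,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
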
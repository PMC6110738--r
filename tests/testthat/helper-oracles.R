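# Independent oracles kept deliberately naive: direct combinatorics and
# per-base counting, no shared code with the implementation under test.

# Two-sided Fisher p by explicit enumeration over all tables with the
# observed margins, using binomial coefficients directly.
fisherEnumOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  xs <- max(0, k - r2):min(k, r1)
  prob <- choose(r1, xs) * choose(r2, k - xs) / choose(n, k)
  obs <- prob[xs == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# Per-base brute-force binning oracle: paints every base of one sample's
# chromosome, then counts statuses inside each fixed-width bin.
perBaseBinOracle <- function(seg, chrom_len, bin_width, majority) {
  z <- integer(chrom_len)
  for (i in seq_len(nrow(seg)))
    if (seg$status[i] != 0L)
      z[(seg$start[i] + 1):seg$end[i]] <- seg$status[i]
  nbins <- ceiling(chrom_len / bin_width)
  idx <- rep(seq_len(nbins), each = bin_width, length.out = chrom_len)
  amp <- rowsum((z == 1L) * 1L, idx)[, 1L]
  del <- rowsum((z == -1L) * 1L, idx)[, 1L]
  out <- integer(nbins)
  out[amp > majority] <- 1L
  out[del > majority] <- -1L
  out
}

# Random non-overlapping ternary segment layout on one chromosome.
randomSegLayout <- function(chrom_len, sample_id = "S1", chrom = "chr1",
                            n_break = 12) {
  cuts <- sort(sample(seq_len(chrom_len - 1), n_break))
  bounds <- c(0, cuts, chrom_len)
  st <- bounds[-length(bounds)]
  en <- bounds[-1L]
  status <- sample(c(-1L, 0L, 1L), length(st), replace = TRUE)
  data.frame(sample_id = sample_id, chrom = chrom, start = st, end = en,
             value = c(-0.8, 0.01, 0.8)[status + 2L], status = status,
             stringsAsFactors = FALSE)
}

# Set-union coverage oracle: loop over samples, literal definition.
coverageOracle <- function(altered, reps, samples) {
  hit <- vapply(samples, function(s) any(altered[reps, s]), logical(1))
  mean(hit)
}

# Minimal cohort with a handful of samples for reader/assignment tests.
tinyClinical <- function(ids = c("S1", "S2", "S3")) {
  data.frame(sample_id = ids, group = "UNASSIGNED", ancestry = "UNKNOWN",
             age = NA_real_, psa = NA_real_, gleason = "UNKNOWN",
             stage = "UNKNOWN", bcr_event = "unknown", bcr_time = NA_real_,
             stringsAsFactors = FALSE)
}

# The lean simulation configuration used by the recovery suites:
# 200/300 samples, planted frequency differences of 0.25 next to matched
# null genes, and a DE structure whose true shared fraction is 70%
# (14 shared + 2 positive-only + 3 negative-only planted genes, plus the
# fusion-driven target-gene overexpression which is itself a true
# positive-only DE gene).
leanRecoveryConfig <- function(seed = 1L) {
  simConfig(
    n_pos = 200L, n_neg = 300L, n_normal = 30L,
    alt_spec = data.frame(
      gene = c("M1", "M0", "D1", "D0", "F1", "F0"),
      class = c("mut", "mut", "del", "del", "fusion", "fusion"),
      freq_pos = c(0.05, 0.10, 0.10, 0.20, 0.05, 0.10),
      freq_neg = c(0.30, 0.10, 0.35, 0.20, 0.30, 0.10),
      partner = c(NA, NA, NA, NA, "P1", "P0"),
      stringsAsFactors = FALSE),
    de_spec = data.frame(
      gene = sprintf("DEG%02d", 1:19), fold_change = 4,
      direction = rep_len(c("up", "down"), 19),
      group = rep(c("both", "pos", "neg"), c(14L, 2L, 3L)),
      stringsAsFactors = FALSE),
    meth_spec = data.frame(gene = character(), n_probes = integer(),
                           region_class = character(),
                           effect = character(), cis = logical(),
                           stringsAsFactors = FALSE),
    seed = seed)
}

# Constructed methylation fixture: `n_pass` probes engineered to survive
# all five cascade filters among decoys that each fail exactly one stage.
# 30 tumor + 30 normal samples; returns the pieces plus expected
# per-stage survivor counts.
methCascadeFixture <- function(n_pass = 5L, n_per_decoy = 20L, seed = 42L) {
  set.seed(seed)
  tumor <- sprintf("T%02d", 1:30)
  normal <- sprintf("N%02d", 1:30)
  ids <- c(tumor, normal)
  probes <- list(); anno <- list(); genes_down <- character()
  expr_rows <- list()
  add <- function(name, chrom, gene, cls, beta, down_gene) {
    probes[[name]] <<- beta
    anno[[name]] <<- data.frame(probe = name, chrom = chrom, gene = gene,
                                region_class = cls,
                                stringsAsFactors = FALSE)
    if (down_gene) genes_down <<- c(genes_down, gene)
  }
  # betas decreasing in expression -> strong negative cis correlation
  mkbeta <- function(expr_z, hi = 0.75, slope = -0.1, noise = 0.02) {
    pmin(pmax(hi + slope * expr_z + stats::rnorm(30, 0, noise), 0.01), 0.99)
  }
  k <- 0L
  gene_expr <- function(gene, down) {
    mu <- if (down) c(rep(100, 30), rep(400, 30)) else rep(400, 60)
    cnt <- stats::rnbinom(60, mu = mu, size = 20)
    expr_rows[[gene]] <<- cnt
    cnt
  }
  for (i in seq_len(n_pass)) {
    k <- k + 1L; g <- sprintf("GP%02d", i)
    cnt <- gene_expr(g, down = TRUE)
    z <- as.numeric(scale(log2(cnt[1:30] + 1)))
    add(sprintf("pass%02d", i), "chr1", g, "TSS200",
        c(mkbeta(z), stats::rbeta(30, 2, 8) * 0.3 + 0.05), TRUE)
  }
  for (i in seq_len(n_per_decoy)) {   # stage 1: sex chromosome
    g <- sprintf("GX%02d", i); gene_expr(g, TRUE)
    add(sprintf("sex%02d", i), "chrX", g, "TSS200",
        c(rep(0.7, 30), rep(0.2, 30)), FALSE)
  }
  for (i in seq_len(n_per_decoy)) {   # stage 2: delta beta too small
    g <- sprintf("GD%02d", i)
    cnt <- gene_expr(g, TRUE); z <- as.numeric(scale(log2(cnt[1:30] + 1)))
    add(sprintf("small%02d", i), "chr2", g, "TSS200",
        c(mkbeta(z, hi = 0.3, slope = -0.02), rep(0.2, 30) +
            stats::rnorm(30, 0, 0.01)), FALSE)
  }
  for (i in seq_len(n_per_decoy)) {   # stage 3: non-promoter probe
    g <- sprintf("GB%02d", i)
    cnt <- gene_expr(g, TRUE); z <- as.numeric(scale(log2(cnt[1:30] + 1)))
    add(sprintf("body%02d", i), "chr3", g, "other",
        c(mkbeta(z), stats::rbeta(30, 2, 8) * 0.3 + 0.05), FALSE)
  }
  for (i in seq_len(n_per_decoy)) {   # stage 4: positive correlation
    g <- sprintf("GC%02d", i)
    cnt <- gene_expr(g, TRUE); z <- as.numeric(scale(log2(cnt[1:30] + 1)))
    add(sprintf("poscor%02d", i), "chr4", g, "TSS200",
        c(mkbeta(z, slope = +0.1), stats::rbeta(30, 2, 8) * 0.3 + 0.05),
        FALSE)
  }
  for (i in seq_len(n_per_decoy)) {   # stage 5: gene not down in tumor
    g <- sprintf("GU%02d", i)
    cnt <- gene_expr(g, FALSE); z <- as.numeric(scale(log2(cnt[1:30] + 1)))
    add(sprintf("flat%02d", i), "chr5", g, "TSS200",
        c(mkbeta(z), stats::rbeta(30, 2, 8) * 0.3 + 0.05), FALSE)
  }
  meth <- do.call(rbind, probes)
  dimnames(meth) <- list(names(probes), ids)
  expr <- do.call(rbind, expr_rows)
  dimnames(expr) <- list(names(expr_rows), ids)
  list(meth = meth, anno = do.call(rbind, anno), expr = expr,
       tumor = tumor, normal = normal,
       expected = c(stage1 = n_pass + 4L * n_per_decoy,
                    stage2 = n_pass + 3L * n_per_decoy,
                    stage3 = n_pass + 2L * n_per_decoy,
                    stage4 = n_pass + 1L * n_per_decoy,
                    stage5 = n_pass),
       n_pass = n_pass)
}
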
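#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure the generator plants: group sizes,
#' per-gene alteration frequencies per group and event class, the
#' copy-number/expression coupling, the methylation/expression cis
#' coupling, differential-expression effects, clinical category
#' proportions per group, and the recurrence hazard model. Defaults
#' emulate a two-group tumor cohort of the kind the pipeline targets:
#' ~200/300 samples, a handful of group-enriched mutation, deletion,
#' amplification and fusion genes at frequencies in the 4-35\% range,
#' negative-binomial counts (dispersion 0.1), beta-distributed
#' methylation (baseline mean 0.2, hypermethylated mean 0.7), and a
#' miniature multi-chromosome genome so the 10 kb binning has structure
#' to work on.
#'
#' @param n_pos,n_neg,n_normal sample counts (tumor groups and normals).
#' @param alt_spec data.frame(gene, class, freq_pos, freq_neg, partner)
#'   with class in mut/amp/del/fusion; partner required for fusions.
#' @param de_spec data.frame(gene, fold_change, direction, group) with
#'   direction up/down and group both/pos/neg (tumor vs normal shift).
#' @param meth_spec data.frame(gene, n_probes, region_class, effect,
#'   cis) with effect in tumor/neg/pos/none.
#' @param cnv_expr_effect log2 expression shift per copy gain (negated
#'   for losses).
#' @param meth_expr_rho target negative beta/expression correlation for
#'   cis-flagged probes (approximate, logit-scale coupling).
#' @param erg_fusion plant the subtype-defining 3' fusion (gene "ERG",
#'   5' partner TMPRSS2 94.1\% / SLC45A3 otherwise) in every positive
#'   sample, with dual-source evidence.
#' @param erg_expr_fold expression fold of the target gene in
#'   fusion-positive samples.
#' @param clinical_props optional per-variable list of per-group
#'   category probabilities (defaults mirror the published cohort).
#' @param bcr list(base_hazard, hr, stratum, censor_time): exponential
#'   recurrence times; `stratum` is "group" or a gene symbol.
#' @param chrom_sizes named toy chromosome lengths (bp).
#' @param n_background_genes unaltered filler genes.
#' @param seed integer random seed.
#' @return validated config list of class `SimConfig`.
#' @export
simConfig <- function(n_pos = 200L, n_neg = 300L, n_normal = 52L,
                      alt_spec = NULL, de_spec = NULL, meth_spec = NULL,
                      cnv_expr_effect = 1, meth_expr_rho = -0.6,
                      erg_fusion = TRUE, erg_expr_fold = 8,
                      clinical_props = NULL,
                      bcr = list(base_hazard = 0.004, hr = 1,
                                 stratum = "group", censor_time = 120),
                      chrom_sizes = c(chr1 = 3e6, chr2 = 3e6,
                                      chr3 = 3e6, chr4 = 3e6),
                      n_background_genes = 200L, seed = 1L) {
  if (is.null(alt_spec)) {
    alt_spec <- data.frame(
      gene = c("SPOP", "CDK12", "TP53", "MYC", "ZNF292", "FRK",
               "NKX3-1", "RB1", "CDH13", "PTEN", "TTC6", "ETV1"),
      class = c("mut", "mut", "mut", "amp", "del", "del",
                "del", "del", "del", "del", "fusion", "fusion"),
      freq_pos = c(0.04, 0.01, 0.10, 0.08, 0.08, 0.08,
                   0.30, 0.22, 0.20, 0.18, 0.00, 0.00),
      freq_neg = c(0.12, 0.05, 0.08, 0.25, 0.22, 0.223,
                   0.35, 0.25, 0.22, 0.10, 0.037, 0.047),
      partner = c(rep(NA, 10), "MIPOL1", "PRT01"),
      stringsAsFactors = FALSE)
  }
  if (is.null(de_spec)) {
    de_spec <- data.frame(
      gene = c(sprintf("DEG%02d", 1:6), "HYPT01", "HYPT02"),
      fold_change = 4,
      direction = c(rep(c("up", "down"), 3), "down", "down"),
      group = c(rep("both", 4), "pos", "neg", "both", "both"),
      stringsAsFactors = FALSE)
  }
  if (is.null(meth_spec)) {
    meth_spec <- data.frame(
      gene = c("HYPT01", "HYPT02", "DEG01", "DEG02"),
      n_probes = c(2L, 1L, 1L, 1L),
      region_class = c("TSS200", "TSS1500", "TSS200", "other"),
      effect = c("tumor", "tumor", "none", "none"),
      cis = c(TRUE, TRUE, FALSE, FALSE),
      stringsAsFactors = FALSE)
  }
  if (is.null(clinical_props)) {
    clinical_props <- list(
      gleason = list(
        pos = c(LE6 = 19, G3p4 = 70, G4p3_8to10 = 111, UNKNOWN = 1) / 201,
        neg = c(LE6 = 25, G3p4 = 76, G4p3_8to10 = 195, UNKNOWN = 0) / 296),
      stage = list(
        pos = c(pT2ab = 14, pT2c = 64, pT3a = 65, pT3b = 54, pT4 = 3,
                UNKNOWN = 1) / 201,
        neg = c(pT2ab = 9, pT2c = 100, pT3a = 93, pT3b = 81, pT4 = 7,
                UNKNOWN = 6) / 296),
      ancestry = list(
        pos = c(CA = 131, AA = 14, ASIAN = 2, UNKNOWN = 54) / 201,
        neg = c(CA = 148, AA = 26, ASIAN = 3, UNKNOWN = 119) / 296))
  }
  cfg <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              n_normal = as.integer(n_normal), alt_spec = alt_spec,
              de_spec = de_spec, meth_spec = meth_spec,
              cnv_expr_effect = cnv_expr_effect,
              meth_expr_rho = meth_expr_rho, erg_fusion = erg_fusion,
              erg_expr_fold = erg_expr_fold,
              clinical_props = clinical_props, bcr = bcr,
              chrom_sizes = chrom_sizes,
              n_background_genes = as.integer(n_background_genes),
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' @rdname simConfig
#' @param config a `SimConfig`.
#' @export
validateSimConfig <- function(config) {
  a <- config$alt_spec
  if (config$n_pos < 2L || config$n_neg < 2L)
    stop("need at least 2 samples per group")
  if (nrow(a)) {
    if (!all(a$class %in% .EVENT_CLASSES)) stop("unknown event class")
    if (any(a$freq_pos < 0 | a$freq_pos > 1 | a$freq_neg < 0 |
              a$freq_neg > 1))
      stop("alteration frequencies must lie in [0,1]")
    fus <- a[a$class == "fusion", , drop = FALSE]
    if (nrow(fus) && (any(is.na(fus$partner)) ||
                      any(fus$partner == fus$gene)))
      stop("fusion event without a distinct partner gene")
  }
  if (nrow(config$de_spec) &&
      !all(config$de_spec$direction %in% c("up", "down")))
    stop("de_spec direction must be up/down")
  invisible(TRUE)
}

.placeGenes <- function(symbols, roles, chrom_sizes) {
  nc <- length(chrom_sizes)
  spacing <- 250000; offset <- 150000; gwidth <- 20000
  chrom <- names(chrom_sizes)[((seq_along(symbols) - 1L) %% nc) + 1L]
  slot <- (seq_along(symbols) - 1L) %/% nc
  start <- offset + slot * spacing
  if (any(start + gwidth + 60000 > chrom_sizes[chrom]))
    stop("too many genes for the toy genome; enlarge chrom_sizes")
  gr <- GRanges(chrom, IRanges(start = start + 1, width = gwidth))
  S4Vectors::mcols(gr)$symbol <- symbols
  S4Vectors::mcols(gr)$role <- roles
  GenomeInfoDb::seqlengths(gr) <- chrom_sizes[GenomeInfoDb::seqlevels(gr)]
  gr
}

.armRegions <- function(chrom_sizes) {
  rows <- list()
  for (ch in names(chrom_sizes)) {
    size <- chrom_sizes[[ch]]
    cen <- floor(size * 0.4 / 10000) * 10000   # bin-aligned centromere
    arms <- list(p = c(0, cen), q = c(cen, size))
    for (arm in names(arms)) {
      s <- arms[[arm]][1L]; e <- arms[[arm]][2L]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e, name = paste0(ch, arm),
        level = "arm", stringsAsFactors = FALSE)
      mid <- floor((s + e) / 2 / 10000) * 10000
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = c(s, mid), end = c(mid, e),
        name = paste0(ch, arm, 1:2), level = "cytoband",
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GRanges(df$chrom, IRanges(start = df$start + 1, end = df$end))
  S4Vectors::mcols(gr)$name <- df$name
  S4Vectors::mcols(gr)$level <- df$level
  gr
}

.drawCategories <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a full synthetic cohort
#'
#' Draws every layer the pipeline consumes under one seed: clinical
#' records with group-dependent category proportions and exponential
#' recurrence times, dual-source fusion calls (including the planted
#' subtype-defining fusion), nonsilent/silent mutation records,
#' SEG-style copy-number segments (whole-gene events at log2 +/-0.8
#' with a 50 kb flank over a neutral background), negative-binomial
#' expression counts coupled to copy number and to the planted
#' differential-expression effects, and beta-distributed methylation
#' with negative cis coupling for flagged probes. Identical seeds give
#' identical cohorts; per-gene event indicators are independent
#' binomial draws at the configured group frequencies.
#'
#' @param config a `SimConfig` from [simConfig()].
#' @return list with `cohort` (an [ErgCohort-class], groups assigned
#'   from the simulated fusion calls), `normal_ids`, and `truth`
#'   (realized events per gene/class/sample and the planted specs).
#' @export
simulateCohort <- function(config) {
  validateSimConfig(config)
  set.seed(config$seed)
  np <- config$n_pos; nn <- config$n_neg; nm <- config$n_normal
  pos_ids <- sprintf("POS%04d", seq_len(np))
  neg_ids <- sprintf("NEG%04d", seq_len(nn))
  norm_ids <- if (nm) sprintf("NORM%03d", seq_len(nm)) else character()
  tumor_ids <- c(pos_ids, neg_ids)
  a <- config$alt_spec

  ## gene universe and annotation
  partner_genes <- unique(stats::na.omit(a$partner))
  erg_genes <- if (config$erg_fusion) c("ERG", "TMPRSS2", "SLC45A3")
  else character()
  bg <- if (config$n_background_genes)
    sprintf("BG%03d", seq_len(config$n_background_genes)) else character()
  ## only genes that need genomic coordinates (events, fusion partners,
  ## methylation cis partners) are placed on the toy genome; the expression
  ## background stays coordinate-free so the count universe can be large
  placed <- unique(c(a$gene, partner_genes, erg_genes,
                     config$meth_spec$gene))
  symbols <- unique(c(placed, config$de_spec$gene, bg))
  roles <- rep("OTHER", length(placed))
  roles[placed %in% a$gene[a$class == "del"]] <- "TSG"
  roles[placed %in% a$gene[a$class == "amp"]] <- "ONCOGENE"
  genes <- .placeGenes(placed, roles, config$chrom_sizes)
  regions <- .armRegions(config$chrom_sizes)

  ## realized alteration events: independent binomial draws per gene
  events <- list()
  for (i in seq_len(nrow(a))) {
    hit <- c(pos_ids[stats::runif(np) < a$freq_pos[i]],
             neg_ids[stats::runif(nn) < a$freq_neg[i]])
    if (length(hit))
      events[[length(events) + 1L]] <- data.frame(
        gene = a$gene[i], class = a$class[i], sample_id = hit,
        stringsAsFactors = FALSE)
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(gene = character(), class = character(),
               sample_id = character(), stringsAsFactors = FALSE)

  ## fusions
  fus_rows <- list()
  if (config$erg_fusion) {
    partner <- ifelse(stats::runif(np) < 0.941, "TMPRSS2", "SLC45A3")
    in_a <- stats::runif(np) < 0.85
    in_b <- stats::runif(np) < 0.85
    in_a[!in_a & !in_b] <- TRUE
    for (i in seq_len(np)) {
      src <- c("SOURCE_A", "SOURCE_B")[c(in_a[i], in_b[i])]
      fus_rows[[length(fus_rows) + 1L]] <- data.frame(
        sample_id = pos_ids[i], gene_5p = partner[i], gene_3p = "ERG",
        source = src, stringsAsFactors = FALSE)
    }
  }
  fev <- events[events$class == "fusion", , drop = FALSE]
  if (nrow(fev)) {
    prt <- stats::setNames(a$partner, a$gene)
    for (i in seq_len(nrow(fev))) {
      both <- stats::runif(1) < 0.5
      src <- if (both) c("SOURCE_A", "SOURCE_B") else
        sample(c("SOURCE_A", "SOURCE_B"), 1L)
      fus_rows[[length(fus_rows) + 1L]] <- data.frame(
        sample_id = fev$sample_id[i], gene_5p = unname(prt[fev$gene[i]]),
        gene_3p = fev$gene[i], source = src, stringsAsFactors = FALSE)
    }
  }
  fusions <- if (length(fus_rows)) do.call(rbind, fus_rows) else
    .emptyFusions()

  ## mutations (+ silent background noise)
  mev <- events[events$class == "mut", , drop = FALSE]
  mutations <- if (nrow(mev)) data.frame(
    sample_id = mev$sample_id, gene = mev$gene,
    variant_class = "nonsilent", stringsAsFactors = FALSE)
  else .emptyMutations()
  if (length(bg)) {
    sil <- which(stats::runif(length(bg) * length(tumor_ids)) < 0.01)
    if (length(sil)) {
      gi <- ((sil - 1L) %% length(bg)) + 1L
      si <- ((sil - 1L) %/% length(bg)) + 1L
      mutations <- rbind(mutations, data.frame(
        sample_id = tumor_ids[si], gene = bg[gi],
        variant_class = "silent", stringsAsFactors = FALSE))
    }
  }

  ## copy-number segments: gene +/- 50 kb events over a neutral background
  cev <- events[events$class %in% c("amp", "del"), , drop = FALSE]
  gstart <- stats::setNames(GenomicRanges::start(genes) - 1,
                            S4Vectors::mcols(genes)$symbol)
  gend <- stats::setNames(GenomicRanges::end(genes),
                          S4Vectors::mcols(genes)$symbol)
  gchrom <- stats::setNames(as.character(seqnames(genes)),
                            S4Vectors::mcols(genes)$symbol)
  sid <- character(); sch <- character()
  sst <- numeric(); sen <- numeric(); sva <- numeric()
  ev_key <- if (nrow(cev)) paste(cev$sample_id, gchrom[cev$gene]) else
    character()
  combos <- expand.grid(sample_id = tumor_ids,
                        chrom = names(config$chrom_sizes),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plain <- !paste(combos$sample_id, combos$chrom) %in% ev_key
  n_plain <- sum(plain)
  if (n_plain) {
    sid <- combos$sample_id[plain]
    sch <- combos$chrom[plain]
    sst <- rep(0, n_plain)
    sen <- unname(unlist(config$chrom_sizes)[sch])
    sva <- round(stats::runif(n_plain, -0.05, 0.05), 4)
  }
  if (nrow(cev)) {
    splitkey <- paste(cev$sample_id, gchrom[cev$gene])
    for (k in unique(splitkey)) {
      e_ch <- cev[splitkey == k, , drop = FALSE]
      s <- e_ch$sample_id[1L]
      ch <- gchrom[[e_ch$gene[1L]]]
      size <- config$chrom_sizes[[ch]]
      st <- pmax(0, gstart[e_ch$gene] - 50000)
      en <- pmin(size, gend[e_ch$gene] + 50000)
      o <- order(st)
      st <- st[o]; en <- en[o]
      val <- ifelse(e_ch$class[o] == "amp", 0.8, -0.8)
      bounds <- c(0, as.vector(rbind(st, en)), size)
      starts <- bounds[-length(bounds)]
      ends <- bounds[-1L]
      vals <- rep(NA_real_, length(starts))
      vals[seq_along(st) * 2] <- val   # even slots are the event intervals
      keep <- ends > starts
      starts <- starts[keep]; ends <- ends[keep]; vals <- vals[keep]
      neutral <- is.na(vals)
      vals[neutral] <- round(stats::runif(sum(neutral), -0.05, 0.05), 4)
      sid <- c(sid, rep(s, length(starts)))
      sch <- c(sch, rep(ch, length(starts)))
      sst <- c(sst, starts); sen <- c(sen, ends); sva <- c(sva, vals)
    }
  }
  segments <- if (length(sid))
    data.frame(sample_id = sid, chrom = sch, start = sst, end = sen,
               value = sva, stringsAsFactors = FALSE)
  else .emptySegments()

  ## expression: NB counts with CNV, DE and fusion-activation effects
  all_ids <- c(tumor_ids, norm_ids)
  ngene <- length(symbols)
  mu_g <- exp(stats::rnorm(ngene, log(300), 0.7))
  lfc <- matrix(0, ngene, length(all_ids),
                dimnames = list(symbols, all_ids))
  if (nrow(cev)) {
    sign_ev <- ifelse(cev$class == "amp", 1, -1) * config$cnv_expr_effect
    lfc[cbind(match(cev$gene, symbols), match(cev$sample_id, all_ids))] <-
      sign_ev
  }
  d <- config$de_spec
  for (i in seq_len(nrow(d))) {
    tg <- switch(d$group[i], both = tumor_ids, pos = pos_ids,
                 neg = neg_ids)
    sh <- log2(d$fold_change[i]) * ifelse(d$direction[i] == "up", 1, -1)
    lfc[d$gene[i], tg] <- lfc[d$gene[i], tg] + sh
  }
  if (config$erg_fusion) {
    fus_pos <- unique(fusions$sample_id[fusions$gene_3p == "ERG"])
    lfc["ERG", fus_pos] <- lfc["ERG", fus_pos] + log2(config$erg_expr_fold)
  }
  libf <- exp(stats::rnorm(length(all_ids), 0, 0.2))
  mu <- mu_g * 2^lfc
  mu <- sweep(mu, 2L, libf, "*")
  expr <- matrix(stats::rnbinom(length(mu), mu = mu, size = 10),
                 ngene, length(all_ids),
                 dimnames = list(symbols, all_ids))

  ## methylation: beta-distributed probes, optional cis coupling
  ms <- config$meth_spec
  probe_rows <- list(); beta_rows <- list()
  if (nrow(ms)) {
    lexpr <- cpmLog2(expr)
    conc <- 10
    for (i in seq_len(nrow(ms))) {
      g <- ms$gene[i]
      eff_ids <- switch(ms$effect[i], tumor = tumor_ids, pos = pos_ids,
                        neg = neg_ids, none = character())
      m_s <- stats::setNames(rep(0.2, length(all_ids)), all_ids)
      m_s[eff_ids] <- 0.7
      for (k in seq_len(ms$n_probes[i])) {
        pr <- sprintf("cg_%s_%d", g, k)
        lgt <- stats::qlogis(m_s) + stats::rnorm(length(all_ids), 0, 0.6)
        if (isTRUE(ms$cis[i])) {
          z <- as.numeric(scale(lexpr[g, all_ids]))
          rho <- abs(config$meth_expr_rho)
          w <- rho / sqrt(1 - rho^2) * 0.6
          lgt <- lgt - w * z
        }
        beta_rows[[pr]] <- stats::rbeta(
          length(all_ids), shape1 = stats::plogis(lgt) * conc,
          shape2 = (1 - stats::plogis(lgt)) * conc)
        probe_rows[[length(probe_rows) + 1L]] <- data.frame(
          probe = pr, chrom = gchrom[[g]], gene = g,
          region_class = ms$region_class[i], stringsAsFactors = FALSE)
      }
    }
  }
  meth <- if (length(beta_rows)) {
    m <- do.call(rbind, beta_rows)
    dimnames(m) <- list(names(beta_rows), all_ids)
    m
  } else matrix(numeric(), 0, 0)
  probe_anno <- if (length(probe_rows)) do.call(rbind, probe_rows) else
    .emptyProbeAnno()

  ## clinical covariates, group labels from the simulated fusion calls
  asg <- assignGroups(fusions, sample_ids = tumor_ids)
  grp <- stats::setNames(asg$group, asg$sample_id)
  cp <- config$clinical_props
  drawvar <- function(var) {
    v <- character(length(tumor_ids))
    v[seq_len(np)] <- .drawCategories(np, cp[[var]]$pos)
    v[np + seq_len(nn)] <- .drawCategories(nn, cp[[var]]$neg)
    v
  }
  bcfg <- config$bcr
  risk <- if (identical(bcfg$stratum, "group")) {
    grp[tumor_ids] == "ERG_NEG"
  } else {
    tumor_ids %in% events$sample_id[events$gene == bcfg$stratum]
  }
  rate <- bcfg$base_hazard * ifelse(risk, bcfg$hr, 1)
  t_ev <- stats::rexp(length(tumor_ids), rate)
  event <- t_ev <= bcfg$censor_time
  cl <- data.frame(
    sample_id = c(tumor_ids, norm_ids),
    group = c(unname(grp[tumor_ids]), rep("UNASSIGNED", nm)),
    ancestry = c(drawvar("ancestry"), rep("UNKNOWN", nm)),
    age = round(c(stats::rnorm(length(tumor_ids), 61.5, 6),
                  rep(NA_real_, nm))),
    psa = round(c(stats::rlnorm(length(tumor_ids), log(1.7), 0.8),
                  rep(NA_real_, nm)), 2),
    gleason = c(drawvar("gleason"), rep("UNKNOWN", nm)),
    stage = c(drawvar("stage"), rep("UNKNOWN", nm)),
    bcr_event = c(ifelse(event, "yes", "no"), rep("unknown", nm)),
    bcr_time = c(pmax(round(pmin(t_ev, bcfg$censor_time), 1), 0.1),
                 rep(NA_real_, nm)),
    tissue = rep(c("tumor", "normal"), c(length(tumor_ids), nm)),
    stringsAsFactors = FALSE)

  cohort <- ErgCohort(clinical = cl, fusions = fusions,
                      mutations = mutations, segments = segments,
                      expression = expr, methylation = meth,
                      probe_anno = probe_anno, genes = genes,
                      regions = regions,
                      genome = unlist(config$chrom_sizes))
  list(cohort = cohort, normal_ids = norm_ids,
       truth = list(events = events, groups = grp,
                    de_spec = config$de_spec,
                    meth_spec = config$meth_spec))
}
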
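#' Assign fusion-defined groups from dual-source fusion calls
#'
#' A sample is ERG-positive when any fusion call with the target gene at
#' the 3' end is present in either evidence source; all other cohort
#' samples are ERG-negative. Assignment is idempotent and independent of
#' the row order of the fusion table. Samples supported by exactly one
#' source are flagged as candidates for the expression check
#' (see [expressionCheck()]).
#'
#' @param fusions fusion-call data.frame (sample_id, gene_5p, gene_3p,
#'   source) or an `ErgCohort`.
#' @param sample_ids all cohort sample identifiers (taken from the
#'   clinical table when `fusions` is a cohort).
#' @param target_gene 3' fusion partner defining the positive group.
#' @return data.frame with sample_id, group, evidence (comma-separated
#'   source set), single_source (logical: supported by exactly one
#'   source).
#' @export
assignGroups <- function(fusions, sample_ids = NULL, target_gene = "ERG") {
  if (is(fusions, "ErgCohort")) {
    if (is.null(sample_ids)) sample_ids <- clinical(fusions)$sample_id
    fusions <- fusionCalls(fusions)
  }
  stopifnot(!is.null(sample_ids))
  hit <- fusions[fusions$gene_3p == target_gene, , drop = FALSE]
  ev <- lapply(split(hit$source, hit$sample_id), function(s) sort(unique(s)))
  out <- data.frame(sample_id = as.character(sample_ids),
                    group = "ERG_NEG",
                    evidence = "",
                    single_source = FALSE,
                    stringsAsFactors = FALSE)
  idx <- match(names(ev), out$sample_id)
  keep <- !is.na(idx)
  out$group[idx[keep]] <- "ERG_POS"
  out$evidence[idx[keep]] <- vapply(ev[keep], paste, character(1L),
                                    collapse = ",")
  out$single_source[idx[keep]] <- lengths(ev[keep]) == 1L
  out
}

#' Stratify a cohort in place
#'
#' Runs [assignGroups()] on the cohort's own fusion calls and writes the
#' labels into the clinical table.
#'
#' @param cohort an `ErgCohort`.
#' @param target_gene 3' fusion partner defining the positive group.
#' @return the cohort with groups assigned.
#' @export
stratifyCohort <- function(cohort, target_gene = "ERG") {
  asg <- assignGroups(cohort, target_gene = target_gene)
  g <- stats::setNames(asg$group, asg$sample_id)
  sampleGroups(cohort) <- g
  cohort
}

#' Expression support check for ambiguously called samples
#'
#' Tests whether the target gene is expressed higher in a set of
#' ambiguous samples than in confirmed fusion-negative samples (Welch t
#' on log2-CPM). With a single ambiguous sample a z-score against the
#' negative-group distribution is used instead (a Welch test needs two
#' observations per side).
#'
#' @param cohort an `ErgCohort` with groups assigned.
#' @param ambiguous_ids sample identifiers to check.
#' @param target_gene gene whose expression carries the evidence.
#' @param tail `"two"` (default) or `"greater"`.
#' @return list with `p`, `statistic`, `test_used`, and `support`
#'   (`TRUE` when p < `thresholds$expr_check_p`).
#' @export
expressionCheck <- function(cohort, ambiguous_ids, target_gene = "ERG",
                            tail = "two") {
  expr <- exprCounts(cohort)
  if (!target_gene %in% rownames(expr))
    stop("target gene ", target_gene, " absent from expression matrix")
  th <- thresholds(cohort)
  g <- sampleGroups(cohort)
  neg_ids <- setdiff(names(g)[g == "ERG_NEG" & names(g) %in% colnames(expr)],
                     ambiguous_ids)
  ambiguous_ids <- intersect(ambiguous_ids, colnames(expr))
  if (!length(ambiguous_ids)) stop("no ambiguous sample in expression matrix")
  lx <- cpmLog2(expr)[target_gene, ]
  x <- lx[ambiguous_ids]
  y <- lx[neg_ids]
  if (length(x) == 1L) {
    z <- (x - mean(y)) / stats::sd(y)
    p <- if (tail == "two") 2 * stats::pnorm(-abs(z)) else
      stats::pnorm(z, lower.tail = FALSE)
    res <- list(statistic = unname(z), p = unname(p), test_used = "z_score")
  } else {
    res <- welchT(x, y, tail = if (tail == "two") "two" else "greater")
  }
  res$support <- res$p < th$expr_check_p
  res
}

.clinicalRowSets <- function(cl) {
  list(
    gleason = list(var = "gleason",
                   cats = c("LE6", "G3p4", "G4p3_8to10")),
    stage = list(var = "stage",
                 cats = c("pT2ab", "pT2c", "pT3a", "pT3b", "pT4")),
    ancestry = list(var = "ancestry", cats = c("CA", "AA", "ASIAN")),
    psa_recurrence = list(var = "bcr_event", cats = c("yes", "no"))
  )
}

#' Group-stratified clinical association table
#'
#' One row per category of Gleason grade, pathologic stage, ancestry and
#' PSA recurrence: per-group counts and the 2x2 association test of that
#' category against all other samples. Samples with unknown values stay
#' in the complement, so denominators are always the full group sizes.
#' Rows whose table is degenerate (e.g. one group empty) carry the error
#' in `test_used` instead of a p-value.
#'
#' @param cohort an `ErgCohort` with groups assigned.
#' @return data.frame: variable, category, overall, n_pos, n_neg,
#'   freq_pos, freq_neg, test_used, p.
#' @export
clinicalTable <- function(cohort) {
  cl <- clinical(cohort)
  th <- thresholds(cohort)
  pos <- cl$group == "ERG_POS"
  neg <- cl$group == "ERG_NEG"
  np <- sum(pos); nn <- sum(neg)
  rows <- list()
  for (set in .clinicalRowSets(cl)) {
    v <- cl[[set$var]]
    for (cat in set$cats) {
      a <- sum(pos & v == cat); cc <- sum(neg & v == cat)
      res <- tryCatch(assocTest(a, np - a, cc, nn - cc, th),
                      error = function(e)
                        list(statistic = NA_real_, p = NA_real_,
                             test_used = paste0("error: ", conditionMessage(e))))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = set$var, category = cat, overall = a + cc,
        n_pos = a, n_neg = cc,
        freq_pos = if (np) a / np else NA_real_,
        freq_neg = if (nn) cc / nn else NA_real_,
        test_used = res$test_used, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Reference clinical cohort from published marginal counts
#'
#' Reconstructs a 497-sample cohort (201 fusion-positive, 296
#' fusion-negative) whose per-group category counts equal the published
#' clinical distribution table of the TCGA primary prostate cancer
#' analysis: Gleason 19/70/111 vs 25/76/195, stages 14/64/65/54/3 vs
#' 9/100/93/81/7, ancestry 131/14/2 vs 148/26/3, PSA recurrence 23/146
#' vs 35/215, remainders unknown. Individual category assignments are
#' independent across variables (only the margins are published), which
#' is exactly what the per-row association tests consume.
#'
#' @return An [ErgCohort-class] with a clinical layer only.
#' @export
table1Cohort <- function() {
  fill <- function(n, counts, cats, unknown) {
    v <- rep(unknown, n)
    i <- 1L
    for (k in seq_along(cats)) {
      if (counts[k] > 0L) v[i:(i + counts[k] - 1L)] <- cats[k]
      i <- i + counts[k]
    }
    v
  }
  np <- 201L; nn <- 296L
  cl <- data.frame(
    sample_id = c(sprintf("POS%03d", seq_len(np)),
                  sprintf("NEG%03d", seq_len(nn))),
    group = rep(c("ERG_POS", "ERG_NEG"), c(np, nn)),
    ancestry = c(fill(np, c(131L, 14L, 2L), c("CA", "AA", "ASIAN"), "UNKNOWN"),
                 fill(nn, c(148L, 26L, 3L), c("CA", "AA", "ASIAN"), "UNKNOWN")),
    age = NA_real_, psa = NA_real_,
    gleason = c(fill(np, c(19L, 70L, 111L), c("LE6", "G3p4", "G4p3_8to10"),
                     "UNKNOWN"),
                fill(nn, c(25L, 76L, 195L), c("LE6", "G3p4", "G4p3_8to10"),
                     "UNKNOWN")),
    stage = c(fill(np, c(14L, 64L, 65L, 54L, 3L),
                   c("pT2ab", "pT2c", "pT3a", "pT3b", "pT4"), "UNKNOWN"),
              fill(nn, c(9L, 100L, 93L, 81L, 7L),
                   c("pT2ab", "pT2c", "pT3a", "pT3b", "pT4"), "UNKNOWN")),
    bcr_event = c(fill(np, c(23L, 146L), c("yes", "no"), "unknown"),
                  fill(nn, c(35L, 215L), c("yes", "no"), "unknown")),
    bcr_time = NA_real_,
    stringsAsFactors = FALSE)
  ErgCohort(clinical = cl)
}

#' Biochemical-recurrence survival comparison
#'
#' Log-rank comparison of recurrence-free survival between two strata
#' (by default the fusion groups). Samples with unknown event status or
#' missing follow-up time are excluded; each stratum must retain at
#' least two samples.
#'
#' @param cohort an `ErgCohort` with bcr_event / bcr_time filled.
#' @param strata named vector (by sample_id) with two levels, or `NULL`
#'   for the fusion groups.
#' @return list with `statistic`, `p`, `test_used`, and `table` (per
#'   stratum: n, events).
#' @export
bcrCompare <- function(cohort, strata = NULL) {
  cl <- clinical(cohort)
  if (is.null(strata)) {
    strata <- stats::setNames(cl$group, cl$sample_id)
    strata <- strata[strata %in% c("ERG_POS", "ERG_NEG")]
  }
  s <- as.character(strata[cl$sample_id])
  usable <- !is.na(s) & cl$bcr_event %in% c("yes", "no") & !is.na(cl$bcr_time)
  cl <- cl[usable, , drop = FALSE]
  s <- s[usable]
  lv <- sort(unique(s))
  if (length(lv) != 2L) stop("need exactly two strata with usable data")
  i1 <- s == lv[1L]; i2 <- s == lv[2L]
  if (sum(i1) < 2L || sum(i2) < 2L)
    stop("need at least 2 usable samples per stratum")
  res <- logrankTest(cl$bcr_time[i1], cl$bcr_event[i1] == "yes",
                     cl$bcr_time[i2], cl$bcr_event[i2] == "yes")
  res$table <- data.frame(stratum = lv, n = c(sum(i1), sum(i2)),
                          events = c(sum(cl$bcr_event[i1] == "yes"),
                                     sum(cl$bcr_event[i2] == "yes")),
                          stringsAsFactors = FALSE)
  res
}
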
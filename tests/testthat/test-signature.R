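mkAm <- function(calls_list, samples) {
  genes <- names(calls_list)
  calls <- array(FALSE, c(length(genes), length(samples), 4),
                 dimnames = list(genes, samples,
                                 c("mut", "amp", "del", "fusion")))
  for (g in genes)
    for (cls in names(calls_list[[g]]))
      calls[g, calls_list[[g]][[cls]], cls] <- TRUE
  new("AlterationMatrix", calls = calls)
}

test_that("candidate selection applies the recurrence floors", {
  pos <- sprintf("P%02d", 1:50); neg <- sprintf("N%02d", 1:100)
  groups <- setNames(rep(c("ERG_POS", "ERG_NEG"), c(50, 100)), c(pos, neg))
  am <- mkAm(list(
    MUT11 = list(mut = neg[1:11]),          # 11% mutation -> candidate
    DEL14 = list(del = neg[1:14]),          # 14% SCNA -> below floor
    DEL20 = list(del = c(neg[1:20], pos[1:2]))), c(pos, neg))
  cand <- selectCandidates(am, groups)
  expect_setequal(cand$gene, c("MUT11", "DEL20"))
  expect_equal(cand$event_class[cand$gene == "MUT11"], "mut")
  d20 <- cand[cand$gene == "DEL20", ]
  expect_equal(d20$freq_neg, 0.20)
  expect_true(d20$higher_in_neg)   # 20% vs 4%
  cand2 <- selectCandidates(am, groups, druggable = "DEL20")
  expect_true(cand2$druggable[cand2$gene == "DEL20"])
  expect_equal(cand2$n_flags[cand2$gene == "DEL20"], 2)
})

test_that("planted copy-number/expression coupling sets the correlation flag", {
  hits <- vapply(1:10, function(s) {
    cfg <- simConfig(n_pos = 60, n_neg = 90, n_normal = 0,
                     alt_spec = data.frame(
                       gene = "AMPG", class = "amp", freq_pos = 0.2,
                       freq_neg = 0.3, partner = NA),
                     cnv_expr_effect = 1, n_background_genes = 40,
                     seed = 200 + s)
    sim <- simulateCohort(cfg)
    g <- sim$truth$groups
    am <- buildAlterationMatrix(sim$cohort, names(g))
    cand <- selectCandidates(am, g, expr = exprCounts(sim$cohort)[, names(g)])
    isTRUE(cand$cnv_expr_correlated[cand$gene == "AMPG"])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("clustering groups identical patterns and splits disjoint ones", {
  samples <- sprintf("N%02d", 1:40)
  groups <- setNames(rep("ERG_NEG", 40), samples)
  am <- mkAm(list(
    A1 = list(del = samples[1:20]),
    A2 = list(del = samples[1:20]),          # identical to A1
    B1 = list(mut = samples[21:40]),         # disjoint from A*
    Z0 = list()), samples)
  cand <- data.frame(gene = c("A1", "A2", "B1", "Z0"),
                     event_class = c("del", "del", "mut", "del"),
                     freq_neg = c(0.5, 0.5, 0.5, 0), freq_pos = 0,
                     higher_in_neg = FALSE, druggable = FALSE,
                     cnv_expr_correlated = FALSE, n_flags = 0,
                     stringsAsFactors = FALSE)
  expect_warning(cl <- clusterCandidates(cand, am, groups), "Z0")
  expect_equal(cl[["A1"]], cl[["A2"]])
  expect_false(cl[["B1"]] == cl[["A1"]])
  # single candidate gives a singleton cluster
  single <- clusterCandidates(cand[1, ], am, groups)
  expect_equal(unname(single), 1L)
})

test_that("representative ranking prefers priority flags, then frequency, then symbol", {
  cand <- data.frame(
    gene = c("A", "B", "C", "D", "E"),
    event_class = "del",
    freq_neg = c(0.20, 0.30, 0.25, 0.25, 0.40),
    freq_pos = 0.05,
    higher_in_neg = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    druggable = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    cnv_expr_correlated = FALSE, stringsAsFactors = FALSE)
  cand$n_flags <- cand$higher_in_neg + cand$druggable +
    cand$cnv_expr_correlated
  clusters <- c(A = 1L, B = 1L, C = 2L, D = 2L, E = 3L)
  out <- pickRepresentatives(clusters, cand)
  # cluster 1: A has 2 flags, beats B's higher frequency
  # cluster 2: tie on flags -> frequency tie -> alphabetical C
  expect_setequal(out$representatives, c("A", "C", "E"))
  expect_equal(out$representatives[1], "E")  # ordered by frequency
  capped <- pickRepresentatives(clusters, cand, n_max = 2)
  expect_equal(length(capped$representatives), 2L)
})

test_that("coverage equals the set-union oracle and is monotone", {
  samples <- sprintf("S%d", 1:4)
  am <- mkAm(list(A = list(del = c("S1", "S2")),
                  B = list(mut = c("S2", "S3")),
                  C = list()), samples)
  cov <- signatureCoverage(c("A", "B"), am, samples)
  expect_equal(cov$coverage, 0.75)
  expect_equal(sum(cov$flags), 3L)
  expect_warning(z <- signatureCoverage(character(), am, samples),
                 "empty representative")
  expect_equal(z$coverage, 0)
  expect_equal(signatureCoverage("C", am, samples)$coverage, 0)
  one <- mkAm(list(ALL = list(amp = samples)), samples)
  expect_equal(signatureCoverage("ALL", one, samples)$coverage, 1)
  # property: oracle agreement and monotonicity on random matrices
  set.seed(13)
  for (i in 1:50) {
    ng <- sample(2:8, 1); ns <- sample(3:15, 1)
    ss <- sprintf("S%02d", 1:ns)
    gl <- setNames(lapply(1:ng, function(j)
      list(del = ss[runif(ns) < 0.3])), sprintf("G%02d", 1:ng))
    m <- mkAm(gl, ss)
    reps <- sample(names(gl), sample(ng, 1))
    got <- signatureCoverage(reps, m, ss)$coverage
    expect_equal(got, coverageOracle(alteredMatrix(m), reps, ss))
    if (length(reps) < ng) {
      extra <- c(reps, sample(setdiff(names(gl), reps), 1))
      expect_gte(signatureCoverage(extra, m, ss)$coverage, got)
    }
  }
})

test_that("oncoprint orders genes by frequency and samples by first altered gene", {
  samples <- sprintf("S%d", 1:5)
  am <- mkAm(list(LOW = list(mut = "S5"),
                  HIGH = list(del = c("S1", "S2", "S3"))), samples)
  op <- signatureCoverage(c("LOW", "HIGH"), am, samples)$oncoprint
  expect_equal(rownames(op), c("HIGH", "LOW"))
  expect_equal(op["HIGH", 1:3], c(S1 = "D", S2 = "D", S3 = "D"))
  expect_equal(unname(op["LOW", 4]), "M")
})

test_that("planted redundant clusters recover one representative each", {
  ok <- vapply(1:10, function(s) {
    set.seed(900 + s)
    nn <- 120
    ss <- sprintf("N%03d", 1:nn)
    groups <- setNames(rep("ERG_NEG", nn), ss)
    # three independent driver patterns, each with a correlated shadow
    drivers <- lapply(1:3, function(k) ss[runif(nn) < 0.3])
    gl <- list()
    for (k in 1:3) {
      base <- drivers[[k]]
      shadow <- union(base[runif(length(base)) < 0.9],
                      sample(ss, 2))
      gl[[sprintf("DRV%d", k)]] <- list(del = base)
      gl[[sprintf("SHA%d", k)]] <- list(del = shadow)
    }
    am <- mkAm(gl, ss)
    cand <- selectCandidates(am, groups)
    cl <- clusterCandidates(cand, am, groups)
    reps <- pickRepresentatives(cl, cand)$representatives
    # one member per planted cluster pair
    pairs <- lapply(1:3, function(k) sprintf(c("DRV%d", "SHA%d"), k))
    n_per <- vapply(pairs, function(p) sum(reps %in% p), integer(1))
    planted_cov <- mean(vapply(ss, function(s)
      any(unlist(drivers) == s), logical(1)))
    got_cov <- signatureCoverage(reps, am, ss)$coverage
    all(n_per == 1L) && abs(got_cov - planted_cov) <= 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
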
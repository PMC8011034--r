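test_that("R-M window counts follow the two counting modes", {
  g <- makeGenes(c("v", "anchor", "hv", "plain"))
  dom <- makeHits(c("v", "hv", "hv"), c("Vsr", "HNH_2", "Vsr"))
  w <- extractWindow(g, "anchor", 10)
  rm <- defaultRMReference()
  expect_equal(countRMInWindows(w, dom, rm, "families_per_gene"), 3L)
  expect_equal(countRMInWindows(w, dom, rm, "genes"), 2L)
  expect_equal(countRMInWindows(w, dom[0, ], rm), 0L)
  # a family hit twice on one product counts once
  dup <- makeHits(c("v", "v"), c("Vsr", "Vsr"))
  expect_equal(countRMInWindows(w, dup, rm), 1L)
})

test_that("window R-M counts equal a naive recount on random cohorts", {
  set.seed(31)
  for (rep in 1:6) {
    res <- generateCohort(smallRandomSpec(seed = 6000 + rep))
    co <- res$cohort
    anchors <- unlist(lapply(res$truth$genomes, `[[`, "anchors"))
    ws <- extractWindows(co, anchors, 5)
    for (mode in c("families_per_gene", "genes"))
      expect_equal(countRMInWindows(ws, domainHits(co), rmReference(co),
                                    mode),
                   oracleRMCount(ws, domainHits(co), rmReference(co), mode))
  }
})

test_that("genome shuffling preserves the gene-identity multiset", {
  res <- generateCohort(cohortSpec(nGenomes = 1, contigsPerGenome = 2,
                                   genesPerContig = 20, seed = 12))
  g <- geneTable(res$cohort)
  ps <- shuffleGenome(g, rng_seed = 5)
  expect_setequal(ps$protein_id, g$protein_id)
  expect_equal(ps[c("contig_id", "rank", "start", "end")],
               g[order(g$contig_id, g$rank),
                 c("contig_id", "rank", "start", "end")],
               ignore_attr = TRUE)
  # determinism contract
  expect_identical(shuffleGenome(g, rng_seed = 5), ps)
  expect_false(identical(shuffleGenome(g, rng_seed = 6)$protein_id,
                         ps$protein_id))
  # single-gene genome: identity permutation
  solo <- makeGenes("only")
  expect_identical(shuffleGenome(solo, 1)$protein_id, "only")
  # per-contig mode keeps identities on their contig
  pc <- shuffleGenome(g, rng_seed = 5, perContig = TRUE)
  for (ct in unique(g$contig_id))
    expect_setequal(pc$protein_id[pc$contig_id == ct],
                    g$protein_id[g$contig_id == ct])
})

test_that("the sampled null matches the hypergeometric expectation", {
  # 100 loci, 10 R-M genes, 1 anchor, k = 10: windows of 20 genes drawn
  # without replacement from 99 non-anchor loci carrying 10 R-M genes
  ids <- sprintf("p%03d", 1:100)
  g <- makeGenes(ids)
  rmGenes <- sprintf("p%03d", seq(5, 95, by = 10))
  co <- GenomeCohort(genes = g, domains = makeHits(rmGenes, "Vsr"),
                     rmref = defaultRMReference())
  nd <- simulateNull(co, "p050", k = 10, n_sims = 2000, base_seed = 9)
  # anchors shuffle too, so the window truncates near contig ends:
  # E[count] = E[window size over anchor positions] * R / (n - 1)
  ws <- vapply(1:100, function(p)
    (min(100, p + 10) - max(1, p - 10) + 1) - 1, numeric(1))
  expected <- mean(ws) * 10 / 99
  se <- sd(nullCounts(nd)) / sqrt(nd@nSims)
  expect_lt(abs(mean(nullCounts(nd)) - expected), 3 * se)
})

test_that("the sampled null agrees with exact permutation enumeration", {
  # 6-locus genome: enumerate all 720 permutations exactly
  ids <- sprintf("q%d", 1:6)
  g <- makeGenes(ids)
  co <- GenomeCohort(genes = g,
                     domains = makeHits(c("q2", "q5"), c("Vsr", "HNH_2")),
                     rmref = defaultRMReference())
  score <- c(0, 1, 0, 0, 1, 0)          # R-M families per locus identity
  k <- 2L
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ]
  exact <- apply(perms, 1, function(p) {
    pos <- which(p == 3L)               # anchor q3 sits at original locus 3
    win <- setdiff(max(1, pos - k):min(6, pos + k), pos)
    sum(score[p[win]])
  })
  nd <- simulateNull(co, "q3", k = k, n_sims = 2000, base_seed = 21)
  se <- sd(nullCounts(nd)) / sqrt(nd@nSims)
  expect_lt(abs(mean(nullCounts(nd)) - mean(exact)), 3 * se)
  expect_equal(nd@observed, sum(score[c(1, 2, 4, 5)]))
})

test_that("simulateNull is deterministic and validates its inputs", {
  res <- generateCohort(cohortSpec(nGenomes = 1, genesPerContig = 40,
                                   seed = 44))
  co <- res$cohort
  aid <- res$truth$genomes[[1]]$anchors
  a <- simulateNull(co, aid, k = 5, n_sims = 50, base_seed = 3)
  b <- simulateNull(co, aid, k = 5, n_sims = 50, base_seed = 3)
  expect_identical(nullCounts(a), nullCounts(b))
  expect_identical(observedCount(a), observedCount(b))
  expect_equal(length(nullCounts(simulateNull(co, aid, k = 5, n_sims = 1,
                                              base_seed = 1))), 1L)
  expect_error(simulateNull(co, "ghost", k = 5, n_sims = 2), "absent")
})

test_that("observed null count equals the window-based recount", {
  set.seed(19)
  for (rep in 1:4) {
    res <- generateCohort(smallRandomSpec(seed = 7000 + rep))
    co <- res$cohort
    for (gid in names(res$truth$genomes)) {
      anchors <- res$truth$genomes[[gid]]$anchors
      if (!length(anchors)) next
      nd <- simulateNull(co, anchors, k = 4, n_sims = 2, base_seed = 8)
      ws <- extractWindows(co, anchors, 4)
      expect_equal(observedCount(nd),
                   countRMInWindows(ws, domainHits(co), rmReference(co)))
    }
  }
})

test_that("the enrichment t-test matches hand arithmetic and conventions", {
  # textbook pooled-variance check on a 3-vs-3 sample
  x <- c(5, 7, 6); y <- c(2, 3, 1)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  tHand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  res <- enrichmentTest(x, y)
  expect_equal(res$t_statistic, tHand, tolerance = 1e-12)
  expect_equal(res$p_one_tailed, pt(tHand, df = 4, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical samples: t = 0, p = 0.5, not significant
  same <- enrichmentTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_one_tailed, 0.5)
  expect_equal(same$stars, "ns")

  # degenerate zero-variance samples with equal means: flagged, p = 0.5
  dg <- enrichmentTest(c(2, 2), c(2, 2))
  expect_true(dg$degenerate)
  expect_equal(dg$p_one_tailed, 0.5)

  expect_error(enrichmentTest(numeric(), 1:3), "non-empty")
  expect_error(enrichmentTest(1, 1:3), "at least 2")
})

test_that("star bands follow the significance thresholds", {
  expect_equal(starsFromP(c(0.2, 0.05, 0.01, 0.001, 0.0001, 1e-6)),
               c("ns", "*", "**", "***", "****", "****"))
})

test_that("mix pooling concatenates member nulls and validates coverage", {
  res <- generateCohort(cohortSpec(nGenomes = 4, genesPerContig = 30,
                                   seed = 23))
  co <- res$cohort
  nulls <- lapply(names(res$truth$genomes), function(gid)
    simulateNull(co, res$truth$genomes[[gid]]$anchors, k = 3, n_sims = 25,
                 base_seed = 2))
  mix <- data.frame(genome_id = genomeIDs(co),
                    mix_id = c("m1", "m1", "m2", "m2"))
  pooled <- poolMixes(nulls, mix)
  expect_equal(lengths(pooled), c(m1 = 50L, m2 = 50L))
  expect_equal(pooled$m1, c(nullCounts(nulls[[1]]), nullCounts(nulls[[2]])))

  mix$mix_id[2] <- "m2"
  expect_equal(attr(poolMixes(nulls, mix), "mix_sizes"),
               c(m1 = 1L, m2 = 3L))
  expect_error(poolMixes(nulls, rbind(mix, mix[1, ])), "more than one mix")
  expect_error(poolMixes(nulls, mix[-1, ]), "missing")
})
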
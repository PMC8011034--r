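test_that("identical seeds give byte-identical cohorts on disk", {
  spec <- cohortSpec(nGenomes = 3, genesPerContig = 40, seed = 101)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generateCohort(spec, dir = d1)
  generateCohort(spec, dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # a different seed changes the cohort
  d3 <- withr::local_tempdir()
  generateCohort(cohortSpec(nGenomes = 3, genesPerContig = 40,
                            seed = 102), dir = d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "domains.domtblout"))),
    unname(tools::md5sum(file.path(d3, "domains.domtblout")))))
})

test_that("emitted files are parseable with zero warnings and round-trip", {
  spec <- cohortSpec(nGenomes = 4, contigsPerGenome = 2,
                     genesPerContig = 30, seed = 55)
  d <- withr::local_tempdir()
  res <- generateCohort(spec, dir = d)
  expect_no_warning(back <- readCohort(d))
  expect_equal(geneTable(back), geneTable(res$cohort))
  expect_equal(rmReference(back), rmReference(res$cohort))
  expect_equal(taxonomyTable(back), taxonomyTable(res$cohort))
  expect_setequal(domainHits(back)$protein_id,
                  domainHits(res$cohort)$protein_id)
  expect_equal(sort(ogMap(back)$protein_id),
               sort(ogMap(res$cohort)$protein_id))
})

test_that("the truth record is consistent with the emitted tables", {
  spec <- cohortSpec(nGenomes = 6, genesPerContig = 50, pLink = 0.8,
                     seed = 77)
  res <- generateCohort(spec)
  g <- geneTable(res$cohort)
  for (gid in names(res$truth$genomes)) {
    t <- res$truth$genomes[[gid]]
    ids <- g$protein_id[g$genome_id == gid]
    expect_true(all(t$anchors %in% ids))
    expect_true(all(t$rm_near %in% ids))
    expect_true(all(t$rm_background %in% ids))
    if (nrow(t$partners)) {
      expect_true(all(t$partners$partner %in% ids))
      # realized distances respect linkD and match the gene table
      for (j in seq_len(nrow(t$partners))) {
        ra <- g$rank[g$protein_id == t$partners$anchor[j]]
        rp <- g$rank[g$protein_id == t$partners$partner[j]]
        expect_equal(abs(ra - rp), t$partners$distance[j])
        expect_lte(t$partners$distance[j], spec@linkD)
      }
    }
  }
  # every planted partner carries the GHKL domain
  partners <- unlist(lapply(res$truth$genomes,
                            function(t) t$partners$partner))
  dom <- domainHits(res$cohort)
  expect_true(all(partners %in%
                    dom$protein_id[dom$domain_name == "HATPase_c"]))
})

test_that("boundary linkage rates plant exactly as requested", {
  # pLink = 1: every anchor has a partner within linkD
  res1 <- generateCohort(cohortSpec(nGenomes = 20, genesPerContig = 30,
                                    pLink = 1, seed = 5))
  expect_equal(res1$truth$realized_linkage, 1)
  # pLink = 0: no partners at all
  res0 <- generateCohort(cohortSpec(nGenomes = 20, genesPerContig = 30,
                                    pLink = 0, seed = 5))
  expect_equal(res0$truth$n_linked, 0L)
  expect_false("HATPase_c" %in% domainHits(res0$cohort)$domain_name)
})

test_that("planted R-M rates are recovered near and far from anchors", {
  spec <- cohortSpec(nGenomes = 60, genesPerContig = 100,
                     lambdaNear = 0.3, lambdaBg = 0.05, rmWindow = 10,
                     paralogProb = 0, seed = 31)
  res <- generateCohort(spec)
  g <- geneTable(res$cohort)
  nearTot <- 0L; nearHit <- 0L; farTot <- 0L; farHit <- 0L
  for (gid in names(res$truth$genomes)) {
    t <- res$truth$genomes[[gid]]
    gg <- g[g$genome_id == gid, ]
    aRank <- gg$rank[match(t$anchors, gg$protein_id)]
    rmIds <- c(t$rm_near, t$rm_background)
    for (i in seq_len(nrow(gg))) {
      if (gg$protein_id[i] %in% t$anchors) next
      isNear <- any(abs(gg$rank[i] - aRank) <= spec@rmWindow)
      hit <- gg$protein_id[i] %in% rmIds
      if (isNear) { nearTot <- nearTot + 1L; nearHit <- nearHit + hit }
      else { farTot <- farTot + 1L; farHit <- farHit + hit }
    }
  }
  seNear <- sqrt(0.3 * 0.7 / nearTot)
  seFar <- sqrt(0.05 * 0.95 / farTot)
  expect_lt(abs(nearHit / nearTot - 0.3), 3 * seNear)
  expect_lt(abs(farHit / farTot - 0.05), 3 * seFar)
})

test_that("a null spec (lambdaNear = lambdaBg) plants no spatial signal", {
  spec <- cohortSpec(nGenomes = 40, genesPerContig = 100,
                     lambdaNear = 0.15, lambdaBg = 0.15, rmWindow = 10,
                     paralogProb = 0, seed = 13)
  res <- generateCohort(spec)
  g <- geneTable(res$cohort)
  near <- integer(); far <- integer()
  for (gid in names(res$truth$genomes)) {
    t <- res$truth$genomes[[gid]]
    gg <- g[g$genome_id == gid, ]
    aRank <- gg$rank[match(t$anchors, gg$protein_id)]
    rmIds <- c(t$rm_near, t$rm_background)
    sel <- !(gg$protein_id %in% t$anchors)
    isNear <- vapply(gg$rank, function(r)
      any(abs(r - aRank) <= spec@rmWindow), logical(1))
    hit <- gg$protein_id %in% rmIds
    near <- c(near, hit[sel & isNear]); far <- c(far, hit[sel & !isNear])
  }
  # two-proportion test: rates statistically indistinguishable
  p <- prop.test(c(sum(near), sum(far)), c(length(near), length(far)))
  expect_gt(p$p.value, 0.001)
})

test_that("lambdaBg = 0 confines R-M genes to anchor vicinities", {
  spec <- cohortSpec(nGenomes = 10, genesPerContig = 80, lambdaBg = 0,
                     lambdaNear = 0.4, rmWindow = 5, seed = 21)
  res <- generateCohort(spec)
  g <- geneTable(res$cohort)
  rmFams <- rmFamilies(rmReference(res$cohort))
  dom <- domainHits(res$cohort)
  rmIds <- unique(dom$protein_id[dom$domain_name %in% rmFams])
  for (pid in rmIds) {
    gid <- g$genome_id[g$protein_id == pid]
    t <- res$truth$genomes[[gid]]
    gg <- g[g$genome_id == gid, ]
    aRank <- gg$rank[match(t$anchors, gg$protein_id)]
    aCtg <- gg$contig_id[match(t$anchors, gg$protein_id)]
    r <- gg$rank[gg$protein_id == pid]
    ctg <- gg$contig_id[gg$protein_id == pid]
    expect_true(any(aCtg == ctg & abs(aRank - r) <= spec@rmWindow))
  }
})

test_that("architecture fixtures recover the requested group counts", {
  n <- c(g1 = 17, g2 = 4, g3 = 2, g4 = 1)
  d <- withr::local_tempdir()
  fx <- makeArchitectureFixtures(n, seed = 3, dir = d)
  calls <- classifyArchitectures(fx$hits)
  expect_equal(vapply(1:4, function(g) sum(calls$group == g), integer(1)),
               unname(n))
  # the emitted domtblout reproduces the same calls
  back <- readDomtblout(file.path(d, "architecture.domtblout"))
  expect_equal(classifyArchitectures(back)[c("protein_id", "group")],
               calls[c("protein_id", "group")])
  exp <- read.delim(file.path(d, "expected_calls.tsv"))
  expect_equal(calls$group[match(exp$protein_id, calls$protein_id)],
               exp$group)
})

test_that("infeasible cohort specs are rejected", {
  expect_error(cohortSpec(genesPerContig = 3, linkD = 3), "infeasible")
  expect_error(cohortSpec(pLink = 1.5), "probabilities")
  expect_error(cohortSpec(nGenomes = 0), "positive")
})
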
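edgeOf <- function(g, s, t) {
  el <- networkEdgeTable(g)
  el[el$source == s & el$target == t, ]
}

# one genus, one anchor window with the label order C5-Mtase, RR-like
# (the OG-labeled anchor), Vsr
tinyNetworkCohort <- function(genus = "Pectobacterium") {
  g <- makeGenes(c("mt", "anchor", "vs"), genome_id = "g1")
  dom <- makeHits(c("mt", "vs"), c("DNA_methylase", "Vsr"))
  og <- data.frame(protein_id = "anchor", og_label = "OG_A")
  tax <- data.frame(genome_id = "g1", phylum = "Proteobacteria",
                    class = NA, order = NA, family = NA, genus = genus,
                    species = "P sp")
  co <- GenomeCohort(genes = g, domains = dom, ogmap = og,
                     rmref = defaultRMReference(), taxonomy = tax)
  list(cohort = co, window = extractWindow(geneTable(co), "anchor", 3))
}

test_that("consecutive gene labels become directed 5'->3' edges", {
  x <- tinyNetworkCohort()
  co <- x$cohort
  net <- buildNetwork(x$window, domainHits(co), ogMap(co), rmReference(co),
                      taxonomyTable(co))
  expect_setequal(igraph::V(net)$name, c("DNA_methylase", "OG_A", "Vsr"))
  expect_equal(edgeOf(net, "DNA_methylase", "OG_A")$weight, 1L)
  expect_equal(edgeOf(net, "OG_A", "Vsr")$weight, 1L)
  expect_equal(igraph::ecount(net), 2L)
  # node typing from the R-M reference
  rmt <- setNames(igraph::V(net)$rm_types, igraph::V(net)$name)
  expect_equal(unname(rmt["Vsr"]), "V-gene")
  expect_equal(unname(rmt["OG_A"]), "")
})

test_that("edge weights count distinct genera, not strains", {
  # the same adjacency in three strains of one genus weighs 1
  windows <- list(); genes <- list(); doms <- list(); tax <- list()
  for (i in 1:3) {
    gid <- paste0("s", i)
    g <- makeGenes(c(paste0("mt", i), paste0("a", i), paste0("vs", i)),
                   genome_id = gid)
    genes[[i]] <- g
    doms[[i]] <- makeHits(c(paste0("mt", i), paste0("vs", i)),
                          c("DNA_methylase", "Vsr"))
    tax[[i]] <- data.frame(genome_id = gid, phylum = NA, class = NA,
                           order = NA, family = NA,
                           genus = "Klebsiella",
                           species = paste("K sp", i))
  }
  og <- data.frame(protein_id = c("a1", "a2", "a3"), og_label = "OG_A")
  co <- GenomeCohort(genes = do.call(rbind, genes),
                     domains = do.call(rbind, doms), ogmap = og,
                     rmref = defaultRMReference(),
                     taxonomy = do.call(rbind, tax))
  ws <- extractWindows(co, c("a1", "a2", "a3"), 3)
  net <- buildNetwork(ws, domainHits(co), ogMap(co), rmReference(co),
                      taxonomyTable(co))
  expect_equal(edgeOf(net, "DNA_methylase", "OG_A")$weight, 1L)
  # weights always equal the cardinality of the genera set
  el <- networkEdgeTable(net)
  expect_equal(el$weight,
               lengths(strsplit(el$genera, ",", fixed = TRUE)))
})

test_that("genomes without a genus are skipped with a warning", {
  x <- tinyNetworkCohort(genus = NA)
  co <- x$cohort
  expect_warning(
    net <- buildNetwork(x$window, domainHits(co), ogMap(co),
                        rmReference(co), taxonomyTable(co)),
    "genus")
  expect_equal(igraph::vcount(net), 0L)
})

test_that("edge weights equal the exhaustive adjacency enumeration", {
  set.seed(66)
  for (rep in 1:6) {
    res <- generateCohort(smallRandomSpec(seed = 8000 + rep))
    co <- res$cohort
    anchors <- unlist(lapply(res$truth$genomes, `[[`, "anchors"))
    ws <- extractWindows(co, anchors, 3)
    net <- buildNetwork(ws, domainHits(co), ogMap(co), rmReference(co),
                        taxonomyTable(co), filter = FALSE)
    got <- networkEdgeTable(net)
    got <- got[order(got$source, got$target), c("source", "target",
                                                "weight")]
    rownames(got) <- NULL
    want <- oracleEdgeWeights(ws, domainHits(co), ogMap(co),
                              taxonomyTable(co))
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("reversing contig order reverses edge directions, keeps weights", {
  set.seed(13)
  res <- generateCohort(smallRandomSpec(seed = 8100))
  co <- res$cohort
  anchors <- unlist(lapply(res$truth$genomes, `[[`, "anchors"))
  fwd <- buildNetwork(extractWindows(co, anchors, 3), domainHits(co),
                      ogMap(co), rmReference(co), taxonomyTable(co),
                      filter = FALSE)
  flipped <- flipCohort(co)
  rev <- buildNetwork(extractWindows(flipped, anchors, 3),
                      domainHits(flipped), ogMap(flipped),
                      rmReference(flipped), taxonomyTable(flipped),
                      filter = FALSE)
  a <- networkEdgeTable(fwd)[c("source", "target", "weight")]
  b <- networkEdgeTable(rev)[c("target", "source", "weight")]
  names(b) <- c("source", "target", "weight")
  a <- a[order(a$source, a$target), ]; rownames(a) <- NULL
  b <- b[order(b$source, b$target), ]; rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("the R-M retention filter keeps R-M neighborhoods, idempotently", {
  # chain: bgA -> bgB -> Vsr -> bgC ; bgA has no R-M neighbor and drops
  g <- makeGenes(c("bgA", "bgB", "anchor", "bgC"))
  dom <- makeHits(c("bgA", "bgB", "anchor", "bgC"),
                  c("ABC_tran", "Helicase_C", "Vsr", "HTH_1"))
  co <- GenomeCohort(genes = g, domains = dom,
                     rmref = defaultRMReference())
  w <- extractWindow(geneTable(co), "anchor", 3)
  tax <- data.frame(genome_id = "gA", phylum = NA, class = NA, order = NA,
                    family = NA, genus = "Geobacter", species = "G sp")
  net <- buildNetwork(w, domainHits(co), ogMap(co), rmReference(co), tax)
  expect_setequal(igraph::V(net)$name, c("Helicase_C", "Vsr", "HTH_1"))
  again <- retainRMNeighborhood(net)
  expect_equal(igraph::vcount(again), igraph::vcount(net))
  expect_equal(networkEdgeTable(again), networkEdgeTable(net))
})

test_that("non-R-M leaves of a hub collapse into one counted aggregate", {
  # hub DNA_methylase with 5 non-R-M leaf neighbors and one Vsr neighbor
  genes <- list(); doms <- list(); tax <- list(); ogs <- list()
  leaves <- c("ABC_tran", "HTH_1", "MFS_1", "Helicase_C", "Ntox28")
  for (i in 1:5) {
    gid <- paste0("h", i)
    # gene order: leaf, methylase hub, anchor, Vsr -- so the anchor's OG
    # node keeps a second (R-M) connection and is not a collapsible leaf
    g <- makeGenes(c(paste0("L", i), paste0("M", i), paste0("A", i),
                     paste0("V", i)), genome_id = gid)
    genes[[i]] <- g
    doms[[i]] <- makeHits(c(paste0("L", i), paste0("M", i), paste0("V", i)),
                          c(leaves[i], "DNA_methylase", "Vsr"))
    ogs[[i]] <- data.frame(protein_id = paste0("A", i), og_label = "OG_A")
    tax[[i]] <- data.frame(genome_id = gid, phylum = NA, class = NA,
                           order = NA, family = NA,
                           genus = paste0("Genus", i),
                           species = paste0("sp", i))
  }
  co <- GenomeCohort(genes = do.call(rbind, genes),
                     domains = do.call(rbind, doms),
                     ogmap = do.call(rbind, ogs),
                     rmref = defaultRMReference(),
                     taxonomy = do.call(rbind, tax))
  ws <- extractWindows(co, paste0("A", 1:5), 3)
  net <- buildNetwork(ws, domainHits(co), ogMap(co), rmReference(co),
                      taxonomyTable(co))
  merged <- collapseNonRMNeighbors(net, "DNA_methylase")
  vn <- igraph::V(merged)$name
  expect_false(any(leaves %in% vn))
  agg <- vn[grepl("^non-RM", vn)]
  expect_length(agg, 1L)
  expect_equal(igraph::vertex_attr(merged, "merged_count",
                                   match(agg, vn)), 5L)
  # leaf -> hub adjacencies pooled across the five genera
  expect_equal(edgeOf(merged, agg, "DNA_methylase")$weight, 5L)
  # OG_A nodes are kept: they neighbor the methylase hub
  expect_true("OG_A" %in% vn)

  # no non-R-M leaves: the network is unchanged
  x <- tinyNetworkCohort()
  co2 <- x$cohort
  net2 <- buildNetwork(x$window, domainHits(co2), ogMap(co2),
                       rmReference(co2), taxonomyTable(co2))
  merged2 <- collapseNonRMNeighbors(net2, "Vsr")
  expect_equal(sort(igraph::V(merged2)$name), sort(igraph::V(net2)$name))
  expect_error(collapseNonRMNeighbors(net2, "absent"), "not present")
})
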
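#' Construct a CohortSpec
#'
#' Parameters of the synthetic cohort generator. The defaults emulate the
#' scaled-down study conditions used throughout the package's validation:
#' 25 single-contig genomes of 200 genes, every genome carrying an anchor
#' (4.8% of anchor-bearing genomes carry 2-3 paralogs), partners planted
#' within 3 genes of an anchor at rate 0.916, and R-M domains planted at a
#' 5-fold elevated per-locus rate (0.25 vs 0.05) within 10 genes of an
#' anchor.
#'
#' @param nGenomes number of genomes.
#' @param contigsPerGenome contigs per genome.
#' @param genesPerContig genes per contig.
#' @param anchorProb probability a genome carries an anchor.
#' @param paralogProb probability an anchor-bearing genome carries 2-3
#'   anchor paralogs.
#' @param pLink probability a partner is planted within `linkD` of an
#'   anchor.
#' @param linkD maximum planted partner distance (gene ranks).
#' @param lambdaNear per-locus R-M probability within `rmWindow` of an
#'   anchor.
#' @param lambdaBg background per-locus R-M probability.
#' @param rmWindow half-width of the R-M-enriched zone (genes).
#' @param seed integer master seed.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nGenomes = 25L, contigsPerGenome = 1L,
                       genesPerContig = 200L, anchorProb = 1,
                       paralogProb = 0.048, pLink = 0.916, linkD = 3L,
                       lambdaNear = 0.25, lambdaBg = 0.05, rmWindow = 10L,
                       seed = 1L) {
  new("CohortSpec", nGenomes = as.integer(nGenomes),
      contigsPerGenome = as.integer(contigsPerGenome),
      genesPerContig = as.integer(genesPerContig),
      anchorProb = anchorProb, paralogProb = paralogProb, pLink = pLink,
      linkD = as.integer(linkD), lambdaNear = lambdaNear,
      lambdaBg = lambdaBg, rmWindow = as.integer(rmWindow),
      seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d genome(s) x %d contig(s) x %d genes (seed %d)\n",
    object@nGenomes, object@contigsPerGenome, object@genesPerContig,
    object@seed))
  cat(sprintf("  anchors: P=%g (paralogs %g); link: P=%g within %d genes\n",
              object@anchorProb, object@paralogProb, object@pLink,
              object@linkD))
  cat(sprintf("  R-M rates: %g near (±%d genes) vs %g background\n",
              object@lambdaNear, object@rmWindow, object@lambdaBg))
})

#' Built-in R-M reference of representative domain families
#'
#' A representative subset of R-M-associated Pfam families with their R-M
#' types: the C-5 cytosine methylase (`DNA_methylase`, type II), adenine
#' methylase (`N6_N4_Mtase`, found in types I-III), type II endonucleases
#' (`HNH_2`, `MvaI_BcnI`, `EcoRII-C`), type I restriction components
#' (`ResIII`, `HSDR`), and the very-short-patch repair endonuclease
#' (`Vsr`, a V gene).
#'
#' @return R-M reference data.frame (see [readRMReference()]).
#' @export
defaultRMReference <- function() {
  df <- data.frame(
    domain_name = c("DNA_methylase", "N6_N4_Mtase", "Vsr", "HNH_2",
                    "MvaI_BcnI", "EcoRII-C", "ResIII", "HSDR"),
    rm_types = c("II", "I,II,III", "V-gene", "II", "II", "II", "I", "I"),
    stringsAsFactors = FALSE)
  df$multi <- grepl(",", df$rm_types)
  df
}

## R-M family sampling weights (methylases dominate, as in real
## neighborhoods); background (non-R-M) vocabulary
rmVocabWeights <- function() {
  c(DNA_methylase = 0.30, N6_N4_Mtase = 0.15, Vsr = 0.15, HNH_2 = 0.12,
    MvaI_BcnI = 0.08, `EcoRII-C` = 0.05, ResIII = 0.08, HSDR = 0.07)
}

backgroundVocab <- function() {
  c("ABC_tran", "Helicase_C", "HTH_1", "MFS_1", "Response_reg", "HisKA",
    "CdiI_3", "Ntox28", "Acetyltransf_1", "Glycos_transf_2")
}

defaultTaxonomyPool <- function() {
  data.frame(
    genus = c("Pectobacterium", "Klebsiella", "Yersinia", "Acinetobacter",
              "Geobacter", "Bacteroides", "Flavobacterium",
              "Chryseobacterium"),
    family = c("Pectobacteriaceae", "Enterobacteriaceae", "Yersiniaceae",
               "Moraxellaceae", "Geobacteraceae", "Bacteroidaceae",
               "Flavobacteriaceae", "Weeksellaceae"),
    order = c("Enterobacterales", "Enterobacterales", "Enterobacterales",
              "Pseudomonadales", "Desulfuromonadales", "Bacteroidales",
              "Flavobacteriales", "Flavobacteriales"),
    class = c("Gammaproteobacteria", "Gammaproteobacteria",
              "Gammaproteobacteria", "Gammaproteobacteria",
              "Deltaproteobacteria", "Bacteroidia", "Flavobacteriia",
              "Flavobacteriia"),
    phylum = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
               "Proteobacteria", "Proteobacteria", "Bacteroidetes",
               "Bacteroidetes", "Bacteroidetes"),
    stringsAsFactors = FALSE)
}

## log-uniform e-values in [1e-30, 1e-8]
sampleEvalues <- function(n) 10^stats::runif(n, -30, -8)

#' Plant R-M domain families on a genome's loci
#'
#' Every locus within `rmWindow` gene ranks of an anchor (anchors
#' themselves excluded) carries an R-M family with probability
#' `lambdaNear`; every other locus with probability `lambdaBg`. Families
#' are drawn from the R-M vocabulary with methylase-heavy weights.
#'
#' @param genes ranked gene data.frame for one genome.
#' @param anchors anchor protein ids within `genes`.
#' @param spec a [CohortSpec-class] (rates and window are read from it).
#' @param seed integer seed for this planting.
#' @return data.frame protein_id, domain_name, provenance
#'   (`"near"`/`"background"`); zero rows when nothing was planted.
#' @export
plantRMClusters <- function(genes, anchors, spec, seed = spec@seed) {
  stopifnot(is(spec, "CohortSpec"))
  nearAnchor <- rep(FALSE, nrow(genes))
  aidx <- match(anchors, genes$protein_id)
  aidx <- aidx[!is.na(aidx)]
  for (i in aidx) {
    sel <- genes$contig_id == genes$contig_id[i] &
      abs(genes$rank - genes$rank[i]) <= spec@rmWindow
    nearAnchor <- nearAnchor | sel
  }
  eligible <- setdiff(seq_len(nrow(genes)), aidx)
  eligible <- eligible[!is.na(genes$protein_id[eligible])]
  if (!length(eligible))
    return(data.frame(protein_id = character(), domain_name = character(),
                      provenance = character(), stringsAsFactors = FALSE))
  withSeed(seed, {
    p <- ifelse(nearAnchor[eligible], spec@lambdaNear, spec@lambdaBg)
    hit <- stats::runif(length(eligible)) < p
    idx <- eligible[hit]
    w <- rmVocabWeights()
    fam <- sample(names(w), length(idx), replace = TRUE, prob = w)
    data.frame(protein_id = genes$protein_id[idx], domain_name = fam,
               provenance = ifelse(nearAnchor[idx], "near", "background"),
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic annotated genome cohort
#'
#' Builds a cohort with planted statistical structure: anchor genes
#' (grouped as `OG_A`, no domain hits, emulating response-regulator-like
#' genes), partner genes carrying a GHKL `HATPase_c` domain (`OG_B`)
#' planted within `linkD` gene ranks of an anchor with probability
#' `pLink`, R-M-domain genes at elevated density near anchors, background
#' domains and ortholog groups on the remaining genes, and a small
#' taxonomy. Gene coordinates are non-overlapping fixed-width intervals
#' (only ordering matters to the statistics). All randomness derives from
#' `spec@seed`; identical specs give byte-identical cohorts. Ortholog
#' groups that would end up with a single member cohort-wide are dropped
#' from the OG map so every emitted file round-trips without warnings.
#'
#' @param spec a [CohortSpec-class].
#' @param dir optional output directory; when given the cohort files and
#'   the truth record are written via [writeCohort()].
#' @param gff3 also emit per-genome GFF3 when writing.
#' @return List with elements `cohort` (a [GenomeCohort-class]) and
#'   `truth` (the machine-readable truth record: per-genome anchor loci,
#'   partner loci with realized distances, R-M loci with provenance, and
#'   realized linkage bookkeeping).
#' @export
generateCohort <- function(spec, dir = NULL, gff3 = FALSE) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  geneL <- list(); domL <- list(); ogL <- list(); taxL <- list()
  truthG <- list()
  pool <- defaultTaxonomyPool()
  for (gi in seq_len(spec@nGenomes)) {
    gid <- sprintf("g%04d", gi)
    gseed <- deriveSeed(spec@seed, gi * 7L)
    res <- withSeed(gseed, generateGenome(gid, spec))
    geneL[[gi]] <- res$genes
    domL[[gi]] <- res$domains
    ogL[[gi]] <- res$ogmap
    truthG[[gid]] <- res$truth
    taxL[[gi]] <- withSeed(deriveSeed(spec@seed, gi * 7L + 3L), {
      row <- pool[sample.int(nrow(pool), 1L), ]
      data.frame(genome_id = gid, phylum = row$phylum, class = row$class,
                 order = row$order, family = row$family, genus = row$genus,
                 species = sprintf("%s sp. %s", row$genus, gid),
                 stringsAsFactors = FALSE)
    })
  }
  genes <- do.call(rbind, geneL)
  domains <- do.call(rbind, domL)
  ogmap <- do.call(rbind, ogL)
  ## drop singleton ortholog groups (OrthoMCL groups span >= 2 members)
  sizes <- table(ogmap$og_label)
  ogmap <- ogmap[ogmap$og_label %in% names(sizes)[sizes >= 2L], ,
                 drop = FALSE]
  rownames(genes) <- rownames(domains) <- rownames(ogmap) <- NULL
  cohort <- GenomeCohort(genes = genes, domains = domains, ogmap = ogmap,
                         rmref = defaultRMReference(),
                         taxonomy = do.call(rbind, taxL))
  nAnchors <- sum(vapply(truthG, function(t) length(t$anchors), integer(1)))
  nLinked <- sum(vapply(truthG, function(t) sum(unlist(t$linked)),
                        integer(1)))
  truth <- list(seed = spec@seed, n_genomes = spec@nGenomes,
                n_anchors = nAnchors, n_linked = nLinked,
                realized_linkage = if (nAnchors) nLinked / nAnchors
                                   else NA_real_,
                genomes = truthG)
  if (!is.null(dir)) writeCohort(cohort, dir, truth = truth, gff3 = gff3)
  list(cohort = cohort, truth = truth)
}

## one genome: loci, anchors, partners, R-M and background annotation.
## Caller provides the RNG state.
generateGenome <- function(gid, spec) {
  nc <- spec@contigsPerGenome
  npc <- spec@genesPerContig
  n <- nc * npc
  contig <- rep(sprintf("%s_ctg%02d", gid, seq_len(nc)), each = npc)
  rank <- rep(seq_len(npc) - 1L, times = nc)
  genes <- data.frame(
    genome_id = gid, contig_id = contig, rank = rank,
    start = rank * 1000L + 1L, end = rank * 1000L + 900L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    protein_id = sprintf("%s_c%02d_p%04d", gid,
                         rep(seq_len(nc), each = npc), rank),
    stringsAsFactors = FALSE)
  ## anchors
  nAnchor <- 0L
  if (stats::runif(1) < spec@anchorProb)
    nAnchor <- if (stats::runif(1) < spec@paralogProb)
      sample(2:3, 1L) else 1L
  nAnchor <- min(nAnchor, n)
  aidx <- if (nAnchor) sort(sample.int(n, nAnchor)) else integer()
  anchors <- genes$protein_id[aidx]
  ## partners: one per anchor with probability pLink, within linkD ranks
  partnerRows <- list()
  taken <- aidx
  linked <- logical(length(aidx))
  for (j in seq_along(aidx)) {
    if (stats::runif(1) >= spec@pLink) next
    i <- aidx[j]
    offs <- sample(c(-(1:spec@linkD), 1:spec@linkD))
    for (o in offs) {
      r <- genes$rank[i] + o
      cand <- which(genes$contig_id == genes$contig_id[i] &
                      genes$rank == r)
      if (length(cand) == 1L && !(cand %in% taken)) {
        taken <- c(taken, cand)
        linked[j] <- TRUE
        partnerRows[[length(partnerRows) + 1L]] <- data.frame(
          anchor = genes$protein_id[i], partner = genes$protein_id[cand],
          distance = abs(o), stringsAsFactors = FALSE)
        break
      }
    }
  }
  partners <- if (length(partnerRows)) do.call(rbind, partnerRows)
              else data.frame(anchor = character(), partner = character(),
                              distance = integer(),
                              stringsAsFactors = FALSE)
  ## R-M planting (anchors excluded; partners eligible)
  rm <- plantRMClusters(genes, anchors, spec,
                        seed = deriveSeed(spec@seed,
                                          sum(utf8ToInt(gid)) * 13L))
  ## background domains on remaining genes (about half carry one)
  special <- c(anchors, partners$partner, rm$protein_id)
  rest <- setdiff(genes$protein_id, special)
  bg <- rest[stats::runif(length(rest)) < 0.5]
  bgFam <- sample(backgroundVocab(), length(bg), replace = TRUE)
  dom <- rbind(
    if (nrow(partners)) data.frame(protein_id = partners$partner,
                                   domain_name = "HATPase_c",
                                   stringsAsFactors = FALSE),
    if (nrow(rm)) rm[c("protein_id", "domain_name")],
    if (length(bg)) data.frame(protein_id = bg, domain_name = bgFam,
                               stringsAsFactors = FALSE))
  if (is.null(dom))
    dom <- data.frame(protein_id = character(), domain_name = character(),
                      stringsAsFactors = FALSE)
  domains <- if (nrow(dom)) data.frame(
    protein_id = dom$protein_id, domain_name = dom$domain_name,
    accession = NA_character_, evalue = sampleEvalues(nrow(dom)),
    env_start = 10L, env_end = 170L, protein_length = 300L,
    stringsAsFactors = FALSE) else emptyDomainTable()
  ## ortholog groups: anchors OG_A, partners OG_B, domain-less background
  ## genes spread over a shared pool, leaving some genes unassigned
  noDomain <- setdiff(rest, bg)
  ogPool <- sprintf("OG_%d", c(8L, 16L, 20L, 24L, 294L))
  assigned <- noDomain[stats::runif(length(noDomain)) < 0.6]
  ogmap <- rbind(
    if (length(anchors)) data.frame(protein_id = anchors,
                                    og_label = "OG_A",
                                    stringsAsFactors = FALSE),
    if (nrow(partners)) data.frame(protein_id = partners$partner,
                                   og_label = "OG_B",
                                   stringsAsFactors = FALSE),
    if (length(assigned)) data.frame(
      protein_id = assigned,
      og_label = sample(ogPool, length(assigned), replace = TRUE),
      stringsAsFactors = FALSE))
  if (is.null(ogmap)) ogmap <- emptyOGTable()
  list(genes = genes, domains = domains, ogmap = ogmap,
       truth = list(
         anchors = anchors,
         partners = partners,
         linked = setNames(as.list(linked), anchors),
         rm_near = rm$protein_id[rm$provenance == "near"],
         rm_background = rm$protein_id[rm$provenance == "background"]))
}

#' Synthetic domain-hit fixtures for the architecture classifier
#'
#' Emits synthetic proteins whose envelope layouts realize the four
#' architecture groups (N-terminal `HATPase_c_3` at 5-160, focal `HEF_HK`
#' at 200-260, C-terminal `HATPase_c` at 300-420), plus optional boundary
#' cases: a companion whose midpoint falls inside the focal envelope, a
#' sub-threshold and an at-threshold focal e-value (both excluded from the
#' expected calls), and overlapping same-family duplicate hits.
#'
#' @param n named integer vector `c(g1=, g2=, g3=, g4=)` of proteins per
#'   group.
#' @param seed integer seed for the e-value draws.
#' @param boundary also emit the boundary-case proteins.
#' @param dir optional directory: writes `architecture.domtblout` and
#'   `expected_calls.tsv`.
#' @return List with `hits` (domain-hit data.frame) and `expected`
#'   (data.frame protein_id, group).
#' @export
makeArchitectureFixtures <- function(n = c(g1 = 174L, g2 = 34L, g3 = 11L,
                                           g4 = 3L),
                                     seed = 1L, boundary = FALSE,
                                     dir = NULL) {
  stopifnot(all(c("g1", "g2", "g3", "g4") %in% names(n)), all(n >= 0))
  hitRows <- list(); expRows <- list()
  addHit <- function(pid, fam, ev, s, e, len)
    hitRows[[length(hitRows) + 1L]] <<- data.frame(
      protein_id = pid, domain_name = fam, accession = NA_character_,
      evalue = ev, env_start = s, env_end = e, protein_length = len,
      stringsAsFactors = FALSE)
  withSeed(seed, {
    for (grp in 1:4) {
      ng <- n[[paste0("g", grp)]]
      if (!ng) next
      for (i in seq_len(ng)) {
        pid <- sprintf("arch_g%d_%04d", grp, i)
        len <- sample(430:470, 1L)
        addHit(pid, "HEF_HK", sampleEvalues(1), 200L, 260L, len)
        if (grp %in% c(1L, 3L))
          addHit(pid, "HATPase_c_3", sampleEvalues(1), 5L, 160L, len)
        if (grp %in% c(1L, 2L))
          addHit(pid, "HATPase_c", sampleEvalues(1), 300L, 420L, len)
        expRows[[length(expRows) + 1L]] <- data.frame(
          protein_id = pid, group = grp, stringsAsFactors = FALSE)
      }
    }
    if (boundary) {
      ## companion midpoint inside the focal envelope: no N flag -> group 2
      addHit("arch_mid_inside", "HEF_HK", 1e-20, 200L, 260L, 450L)
      addHit("arch_mid_inside", "HATPase_c_3", 1e-18, 180L, 260L, 450L)
      addHit("arch_mid_inside", "HATPase_c", 1e-15, 300L, 420L, 450L)
      expRows[[length(expRows) + 1L]] <- data.frame(
        protein_id = "arch_mid_inside", group = 2L,
        stringsAsFactors = FALSE)
      ## focal e-values at/above the stringent threshold: excluded
      addHit("arch_weak_focal", "HEF_HK", 1e-4, 200L, 260L, 450L)
      addHit("arch_at_threshold", "HEF_HK", 1e-5, 200L, 260L, 450L)
      ## overlapping duplicate companion hits: merged to the best e-value
      addHit("arch_overlap", "HEF_HK", 1e-22, 200L, 260L, 450L)
      addHit("arch_overlap", "HATPase_c", 1e-12, 300L, 420L, 450L)
      addHit("arch_overlap", "HATPase_c", 1e-9, 350L, 430L, 450L)
      expRows[[length(expRows) + 1L]] <- data.frame(
        protein_id = "arch_overlap", group = 2L, stringsAsFactors = FALSE)
    }
  })
  hits <- do.call(rbind, hitRows)
  expected <- do.call(rbind, expRows)
  expected <- expected[order(expected$protein_id), , drop = FALSE]
  rownames(hits) <- rownames(expected) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeDomtblout(hits, file.path(dir, "architecture.domtblout"))
    write.table(expected, file.path(dir, "expected_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(hits = hits, expected = expected)
}
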
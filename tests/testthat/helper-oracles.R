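# Brute-force oracles and small fixture builders shared across tests.
# Oracles deliberately re-derive each statistic with naive loops, staying
# independent of the package's implementation paths.

# a tiny hand-built genome: one genome, explicit ranks/proteins
makeGenes <- function(protein_id, contig_id = "c1", genome_id = "gA",
                      strand = NULL) {
  n <- length(protein_id)
  if (is.null(strand)) strand <- rep("+", n)
  ranks <- unlist(lapply(split(seq_len(n), contig_id), seq_along)) - 1L
  if (length(unique(contig_id)) == 1L) ranks <- seq_len(n) - 1L
  data.frame(genome_id = genome_id, contig_id = contig_id,
             rank = ranks, start = ranks * 1000L + 1L,
             end = ranks * 1000L + 900L, strand = strand,
             protein_id = protein_id, stringsAsFactors = FALSE)
}

makeHits <- function(protein_id, domain_name, evalue = 1e-20,
                     env_start = 10L, env_end = 170L, length = 300L) {
  data.frame(protein_id = protein_id, domain_name = domain_name,
             accession = NA_character_, evalue = evalue,
             env_start = env_start, env_end = env_end,
             protein_length = length, stringsAsFactors = FALSE)
}

smallRandomSpec <- function(seed, maxGenes = 50L) {
  cohortSpec(nGenomes = sample(1:3, 1), contigsPerGenome = sample(1:2, 1),
             genesPerContig = sample(5:(maxGenes %/% 2), 1),
             anchorProb = 1, paralogProb = 0.3, pLink = runif(1, 0.3, 1),
             linkD = 3L, lambdaNear = runif(1, 0.1, 0.4),
             lambdaBg = runif(1, 0, 0.2), rmWindow = 5L, seed = seed)
}

# exhaustive all-pairs linkage scan (contig-wide exclusion rule)
oracleLinkage <- function(cohort, anchorIds, partnerIds, d,
                          min_neighbors = 1L) {
  g <- geneTable(cohort)
  n_regions <- 0L; n_linked <- 0L; n_excluded <- 0L
  for (a in anchorIds) {
    i <- which(g$protein_id == a)
    same <- which(g$genome_id == g$genome_id[i] &
                    g$contig_id == g$contig_id[i])
    if (length(same) - 1L < min_neighbors) {
      n_excluded <- n_excluded + 1L
      next
    }
    n_regions <- n_regions + 1L
    hit <- FALSE
    for (j in same) {
      if (j == i) next
      if (abs(g$rank[j] - g$rank[i]) <= d &&
          !is.na(g$protein_id[j]) && g$protein_id[j] %in% partnerIds)
        hit <- TRUE
    }
    if (hit) n_linked <- n_linked + 1L
  }
  list(n_regions = n_regions, n_linked = n_linked, n_excluded = n_excluded,
       linkage = if (n_regions) n_linked / n_regions else NA_real_)
}

# naive double-loop recount of window domain labels
oracleTabulate <- function(windows, domains, ogmap) {
  counts <- list()
  bump <- function(lab) counts[[lab]] <<- (counts[[lab]] %||% 0L) + 1L
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (w in windows) {
    g <- windowGenes(w)
    for (i in seq_len(nrow(g))) {
      p <- g$protein_id[i]
      if (is.na(p)) { bump("na"); next }
      fams <- unique(domains$domain_name[domains$protein_id == p])
      if (length(fams)) { for (f in fams) bump(f); next }
      og <- ogmap$og_label[ogmap$protein_id == p]
      bump(if (length(og)) og else "na")
    }
  }
  out <- data.frame(label = names(counts),
                    count = as.integer(unlist(counts)),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$label, method = "radix"), , drop = FALSE]
}

# naive R-M window recount in both modes
oracleRMCount <- function(windows, domains, rmref, mode) {
  fams <- rmref$domain_name
  total <- 0L
  for (w in windows) {
    g <- windowGenes(w)
    for (i in seq_len(nrow(g))) {
      p <- g$protein_id[i]
      if (is.na(p)) next
      k <- length(unique(domains$domain_name[
        domains$protein_id == p & domains$domain_name %in% fams]))
      total <- total + if (mode == "genes") as.integer(k > 0) else k
    }
  }
  total
}

# exhaustive adjacency enumeration for the 5'->3' network
oracleEdgeWeights <- function(windows, domains, ogmap, taxonomy,
                              bridge = TRUE) {
  seen <- list()  # key -> genus set
  for (w in windows) {
    gid <- anchorGene(w)$genome_id
    genus <- taxonomy$genus[taxonomy$genome_id == gid]
    if (!length(genus) || is.na(genus)) next
    g <- rbind(upstreamGenes(w), anchorGene(w), downstreamGenes(w))
    g <- g[order(g$rank), ]
    labs <- lapply(g$protein_id, function(p) {
      if (is.na(p)) return(character())
      fams <- unique(domains$domain_name[domains$protein_id == p])
      if (length(fams)) return(fams)
      og <- ogmap$og_label[ogmap$protein_id == p]
      if (length(og)) og else character()
    })
    if (bridge) labs <- labs[lengths(labs) > 0]
    if (length(labs) < 2) next
    for (i in seq_len(length(labs) - 1)) {
      for (a in labs[[i]]) for (b in labs[[i + 1]]) {
        key <- paste(a, b, sep = "\r")
        seen[[key]] <- union(seen[[key]], genus)
      }
    }
  }
  if (!length(seen))
    return(data.frame(source = character(), target = character(),
                      weight = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(names(seen), "\r", fixed = TRUE)
  out <- data.frame(source = vapply(parts, `[`, "", 1),
                    target = vapply(parts, `[`, "", 2),
                    weight = lengths(seen), stringsAsFactors = FALSE)
  out[order(out$source, out$target), , drop = FALSE]
}

# flip every strand and reverse every contig's gene order
flipCohort <- function(cohort) {
  g <- geneTable(cohort)
  out <- do.call(rbind, lapply(split(g, paste(g$genome_id, g$contig_id)),
    function(ct) {
      E <- max(ct$end)
      new <- ct
      new$start <- E - ct$end + 1L
      new$end <- E - ct$start + 1L
      new$strand <- ifelse(ct$strand == "+", "-", "+")
      new
    }))
  GenomeCohort(genes = assignRanks(out), domains = domainHits(cohort),
               ogmap = ogMap(cohort), rmref = rmReference(cohort),
               taxonomy = taxonomyTable(cohort))
}

# deterministic cohort reproducing the printed region bookkeeping:
# `nAnchors` anchor regions of which `nExcluded` are unsuitable (anchor
# alone on its contig) and `nLinked` carry a GHKL partner within d genes
makeBookkeepingCohort <- function(nAnchors = 664L, nExcluded = 20L,
                                  nLinked = 590L, d = 3L) {
  geneL <- list(); domL <- list(); anchors <- character()
  for (i in seq_len(nAnchors)) {
    gid <- sprintf("bk%04d", i)
    aid <- paste0(gid, "_anchor")
    anchors <- c(anchors, aid)
    if (i <= nExcluded) {
      geneL[[i]] <- makeGenes(aid, genome_id = gid)
      next
    }
    linked <- i <= nExcluded + nLinked
    pid <- paste0(gid, "_nbr")
    # partner at distance cycling 1..d when linked, beyond d when not
    dist <- if (linked) (i %% d) + 1L else d + 2L
    ids <- c(aid, paste0(gid, "_fill", 1:7))
    ids[1 + dist] <- pid
    geneL[[i]] <- makeGenes(ids, genome_id = gid)
    if (linked) domL[[length(domL) + 1L]] <- makeHits(pid, "HATPase_c")
  }
  cohort <- GenomeCohort(genes = do.call(rbind, geneL),
                         domains = do.call(rbind, domL),
                         rmref = defaultRMReference())
  list(cohort = cohort, anchors = anchors)
}
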
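#' Extract the gene window around an anchor
#'
#' Collects up to `k` genes on each side of the anchor on its contig. Sides
#' are oriented by the anchor's strand by default: for an anchor on the
#' minus strand, "upstream" genes are those at higher contig ranks.
#' `orientByStrand = FALSE` keeps raw contig order (upstream = lower ranks).
#' A side with fewer than `k` genes available is flagged truncated;
#' with `k = 0` both sides are empty and no flags are set.
#'
#' @param genes ranked gene data.frame (one or more genomes).
#' @param anchor a protein identifier present in `genes`, or a one-row gene
#'   data.frame.
#' @param k window half-width in genes (>= 0).
#' @param orientByStrand orient sides by the anchor strand (default TRUE).
#' @return A [NeighborhoodWindow-class].
#' @export
extractWindow <- function(genes, anchor, k, orientByStrand = TRUE) {
  stopifnot(k >= 0)
  k <- as.integer(k)
  if (is.character(anchor)) {
    i <- which(genes$protein_id == anchor)
    if (!length(i)) stopf("anchor '%s' not found in gene table", anchor)
    if (length(i) > 1L)
      stopf("anchor '%s' matches several loci; pass a one-row gene table",
            anchor)
    anchor <- genes[i, , drop = FALSE]
  }
  stopifnot(nrow(anchor) == 1L)
  ctg <- genes[genes$genome_id == anchor$genome_id &
               genes$contig_id == anchor$contig_id, , drop = FALSE]
  ctg <- ctg[order(ctg$rank), , drop = FALSE]
  r <- anchor$rank
  n <- nrow(ctg)
  lo <- ctg[ctg$rank >= r - k & ctg$rank < r, , drop = FALSE]   # lower ranks
  hi <- ctg[ctg$rank > r & ctg$rank <= r + k, , drop = FALSE]   # higher ranks
  lo <- lo[order(-lo$rank), , drop = FALSE]  # nearest first
  hi <- hi[order(hi$rank), , drop = FALSE]
  flip <- orientByStrand && anchor$strand == "-"
  up <- if (flip) hi else lo
  dn <- if (flip) lo else hi
  truncUp <- k > 0L && nrow(up) < k
  truncDn <- k > 0L && nrow(dn) < k
  new("NeighborhoodWindow", anchor = anchor, upstream = up, downstream = dn,
      k = k, truncatedUp = truncUp, truncatedDown = truncDn)
}

#' Extract windows for a set of anchors
#'
#' @param cohort a [GenomeCohort-class] or a ranked gene data.frame.
#' @param anchors character vector of anchor protein ids, or an OG label
#'   (resolved through the cohort's OG map).
#' @param k window half-width in genes.
#' @param orientByStrand see [extractWindow()].
#' @return A list of [NeighborhoodWindow-class] objects, one per anchor
#'   locus.
#' @export
extractWindows <- function(cohort, anchors, k, orientByStrand = TRUE) {
  genes <- if (is(cohort, "GenomeCohort")) geneTable(cohort) else cohort
  ids <- resolveAnchors(cohort, anchors)
  idx <- match(ids, genes$protein_id)
  if (anyNA(idx))
    stopf("anchor(s) not found: %s", paste(ids[is.na(idx)], collapse = ", "))
  lapply(idx, function(i)
    extractWindow(genes, genes[i, , drop = FALSE], k, orientByStrand))
}

## anchors may be protein ids or a single OG label
resolveAnchors <- function(cohort, anchors) {
  if (length(anchors) == 1L && grepl("^OG_", anchors) &&
      is(cohort, "GenomeCohort")) {
    og <- ogMap(cohort)
    ids <- og$protein_id[og$og_label == anchors]
    if (!length(ids)) stopf("no proteins in ortholog group '%s'", anchors)
    genes <- geneTable(cohort)
    ids <- ids[ids %in% genes$protein_id]
    if (!length(ids))
      stopf("ortholog group '%s' has no members in the gene table", anchors)
    return(sort(ids))
  }
  if (!length(anchors)) stopf("empty anchor set")
  anchors
}

## protein ids satisfying a partner predicate: an OG label or a set of
## domain family names
resolvePartners <- function(cohort, partner) {
  og <- ogMap(cohort)
  dom <- domainHits(cohort)
  if (all(grepl("^OG_", partner))) {
    og$protein_id[og$og_label %in% partner]
  } else {
    unique(dom$protein_id[dom$domain_name %in% partner])
  }
}

#' Co-localization (linkage) between anchors and partner genes
#'
#' For each anchor region, tests whether at least one gene within gene-rank
#' distance `d` on the same contig satisfies the partner predicate (an OG
#' label, or a set of domain family names). Distance is strand-agnostic
#' (adjacent gene = 1). Regions whose anchor contig provides fewer than
#' `min_neighbors` other genes are excluded as unsuitable for contextual
#' analysis (emulating incomplete-assembly exclusions) and tallied
#' separately; the exclusion rule is independent of `d`, which makes
#' linkage monotone non-decreasing in `d`.
#'
#' @param cohort a [GenomeCohort-class].
#' @param anchors anchor protein ids, or an OG label.
#' @param partner partner predicate: OG label(s) (prefix `OG_`) or domain
#'   family names.
#' @param d maximum gene-rank distance (>= 1).
#' @param min_neighbors minimum same-contig neighbor genes for a region to
#'   be analyzable (default 1).
#' @return One-row data.frame: d, n_regions, n_linked, linkage, n_excluded.
#' @examples
#' # see vignette("RMcontext-methods") for a worked example
#' @export
computeLinkage <- function(cohort, anchors, partner, d, min_neighbors = 1L) {
  stopifnot(is(cohort, "GenomeCohort"), d >= 1)
  d <- as.integer(d)
  genes <- geneTable(cohort)
  ids <- resolveAnchors(cohort, anchors)
  if (!length(ids)) stopf("empty anchor set")
  idx <- match(ids, genes$protein_id)
  if (anyNA(idx))
    stopf("anchor(s) not found: %s", paste(ids[is.na(idx)], collapse = ", "))
  partners <- resolvePartners(cohort, partner)
  key <- paste(genes$genome_id, genes$contig_id, sep = "\r")
  contigSize <- table(key)
  isPartner <- !is.na(genes$protein_id) & genes$protein_id %in% partners
  n_excluded <- 0L
  n_linked <- 0L
  n_regions <- 0L
  for (i in idx) {
    neighbors <- as.integer(contigSize[[key[i]]]) - 1L
    if (neighbors < min_neighbors) {
      n_excluded <- n_excluded + 1L
      next
    }
    n_regions <- n_regions + 1L
    sel <- key == key[i] & genes$rank != genes$rank[i] &
      abs(genes$rank - genes$rank[i]) <= d
    if (any(isPartner[sel])) n_linked <- n_linked + 1L
  }
  data.frame(d = d, n_regions = n_regions, n_linked = n_linked,
             linkage = if (n_regions) n_linked / n_regions else NA_real_,
             n_excluded = n_excluded)
}

#' Sweep linkage over a range of distances
#'
#' @inheritParams computeLinkage
#' @param d_values integer vector of distances.
#' @return data.frame with one row per distance (see [computeLinkage()]).
#' @export
linkageSweep <- function(cohort, anchors, partner, d_values = 1:5,
                         min_neighbors = 1L) {
  do.call(rbind, lapply(d_values, function(d)
    computeLinkage(cohort, anchors, partner, d, min_neighbors)))
}

#' Tabulate domain families in neighborhood windows
#'
#' For each window gene, each distinct domain family on its product counts
#' once. A gene whose product has no domain hit contributes its ortholog
#' group label instead; a gene with neither (including non-coding loci)
#' contributes the label `"na"`. Counts are summed over all windows.
#'
#' @param windows a list of [NeighborhoodWindow-class] (or a single one).
#' @param domains domain-hit data.frame.
#' @param ogmap OG assignment data.frame.
#' @return data.frame label, count, rank (1 = most frequent), ordered by
#'   decreasing count then label.
#' @export
tabulateNeighborhoodDomains <- function(windows, domains, ogmap) {
  if (is(windows, "NeighborhoodWindow")) windows <- list(windows)
  labs <- unlist(lapply(windows, function(w) {
    g <- windowGenes(w)
    if (!nrow(g)) return(character())
    unlist(lapply(seq_len(nrow(g)), function(i)
      geneLabels(g$protein_id[i], domains, ogmap)))
  }))
  if (!length(labs))
    return(data.frame(label = character(), count = integer(),
                      rank = integer(), stringsAsFactors = FALSE))
  tab <- table(labs)
  out <- data.frame(label = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$label, method = "radix"), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

## labels contributed by one gene product: distinct domain families, else
## the OG label, else "na"
geneLabels <- function(protein_id, domains, ogmap) {
  if (is.na(protein_id)) return("na")
  fam <- unique(domains$domain_name[domains$protein_id == protein_id])
  if (length(fam)) return(fam)
  og <- ogmap$og_label[match(protein_id, ogmap$protein_id)]
  if (!is.na(og)) og else "na"
}

#' Top fraction of best-represented labels
#'
#' Returns the `ceiling(fraction * n_labels)` labels with the highest
#' counts, ordering count-descending then label-ascending; ties at the
#' cutoff are broken by that ordering.
#'
#' @param counts data.frame with label, count (as from
#'   [tabulateNeighborhoodDomains()]).
#' @param fraction proportion in (0, 1].
#' @return The subset data.frame, re-ranked.
#' @export
topFractionDomains <- function(counts, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!nrow(counts)) return(counts)
  counts <- counts[order(-counts$count, counts$label, method = "radix"), ,
                   drop = FALSE]
  nkeep <- as.integer(ceiling(fraction * nrow(counts)))
  out <- counts[seq_len(nkeep), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
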
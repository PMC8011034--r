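#' Construct a GenomeCohort
#'
#' Assemble the integrated data model from its component tables. Missing
#' tables default to empty; the validity method enforces the model's
#' invariants (coordinates, rank bijection per contig, unique protein to OG
#' assignment, known R-M type labels).
#'
#' @param genes gene table as returned by [readGeneTable()].
#' @param domains domain-hit table as returned by [readDomtblout()].
#' @param ogmap ortholog-group table as returned by [readGroups()].
#' @param rmref R-M reference as returned by [readRMReference()].
#' @param taxonomy taxonomy table as returned by [readTaxonomy()].
#' @return A [GenomeCohort-class] object.
#' @examples
#' genes <- data.frame(genome_id = "g1", contig_id = "c1", rank = 0:1,
#'                     start = c(1L, 1001L), end = c(900L, 1900L),
#'                     strand = "+", protein_id = c("p1", "p2"))
#' GenomeCohort(genes)
#' @export
GenomeCohort <- function(genes = emptyGeneTable(),
                         domains = emptyDomainTable(),
                         ogmap = emptyOGTable(),
                         rmref = emptyRMTable(),
                         taxonomy = emptyTaxonomyTable()) {
  if (!"accession" %in% names(domains)) domains$accession <- NA_character_
  if (!"protein_length" %in% names(domains))
    domains$protein_length <- NA_integer_
  new("GenomeCohort", genes = as.data.frame(genes),
      domains = as.data.frame(domains), ogmap = as.data.frame(ogmap),
      rmref = as.data.frame(rmref), taxonomy = as.data.frame(taxonomy))
}

#' @rdname GenomeCohort
#' @param object,x a GenomeCohort.
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' @rdname GenomeCohort
#' @export
setGeneric("domainHits", function(x) standardGeneric("domainHits"))

#' @rdname GenomeCohort
#' @export
setGeneric("ogMap", function(x) standardGeneric("ogMap"))

#' @rdname GenomeCohort
#' @export
setGeneric("rmReference", function(x) standardGeneric("rmReference"))

#' @rdname GenomeCohort
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))

#' @rdname GenomeCohort
#' @export
setGeneric("genomeIDs", function(x) standardGeneric("genomeIDs"))

#' @rdname GenomeCohort
#' @export
setMethod("geneTable", "GenomeCohort", function(x) x@genes)

#' @rdname GenomeCohort
#' @export
setMethod("domainHits", "GenomeCohort", function(x) x@domains)

#' @rdname GenomeCohort
#' @export
setMethod("ogMap", "GenomeCohort", function(x) x@ogmap)

#' @rdname GenomeCohort
#' @export
setMethod("rmReference", "GenomeCohort", function(x) x@rmref)

#' @rdname GenomeCohort
#' @export
setMethod("taxonomyTable", "GenomeCohort", function(x) x@taxonomy)

#' @rdname GenomeCohort
#' @export
setMethod("genomeIDs", "GenomeCohort",
          function(x) unique(x@genes$genome_id))

setMethod("show", "GenomeCohort", function(object) {
  g <- object@genes
  cat("GenomeCohort with", length(unique(g$genome_id)), "genome(s),",
      nrow(g), "gene loci\n")
  cat("  domain hits:   ", nrow(object@domains), "\n")
  cat("  OG assignments:", nrow(object@ogmap),
      sprintf("(%d groups)", length(unique(object@ogmap$og_label))), "\n")
  cat("  R-M reference: ", nrow(object@rmref), "domain families\n")
  cat("  taxonomy:      ", nrow(object@taxonomy), "genomes\n")
})

#' Subset a cohort to one genome
#'
#' @param x a [GenomeCohort-class].
#' @param genome_id genome identifier to keep.
#' @return A GenomeCohort restricted to the genome's loci (domain hits and
#'   OG assignments are restricted to proteins present in that genome).
#' @export
subsetGenome <- function(x, genome_id) {
  stopifnot(is(x, "GenomeCohort"))
  g <- x@genes[x@genes$genome_id %in% genome_id, , drop = FALSE]
  if (!nrow(g)) stopf("genome '%s' not found in cohort", genome_id)
  pid <- g$protein_id[!is.na(g$protein_id)]
  GenomeCohort(genes = g,
               domains = x@domains[x@domains$protein_id %in% pid, ,
                                   drop = FALSE],
               ogmap = x@ogmap[x@ogmap$protein_id %in% pid, , drop = FALSE],
               rmref = x@rmref,
               taxonomy = x@taxonomy[x@taxonomy$genome_id %in% genome_id, ,
                                     drop = FALSE])
}

#' @describeIn NeighborhoodWindow-class the anchor gene (one-row data.frame).
#' @param x a NeighborhoodWindow.
#' @export
setGeneric("anchorGene", function(x) standardGeneric("anchorGene"))

#' @describeIn NeighborhoodWindow-class upstream genes, nearest first.
#' @export
setGeneric("upstreamGenes", function(x) standardGeneric("upstreamGenes"))

#' @describeIn NeighborhoodWindow-class downstream genes, nearest first.
#' @export
setGeneric("downstreamGenes", function(x) standardGeneric("downstreamGenes"))

#' @describeIn NeighborhoodWindow-class all window genes (both sides, anchor
#'   excluded) in contig order.
#' @export
setGeneric("windowGenes", function(x) standardGeneric("windowGenes"))

#' @rdname NeighborhoodWindow-class
#' @export
setMethod("anchorGene", "NeighborhoodWindow", function(x) x@anchor)

#' @rdname NeighborhoodWindow-class
#' @export
setMethod("upstreamGenes", "NeighborhoodWindow", function(x) x@upstream)

#' @rdname NeighborhoodWindow-class
#' @export
setMethod("downstreamGenes", "NeighborhoodWindow", function(x) x@downstream)

#' @rdname NeighborhoodWindow-class
#' @export
setMethod("windowGenes", "NeighborhoodWindow", function(x) {
  w <- rbind(x@upstream, x@downstream)
  w[order(w$rank), , drop = FALSE]
})

setMethod("show", "NeighborhoodWindow", function(object) {
  cat(sprintf("NeighborhoodWindow k=%d around %s (%s:%s rank %d, %s)\n",
              object@k,
              object@anchor$protein_id %||% "<non-coding>",
              object@anchor$genome_id, object@anchor$contig_id,
              object@anchor$rank, object@anchor$strand))
  cat(sprintf("  upstream %d gene(s)%s, downstream %d gene(s)%s\n",
              nrow(object@upstream),
              if (object@truncatedUp) " [truncated]" else "",
              nrow(object@downstream),
              if (object@truncatedDown) " [truncated]" else ""))
})

#' @describeIn NullDistribution-class the null counts vector.
#' @param x a NullDistribution.
#' @export
setGeneric("nullCounts", function(x) standardGeneric("nullCounts"))

#' @describeIn NullDistribution-class the observed (real-genome) count.
#' @export
setGeneric("observedCount", function(x) standardGeneric("observedCount"))

#' @rdname NullDistribution-class
#' @export
setMethod("nullCounts", "NullDistribution", function(x) x@counts)

#' @rdname NullDistribution-class
#' @export
setMethod("observedCount", "NullDistribution", function(x) x@observed)

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution for %s: %d pseudogenomes (k=%d, mode=%s)\n",
              object@genomeId, object@nSims, object@k, object@mode))
  cat(sprintf("  observed %g vs null mean %.3f [q95 %g], empirical p = %.4g\n",
              object@observed, mean(object@counts),
              stats::quantile(object@counts, 0.95, names = FALSE),
              empiricalPValue(object@observed, object@counts)))
})
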
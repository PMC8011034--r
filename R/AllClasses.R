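#' GenomeCohort: an annotated bacterial genome cohort
#'
#' Container for the integrated data model of a gene-neighborhood analysis:
#' ranked gene tables for one or more genomes, protein domain hits, ortholog
#' group (OG) assignments, a restriction-modification (R-M) reference mapping
#' domain families to R-M types, and a taxonomy table.
#'
#' Gene coordinates are 1-based inclusive; gene ranks are 0-based consecutive
#' integers within each contig, ordered by start coordinate (ties broken by
#' end, then protein identifier). Non-coding loci may carry `NA` as
#' `protein_id`; they occupy a rank but carry no domains.
#'
#' @slot genes data.frame with columns genome_id, contig_id, rank, start,
#'   end, strand, protein_id.
#' @slot domains data.frame with columns protein_id, domain_name, accession,
#'   evalue, env_start, env_end, protein_length.
#' @slot ogmap data.frame with columns protein_id, og_label.
#' @slot rmref data.frame with columns domain_name, rm_types
#'   (comma-separated labels from I, II, III, IV, V-gene), multi.
#' @slot taxonomy data.frame with columns genome_id, phylum, class, order,
#'   family, genus, species.
#'
#' @seealso [GenomeCohort()] for the constructor, [geneTable()],
#'   [domainHits()], [ogMap()], [rmReference()], [taxonomyTable()].
#' @export
setClass("GenomeCohort",
  representation(genes = "data.frame", domains = "data.frame",
                 ogmap = "data.frame", rmref = "data.frame",
                 taxonomy = "data.frame"))

validGenomeCohort <- function(object) {
  msg <- character()
  g <- object@genes
  ok <- try(checkColumns(g, c("genome_id", "contig_id", "rank", "start",
                              "end", "strand", "protein_id"), "gene table"),
            silent = TRUE)
  if (inherits(ok, "try-error")) return(conditionMessage(attr(ok, "condition")))
  if (nrow(g)) {
    if (any(g$start > g$end))
      msg <- c(msg, "gene table has start > end")
    if (!all(g$strand %in% c("+", "-")))
      msg <- c(msg, "gene strand must be '+' or '-'")
    key <- paste(g$genome_id, g$contig_id)
    bad <- vapply(split(g$rank, key), function(r)
      !identical(sort(as.integer(r)), seq_len(length(r)) - 1L), logical(1))
    if (any(bad))
      msg <- c(msg, paste0("contig ranks not consecutive 0..n-1 in: ",
                           paste(names(bad)[bad], collapse = ", ")))
    pid <- g$protein_id[!is.na(g$protein_id)]
    dup <- unique(pid[duplicated(pid)])
    if (length(dup))
      msg <- c(msg, paste0("duplicate protein_id in gene table: ",
                           paste(head(dup, 5), collapse = ", ")))
  }
  og <- object@ogmap
  if (nrow(og) && anyDuplicated(og$protein_id))
    msg <- c(msg, "a protein maps to more than one ortholog group")
  rm <- object@rmref
  if (nrow(rm)) {
    types <- strsplit(rm$rm_types, ",", fixed = TRUE)
    bad <- !vapply(types, function(t)
      length(t) >= 1L && all(t %in% setdiff(RM_TYPE_LABELS, "multi")),
      logical(1))
    if (any(bad))
      msg <- c(msg, paste0("invalid R-M type labels for: ",
                           paste(rm$domain_name[bad], collapse = ", ")))
  }
  tx <- object@taxonomy
  if (nrow(tx) && anyDuplicated(tx$genome_id))
    msg <- c(msg, "duplicate genome_id in taxonomy")
  if (length(msg)) msg else TRUE
}

setValidity("GenomeCohort", validGenomeCohort)

#' NeighborhoodWindow: genes around an anchor locus
#'
#' The ordered genes within k gene ranks up- and downstream of an anchor
#' gene on its contig. By default up/downstream are oriented by the anchor's
#' strand (an anchor on the minus strand has its sides swapped relative to
#' contig order). Sides are ordered nearest-first and never contain the
#' anchor itself; a truncation flag is set on a side with fewer than k genes
#' available on the contig.
#'
#' @slot anchor one-row gene data.frame (the anchor locus).
#' @slot upstream gene data.frame, nearest gene first.
#' @slot downstream gene data.frame, nearest gene first.
#' @slot k integer window half-width in genes.
#' @slot truncatedUp,truncatedDown logical truncation flags.
#' @export
setClass("NeighborhoodWindow",
  representation(anchor = "data.frame", upstream = "data.frame",
                 downstream = "data.frame", k = "integer",
                 truncatedUp = "logical", truncatedDown = "logical"))

setValidity("NeighborhoodWindow", function(object) {
  msg <- character()
  if (nrow(object@anchor) != 1L) msg <- c(msg, "anchor must be one gene")
  if (object@k < 0L) msg <- c(msg, "k must be >= 0")
  if (nrow(object@upstream) > object@k || nrow(object@downstream) > object@k)
    msg <- c(msg, "window side larger than k")
  ctg <- unique(c(object@anchor$contig_id, object@upstream$contig_id,
                  object@downstream$contig_id))
  if (length(ctg) > 1L) msg <- c(msg, "window genes span several contigs")
  if (length(msg)) msg else TRUE
})

#' NullDistribution: pseudogenome null for windowed R-M counts
#'
#' Per-genome empirical null distribution of the anchor-window R-M domain
#' count over shuffled pseudogenomes, together with the observed count on
#' the real genome.
#'
#' @slot genomeId genome identifier.
#' @slot nSims number of pseudogenomes simulated.
#' @slot counts numeric vector of length nSims (one windowed count per
#'   pseudogenome, summed over all anchor windows).
#' @slot observed the real genome's count.
#' @slot k window half-width used.
#' @slot mode counting mode, "families_per_gene" or "genes".
#' @slot baseSeed integer base seed of the simulation.
#' @export
setClass("NullDistribution",
  representation(genomeId = "character", nSims = "integer",
                 counts = "numeric", observed = "numeric", k = "integer",
                 mode = "character", baseSeed = "integer"))

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (length(object@counts) != object@nSims)
    msg <- c(msg, "length(counts) must equal nSims")
  if (any(object@counts < 0) || object@observed < 0)
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Describes a synthetic annotated genome cohort with planted statistical
#' structure: anchor genes (response-regulator-like, grouped as OG_A),
#' partner genes (GHKL-domain, OG_B) planted within `linkD` gene ranks of an
#' anchor with probability `pLink`, and R-M-domain genes planted at per-locus
#' rate `lambdaNear` within `rmWindow` genes of an anchor versus `lambdaBg`
#' elsewhere.
#'
#' @slot nGenomes number of genomes.
#' @slot contigsPerGenome contigs per genome.
#' @slot genesPerContig genes per contig.
#' @slot anchorProb probability that a genome carries an anchor.
#' @slot paralogProb probability an anchor-bearing genome carries 2-3
#'   anchor paralogs instead of one.
#' @slot pLink probability a partner is planted within linkD of an anchor.
#' @slot linkD maximum planted partner distance in gene ranks.
#' @slot lambdaNear per-locus R-M probability within rmWindow of an anchor.
#' @slot lambdaBg background per-locus R-M probability.
#' @slot rmWindow half-width (genes) of the R-M-enriched zone.
#' @slot seed integer master seed; identical seeds give identical cohorts.
#' @export
setClass("CohortSpec",
  representation(nGenomes = "integer", contigsPerGenome = "integer",
                 genesPerContig = "integer", anchorProb = "numeric",
                 paralogProb = "numeric", pLink = "numeric",
                 linkD = "integer", lambdaNear = "numeric",
                 lambdaBg = "numeric", rmWindow = "integer",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  probs <- c(object@anchorProb, object@paralogProb, object@pLink,
             object@lambdaNear, object@lambdaBg)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must be in [0,1]")
  if (object@linkD < 1L) msg <- c(msg, "linkD must be >= 1")
  if (object@nGenomes < 1L || object@contigsPerGenome < 1L ||
      object@genesPerContig < 1L)
    msg <- c(msg, "cohort dimensions must be positive")
  if (object@linkD >= object@genesPerContig)
    msg <- c(msg, "infeasible spec: linkD must be smaller than genesPerContig")
  if (length(msg)) msg else TRUE
})
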
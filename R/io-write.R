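#' Write a gene table in the package TSV dialect
#'
#' Columns genome_id, contig_id, start, end, strand, protein_id (rank is
#' recomputed on read). Missing protein identifiers are written as `NA`.
#'
#' @param genes ranked gene data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  out <- genes[c("genome_id", "contig_id", "start", "end", "strand",
                 "protein_id")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene table as GFF3
#'
#' Emits one CDS feature per locus with ID/protein_id attributes, via
#' rtracklayer. Non-coding loci (no protein id) get a locus ID only.
#'
#' @param genes ranked gene data.frame for one genome.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneTableGFF3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- ifelse(is.na(genes$protein_id),
                  sprintf("locus_%s_%d", genes$contig_id, genes$rank),
                  genes$protein_id)
  gr$protein_id <- genes$protein_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a network as SIF
#'
#' Simple interaction format: `source <relation> target`, one edge per line;
#' an empty network yields an empty file.
#'
#' @param edges data.frame with columns source, target (and optionally
#'   relation).
#' @param path output file.
#' @param relation default relation label.
#' @return `path`, invisibly.
#' @export
writeSIF <- function(edges, path, relation = "adjacent_to") {
  if (is.null(edges) || !nrow(edges)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  rel <- if ("relation" %in% names(edges)) edges$relation else relation
  writeLines(paste(edges$source, rel, edges$target, sep = "\t"), path)
  invisible(path)
}

#' Write a network as GraphML
#'
#' @param graph an igraph object (see [buildNetwork()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(graph, path) {
  g <- graph
  ## igraph cannot serialize list attributes; flatten genera sets
  if ("genera" %in% igraph::edge_attr_names(g) &&
      is.list(igraph::edge_attr(g, "genera")))
    g <- igraph::set_edge_attr(g, "genera",
      value = vapply(igraph::edge_attr(g, "genera"), paste, character(1),
                     collapse = ","))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Edge list of a network graph
#'
#' @param graph an igraph object with `weight` and `genera` edge attributes.
#' @return data.frame source, target, weight, genera.
#' @export
networkEdgeTable <- function(graph) {
  if (igraph::ecount(graph) == 0L)
    return(data.frame(source = character(), target = character(),
                      weight = integer(), genera = character(),
                      stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(graph)
  genera <- igraph::edge_attr(graph, "genera")
  if (is.list(genera))
    genera <- vapply(genera, paste, character(1), collapse = ",")
  data.frame(source = el[, 1], target = el[, 2],
             weight = as.integer(igraph::edge_attr(graph, "weight")),
             genera = genera, stringsAsFactors = FALSE)
}

#' Write tabular and network results with a manifest
#'
#' Writes each table as a header-bearing TSV, the network (if any) as both
#' SIF and GraphML, and returns a manifest listing every file with its row
#' or edge count.
#'
#' @param tables named list of data.frames.
#' @param network optional igraph object.
#' @param outdir output directory (created if needed).
#' @return Manifest data.frame with columns file, kind, n (rows or edges),
#'   invisibly written to `manifest.tsv` as well.
#' @export
writeOutputs <- function(tables = list(), network = NULL, outdir = ".") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stopf("cannot create output directory %s", outdir)
  manifest <- data.frame(file = character(), kind = character(),
                         n = integer(), stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    f <- file.path(outdir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest <- rbind(manifest, data.frame(
      file = basename(f), kind = "table", n = nrow(tables[[nm]])))
  }
  if (!is.null(network)) {
    edges <- networkEdgeTable(network)
    writeSIF(edges, file.path(outdir, "network.sif"))
    writeGraphML(network, file.path(outdir, "network.graphml"))
    write.table(edges, file.path(outdir, "network_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ne <- igraph::ecount(network)
    manifest <- rbind(manifest,
      data.frame(file = c("network.sif", "network.graphml",
                          "network_edges.tsv"),
                 kind = "network", n = ne))
  }
  write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Write a synthetic cohort to disk
#'
#' Layout: `genes/<genome_id>.tsv` (one per genome, package TSV dialect),
#' `genes_gff3/<genome_id>.gff3`, `domains.domtblout`, `groups.txt`
#' (OrthoMCL dialect), `rm_reference.tsv`, `taxonomy.tsv`, and, when a truth
#' record is supplied, `truth.json`.
#'
#' @param cohort a [GenomeCohort-class].
#' @param dir output directory.
#' @param truth optional truth record list (from [generateCohort()]).
#' @param gff3 also write per-genome GFF3 files.
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, truth = NULL, gff3 = FALSE) {
  stopifnot(is(cohort, "GenomeCohort"))
  dir.create(file.path(dir, "genes"), recursive = TRUE, showWarnings = FALSE)
  g <- geneTable(cohort)
  for (gid in unique(g$genome_id))
    writeGeneTable(g[g$genome_id == gid, ],
                   file.path(dir, "genes", paste0(gid, ".tsv")))
  if (gff3) {
    dir.create(file.path(dir, "genes_gff3"), showWarnings = FALSE)
    for (gid in unique(g$genome_id))
      writeGeneTableGFF3(g[g$genome_id == gid, ],
                         file.path(dir, "genes_gff3", paste0(gid, ".gff3")))
  }
  writeDomtblout(domainHits(cohort), file.path(dir, "domains.domtblout"))
  writeGroups(ogMap(cohort), file.path(dir, "groups.txt"))
  rm <- rmReference(cohort)
  write.table(rm[c("domain_name", "rm_types")],
              file.path(dir, "rm_reference.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(taxonomyTable(cohort), file.path(dir, "taxonomy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write domain hits in HMMER3 domtblout format
#'
#' Emits a minimal but column-complete per-domain table (23 columns) that
#' [readDomtblout()] round-trips.
#'
#' @param domains domain-hit data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDomtblout <- function(domains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"),
    con)
  if (nrow(domains)) {
    len <- domains$protein_length
    len[is.na(len)] <- domains$env_end[is.na(len)] + 50L
    acc <- domains$accession
    acc[is.na(acc)] <- "-"
    lines <- sprintf(
      "%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f -",
      domains$domain_name, acc,
      domains$env_end - domains$env_start + 1L,
      domains$protein_id, "-", len,
      domains$evalue, 50, 0.1, 1L, 1L, domains$evalue, domains$evalue,
      50, 0.1,
      1L, domains$env_end - domains$env_start + 1L,
      domains$env_start, domains$env_end,
      domains$env_start, domains$env_end, 0.95)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write an OrthoMCL-style groups file
#'
#' @param ogmap data.frame with protein_id, og_label.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGroups <- function(ogmap, path) {
  if (!nrow(ogmap)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  sp <- split(ogmap$protein_id, ogmap$og_label)
  sp <- sp[order(names(sp))]
  writeLines(sprintf("%s: %s", names(sp),
                     vapply(sp, paste, character(1), collapse = " ")), path)
  invisible(path)
}
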
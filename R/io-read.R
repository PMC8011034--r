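#' Assign within-contig gene ranks
#'
#' Orders genes by start coordinate within each (genome, contig) and assigns
#' 0-based consecutive ranks. Ties on start are broken by end, then by
#' protein identifier.
#'
#' @param genes gene data.frame with genome_id, contig_id, start, end,
#'   strand, protein_id.
#' @return The same table with a `rank` column, sorted by genome, contig,
#'   rank.
#' @export
assignRanks <- function(genes) {
  checkColumns(genes, c("genome_id", "contig_id", "start", "end", "strand",
                        "protein_id"), "gene table")
  if (!nrow(genes)) return(emptyGeneTable())
  o <- order(genes$genome_id, genes$contig_id, genes$start, genes$end,
             genes$protein_id, method = "radix")
  genes <- genes[o, , drop = FALSE]
  key <- paste(genes$genome_id, genes$contig_id, sep = "\r")
  genes$rank <- as.integer(stats::ave(seq_len(nrow(genes)), key,
                                      FUN = seq_along)) - 1L
  rownames(genes) <- NULL
  genes[c("genome_id", "contig_id", "rank", "start", "end", "strand",
          "protein_id")]
}

#' Read a gene table
#'
#' Reads per-genome gene loci either from the package's TSV dialect
#' (columns genome_id, contig_id, start, end, strand, protein_id) or from
#' GFF3. Coordinates are 1-based inclusive; ranks are (re)assigned from
#' start coordinates via [assignRanks()].
#'
#' @param path input file.
#' @param dialect `"tsv"` (default) or `"gff3"`.
#' @param genome_id genome identifier to use for GFF3 input (GFF3 carries
#'   none); defaults to the file name without extension.
#' @param feature_type GFF3 feature types treated as gene loci.
#' @return A ranked gene data.frame (see [GenomeCohort()]).
#' @export
readGeneTable <- function(path, dialect = c("tsv", "gff3"),
                          genome_id = NULL,
                          feature_type = c("CDS", "gene")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("gene table not found: %s", path)
  genes <- if (dialect == "tsv") {
    readGeneTSV(path)
  } else {
    readGeneGFF3(path, genome_id %||%
                   sub("\\.[^.]*$", "", basename(path)), feature_type)
  }
  if (!nrow(genes)) {
    warnf("gene table '%s' is empty", path)
    return(emptyGeneTable())
  }
  if (any(genes$start > genes$end))
    stopf("gene table '%s': start > end", path)
  genes <- assignRanks(genes)
  pid <- genes$protein_id[!is.na(genes$protein_id)]
  for (gid in unique(genes$genome_id)) {
    p <- genes$protein_id[genes$genome_id == gid]
    p <- p[!is.na(p)]
    if (anyDuplicated(p))
      stopf("duplicate protein_id within genome '%s': %s", gid,
            paste(unique(p[duplicated(p)]), collapse = ", "))
  }
  genes
}

readGeneTSV <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(emptyGeneTable())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  need <- c("genome_id", "contig_id", "start", "end", "strand", "protein_id")
  if (!all(need %in% header))
    stopf("gene TSV '%s': header must contain %s", path,
          paste(need, collapse = ", "))
  n <- length(header)
  for (i in seq_along(fields)[-1]) {
    if (length(fields[[i]]) != n)
      stopf("gene TSV '%s': malformed line %d (%d fields, expected %d)",
            path, i, length(fields[[i]]), n)
  }
  if (length(fields) == 1L) return(emptyGeneTable())
  m <- do.call(rbind, fields[-1])
  colnames(m) <- header
  df <- as.data.frame(m, stringsAsFactors = FALSE)[need]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end))
    stopf("gene TSV '%s': non-integer coordinates", path)
  df$protein_id[df$protein_id %in% c("", "NA", ".")] <- NA_character_
  df
}

readGeneGFF3 <- function(path, genome_id, feature_type) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  if ("CDS" %in% as.character(gr$type))
    gr <- gr[as.character(gr$type) == "CDS"]
  if (!length(gr)) return(emptyGeneTable())
  meta <- S4Vectors::mcols(gr)
  pid <- if ("protein_id" %in% names(meta)) as.character(meta$protein_id)
         else if ("ID" %in% names(meta)) as.character(meta$ID)
         else if ("Name" %in% names(meta)) as.character(meta$Name)
         else rep(NA_character_, length(gr))
  data.frame(genome_id = genome_id,
             contig_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                             "-", "+"),
             protein_id = pid, stringsAsFactors = FALSE)
}

#' Read HMMER3 per-domain tabular output (domtblout)
#'
#' Parses hmmscan `--domtblout` files: one row per domain hit, with the
#' per-domain independent e-value (column 13) as `evalue` and the envelope
#' coordinates (columns 20-21) as `env_start`/`env_end`. The query (protein)
#' length from column 6 is kept as `protein_length`.
#'
#' @param path domtblout file.
#' @return A domain-hit data.frame (see [GenomeCohort()]); file order is
#'   preserved.
#' @export
readDomtblout <- function(path) {
  if (!file.exists(path)) stopf("domtblout not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) return(emptyDomainTable())
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) < 22L)
  if (length(bad))
    stopf("domtblout '%s': line %d has %d columns, expected >= 22",
          path, idx[bad[1]], length(fields[[bad[1]]]))
  m <- t(vapply(fields, function(f) f[1:22], character(22)))
  df <- data.frame(
    protein_id = m[, 4], domain_name = m[, 1],
    accession = ifelse(m[, 2] == "-", NA_character_, m[, 2]),
    evalue = as.numeric(m[, 13]),
    env_start = as.integer(m[, 20]), env_end = as.integer(m[, 21]),
    protein_length = as.integer(m[, 6]), stringsAsFactors = FALSE)
  if (anyNA(df$evalue) || any(df$evalue < 0))
    stopf("domtblout '%s': invalid i-Evalue values", path)
  if (any(df$env_start > df$env_end))
    stopf("domtblout '%s': envelope start > end", path)
  df
}

#' Read an OrthoMCL-style groups file
#'
#' One group per line, `"OG_4: idA idB idC"`. Singleton groups are accepted
#' with a warning; a protein listed in two groups is an error.
#'
#' @param path groups file.
#' @return A data.frame with columns protein_id, og_label; the per-group
#'   sizes are attached as attribute `"group_sizes"` (named integer vector).
#' @export
readGroups <- function(path) {
  if (!file.exists(path)) stopf("groups file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- emptyOGTable()
    attr(out, "group_sizes") <- integer()
    return(out)
  }
  parts <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stopf("groups file '%s': malformed line %d (no ':')", path, bad[1])
  labels <- trimws(vapply(parts, `[`, character(1), 1L))
  members <- lapply(parts, function(p) strsplit(trimws(p[2]), "\\s+")[[1]])
  members <- lapply(members, function(m) m[nzchar(m)])
  if (any(lengths(members) == 1L))
    warnf("groups file '%s': %d singleton group(s)", path,
          sum(lengths(members) == 1L))
  df <- data.frame(protein_id = unlist(members),
                   og_label = rep(labels, lengths(members)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$protein_id)) {
    dup <- unique(df$protein_id[duplicated(df$protein_id)])
    stopf("groups file '%s': protein(s) in more than one group: %s", path,
          paste(head(dup, 5), collapse = ", "))
  }
  attr(df, "group_sizes") <- setNames(lengths(members), labels)
  df
}

#' Read an R-M reference table
#'
#' TSV with columns `domain_name` and `rm_types` (comma-separated labels
#' from I, II, III, IV, V-gene), emulating a curated library of
#' experimentally characterized restriction-modification proteins. Domains
#' carrying more than one type are flagged `multi`.
#'
#' @param path TSV file.
#' @return A data.frame with columns domain_name, rm_types, multi.
#' @export
readRMReference <- function(path) {
  if (!file.exists(path)) stopf("R-M reference not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  checkColumns(df, c("domain_name", "rm_types"), "R-M reference")
  if (!nrow(df)) return(emptyRMTable())
  types <- lapply(strsplit(df$rm_types, ","), trimws)
  bad <- !vapply(types, function(t)
    length(t) >= 1L && all(nzchar(t)) &&
      all(t %in% setdiff(RM_TYPE_LABELS, "multi")), logical(1))
  if (any(bad))
    stopf("R-M reference '%s': unknown type label for domain(s): %s", path,
          paste(df$domain_name[bad], collapse = ", "))
  data.frame(domain_name = df$domain_name,
             rm_types = vapply(types, paste, character(1), collapse = ","),
             multi = lengths(types) > 1L, stringsAsFactors = FALSE)
}

#' Look up the R-M types of a domain family
#'
#' @param rmref R-M reference data.frame.
#' @param domain_name character vector of domain families.
#' @return A list of character vectors of types (empty for families absent
#'   from the reference).
#' @export
rmTypesOf <- function(rmref, domain_name) {
  i <- match(domain_name, rmref$domain_name)
  out <- vector("list", length(domain_name))
  hit <- !is.na(i)
  out[hit] <- strsplit(rmref$rm_types[i[hit]], ",", fixed = TRUE)
  out[!hit] <- list(character())
  names(out) <- domain_name
  out
}

#' Domain families classified as R-M-related
#'
#' @param rmref R-M reference data.frame.
#' @return Character vector of R-M-classified domain family names.
#' @export
rmFamilies <- function(rmref) unique(rmref$domain_name)

#' Read a taxonomy table
#'
#' TSV with genome_id and any of phylum, class, order, family, genus,
#' species; missing ranks are filled with NA.
#'
#' @param path TSV file.
#' @return A taxonomy data.frame keyed by genome_id.
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) stopf("taxonomy not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  checkColumns(df, "genome_id", "taxonomy")
  for (col in c("phylum", "class", "order", "family", "genus", "species"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  if (anyDuplicated(df$genome_id))
    stopf("taxonomy '%s': duplicate genome_id", path)
  df[c("genome_id", "phylum", "class", "order", "family", "genus",
       "species")]
}

#' Read a whole cohort directory
#'
#' Convenience loader for the layout written by [writeCohort()]:
#' `genes/<genome>.tsv`, `domains.domtblout`, `groups.txt`,
#' `rm_reference.tsv`, `taxonomy.tsv`.
#'
#' @param dir cohort directory.
#' @return A [GenomeCohort-class].
#' @export
readCohort <- function(dir) {
  gfiles <- sort(list.files(file.path(dir, "genes"), pattern = "\\.tsv$",
                            full.names = TRUE))
  if (!length(gfiles)) stopf("no gene tables under %s/genes", dir)
  genes <- do.call(rbind, lapply(gfiles, readGeneTable))
  GenomeCohort(
    genes = genes,
    domains = readDomtblout(file.path(dir, "domains.domtblout")),
    ogmap = readGroups(file.path(dir, "groups.txt")),
    rmref = readRMReference(file.path(dir, "rm_reference.tsv")),
    taxonomy = readTaxonomy(file.path(dir, "taxonomy.tsv")))
}
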
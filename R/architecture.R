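#' Bona fide proteins for a focal domain
#'
#' Keeps proteins whose best hit of the focal family has an independent
#' e-value strictly below the threshold (stringent default 1e-05; a hit at
#' exactly the threshold is excluded).
#'
#' @param hits domain-hit data.frame.
#' @param focal focal domain family name (e.g. `"HEF_HK"`).
#' @param evalue_max e-value threshold (> 0).
#' @return Character vector of protein ids.
#' @export
filterBonaFide <- function(hits, focal = "HEF_HK", evalue_max = 1e-5) {
  stopifnot(evalue_max > 0)
  f <- hits[hits$domain_name == focal, , drop = FALSE]
  if (!nrow(f)) return(character())
  best <- vapply(split(f$evalue, f$protein_id), min, numeric(1))
  sort(names(best)[best < evalue_max])
}

## merge chain-overlapping same-family hits, keeping the best-e-value hit
## of each overlap cluster
mergeOverlappingHits <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  out <- list()
  for (fam in unique(hits$domain_name)) {
    h <- hits[hits$domain_name == fam, , drop = FALSE]
    h <- h[order(h$env_start, h$env_end), , drop = FALSE]
    cluster <- cumsum(c(1L, as.integer(
      h$env_start[-1] > cummax(h$env_end)[-nrow(h)])))
    for (cl in split(seq_len(nrow(h)), cluster))
      out[[length(out) + 1L]] <- h[cl[which.min(h$evalue[cl])], ,
                                   drop = FALSE]
  }
  do.call(rbind, out)
}

#' Classify the domain architecture of one protein
#'
#' Calls one of four architecture groups for a protein carrying a bona fide
#' focal domain, from the position of its GHKL companion domains:
#' group 1 has both an N-terminal `HATPase_c_3` and a C-terminal
#' `HATPase_c`, group 2 only the C-terminal companion, group 3 only the
#' N-terminal companion, and group 4 neither. A companion is N-terminal
#' when its envelope midpoint lies before the focal envelope start, and
#' C-terminal when its midpoint lies after the focal envelope end (a
#' companion whose midpoint falls inside the focal envelope sets no flag).
#' Overlapping same-family hits are merged to the best-e-value hit before
#' evaluation; companions use the same e-value threshold as the focal
#' domain. Other families present are recorded in `extra_domains` without
#' affecting the group.
#'
#' @param hits domain-hit data.frame for one protein.
#' @param focal focal family name.
#' @param nterm_family,cterm_family companion family names.
#' @param evalue_max e-value threshold applied to focal and companions.
#' @return One-row data.frame: protein_id, group, has_nterm_hatpase_c3,
#'   has_cterm_hatpase_c, focal_evalue, length, extra_domains.
#' @export
classifyArchitecture <- function(hits, focal = "HEF_HK",
                                 nterm_family = "HATPase_c_3",
                                 cterm_family = "HATPase_c",
                                 evalue_max = 1e-5) {
  pid <- unique(hits$protein_id)
  if (length(pid) != 1L)
    stopf("classifyArchitecture expects hits of a single protein")
  hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
  hits <- mergeOverlappingHits(hits)
  f <- hits[hits$domain_name == focal, , drop = FALSE]
  if (!nrow(f))
    stopf("protein '%s' has no bona fide %s hit", pid, focal)
  fbest <- f[which.min(f$evalue), ]
  mid <- (hits$env_start + hits$env_end) / 2
  nflag <- any(hits$domain_name == nterm_family & mid < fbest$env_start)
  cflag <- any(hits$domain_name == cterm_family & mid > fbest$env_end)
  group <- if (nflag && cflag) 1L else if (cflag) 2L else if (nflag) 3L
           else 4L
  extra <- setdiff(unique(hits$domain_name),
                   c(focal, nterm_family, cterm_family))
  len <- suppressWarnings(max(hits$protein_length, na.rm = TRUE))
  if (!is.finite(len)) len <- NA_integer_
  data.frame(protein_id = pid, group = group,
             has_nterm_hatpase_c3 = nflag, has_cterm_hatpase_c = cflag,
             focal_evalue = fbest$evalue, length = as.integer(len),
             extra_domains = paste(sort(extra), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Classify architectures for all bona fide focal proteins
#'
#' @param hits domain-hit data.frame (any number of proteins).
#' @inheritParams classifyArchitecture
#' @return data.frame of [classifyArchitecture()] calls, one row per bona
#'   fide protein, ordered by protein_id.
#' @export
classifyArchitectures <- function(hits, focal = "HEF_HK",
                                  nterm_family = "HATPase_c_3",
                                  cterm_family = "HATPase_c",
                                  evalue_max = 1e-5) {
  keep <- filterBonaFide(hits, focal, evalue_max)
  if (!length(keep))
    return(data.frame(protein_id = character(), group = integer(),
                      has_nterm_hatpase_c3 = logical(),
                      has_cterm_hatpase_c = logical(),
                      focal_evalue = numeric(), length = integer(),
                      extra_domains = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(keep, function(p)
    classifyArchitecture(hits[hits$protein_id == p, , drop = FALSE],
                         focal, nterm_family, cterm_family, evalue_max)))
  rownames(out) <- NULL
  out
}

#' Collapse redundant proteins to one representative per species
#'
#' Removes redundancy typically caused by multiple strains of the same
#' species: within each species, the protein with the lowest focal
#' e-value survives, ties broken by greatest length, then lexicographically
#' smallest protein id. Proteins whose genome lacks a species are retained
#' in per-genome "species-unknown" buckets with a warning. Idempotent.
#'
#' @param proteins data.frame with protein_id, genome_id, focal_evalue,
#'   length (e.g. architecture calls joined to a protein-to-genome map).
#' @param taxonomy taxonomy data.frame with genome_id, species.
#' @return The surviving subset of `proteins`.
#' @export
collapseRedundant <- function(proteins, taxonomy) {
  checkColumns(proteins, c("protein_id", "genome_id", "focal_evalue",
                           "length"), "protein table")
  sp <- taxonomy$species[match(proteins$genome_id, taxonomy$genome_id)]
  sp[!is.na(sp) & !nzchar(sp)] <- NA_character_
  unknown <- is.na(sp)
  if (any(unknown)) {
    warnf("%d protein(s) from genome(s) without species; kept in per-genome buckets",
          sum(unknown))
    sp[unknown] <- paste0("species-unknown:", proteins$genome_id[unknown])
  }
  keep <- vapply(split(seq_len(nrow(proteins)), sp), function(i) {
    p <- proteins[i, , drop = FALSE]
    o <- order(p$focal_evalue, -p$length, p$protein_id, method = "radix")
    i[o[1]]
  }, integer(1))
  out <- proteins[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize architecture group counts and companion-domain shares
#'
#' @param calls architecture-call data.frame (see
#'   [classifyArchitectures()]).
#' @return One-row data.frame: g1..g4 counts, total, and the shares of
#'   proteins with an N-terminal companion `(g1+g3)/total` and a C-terminal
#'   companion `(g1+g2)/total`, as percentages rounded to one decimal.
#' @export
summarizeArchitectures <- function(calls) {
  if (!nrow(calls)) stopf("no architecture calls to summarize")
  n <- vapply(1:4, function(g) sum(calls$group == g), integer(1))
  total <- sum(n)
  data.frame(g1 = n[1], g2 = n[2], g3 = n[3], g4 = n[4], total = total,
             nterm_share_pct = round(100 * (n[1] + n[3]) / total, 1),
             cterm_share_pct = round(100 * (n[1] + n[2]) / total, 1))
}

#' Phyletic distribution of architecture groups
#'
#' Contingency table of taxon (at the chosen rank) by architecture group,
#' with row and column margins. Calls whose genome is absent from the
#' taxonomy (or has no name at that rank) fall into `"unclassified"`.
#'
#' @param calls architecture-call data.frame.
#' @param genome_of named character vector or data.frame (protein_id,
#'   genome_id) mapping proteins to genomes.
#' @param taxonomy taxonomy data.frame.
#' @param level taxonomic rank: phylum, class, order or family.
#' @return data.frame with one row per taxon plus a `Total` margin row;
#'   columns `g1..g4` plus `Total`.
#' @export
phyleticDistribution <- function(calls, genome_of, taxonomy,
                                 level = c("phylum", "class", "order",
                                           "family")) {
  level <- match.arg(level)
  if (is.data.frame(genome_of))
    genome_of <- setNames(genome_of$genome_id, genome_of$protein_id)
  gid <- unname(genome_of[calls$protein_id])
  taxon <- taxonomy[[level]][match(gid, taxonomy$genome_id)]
  taxon[is.na(taxon) | !nzchar(taxon)] <- "unclassified"
  tab <- table(taxon = taxon, group = factor(calls$group, levels = 1:4))
  out <- as.data.frame.matrix(tab)
  names(out) <- paste0("g", 1:4)
  out$Total <- rowSums(out)
  out <- out[order(-out$Total, rownames(out)), , drop = FALSE]
  total <- c(colSums(out[paste0("g", 1:4)]), Total = sum(out$Total))
  out <- rbind(out, Total = as.list(total))
  cbind(taxon = rownames(out), out, row.names = NULL)
}
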
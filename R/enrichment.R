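#' Count R-M domains in neighborhood windows
#'
#' Default mode `"families_per_gene"` sums, over all window genes, the
#' number of distinct R-M-classified domain families on each gene product;
#' mode `"genes"` counts window genes carrying at least one R-M family.
#' The anchor itself is never part of its window.
#'
#' @param windows a [NeighborhoodWindow-class] or list of them.
#' @param domains domain-hit data.frame.
#' @param rmref R-M reference data.frame.
#' @param mode counting mode.
#' @return A non-negative integer count summed over all windows.
#' @export
countRMInWindows <- function(windows, domains, rmref,
                             mode = c("families_per_gene", "genes")) {
  mode <- match.arg(mode)
  if (is(windows, "NeighborhoodWindow")) windows <- list(windows)
  fams <- rmFamilies(rmref)
  rmdom <- domains[domains$domain_name %in% fams, , drop = FALSE]
  total <- 0L
  for (w in windows) {
    g <- windowGenes(w)
    if (!nrow(g)) next
    per <- vapply(g$protein_id, function(p) {
      if (is.na(p)) return(0L)
      length(unique(rmdom$domain_name[rmdom$protein_id == p]))
    }, integer(1))
    total <- total + if (mode == "genes") sum(per > 0L) else sum(per)
  }
  as.integer(total)
}

## per-protein R-M score lookup: distinct R-M families per protein
rmScoreByProtein <- function(domains, rmref, mode) {
  rmdom <- unique(domains[domains$domain_name %in% rmFamilies(rmref),
                          c("protein_id", "domain_name")])
  if (!nrow(rmdom)) return(integer())
  per <- table(rmdom$protein_id)
  s <- as.integer(per)
  if (mode == "genes") s <- as.integer(s > 0L)
  setNames(s, names(per))
}

#' Shuffle a genome into a pseudogenome
#'
#' Uniformly permutes the gene identities (protein ids) of a genome across
#' all its loci -- by default jointly across contigs, anchors included.
#' Locus coordinates, contig structure and ranks are unchanged; domain and
#' OG annotations travel with gene identity. Deterministic for a fixed
#' seed.
#'
#' @param genes ranked gene data.frame for one genome.
#' @param rng_seed integer seed.
#' @param perContig permute within each contig separately.
#' @return The pseudogenome gene table (attributes `"perm"` and `"seed"`
#'   record the permutation and seed).
#' @export
shuffleGenome <- function(genes, rng_seed, perContig = FALSE) {
  stopifnot(nrow(genes) >= 1L)
  if (length(unique(genes$genome_id)) != 1L)
    stopf("shuffleGenome expects a single genome")
  genes <- genes[order(genes$contig_id, genes$rank), , drop = FALSE]
  n <- nrow(genes)
  perm <- withSeed(rng_seed, {
    if (perContig) {
      idx <- seq_len(n)
      unlist(lapply(split(idx, genes$contig_id), function(i)
        i[sample.int(length(i))]), use.names = FALSE)
    } else sample.int(n)
  })
  out <- genes
  out$protein_id <- genes$protein_id[perm]
  rownames(out) <- NULL
  attr(out, "perm") <- perm
  attr(out, "seed") <- rng_seed
  out
}

#' Pseudogenome null distribution of windowed R-M counts
#'
#' Generates `n_sims` pseudogenomes of one genome (per-simulation seeds
#' derived as `base_seed + i`), re-extracts the anchor windows at the
#' anchors' shuffled loci, and records the total R-M count over all anchor
#' windows per pseudogenome, together with the observed count on the real
#' genome.
#'
#' @param cohort a [GenomeCohort-class] (one genome, or anchors restricted
#'   to one genome).
#' @param anchors anchor protein ids (or an OG label) -- all in one genome.
#' @param k window half-width in genes.
#' @param n_sims number of pseudogenomes (>= 1).
#' @param base_seed integer base seed.
#' @param mode counting mode, see [countRMInWindows()].
#' @param perContig shuffle within contigs instead of genome-wide.
#' @return A [NullDistribution-class].
#' @export
simulateNull <- function(cohort, anchors, k, n_sims = 2000L,
                         base_seed = 1L, mode = c("families_per_gene",
                                                  "genes"),
                         perContig = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(cohort, "GenomeCohort"), n_sims >= 1L, k >= 0L)
  genes <- geneTable(cohort)
  ids <- resolveAnchors(cohort, anchors)
  idx <- match(ids, genes$protein_id)
  if (anyNA(idx))
    stopf("anchor(s) absent from gene table: %s",
          paste(ids[is.na(idx)], collapse = ", "))
  gid <- unique(genes$genome_id[idx])
  if (length(gid) != 1L)
    stopf("anchors span several genomes; simulate one genome at a time")
  g <- genes[genes$genome_id == gid, , drop = FALSE]
  g <- g[order(g$contig_id, g$rank), , drop = FALSE]
  n <- nrow(g)
  score <- rmScoreByProtein(domainHits(cohort), rmReference(cohort), mode)
  s <- unname(score[match(g$protein_id, names(score))])
  s[is.na(s)] <- 0L
  ## contig bounds in the global locus ordering (contigs are contiguous)
  ctg <- factor(g$contig_id, levels = unique(g$contig_id))
  csize <- tabulate(ctg)
  cend <- cumsum(csize)
  cstart <- cend - csize + 1L
  locLo <- cstart[as.integer(ctg)]
  locHi <- cend[as.integer(ctg)]
  aloc <- match(ids, g$protein_id)
  windowSum <- function(sv, pos) {
    cs <- cumsum(sv)
    lo <- pmax(locLo[pos], pos - k)
    hi <- pmin(locHi[pos], pos + k)
    base <- numeric(length(lo))
    base[lo > 1L] <- cs[lo[lo > 1L] - 1L]
    sum(cs[hi] - base - sv[pos])
  }
  observed <- windowSum(s, aloc)
  counts <- numeric(n_sims)
  contigIdx <- if (perContig) split(seq_len(n), ctg) else NULL
  for (i in seq_len(n_sims)) {
    perm <- withSeed(deriveSeed(base_seed, i), {
      if (perContig)
        unlist(lapply(contigIdx, function(ii) ii[sample.int(length(ii))]),
               use.names = FALSE)
      else sample.int(n)
    })
    counts[i] <- windowSum(s[perm], match(aloc, perm))
  }
  new("NullDistribution", genomeId = gid, nSims = as.integer(n_sims),
      counts = counts, observed = as.numeric(observed), k = as.integer(k),
      mode = mode, baseSeed = as.integer(base_seed))
}

#' Empirical tail p-value
#'
#' `(1 + #\{null >= observed\}) / (1 + n_null)`, the add-one permutation
#' p-value for the one-sided "greater" alternative.
#'
#' @param observed observed statistic (scalar, or a vector whose mean is
#'   used).
#' @param null numeric vector of null statistics.
#' @return p-value in (0, 1].
#' @export
empiricalPValue <- function(observed, null) {
  obs <- mean(observed)
  (1 + sum(null >= obs)) / (1 + length(null))
}

#' Significance stars for a p-value
#'
#' Thresholds: `ns` (p > 0.05), `*` (p <= 0.05), `**` (p <= 0.01),
#' `***` (p <= 0.001), `****` (p <= 0.0001).
#'
#' @param p numeric p-value(s).
#' @return Character vector of star labels.
#' @export
starsFromP <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

#' One-tailed enrichment test of observed versus null counts
#'
#' Student's pooled-variance two-sample t-test with alternative
#' "real greater than null" (Welch's test available via `flavor`), plus the
#' add-one empirical p-value of the real-sample mean against the null
#' counts, and significance stars.
#'
#' @param real_counts numeric vector of observed per-genome counts (>= 2
#'   values for the t-test).
#' @param null_counts numeric vector of pooled null counts.
#' @param alternative only `"greater"` is meaningful for enrichment;
#'   other [stats::t.test()] alternatives are accepted.
#' @param flavor `"student"` (pooled variance, default) or `"welch"`.
#' @param id identifier copied into the result row (genome or mix id).
#' @return One-row data.frame: id, n_real, n_null, t_statistic,
#'   p_one_tailed, empirical_p, stars, degenerate.
#' @export
enrichmentTest <- function(real_counts, null_counts,
                           alternative = "greater",
                           flavor = c("student", "welch"), id = NA_character_) {
  flavor <- match.arg(flavor)
  if (!length(real_counts) || !length(null_counts))
    stopf("both samples must be non-empty")
  if (length(real_counts) < 2L || length(null_counts) < 2L)
    stopf("the t-test needs at least 2 values per sample")
  degenerate <- FALSE
  if (stats::sd(real_counts) == 0 && stats::sd(null_counts) == 0) {
    dm <- mean(real_counts) - mean(null_counts)
    degenerate <- TRUE
    t_stat <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 0.5 else if (dm > 0) 0 else 1
  } else {
    tt <- stats::t.test(real_counts, null_counts,
                        alternative = alternative,
                        var.equal = (flavor == "student"))
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  data.frame(id = id, n_real = length(real_counts),
             n_null = length(null_counts), t_statistic = t_stat,
             p_one_tailed = p,
             empirical_p = empiricalPValue(real_counts, null_counts),
             stars = starsFromP(p), degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Pool per-genome null distributions into mixes
#'
#' Concatenates the null counts of the member genomes of each mix (e.g.,
#' five mixes of five genomes each for a 25-genome simulation).
#'
#' @param null_dists list of [NullDistribution-class] objects.
#' @param mix_assignment data.frame with columns genome_id, mix_id; every
#'   simulated genome must appear in exactly one mix.
#' @return Named list of pooled numeric count vectors, one per mix, with a
#'   `"mix_sizes"` attribute (genomes per mix).
#' @export
poolMixes <- function(null_dists, mix_assignment) {
  checkColumns(mix_assignment, c("genome_id", "mix_id"), "mix assignment")
  if (anyDuplicated(mix_assignment$genome_id))
    stopf("genome(s) assigned to more than one mix: %s",
          paste(unique(mix_assignment$genome_id[
            duplicated(mix_assignment$genome_id)]), collapse = ", "))
  gids <- vapply(null_dists, function(nd) nd@genomeId, character(1))
  miss <- setdiff(gids, mix_assignment$genome_id)
  if (length(miss))
    stopf("genome(s) missing from the mix assignment: %s",
          paste(miss, collapse = ", "))
  names(null_dists) <- gids
  mixes <- split(mix_assignment$genome_id, mix_assignment$mix_id)
  out <- lapply(mixes, function(members)
    unlist(lapply(null_dists[intersect(members, gids)], nullCounts),
           use.names = FALSE))
  attr(out, "mix_sizes") <- vapply(mixes, function(m)
    sum(m %in% gids), integer(1))
  out
}

#' Per-genome null summary table
#'
#' @param null_dists list of [NullDistribution-class] objects.
#' @return data.frame genome_id, n_sims, observed, null_mean, null_q95,
#'   empirical_p, stars.
#' @export
nullSummaryTable <- function(null_dists) {
  do.call(rbind, lapply(null_dists, function(nd) {
    p <- empiricalPValue(nd@observed, nd@counts)
    data.frame(genome_id = nd@genomeId, n_sims = nd@nSims,
               observed = nd@observed, null_mean = mean(nd@counts),
               null_q95 = stats::quantile(nd@counts, 0.95, names = FALSE),
               empirical_p = p, stars = starsFromP(p),
               stringsAsFactors = FALSE)
  }))
}
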
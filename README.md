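# RMcontext

Gene-neighborhood analysis of restriction–modification (R–M) systems
around two-component-like anchor genes in bacterial genome cohorts.

Prokaryotic genes that cooperate tend to co-localize. RMcontext is for
comparative genomicists who want to quantify that signal around a family
of anchor genes across hundreds of annotated genomes: how often a partner
gene sits within a few loci of the anchor, whether R–M domain families
are enriched in the anchor's neighborhood beyond what gene-content
shuffling explains, in what 5′→3′ order the surrounding domains appear,
and how the anchor-associated proteins are built from their domains.

## The statistics at the core

* **Linkage.** For anchors resolved from an ortholog group (OG) or a
  protein list, and a partner predicate (OG label or domain families),
  the linkage at distance *d* is
  `L(d) = n_linked / n_regions`, where a region is linked when ≥ 1 gene
  within *d* gene ranks of the anchor on its contig satisfies the
  predicate. Regions on contigs with fewer than `min_neighbors` other
  genes are excluded as unsuitable and reported separately; `L(d)` is
  monotone non-decreasing in *d*.
* **Pseudogenome enrichment.** Each genome's gene identities are
  permuted uniformly across its loci (annotations travel with the
  identity; coordinates stay). For each of `n_sims` pseudogenomes the
  anchor windows (±*k* genes) are re-extracted at the anchors' new loci
  and their R–M content counted — by default the sum over window genes of
  distinct R–M-classified Pfam families per product. Observed counts are
  compared against pooled nulls with a one-tailed Student's
  pooled-variance *t*-test (real > null), alongside the add-one empirical
  p-value `(1 + #{null ≥ mean(obs)}) / (1 + n_null)` and star bands
  (`ns` > 0.05 through `****` ≤ 1e-4).
* **5′→3′ co-occurrence network.** Within ±3-gene windows, consecutive
  gene labels (domain families, or OG labels for domain-less products)
  form directed edges in raw contig order, weighted by the number of
  distinct **genera** supporting the adjacency; only R–M nodes and their
  direct neighbors are retained.
* **Domain architectures.** Proteins with a bona fide focal domain
  (best e-value < 1e-05) are classified by envelope-midpoint position of
  their GHKL companions: group 1 = N-terminal `HATPase_c_3` **and**
  C-terminal `HATPase_c`, group 2 = C-terminal only, group 3 = N-terminal
  only, group 4 = neither; summaries report the companion shares
  `(g1+g3)/total` and `(g1+g2)/total` and taxon × group tables.

A seedable synthetic-cohort generator plants all of this structure
(anchors, partners at a chosen linkage rate, spatial R–M enrichment,
taxonomy) and emits the same file formats the readers accept — GFF3 or a
TSV gene-table dialect, HMMER3 `domtblout`, OrthoMCL `groups`, TSV
taxonomy/R–M reference — plus a machine-readable truth record, so every
stage is testable end to end without downloads.

## Worked example

```r
library(RMcontext)

spec <- cohortSpec(nGenomes = 25, genesPerContig = 200, seed = 7)
res  <- generateCohort(spec)
co   <- res$cohort
co
#> GenomeCohort with 25 genome(s), 5000 gene loci
#>   domain hits:    2653
#>   OG assignments: 1419 (7 groups)
#>   R-M reference:  8 domain families
#>   taxonomy:       25 genomes

linkageSweep(co, "OG_A", "HATPase_c", 1:3)
#>   d n_regions n_linked linkage n_excluded
#> 1 1        25        5    0.20          0
#> 2 2        25       15    0.60          0
#> 3 3        25       23    0.92          0
```

The 25 anchor regions (OG_A) carry a GHKL partner within three genes in
92% of cases — the planted rate was 0.916. The pseudogenome null for one
genome:

```r
nd <- simulateNull(co, res$truth$genomes[["g0001"]]$anchors, k = 10,
                   n_sims = 2000, base_seed = 104729)
nd
#> NullDistribution for g0001: 2000 pseudogenomes (k=10, mode=families_per_gene)
#>   observed 5 vs null mean 1.288 [q95 3], empirical p = 0.005497
```

Five R–M families sit within ten genes of this genome's anchor, against
1.3 expected under shuffling: about four-fold enrichment, in the top 0.6%
of the null. Architecture classification on generated fixtures with the
canonical group sizes:

```r
fx <- makeArchitectureFixtures(c(g1 = 174, g2 = 34, g3 = 11, g4 = 3))
summarizeArchitectures(classifyArchitectures(fx$hits))
#>    g1 g2 g3 g4 total nterm_share_pct cterm_share_pct
#> 1 174 34 11  3   222            83.3            93.7
```

So 83.3% of the 222 proteins carry the N-terminal companion and 93.7%
the C-terminal one.

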
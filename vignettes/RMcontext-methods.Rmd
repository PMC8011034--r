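---
title: "RMcontext: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RMcontext: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RMcontext)
```

## Scope and scientific background

Bacterial genes that work together tend to live together: functionally
coupled genes are repeatedly found within a few loci of each other across
distantly related genomes. RMcontext implements the comparative-genomics
machinery needed to exploit this signal around a family of anchor genes —
in the motivating application, response-regulator-like genes of a putative
two-component system that co-reside with GHKL-superfamily ATPase partners
and with restriction–modification (R–M) systems. The package answers four
questions:

1. **Linkage** — in what fraction of anchor regions does a partner gene
   (defined by ortholog group or by domain content) occur within *d* genes
   of the anchor?
2. **Enrichment** — are R–M domain families over-represented in the
   ±*k*-gene neighborhoods of the anchors, relative to a permutation null
   in which each genome's gene content is shuffled across its loci
   ("pseudogenomes")?
3. **Organization** — in what 5′→3′ order do domain families appear around
   the anchors, summarized as a directed co-occurrence network weighted by
   the number of genera supporting each adjacency?
4. **Architecture** — how are the anchor-partner proteins built, classified
   into four groups by the presence of an N-terminal and/or C-terminal
   GHKL companion domain, and how are the groups distributed across taxa?

Everything operates on gene *ranks* (order along a contig), not base
pairs: the distance between adjacent genes is 1 regardless of intergenic
spacing. This matches how neighborhood ranges are described in the
comparative-genomics literature ("ten genes up- and downstream") and makes
the permutation null exact, because shuffling preserves the locus
scaffold.

## Data model

A `GenomeCohort` bundles five tables:

* **genes** — one row per locus: genome, contig, 0-based rank (assigned by
  start coordinate; ties broken by end, then protein id), 1-based
  inclusive coordinates, strand, protein id (`NA` for non-coding loci,
  which occupy a rank but carry no domains).
* **domains** — HMMER3 `domtblout` per-domain hits: family, independent
  e-value (the per-domain statistic, not the full-sequence one, because
  positional architecture calls need per-domain significance), envelope
  coordinates, and the protein length.
* **ogmap** — ortholog-group assignments (OrthoMCL `groups` dialect); a
  protein belongs to at most one group.
* **rmref** — the R–M reference: domain family → R–M types (I–IV and
  V-gene, for very-short-patch repair endonucleases). Families with more
  than one type are flagged `multi`. The built-in
  `defaultRMReference()` covers a representative set: C5 methylase
  (`DNA_methylase`, II), adenine methylase (`N6_N4_Mtase`, I/II/III),
  `Vsr` (V-gene), the type II endonucleases `HNH_2`, `MvaI_BcnI`,
  `EcoRII-C`, and the type I components `ResIII`, `HSDR`.
* **taxonomy** — genome → phylum … species.

Validity methods enforce the invariants (rank bijection per contig,
coordinate sanity, unique OG membership, known R–M type labels) at
construction time.

## Neighborhood windows and linkage

`extractWindow()` collects up to *k* genes on each side of an anchor on
its contig. Sides are oriented by the anchor's strand — "upstream of the
anchor" is a biological statement, so a minus-strand anchor has its sides
swapped relative to contig order (`orientByStrand = FALSE` restores raw
order). A side with fewer than *k* genes available is flagged truncated.
The anchor is never part of its own window.

`computeLinkage()` counts a region as linked when at least one gene
within rank distance *d* (strand-agnostic, same contig) satisfies the
partner predicate. Regions whose contig provides fewer than
`min_neighbors` other genes (default 1) are excluded as unsuitable and
tallied separately — the analogue of dropping regions that sit on
fragmented assemblies with no usable context. The exclusion rule is
deliberately independent of *d*: if suitability were judged inside the
*d*-window, enlarging *d* could admit new, systematically unlinked
regions and the linkage curve would no longer be monotone; with a
contig-wide rule, `linkage(d)` is monotone non-decreasing by
construction, which the test suite asserts as a property.

`tabulateNeighborhoodDomains()` implements the reporting convention used
for neighborhood censuses: each window gene contributes each of its
distinct domain families once; a gene whose product has no known domain
contributes its ortholog-group label; a gene with neither contributes
`"na"`. `topFractionDomains()` keeps the `ceiling(fraction × labels)`
best-represented labels, ordered count-descending then label-ascending,
with ties at the cutoff resolved by that ordering (so results are
deterministic).

## Pseudogenome permutation null

`shuffleGenome()` draws a uniform permutation of the gene identities of a
genome across all of its loci — jointly across contigs, anchors included
(a per-contig mode exists behind a flag). Coordinates, contig structure
and ranks never change; domain and OG annotations travel with the
identity. `simulateNull()` repeats this `n_sims` times, re-extracts the
anchor windows wherever the anchors landed, and counts R–M content per
pseudogenome; per-simulation seeds are `base_seed + i`, so a run is fully
reproducible from one integer. When simulating several genomes or
replicates, give each its own well-separated `base_seed` (e.g. multiples
of a large prime): adjacent base seeds make consecutive simulations share
most of their seed stream across runs, which correlates the resulting
null distributions.

Two counting units are exposed, because "number of R–M domains" is
ambiguous: the default `families_per_gene` sums the distinct
R–M-classified families per window gene (a gene carrying a methylase and
an endonuclease domain counts 2), while `genes` counts window genes with
at least one R–M family. Reports name the mode used.

Because the anchor shuffles too, the windowed count under the null is a
sum over a window that truncates when the anchor lands near a contig end.
For a single-contig genome of *n* loci with *R* single-family R–M genes,
the exact null mean is `mean(window sizes over anchor positions) × R /
(n − 1)` — e.g. 18.9 × 10/99 ≈ 1.91 for n = 100, R = 10, k = 10 (not
20 × 10/99 ≈ 2.02, which ignores truncation). The test suite checks the
simulated mean against this closed form and against exhaustive
enumeration of all n! permutations for tiny genomes.

`enrichmentTest()` compares observed per-genome counts against pooled
null counts with Student's pooled-variance one-tailed *t*-test
(real > null; Welch's variant is available), reports the add-one
empirical p-value `(1 + #{null ≥ mean(real)}) / (1 + n_null)`, and maps
p to the conventional star bands (`ns` > 0.05 … `****` ≤ 0.0001). Two
zero-variance samples with equal means yield p = 0.5 and a `degenerate`
flag rather than an error. `poolMixes()` concatenates per-genome nulls
into named mixes (e.g. five mixes of five genomes) after checking that
every genome belongs to exactly one mix.

## The 5′→3′ co-occurrence network

`buildNetwork()` lays out each anchor window (anchor included) in raw
contig 5′→3′ order — here direction is a property of the replicon, not of
the anchor's strand. Each gene is labeled by all of its distinct domain
families (flag for best-hit-only), or by its OG label when it has no
domain; label-less genes are bridged over by default, since the network
depicts domain order rather than locus order (a strict-adjacency flag
disables bridging). Every label of gene *i* connects to every label of
gene *i + 1* with a directed edge. Edges are deduplicated per genus: the
weight is the number of distinct genera in which the adjacency was seen,
never the number of strains. Genomes lacking a genus in the taxonomy are
skipped with a warning.

The retention filter keeps R–M-classified nodes and any node with at
least one R–M-classified neighbor, then takes the induced subgraph. R–M
nodes are retained unconditionally so that the filter is idempotent: a
kept non-R–M node's R–M witness is itself always kept.
`collapseNonRMNeighbors()` merges the non-R–M neighbors of a hub whose
only connection is that hub into a single aggregate node recording the
merged-label count — the standard visual simplification for a methylase
hub surrounded by dozens of unrelated domains. Output formats are SIF,
GraphML (with `weight`, `genera` and `rm_types` attributes) and a TSV
edge list.

## Architecture classification

`classifyArchitectures()` restricts to bona fide focal proteins: the best
focal-domain hit must have e-value strictly below the stringent threshold
(default 1e-05; a hit at exactly the threshold is excluded). Within a
protein, overlapping same-family hits are merged to the best-e-value hit.
Companion calls are positional, using envelope midpoints against the
focal envelope: an `HATPase_c_3` with midpoint before the focal start is
an N-terminal companion; an `HATPase_c` with midpoint after the focal end
is C-terminal. Midpoints were chosen over strict boundaries because
partial overlaps between adjacent domain envelopes are common in HMMER
output and should not flip a call. The four groups are a total function
of the two flags: both → group 1, C-only → group 2, N-only → group 3,
neither → group 4. Companions reuse the focal e-value threshold. Other
families present are recorded but never affect the group.

`collapseRedundant()` keeps one protein per species (best focal e-value,
then greatest length, then smallest protein id — deterministic and
idempotent), with per-genome "species-unknown" buckets when taxonomy is
incomplete. `summarizeArchitectures()` reports group counts and the
shares with an N-terminal companion, `(g1 + g3)/total`, and a C-terminal
companion, `(g1 + g2)/total`, as percentages to one decimal — for the
canonical count vector (174, 34, 11, 3) these are 83.3% and 93.7% of 222.
`phyleticDistribution()` builds the taxon × group contingency table with
margins at a chosen rank.

## Synthetic cohorts and what they do (and do not) show

`generateCohort()` emits complete, parseable cohorts (gene TSV/GFF3,
domtblout, OrthoMCL groups, R–M reference, taxonomy, and a truth record)
with planted structure:

* anchors (`OG_A`, no domains — mirroring anchor genes whose product has
  no known domain) in each genome with probability `anchorProb`;
  with probability `paralogProb` (default 0.048, the observed rate of
  paralog-bearing strains) a genome carries 2–3 anchor paralogs;
* a GHKL partner (`HATPase_c` domain, `OG_B`) planted within `linkD`
  genes of an anchor with probability `pLink` (default 0.916, the
  linkage the statistic is meant to detect);
* R–M families on loci within `rmWindow` genes of an anchor at per-locus
  rate `lambdaNear` (default 0.25) versus `lambdaBg` elsewhere (default
  0.05, a five-fold enrichment); families drawn methylase-heavy from the
  built-in R–M vocabulary;
* background domains and shared ortholog groups on the remaining genes,
  and a small multi-phylum taxonomy.

Defaults describe a scaled-down study cohort: 25 single-contig genomes of
200 genes. Coordinates are non-overlapping fixed-width intervals because
only gene order enters any statistic. All randomness derives from
`spec@seed`; identical specs give byte-identical files. Ortholog groups
that would be singletons cohort-wide are dropped from the OG map, since
real clustering output spans groups of at least two sequences.

The generator emulates the *statistical* structure of annotated genome
cohorts — ordered loci, planted co-localization, spatial R–M enrichment,
taxonomic nesting — and nothing sequence-level: no nucleotides or amino
acids, no HMM emission realism, no assembly artifacts beyond short
contigs, no horizontal-transfer phylogenetic correlation between genomes.
Passing tests therefore demonstrate that the statistics recover planted
truth under the model's assumptions, not that the biological conclusions
of any particular cohort are correct.

## Numerical and experimental design choices

* **Seeds.** All derived seeds stay below 2³¹ (`deriveSeed()` works
  modulo a prime near the integer maximum). RNG state is always
  restored after use, so library calls never perturb a caller's stream.
* **Tie-breaks.** Gene ranking (start, end, protein id), top-fraction
  ordering (count desc, label asc), and redundancy collapse (e-value,
  length, id) are all total orders, so every result is deterministic.
* **Degenerate inputs.** Empty gene files parse to empty tables with a
  warning; an empty network writes a zero-line SIF; `k = 0` windows are
  empty without truncation flags; constant t-test samples are flagged
  rather than fatal.
* **Problem sizes.** The validation suite uses: 20 random cohorts of at
  most 50 genes for brute-force oracle equivalence; 2000 shuffles of a
  100-locus genome against the closed-form null mean, and full
  enumeration of all 720 permutations of a 6-locus genome; a power run of
  25 genomes × 2000 pseudogenomes at five-fold planted enrichment (every
  mix of five reaches p ≤ 1e-4); linkage recovery at 500 anchors for
  planted rates 0.3/0.6/0.9 within three binomial standard errors; and a
  1000-replicate null calibration.
* **Calibration design.** The add-one empirical p-value of an integer
  count is conservatively biased by ties, by roughly half the count
  distribution's mean point mass. A meaningful uniformity check therefore
  needs a count with wide support: the calibration cohort uses 2500-gene
  genomes, 2–3 anchor paralogs, k = 180 windows and a dense R–M rate
  (`lambdaNear = lambdaBg = 0.5`), giving the count a standard deviation
  near 12 and the Kolmogorov–Smirnov distance of the 1000 replicate
  p-values a comfortable margin below 0.05. Uniformity under the null is
  a property of the permutation procedure, not of the planted rate, so
  the dense-R–M choice trades biological realism for statistical
  resolution, deliberately.

## Limitations

* Linkage treats every anchor paralog as an independent region; if two
  paralogs fall inside each other's windows their regions are correlated,
  which the binomial error bars ignore.
* The pseudogenome null preserves gene multisets but not local
  composition biases (GC skew, operon structure), so real-data
  enrichment p-values inherit the usual caveats of genome-shuffling
  nulls.
* The Student's t-test on pooled counts treats pseudogenome draws as
  independent observations; with 2000 draws per genome its p-values are
  effectively a summary statistic, and the empirical p-value is the more
  honest tail measure for single genomes.
* Network deduplication is per genus, as the weighting is defined in
  genera; strain-level recurrence within a genus is invisible by design.
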
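---
title: "Methods: haploid linkage mapping and assembly evaluation with haplomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haploid linkage mapping and assembly evaluation with haplomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

haplomap builds ultra-dense haploid genetic linkage maps from conifer
megagametophyte genotypes and uses them to interrogate a fragmented genome
assembly.  This vignette is the package's account of the underlying models,
the tunable parameters, the numerical choices, and what the synthetic-data
layer does and does not establish.

## The biological design

Conifer seeds contain the megagametophyte, a haploid maternal tissue
genetically identical to the egg cell's meiotic product.  Genotyping one
megagametophyte per seed therefore samples one gamete of the mother tree:
every informative locus (mother heterozygous) segregates 1:1, phase can be
resolved from the offspring alone, and a single open-pollinated mother gives
a mapping population without a controlled cross.  Norway spruce (*Picea
abies*), the system this package is built around, has 12 chromosomes, a
~20 Gbp genome and a v1.0 assembly fragmented into millions of scaffolds, so
a dense genetic map doubles as an assembly auditor: markers from one
physical scaffold must land in one genetic spot, and a scaffold whose
markers map to two chromosomes, or far apart on one, carries a putative
mis-join.

## Genotype quality control

Genotypes are called under a *diploid* model on purpose: a haploid tissue
cannot yield heterozygous calls, so heterozygotes measure contamination
(residual diploid seed coat) and genotyping error.
`collapse_heterozygous_calls()` turns het calls into missing data and
records the per-sample heterozygous fraction over non-missing calls — the
denominator choice makes it a per-genotyped-call contamination rate.
`filter_samples()` removes samples with more than 10% heterozygous or more
than 20% missing calls; both comparisons are strict (a sample at exactly the
threshold is kept), matching the usual "greater than" phrasing of such
filters.

When the mapping population unknowingly mixes several maternal families,
`cluster_families()` recovers them: PCA on the sample-by-marker matrix
(missing calls mean-imputed per marker, a transient imputation only),
average-linkage hierarchical clustering on the Euclidean distances of the
leading 10 components, and the cut with the best average silhouette width
over k = 2..max_k.  The silhouette is undefined at k = 1, so a
weak-structure floor (`min_silhouette = 0.25`) stands in for it: if no cut
reaches the floor the sample is treated as one family.  Two caveats are
worth stating.  First, with very few chromosomes the shared maternal
haplotype blocks themselves generate within-family clusters; with the 12
chromosomes of the real design this structure averages out, and the
package's tests cluster on 12-chromosome simulations for exactly this
reason.  Second, all of these specifics (components, linkage, floor) are
conventional but not canonical; they are arguments, not constants.

`recode_testcross()` applies the one-parent-informative testcross coding: a
marker is kept for a family iff both alleles are observed in it.  A
consequence the analysis scripts surface deliberately: an allele-flip error
at a maternal-*homozygous* locus fakes a second allele and passes this rule,
producing a marker with a grotesquely distorted ratio (e.g. 418:2).  The
chi-square segregation test (`test_segregation_distortion()`, df = 1 against
1:1, Bonferroni over testable bins) flags these reliably, and the analysis
workflow excludes flagged markers before mapping.  This stands in for the
marker-level SNP filters a real pipeline applies upstream; the package keeps
it a visible, configurable step rather than hard-coding it.

## Linkage mapping

**Binning.** Markers with byte-identical segregation signatures (including
the missing pattern — "exact" mode) are recombinationally inseparable and
collapse into one bin; the member with the fewest missing calls represents
the bin, ties broken by marker id.  Exactness is a deliberate choice: merging
signatures that differ only in missingness would silently impute.

**Two-point estimation.** For two haploid signatures with `n`
pairwise-complete samples and `k` mismatches, phase is chosen to make
recombinants `min(k, n - k)`, `r = recombinants / n`, and
`LOD = k' log10(2r) + (n - k') log10(2(1 - r))`, which is `n log10 2` at
`r = 0`.  `linkage_data()` computes all pairs at once with matrix products;
a property test checks it against the scalar implementation pair by pair.

**Grouping.** Bins are linked when `LOD >= 8` and `r <= 0.35`; linkage
groups are the connected components of that graph.  Transitive closure is
intentional — a chain a–b–c groups even if a–c alone would not pass.

**Ordering.** RECORD builds an order by greedy insertion: bins arrive in a
random sequence and each is placed where it minimally increases COUNT, the
total number of observed recombination events between adjacent bins.  For
haploid data COUNT is the sum of phase-aligned adjacent mismatch counts; the
per-informative-sample normalized count is used only to break ties, so
differing missingness cannot dominate the objective.  The procedure repeats
16 times (`n_counts`) from different random sequences and keeps the lowest
COUNT.  Orders are reported with the lexicographically lower bin id first,
fixing the global reversal ambiguity everywhere downstream.

**Ripple.** `ripple_window()` slides a 10-bin window in 1-bin steps and
accepts a within-window permutation only if it strictly lowers COUNT,
iterating until a pass changes nothing (COUNT is therefore monotone).  A
10-marker window cannot enumerate 10! permutations; the policy is exhaustive
enumeration for windows of 8 or fewer bins, and otherwise all circular
shifts, all adjacent transpositions and 5,000 seeded random permutations.
This is a documented bounded-runtime approximation of full rippling.

**Distances.** Adjacent recombination fractions map to cM through the
Kosambi function `d = 25 ln((1+2r)/(1-2r))`, cumulative from 0.  An
adjacency at `r = 0.5` would be infinitely long and is rejected as a
grouping/ordering failure rather than clamped.  The gamete simulator is
Poisson/no-interference (Haldane-consistent), so Kosambi-mapped recovered
lengths sit a few percent *below* the simulated truth; recovery tests
therefore assert length agreement only within 15%, while order agreement
(Kendall tau) is asserted tightly.

## Consensus maps

Component maps from different families are merged per linkage group by
constrained L1 optimization, the contract popularized by LPmerge.  For a
maximum-interval setting K, each component contributes ordinal constraints
`x_j - x_i >= 0` for marker pairs at most K intervals apart in its order
(pairs tied in cM contribute nothing); the consensus positions x minimize
the weighted sum of absolute deviations from the component positions, each
component getting one free additive shift.  The LP is solved exactly as a
constrained median regression (`quantreg::rq.fit.fnc`), after two graph
steps: conflicting constraints — cycles in the strict-precedence digraph —
are deleted from the lowest-ranked components first (components ranked by
marker count), and the surviving DAG is transitively reduced so the solver
sees only non-redundant rows.  K runs over 1..10; each candidate is scored
by the mean per-component RMSE over shared markers at the optimal L1 shift,
and the lowest mean RMSE wins, ties toward the smallest K.  A brute-force
small-instance oracle (grid search with closed-form median shifts) pins the
solver's objective on conflicting toys in the tests.

Linkage-group identity across components is decided by shared-scaffold
majority vote against the largest component, ties toward the larger shared
count.  Order agreement is always Kendall's tau-b: bins make exact cM ties
common, so the tie-corrected variant is the only defensible one.

## Map inflation

Genotyping errors fake recombination events and stretch a dense map.  The
subsampling estimate measures this directly: per LG, sample `n_bins` bins
without replacement, re-order with 10 RECORD rounds, re-measure the Kosambi
length, repeat `n_rounds` times; the difference between the observed
full-map length and the mean subsample length, divided by the LG's total bin
count, is the inflation per marker bin.  Subsampled bins keep their full
signatures (no re-binning) and LG assignments are reused, not re-grouped.
Two bias notes: the subsample's end bins trim a little true length, so even
error-free data shows a slightly positive estimate, and the estimate scales
with how far `n_bins` sits below the LG's bin count.  The desk-scale runs in
the acceptance checks use LGs of 80 bins with subsamples of 60 (and the
analysis scripts ~30-bin LGs with subsamples of 20), sizes at which the
error signal dominates the end-trimming bias by an order of magnitude.

## Assembly evaluation

`classify_scaffolds()` applies the 5 cM rule to every scaffold with mapped
markers: one LG and a span under 5 cM is `consistent`; one LG with a span
exceeding 5 cM is an `intra-split`; markers on k LGs is an `inter-split-k`.
A span of exactly 5 cM counts as consistent — splits are defined by
*exceeding* the interval.  `crosscheck_component_support()` asks whether any
single component map reproduces a consensus split (`supported`), whether
some component co-locates the markers instead (`artifact` — the signature of
a merge artifact), or whether no component carries two of the markers
(`unverifiable`).  `annotate_splits()` localizes each split to the interval
between the two nearest disagreeing markers in scaffold bp order — the
tightest localizable interval — categorizes it (`within-gene` when one gene
model contains both flanking markers; `interior-region` when the scaffold's
5' and 3' markers co-map around a wandering interior; otherwise
`between-genes`) and flags overlap with an N-gap span (`at_contig_join`).
Coordinate conventions are fixed package-wide and tested once: marker loci
and gene models are 1-based inclusive bp, contig and gap spans 0-based
half-open.

## Synteny comparison

Inter-map comparison consumes a correspondence table (the output of an
external reciprocal-best-hit search; the package validates the TSV contract
but never runs alignment), keeps rows with identity strictly above 95% and
the RBH flag set, and counts comparisons per LG pair.  Homology is majority
vote per query LG (ties by larger order tau, then LG id); the homologous
fraction is invariant under LG relabeling, and per-pair order agreement is
again tau-b.

## Population-genetic scans

Hard site filters mirror standard cohort practice: bi-allelic SNPs inside
the extended probe regions (120 bp probes ±100 bp) with QD > 5, MQ > 50 and
total DP within [3000, 16000], then samples over 25% missing are dropped;
every removal is counted per rule in a filter ledger.  Note the DP window is
cohort-specific (it scales with sample count); synthetic fixtures scale it
accordingly.

Per probe: S is the count of segregating sites; pi is
`sum(2 p (1-p) n/(n-1))` over sites — exactly the mean pairwise difference
count — divided by the *callable* sites of the extended region (the nominal
length is not the denominator; with missing data the callable count is the
defensible one, and it is an argument).  Tajima's D follows the 1989
definition with constants computed from the mean per-segregating-site
chromosome count; D is reported as missing when S = 0 (and is exactly 0
whenever pi equals S/a1, a fixture the tests construct).  Kelly's ZnS is the
mean squared correlation of allele dosages over all pairs of segregating
sites, computed on pairwise-complete samples; for unphased diploid dosages
this is composite LD, a documented deviation from haplotype r².  Diploid
panels are treated as 2n haplotypes of unknown phase throughout.

Probes absent from the map borrow the coordinates of the physically closest
(bp) mapped probe on the same scaffold; a distance tie anchors to the
smaller cM, then the smaller probe id, keeping anchoring deterministic.
Sliding windows are half-open `[k, k+10)` cM advancing 1 cM, means are
unweighted over probes with defined values, and empty windows are emitted
(n = 0, missing mean) rather than dropped, so tracks are alignable across
statistics.

## The synthetic-data layer

The simulators define the package's testbed and its claims:

* `simulate_true_map()` — 12 chromosomes of 100 cM by default.  Loci can be
  placed uniformly or in scaffold-scale clusters (`clusters_per_chr`,
  cluster span 0.4 cM): physical scaffolds cover a near-point genetic
  interval (hundreds of kb against Mb-per-cM), and the clustered geometry is
  what makes multi-marker scaffolds genetically tight, as in real data.
* `simulate_haploid_family()` — gametes with Poisson crossovers (no
  interference), uniform breakpoints, optional allele-flip error (the
  mechanism behind map inflation; dropout is modelled as missingness, not
  error) and missingness.  Maternal genotypes make loci informative or not
  per family.
* `simulate_assembly()` — scaffolds of 1–11 markers assembled from
  contiguous true-map runs, contigs separated by N-gaps, gene models inside
  contigs plus one gene spanning the first gap of every multi-contig
  scaffold (so a join there splits *within* a gene model).  Planted
  inter-chimeras concatenate runs from 2–3 chromosomes, intra-chimeras two
  runs at least 8 cM apart (comfortably beyond the 5 cM rule under Kosambi
  shrinkage); joins sit at a gap span by default, optionally inside a
  contig.  A non-chimeric run is truncated at 1 cM of genetic span
  (`run_span_cM`) — the realistic scaffold geometry — rather than allowed to
  spread.
* `simulate_coalescent_probe()` — the standard single-population neutral
  coalescent under infinite sites: waiting times Exp(k(k-1)/2), mutations
  Poisson(theta/2 per unit branch length), positions uniform.  Expectations
  used as oracles: E[S] = theta·a1(n), E[pairwise difference] = theta.

Everything is seed-deterministic, and determinism is asserted for all four
generators.

What passing on this testbed does **not** show about real data: no linkage
disequilibrium structure beyond the cross, no locus-specific error or
missingness (both are i.i.d.), no segregation distortion of biological
origin, no population structure or selection in the coalescent panels, no
sequence-level artifacts (the simulators never emit read or base data), and
crossover interference is absent by construction, so the Kosambi/Haldane
mismatch is a known systematic rather than a subject of inference.

## Problem sizes and numerical conventions

The standard desk-scale designs (used by the tests, the acceptance script
and the analysis drivers) are: order recovery and inflation on 12
chromosomes × 80 loci with 800 gametes; chimera detection on 500 scaffolds
over a 12 × 130-locus clustered map with 400 gametes; coalescent checks on
2,000 panels of 20 haplotypes at theta = 5; the narrative analysis on three
families (260/220/420) with 0.3% error, 5% missingness and 2% contamination.
Tie-breaks are lexicographic by id everywhere an order is otherwise
arbitrary; every Monte-Carlo assertion is a 3-SD/3-SE band or a fixed-seed
comparison; and all randomness flows from explicit integer seeds.

## Known limitations

* RECORD plus bounded rippling is a heuristic; on noisy ultra-dense maps it
  can leave local order errors that inflate lengths (which is precisely what
  the inflation estimator measures).
* The consensus solver's constraint-deletion order (lower-ranked components
  first, per strongly connected component) is a policy, not an optimum;
  different deletion orders can yield different, equally feasible merges.
* Tajima's D uses the mean sample size across segregating sites; with
  heavy, uneven missingness a per-site treatment would differ.
* The silhouette-based family count is only as good as the separation in
  the leading components; pathological designs (few chromosomes, tiny
  families) confuse it, as discussed above.
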
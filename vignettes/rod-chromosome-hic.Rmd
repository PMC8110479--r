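---
title: "Analysing Hi-C maps of rod-shaped dinoflagellate chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing Hi-C maps of rod-shaped dinoflagellate chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Dinoflagellate chromosomes are permanently condensed, liquid-crystalline
rods. In Hi-C maps this produces a characteristic signature that differs
from every other well-studied eukaryote: contact frequency $P(s)$ decays
very shallowly (exponent around $-0.4$) out to a rod-length scale of a few
megabases and then drops steeply; there are no A/B compartments and no
point loops; instead each chromosome is a linear series of structural
domains whose boundaries coincide with the sites where two blocks of
co-oriented, convergently transcribed genes meet, and which dissolve when
transcription is blocked. `dinochrom` implements the full analysis stack
for this kind of genome — matrix building and balancing, insulation-based
boundary calling, $P(s)$ regime analysis, Hi-C-assisted karyotyping and
scaffolding, gene-orientation architecture, and aggregate observed/expected
maps — together with a seeded synthetic-data generator that plants every
one of those signals as ground truth, so each stage can be scored
end-to-end.

This vignette explains the models and the decisions behind them. Nothing
reported here is asserted from memory: every number the package claims is
recomputed by the test suite or by `scripts/acceptance.R`.

## Data model

All coordinates are 0-based and half-open internally; 1-based formats
(GFF3, pairs) are converted at the I/O boundary, which confines off-by-one
handling to one file. A `contact_matrix` stores raw counts as a symmetric
sparse matrix plus per-bin balancing weights applied lazily, so raw and
balanced views coexist. Binned matrices travel on disk as a plain-text
triplet dialect (`*.bins.tsv` + `*.triplets.tsv`) so that no binary
container is ever required.

## Balancing

`ice_balance()` fits multiplicative per-bin weights by iterative
correction until the coefficient of variation of unmasked marginals falls
below `tol` (default `1e-5`, at most `max_iter = 200` sweeps; failure to
converge sets a flag rather than erroring). Bins with zero coverage, or
whose raw marginal deviates from the median by more than `mad_filter = 5`
median absolute deviations, are masked. The source study does not state
its low-coverage filter; the MAD rule is standard practice and exposed as
a parameter. Weights are normalised so the mean balanced marginal is 1.

## Insulation and domain boundaries

The insulation score of bin $i$ is the mean balanced contact over all bin
pairs $(j, k)$ with $i - w \le j < i < k \le i + w$, where the window $W$
is 500 kb at 10-kb resolution ($w = 50$); the reported score is
$\log_2(\text{raw}/\text{chromosome mean})$. Bins within $W$ of a
chromosome end, or whose window square is more than half masked, are
undefined — assembly gaps must not fabricate boundaries, so nothing is
imputed. Chromosomes shorter than $2W$ yield no profile at all, mirroring
the exclusion of the shortest chromosomes in published work.

Boundary calling follows the delta-vector construction: $\Delta(i)$ is the
mean score over $(i, i+100\,\text{kb}]$ minus the mean over
$[i-100\,\text{kb}, i)$; candidates sit at downward-to-upward zero
crossings, and strength is the height difference between the nearest delta
extrema flanking the crossing. Calls with strength below 0.2 are dropped.
The delta span is not stated in the source methods; 100 kb follows the
cited insulation tool's convention and is a config field. Automated
refinement then snaps each call to the minimal score within ±2 bins (the
published pipeline did this manually); a call moves only to a *unique*
strict minimum — ties keep the original position. `contig_filter()`
implements the contiguity rule: a boundary is `in_contig` when its 10-kb
interval plus 10 kb on each side contains no run of 24 or more Ns.

The summed-area-table implementation is checked against a brute-force
double loop to $10^{-12}$ relative error on random dense matrices.

## Contact-probability scaling

`ps_from_pairs()` bins cis separations geometrically (factor $2^{1/8}$)
and divides per chromosome by the number of possible locus pairs at those
separations, then pools chromosomes weighted by observation count so long
chromosomes do not dominate. `segment_regimes()` fits a continuous
piecewise-linear function in log–log space by exhaustive breakpoint search
(two knots by default), which localises the rod-length drop; the regime-II
exponent is additionally fitted by OLS over an explicit range (default
50 kb–2 Mb genome-wide; scaled runs use a range tied to the cutoff).
Regime I in real data is dominated by non-informative ligation products
and is reported but not interpreted.

Per-domain-square curves (`ps_domain_squares()`, 50-kb bins) average each
diagonal of every square defined by the boundary grid, dropping the
smallest and largest separation of off-diagonal squares (single-cell
diagonals). `gap_shift()` overlays an inter-domain curve on a reference by
grid search over x-shifts, minimising the squared difference of
$\log_{10} P$; the argmin estimates the inert spacer between domains and
is flagged when censored at the grid limit.

`terminal_vs_internal()` compares the two terminal domains of each
chromosome (at least three domains required) with the internal ones. The
ratio averages *separation-matched* terminal/internal ratios, so unequal
domain sizes cannot bias it, and it uses the matrix as given — balanced
values when weights exist, raw counts otherwise. On synthetic data the raw
matrix is the right input: the generator emits bias-free counts, and
iterative correction would flatten genuine terminal compaction into the
weights (it equalises marginals by construction). With 50-kb analysis bins
the largest in-domain separations are diluted by partial bin overlap at
domain edges — boundaries do not sit on the 50-kb grid, exactly as in real
data — so a planted twofold enrichment reads as roughly 1.9.

## Hi-C-assisted karyotyping and scaffolding

Under a rod-length cutoff, a chromosome is a *contact chain*: scaffolds
interact strongly only with neighbours within the cutoff, and chimeric
(misjoined) scaffolds are strong *bridges* between two chains. Both
properties defeat any single clustering recipe, so the stage is iterative
(`karyotype_pipeline()`):

1. **Tree pass.** Scaffold similarity is the mean balanced trans contact
   per bin pair (length-free). An average-linkage dendrogram provides
   candidate partitions; each is refined by reassigning every scaffold to
   its maximal-affinity cluster, and `k` is chosen by weighted-graph
   modularity. Merge-height gaps are *not* used for `k`: with chain
   topology the within-chromosome merge heights spread almost up to the
   trans level and the gap criterion is uninformative.
2. **Misjoin splitting** (`split_misjoins()`) combines two detectors: runs
   of per-bin cluster affinity (absorbing runs shorter than
   `persistence = 3` bins, so a junction in a terminal bin yields no cut),
   and a cluster-free scan for internal contact discontinuities — a
   chimeric junction joins genomically unlinked flanks, so the mean
   contact across it sits two orders of magnitude below the scaffold
   median. The discontinuity detector is essential for chimeras whose two
   chromosomes were confounded into a single cluster, where affinity runs
   are blind by construction. Affinity cuts must themselves sit at a
   discontinuity (min within ±3 bins below 0.3× the median), which
   rejects noise runs; cut positions are refined to the bin boundary with
   maximal affinity contrast. Measured on the synthetic family, junction
   dips are ≤ 0.20× the median while genuine interior positions stay
   ≥ 0.34×; the thresholds (0.25/0.3) sit inside that two-sided margin
   and are parameters.
3. **Component pass.** After two split/re-cluster rounds, subscaffolds are
   clustered as connected components of the strong-link graph: pairs whose
   mean contact exceeds `link_factor = 50` times the median pairwise level
   (the trans background; adjacency links sit 100–1000× above it).
   Member contacts for this graph are computed on edge-trimmed bins
   (2-bin trim), because a residual sub-persistence misjoin stub lives in
   a member's outermost bins and can fake a cross-chromosome link.

Scaffolds whose second-best cluster affinity exceeds `ambiguity_ratio =
0.35` times the best are set aside (the high-copy, multi-chromosome
interactors of real assemblies end up here; `assign_high_copy()` then
places each such cluster on its maximal-contact chromosome, and
`copy_number()` estimates relative copy number as the median coverage
ratio against placed sequence). `order_orient()` chains subscaffolds
greedily by strongest contact, refines with 2-opt on an
adjacency-weighted log-contact score, and orients each member by the
contact asymmetry of its two halves toward its neighbours; confidence is
the normalised margin $|a-b|/(a+b)$. Whole-chromosome reversal is
unresolvable from Hi-C and treated as an equivalence class.

## Gene architecture

`find_blocks()` run-length encodes gene strands; genes sharing a start are
pre-sorted by end then id so the encoding is deterministic.
`orientation_change_stats()` counts strand changes in sliding 10-gene
windows against the exact Binomial$(9, 1/2)$ null of independent
orientation. `call_sites()` classifies each adjacent block pair as
convergent (`+` then `-`) or divergent (`-` then `+`), placing the site at
the midpoint of the inter-block interval (midpoint of the overlap,
flagged, if the blocks overlap). When stranded expression is supplied, a
block qualifies only if at least half its span carries coverage of at
least `min_expr` on its own strand — a reproducible proxy for the manual
curation of expressed blocks in the source study, and a config field.

Track machinery (GC in 10-kb windows with >50 %-N masking, interval-count
densities, `feature_profile()` with orientation-aware strand swapping,
`telomere_profile()` mirroring both chromosome ends, Pearson
`track_correlations()` at 100-kb windows) uses run-length-encoded coverage
and windowed view means throughout. "100-bp sliding windows" is
implemented as a non-overlapping 100-bp tiling (window = step), both
exposed.

## Aggregate maps

`expected_by_distance()` computes per-chromosome (or pooled) per-diagonal
means of balanced contacts, smoothed by a 3-bin running mean in log space;
`pileup()` averages observed/expected submatrices across sites,
orientation-aligned, dropping sites whose flank leaves the chromosome.
Cells average obs/exp **linearly** across sites and the map reports
$\log_{10}$ of that mean: at realistic depth most single-site 10-kb cells
are empty, so a mean of per-site logs is dominated by the zero floor
(`1e-4`); the per-site log mean is kept as a secondary field. Because the
expected model is fitted on the same map, it absorbs the genome-average
cross-boundary attenuation; the statistic that recovers the per-crossing
attenuation is therefore the separation-matched cross/within ratio
(`pileup_boundary_depletion()`), which equals the planted $\beta$ exactly.
`compare_conditions()` returns the elementwise $\log_2$ ratio of two
linear-scale pileups.

## The synthetic generator

`synthetic_spec()` fixes the study conditions; every generator is fully
deterministic given the seed. The scaled-down default ("desk") profile is
8 chromosomes / 40 Mb, decay exponent $\alpha = -0.4$, rod cutoff
$d_{\max} = 1$ Mb (scaled from ~3 Mb in proportion to the genome),
cross-boundary attenuation $\beta = 0.5$, twofold terminal compaction
$\tau = 2$, 5 % trans contacts, 2 % divergent-site stripe pairs and
$10^6$ pairs — it runs end-to-end in well under five minutes on one CPU.
Test and acceptance runs state their sizes in code.

Design points worth knowing:

* **Gene layout.** Blocks alternate strand with geometric gene counts
  (mean 9). A block additionally occupies at least `min_block_span`
  (250 kb scaled): gene counts keep the geometric law, but two convergent
  junctions are never planted closer than the method's own resolution —
  visible domains in this system are several hundred kb to Mb, and twin
  boundaries 100 kb apart would be unresolvable by any insulation caller
  with a ±100-kb delta span.
* **Terminal domains** are single blocks spanning exactly
  `terminal_span = 500` kb, so the outermost junctions are convergent
  boundaries and the $\tau$ enrichment applies to precisely the pairs
  inside them. With `terminal_span` equal to the insulation window, the
  terminal-boundary neighbourhood falls in the undefined edge zone;
  recovery scoring (`score_boundary_calls()`) therefore restricts to
  planted boundaries whose delta context is defined — no caller can
  assess the others, just as published analyses exclude chromosomes too
  short for insulation.
* **Distance sampling** uses inverse-CDF draws from the truncated power
  law with a hard tail suppression of 0.01 beyond $d_{\max}$ (regime III
  is dropped, not zero), a bounded-rejection step for $\beta$, $\tau$ and
  an $(L-s)/L$ edge factor so the per-possible-pair estimator recovers
  $\alpha$ without chromosome-edge bias.
* **Stripes** at divergent sites are anchored within a `stripe_width` =
  50-kb window and reach partners at *uniform* distances up to the
  cutoff. Both choices are forced by realism: a single-bin anchor doubles
  one bin's marginal and is masked by the balancing MAD filter, and a
  stripe with the background's own decay profile is a pure row bias that
  iterative correction removes exactly.
* **Treatment.** `apply_treatment()` sets $\beta = 1$ and removes
  stripes, nothing else — the transcription-blocked condition.
* **Fragmentation.** `fragment_assembly()` cuts chromosomes into
  ~`target_n50` pieces (minimum ~0.35× so no unplaceable slivers arise),
  randomly orients each, and concatenates a `misjoin_rate` fraction into
  cross-chromosome chimeras, recording every junction.

What the generator does **not** emulate: sequence-level realism (codon
structure, real repeat sequences), restriction-fragment geometry and
ligation artefacts (regime I), coverage biases (so balancing is close to
a no-op on synthetic maps and genuinely biased real data is exercised
only through the algebra of the weights), condensin/cohesin loop point
anchors, and cell-cycle heterogeneity. Passing the synthetic suite
therefore demonstrates the correctness of the measurement machinery and
the recoverability of planted signals at realistic depth — not that real
data are this clean.

## Problem sizes and runtime

The default test suite and the acceptance script use the desk profile
(40-Mb genomes at $10^6$ pairs; two to five generator replicates per
check; a gene-dense 60-Mb layout with ~20,000 genes for block
statistics). The full suite runs in a few minutes on one CPU, the
acceptance script in about a minute.

## Known limitations

* Boundary strength follows one published variant of the delta-extremum
  definition; other insulation tools differ in detail, and exact
  reproduction of curated boundary counts from real data also required
  manual inspection, which is out of scope.
* The karyotype stage assumes trans noise well below adjacency signal
  (two orders of magnitude in the synthetic family); very shallow maps
  would need larger coarse bins.
* `copy_number()` uses coverage medians only; it does not model
  mappability or GC bias in coverage.
* The CLI (`exec/dinochrom`) is a thin wrapper over the same functions;
  the R API is the primary interface.
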
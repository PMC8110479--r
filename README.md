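# dinochrom

Chromosome-scale Hi-C analysis for genomes with rod-like, permanently
condensed chromosomes — the situation found in dinoflagellates such as the
coral endosymbiont *Symbiodinium microadriaticum*. These genomes break most
assumptions behind standard Hi-C toolchains: contact probability decays
only as $P(s) \sim s^{-0.4}$ out to a rod-length cutoff of a few megabases
and then collapses; there are no A/B compartments and no point loops; each
chromosome folds as a linear series of domains whose boundaries sit where
blocks of co-oriented genes converge, and which disappear when
transcription is blocked.

`dinochrom` is an R package for researchers studying such genomes (or
building simulations of them). It provides:

* **genome/matrix I/O** — FASTA, GFF3, BED, bedGraph, pairs, and a
  plain-text triplet format for binned matrices; genome binning and
  iterative-correction (ICE) balancing;
* **insulation analysis** — insulation score (window $W$ = 500 kb at
  10-kb bins), delta-vector boundary calling with a strength ≥ 0.2
  threshold, ±2-bin refinement, and an N-gap contiguity filter
  (< 24 consecutive Ns in the 30-kb boundary neighbourhood);
* **contact scaling** — genome-wide $P(s)$ per possible locus pair,
  piecewise log–log regime segmentation, per-domain-square curves,
  inter-domain gap-shift estimation, terminal-vs-internal domain
  compaction;
* **Hi-C-assisted assembly** — karyotyping (clustering scaffolds into
  chromosomes), misjoin splitting at contact discontinuities, ordering
  and orienting subscaffolds, high-copy cluster placement, coverage-based
  copy number;
* **gene architecture** — co-oriented gene blocks, orientation-change
  statistics against the binomial null, convergent/divergent site
  calling, GC/density/expression tracks with feature-centred and
  telomere-centred profiles;
* **aggregate maps** — distance-decay expected models,
  observed/expected pileups around boundaries and sites, condition
  comparison (e.g. transcription-blocked vs control);
* **a synthetic-data generator** that plants all of the above as ground
  truth (power-law decay with rod cutoff, boundary attenuation $\beta$,
  telomeric compaction $\tau$, alternating gene blocks, GC gradients,
  stripes, misjoined scaffolds, a treatment switch), fully deterministic
  under a seed.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and result types have `autoplot()` methods.

## Worked example

Simulate the scaled-down default profile (8 chromosomes / 40 Mb, 1 Mb rod
cutoff, $\beta = 0.5$, $\tau = 2$, $10^6$ pairs), then run the boundary and
scaling analyses against the planted truth:

```r
library(dinochrom)
spec <- synthetic_spec(seed = 1)           # desk profile: 8 chromosomes / 40 Mb
genome <- generate_genome(spec)
pairs  <- generate_contacts(genome)

cm   <- ice_balance(pairs_to_matrix(pairs, bin_genome(genome$assembly, 1e4)))
prof <- insulation_score(cm)
bounds <- refine_boundaries(call_boundaries(prof), prof)
cat("called boundaries:", nrow(bounds), "| planted:", nrow(genome$truth$boundaries), "\n")

sc <- score_boundary_calls(bounds, genome$truth$boundaries, 1e4, profile = prof)
cat(sprintf("recall %.2f, precision %.2f over %d assessable boundaries\n",
            sc$recall, sc$precision, sc$n_truth))

curve <- ps_from_pairs(pairs, genome$assembly)
fit <- fit_exponent(curve, fit_range = c(5e4, 5e5))
cat(sprintf("P(s) regime-II exponent: %.2f (se %.3f)\n", fit$exponent, fit$se))

tb <- genome$truth$boundaries
tvi <- terminal_vs_internal(pairs_to_matrix(pairs, bin_genome(genome$assembly, 5e4)),
                            tibble::tibble(chrom = tb$chrom, start = tb$pos),
                            s_max = spec$d_max / 3)
cat(sprintf("terminal/internal contact ratio: %.2f\n", tvi$ratio))
```

Output:

```
called boundaries: 28 | planted: 44
recall 1.00, precision 1.00 over 28 assessable boundaries
P(s) regime-II exponent: -0.58 (se 0.014)
terminal/internal contact ratio: 1.91
```

What the numbers mean: 28 of the 44 planted boundaries lie far enough from
chromosome ends for the insulation delta to be defined (the terminal-domain
junctions sit at the edge of the defined region by construction); all 28
are recovered within ±1 bin with no false calls. The *genome-wide* $P(s)$
exponent (−0.58) is steeper than the generating within-domain exponent
(−0.4) because cross-boundary attenuation thins long-range pairs — the same
direction of difference real maps show between genome-wide and
within-domain fits. Repeating on a $\beta = 1$ map returns −0.40. The
terminal domains are about twofold compacted, read as ~1.9 at 50-kb bins
because domain edges do not sit on the bin grid.

The full pipeline can also be driven from one YAML config
(`run_pipeline("config.yaml")`, profiles under `inst/profiles/`) or from
the thin CLI in `exec/dinochrom`
(`dinochrom simulate | insulation | scaling | run`).

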
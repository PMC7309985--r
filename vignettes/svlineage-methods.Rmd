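---
title: "Consensus SV calling and phylogenetic gain/loss analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus SV calling and phylogenetic gain/loss analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svlineage)
```

# The analysis model

`svlineage` treats a structural variant (SV) as a derived state relative
to a common reference genome: several species of a radiation are mapped
to one outgroup-like reference, per-species calls from multiple read-pair
callers are reduced to a consensus, merged across species, and each
resulting presence/absence pattern is interpreted on a dated, rooted
phylogeny. The package's assumptions, in decreasing order of importance:

* **Single origin (Dollo).** An SV allele arises once; absence in a
  descendant of the gain branch is a loss. This is the natural model for
  large rearrangements, whose recurrent origin at base-pair-identical
  breakpoints is unlikely.
* **Root state is absence.** Because the SV is defined against the
  reference, presence is derived. For events present in *all* analyzed
  species the polarity is genuinely ambiguous (the change may have
  happened on the reference lineage); such gains sit on the root/stem
  branch and are flagged (`root_polarity_flag`) rather than suppressed.
* **Caller errors are interval noise.** Callers miss events
  (sensitivity), perturb breakpoints (jitter), and emit spurious calls;
  two-caller agreement at high reciprocal overlap is the error filter.

# Coordinates and containers

All intervals are 0-based half-open (BED convention); VCF, Breakdancer
and RepeatMasker inputs are 1-based inclusive and converted exactly once,
on read. Records and consensus events are plain data frames with
documented columns, so every intermediate is directly inspectable and
serializable to TSV/BED.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_libraries`, `min_read_pairs` | 2, 5 | count | library- and read-pair support floors for Breakdancer/Pindel calls |
| `breakdancer_min_score` | 99 | score | Breakdancer's maximum confidence; `>= 99` is an equality in practice |
| `min_deletion_size` | 1000 | nt | read-pair pipelines over-call sub-kb deletions; floor is boundary-inclusive |
| `within_tool_threshold`, `cross_tool_threshold` | 0.90 | fraction | reciprocal-overlap identity for redundant/confirmed calls |
| `ins_window`, `tra_window` | 100, 1000 | nt | breakpoint-window matching where reciprocal overlap is undefined |
| size bands | 50/80/90/95% at 0.5 kb, 1 kb, 10 kb | fraction | breakpoint noise is relatively larger for small events; bands are bottom-inclusive |
| `elim_cutoff`, `node_size` | 0.01, 5 | p, genes | elim elimination threshold; minimum annotation for a testable GO term |
| `n_samples` | 10,000 | draws | permutation count; sets the empirical p floor at 1e-04 |
| divergence bin width | 5 | % | repeat landscape resolution |

The deletion floor is applied after per-species consensus building and
before cross-species merging (configurable, `del_floor_stage`): the
consensus step benefits from all calls, while cross-species comparisons
should not be driven by events the analysis will discard.

# Design choices where the design was open

* **Cluster representative.** A merged cluster is represented by the
  member with the highest read-pair support (ties: leftmost start, then
  smallest end, then record id). Support-weighted choice favors the
  best-evidenced breakpoints; all tie-breaks are total, so merging is
  deterministic and invariant to input order.
* **Single-linkage transitivity.** "Merge calls with ≥ 90% reciprocal
  overlap" is implemented as single-linkage clustering, matching what
  iterated pairwise `bedtools`-style merging converges to. A chain
  A~B~C merges into one event even when A and C fall below the
  threshold; the brute-force equivalence tests cover exactly this case.
* **Greedy one-to-one two-tool matching.** Candidate cross-caller pairs
  are consumed in decreasing overlap order, each record participating at
  most once. One-to-many intersections therefore resolve toward the best
  partner.
* **Cross-band pairs use the stricter threshold.** When two events fall
  in different size bands, the larger event's stricter threshold governs
  — the conservative reading that avoids spurious multi-species events.
* **Union deduplication.** The three pairwise two-tool sets are unioned
  and deduplicated by one more single-linkage pass at the cross-tool
  threshold, merging caller provenance.
* **elim reporting.** `annotated`/`significant`/`expected` are classic
  (propagated) counts while `p_elim` uses the current, possibly reduced
  gene sets — the same reporting convention as the reference
  implementation of the elim algorithm. With `elim_cutoff = 0` the
  procedure reduces exactly to classic one-sided Fisher tests. Term
  processing order is greatest depth first (longest path to the root),
  ties lexicographic, for determinism.
* **Liftover endpoint rule.** An interval maps iff both its first and
  last base are covered by blocks of one chain. Fraction-based rescue
  (minMatch-style) is deliberately not emulated; unmapped inversions and
  duplications are expected and reported as such.
* **Mann–Whitney tests** use `stats::wilcox.test` (exact for small
  samples without ties, normal approximation with tie correction
  otherwise); fully tied comparisons report p = 1 by construction. The
  direction label compares the U statistic to its null mean.

# The permutation null

Segments are relocated independently and uniformly among all valid start
positions in the workspace (an interval is chosen with probability
proportional to the number of starts it offers). Two consequences:

* Relocated segments may overlap one another (full GAT forbids
  self-overlap). The null statistic is the *sum of per-segment overlaps*
  with the annotation; the observed statistic is the union overlap. For
  disjoint observed segments — consensus SV intervals are disjoint by
  construction — the two coincide, and at the simulated segment
  densities the self-collision inflation of the null mean is well below
  the Monte-Carlo error.
* The worked calibration case is exact: a 10 nt segment on a 100 nt
  workspace against a 50 nt annotation has 91 equally likely placements
  and a closed-form null mean of 455/91 = 5.0, which the sampler must hit
  within Monte-Carlo tolerance.

Empirical p-values are one-sided in the observed direction with floor
`1/n_samples`; `p_enriched`/`p_depleted` are also returned, because only
a fixed-direction p-value is uniform under the null (the
direction-selected p is supported on roughly (0, 0.5] by construction,
which matters when checking calibration).

# What the synthetic generator emulates — and what it does not

The generator produces every input the pipeline consumes, with known
truth: gains as Poisson counts per branch (events/MY per class),
whole-event losses as Poisson state flips on descendant branches,
log-normal event sizes per class, per-caller sensitivity/jitter/false
positives with support metadata that passes the default filters for true
calls, repeat annotations with one class planted at a chosen density
fold inside true inversions, uniformly placed genes, a three-level GO
DAG with one term planted on inversion-contained genes, and per-species
alignment blocks that tile the reference excluding that species' true
deletions (so truth deletions are 0% discordant and non-deleted
intervals are fully spanned).

Default conditions: the four-species radiation tree
`(((Mzebra:5,Pnyererei:5):2.5,Hburtoni:7.5):4.5,Nbrichardi:12):6;`
(divergence times in MY are standard East African cichlid estimates; the
6 MY stem lets shared-by-all events arise), gain rates
DEL 22, DUP 8, INV 9, INS 6, TRA 3 events/MY (~2,000 events in total),
loss rate 0.01/MY, deletion sizes log-normal(meanlog 8.3, sdlog 1.0)
truncated at 1 kb — which puts roughly one in five deletions above
10 kb, the size spectrum read-pair pipelines retain after sub-kb
filtering — and DUP/INV sizes log-normal(8.6, 1.1) with a 300 nt floor.
The genome is 5 contigs of 10 Mb: large enough that ~2,000
non-overlapping events and their flanks are placed without crowding,
small enough that the full suite runs in minutes on one CPU (the same
problem size is used by the acceptance checks).

Three deliberate idealizations, which bound what passing tests show
about real data:

* **Truth events never overlap within a class**, so recovery can be
  scored by identity matching. Real genomes nest and stack SVs.
* **Losses are whole-event flips.** Partial reversions or secondary
  rearrangements inside an SV are not modeled.
* **The recorded truth is the Dollo-minimal representation** of each
  event's surviving presence pattern. If, say, both children of a clade
  lose an event independently, leaf data cannot distinguish two losses
  from one clade-level loss — only the minimal scenario is identifiable,
  so that is what the generator records and what recovery is scored
  against. Events lost everywhere are dropped as unobservable.
* **Planted enrichment is defined on the fold-change scale**: the
  boosted repeat class is placed so that its density inside true
  inversions is `repeat_boost_factor` times the genome-wide average —
  the quantity the permutation test estimates. An inside/outside density
  *ratio* of B would instead be recovered as the smaller fold
  B/(1+(B−1)f), deflated by the inversion space fraction f; defining the
  plant on the measured scale keeps "plant 3× → recover ≈ 3×" true.

Caller jitter is rounded normal noise on each breakpoint, clamped to the
contig. With jitter sd 50 nt, two callers' versions of the same ≥ 10 kb
event essentially always exceed 90% reciprocal overlap, while sub-1.5 kb
events can fail the two-tool threshold — that is the mechanism behind
the residual per-branch under-recovery (a few percent at the default
conditions), and it mirrors the behavior of real multi-caller pipelines
on small events.

# Numerical and degenerate-input choices

* Reciprocal overlap errors on zero-length intervals (undefined
  fraction); INS/TRA records are 1 nt breakpoints and are matched by
  windows instead.
* Empty inputs flow through: zero SVs produce zero-row tables and a
  successful run; a branch with events but no usable length reports an
  undefined rate (`rate_undefined`) instead of failing.
* A segment longer than every workspace interval is an error naming the
  segment; a segment equal to an interval's length has exactly one
  placement.
* `expected == 0` with positive observed overlap reports infinite fold
  at the p floor; both zero marks the track untestable.
* All randomness is seed-derived; identical seeds give byte-identical
  output files (numbers are formatted with `%.10g` before writing).

# Known limitations

* Genotypes, allele frequencies and within-species polymorphism are out
  of scope; presence/absence is per species.
* The GO reader understands only `is_a`-style child→parent edges;
  weight01/parent-child algorithms are not implemented.
* The liftover is block-exact and intended for validation-scale use, not
  as a general-purpose liftOver replacement.
* The tandem-duplication exon-evidence filter used in gene-level
  analyses of duplications is consumed as a precomputed boolean where
  provided, never computed from alignments.
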
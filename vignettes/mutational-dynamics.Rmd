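---
title: "Mutational dynamics in evolve-and-resequence experiments: models and methods"
author: "evoreseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoreseq)
```

# Scope

`evoreseq` analyses time-resolved whole-genome sequencing of asexually
propagating microbial populations under sustained selection — the kind of
data produced by a multi-year turbidostat evolution experiment in which
populations are sequenced deeply (~500x) at regular intervals and a few
clones (~80x) are isolated at each time point. The package covers the
downstream analysis only: it consumes variant tables, binned read-depth
tracks, competition-assay read-outs and interaction-network edge lists.
Read alignment, variant calling and effect annotation are upstream of the
package and are expected from standard tools.

A Wright-Fisher style simulator of the whole experiment is a first-class
component: every analysis stage is validated against simulations in which
the truth — lineage structure, selection coefficients, planted
copy-number events — is known exactly.

# The simulator

## Evolutionary model

`simulate_evolution()` propagates an asexual population by discrete
Wright-Fisher generations. Each lineage `i` carries the mutations of its
ancestral path; its fitness is `exp(level * S_i)` with `S_i` the summed
selection coefficients on that path and `level` the current value of a
stepwise stress schedule (so raising the stress sharpens all fitness
differentials; the schedule mimics a ramp stepped every 25 generations).
After deterministic selection, the next generation is an exact
multinomial resample of `N * (1 - death_rate)` division events.
Generations count divisions; the optional death rate models the regime
near growth-arresting stress in which part of each generation's offspring
is lost, without attempting a full birth-death model.

New beneficial mutations arise per lineage at rate
`beneficial_rate x lineage count`, with selection coefficients drawn from
an exponential distribution with mean `dfe_mean` — the standard minimal
choice for a beneficial-effects distribution; each mutation founds a new,
perfectly linked lineage (no recombination). The mutation supply is split
between SNPs (72%) and indels, matching the observed spectrum of such
experiments; a mutator event multiplies the class-specific supply of one
lineage and its descendants, and a ploidy event creates a
whole-genome-duplicated lineage with a configurable advantage.

The simulated scale is deliberately reduced. The physical experiment runs
at ~1e10 cells, which neither needs nor permits direct resampling; the
default calibration uses an effective size of 1e5 (2e4 in the bundled
analysis scripts) with `beneficial_rate` chosen so that several
beneficial lineages segregate simultaneously — the clonal-interference
regime the analysis targets. Consequences of the reduced scale: drift is
stronger and the mutation supply smaller than in the experiment, so
simulated mutation counts are in the tens, not thousands. Tests and
calibration checks are designed around properties that survive this
scaling (unbiasedness, logistic growth of selected lineages, cohort
recovery), not around absolute counts.

The sampling distribution of a selected lineage was checked against the
closed-form logistic `f(t) = f0 e^{st} / (1 - f0 + f0 e^{st})`: over 200
replicate simulations the mean trajectory agrees within Monte-Carlo
error (see `test-simulate.R`).

## Observation model

`observe_sequencing()` reports, per sampled generation, binomial draws of
each mutation's allele frequency at Poisson-distributed depth (defaults
500x for populations, 80x for clones). Mutations on a diploid background
are heterozygous and segregate at half their cell frequency, which is
what a variant caller reports; the analysis side can invert this (see
below). Clones are drawn without replacement proportional to lineage
frequency, mimicking picking distinct colonies. Depth tracks are Poisson
read counts per fixed-width bin with mean
`coverage x bin / read_length x copy / ploidy`, with planted CNV events
overriding `copy` on carrier lineages.

What the simulator does **not** emulate: mapping artefacts and repeat
regions (real sub-telomeres are filtered for this reason; simulated
positions are uniform), linkage breakup by rare outcrossing, GC and
mappability bias in depth tracks, batch effects between sequencing runs,
and back-mutation. Passing tests therefore demonstrate correctness of
the algorithms under an idealised noise model, not robustness to every
artefact of real data.

# Variant processing

The filters mirror the final-processing stage of a resequencing
pipeline, in the order they are meant to run:

* `filter_subtelomeric()`: drops variants within 15 kb of either
  chromosome end (1-based inclusive; `pos <= margin` or
  `pos > length - margin`). The margin convention is symmetric because
  the underlying motivation — unreliable calls in repeat-rich ends — is.
* `filter_static_trajectories()`: keeps variants whose frequency range
  across observed time points exceeds 10% — read as an *absolute* range
  with *strict* inequality, the same convention as the
  clonal-interference "drops more than 10%" rule; a relative reading is
  available by scaling the input. Comparisons carry a 1e-9 guard so a
  range of exactly 0.10 is never kept by floating-point accident.
  Missing time points are ignored here (absent, not zero), which avoids
  spurious extinction signals from unsequenced time points.
* `filter_for_haplotyping()`: removes multi-allelic sites, variants with
  mixed zygosity across clones, and variants never reaching 20%
  frequency.
* `adjust_heterozygous_frequencies()`: in a diploid population a
  mutation carried heterozygously by *every* cell shows a 50% allele
  frequency; where clone data confirm heterozygosity in all clones of a
  time point and the population frequency is within ±0.10 of 0.5, the
  cell-level frequency is reported as `min(1, 2f)`. The ±0.10 band is a
  noise allowance: at 500x the binomial standard error at f = 0.5 is
  ~0.022, and the band covers ~4.5 of them.

`classify_mutations()` summarises distinct sites by class (SNP/indel),
context (coding when overlapping an annotated gene interval, via
`GenomicRanges`), and effect labels carried on the input.

# Haplotype cohorts and Muller diagrams

Mutations sweeping together on one genetic background have correlated
frequency trajectories. `cluster_trajectories()` groups them by
agglomerative clustering (`stats::hclust`, complete linkage) on the
Euclidean distance between trajectories, cut at a threshold (default
0.3). Complete linkage is the right linkage for this construct: it
bounds the *maximum* pairwise distance within a cohort, which is the
literal meaning of "these mutations move together". The threshold is not
printed in the source literature of this approach; 0.3 was fixed a
priori as roughly three binomial standard errors at 500x summed over a
nine-point trajectory, and planted-cohort simulations at that depth are
recovered perfectly at this setting. Interior missing time points are
linearly interpolated first (`trajectory_matrix()`), leading gaps are
zero-filled, trailing gaps carry the last value forward.

`clonal_interference_stats()` flags, per mutation, *extinction*
(observed above zero, zero at the final time point) and *decline* (any
later observation more than 10% — strict — below the running maximum);
both are direct signatures of lineages outcompeted after rising.

`build_muller()` infers the nesting forest: cohort B nests in the
earliest-compatible cohort A when A predates B and B's frequency never
exceeds A's by more than `epsilon` while B is present; among eligible
parents the one with the smallest mean excess is chosen (the tightest
containing background). `epsilon` defaults to 0.02 (~2 binomial standard
errors at 500x and f ~ 0.1); analyses running after the heterozygous
adjustment should widen it, since doubling frequencies doubles their
noise. Known limitation: frequency containment cannot distinguish a
nested cohort from a smaller *sibling* on the same background whose
frequency happens to stay below its sibling's; on such configurations
the inferred parent may be one level too deep. The truth-comparison
tests use planted lineage trees where this ambiguity does not arise, and
genuinely ambiguous cases are exactly those a human curator also cannot
resolve from frequencies alone.

# CNV and aneuploidy calling

Depth tracks are aggregated to 500-bp bins; bins with fewer than 10
reads are masked (`bin_and_mask()`). Log2 ratios are taken against the
genome-wide *median* unmasked bin count (`log2_ratio()`), which
represents the copy-neutral state and is robust to focal events; an
assumed ploidy other than 2 rescales the baseline so ratios stay on the
diploid-expectation scale. On that scale a single-copy gain in a diploid
sits at `log2(3/2) = 0.58` and a hemizygous loss at `log2(1/2) = -1` —
the edges of the conventional display bands (0.23–0.58 for gains, −0.23
to −1 for losses), which are tracked separately from the calling limits
(±0.25) because the two serve different purposes (plot annotation vs
calling).

Segmentation (`segment_log2()`) is circular-binary-segmentation style:
the window of bins maximising the two-sample t-statistic of inside
vs outside mean log2 is accepted as a (pair of) breakpoints when its
p-value clears `alpha = 1e-9` and every resulting piece keeps at least 5
bins, then the procedure recurses. Two numerical choices matter:

* the t-statistic uses a **pooled** variance, as in classical CBS — a
  per-window (Welch) variance lets short, accidentally homogeneous
  windows outscore the true event and truncates calls (measured on
  planted 25-bin events: 17/50 recovered with Welch weighting vs 50/50
  with pooled variance, at an unchanged 0/1000 false-positive rate on
  neutral chromosomes);
* the most extreme 5% of bins per chromosome (2.5% per tail) are
  excluded from breakpoint evidence but still receive their segment's
  call; trimmed bins falling between two segments join the side whose
  mean is closer to their own value.

`call_segments()` applies the ±0.25 limits, merges adjacent same-call
segments, and labels display bands. `summarize_recurrence()` reports the
fraction of clones carrying a non-neutral call per bin and flags
whole-chromosome aneuploidy when ≥ 90% of a chromosome's bins share one
call — that threshold is a conservative definition of "whole chromosome"
given edge-bin masking.

# Recurrently mutated genes

Under a uniform null, each of `n` coding mutations hits a gene of coding
length `L` with probability `L/G` (`G` = total coding content of the
genome, 9,080,922 nt for the yeast reference used as the running
example); the hit count is binomial. `gene_hit_pvalue()` returns the
upper tail `P(X >= k)` via the survival function — a point mass is
printable (`point_mass = TRUE`) but is not a test, so the tail is the
default. Agreement with direct summation of binomial point masses is
maintained to 1e-12 relative error over the tested grid (n ≤ 1000,
k ≤ 10); reference values in the test suite were generated once with
exact rational arithmetic. Benjamini–Hochberg adjustment across genes is
applied by default.

`multihit_census()` counts distinct mutated positions per gene
(duplicates at the same nucleotide collapse — they are more likely one
event observed twice than two events) and reports how many genes are
hit exactly m times. `census_significance()` simulates the null census;
its comparison statistic is the number of genes with *at least* m hits,
because the exact-m count is non-monotone in the mutation supply (with
enough mutations, few genes are hit *exactly* twice — they are hit more
often), which would make large observed censuses look spuriously
"significant" in the wrong direction.

# Fitness estimation

`endpoint_selection()` implements the standard log-ratio estimator
`s = (ln(U_f/R_f) - ln(U_i/R_i)) / T` from competition endpoint counts;
relative fitness is reported as `1 + s`. `correct_counts()` applies two
corrections whose exact algebra a methods section rarely prints, so the
package states its own: (i) a fraction `phi` of labeled reference cells
scoring as unlabeled is undone by inflating `R` to `R/(1-phi)` and
removing the same cells from `U`; (ii) a marker cost `s_m` is *added to
s* (not to the counts) — the corrected output flags this convention.

`slope_fitness()` fits the log fluorescence ratio against generations
per replicate series — robustly (IRLS with bisquare weights via
`MASS::rlm`) for ≥ 4 points, ordinary least squares below that —
negates slopes of dye-swapped series, subtracts the parental-vs-parental
control slope, and averages across replicates with a standard error.
`concentration_response()` compares replicate coefficients across
stress concentrations by one-way ANOVA plus Welch contrasts against the
reference condition; its type-I error calibration is itself tested
(0.03–0.07 at nominal 0.05 over 1000 null simulations).

# Probabilistic sub-network inference

To ask whether independently mutated genes converge on shared pathways,
the mutated gene set is connected over a typed interaction graph
(metabolic / protein-protein / protein-DNA; protein-protein edges count
as two directed arcs). `probabilize()` maps each edge (u→v) to a
probability from the percentile rank of out-degree(v) among all edge
terminal nodes: `p = p_min + (p_max - p_min)(1 - rank)`, ties sharing
average ranks, defaults (0.1, 0.9). This penalizes paths through hubs,
forcing explanations through specific rather than promiscuous nodes.

`k_best_paths()` enumerates up to k = 100 loop-free paths of at most 4
edges by depth-first branch-and-bound, pruning partial products below
the 0.01 search cutoff (and below the current k-th best); it matches
exhaustive path enumeration exactly on randomized graphs.

`select_subnetwork()` greedily accepts candidate paths (union of k-best
over all ordered mutated-gene pairs, in decreasing probability) whenever
the path's probability exceeds `cost x (new edges introduced)`. The cost
is the resolution knob: larger costs give smaller, nested networks
(monotonicity is tested), infinite cost an empty one; 0.25 suits pooled
gene lists, ~0.05 small per-population lists, ~0.5 very large
(mutator-derived) lists. The design was genuinely open here: a
log-probability gain (`ln p - c x new`) can never be positive for
p ≤ 1, so the package uses the probability itself as the gain — the
simplest rule that preserves the intended cost behaviour. Greedy
selection is a heuristic; against exhaustive subset search on small
random instances it attains the optimum in ~80% of cases and at least
86% of the optimal objective in the rest (asserted in the tests at a
0.8 floor).

# Problem sizes and reproducibility

All randomized components are seed-deterministic. The bundled analysis
scripts (`analysis/01...07`) run the full pipeline on a simulated
experiment with an effective population of 2e4 over 200 generations and
nine sequencing time points; the acceptance script re-measures estimator
calibration on 100-replicate batches, CNV operating characteristics on
50 planted and 1000 neutral chromosomes of 100–200 bins, and path-search
exactness on 100 random 8-node graphs. These sizes were chosen as the
smallest at which the Monte-Carlo error of each check is comfortably
below its tolerance.
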
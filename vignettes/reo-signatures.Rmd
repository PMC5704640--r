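---
title: "REO consistency and reversal-pair signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{REO consistency and reversal-pair signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reosig)
```

## The model in one paragraph

Amplifying picogram-scale RNA distorts expression magnitudes
multiplicatively and stochastically, and silences lowly expressed genes
outright (dropout). Both distortions act mostly *within* a gene — they
rescale or remove its value — while the *ordering* of two genes inside
one sample only flips when the distortion exceeds their expression gap.
`reosig` therefore treats the within-sample relative expression ordering
(REO) of a gene pair, $G_i > G_j$ or $G_i < G_j$, as the unit of signal,
and everything in the package reduces to counting pairs: how many
orderings a reference set fixes, how many of them a query profile
maintains, and how a panel of class-reversed pairs votes on a sample.
Because REOs depend on expression values only through ranks, every
output is invariant under any strictly increasing per-sample transform —
normalization choices, within reason, stop mattering. That invariance is
asserted directly in the test suite.

## Stable pairs and the consistency score

Two rules define a reference pair set:

* **replicate identity** (`stable_pairs_replicates()`): the pair has the
  identical strict direction in both technical replicates of a sample;
* **cohort frequency** (`stable_pairs_frequency()`): one direction holds
  in more than a fraction `f` of samples (default `f = 0.99`, strict
  `>`); unanimity across a cohort is `f = 1` with `strict = FALSE`.

Ties count against stability in both rules: a tie is evidence that the
pair's ordering is not resolved, so it never contributes a direction.

The consistency of a query profile against a reference set is the score
$k/n$: $n$ reference pairs evaluated, $k$ of them maintaining their
direction strictly in the query. Under the default
`tie_policy = "discordant"` a query tie stays in $n$ and is not counted
in $k$ — the pair failed to maintain its ordering; `"drop"` removes such
pairs from both counts and is provided for sensitivity analysis.

Close-ranked pairs are the fragile ones, so
`exclude_fraction = x` removes the $\lfloor x\,n\rfloor$ pairs with the
smallest mean absolute rank difference across the defining samples
before scoring. Two numerical details make this deterministic: the drop
count is a floor, never a rounding, and ties at the cut are broken by
lexicographic gene-id pair order.

When the reference is every pair of a single tie-free profile, the score
has a closed form: $k/n = (1 + \tau_a)/2$ with $\tau_a$ Kendall's tau-a
between reference and query. The acceptance tests assert this equality
to $10^{-12}$ against `stats::cor`.

### Scaling

A genome-scale reference (say 20,000 genes) implies $2\times10^8$ pairs,
which must never be materialized. `stable_pairs_replicates(...,
materialize = FALSE)` stores only the defining rank profiles; the
compiled scoring kernel then streams over pairs twice — one pass builds
an exact integer histogram of rank-difference keys (average-rank ties
make all ranks multiples of 1/2, so $2m\times$ the mean difference over
$m$ samples is integral), from which the exclusion cutoff and the number
of ties to drop at the cutoff follow; the second pass counts $n$ and $k$
for the retained pairs, visiting pairs in lexicographic order so the
cutoff tie-break matches the materialized path bit for bit. Correctness
of both paths is defined by a naive double-loop oracle at small gene
counts, which the test suite runs on every build.

## Amplification-bias metrics

Fold changes are computed between replicate-averaged low- and high-input
profiles (`replicate_average()` is a plain arithmetic mean). Two
magnitudes are reported per gene: the directional ratio low/high and the
symmetric fold change $\max(\text{low}/\text{high},
\text{high}/\text{low}) \ge 1$. The headline metric — the proportion of
genes with FC ≥ 2 — uses the symmetric value, because distortion in
either direction is distortion; the directional value is retained in the
table for inspection.

Zeros make ratios undefined. The default `zero_policy = "exclude"` drops
the gene from the proportion's numerator and denominator and reports it
in `n_genes_undefined`, inventing no magnitudes; a pseudocount policy
`(low + c)/(high + c)` is available where a defined value for every gene
matters more.

The coefficient of variation of fold changes admits two axes, and the
package had to pick a default where the convention is genuinely open: by
default each gene's directional FC is averaged over all (low replicate ×
high replicate) pairings and the CV (sd/mean, $n-1$ denominator) is
taken **across genes** — one number per condition and level, dominated
by between-gene distortion spread. The alternative
(`axis = "over_replicate_pairs"`, the mean across genes of each gene's
CV over its pairings) isolates within-gene reproducibility instead.
Both are exposed; the summaries log which was used.

## Reversal-pair signatures

Discovery (`find_reversal_pairs()`) keeps pairs stable within each class
— by default unanimously, the right rule for the modest, clean cohorts
signatures are trained on; the frequency rule is available for noisier
ones — with opposite directions between classes. Each pair is scored by
its reversal degree, the geometric mean of the class-wise mean absolute
rank differences (unit: ranks): a pair only scores high if it is well
separated in *both* classes, and the measure is symmetric under class
relabeling.

`select_signature()` walks odd $k = 1, 3, 5, \dots$ over the
degree-sorted candidates, classifies the training cohorts by majority
vote at each $k$, and returns the smallest $k$ attaining the maximal
geometric mean of sensitivity and specificity. The default `k_max` of 25
reflects that degree-sorted candidate lists decay quickly and training
cohorts are small — the selection path is attached (`$k_path`) so the
choice can always be audited, and `k_max` is a plain argument. Odd $k$
prevents full-vote ties; ties can still arise after pairs are dropped at
classification time, which is why a tie yields the `"unclassified"`
label, scored as wrong for the sample's true class. Silent abstention
would inflate performance.

Classification drops a pair for a sample when either gene is absent from
the platform (the matrix rows) or when the two values tie — and two
zeros are a tie: in high-dropout data a 0-vs-0 comparison carries no
ordering information, and letting it vote would fabricate evidence. One
zero against a positive value, by contrast, is a legitimate strict
ordering. `min_evaluated` guards against samples voted on by almost
nothing.

For high-dropout targets the package supports `k = "all"`: with ~90% of
genes zero per cell, any small panel risks being entirely unmeasured, so
the full reversal list votes and robustness comes from numbers.
`filter_signature_rank_diff()` then prunes the union of the bottom
$\lfloor x\,n\rfloor$ pairs by training mean rank difference in *either*
class — a pair close-ranked in even one class votes unreliably there.

## Pseudo-bulk pooling

`make_pooling_plan()` reproduces round-then-remainder sizing: $g$ groups
over $n$ cells give $g-1$ groups of $\mathrm{round}(n/g)$ and a
remainder group — 272 cells in 11 groups is 10×25 + 1×22, 157 cells is
10×14 + 1×17, both verified in the tests. Assignment is a uniform random
permutation partition; cells carry no usable donor annotation in the
motivating data, so patient structure is deliberately ignored.
`pool_sum()` adds member cells per gene, conserving the grand total
exactly. The repeated experiment re-randomizes both classes
independently each repeat, with separate deterministic seed streams
per class derived from the master seed (`derive_seed(seed, stage,
repeat)`), so adding a stage or class never shifts another's stream and
any run is bit-for-bit reproducible.

## What the generator emulates — and what it does not

`simulation_config()` describes three designs:

* **Dilution ladder.** True levels are log-normal
  (`baseline_meanlog = 3`, `baseline_sdlog = 1.5` — a heavy right tail
  typical of expression data). High-input replicates carry small
  multiplicative log-normal noise (`high_input_sigma = 0.05`); each
  dilution level applies larger noise plus expression-dependent dropout,
  with the schedules constrained to be monotone in input mass. The noise
  family is multiplicative log-normal because amplification distortion
  is ratio-scale; the default sigmas (0.65/1.1/1.5/1.9 for
  1000/100/50/25 pg) were set once, from the normal-tail relation
  between sigma and the probability of a two-fold change, so that the
  proportion of genes at symmetric FC ≥ 2 spans roughly 0.1–0.65 across
  the ladder — the regime reported for real dilution series.
* **Two-class cohorts.** Class B equals class A's truth except that each
  planted pair's two gene levels are swapped, guaranteeing opposite
  strict orderings at the configured rank separation (default 50 pairs,
  separation 200 ranks among 2,000 genes). One consequence is worth
  knowing: the swap also reverses every pair formed by a planted gene
  and a gene ranked between the swapped levels, so discovery returns a
  superset of the planted list. Those incidental pairs are genuine
  reversals of the generative model, and their reversal degree
  $\sqrt{d_A d_B}$ with $d_A + d_B$ at most the planted separation is
  strictly below it — at zero noise the planted pairs are exactly the
  top of the degree ordering, and under cohort noise
  (`cohort_sigma = 0.05`, small enough that a 200-rank gap essentially
  never flips within a 20-sample class) they remain at the top up to
  near-ties.
* **Single cells.** Per-cell multiplicative noise plus independent
  per-gene zeroing with probability `min(0.995, c·w)`, where the weight
  `w` falls linearly with expression rank (the simplest monotone model
  of the observation that dropout concentrates in lowly expressed
  genes) and `c` is calibrated by root-finding so the expected per-cell
  zero fraction equals `sc_dropout_target` (default 0.9). A target that
  high under a linear weight forces saturation: the lowest-expressed
  ~four-fifths of genes sit at the 0.995 cap and are effectively
  unmeasurable even after pooling. That truncation is accepted as a
  limitation rather than papered over with a different weight shape.

The generator reproduces the *statistical footprint* of amplified
low-input data, not its mechanism: no sequence-level effects (GC
content, transcript length, 3′ bias), no chemistry differences between
protocols, no batch structure, no correlated dropout between genes, and
cohort noise that is honestly i.i.d. where real tumors are heterogeneous.
Passing tests on this data therefore demonstrate the pipeline's internal
correctness and the qualitative robustness ordering (REOs outlast
magnitudes as input falls), not clinical performance on any real cohort.

```{r ladder, eval = TRUE}
cfg <- simulation_config(n_genes = 300)
hi <- simulate_high_input(cfg, seed = 1)
ref <- stable_pairs_replicates(hi$matrix[, 1], hi$matrix[, 2],
                               materialize = FALSE)
sapply(seq_len(nrow(cfg$dilution_levels)), function(l) {
  lvl <- cfg$dilution_levels[l, ]
  low <- simulate_low_input(hi$truth, lvl$noise_sigma, lvl$dropout_base,
                            seed = 10 + l)
  consistency_score(ref, low[, 1])$score
})
```

## Degenerate inputs and edge rules

* Duplicate gene rows, negative values, and `NA`s are validation errors,
  never silently repaired; genes absent from a platform are absent rows,
  handled by `intersect_genes()` before any pair evaluation.
* `f ≤ 0.5` in a frequency rule is rejected — below a majority the
  direction would be ambiguous.
* An all-tied profile ranks every gene at $(G+1)/2$ and stabilizes no
  pair.
* A sample with fewer measurable signature pairs than `min_evaluated`
  raises an error rather than receiving a near-random label.
* Fold-change CVs require at least two values along the chosen axis and
  a nonzero mean.

## Problem sizes in the shipped tests

The test suite exercises the oracle comparisons at 20–50 genes (where
exhaustive double loops are instant), the tau identity at 200 genes, the
recovery and trend experiments at the default 2,000-gene configuration
with 20 seeds, and the pooling experiment at the full 272 + 157 cells
with 100 repeats — sizes chosen so the whole suite completes in a few
minutes on one core while still covering every code path, including the
streaming kernel, at non-trivial scale.

## Known limitations

* The consistency analysis compares a replicate-derived stable set
  against each low-input replicate singly; comparing stable sets to
  stable sets is possible with the same primitives but is not the
  default reading.
* Probe-to-gene collapsing for bead arrays is out of scope: input
  matrices must arrive pre-collapsed, one row per gene.
* No significance testing is attached to consistency scores, and no
  cross-validation machinery beyond user-supplied train/validation
  splits: the package computes the quantities; experimental design
  stays with the analyst.
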
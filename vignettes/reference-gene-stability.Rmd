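---
title: "Selecting and validating RT-qPCR reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating RT-qPCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Reverse-transcription quantitative PCR measures a transcript's abundance as
the quantification cycle Cq: the PCR cycle at which fluorescence crosses a
threshold. One cycle corresponds to roughly a factor E (the amplification
efficiency, about 2) in template abundance. Because Cq also reflects RNA
input, reverse-transcription yield and other technical factors, genes of
interest (GOIs) are normalized against *reference genes* assumed to be
stably expressed. When a "reference" in fact responds to the treatment, its
biological variation is imprinted — inverted — on every normalized profile.
A reference with `a` cycles of treatment-driven variation used in place of
one with `b` cycles distorts fold changes by `2^(a-b)`; with a 3.22- versus
0.3-cycle pair that is already a `r round(fold_discrepancy(3.22, 0.3), 2)`-fold
error, and a ten-cycle expression gap corresponds to a factor
`r fold_discrepancy(10, 0)`. Candidate references therefore have to be
screened for stability in every tissue and treatment regime.

refstab implements the four screening algorithms most used for this job,
a consensus aggregation of their rankings, and the downstream
normalization-factor quantification, all on a common data model, together
with a synthetic Cq generator with known ground truth so the entire chain
can be validated without any laboratory data.

## Data model

A `cq_dataset()` is a long table of Cq values keyed by gene and sample,
annotated with tissue, condition (e.g. a time point of a salt-stress
course), biological replicate and optionally technical replicate. Present
Cq values must be finite and inside (0, 45) cycles; failed wells are `NA`
and are dropped pairwise downstream. Technical replicates are collapsed by
arithmetic mean (`average_technical_replicates()`) before every analysis
here; the stability algorithms treat each biological sample (condition x
replicate) as one observation. Datasets spanning several tissues are sliced
with `filter_tissue()` — each cohort is analysed separately, and the
command-line layer simply loops over tissues.

Efficiencies are carried as fold amplification per cycle (`2.0` = perfect
doubling, typical standard-curve values 1.9–2.1), not as percentages. A
gene without an entry defaults to 2.0 with a warning. Values outside
[1.6, 2.2] warn but are accepted.

Quantity-based methods work on relative quantities
`q = E^-(Cq - min Cq)` (`to_quantities()`), anchored so each gene's most
abundant sample has q = 1 exactly.

## The four stability algorithms

**Pairwise delta-Ct** (`pairwise_dct()`). For every gene pair, the SD
across samples of the Cq difference; a gene's score (mSD) is the mean of
its pairwise SDs. It uses raw Cq only — no efficiency correction — which
is exactly why it is popular for quick pre-screens. SDs use the n-1
denominator. Ties in mSD are broken lexicographically by gene id and
flagged.

**Model-based decomposition** (`normfinder_stability()`). Log2 quantities
are centered within each sample (removing sample-wide loading effects) and
decomposed per group into an intragroup variance (bias-corrected, clipped
at zero) and an intergroup deviation, shrunk toward zero by an
empirical-Bayes factor; the stability value is the group mean of
`|d| + sqrt(sigma2/n)`. The original tool is a discontinued spreadsheet
applet; this implementation follows the published variance-decomposition
scheme, and rank agreement — not byte agreement with the applet — is the
contract, enforced by simulation tests. The grouping variable defaults to
the biological replicate (three groups of six time points in the default
panel); grouping by condition is a parameter, since with a time-course
design either reading of "group" is defensible.

**geNorm** (`genorm_m()`, `genorm_rank()`). M is the mean SD of log2
expression ratios against all other genes; the gene with the highest M is
excluded and M recomputed until two genes remain, which share rank 1
(their mutual ratio SD cannot separate them). When a full permutation is
needed (for aggregation) the final pair is ordered by its M values in the
full starting set. `pairwise_variation()` gives the V(n/n+1) series —
the SD of log2 ratios of normalization factors built from the top n and
top n+1 genes — and `recommend_count()` applies the standard decision
rule: the smallest n with V < 0.15, floored at three genes; if nothing
falls below the threshold, n+1 genes at the series minimum.

**GrayNorm** (`graynorm_score()`, `graynorm_rank_all()`). Quantities are
calibrated to the control condition (`q = E^(mean control Cq - Cq)`), the
normalization factor NF of a combination is the per-sample geometric mean,
and 1/NF is averaged per condition. A perfect combination has every
condition average at 1.0; the *cumulative deviation* (sum over treated
conditions of `|mean 1/NF - 1|`) is the primary ranking key, with the
coefficient of variation of the condition averages (`cv_inter`, %)
reported alongside. Every combination of the candidates is enumerated
(guarded at 20 genes, ~10^6 sets), and `select_combination()` picks the
best set of at least three genes. Because deviations are measured on the
linear 1/NF scale, up- and down-regulated references of equal cycle
amplitude are not penalized symmetrically — a property inherited from the
method's definition, worth keeping in mind when amplitudes are compared
across signs.

One numerical choice deserves a note: condition averages of 1/NF (and the
per-gene control calibration) use *geometric* means. This makes the
control condition's average exactly 1 by construction and makes the score
invariant to which scale (NF or 1/NF) is averaged; arithmetic averaging
would leave the control systematically above 1 by Jensen's inequality.

## Consensus by Cross-Entropy Monte Carlo

Different algorithms rank differently; `aggregate_ce()` merges k full
rankings into the ordering minimizing the (weighted) sum of Spearman
footrule distances (sum of absolute rank displacements). The optimizer
maintains an item-by-position probability matrix, initially uniform; each
iteration samples N permutations sequentially without replacement
proportional to the matrix, scores them, and updates the matrix toward
the elite fraction's empirical position frequencies, retaining a fraction
`smoothing` of the old matrix: `p <- (1 - w) f + w p`. Defaults are
`N = max(100, 10 G^2)`, elite fraction `rho = 0.1`, `smoothing = 0.25`,
patience 15 iterations, and the best permutation ever sampled is
returned with its exactly recomputable objective and trace. Given a seed
the search is fully reproducible. `aggregate_exhaustive()` enumerates all
permutations (up to 9 items) as the exact reference; on 6-item instances
the CE search recovers the exhaustive optimum in at least 95% of seeded
runs, a property pinned by the test suite.

## Quantification and strategy comparison

`relative_quantity()` computes `RQ = E^(mean control Cq - Cq)`, so
induction (earlier amplification) gives RQ > 1 and the control's geometric
mean RQ is exactly 1. Note the sign convention: defining the exponent as
"stressed minus control" would invert every induction; refstab fixes the
biologically coherent direction and documents it here. `normalize_expression()`
divides by the NF of a chosen reference set and adds the log2 display
transform. `compare_strategies()` evaluates several candidate reference
sets at once: per GOI and condition it reports mean ± SE of log2
expression over biological replicates, and per strategy the mean absolute
log2 deviation from the non-normalized profile — a stable set corrects
technical variation without dragging the profile away from the raw data,
so smaller deviation indicates less reference-carried bias.

## The synthetic generator: what it emulates and what it does not

`simulate_cq()` draws
`Cq = mean_cq + beta * f(condition) + b + e`, with `f` a deterministic
response shape of unit range (flat, monotone ramp, or a pulse that rises
and falls — the pattern of transiently induced genes), `b ~ N(0, sigma_b)`
a biological deviate shared by all genes of one biological sample
(emulating RNA input and RT differences, the variation references exist
to remove), and `e ~ N(0, sigma_t)` independent technical noise per well.
Genes of interest are specified by a true log2 fold-change trajectory,
converted to Cq shifts through their own efficiency, so recovery of the
trajectory after normalization can be checked exactly. Co-regulation is
expressed by giving genes the same shape; a shared deterministic response
is what co-regulation looks like to every method here.

`sim_salt_timecourse()` is the package's reference panel: 10 candidate
references plus 9 GOIs, 3 tissues x 6 time points (0–12 h, time 0 the
control) x 3 biological x 3 technical replicates; baselines span about
19.6–32.4 cycles and reference response amplitudes 0.5–3.3 cycles, the
range reported for real salt-stress panels, with `TUB` (3.3) and `Actin`
(2.5) the designated unstable candidates. Noise defaults are
`sigma_b = 0.2`, `sigma_t = 0.1` cycles — a stated assumption (replicate-level
variance decompositions are rarely published), tunable in the config. All
response amplitudes of the designated-unstable genes are positive (Cq up
under stress) so that the ground-truth ordering by |beta| is also the
ordering GrayNorm's sign-asymmetric deviation induces.

What the generator does **not** model: amplification curves and efficiency
estimation (efficiencies are inputs), inter-run calibration, probe
saturation, heavy-tailed or Cq-dependent noise, and condition-specific
replicate imbalance. Passing the recovery suites therefore shows the
algorithms are implemented correctly and are sensitive at realistic
effect/noise ratios — not that any particular laboratory panel will rank
identically.

## Problem sizes and numerical choices

The validation suites use sizes chosen to exercise every code path while
staying desk-scale: oracle equivalence on 200 random 4-gene x 6-sample
datasets (agreement to 1e-12); CE vs exhaustive on 100 three-list,
six-item instances; recovery on 100 seeded replicates of the default
panel (one tissue per seed, cycling through the three); GOI recovery on
100 replicates of a five-reference design with one contaminant. Degenerate
inputs are handled deterministically: geNorm ties exclude the
lexicographically last gene (recorded in the result), mSD ties are broken
by gene id and flagged, empty probability columns in the CE sampler fall
back to uniform sampling over the remaining items, and variance estimates
clipped at zero are reported as zero rather than negative.

## Limitations

- The model-based decomposition is a faithful implementation of the
  published scheme, not a byte-level port of the retired spreadsheet tool;
  small numeric differences from historical outputs are expected even
  where rankings agree.
- geNorm cannot separate its final pair, and none of the methods can
  distinguish perfect co-regulation from perfect stability; the
  three-gene floor in `recommend_count()` and `select_combination()` is
  the standard mitigation, not a solution.
- GrayNorm's cumulative deviation is asymmetric in response sign (linear
  scale); combinations mixing strongly induced and repressed references
  can score better than either gene alone, which is by design
  (cancellation in the geometric mean) but can surprise.
- All methods assume one cohort; tissues or experiments must be analysed
  separately, as the per-tissue looping in the CLI does.

## A worked run

```{r, eval = FALSE}
sim <- sim_salt_timecourse(seed = 1)
leaf <- average_technical_replicates(filter_tissue(sim$dataset, "leaf"))
refs <- sim$truth$genes$gene[sim$truth$genes$role == "reference"]
leaf_ref <- cq_dataset(leaf[leaf$gene %in% refs, ])

q <- to_quantities(leaf_ref, sim$efficiencies)
rankings <- list(
  dct = ranking_order(pairwise_dct(leaf_ref)),
  normfinder = ranking_order(normfinder_stability(leaf_ref, sim$efficiencies)),
  genorm = ranking_order(genorm_rank(q)),
  graynorm = ranking_order(graynorm_gene_ranking(
    graynorm_rank_all(leaf_ref, sim$efficiencies, "0h", max_size = 1))))
aggregate_ce(rankings, seed = 1)

ranked <- graynorm_rank_all(leaf_ref, sim$efficiencies, "0h")
select_combination(ranked, min_genes = 3)
```

The same chain is available from a shell via the `refstab` script
(`refstab simulate`, `rank`, `aggregate`, `graynorm`, `normalize`), each
subcommand a thin wrapper over the functions above.
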
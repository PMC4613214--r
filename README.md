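# refstab

Reference-gene stability evaluation and normalization for RT-qPCR.

Relative quantification by RT-qPCR stands or falls with the reference
(housekeeping) genes used to normalize it: a "reference" that itself
responds to the treatment imprints its biological variation on every gene
of interest. If one candidate varies by `a` cycles under treatment and
another by `b`, swapping them distorts every normalized fold change by
`2^(a-b)` — a 3.22- vs 0.3-cycle pair already gives a 7.57-fold error.
refstab is for anyone validating candidate references for a new species,
tissue panel or stress regime before quantifying genes of interest.

## What it implements

On a common annotated Cq data model (gene x sample, with tissue,
condition and replicate structure, CSV/TSV I/O):

- **Pairwise ΔCt**: rank genes by the mean SD (mSD) of pairwise Cq
  differences, `mSD_i = mean_j SD_s(Cq_is - Cq_js)`; raw Cq only.
- **Model-based decomposition** (NormFinder-style): on sample-centered
  log2 quantities, per-group intragroup variance (bias-corrected) plus
  shrunken intergroup deviation; stability
  `= mean_k(|d_gk| + sqrt(sigma2_gk / n_k))`; includes the best-pair
  search.
- **geNorm**: `M_j = mean_k SD_s(log2 q_js/q_ks)` with iterative
  exclusion, normalization factors (geometric means), the pairwise
  variation series `V_n/n+1` and the gene-count rule (V < 0.15,
  three-gene floor, minimum-of-V fallback).
- **GrayNorm**: every reference-gene combination scored by how far its
  condition-averaged reciprocal normalization factor 1/NF strays from
  1.0 relative to the control condition (cumulative deviation, with
  cv_inter reported), full 2^G enumeration and minimum-size selection.
- **Consensus**: Cross-Entropy Monte-Carlo minimization of total Spearman
  footrule distance across method rankings, with an exhaustive
  enumerator as exact reference.
- **Quantification**: `RQ = E^(mean control Cq - Cq)`, division by the
  NF of a chosen reference set, log2 display transform,
  `fold_discrepancy()`, and side-by-side comparison of normalization
  strategies.
- **Synthetic data**: a Cq generator with known ground truth (per-gene
  response amplitudes and shapes, shared biological deviates, technical
  noise, true GOI log2 trajectories) plus a preset 10-reference +
  9-GOI, 3-tissue salt time-course panel.

A command-line wrapper (`exec/refstab`) chains the stages:
`simulate`, `summarize`, `rank`, `aggregate`, `graynorm`, `normalize`.

## Worked example

```r
library(refstab)

sim <- sim_salt_timecourse(seed = 1)          # synthetic panel, known truth
leaf <- average_technical_replicates(filter_tissue(sim$dataset, "leaf"))
refs <- sim$truth$genes$gene[sim$truth$genes$role == "reference"]
leaf_ref <- cq_dataset(leaf[leaf$gene %in% refs, ])

pairwise_dct(leaf_ref)$ranking
#> # A tibble: 10 × 5
#>    gene   score  rank tied  method
#>  1 HIS    0.514     1 FALSE dct
#>  2 60S    0.516     2 FALSE dct
#>  3 UBQ    0.558     3 FALSE dct
#>  ...
#>  9 TUB    1.09      9 FALSE dct
#> 10 Actin  1.14     10 FALSE dct
```

The score is the mSD in cycles: HIS's pairwise Cq differences wobble by
~0.51 cycles on average, while TUB and Actin — the panel's designated
salt-responsive candidates — are correctly pushed to the bottom. Running
all four methods and merging them:

```r
q <- to_quantities(leaf_ref, sim$efficiencies)
rankings <- list(
  dct        = ranking_order(pairwise_dct(leaf_ref)),
  normfinder = ranking_order(normfinder_stability(leaf_ref, sim$efficiencies)),
  genorm     = ranking_order(genorm_rank(q)),
  graynorm   = ranking_order(graynorm_gene_ranking(
    graynorm_rank_all(leaf_ref, sim$efficiencies, "0h", max_size = 1))))
aggregate_ce(rankings, seed = 1)
#> <rank_aggregation> CE consensus (objective 36):
#>   HIS > 60S > UBQ > EF1a > eIF-5A > GIIa > RP > GAPDH > TUB > Actin
```

The objective (36) is the summed footrule distance of the consensus to
the four inputs, exactly recomputable from the output. GrayNorm's
combination search recommends a multi-gene normalizer directly:

```r
select_combination(graynorm_rank_all(leaf_ref, sim$efficiencies, "0h"),
                   min_genes = 3)
#> [1] "GAPDH" "HIS"   "RP"    "UBQ"     (cumulative deviation 0.181)
```

and the geNorm V-series agrees that three genes suffice here
(`recommend_count()`: n = 3, rule "minimum-genes floor").

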
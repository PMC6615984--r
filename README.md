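# omicsalign

Detection, classification and correction of sample-labeling errors (swaps
and mislabelings) between paired omics profile matrices, using intrinsic
biological *cis*-associations as a per-sample barcode.

## Why

Multi-omics studies merge expression, methylation, copy-number, miRNA and
protein profiles by annotated sample barcodes. Swapped or mislabeled samples
pass per-platform quality control yet silently corrupt every integrative
analysis. But the two profiles of one individual are tied together by
cis-acting regulation — SNP–transcript, CpG–gene (negative), CNV–gene,
miRNA–host gene, protein–mRNA pairs. Each significant cis pair is one noisy
bit of an intrinsic barcode; a few hundred bits identify a sample regardless
of its label. `omicsalign` is for anyone curating paired omics matrices —
consortium data managers, core facilities, or analysts about to run an
integrative model.

## The method in brief

For Type-A sample *i* and Type-B sample *j*, the similarity is

> S(A_i, B_j) = corr( RT(A_{1..N, i}), RT(B_{1..N, j}) )

the Pearson correlation of normal-rank-transformed values
(RT(x) = Φ⁻¹((rank − ½)/n)) over the N cis feature pairs significant at
BH *q* < 0.05, each oriented by the sign of its association. Two matchers
turn scores into decisions:

- **rank**: self-aligned iff S(A_i, B_i) ranks in the top 5% of its row and
  column (top 20 when > 400 samples); reciprocal best matches among the rest
  are cross-aligned.
- **probability** (default): each pair's score is judged against a
  bivariate-normal model of the cloud (S(A_i, B_m), S(A_m, B_j)) over
  matched pairs *m*, augmented with 1,000 permuted pseudo-profile pairs.
  With Mahalanobis distance r, the p-value of a chance match is
  p = p₀·exp(−r²/2) for annotated pairs (prior p₀ = 1/N_s) and exp(−r²/2)
  otherwise; self/cross decisions take the row- and column-wise unique
  minimum p subject to score floors (mean − 2.576·sd and mean − 1·sd of the
  self-self scores), with a rescue step for p-values ranking in the top 5.

Alignment and cis discovery are iterated until the statuses stabilize.
Verdicts across ≥ 2 data-type pairings are merged into a patient-centric
graph that localizes the platform carrying the error (swap vs single
mislabel) and drives column-level correction.

## Worked example

Simulate a paired dataset with 300 planted cis-associations, 2,000 null
pairs, 100 core samples (+10% unmatched extras per type) and a 4% label
error in Type B, then align:

```r
library(omicsalign)

d <- simulate_dataset(sim_config(n_cis = 300, m = 100, error_rate = 0.04,
                                 seed = 1))
d$injected_errors
#>   sample new_label
#> 1  S0006     S0079
#> 2  S0070     S0006
#> 3  S0079     S0085
#> 4  S0085     S0070

res <- align_profiles(d$mat_a, d$mat_b, d$candidates,
                      config = match_config(seed = 1), verbose = TRUE)
#> iteration 1: 255 significant cis pairs, 96 self, 3 cross
#> iteration 2: 264 significant cis pairs, 96 self, 4 cross
#> iteration 3: 262 significant cis pairs, 96 self, 4 cross
res
#> alignment_result [probability]: 96 self-aligned, 4 cross-aligned,
#> 0 unaligned (converged: TRUE, 3 iterations)

res[res$status == "cross_aligned", ]
#> sample_a sample_b        status     score      p_value iteration
#>    S0006    S0079 cross_aligned 0.4502794 3.505073e-22         3
#>    S0070    S0006 cross_aligned 0.3630724 8.853848e-16         3
#>    S0079    S0085 cross_aligned 0.4457394 9.679762e-21         3
#>    S0085    S0070 cross_aligned 0.4588797 3.401516e-25         3
```

The four planted label moves are recovered exactly — each cross-alignment
maps a Type-A sample to the Type-B column that truly holds its profile, at
p-values of 1e-15 and below — and scoring against the known truth gives

```r
evaluate_alignment(res, d$truth)
#> $sensitivity [1] 1
#> $precision   [1] 1
#> $f_measure   [1] 1
```

On real matrices, start from `read_profile_matrix()`,
`filter_missing_features()`, `normalize_log2_quantile()`, build candidates
with `map_candidates_by_proximity()` (annotation-driven, 1 Mb window or
nearest TSS) or `map_candidates_by_identity()` (explicit miRNA–host /
protein–mRNA maps), and integrate several pairings with
`build_patient_view()` → `infer_error_source()` → `apply_correction()`.
A command-line wrapper with `simulate`, `match`, `evaluate`, `grid` and
`integrate` subcommands lives at `inst/cli/omicsalign.R`.

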
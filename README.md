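# netent

Multivariate entropy of gene expression and protein–protein interaction
(PPI) networks across disease stages.

## The problem

Multi-stage diseases — the motivating case is carcinogenesis (e.g. normal
skin → benign nevi → melanoma in situ → invasive melanoma) — often show a
*sudden* change in the variability structure of gene expression at the
transition from a pre-disease to a disease state, before mean expression
levels give a clear signal. `netent` quantifies that variability with the
differential entropy of a multivariate Gaussian fitted per stage, both
globally and on small PPI neighborhoods, and uses the stage-to-stage
entropy trajectory as a candidate early-warning signal. It is aimed at
computational biologists with a genes × samples expression matrix, a
sample-to-stage assignment, and a PPI edge list.

## The statistic

For log2 expression modeled as an *n*-dimensional Gaussian with covariance
**K**, the differential entropy in bits is

```
h = ½ · log2( (2πe)^n · |K| )
```

Three quantities are tracked per stage *t*:

* **global expression entropy** `h_global(t)` — entropy of the stage's
  matrix over all selected genes (covariance taken with samples as the
  variables and genes as the observations, the orientation that stays
  nonsingular when genes outnumber samples);
* **local-network entropies** `h_i(t)` — one per PPI node *i*, computed on
  the submatrix of the node and its first neighbors (genes as variables);
* **average network entropy** `H(t) = −(1/n) Σ h_i(t)` — the sign-flipped
  mean, positive for the concentrated covariances typical of log2
  expression.

Genes enter the analysis through a **double filter** versus the control
stage: BH-adjusted Welch-t p-value < 0.05 *and* fold change > 1.5.
Local entropies are binned into **entropy groups** — half-open intervals
anchored at 0 and sized from the healthy stage's range — and genes that
change group between stages are reported as **transition genes**.
Stage-versus-control differences in local entropy are tested with the
Wilcoxon rank-sum test (exact for small tie-free samples).

## Worked example

Everything runs offline via the synthetic-study generator, which draws
multi-stage expression with a known covariance and lets you plant an exact
entropy shift at a chosen stage:

```r
library(netent)

study <- plant_transition(
  synthetic_study(n_genes = 30, n_stages = 3, samples_per_stage = 6, seed = 8),
  delta_bits = 3, stage_index = 3)      # +3-bit true shift at stage_2
# give twelve genes a mean shift so the double filter has work to do
for (i in 2:3) {
  m <- study$stages[[i]]
  mu <- m$mu; mu[1:12] <- mu[1:12] + 2
  study$stages[[i]] <- synthetic_stage_model(m$stage_label, mu, m$sigma,
                                             m$observation_model)
}
drawn  <- sample_expression(study)
report <- run_pipeline(drawn$expression, drawn$manifest, study$graph)
report
#> netent report: 10 selected genes, coverage 100.0%
#>     stage  h_global        H
#> 1  normal  9.549869 14.65657
#> 2 stage_1 10.644737 13.33746
#> 3 stage_2 10.763183 12.86107
#> largest global change: normal -> stage_1 (+1.0949 bits)
#> largest network change: normal -> stage_1 (-1.3191 bits)
```

The double filter recovered 10 of the 12 mean-shifted genes (and no
others), all of which mapped onto the interactome (coverage 100%). The
trajectory columns are the two series described above; the "largest
change" lines flag the consecutive stage pair with the biggest jump in
each series. Transition genes for a pair, with their entropies and bins
before and after:

```r
report$transitions[["stage_1 -> stage_2"]]
#>   gene    h_from      h_to bin_from bin_to
#> 1   g3 -4.760333 -2.841249       -2     -1
#> 2   g7 -3.467622 -1.908602       -2     -1
#> 3   g8  6.301157  4.689546        2      1
#> 4   g9  8.419912  9.017584        2      3

report$comparisons$stage_2
#> Wilcoxon rank-sum: W = 53, p = 0.8534 (exact; n = 10 vs 10)
```

`write_report(report, "out/")` serializes everything as JSON + TSV;
`write_synthetic_study(study, "study/")` writes the study itself
(expression, manifest, edge list, ground truth) as plain text.

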
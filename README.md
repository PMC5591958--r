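# empmirnet

Integrative analysis linking circulating **endothelial microparticle
(PECAM+ EMP)** levels to plasma **miRNA expression**. Endothelial damage —
for instance from the disturbed aortic flow of bicuspid aortic valve (BAV)
disease — sheds PECAM+ microparticles into plasma; this package identifies
the circulating miRNAs whose expression tracks those EMP counts, infers
their co-expression network, finds its hubs and its genomic hot-spots
(such as the 14q32 / *DLK1-DIO3* miRNA cluster), and validates candidates
by qPCR. It is aimed at cardiovascular systems-biology analysts working
with summarized miRNA array (or comparable) expression matrices plus a
per-sample microparticle readout.

## The model at the core

After keeping miRNAs detected in ≥ 5% of samples and selecting those with
Spearman *p* < 0.05 against log EMP counts, the co-expression network is a
**Gaussian graphical model**: edges are non-zero partial correlations

&nbsp;&nbsp;ρ<sub>ij</sub> = −ω<sub>ij</sub> / √(ω<sub>ii</sub> ω<sub>jj</sub>),&nbsp;&nbsp; Ω = R<sup>−1</sup>,

computed from the shrinkage correlation estimate
R = (1−λ\*) R<sub>emp</sub> + λ\* I with the analytic intensity
λ\* = Σ V̂ar(r<sub>ij</sub>) / Σ r<sub>ij</sub>². Edge significance comes
from the empirical-Bayes mixture
f(ρ) = η₀ f₀(ρ; κ) + (1−η₀)/2, where
f₀(ρ; κ) ∝ (1−ρ²)<sup>(κ−3)/2</sup> is the null density of a correlation
with κ effective degrees of freedom; an edge is kept when its posterior
probability 1 − fdr(ρ) exceeds 0.95 (local FDR < 5%). Hubs are ranked by
rank-sum over degree, betweenness, stress, closeness and radiality, and
genomic regions are scored with the upper-tail hypergeometric test
P(X ≥ k) for k of n network miRNAs falling in a K-member region out of N
assayed. qPCR validation uses 2^−ΔΔCt with ΔCt = Ct<sub>miRNA</sub> −
Ct<sub>U6</sub>, referenced to the control (TAV) group.

## Worked example

The synthetic generator reproduces the statistical design of a
24-sample discovery cohort (1,205 assayed miRNAs, three valve-morphology
groups) with a planted network, EMP coupling and one enriched genomic
region, plus the ground truth to score recovery:

```r
library(empmirnet)
res <- runPipeline(syntheticConfig(seed = 1), out_dir = "emp_run")
#> simulate: 1205 features x 24 samples (seed 1)
#> filter: 277 of 1205 features expressed (>= 5% of samples)
#> associate: 168 of 277 features with p < 0.05
#> network: lambda* = 0.150, eta0 = 0.998, kappa = 1246.7; 18 nodes, 9 edges
#> topology: top hub miR-SYN-0008
#> enrich: top region 14q32 (p = 0.00522)
#> manifest: 15 artifacts
head(res$enrichment, 3)
#>       region k  K  n    N       p     q
#>        14q32 4 50 18 1205 0.00522 0.104
#>    region-16 2 60 18 1205 0.22464 0.768
#>    region-05 2 61 18 1205 0.23027 0.768
```

Reading the output: 277 of 1,205 miRNAs pass the 5% detection rule; 168
(61%) of them correlate with log EMP at *p* < 0.05; with only 24 samples
the posterior-0.95 rule keeps just the 9 strongest co-expression links
(all true links of the planted network — the selection is calibrated to
be conservative, see the methods vignette), and the planted "14q32"
region already tops the enrichment table (4 of the 18 network miRNAs sit
in the 50-member region; hypergeometric *p* = 0.0052). The EMP group
comparison on the same run gives ANOVA F = 3.68, *p* = 0.043, with the
largest Tukey contrast between dilated-BAV and control (TAV) samples.

At a well-powered cohort size the full planted story is recovered:

```r
res300 <- runPipeline(syntheticConfig(seed = 1, n_samples = 300),
                      out_dir = "emp_run300")
#> network: ... 131 nodes, 77 edges
#> topology: top hub miR-SYN-0001     # the planted hub
#> enrich: top region 14q32 (p = 2.30e-07)
```

Here all 131 network miRNAs and every planted edge are found (false
discovery proportion 0), the planted hub ranks first on all five
centralities, and the enrichment reproduces the canonical
k = 19, n = 131, K = 50, N = 1205 configuration.

A qPCR validation stage (`with_qpcr = TRUE`) simulates an independent
36-sample cohort, computes 2^−ΔΔCt fold changes against U6 and the TAV
group, and correlates them with log EMP (`validateCorrelations()`).

## File formats

Expression matrices are CSV/TSV (features × samples, first column the
feature id) with an optional 0/1 detection-flag file of the same shape;
sample tables are TSV (`sample_id`, `group`, `emp_per_ul`); miRNA loci
are BED, 0-based half-open, with the region label in the (non-standard
but BED-tolerant) seventh column; gene sets are GMT; networks export to
GraphML (with `pcor`, `prob`, `sign` edge attributes) and SIF
(`nodeA pp nodeB`). A thin command-line front end is included at
`inst/scripts/emp-mirnet.R` (`simulate` and `run-all` subcommands).

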
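# pathscore

Pathway-centric analysis of gene-expression data: instead of hunting for
single genes associated with a phenotype, `pathscore` converts a normalized
expression matrix into per-sample **activity** and **consistency** scores
for each pathway in a curated interaction network collection, then ranks
pathways by association with sample class, a continuous response, survival,
or gene-level alterations. It is aimed at analysts working with
microarray-style cohorts (cell-line panels, tumor collections) who want
quantitative, per-sample pathway descriptors that slot directly into
downstream statistics.

## The model

**Up/down normalization.** Each probeset's intensities across samples are
fitted with a two-component gamma mixture

    f(x) = w·Gamma(x; k_d, θ_d) + (1−w)·Gamma(x; k_u, θ_u)

by EM (deterministic initialization, Newton M-step). The posterior
probability of the higher-mean ("up") component replaces every intensity,
putting all probesets on a common [0, 1] scale.

**Interaction metrics.** A pathway is a connected set of interactions,
each with promoter/inhibitor inputs and outputs over molecules (molecules
may be multi-gene complexes). With p(A) the up-probability of molecule A:

    activity     A = Π p(promoter) · Π (1 − p(inhibitor))
    consistency  C = A·P_out + (1−A)·(1−P_out),   P_out = Π p(output)

Activity is the interaction's potential to occur; consistency is the
probability that the observed outputs agree with that potential.
Interaction scores are averaged (unweighted) into pathway scores, one
activity and one consistency value per pathway per sample.

**Association tests.** Wilcoxon rank-sum (binary class; exact for small
samples), Pearson correlation with t-test (continuous), exact 1-D
two-means split + Kaplan–Meier/logrank (survival), and per-sample
hypergeometric enrichment combined by Fisher's omnibus χ² (gene hits),
with Bonferroni (default) or Benjamini–Hochberg adjustment.

## Worked example

```r
library(pathscore)

# a fully ground-truthed synthetic cohort: 6 pathways, 28 samples,
# a continuous response planted on pathway pw01
spec   <- synth_spec(seed = 5, n_pathways = 6)
bundle <- plant_signal(generate_bundle(spec), "correlation")

ud <- updown_normalize(bundle$expr)
ud
#> Up-probability matrix: 448 probesets x 28 samples
#>   degenerate probesets: 0
#>   converged fits:       448

scores <- score_pathways(ud$probs, bundle$nets, bundle$mapping)
scores
#> Pathway scores: 6 pathways x 28 samples
#>   activity    range: 0.00389 - 0.58
#>   consistency range: 0.227 - 0.93
#>   unscoreable entries: 0

res <- run_analysis(scores, bundle$clinical$continuous,
                    test = "correlation")
head(as.data.frame(res), 3)
#>   pathway_id   metric  statistic        p_raw flag   p_adjusted
#> 1       pw01 activity  0.8943096 1.426626e-10 <NA> 1.711951e-09
#> 2       pw02 activity -0.4908944 7.991113e-03 <NA> 9.589335e-02
#> 3       pw03 activity  0.3399345 7.674533e-02 <NA> 9.209440e-01
```

The planted pathway `pw01` tops the ranking: its activity correlates with
the response at r = 0.89 (raw p ≈ 1e−10, Bonferroni-adjusted ≈ 2e−9 across
the 12-hypothesis family), while the best decoy does not survive
adjustment. The same pipeline is available from the shell via the wrapper
in `inst/cli/pathscore` (`simulate`, `normalize`, `score`, `analyze`,
`heatmap`, `draw`).

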
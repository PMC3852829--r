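# tfimpact

Ranks transcription factors (TFs) by their impact on a biological
transition — the motivating case is the epithelial-to-mesenchymal
transition (EMT) in lung adenocarcinoma cells — by integrating ChIP-Seq
binding sites with two-group differential expression. It is aimed at
computational biologists who have per-TF peak calls (narrowPeak/BED) and a
gene-by-sample expression matrix, and want a ranked list of candidate
regulators plus the functional categories their targets act through.

## The statistic

**Regulatory potential.** For gene *g* with TSS *t*, each binding site *i*
whose anchor point (summit, else interval midpoint) lies within a
regulatory distance *D* of *t* contributes a distance-decayed weight:

    S_g = sum_{i=1}^{k} exp(-(0.5 + 4 * delta_i)),   delta_i = |anchor_i - t| / D

so a site at the TSS contributes `exp(-0.5) ≈ 0.61` and a site at the
cutoff `exp(-4.5) ≈ 0.011`. The top-*N* genes by `S_g` (N = 100, 200, 500,
800 by default) form the TF's regulated set M*N*.

**Impact score.** With `n_t` regulated genes of which `n_e` are in the up-
(or down-) regulated DE set, the impact score is `R = n_e / n_t`, and its
significance is the hypergeometric tail

    P(X >= n_e | N, M = n_t, n = |DE set|)

over a universe of *N* genes (annotation ∩ DE-tested genes). The scan
repeats this for every TF, replicate, distance cutoff `D ∈ {1,3,5,10} kb`
and set size, flagging cells with `p < 0.001`.

**Two-stage enrichment.** Categories (GMT) enriched among the top TF's
regulated genes (BH-adjusted hypergeometric, `adj p < 0.05`) are then
cross-tested for enrichment of up/down DE genes *within their regulated
members*; categories passing both stages are called transition-related.

Supporting machinery: strict q-value filtering and cross-cell-line
consensus peaks (span intersection of chained-overlap clusters), a Welch
t-test + Benjamini–Hochberg DE engine (external up/down lists can be
injected instead), and a fully seeded synthetic-data generator with a
planted regulator for end-to-end validation.

## Worked example

```r
library(tfimpact)

cfg   <- simulation_config(seed = 42, n_genes = 500, n_tfs = 4,
                           n_target_genes = 100, background_peaks_per_tf = 800,
                           n_categories = 15)
ann   <- simulate_annotation(cfg)   # 500 genes on one chromosome
peaks <- simulate_peaks(cfg, ann)   # 4 TFs x 2 replicates; TF1 is planted
expr  <- simulate_expression(cfg, ann)

m    <- filter_low_variability(expr, min_sd = 0.1)
de   <- differential_expression(m, alpha = 0.01)
sets <- de_gene_sets(de, alpha = 0.01)
#> 500 genes tested: 64 up, 65 down

res <- scan_impact(peaks, ann, sets$up, sets$down, Ns = c(100L, 200L),
                   Ds = c(1000L, 10000L), tested_genes = de$gene_id)
rk  <- rank_impact(res)
rk[rk$set_size_N == 100 & rk$cutoff_D == 1000, ][1:4, ]
#>   tf_name replicate n_t R_down       p_down significant_down rank
#> 1     TF1      rep1 100   0.64 1.869731e-53             TRUE    1
#> 2     TF1      rep2 100   0.62 1.423619e-48             TRUE    1
#> 3     TF2      rep1  10   0.20 3.810238e-01            FALSE    2
#> 4     TF4      rep1   5   0.20 5.030760e-01            FALSE    3

top_tf(res, 200L)
#>   tf_name mean_R_down  mean_p_down set_size_N
#> 1     TF1   0.4991789 2.561043e-33        200
```

Reading the output: 64% of the planted factor's 100 strongest predicted
targets are significantly down-regulated (`R_down = 0.64`), far beyond the
~13% a random 100-gene set would overlap (hypergeometric
`p ≈ 2e-53`), while background factors sit at chance with few genes
carrying any near-TSS binding at 1 kb (`n_t` 5–10). `top_tf` averages
`R_down` across replicates on the M200 sets and names the planted factor.

The same analysis runs from files via the CLI
(`inst/exec/tfimpact`): `simulate`, `peaks consensus`, `rp`, `de`, `scan`,
`enrich`, and `run-all --config cfg.json`, which writes per-stage TSVs and
a `report.json` naming the top factor and its transition-related
categories.

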
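# darkatlas

Dark diversity estimation from gridded presence/absence atlas data.

**Dark diversity** is the invisible half of a site's species pool: species
that tolerate the site's environment and occur in the surrounding region,
yet are absent. Together with observed richness it yields the *completeness
of site diversity*, `ln(observed / dark)`, a cross-site comparable measure
of how much of the potential flora a site realizes. The package is aimed at
community ecologists and macroecologists working with atlas-style grids
(site × species 0/1 matrices with projected cell coordinates).

It implements, end to end:

* **SCO (species co-occurrence)** — Beals smoothing
  `P_ij = (1/S_i) Σ_{k≠j} N_jk I_ik / N_k`, with per-species inclusion
  thresholds at the 5% quantile of occupied-cell values; a species is dark
  at a site when absent there with `P_ij` strictly above its threshold.
* **SDM (species distribution modelling)** — per-species binomial GAMs on
  environmental variables, repeated 80/20 calibration/evaluation splits,
  binarized at the threshold maximizing the true skill statistic
  (TSS = sensitivity + specificity − 1).
* **Spatial filters** — a geographic radius filter (default 500 km) and a
  dispersion-field filter (cells sharing >50% of the focal cell's species).
* **Combination** — consensus (both methods) and composite (either method)
  dark diversity, per-site sizes and completeness.
* **Method comparison** — overlap coefficient `|A∩B| / min(|A|,|B|)`,
  exact hypergeometric overlap tests with mean/median/%>α summaries, and
  type II (major-axis) regression of ln dark sizes with an F-based slope CI
  tested against the 1:1 line.
* **Synthetic atlas** — a virtual-species generator (Gaussian niches on
  autocorrelated gradients, dispersal-limited ranges) with known
  ground-truth dark diversity for validating the whole pipeline.

See `vignettes/dark-diversity-methods.Rmd` for the model details and every
numerical convention.

## Worked example

```r
library(darkatlas)

cfg <- pipeline_config(seed = 1)          # min_occ 20, 5% quantile, 500 km, 80/20 x5
res <- run_pipeline(cfg, out_dir = "run1")

ncol(res$occ)                             # species surviving the >=20-cell filter
summary(res$summary$dark_sco)             # per-site SCO dark sizes
res$comparison$regression                 # major-axis fit of ln dark sizes
res$comparison$overlap                    # overlap + hypergeometric summaries
```

On the default synthetic scenario (20 × 20 grid of 50-km cells, 4
environmental variables, 80 virtual species, seed 1) this prints:

```
species analyzed: 46 of 80 simulated
mean observed richness: 6.3
mean dark size  SCO: 15.5  SDM: 7.9  consensus: 6.8  composite: 16.6
mean completeness SCO: -0.92
major-axis: slope 1.07 (95% CI 0.99-1.17), R2 0.60, n 377
overlap: median coefficient 0.92, median p 0.0073, %p>0.05 26.2%
```

Reading: the two estimators' per-site dark sizes are strongly associated on
the ln scale (R² = 0.60) with a major axis near the 1:1 line; their species
composition agrees far beyond chance (median overlap coefficient 0.92;
median hypergeometric p ≈ 0.007, i.e. at a typical site the observed
overlap would be that extreme under random draws less than 1% of the time).
Mean completeness is negative because in this sparse synthetic world the
estimated pool of a typical cell exceeds its observed richness.

The same run is available from the shell:

```sh
Rscript inst/exec/darkatlas pipeline --seed 1 --out-dir run1
```

Subcommands `simulate`, `estimate --method {sco,sdm,both}`, `filter`,
`combine`, `compare` operate on CSV files and chain together; every output
carries a `# key=value` metadata header with the full configuration and
seed, and reruns of a seed are byte-identical.

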
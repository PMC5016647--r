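---
title: "Estimating dark diversity from atlas grids: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dark diversity from atlas grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkatlas)
```

## The problem

Observed species richness tells only half of a site's diversity story. The
other half is *dark diversity*: species that could live at a site — they
tolerate its environment and occur in the surrounding region — but happen to
be absent. Quantifying it turns a presence/absence atlas into an estimate of
the site-specific species pool, and the ratio of realized to potential
diversity (*completeness*) into a comparable index across sites.

Dark diversity cannot be observed directly, so it is estimated, and any
estimate depends on the estimator. This package implements the two standard
families and the machinery to compare them on equal footing.

## The two estimators

### Species co-occurrence (SCO)

The Beals smoothing index estimates the probability that species $j$ occurs
at site $i$ from its joint occurrences with the species actually present
there:

$$P_{ij} = \frac{1}{S_i} \sum_{k \neq j} \frac{N_{jk}\, I_{ik}}{N_k}$$

where $S_i$ is the richness of site $i$ excluding $j$, $N_{jk}$ the number
of joint occurrences of $j$ and $k$ over all sites, $N_k$ the number of
occurrences of $k$, and $I_{ik}$ the 0/1 incidence. A species joins dark
diversity at a site when it is **absent** there and $P_{ij}$ **strictly
exceeds** its per-species threshold: the 5% quantile (linear interpolation
between order statistics, position $h = (n-1)q + 1$) of its $P$ values in
cells where it is actually present.

Two conventions are deliberate:

* **Focal-site counts.** The literal formula counts joint occurrences over
  all sites, including the focal one. A leave-one-out variant (removing the
  focal site from $N_k$ and $N_{jk}$ before evaluating there) exists in the
  literature; both are implemented (`include_focal_site`), the literal
  reading is the default.
* **Empty neighborhoods.** At a site where $S_i = 0$ for a focal species,
  the sum has no support; $P$ is set to 0 (keeping such species out of dark
  diversity rather than inventing evidence) and the site is flagged.

### Species distribution modelling (SDM)

Each species gets a binomial additive model with logit link on the
environmental variables (`mgcv::gam`, thin-plate smooths). Conventions:

* **Smoothness budget**: basis dimension $k = 4$ per continuous variable
  with automatic shrinkage (`select = TRUE`, REML). Atlas responses are
  smooth, broad gradients; a lean basis resists overfitting rare species.
* **Splits**: 80% calibration / 20% evaluation, repeated (default 5 random
  splits). On each evaluation set the predicted probabilities are binarized
  at the threshold maximizing the true skill statistic
  ($TSS = \text{sensitivity} + \text{specificity} - 1$), scanning the
  sorted unique predictions plus 0 and 1; ties go to the smallest
  threshold.
* **Aggregation**: per-repeat TSS thresholds are averaged arithmetically
  and a final model refitted on all sites supplies the predictions that are
  binarized — this stabilizes the threshold while spending every
  observation on the final prediction. The source method description does
  not fix this step; the choice is ours and is recorded in output metadata.
* **Membership** uses `>=` (a predicted value equal to the threshold counts
  as suitable): the threshold is itself a predicted value and should remain
  on the suitable side.
* **Fallback**: non-converging or failing smooth fits fall back to logistic
  regression with linear + quadratic terms (flagged per species); species
  failing both routes are excluded and logged rather than silently kept.
* **No ensemble**: one algorithm, deliberately — multi-algorithm ensembles
  drop species that individual methods cannot fit.

## Spatial filters

Environmental suitability is necessary but not sufficient: a dark-diversity
candidate must also be reachable and biogeographically plausible. Two
filters apply to any membership matrix, as a pure conjunction (they only
remove members):

* **Radius filter**: the species must occur within `radius_km` (default
  500 km; center-to-center Euclidean distance on the projected grid,
  boundary inclusive — the round 500 km equals exactly 10 cell widths on a
  50-km grid).
* **Dispersion field**: the species must occur in at least one cell of the
  focal cell's dispersion field — the cells sharing *strictly more* than
  `dispersion_fraction` (default 50%) of the focal cell's species, plus the
  focal cell itself. A focal cell with zero richness has a vacuous
  criterion; its field is just itself, which adds no members.

## Combining and summarizing

*Consensus* dark diversity is the cellwise AND of two methods' memberships,
*composite* the OR; per site they obey
$|\text{consensus}| \le \min(|A|,|B|) \le |\text{composite}| = |A|+|B|-|\text{consensus}|$.
Completeness of site diversity is $\ln(S / D)$ for observed richness $S$
and dark size $D$. When $D = 0$ or $S = 0$ the index is undefined and the
site's value is left missing (empty CSV field) rather than patched with a
pseudo-count that would bias downstream correlations; the count of such
sites is visible in the summary table.

## Comparing methods

* **Overlap coefficient**: $|A \cap B| / \min(|A|, |B|)$ — insensitive to
  the size difference between the two estimates.
* **Hypergeometric overlap test**: with $N$ the number of species absent
  from the site, $x_1, x_2$ the two dark sizes and $o$ the overlap, the
  upper-tail probability $P(X \ge o)$, $X \sim$
  Hypergeometric$(N, x_2, x_1)$, computed exactly with `stats::phyper`.
  The definition of $N$ has two readings. The literal one — every species
  absent from the site — is the default (`overlap_universe =
  "all_absent"`). Restricting $N$ to absent species that pass the spatial
  eligibility filters (`"filtered"`) sounds stricter but is statistically
  weak at small pool sizes: dark sizes approach $N$, the null already
  forces high overlap, and the test loses power regardless of how well the
  methods agree. Both modes are implemented and labelled.
* **Type II (major-axis) regression** of $\ln$ dark sizes over sites where
  both are positive (excluded sites counted and reported): slope
  $b = \frac{s_{yy}-s_{xx}+\sqrt{(s_{yy}-s_{xx})^2+4s_{xy}^2}}{2 s_{xy}}$,
  line through the means, $R^2$ = squared Pearson correlation, and the
  classical one-degree-of-freedom F-based confidence interval for the
  slope (Jolicoeur's method): with covariance eigenvalues
  $\lambda_1 \ge \lambda_2$,
  $H = F_{(1-\alpha);1,n-2}\,/\,[(\lambda_1/\lambda_2 +
  \lambda_2/\lambda_1 - 2)(n-2)]$ and slope limits
  $\tan(\arctan b \pm \arctan\sqrt{H/(1-H)})$; a CI reaching the vertical
  is reported as unbounded. Whether the CI contains 1 is the deviation
  test against the 1:1 line. Major axis (not standardized major axis) is
  the estimator because both variables are on the same ln-count scale.

## The synthetic atlas

Real atlas data are licensed and scattered; validation instead runs on a
generated world whose dark diversity is known by construction.

* **Landscape**: default 20 × 20 grid of 50-km cells (a 1000-km square).
* **Environment**: 4 variables, each a linear south–north gradient
  (amplitude 10 units) plus Gaussian noise with exponential spatial
  covariance (sd 3, range 200 km) — smooth, autocorrelated fields like
  climate surfaces.
* **Species**: 80 virtual species with Gaussian (unimodal) niche responses,
  $p(\text{occur}) = p_{max} \exp(-\sum_v (e_v - \mu_v)^2 / 2\sigma_v^2)$,
  optima uniform over the observed environmental span, breadths 1–3
  per-variable standard deviations, $p_{max}$ uniform in 0.3–0.9. The
  breadth range was fixed once on occupancy realism grounds: with a
  4-variable Gaussian niche, narrower breadths left only ~12/80 species
  above the 20-cell minimum-occurrence filter, which is not an atlas-like
  world; at 1–3 sd roughly half the pool survives the filter with a
  realistic mix of rare and common species.
* **Dispersal limitation**: 40% of species get a finite range (radius
  200–500 km around a random cell) and are sampled only inside it —
  guaranteeing suitable-but-absent cells, i.e. true dark diversity.
* **Sampling**: independent Bernoulli draw per cell; the min-occurrence
  filter (≥ 20 cells) then removes rare species, mirroring real atlas
  practice.
* **Truth**: a cell is *true dark* for a species when the species is
  absent and its suitability is at least half its own $p_{max}$
  (`truth_cutoff = 0.5`). There is no observable truth in real data; this
  cutoff is an evaluation convention, labelled as such. Because whether a
  suitable cell *outside* a species' range should count as true dark
  depends on which filter is being evaluated, both variants are emitted
  (`true_dark`, `true_dark_in_range`) rather than choosing.

What a green test does establish: the estimators recover known suitability
structure (AUC against generator truth), the two methods agree beyond the
hypergeometric null, and the entire pipeline is deterministic given a seed.
What it does not: realism of European floristic composition, species–area
scaling, sampling effort biases, taxonomic noise — none of which the
generator attempts.

## Numerical and degenerate-input conventions

* Thresholds: strict `>` for SCO (per the defining wording "greater
  than"), `>=` for SDM (threshold is a prediction); quantile type 7.
* Beals values are clamped to $[0,1]$ against floating-point fuzz.
* Hypergeometric arguments are validated against
  $\max(0, x_1+x_2-N) \le o \le \min(x_1, x_2)$ with the violated
  inequality named.
* TSS requires both classes in the evaluation set; single-class evaluation
  splits are dropped (a species loses that repeat, not its membership).
* Regression needs $\ge 3$ sites with both dark sizes positive; otherwise
  it is omitted with a warning while overlap statistics still run.
* Every output CSV carries a `# key=value` header echoing the full
  configuration including the seed; no timestamps are written, so a rerun
  of the same seed reproduces outputs byte for byte.

## Known limitations

* Distances are planar Euclidean on projected coordinates; no great-circle
  handling, matching UTM-style atlas grids.
* The boundary effect of a finite study window on dark diversity at edge
  cells is not corrected; the synthetic landscape is self-contained.
* Dark diversity here is binary per method; the two-level
  consensus/composite scheme is as far as the semiquantitative combination
  goes.
* With small species pools (tens of species), per-site hypergeometric
  tests have limited resolution; summaries over sites remain informative.
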
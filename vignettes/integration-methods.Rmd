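---
title: "Gene-centric multi-omics integration with low-rank denoising"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric multi-omics integration with low-rank denoising}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicblocks)
```

## The problem

Whole-genome studies of DNA methylation and gene expression often arrive as a
single gene-centric table: genes in rows, and in columns one expression
variable plus six methylation variables — promoter and gene body, each
quantified in the CG, CHG and CHH cytosine contexts — repeated for every
population or individual. With ten populations that is 70 columns. Two
questions drive the analysis: at the genome scale, how do the methylation
compartments and contexts relate to expression; and at the gene scale, which
genes show a *shared* methylation–expression interplay across all
populations — candidate "master drivers" whose high methylation accompanies
low expression everywhere.

The obstacle is that most of the variance in such a table is either common
to all columns of one omics kind (populations are strongly correlated) or
idiosyncratic to a single gene in a single variable (noise). omicblocks
implements a workflow that separates these: a design-weighted multi-block
partial least squares (PLS) extracts the variation *shared across omics
blocks*, a low-rank "denoising" step discards what the components do not
capture, and an extreme-profile rule then reads candidate drivers off the
standardised, denoised matrix.

## The model

The variables are partitioned into $J = 7$ blocks $X_1, \dots, X_J$ (one
expression block, six methylation blocks), all sharing the gene rows, each
centered and scaled. A symmetric design matrix $C = (c_{jk})$, $c_{jj} = 0$,
weights the block pairs: by default $c_{jk} = 1$ between expression and each
methylation block and $c_{jk} = 0.1$ between methylation blocks, focusing the
fit on methylation–expression interplay while retaining a weak pull between
methylation contexts.

For each component $h = 1, \dots, H$ (default $H = 2$) the fit seeks
unit-norm loading vectors $a_j$ with variates $t_j = X_j a_j$ maximising

$$\sum_{j < k} c_{jk}\, g\!\left(\operatorname{cov}(t_j, t_k)\right),$$

with $g$ the identity under the default `horst` scheme (absolute value:
`centroid`; square: `factorial`). The inner loop is a Gauss–Seidel block
relaxation: each $a_j$ is updated in turn to
$X_j^\top \omega_j / \lVert X_j^\top \omega_j \rVert$ where
$\omega_j = \sum_k c_{jk} s_{jk} t_k$ and $s_{jk}$ is the scheme weight.
Updating blocks sequentially (rather than all at once) makes the objective
monotonically non-decreasing, which the test suite asserts on every fit.
After each component every block is deflated on its own variate,
$X_j \leftarrow X_j - t_j (t_j^\top X_j) / (t_j^\top t_j)$, which makes one
block's variates mutually orthogonal across components.

With two blocks and $c_{12} = 1$ the first component has a closed form: the
leading singular-vector pair of $X_1^\top X_2$. The implementation is checked
against that closed form on randomised instances, and against an independent
multi-block reference implementation, in the tests.

**Denoising.** Each block is split exactly as $X_j = \hat X_j + R_j$ with
$\hat X_j = T_j (T_j^\top T_j)^{-1} T_j^\top X_j$, the orthogonal projection
of the block onto the span of its variates. Because the variates carry the
cross-block covariance the design emphasises, $\hat X_j$ retains variability
shared across omics variables, while $R_j$ collects variability specific to
one gene or one variable. Projection was chosen over a literal
"components times loadings" product because, under own-variate deflation,
the two coincide while projection additionally guarantees the exact
decomposition $X = \hat X + R$ with $R \perp \operatorname{span}(T)$ and
idempotence — both asserted to machine precision in the tests.

**Clustered image map.** The transforms are applied in a fixed order:
denoise, then an optional second column standardisation (`scale2`), then an
optional clamp of all values into $[-2, 2]$ (`cutoff`). The blocks are
concatenated and genes and variables are each clustered with Ward linkage
on Euclidean distances (the `ward.D2` convention, i.e. the modern squared
Ward criterion reported on the distance scale; the merge sequence is
verified against a brute-force Lance–Williams agglomerator). Cutting the
gene dendrogram into $k = 4$ groups recovers gene typologies of
methylation–expression regulation; group labels are assigned by first gene
appearance so they are stable under relabelling.

**Selection.** On the standardised (and, for the denoised set, re-scaled)
matrix, a gene is a master-driver candidate when *every* methylation value
exceeds 1 and *every* expression value is below $-1$, strict inequalities.
The thresholds act on the unclamped values; with the default bounds the
clamp cannot change a $\pm 1$ comparison, so the order is immaterial.
Because the rule quantifies over all values it is undefined under
missingness — selection therefore runs on the complete-case gene set.
Denoised and non-denoised candidate sets are compared as a two-set Venn
partition, and the per-cell effect of denoising is quantified MA-style:
$M = \text{denoised} - \text{non-denoised}$ (the log2 fold change introduced
by denoising, denoised in the numerator), $A$ their mean, flagged when
$|M| > 1$.

## Preprocessing and exploration

Raw values are non-negative (TPM-normalised expression; read-by-density
methylation). Preprocessing applies, in order: a presence filter (a gene
must have at least one non-missing expression *and* one non-missing
methylation value), a per-gene missing-fraction filter (default tolerance
10% of a gene's cells; the threshold is per gene, since filtering genes is
the only reading that yields a gene count), and the transform
$\log_2(1 + x)$ — the pseudo-count 1 maps zeros to zero and treats
TPM $\le 1$ as unexpressed; the same transform is applied uniformly to both
omics layers. Centering and scaling use non-missing cells only, with the
sample ($n-1$) standard deviation.

Exploration offers a Spearman correlation matrix over pairwise-complete
observations with average ranks for ties (the only option compatible with
a matrix that retains genes carrying missing cells), ordered by the angular
order of the eigenvectors: each variable gets the angle
$\operatorname{atan2}(e_{2i}, e_{1i})$ in the plane of the two leading
eigenvectors of the correlation matrix, mapped to $[0, 2\pi)$, and
variables are sorted by ascending angle, ties broken by input index. The
circular order is anchored at the smallest angle; when all off-diagonal
correlations vanish the eigenbasis is arbitrary and the input order is
kept. PCA on data that still contain missing cells uses NIPALS: each
component alternates masked regressions of scores on loadings, skipping
missing cells in every sum, with tolerance $10^{-6}$ on the relative score
change, at most 500 iterations, and the sign fixed so the
largest-magnitude loading is positive. On complete data this reproduces
SVD-based PCA to numerical precision.

## The synthetic generator

`simulate_omics()` emits a matrix with the structure of the motivating data
so every stage is testable without downloads. For gene $g$ of typology $c$,
variable kind $k$ and population $q$:

$$x_{gkq} = \mu_k + \sigma\, \tau_{ck} + s_g +
  \sigma\left(\sqrt{\rho}\, u_{gk} + \sqrt{1-\rho}\, e_{gkq}\right)$$

on the log2-like scale, with baselines $\mu_k$ (4 for expression, 3 for
methylation), noise scale $\sigma$ (default 1), a gene effect $s_g$ shared
across all variables (sd 0.3), a gene-by-kind effect $u_{gk}$ shared across
populations, and population noise $e_{gkq}$; $\rho$ (default 0.9) sets the
inter-population correlation of the noise. The four typology templates
$\tau_{ck}$ encode the canonical gene categories — (1) highly expressed,
lowly methylated; (2) lowly expressed, low CG gene-body methylation,
moderate elsewhere; (3) highly methylated, moderately-low expression;
(4) highly expressed with high CG gene-body methylation — with contrasts of
$\pm 2$ noise-sd for high/low and $0.75$ for moderate. The contrasts are
the generator's calibration contract: they are set so that the four
typologies are recoverable by the pipeline's own $k = 4$ Ward cut
(adjusted Rand index about 0.94 at the defaults, as recomputed by
`scripts/acceptance.R`), clearly separated but far from trivially so: the
per-kind contrasts are comparable to the per-kind noise, so recovery
genuinely relies on pooling information across kinds and populations.

Three deliberate departures from a plain Gaussian factory mimic features
the pipeline must survive. Expression carries a zero-inflation mass: cells
collapse to 0 with probability up to 0.3, increasing as the latent
expression falls, reproducing the bimodal expressed/unexpressed split.
Promoter methylation noise (both $u$ and $e$) is a standardised Student
$t_3$, so a few genes have extreme promoter values even on the log scale.
Missingness (5% of cells overall) is gene-clustered: a random 35% of
non-driver genes carry all missing cells. Uniform per-cell missingness at
5% would leave only $0.95^{70} \approx 2.7\%$ of genes complete, whereas
real aggregated tables lose several variables at once for low-coverage
genes and keep a majority of genes complete — the two-level scheme
reproduces that (about 65% complete genes), which also keeps the
complete-case integration stage meaningful.

Drivers (default 30 of 2000 genes) override their template: every
methylation kind is planted `driver_effect` (default 2.5) *marginal*
standard deviations above the analytic column mean, expression the same
amount below. The marginal-sd unit matters: the selection thresholds act on
column-standardised values, and the column sd includes the typology spread,
so planting in noise-sd units would silently shrink the effect. Drivers
are always complete (the selection rule is undefined otherwise), and the
scoreboard's adjusted Rand index excludes them: their typology label no
longer describes their overwritten profile.

What passing tests on this generator do *not* show: the simulator targets
structure, not realism. It does not reproduce the poplar data's marginal
distributions, gene count, linkage between neighbouring genes, or
population stratification beyond a single correlation parameter, and its
missingness — though gene-clustered — carries no coverage mechanism. Results
on real data additionally depend on upstream normalisation choices the
package deliberately starts after.

## Numerical choices and degenerate inputs

* Multi-block PLS initialises each loading with the block's leading right
  singular vector — deterministic, no seed needed; tolerance $10^{-6}$ on
  the sup-norm loading change, at most 100 inner iterations;
  non-convergence is a recorded warning, not an error. Signs are fixed so
  each loading's largest-magnitude entry is positive, ties to the lowest
  index. A block with all-zero design weights has no inner target and is
  an error, as is any missing value.
* Both PLS modes deflate every block on its own variate; the alternative
  response-block deflation is not offered because only variates and
  loadings feed the downstream steps, where the two conventions agree.
* Zero-variance columns are an error at every scaling step (they admit no
  z-score), constant rows are fine.
* Tree cutting uses the standard cut into $k$ maximal branches;
  `k_groups` beyond the gene count is an error.
* Writing numeric tables uses 17 significant digits, so write/read
  round-trips are bit-exact; "NA" and the empty string are the missing
  tokens, delimiters follow the file extension (no sniffing).

## Problem sizes

The test suite works at deliberately small scale — blocks of tens of genes
for the oracle comparisons, 8-row instances for the exhaustive Ward
agglomerator, a 200×10 rank-2-dominant matrix for NIPALS recovery — and the
end-to-end recovery runs the generator's full default conditions (2000
genes × 70 variables) over ten seeds, which completes in well under a
minute. The same sizes are recomputed from scratch by
`scripts/acceptance.R`.

## A worked run

```{r, eval = FALSE}
sim <- simulate_omics(sim_config(), seed = 1)
res <- run_pipeline(pipeline_config(matrix = sim$matrix, log_input = FALSE,
                                    out_dir = "run1"))
scoreboard(sim$truth, res$selected$denoised,
           res$results$cim_denoised$clusters)
```

## Known limitations

* No sparse variable selection, discriminant variants, cross-validation of
  $H$, or prediction API — the package covers the unsupervised
  description/selection workflow only.
* No imputation and no batch-effect correction; missing values are handled
  by deletion, and batch structure must be addressed upstream.
* Functional enrichment of candidate sets is out of scope (it requires an
  organism background database).
* The integration stage requires complete cases; with heavily and
  uniformly missing data the complete-case set can become small, and the
  per-gene missing-fraction filter should be tightened upstream instead.
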
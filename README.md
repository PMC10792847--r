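# omicblocks

Gene-centric multi-omics block integration with low-rank denoising and
master-driver selection.

## What it is for

Plant epigenomics studies routinely produce a single gene-centric table:
genes in rows and, in columns, one gene-expression variable plus six DNA
methylation variables — promoter and gene body, each in the CG, CHG and CHH
cytosine contexts — repeated for every population (70 columns for ten
populations). omicblocks takes such a matrix (plus a small metadata sidecar
describing each column) and answers two questions:

1. **Genome scale** — how do the methylation compartments/contexts and
   expression co-vary across populations?
2. **Gene scale** — which genes show a methylation–expression interplay
   shared by *all* populations ("master drivers": high methylation with low
   expression everywhere)?

## The method

The variables are split into $J = 7$ blocks $X_1,\dots,X_J$ sharing the
gene rows. A symmetric design matrix $C=(c_{jk})$ weights block pairs —
by default 1 between expression and each methylation block, 0.1 between
methylation blocks, 0 on the diagonal. For each of $H = 2$ components, a
multi-block PLS finds unit-norm loadings $a_j$ with variates
$t_j = X_j a_j$ maximising

$$\sum_{j<k} c_{jk}\, g\!\left(\mathrm{cov}(t_j,t_k)\right),$$

by a monotone Gauss–Seidel relaxation ($g$ = identity under the default
`horst` scheme), deflating each block on its own variate between
components. Each block is then **denoised** by the exact decomposition
$X_j = \hat X_j + R_j$, where
$\hat X_j = T_j (T_j^\top T_j)^{-1} T_j^\top X_j$ projects the block onto
its variate span: $\hat X_j$ keeps variability shared across omics
variables, $R_j$ holds gene- or variable-specific noise. A clustered image
map (Ward linkage on Euclidean distances, genes and variables) cut at
$k = 4$ yields gene typologies, and candidates are genes whose standardised
denoised profile has every methylation value $> 1$ and every expression
value $< -1$. An MA comparison ($M$ = denoised − non-denoised, flag
$|M|>1$) quantifies per variable what denoising changed.

The package also provides the supporting stages: presence and per-gene
missing-fraction filters, the $\log_2(1+x)$ transform,
centering/scaling, a pairwise-complete Spearman correlation matrix with
angular-order-of-the-eigenvectors variable ordering, missing-value-tolerant
NIPALS PCA, and a synthetic data generator that plants gene typologies and
drivers with known ground truth.

## Worked example

```r
library(omicblocks)

sim <- simulate_omics(sim_config(), seed = 1)   # 2000 genes, 10 populations
sim$matrix
#> omics_matrix: 2000 genes x 70 variables (10 expression, 60 methylation), 4.96% missing

res <- run_pipeline(pipeline_config(matrix = sim$matrix, log_input = FALSE,
                                    out_dir = "run1"))
#> input: 2000 genes x 70 variables
#> after min-per-class filter: 2000 genes
#> after missing-fraction filter (<= 0.1): 1447 genes
#> PCA explained variance: 67.4%, 12.6%
#> complete-case set for integration: 1300 genes
#> block PLS converged: TRUE, TRUE (iterations 3, 58)
#> candidates: 28 non-denoised, 28 denoised (28 shared, 0 denoised-only)
#> wrote 25 artifacts to run1

res$selected$denoised
#> gene_set (denoised): 28 genes (methylation > 1, expression < -1)

scoreboard(sim$truth, res$selected$denoised, res$results$cim_denoised$clusters)
#> sensitivity 0.933, false discovery proportion 0, adjusted Rand index 0.928
```

The log lines mirror the workflow: the presence filter keeps genes observed
in both omics layers; the 10% per-gene missing filter trims to 1447 genes;
integration runs on the 1300 complete-case genes. The candidate set is read
off the denoised, re-standardised matrix; against the simulator's ground
truth it recovers 93% of the planted drivers with no false discovery, and
the $k=4$ dendrogram cut recovers the planted gene typologies at ARI 0.93.
`plot_cim(res$results$cim_denoised)` draws the clustered heatmap on the
fixed blue–red $[-2,2]$ scale.

Real data enter through files instead of the generator:

```r
m <- read_omics_matrix("matrix.tsv", "metadata.tsv")
res <- run_pipeline(pipeline_config(matrix_path = "matrix.tsv",
                                    metadata_path = "metadata.tsv",
                                    out_dir = "run2"))
```

where `metadata.tsv` has columns `name`, `omic_type`
(`expression`/`methylation`), `feature` (`promoter`/`gene_body`/`none`),
`context` (`CG`/`CHG`/`CHH`/`none`) and `population`. A command-line
wrapper over the same functions lives at `inst/cli/omicblocks.R`
(subcommands `simulate` and `pipeline`).

See `vignettes/integration-methods.Rmd` for the model, the generator's
design and the numerical conventions.

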
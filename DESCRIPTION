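Package: omicblocks
Title: Gene-Centric Multi-Omics Block Integration with Low-Rank Denoising
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Integrates gene-centric omics matrices (e.g. gene expression
    together with promoter and gene-body DNA methylation in the CG, CHG and
    CHH contexts across populations) through design-matrix-weighted
    multi-block partial least squares. Provides preprocessing (presence and
    missing-fraction filters, log2(1+x) transform, centering/scaling,
    clamping), exploratory statistics (pairwise Spearman correlation with
    angular-order-of-eigenvectors variable ordering, NIPALS principal
    component analysis tolerant of missing values), low-rank denoising of
    the fitted blocks with Ward/Euclidean clustered image maps, extraction
    of master-driver genes with extreme methylation/expression profiles,
    MA-based comparison of denoised versus non-denoised data, and a
    synthetic data generator with planted gene typologies and drivers for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    grDevices,
    mclust,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
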
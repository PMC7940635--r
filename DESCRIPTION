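Package: atacdenoise
Title: Denoising and Base-Pair Resolution Peak Calling for ATAC-seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains dilated residual 1-D convolutional networks that map noisy
    base-pair resolution chromatin-accessibility coverage tracks to a denoised
    coverage track and per-base peak probabilities. Includes Tn5 cut-site
    preprocessing (+4/-5 strand offsets, cut-site extension), Poisson peak
    labeling, genome tiling into padded training windows, a composite
    MSE / Pearson / binary cross-entropy loss, chromosome-based train /
    validation / holdout splits with best-validation checkpointing,
    genome-wide stitched inference, threshold-merge-filter segment calling,
    base-pair resolution evaluation metrics (Pearson, Spearman, MSE, AUPRC,
    AUROC), a background-ensemble z-score caller for differentially
    accessible regions, and a seeded synthetic ATAC-seq read simulator so
    the whole pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
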
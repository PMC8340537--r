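# angleJIVE

Multi-omics studies measure several blocks of data — e.g. DNA methylation,
mRNA and miRNA expression — on the same samples.  Part of the biological
signal is *joint* (shared across platforms, as when methylation regulates
expression) and part is *individual* (specific to one platform).  Analysing
each block separately misses the joint signal; pooling everything obscures
the individual signal.  angleJIVE is for biostatisticians and computational
biologists who want both: it estimates, for $K \ge 2$ feature-by-sample
blocks $X_k$ on a shared sample set, the decomposition

$$X_k = J_k + I_k + \epsilon_k,$$

where the joint components $J_k$ share a common sample-indexed row space
across all blocks, the individual components $I_k$ are block-specific and
orthogonal to it, and $\epsilon_k$ is residual noise — and then uses the
resulting components as predictors of a clinical outcome.

The algorithm is an angle-based joint-and-individual factorization in three
phases: (1) per-block truncated SVD at initial ranks chosen by a two-group
Gaussian profile likelihood on the singular-value scree; (2) SVD of the
stacked row bases — principal-angle analysis — with the joint rank set by
squared singular values exceeding both a resampled Wedin perturbation bound
and a Monte-Carlo random-direction bound; (3) projection onto the joint
basis ($J_k = X_k V_J V_J^\top$) and orthonormal basis subtraction for
$I_k$.  Around the decomposition the package provides assay-specific
preprocessing (M-values, extreme-M and missingness filters for methylation;
counts-per-million filters and log2 for sequencing counts; variance filters;
iterative-SVD imputation; mean-centering), a synthetic multi-block generator
with known ground truth, and a prediction layer that compares the
integrative model against per-block PCA, penalized logistic regression and
covariates-only baselines by stratified cross-validated AUC, plus
random-forest diagnostics (OOB error, Gini importance).

## Worked example

Simulate a three-block blood-omics panel (3000 methylation-like, 1000
mRNA-like, 150 miRNA-like features on 150 samples; joint rank 5, individual
ranks 10/6/6; binary outcome driven by joint and individual scores plus
age/BMI/smoking analogues), decompose it, and compare prediction models:

```r
library(angleJIVE)

cfg  <- syntheticConfig(joint_rank = 5, individual_ranks = c(10, 6, 6),
                        seed = 1)
sim  <- generateBlocks(cfg)
coll <- centerCollection(sim$collection)

rk  <- selectInitialRanks(coll)
fit <- ajive(coll, rk, seed = 1)
fit
#> AjiveResult: 3 blocks, joint rank 5
#>   initial ranks:    15, 11, 11
#>   individual ranks: 11, 7, 7
#>   variance explained (joint / individual / residual):
#>     methylation  0.315 / 0.651 / 0.034
#>     mRNA         0.428 / 0.538 / 0.035
#>     miRNA        0.442 / 0.526 / 0.033

ft <- buildIntegrativeFeatures(fit, covariates(coll), outcome(coll))
cvAUC(ft, "logistic", seed = 1)
#> PredictionReport [logistic]
#>   mean held-out AUC: 0.876 over 10 folds/repeats
#>   in-sample AUC:    0.972
#>   accuracy:         0.913
```

The joint rank 5 is recovered exactly, and the variance split shows the
individual component dominating the methylation-like block — the high
per-block residual structure typical of methylation panels.  The
non-integrative comparator (five principal components per block plus the
same covariates) and the covariates-only baseline score lower on the same
folds:

```r
pca  <- buildPCAFeatures(blocks(coll), covariates(coll), outcome(coll))
covo <- buildCovariateFeatures(covariates(coll), outcome(coll))
meanAUC(cvAUC(pca,  "logistic", seed = 1))   # 0.822
meanAUC(cvAUC(covo, "logistic", seed = 1))   # 0.637

rf <- randomForestEval(ft, n_trees = 1000, seed = 1)
head(rf@importance, 3)
#>   predictor mean_decrease_gini
#> 1    Joint5           8.854865
#> 2    Joint1           6.432514
#> 3    Joint2           5.472161
```

The forest ranks joint components at the top of the Gini-importance list,
i.e. the shared structure carries most of the outcome signal in this
simulation.  `runPipeline()` chains preprocessing, rank selection,
decomposition and all prediction models in one call and writes TSV outputs
plus a JSON reproducibility manifest.

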
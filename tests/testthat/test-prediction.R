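# A small decomposition to build feature tables from.
fitSmall <- function(seed = 55, joint_rank = 2, individual_ranks = c(3, 2, 2),
                     n = 60) {
  cfg <- syntheticConfig(n_samples = n, block_dims = c(200, 120, n),
                         joint_rank = joint_rank,
                         individual_ranks = individual_ranks,
                         block_scales = c(10, 1, 0.1),
                         snr = rep(5, length(individual_ranks)), seed = seed)
  sim <- generateBlocks(cfg)
  coll <- centerCollection(sim$collection)
  fit <- ajive(coll, selectInitialRanks(coll), n_resample = 100,
               n_draws = 100, seed = seed)
  list(fit = fit, coll = coll, sim = sim)
}

test_that("integrative feature tables have the documented column layout", {
  s <- fitSmall()
  ft <- suppressWarnings(buildIntegrativeFeatures(
    s$fit, covariates(s$coll), outcome(s$coll), n_individual = 5))
  rJ <- jointRank(s$fit)
  expIndiv <- sum(pmin(individualRanks(s$fit), 5L))
  expect_equal(ncol(ft@features), rJ + expIndiv + 3L)
  expect_identical(sum(ft@tags == "joint"), as.integer(rJ))
  expect_identical(sum(ft@tags == "covariate"), 3L)
  suppressWarnings(
    expect_warning(buildIntegrativeFeatures(s$fit, covariates(s$coll),
                                            outcome(s$coll),
                                            n_individual = 5),
                   "truncating"))
  # n_individual within every block's rank: no warning, exact counts
  ft2 <- buildIntegrativeFeatures(s$fit, covariates(s$coll),
                                  outcome(s$coll), n_individual = 1)
  expect_equal(ncol(ft2@features),
               rJ + length(individualRanks(s$fit)) + 3L)
  expect_error(buildIntegrativeFeatures(s$fit, covariates(s$coll)[1:10, ],
                                        outcome(s$coll)),
               "alignment")
})

test_that("PCA features equal truncated-SVD scores and count correctly", {
  s <- fitSmall()
  ft <- buildPCAFeatures(blocks(s$coll), covariates(s$coll),
                         outcome(s$coll), n_pcs = 5)
  expect_identical(ncol(ft@features), 3L * 5L + 3L)
  expect_identical(sum(grepl("^pc:", ft@tags)), 15L)
  # oracle: per-block scores = V d from a direct SVD, up to column signs
  X <- blockValues(blocks(s$coll)[[2]])
  sv <- svd(X)
  oracle <- sv$v[, 1:5] %*% diag(sv$d[1:5])
  got <- ft@features[, ft@tags == "pc:mRNA"]
  for (j in 1:5)
    expect_lt(min(max(abs(got[, j] - oracle[, j])),
                  max(abs(got[, j] + oracle[, j]))), 1e-8)
  # a single PC of a rank-1 block carries all its variance
  b1 <- plantedBlock(30, randBasis(20, 1, seed = 110), seed = 111)
  ft1 <- buildPCAFeatures(list(b1), data.frame(z = rnorm(20)),
                          factor(rep(c("a", "b"), 10)), n_pcs = 1)
  pc <- ft1@features[, 1]
  expect_equal(sum(pc^2), sum(blockValues(b1)^2), tolerance = 1e-8)
  expect_error(buildPCAFeatures(list(b1), data.frame(z = rnorm(20)),
                                factor(rep(c("a", "b"), 10)), n_pcs = 20),
               "n_pcs")
})

test_that("rank-based AUC agrees with the all-pairs oracle and pROC", {
  set.seed(120)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    scores <- sample(rnorm(n))
    if (i %% 3 == 0) scores <- round(scores)   # force ties
    y <- runif(n) < plogis(scores)
    if (length(unique(y)) < 2) next
    got <- angleJIVE:::.binaryAUC(scores, factor(y, levels = c(FALSE, TRUE)))
    expect_equal(got, oracleAUC(scores, y), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(121)
  sc <- rnorm(80)
  y <- factor(runif(80) < plogis(sc), levels = c(FALSE, TRUE))
  expect_equal(angleJIVE:::.binaryAUC(sc, y),
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                              direction = "<",
                                              levels = c(FALSE, TRUE)))),
               tolerance = 1e-10)
})

test_that("stratified folds balance classes and are seed-deterministic", {
  y <- factor(rep(c("a", "b"), c(70, 30)))
  f1 <- angleJIVE:::.stratifiedFolds(y, 10, seed = 5)
  f2 <- angleJIVE:::.stratifiedFolds(y, 10, seed = 5)
  expect_identical(f1, f2)
  for (k in 1:10) {
    tab <- table(y[f1 == k])
    expect_lte(abs(tab["a"] - 7), 1)
    expect_lte(abs(tab["b"] - 3), 1)
  }
  expect_error(angleJIVE:::.stratifiedFolds(factor(rep(c("a", "b"),
                                                       c(50, 3))), 10, 1),
               "stratification")
})

test_that("cross-validated AUC is null-calibrated and perfect when separable", {
  set.seed(130)
  x <- matrix(rnorm(500 * 4), 500, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  y <- factor(rep(c("control", "case"), 250), levels = c("control", "case"))
  ft <- new("FeatureTable", features = x, tags = rep("covariate", 4),
            outcome = y)
  aucs <- sapply(1:10, function(s) meanAUC(cvAUC(ft, "logistic", seed = s)))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)

  sep <- matrix(as.numeric(y == "case") * 2 - 1 + 0, ncol = 1,
                dimnames = list(NULL, "perfect"))
  ftSep <- new("FeatureTable", features = sep, tags = "covariate",
               outcome = y)
  rep <- cvAUC(ftSep, "logistic", k = 5, seed = 1)
  expect_equal(meanAUC(rep), 1)
  expect_equal(rep@inSampleAUC, 1)
  expect_identical(length(rep@foldAUCs), 5L)
  expect_identical(rep@folds, angleJIVE:::.stratifiedFolds(y, 5, 1))
})

test_that("Hand-Till multiclass AUC matches the brute-force pair average", {
  # perfect probabilities
  y <- factor(c("Basal", "Her2", "LumA", "LumB", "Basal", "LumA"))
  P <- matrix(0, 6, 4, dimnames = list(NULL, levels(y)))
  P[cbind(seq_len(6), as.integer(y))] <- 1
  expect_equal(multiclassAUC(P, y), 1)
  # uniform probabilities
  U <- matrix(0.25, 6, 4, dimnames = list(NULL, levels(y)))
  expect_equal(multiclassAUC(U, y), 0.5)
  # hand-enumerable 3-class example on 6 samples
  y3 <- factor(c("a", "b", "c", "a", "b", "c"))
  P3 <- rbind(c(.6, .3, .1), c(.2, .5, .3), c(.1, .2, .7),
              c(.5, .4, .1), c(.4, .4, .2), c(.3, .3, .4))
  colnames(P3) <- c("a", "b", "c")
  brute <- function(pr) {
    sel <- y3 %in% pr
    a1 <- oracleAUC(P3[sel, pr[1]], y3[sel] == pr[1])
    a2 <- oracleAUC(P3[sel, pr[2]], y3[sel] == pr[2])
    (a1 + a2) / 2
  }
  expected <- mean(c(brute(c("a", "b")), brute(c("a", "c")),
                     brute(c("b", "c"))))
  expect_equal(multiclassAUC(P3, y3), expected, tolerance = 1e-12)
  expect_error(multiclassAUC(P3 * 2, y3), "sum to 1")
  skip_if_not_installed("pROC")
  got <- multiclassAUC(P3, y3)
  ref <- suppressMessages(as.numeric(pROC::multiclass.roc(y3, P3)$auc))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("multinomial cross-validation runs on 4-class outcomes", {
  s <- fitSmall(seed = 140)
  cfg <- syntheticConfig(n_samples = 120, block_dims = c(150, 100),
                         joint_rank = 2, individual_ranks = c(1, 1),
                         block_scales = c(1, 1), snr = c(5, 5),
                         outcome_kind = "categorical4", seed = 141)
  sim <- generateBlocks(cfg)
  coll <- centerCollection(sim$collection)
  fit <- ajive(coll, selectInitialRanks(coll), n_resample = 50,
               n_draws = 50, seed = 141)
  ft <- suppressWarnings(buildIntegrativeFeatures(fit, covariates(coll),
                                                  outcome(coll)))
  rep <- cvAUC(ft, "multinomial", k = 5, seed = 3)
  expect_true(all(rep@foldAUCs >= 0 & rep@foldAUCs <= 1, na.rm = TRUE))
  expect_gt(meanAUC(rep), 0.5)
})

test_that("lasso protocol keeps covariates unpenalized and finds planted signal", {
  set.seed(150)
  n <- 90
  basis <- randBasis(n, 1, seed = 150)
  b1 <- centerFeatures(plantedBlock(50, basis, seed = 151, name = "b1",
                                    noise_sd = 0.5))
  b2 <- centerFeatures(plantedBlock(40, basis, seed = 152, name = "b2",
                                    noise_sd = 0.5))
  covs <- data.frame(age = rnorm(n, 55, 5), bmi = rnorm(n, 25, 3),
                     smoking = rbinom(n, 1, .4))
  # outcome driven by one omics feature with a large effect
  driver <- blockValues(b1)[1, ]
  y <- factor(ifelse(runif(n) < plogis(3 * scale(driver)), "case",
                     "control"), levels = c("control", "case"))
  if (min(table(y)) < 15) skip("degenerate draw")  # guarded by fixed seed
  rep <- lassoProtocol(list(b1, b2), covs, y, repeats = 10, seed = 9)
  imp <- rep@importance
  expect_gte(imp$selection_freq[imp$predictor == "b1_f001"], 0.9)
  # covariates never penalized: always selected
  for (cv in c("age", "bmi", "smoking"))
    expect_equal(imp$selection_freq[imp$predictor == cv], 1)
  expect_gt(meanAUC(rep), 0.7)
})

test_that("lasso protocol is null-calibrated", {
  set.seed(160)
  n <- 80
  b1 <- centerFeatures(toyBlock(30, n, seed = 161, name = "b1"))
  b2 <- centerFeatures(toyBlock(20, n, seed = 162, name = "b2"))
  covs <- data.frame(age = rnorm(n), bmi = rnorm(n), smoking = rbinom(n, 1, .5))
  y <- factor(rep(c("control", "case"), n / 2), levels = c("control", "case"))
  rep <- lassoProtocol(list(b1, b2), covs, y, repeats = 10, seed = 4)
  expect_gt(meanAUC(rep), 0.3)
  expect_lt(meanAUC(rep), 0.7)
})

test_that("random forest ranks a separating feature first, deterministically", {
  set.seed(170)
  n <- 120
  y <- factor(rep(c("control", "case"), n / 2), levels = c("control", "case"))
  x <- cbind(perfect = as.numeric(y == "case") + 0,
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  ft <- new("FeatureTable", features = x, tags = rep("covariate", 4),
            outcome = y)
  rep <- randomForestEval(ft, n_trees = 200, seed = 2)
  expect_identical(rep@importance$predictor[1], "perfect")
  expect_setequal(rep@importance$predictor, colnames(x))
  rep2 <- randomForestEval(ft, n_trees = 200, seed = 2)
  expect_identical(rep@importance, rep2@importance)
  expect_equal(rep@meanAUC, 1, tolerance = 0.01)

  # pure noise: OOB error near the majority-class rate
  ftN <- new("FeatureTable", features = x[, 2:4],
             tags = rep("covariate", 3), outcome = y)
  repN <- randomForestEval(ftN, n_trees = 300, seed = 3)
  expect_gt(repN@oobError, 30)
})

test_that("integrative features beat PCA features when signal is shared", {
  wins <- 0
  for (s in 1:4) {
    cfg <- syntheticConfig(n_samples = 120, block_dims = c(800, 400, 120),
                           joint_rank = 5, individual_ranks = c(10, 6, 6),
                           seed = 200 + s)
    sim <- generateBlocks(cfg)
    coll <- centerCollection(sim$collection)
    fit <- ajive(coll, selectInitialRanks(coll), n_resample = 100,
                 n_draws = 100, seed = s)
    integ <- suppressWarnings(buildIntegrativeFeatures(
      fit, covariates(coll), outcome(coll)))
    pca <- buildPCAFeatures(blocks(coll), covariates(coll), outcome(coll))
    aInteg <- meanAUC(cvAUC(integ, "logistic", k = 5, seed = s))
    aPCA <- meanAUC(cvAUC(pca, "logistic", k = 5, seed = s))
    if (aInteg >= aPCA) wins <- wins + 1
  }
  expect_gte(wins, 3)
})
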
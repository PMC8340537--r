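#' @include methods.R
NULL

#' Feature table from joint and individual components plus covariates
#'
#' Columns are the `r_J` common normalized score columns, the first
#' `n_individual` individual score columns of every block (truncated with a
#' warning where a block's individual rank is smaller), and the covariates.
#'
#' @param result an [AjiveResult-class].
#' @param covariates data.frame of per-sample covariates, rows aligned with
#'   the decomposition's samples.
#' @param outcome factor outcome aligned with the samples.
#' @param n_individual individual components per block (default 5).
#' @return a [FeatureTable-class] with provenance tags.
#' @export
buildIntegrativeFeatures <- function(result, covariates, outcome,
                                     n_individual = 5L) {
  n <- nrow(result@joint@rowBasis)
  if (n == 0L) n <- ncol(result@J[[1L]])
  if (nrow(covariates) != n)
    stop("alignment error: covariates have ", nrow(covariates),
         " rows but the decomposition has ", n, " samples")
  cols <- list()
  tags <- character(0)
  rJ <- result@joint@rank
  if (rJ > 0L) {
    jm <- result@joint@rowBasis
    colnames(jm) <- paste0("Joint", seq_len(rJ))
    cols <- c(cols, list(jm))
    tags <- c(tags, rep("joint", rJ))
  }
  for (k in seq_along(result@blockNames)) {
    S <- result@individualScores[[k]]
    take <- min(n_individual, ncol(S))
    if (take < n_individual)
      warning("block '", result@blockNames[k], "' has individual rank ",
              ncol(S), " < requested ", n_individual, "; truncating")
    if (take > 0L) {
      Sm <- S[, seq_len(take), drop = FALSE]
      colnames(Sm) <- paste0(result@blockNames[k], "Ind", seq_len(take))
      cols <- c(cols, list(Sm))
      tags <- c(tags, rep(paste0("individual:", result@blockNames[k]), take))
    }
  }
  cv <- as.matrix(data.matrix(covariates))
  colnames(cv) <- names(covariates)
  cols <- c(cols, list(cv))
  tags <- c(tags, rep("covariate", ncol(cv)))
  feats <- do.call(cbind, cols)
  rownames(feats) <- rownames(covariates)
  new("FeatureTable", features = feats, tags = tags,
      outcome = as.factor(outcome))
}

#' Feature table from per-block principal components plus covariates
#'
#' The non-integrative comparator: for every centered block the top `n_pcs`
#' principal-component sample scores (SVD-based, no scaling) are
#' concatenated with the covariates.
#'
#' @param blocks list of centered [OmicsBlock-class] objects.
#' @param covariates,outcome as in [buildIntegrativeFeatures()].
#' @param n_pcs principal components per block (default 5).
#' @return a [FeatureTable-class].
#' @export
buildPCAFeatures <- function(blocks, covariates, outcome, n_pcs = 5L) {
  cols <- list()
  tags <- character(0)
  for (k in seq_along(blocks)) {
    X <- blocks[[k]]@values
    if (n_pcs >= min(dim(X)))
      stop("n_pcs = ", n_pcs, " must be smaller than min(p_k, n) = ",
           min(dim(X)), " for block '", blocks[[k]]@name, "'")
    sv <- svd(X, nu = 0L, nv = n_pcs)
    V <- .fixSigns(sv$v[, seq_len(n_pcs), drop = FALSE])
    S <- V %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
    colnames(S) <- paste0(blocks[[k]]@name, "PC", seq_len(n_pcs))
    cols <- c(cols, list(S))
    tags <- c(tags, rep(paste0("pc:", blocks[[k]]@name), n_pcs))
  }
  cv <- as.matrix(data.matrix(covariates))
  colnames(cv) <- names(covariates)
  cols <- c(cols, list(cv))
  tags <- c(tags, rep("covariate", ncol(cv)))
  feats <- do.call(cbind, cols)
  rownames(feats) <- rownames(covariates)
  new("FeatureTable", features = feats, tags = tags,
      outcome = as.factor(outcome))
}

#' Covariates-only feature table
#'
#' @inheritParams buildPCAFeatures
#' @return a [FeatureTable-class] holding the covariates alone.
#' @export
buildCovariateFeatures <- function(covariates, outcome) {
  cv <- as.matrix(data.matrix(covariates))
  colnames(cv) <- names(covariates)
  new("FeatureTable", features = cv,
      tags = rep("covariate", ncol(cv)), outcome = as.factor(outcome))
}

# Fit a (multinomial) logistic model with a quasi-separation guard: on
# non-convergence, fall back to an essentially unpenalized ridge.
.fitLogistic <- function(x, y, multinomial = FALSE) {
  if (multinomial) {
    fit <- suppressWarnings(
      nnet::multinom(y ~ ., data = data.frame(y = y, x),
                     trace = FALSE, maxit = 500))
    return(list(predict = function(newx) {
      p <- predict(fit, newdata = data.frame(newx), type = "probs")
      if (is.null(dim(p)))
        p <- matrix(p, nrow = 1L, dimnames = list(NULL, names(p)))
      p
    }, note = NULL))
  }
  note <- NULL
  fit <- suppressWarnings(stats::glm.fit(cbind(1, x), y == levels(y)[2L],
                                         family = stats::binomial()))
  if (!fit$converged || any(fit$fitted.values > 1 - 1e-10) ||
      any(fit$fitted.values < 1e-10)) {
    note <- "quasi-separation: tiny-ridge fallback"
    # glmnet needs >= 2 columns; pad single-predictor tables with a zero
    pad <- ncol(x) < 2L
    xr <- if (pad) cbind(x, `.pad` = 0) else x
    rfit <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                           lambda = 1e-8, standardize = FALSE)
    return(list(predict = function(newx) {
      if (pad) newx <- cbind(newx, `.pad` = 0)
      as.numeric(predict(rfit, newx, type = "response"))
    }, note = note))
  }
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(predict = function(newx)
    as.numeric(stats::plogis(cbind(1, newx) %*% beta)), note = note)
}

#' Cross-validated AUC of a component-based logistic model
#'
#' Stratified k-fold cross-validation with seed-fixed fold assignment.
#' Binary outcomes use a rank-based (Mann-Whitney) held-out AUC per fold;
#' four-class outcomes use the Hand-Till pairwise average
#' ([multiclassAUC()]) of multinomial-logistic class probabilities.  The
#' model is also refitted on all samples for an in-sample ROC curve and AUC.
#'
#' @param features a [FeatureTable-class].
#' @param model_kind `"logistic"` (binary) or `"multinomial"` (4-class).
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return a [PredictionReport-class].
#' @export
cvAUC <- function(features, model_kind = c("logistic", "multinomial"),
                  k = 10L, seed = 1L) {
  model_kind <- match.arg(model_kind)
  x <- features@features
  y <- droplevels(features@outcome)
  if (model_kind == "logistic" && nlevels(y) != 2L)
    stop("logistic model needs a binary outcome, got ", nlevels(y), " levels")
  if (model_kind == "multinomial" && nlevels(y) < 3L)
    stop("multinomial model expects more than two classes")
  if (k < 2L) stop("k must be at least 2")
  folds <- .stratifiedFolds(y, k, seed)
  notes <- character(0)
  aucs <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- tryCatch(.fitLogistic(x[tr, , drop = FALSE], y[tr],
                                 multinomial = model_kind == "multinomial"),
                    error = function(e) NULL)
    if (is.null(fit)) {
      notes <- c(notes, paste0("fold ", f, ": fit failed, skipped"))
      warning("fold ", f, " skipped: non-convergent fit")
      next
    }
    if (!is.null(fit$note)) notes <- c(notes, paste0("fold ", f, ": ",
                                                     fit$note))
    pred <- fit$predict(x[!tr, , drop = FALSE])
    aucs[f] <- if (model_kind == "logistic")
      .binaryAUC(pred, y[!tr]) else multiclassAUC(pred, y[!tr])
  }
  full <- .fitLogistic(x, y, multinomial = model_kind == "multinomial")
  predAll <- full$predict(x)
  if (model_kind == "logistic") {
    inAUC <- .binaryAUC(predAll, y)
    roc <- .rocPoints(predAll, y)
    cls <- factor(ifelse(predAll > 0.5, levels(y)[2L], levels(y)[1L]),
                  levels = levels(y))
  } else {
    inAUC <- multiclassAUC(predAll, y)
    roc <- data.frame(fpr = numeric(0), tpr = numeric(0))
    cls <- factor(colnames(predAll)[max.col(predAll)], levels = levels(y))
  }
  new("PredictionReport", modelKind = model_kind, foldAUCs = aucs,
      meanAUC = mean(aucs, na.rm = TRUE), inSampleAUC = inAUC, roc = roc,
      accuracy = mean(cls == y), oobError = NA_real_,
      importance = data.frame(), folds = as.integer(folds),
      seeds = list(fold_seed = seed), notes = notes)
}

#' Hand-Till multiclass AUC
#'
#' Average over all unordered class pairs `(i, j)` of the pairwise measure
#' `(A(i|j) + A(j|i)) / 2`, where `A(i|j)` is the rank-based AUC of class
#' i's predicted probability for separating class i from class j among
#' samples of those two classes.  A one-vs-rest macro average is available
#' as a variant.
#'
#' @param scores samples x classes probability matrix, rows summing to 1;
#'   column names must match the outcome levels.
#' @param labels factor of true classes; every class must appear.
#' @param variant `"hand_till"` (default) or `"one_vs_rest"`.
#' @return single AUC value in `[0, 1]`.
#' @export
multiclassAUC <- function(scores, labels,
                          variant = c("hand_till", "one_vs_rest")) {
  variant <- match.arg(variant)
  labels <- droplevels(as.factor(labels))
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)) && ncol(scores) == nlevels(labels))
    colnames(scores) <- levels(labels)
  if (max(abs(rowSums(scores) - 1)) > 1e-8)
    stop("probability rows must sum to 1")
  lv <- levels(labels)
  if (!all(lv %in% colnames(scores)))
    stop("score columns missing for class(es): ",
         paste(setdiff(lv, colnames(scores)), collapse = ", "))
  if (any(table(labels) == 0L)) stop("class absent from labels")
  if (variant == "one_vs_rest") {
    aucs <- vapply(lv, function(ci)
      .binaryAUC(scores[, ci], factor(labels == ci,
                                      levels = c(FALSE, TRUE))), numeric(1))
    return(mean(aucs))
  }
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  pairAUC <- vapply(pairs, function(pr) {
    sel <- labels %in% pr
    yi <- factor(labels[sel] == pr[1L], levels = c(FALSE, TRUE))
    yj <- factor(labels[sel] == pr[2L], levels = c(FALSE, TRUE))
    (.binaryAUC(scores[sel, pr[1L]], yi) +
       .binaryAUC(scores[sel, pr[2L]], yj)) / 2
  }, numeric(1))
  mean(pairAUC)
}

#' Repeated-split lasso protocol on the raw omics features
#'
#' Per repeat: a stratified split keeps `train_frac` of the samples; an
#' L1-penalized logistic model on the concatenated (standardized) omics
#' features plus covariates — the covariate penalty factors fixed to 0 so
#' they always stay in the model — is tuned by inner k-fold
#' cross-validation on the training portion (minimum mean deviance by
#' default, 1-SE rule optional) and scored by rank-based AUC on the held-out
#' portion.
#'
#' @param blocks list of preprocessed (centered) [OmicsBlock-class] objects.
#' @param covariates data.frame of covariates (never penalized).
#' @param outcome binary factor.
#' @param repeats number of split repeats (default 50).
#' @param train_frac training fraction (default 2/3).
#' @param k_inner inner CV folds (default 10).
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param seed integer seed.
#' @return a [PredictionReport-class]; `foldAUCs` holds the per-repeat
#'   held-out AUCs and the `importance` slot the selection frequency of
#'   every predictor across repeats.
#' @export
lassoProtocol <- function(blocks, covariates, outcome, repeats = 50L,
                          train_frac = 2 / 3, k_inner = 10L,
                          lambda_rule = c("min", "1se"), seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(train_frac > 0, train_frac < 1)
  y <- droplevels(as.factor(outcome))
  if (nlevels(y) != 2L) stop("lasso protocol needs a binary outcome")
  omics <- t(do.call(rbind, lapply(blocks, function(b) b@values)))
  cv <- as.matrix(data.matrix(covariates))
  x <- cbind(omics, cv)
  penalty <- c(rep(1, ncol(omics)), rep(0, ncol(cv)))
  n <- nrow(x)
  seeds <- .subSeeds(seed, repeats)
  aucs <- rep(NA_real_, repeats)
  selected <- matrix(FALSE, repeats, ncol(x),
                     dimnames = list(NULL, colnames(x)))
  notes <- character(0)
  for (r in seq_len(repeats)) {
    set.seed(seeds[r])
    ok <- FALSE
    for (try in seq_len(10L)) {
      tr <- unlist(lapply(split(seq_len(n), y), function(idx)
        sample(idx, round(train_frac * length(idx)))))
      if (nlevels(droplevels(y[tr])) == 2L &&
          nlevels(droplevels(y[-tr])) == 2L) { ok <- TRUE; break }
      notes <- c(notes, paste0("repeat ", r, ": degenerate split redrawn"))
    }
    if (!ok) { notes <- c(notes, paste0("repeat ", r, ": skipped")); next }
    cvfit <- glmnet::cv.glmnet(x[tr, ], y[tr], family = "binomial",
                               alpha = 1, nfolds = k_inner,
                               penalty.factor = penalty, standardize = TRUE)
    lam <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
    pred <- as.numeric(predict(cvfit, x[-tr, ], s = lam, type = "response"))
    aucs[r] <- .binaryAUC(pred, y[-tr])
    co <- as.numeric(stats::coef(cvfit, s = lam))[-1L]
    selected[r, ] <- co != 0
  }
  imp <- data.frame(predictor = colnames(x),
                    selection_freq = colMeans(selected))
  imp <- imp[order(-imp$selection_freq), ]
  new("PredictionReport", modelKind = "lasso", foldAUCs = aucs,
      meanAUC = mean(aucs, na.rm = TRUE), inSampleAUC = NA_real_,
      roc = data.frame(fpr = numeric(0), tpr = numeric(0)),
      accuracy = NA_real_, oobError = NA_real_, importance = imp,
      folds = integer(0), seeds = list(seed = seed, repeat_seeds = seeds),
      notes = notes)
}

#' Random-forest evaluation with OOB diagnostics and Gini importance
#'
#' Fits a forest (default 1000 trees) on the feature table and reports OOB
#' accuracy, OOB classification error in percent, an AUC computed from the
#' OOB class votes (binary: rank-based; multiclass: Hand-Till), and all
#' predictors ranked by mean decrease in Gini impurity.
#'
#' @param features a [FeatureTable-class].
#' @param n_trees number of trees (default 1000).
#' @param seed integer seed.
#' @return a [PredictionReport-class].
#' @export
randomForestEval <- function(features, n_trees = 1000L, seed = 1L) {
  stopifnot(n_trees >= 1L)
  x <- as.data.frame(features@features)
  y <- droplevels(features@outcome)
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = n_trees, importance = FALSE)
  oobPred <- rf$predicted
  acc <- mean(oobPred == y)
  oobErr <- 100 * (1 - acc)
  votes <- rf$votes / rowSums(rf$votes)
  auc <- if (nlevels(y) == 2L) .binaryAUC(votes[, levels(y)[2L]], y)
         else multiclassAUC(votes, y)
  gini <- rf$importance[, "MeanDecreaseGini"]
  imp <- data.frame(predictor = rownames(rf$importance),
                    mean_decrease_gini = as.numeric(gini))
  imp <- imp[order(-imp$mean_decrease_gini), ]
  rownames(imp) <- NULL
  new("PredictionReport", modelKind = "random_forest",
      foldAUCs = numeric(0), meanAUC = auc, inSampleAUC = NA_real_,
      roc = data.frame(fpr = numeric(0), tpr = numeric(0)),
      accuracy = acc, oobError = oobErr, importance = imp,
      folds = integer(0), seeds = list(seed = seed), notes = character(0))
}
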
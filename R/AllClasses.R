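#' @import methods
NULL

.assayKinds <- c("methylation_beta", "methylation_m", "expression_log",
                 "expression_raw", "counts")

#' One omics data block
#'
#' A feature-by-sample real matrix together with its identifiers and assay
#' kind.  Features are rows and samples are columns throughout the package,
#' so the sample-indexed row space of a block lives in n-dimensional space.
#' Missing entries are permitted (`NA`); counts blocks must hold non-negative
#' integers where observed.
#'
#' @slot values numeric matrix, `p_k` features x `n` samples, with unique
#'   row (feature) and column (sample) names.
#' @slot name single string naming the block (e.g. `"methylation"`).
#' @slot assayKind one of `"methylation_beta"`, `"methylation_m"`,
#'   `"expression_log"`, `"expression_raw"`, `"counts"`.
#'
#' @seealso [OmicsBlock()] for the constructor, [MultiOmicsCollection-class].
#' @export
setClass("OmicsBlock",
  representation(values = "matrix", name = "character", assayKind = "character"))

setValidity("OmicsBlock", function(object) {
  v <- object@values
  msg <- character(0)
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry feature (row) and sample (column) names")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, "duplicate feature ids")
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, "duplicate sample ids")
  }
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (length(object@assayKind) != 1L || !object@assayKind %in% .assayKinds)
    msg <- c(msg, paste0("assayKind must be one of: ",
                         paste(.assayKinds, collapse = ", ")))
  if (identical(object@assayKind, "counts")) {
    obs <- v[!is.na(v)]
    if (length(obs) && (any(obs < 0) || any(obs != round(obs))))
      msg <- c(msg, "counts blocks must hold non-negative integers")
  }
  if (length(msg)) msg else TRUE
})

#' A collection of omics blocks on one ordered sample set
#'
#' Holds `K` [OmicsBlock-class] objects whose samples are identical and in
#' identical order, an optional sample covariate table, and an optional
#' outcome (a factor, binary or 4-class).
#'
#' @slot blocks named list of [OmicsBlock-class] objects.
#' @slot covariates data.frame of per-sample covariates (rows follow the
#'   shared sample order), possibly with zero columns.
#' @slot outcome factor of length n, or length 0 when no outcome is attached.
#'
#' @export
setClass("MultiOmicsCollection",
  representation(blocks = "list", covariates = "data.frame",
                 outcome = "factor"))

setValidity("MultiOmicsCollection", function(object) {
  msg <- character(0)
  if (length(object@blocks) < 1L) msg <- c(msg, "at least one block required")
  if (!all(vapply(object@blocks, is, logical(1), "OmicsBlock")))
    msg <- c(msg, "blocks must all be OmicsBlock objects")
  else {
    ids <- lapply(object@blocks, function(b) colnames(b@values))
    if (length(unique(ids)) != 1L)
      msg <- c(msg, "all blocks must share identical ordered sample ids")
    else {
      n <- length(ids[[1L]])
      if (nrow(object@covariates) != 0L && nrow(object@covariates) != n)
        msg <- c(msg, "covariates rows must match sample count")
      if (nrow(object@covariates) == n && ncol(object@covariates) > 0L &&
          !is.null(rownames(object@covariates)) &&
          !identical(rownames(object@covariates), ids[[1L]]))
        msg <- c(msg, "covariate row names must follow the shared sample order")
      if (length(object@outcome) != 0L && length(object@outcome) != n)
        msg <- c(msg, "outcome length must match sample count")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-rule accounting of a filtering step
#'
#' Each applied rule records how many features entered, were removed, and
#' survived; the counts telescope (`in - removed = out`, and each rule's
#' `out` is the next rule's `in`).
#'
#' @slot rules data.frame with columns `rule`, `n_in`, `n_removed`, `n_out`.
#' @export
setClass("FilterReport", representation(rules = "data.frame"))

setValidity("FilterReport", function(object) {
  r <- object@rules
  need <- c("rule", "n_in", "n_removed", "n_out")
  if (!all(need %in% names(r)))
    return("rules must have columns rule, n_in, n_removed, n_out")
  if (nrow(r)) {
    if (any(r$n_in - r$n_removed != r$n_out))
      return("filter counts must telescope: n_in - n_removed = n_out")
    if (nrow(r) > 1L && any(r$n_out[-nrow(r)] != r$n_in[-1L]))
      return("each rule's n_out must equal the next rule's n_in")
  }
  TRUE
})

#' Ground truth of a synthetic multi-block dataset
#'
#' Retains the generating joint and individual score subspaces, loadings,
#' noise levels and outcome linear predictor so recovery of every estimated
#' quantity can be scored against the truth.
#'
#' @slot jointScoreBasis n x joint-rank matrix with orthonormal columns.
#' @slot individualScoreBases per-block orthonormal score bases, each
#'   orthogonal to the joint basis by construction.
#' @slot jointLoadings,individualLoadings per-block loading matrices.
#' @slot noiseSD realized per-block noise standard deviations (before the
#'   global block scale is applied).
#' @slot outcomeLinpred the linear predictor that generated the outcome.
#' @slot config the [syntheticConfig()] list that produced the data.
#' @export
setClass("SyntheticTruth",
  representation(jointScoreBasis = "matrix", individualScoreBases = "list",
                 jointLoadings = "list", individualLoadings = "list",
                 noiseSD = "numeric", outcomeLinpred = "numeric",
                 config = "list"))

#' Profile-likelihood rank selection result
#'
#' @slot initialRanks named integer vector, one initial rank per block.
#' @slot singularValues per-block descending singular-value vectors.
#' @slot profileLoglik per-block profile log-likelihood curves over the
#'   candidate ranks `1..max_rank`.
#' @slot overrides named integer vector of manually imposed ranks.
#' @export
setClass("RankSelection",
  representation(initialRanks = "integer", singularValues = "list",
                 profileLoglik = "list", overrides = "integer"))

setValidity("RankSelection", function(object) {
  msg <- character(0)
  for (k in seq_along(object@singularValues)) {
    sv <- object@singularValues[[k]]
    if (is.unsorted(rev(sv))) msg <- c(msg, "singular values must be non-increasing")
  }
  if (any(object@initialRanks < 1L)) msg <- c(msg, "initial ranks must be >= 1")
  if (length(msg)) msg else TRUE
})

#' First-phase truncated SVD of one block
#'
#' @slot name block name.
#' @slot rank the initial rank `r_k` used for truncation.
#' @slot leftBasis p_k x r_k left singular vectors (feature loadings basis).
#' @slot singularValues the retained singular values, descending.
#' @slot rowBasis n x r_k right singular vectors: an orthonormal basis of the
#'   block's estimated signal row space.
#' @slot noiseThreshold the first discarded singular value (0 if none);
#'   reused downstream as the block's noise scale.
#' @slot discarded the full discarded singular-value spectrum.
#' @export
setClass("BlockSVD",
  representation(name = "character", rank = "integer", leftBasis = "matrix",
                 singularValues = "numeric", rowBasis = "matrix",
                 noiseThreshold = "numeric", discarded = "numeric"))

setValidity("BlockSVD", function(object) {
  msg <- character(0)
  V <- object@rowBasis
  if (ncol(V) != object@rank) msg <- c(msg, "rowBasis must have r_k columns")
  if (ncol(V) > 0) {
    g <- crossprod(V)
    if (max(abs(g - diag(ncol(V)))) > 1e-10)
      msg <- c(msg, "rowBasis columns must be orthonormal (1e-10)")
  }
  d <- object@singularValues
  if (length(d) && (any(d <= 0) || is.unsorted(rev(d))))
    msg <- c(msg, "singular values must be positive and descending")
  if (length(msg)) msg else TRUE
})

#' Joint structure across blocks
#'
#' @slot rank the selected joint rank `r_J` (possibly 0).
#' @slot rowBasis n x r_J orthonormal joint row basis — the common
#'   normalized scores, one score vector per joint component.
#' @slot squaredSingularValues squared singular values of the stacked
#'   row-basis matrix, each in `[0, K]`.
#' @slot wedinThreshold,randomThreshold the two joint-rank thresholds.
#' @export
setClass("JointStructure",
  representation(rank = "integer", rowBasis = "matrix",
                 squaredSingularValues = "numeric",
                 wedinThreshold = "numeric", randomThreshold = "numeric"))

#' Full angle-based joint-and-individual decomposition
#'
#' For every block `X_k` the result holds the joint component `J_k`, the
#' individual component `I_k` and the residual `E_k` with
#' `X_k = J_k + I_k + E_k` exactly, along with scores, loadings, ranks,
#' thresholds and variance-explained proportions.
#'
#' @slot blockNames block names, in input order.
#' @slot J,I,E per-block p_k x n component matrices.
#' @slot individualRanks integer vector of estimated individual ranks.
#' @slot jointLoadings per-block p_k x r_J joint loading matrices
#'   (`X_k %*% V_J`).
#' @slot individualScores per-block n x rank score matrices (right singular
#'   vectors of `I_k` scaled by singular values, decreasing).
#' @slot individualLoadings per-block left singular vectors of `I_k`.
#' @slot joint the shared [JointStructure-class].
#' @slot varianceExplained K x 3 matrix of joint/individual/residual
#'   proportions of variance, rows summing to 1.
#' @slot initialRanks the per-block first-phase ranks used.
#' @slot provenance list of seeds, thresholds and options for reproducibility.
#' @export
setClass("AjiveResult",
  representation(blockNames = "character", J = "list", I = "list", E = "list",
                 individualRanks = "integer", jointLoadings = "list",
                 individualScores = "list", individualLoadings = "list",
                 joint = "JointStructure", varianceExplained = "matrix",
                 initialRanks = "integer", provenance = "list"))

setValidity("AjiveResult", function(object) {
  msg <- character(0)
  K <- length(object@blockNames)
  if (length(object@J) != K || length(object@I) != K || length(object@E) != K)
    msg <- c(msg, "J, I, E must have one matrix per block")
  ve <- object@varianceExplained
  if (nrow(ve) == K && ncol(ve) == 3L) {
    if (any(abs(rowSums(ve) - 1) > 1e-10))
      msg <- c(msg, "variance proportions must sum to 1 per block")
  } else msg <- c(msg, "varianceExplained must be K x 3")
  if (object@joint@rank > 0 && length(object@individualRanks) == K) {
    if (object@joint@rank > min(object@initialRanks))
      msg <- c(msg, "joint rank must not exceed the smallest initial rank")
  }
  if (length(msg)) msg else TRUE
})

#' Samples-by-predictors feature table for prediction models
#'
#' @slot features numeric matrix, samples x predictors, no missing entries.
#' @slot tags provenance tag per predictor, one of `joint`,
#'   `individual:<block>`, `pc:<block>`, `covariate`.
#' @slot outcome factor aligned with the rows of `features`.
#' @export
setClass("FeatureTable",
  representation(features = "matrix", tags = "character", outcome = "factor"))

setValidity("FeatureTable", function(object) {
  msg <- character(0)
  if (anyNA(object@features)) msg <- c(msg, "features must not contain NA")
  if (length(object@tags) != ncol(object@features))
    msg <- c(msg, "one provenance tag per predictor column required")
  ok <- grepl("^(joint|individual:[^:]+|pc:[^:]+|covariate)$", object@tags)
  if (!all(ok)) msg <- c(msg, "malformed provenance tags")
  if (length(object@outcome) != nrow(object@features))
    msg <- c(msg, "outcome length must match the number of samples")
  if (length(msg)) msg else TRUE
})

#' Prediction model evaluation report
#'
#' @slot modelKind one of `logistic`, `multinomial`, `lasso`, `random_forest`.
#' @slot foldAUCs per-fold (or per-repeat) held-out AUCs.
#' @slot meanAUC mean of `foldAUCs`.
#' @slot inSampleAUC AUC of the model refitted on all samples (NA where the
#'   protocol defines none).
#' @slot roc in-sample ROC points (`fpr`, `tpr`), empty for multiclass.
#' @slot accuracy classification accuracy (forest: OOB; others in-sample).
#' @slot oobError OOB classification error in percent (forest only, else NA).
#' @slot importance data.frame ranking predictors by mean Gini decrease
#'   (forest only, else empty).
#' @slot folds fold assignment used (empty where not applicable).
#' @slot seeds list of seeds consumed.
#' @slot notes character log of fallbacks or redraws.
#' @export
setClass("PredictionReport",
  representation(modelKind = "character", foldAUCs = "numeric",
                 meanAUC = "numeric", inSampleAUC = "numeric",
                 roc = "data.frame", accuracy = "numeric",
                 oobError = "numeric", importance = "data.frame",
                 folds = "integer", seeds = "list", notes = "character"))

setValidity("PredictionReport", function(object) {
  msg <- character(0)
  aucs <- object@foldAUCs[!is.na(object@foldAUCs)]
  if (length(aucs) && (any(aucs < 0) || any(aucs > 1)))
    msg <- c(msg, "AUC values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
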
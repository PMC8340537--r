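#' @include AllGenerics.R
NULL

#' Construct an omics block
#'
#' @param values numeric matrix, features as rows, samples as columns; row
#'   and column names are required and must be unique.
#' @param name block name.
#' @param assayKind one of `"methylation_beta"`, `"methylation_m"`,
#'   `"expression_log"`, `"expression_raw"`, `"counts"`.
#' @return a validated [OmicsBlock-class].
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' OmicsBlock(m, "toy", "expression_log")
#' @export
OmicsBlock <- function(values, name, assayKind) {
  new("OmicsBlock", values = as.matrix(values), name = name,
      assayKind = assayKind)
}

#' Construct a multi-omics collection
#'
#' @param blocks list of [OmicsBlock-class] objects on identical ordered
#'   samples; names default to the block names.
#' @param covariates per-sample covariate data.frame (optional).
#' @param outcome factor outcome of length n (optional).
#' @return a validated [MultiOmicsCollection-class].
#' @export
MultiOmicsCollection <- function(blocks, covariates = NULL, outcome = NULL) {
  if (is.null(names(blocks)))
    names(blocks) <- vapply(blocks, function(b) b@name, character(1))
  n <- if (length(blocks)) ncol(blocks[[1L]]@values) else 0L
  if (is.null(covariates)) {
    covariates <- as.data.frame(matrix(nrow = n, ncol = 0L))
    if (length(blocks))
      rownames(covariates) <- colnames(blocks[[1L]]@values)
  }
  if (is.null(outcome)) outcome <- factor()
  new("MultiOmicsCollection", blocks = blocks,
      covariates = covariates, outcome = as.factor(outcome))
}

setMethod("blockValues", "OmicsBlock", function(x) x@values)
setMethod("featureIds", "OmicsBlock", function(x) rownames(x@values))
setMethod("sampleIds", "OmicsBlock", function(x) colnames(x@values))
setMethod("assayKind", "OmicsBlock", function(x) x@assayKind)
setMethod("blockName", "OmicsBlock", function(x) x@name)
setMethod("dim", "OmicsBlock", function(x) dim(x@values))

setMethod("blocks", "MultiOmicsCollection", function(x) x@blocks)
setMethod("covariates", "MultiOmicsCollection", function(x) x@covariates)
setMethod("outcome", "MultiOmicsCollection", function(x) x@outcome)
setMethod("sampleIds", "MultiOmicsCollection",
          function(x) colnames(x@blocks[[1L]]@values))

setMethod("jointRank", "AjiveResult", function(x) x@joint@rank)
setMethod("individualRanks", "AjiveResult", function(x) x@individualRanks)
setMethod("jointScores", "AjiveResult", function(x) x@joint@rowBasis)
setMethod("individualScores", "AjiveResult", function(x) x@individualScores)
setMethod("varianceExplained", "AjiveResult", function(x) x@varianceExplained)
setMethod("initialRanks", "RankSelection", function(x) x@initialRanks)
setMethod("initialRanks", "AjiveResult", function(x) x@initialRanks)
setMethod("meanAUC", "PredictionReport", function(x) x@meanAUC)

setMethod("show", "OmicsBlock", function(object) {
  cat("OmicsBlock '", object@name, "' [", object@assayKind, "]: ",
      nrow(object@values), " features x ", ncol(object@values), " samples",
      sep = "")
  nmiss <- sum(is.na(object@values))
  if (nmiss) cat(", ", nmiss, " missing entries", sep = "")
  cat("\n")
})

setMethod("show", "MultiOmicsCollection", function(object) {
  cat("MultiOmicsCollection:", length(object@blocks), "block(s),",
      ncol(object@blocks[[1L]]@values), "samples\n")
  for (b in object@blocks) show(b)
  if (ncol(object@covariates))
    cat("covariates:", paste(names(object@covariates), collapse = ", "), "\n")
  if (length(object@outcome))
    cat("outcome:", paste(levels(object@outcome), collapse = "/"), "\n")
})

setMethod("show", "RankSelection", function(object) {
  cat("RankSelection (profile likelihood):\n")
  print(object@initialRanks)
  if (length(object@overrides))
    cat("overridden:", paste(names(object@overrides), collapse = ", "), "\n")
})

setMethod("show", "AjiveResult", function(object) {
  cat("AjiveResult:", length(object@blockNames), "blocks, joint rank",
      object@joint@rank, "\n")
  cat("  initial ranks:   ",
      paste(object@initialRanks, collapse = ", "), "\n")
  cat("  individual ranks:",
      paste(object@individualRanks, collapse = ", "), "\n")
  cat("  variance explained (joint / individual / residual):\n")
  ve <- round(object@varianceExplained, 3)
  for (k in seq_along(object@blockNames))
    cat(sprintf("    %-12s %5.3f / %5.3f / %5.3f\n", object@blockNames[k],
                ve[k, 1], ve[k, 2], ve[k, 3]))
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:\n")
  print(object@rules, row.names = FALSE)
})

setMethod("show", "PredictionReport", function(object) {
  cat("PredictionReport [", object@modelKind, "]\n", sep = "")
  if (!is.na(object@meanAUC)) {
    if (length(object@foldAUCs))
      cat("  mean held-out AUC:", round(object@meanAUC, 3),
          "over", length(object@foldAUCs), "folds/repeats\n")
    else
      cat("  OOB AUC:         ", round(object@meanAUC, 3), "\n")
  }
  if (!is.na(object@inSampleAUC))
    cat("  in-sample AUC:   ", round(object@inSampleAUC, 3), "\n")
  if (!is.na(object@accuracy))
    cat("  accuracy:        ", round(object@accuracy, 3), "\n")
  if (!is.na(object@oobError))
    cat("  OOB error (%):   ", round(object@oobError, 2), "\n")
  if (nrow(object@importance))
    cat("  top predictor:   ", object@importance$predictor[1L], "\n")
})

# Internal helper: a zero-row filter report to extend rule by rule.
.emptyReport <- function() {
  new("FilterReport", rules = data.frame(rule = character(0),
      n_in = integer(0), n_removed = integer(0), n_out = integer(0)))
}

.addRule <- function(report, rule, n_in, n_out) {
  rules <- rbind(report@rules,
                 data.frame(rule = rule, n_in = n_in,
                            n_removed = n_in - n_out, n_out = n_out))
  new("FilterReport", rules = rules)
}
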
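#' @include AllClasses.R
NULL

#' @describeIn OmicsBlock-class matrix of values (features x samples)
#' @param x,object an object of the documented class
#' @export
setGeneric("blockValues", function(x) standardGeneric("blockValues"))

#' @describeIn OmicsBlock-class feature identifiers
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @describeIn OmicsBlock-class sample identifiers
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @describeIn OmicsBlock-class assay kind string
#' @export
setGeneric("assayKind", function(x) standardGeneric("assayKind"))

#' @describeIn OmicsBlock-class block name
#' @export
setGeneric("blockName", function(x) standardGeneric("blockName"))

#' @describeIn MultiOmicsCollection-class named list of blocks
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @describeIn MultiOmicsCollection-class covariate data.frame
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @describeIn MultiOmicsCollection-class outcome factor
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))

#' @describeIn AjiveResult-class selected joint rank
#' @export
setGeneric("jointRank", function(x) standardGeneric("jointRank"))

#' @describeIn AjiveResult-class estimated per-block individual ranks
#' @export
setGeneric("individualRanks", function(x) standardGeneric("individualRanks"))

#' @describeIn AjiveResult-class common normalized scores (n x r_J)
#' @export
setGeneric("jointScores", function(x) standardGeneric("jointScores"))

#' @describeIn AjiveResult-class per-block individual score matrices
#' @export
setGeneric("individualScores", function(x) standardGeneric("individualScores"))

#' @describeIn AjiveResult-class joint/individual/residual variance proportions
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @describeIn RankSelection-class chosen initial ranks
#' @export
setGeneric("initialRanks", function(x) standardGeneric("initialRanks"))

#' @describeIn PredictionReport-class mean cross-validated AUC
#' @export
setGeneric("meanAUC", function(x) standardGeneric("meanAUC"))
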
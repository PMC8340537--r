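#' @include methods.R
NULL

#' Read an omics block from TSV/CSV
#'
#' Expected layout: feature ids in the first column, sample ids in the
#' header, one row per feature; empty cells are missing values.  The
#' delimiter is taken from the file extension (`.csv` = comma, otherwise
#' tab).
#'
#' @param path file path.
#' @param assay_kind the block's assay kind (see [OmicsBlock-class]).
#' @param name block name; defaults to the file name without extension.
#' @return a validated [OmicsBlock-class].
#' @export
readBlock <- function(path, assay_kind, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, na.strings = c("", "NA"),
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L)
    stop("parse error in ", path, ": need a feature-id column plus samples")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("parse error in ", path, ": duplicate feature id '",
         ids[duplicated(ids)][1L], "'")
  if (anyDuplicated(names(df)[-1L]))
    stop("parse error in ", path, ": duplicate sample id in header")
  m <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("parse error in ", path, ": non-numeric cell at row ",
         bad[1L, 1L] + 1L, ", column ", bad[1L, 2L] + 1L)
  dimnames(num) <- list(ids, names(df)[-1L])
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  OmicsBlock(num, name, assay_kind)
}

#' Write an omics block as TSV
#'
#' @param block an [OmicsBlock-class].
#' @param path output path; the first column holds feature ids, the header
#'   the sample ids.
#' @export
writeBlock <- function(block, path) {
  df <- data.frame(feature_id = rownames(block@values),
                   block@values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Align blocks and covariates to their common samples
#'
#' Restricts every block and the covariate table to the intersection of
#' their sample ids, in canonical sorted order; dropped samples are
#' reported in the `dropped` attribute.
#'
#' @param block_list list of [OmicsBlock-class] objects.
#' @param covariates optional per-sample data.frame with sample ids as row
#'   names.
#' @param outcome optional outcome vector named by sample id (or aligned to
#'   the covariates).
#' @return a [MultiOmicsCollection-class] on the shared samples.
#' @export
alignSamples <- function(block_list, covariates = NULL, outcome = NULL) {
  idSets <- lapply(block_list, function(b) colnames(b@values))
  if (!is.null(covariates)) idSets <- c(idSets, list(rownames(covariates)))
  shared <- Reduce(intersect, idSets)
  if (length(shared) == 0L)
    stop("alignment error: no sample id shared by all inputs")
  shared <- sort(shared)
  dropped <- lapply(idSets, function(ids) setdiff(ids, shared))
  bl <- lapply(block_list, function(b)
    OmicsBlock(b@values[, shared, drop = FALSE], b@name, b@assayKind))
  cv <- if (!is.null(covariates)) covariates[shared, , drop = FALSE] else NULL
  y <- NULL
  if (!is.null(outcome)) {
    y <- if (!is.null(names(outcome))) outcome[shared]
         else outcome[match(shared, rownames(covariates))]
  }
  out <- MultiOmicsCollection(bl, covariates = cv, outcome = y)
  attr(out, "dropped") <- dropped
  out
}

#' Run the full pipeline on a collection
#'
#' Orchestrates preprocessing, profile-likelihood rank selection, the
#' angle-based decomposition and the prediction comparison (integrative,
#' per-block PCA, covariates-only, lasso, random forest), writing every
#' stage's outputs plus a reproducibility manifest to `out_dir`.
#'
#' @param collection a raw [MultiOmicsCollection-class] with covariates and
#'   a binary or 4-class outcome.
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every stochastic stage consumes a sub-seed
#'   derived from it and recorded in the manifest.
#' @param n_individual,n_pcs,k_folds,lasso_repeats,n_trees stage options.
#' @param preprocess whether to run [preprocessBlock()] per block first
#'   (set `FALSE` when blocks are already filtered and centered).
#' @return the manifest (list), invisibly; also written as JSON.
#' @export
runPipeline <- function(collection, out_dir, seed = 1L, n_individual = 5L,
                        n_pcs = 5L, k_folds = 10L, lasso_repeats = 50L,
                        n_trees = 1000L, preprocess = TRUE) {
  if (length(blocks(collection)) < 2L)
    stop("pipeline stage 'decompose': joint structure undefined for a ",
         "single block")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .subSeeds(seed, 4L)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("angleJIVE")),
                   seed = seed, stages = list())
  stamp <- function(stage, info) {
    manifest$stages[[stage]] <<- info
  }

  t0 <- proc.time()[3L]
  if (preprocess) {
    pre <- lapply(blocks(collection), preprocessBlock)
    bl <- lapply(pre, `[[`, "block")
    reports <- lapply(pre, function(p) p$report@rules)
  } else {
    bl <- lapply(blocks(collection), centerFeatures)
    reports <- list()
  }
  coll <- MultiOmicsCollection(bl, covariates = covariates(collection),
                               outcome = outcome(collection))
  stamp("preprocess", list(reports = reports,
                           dims = lapply(bl, dim),
                           seconds = proc.time()[3L] - t0))

  t0 <- proc.time()[3L]
  rk <- selectInitialRanks(coll)
  stamp("ranks", list(initial_ranks = as.list(initialRanks(rk)),
                      seconds = proc.time()[3L] - t0))

  t0 <- proc.time()[3L]
  fit <- ajive(coll, rk, seed = seeds[1L])
  stamp("decompose", list(joint_rank = jointRank(fit),
                          individual_ranks = as.list(individualRanks(fit)),
                          wedin_threshold = fit@joint@wedinThreshold,
                          random_threshold = fit@joint@randomThreshold,
                          variance_explained =
                            as.data.frame(varianceExplained(fit)),
                          seed = seeds[1L],
                          seconds = proc.time()[3L] - t0))
  for (k in seq_along(bl)) {
    writeBlock(OmicsBlock(fit@J[[k]], paste0(names(bl)[k], "_joint"),
                          "expression_log"),
               file.path(out_dir, paste0(names(bl)[k], "_joint.tsv")))
    writeBlock(OmicsBlock(fit@I[[k]], paste0(names(bl)[k], "_individual"),
                          "expression_log"),
               file.path(out_dir, paste0(names(bl)[k], "_individual.tsv")))
  }
  scores <- jointScores(fit)
  if (ncol(scores)) {
    utils::write.table(data.frame(sample_id = sampleIds(coll), scores),
                       file.path(out_dir, "joint_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  t0 <- proc.time()[3L]
  y <- outcome(coll)
  binary <- nlevels(droplevels(y)) == 2L
  kind <- if (binary) "logistic" else "multinomial"
  integ <- buildIntegrativeFeatures(fit, covariates(coll), y,
                                    n_individual = n_individual)
  pca <- buildPCAFeatures(blocks(coll), covariates(coll), y, n_pcs = n_pcs)
  covOnly <- buildCovariateFeatures(covariates(coll), y)
  repInteg <- cvAUC(integ, kind, k = k_folds, seed = seeds[2L])
  repPCA <- cvAUC(pca, kind, k = k_folds, seed = seeds[2L])
  repCov <- cvAUC(covOnly, kind, k = k_folds, seed = seeds[2L])
  repForest <- randomForestEval(integ, n_trees = n_trees, seed = seeds[3L])
  repLasso <- if (binary)
    lassoProtocol(blocks(coll), covariates(coll), y,
                  repeats = lasso_repeats, seed = seeds[4L]) else NULL
  summary <- data.frame(
    model = c("integrative", "non_integrative_pca", "covariates_only",
              "random_forest_integrative",
              if (binary) "lasso"),
    mean_auc = c(meanAUC(repInteg), meanAUC(repPCA), meanAUC(repCov),
                 meanAUC(repForest), if (binary) meanAUC(repLasso)),
    in_sample_auc = c(repInteg@inSampleAUC, repPCA@inSampleAUC,
                      repCov@inSampleAUC, NA, if (binary) NA),
    accuracy = c(repInteg@accuracy, repPCA@accuracy, repCov@accuracy,
                 repForest@accuracy, if (binary) NA),
    oob_error_pct = c(NA, NA, NA, repForest@oobError, if (binary) NA))
  utils::write.table(summary, file.path(out_dir, "prediction_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(repForest@importance,
                     file.path(out_dir, "forest_importance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stamp("predict", list(summary = summary, cv_seed = seeds[2L],
                        forest_seed = seeds[3L],
                        lasso_seed = if (binary) seeds[4L] else NULL,
                        seconds = proc.time()[3L] - t0))

  outputs <- setdiff(list.files(out_dir, full.names = TRUE),
                     file.path(out_dir, "manifest.json"))
  manifest$checksums <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
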
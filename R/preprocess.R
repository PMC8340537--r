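#' @include methods.R
NULL

# Replace a block's value matrix, keeping name unless a new kind is given.
.replaceValues <- function(block, values, assayKind = block@assayKind) {
  OmicsBlock(values, block@name, assayKind)
}

.rowVar <- function(values) {
  apply(values, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) 0 else var(x)
  })
}

#' Keep the top-n most variable features
#'
#' Feature variance is computed over observed entries; exactly `top_n`
#' features are retained, ordered as in the input block.  Ties at the cut
#' are broken by lexicographic feature id, the smaller id winning.
#'
#' @param block an [OmicsBlock-class].
#' @param top_n number of features to keep; must not exceed the feature count.
#' @return list with `block` (filtered) and `report` (a
#'   [FilterReport-class]).
#' @export
varianceFilter <- function(block, top_n) {
  p <- nrow(block@values)
  if (top_n > p)
    stop("top_n (", top_n, ") exceeds the number of features (", p, ")")
  v <- .rowVar(block@values)
  ord <- order(-v, rownames(block@values), method = "radix")
  keepIds <- rownames(block@values)[ord[seq_len(top_n)]]
  keep <- rownames(block@values) %in% keepIds
  out <- .replaceValues(block, block@values[keep, , drop = FALSE])
  list(block = out,
       report = .addRule(.emptyReport(), "variance_top_n", p, sum(keep)))
}

#' Select CpGs by gene location, top variance, or their union
#'
#' Mirrors the methylation filtering strategy of combining CpGs located on a
#' selected gene set with the most variable CpGs.  Unmapped CpGs are treated
#' as lying on no selected gene.
#'
#' @param cpg_block an [OmicsBlock-class] of CpG features.
#' @param cpg_to_gene named character vector mapping CpG id to gene symbol;
#'   may be partial.
#' @param selected_genes character set of gene symbols (e.g. the genes of the
#'   variance-filtered mRNAs).
#' @param extra_top_n size of the top-variance CpG set added in the union.
#' @param variant `"location_and_variance"` (union, the default),
#'   `"location_only"`, or `"variance_only"`.
#' @return list with `block` and `report`; the report records the location
#'   subset size, the variance subset size and their overlap.
#' @export
geneLocationUnionFilter <- function(cpg_block, cpg_to_gene, selected_genes,
                                    extra_top_n = 0L,
                                    variant = c("location_and_variance",
                                                "location_only",
                                                "variance_only")) {
  variant <- match.arg(variant)
  ids <- rownames(cpg_block@values)
  p <- length(ids)
  genes <- cpg_to_gene[ids]
  locSet <- ids[!is.na(genes) & genes %in% selected_genes]
  varSet <- character(0)
  if (variant != "location_only" && extra_top_n > 0L) {
    v <- .rowVar(cpg_block@values)
    ord <- order(-v, ids, method = "radix")
    varSet <- ids[ord[seq_len(min(extra_top_n, p))]]
  }
  keepIds <- switch(variant,
    location_and_variance = union(locSet, varSet),
    location_only = locSet,
    variance_only = varSet)
  if (length(keepIds) == 0L)
    stop("empty selection: no CpG survives the '", variant, "' filter")
  keep <- ids %in% keepIds
  report <- .addRule(.emptyReport(), paste0("gene_location_", variant),
                     p, sum(keep))
  report@rules$location_set <- length(locSet)
  report@rules$variance_set <- length(varSet)
  report@rules$overlap <- length(intersect(locSet, varSet))
  list(block = .replaceValues(cpg_block,
                              cpg_block@values[keep, , drop = FALSE]),
       report = report)
}

#' Drop features with too much missingness
#'
#' Removes features whose fraction of missing samples is strictly greater
#' than `max_missing_frac` (default 0.40, i.e. "more than 40% missing").
#'
#' @inheritParams varianceFilter
#' @param max_missing_frac threshold in `[0, 1]`.
#' @return list with `block` and `report`.
#' @export
missingnessFilter <- function(block, max_missing_frac = 0.40) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  frac <- rowMeans(is.na(block@values))
  keep <- frac <= max_missing_frac            # strictly-greater are removed
  list(block = .replaceValues(block, block@values[keep, , drop = FALSE]),
       report = .addRule(.emptyReport(), "missingness", length(frac),
                         sum(keep)))
}

#' Methylation beta to M-value transform
#'
#' `M = log2(beta / (1 - beta))`, entrywise; betas of exactly 0 or 1 are
#' clipped by `offset` to avoid infinities.  Missing entries stay missing.
#'
#' @param block an [OmicsBlock-class] with `assayKind = "methylation_beta"`
#'   and observed values in `[0, 1]`.
#' @param offset clipping offset for boundary betas (default `1e-6`).
#' @return the transformed block with `assayKind = "methylation_m"`.
#' @export
betaToMValue <- function(block, offset = 1e-6) {
  if (block@assayKind != "methylation_beta")
    stop("betaToMValue expects a methylation_beta block, got ",
         block@assayKind)
  b <- block@values
  obs <- b[!is.na(b)]
  if (length(obs) && (any(obs < 0) || any(obs > 1)))
    stop("beta values outside [0, 1]")
  b <- pmin(pmax(b, offset), 1 - offset)
  .replaceValues(block, log2(b / (1 - b)), "methylation_m")
}

#' Exclude CpGs with extreme M-values
#'
#' A CpG is removed when its per-feature summary of `|M|` — the mean over
#' observed samples by default, or the maximum under the `"any"` rule —
#' strictly exceeds `bound`.
#'
#' @param block a `methylation_m` [OmicsBlock-class].
#' @param bound positive threshold (default 3).
#' @param rule `"mean"` (default) or `"any"` (remove if any entry exceeds).
#' @return list with `block` and `report`.
#' @export
extremeMValueFilter <- function(block, bound = 3, rule = c("mean", "any")) {
  rule <- match.arg(rule)
  if (block@assayKind != "methylation_m")
    stop("extremeMValueFilter expects a methylation_m block")
  s <- apply(abs(block@values), 1L, function(x)
    if (rule == "mean") mean(x, na.rm = TRUE) else max(x, na.rm = TRUE))
  keep <- s <= bound
  list(block = .replaceValues(block, block@values[keep, , drop = FALSE]),
       report = .addRule(.emptyReport(), paste0("extreme_M_", rule),
                         length(s), sum(keep)))
}

#' Counts-per-million filtering of a sequencing count block
#'
#' CPM is each count divided by its sample's library size times 1e6.
#' Features with mean CPM strictly below `min_cpm` are removed first (the
#' `"all"` rule instead requires CPM below the threshold in every sample);
#' features with zero counts in strictly more than `max_zero_samples`
#' samples are removed second.
#'
#' @param block a `counts` [OmicsBlock-class], fully observed.
#' @param min_cpm CPM threshold (default 1).
#' @param max_zero_samples allowed number of zero-count samples (default 5).
#' @param rule `"mean"` (default) or `"all"` for the CPM criterion.
#' @return list with `block` and `report`; the report itemizes both rules.
#' @export
cpmFilter <- function(block, min_cpm = 1, max_zero_samples = 5L,
                      rule = c("mean", "all")) {
  rule <- match.arg(rule)
  if (block@assayKind != "counts")
    stop("cpmFilter expects a counts block")
  v <- block@values
  lib <- colSums(v)
  if (any(lib == 0))
    stop("sample(s) with zero library size: ",
         paste(colnames(v)[lib == 0], collapse = ", "))
  cpm <- sweep(v, 2L, lib, "/") * 1e6
  p0 <- nrow(v)
  keep1 <- if (rule == "mean") rowMeans(cpm) >= min_cpm
           else apply(cpm, 1L, max) >= min_cpm
  report <- .addRule(.emptyReport(), paste0("cpm_", rule), p0, sum(keep1))
  v <- v[keep1, , drop = FALSE]
  nzero <- rowSums(v == 0)
  keep2 <- nzero <= max_zero_samples
  report <- .addRule(report, "zero_samples", nrow(v), sum(keep2))
  list(block = .replaceValues(block, v[keep2, , drop = FALSE]),
       report = report)
}

#' Entrywise log2 transform
#'
#' @param block an [OmicsBlock-class].
#' @param offset added before taking logs (default 0); `value + offset` must
#'   be positive wherever observed.
#' @return the transformed block with `assayKind = "expression_log"`.
#' @export
log2Transform <- function(block, offset = 0) {
  v <- block@values + offset
  obs <- v[!is.na(v)]
  if (any(obs <= 0))
    stop("non-positive value encountered at offset ", offset)
  .replaceValues(block, log2(v), "expression_log")
}

#' Iterative SVD imputation of missing entries
#'
#' Missing entries are initialized with feature means, then repeatedly
#' overwritten by the rank-`rank` truncated-SVD approximation of the
#' completed matrix until the relative Frobenius change of the imputed
#' entries drops below `tol` or `max_iter` is reached.  Observed entries are
#' never altered.
#'
#' @param block an [OmicsBlock-class]; every feature and sample must have at
#'   least one observed entry.
#' @param rank truncation rank of the iterate (default 10, capped at
#'   `min(p, n) - 1`).
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 200); non-convergence raises a
#'   warning and returns the last iterate.
#' @return the fully observed block, with attributes `iterations` and
#'   `converged`.
#' @export
svdmissImpute <- function(block, rank = 10L, tol = 1e-6, max_iter = 200L) {
  v <- block@values
  miss <- is.na(v)
  if (!any(miss)) {
    out <- block
    attr(out@values, "iterations") <- 0L
    attr(out@values, "converged") <- TRUE
    return(out)
  }
  if (any(rowSums(!miss) == 0L))
    stop("feature(s) with no observed entries cannot be imputed")
  if (any(colSums(!miss) == 0L))
    stop("sample(s) with no observed entries cannot be imputed")
  rank <- min(rank, dim(v) - 1L)
  rowMean <- rowMeans(v, na.rm = TRUE)
  filled <- v
  filled[miss] <- rowMean[row(v)[miss]]
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    sv <- svd(filled, nu = rank, nv = rank)
    approx <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    newImp <- approx[miss]
    delta <- sqrt(sum((newImp - filled[miss])^2)) /
      max(sqrt(sum(filled[miss]^2)), .Machine$double.eps)
    filled[miss] <- newImp
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("svdmissImpute did not converge in ", max_iter, " iterations")
  out <- .replaceValues(block, filled)
  attr(out@values, "iterations") <- iter
  attr(out@values, "converged") <- converged
  out
}

#' Mean-center every feature
#'
#' Each feature row is shifted to mean zero; no variance scaling is applied,
#' since the angle-based decomposition is insensitive to scale
#' heterogeneity across blocks.
#'
#' @param block a fully observed [OmicsBlock-class].
#' @return the centered block.
#' @export
centerFeatures <- function(block) {
  if (anyNA(block@values))
    stop("block has missing entries; impute before centering")
  .replaceValues(block, block@values - rowMeans(block@values))
}

#' Standard preprocessing chain for one block
#'
#' Applies the assay-appropriate sequence: for methylation betas —
#' missingness filter, M-value transform, extreme-M filter, SVD imputation,
#' centering; for counts — CPM filter, log2(x + 1), centering; for
#' already-log expression — optional variance filter, imputation if needed,
#' centering.
#'
#' @param block an [OmicsBlock-class].
#' @param top_n_variance optional variance-filter size for expression blocks.
#' @param max_missing_frac,m_value_bound,min_cpm,max_zero_samples,impute_rank
#'   rule thresholds (see the individual filters).
#' @return list with `block` (preprocessed, centered) and `report`.
#' @export
preprocessBlock <- function(block, top_n_variance = NULL,
                            max_missing_frac = 0.40, m_value_bound = 3,
                            min_cpm = 1, max_zero_samples = 5L,
                            impute_rank = 10L) {
  report <- .emptyReport()
  add <- function(r) {
    report@rules <<- rbind(report@rules, r@rules)
    report <<- new("FilterReport", rules = report@rules)
  }
  if (block@assayKind == "methylation_beta") {
    st <- missingnessFilter(block, max_missing_frac); add(st$report)
    block <- betaToMValue(st$block)
    st <- extremeMValueFilter(block, m_value_bound); add(st$report)
    block <- st$block
    if (anyNA(block@values)) block <- svdmissImpute(block, impute_rank)
  } else if (block@assayKind == "counts") {
    st <- cpmFilter(block, min_cpm, max_zero_samples); add(st$report)
    block <- log2Transform(st$block, offset = 1)
  } else {
    if (!is.null(top_n_variance)) {
      st <- varianceFilter(block, top_n_variance); add(st$report)
      block <- st$block
    }
    if (anyNA(block@values)) block <- svdmissImpute(block, impute_rank)
  }
  list(block = centerFeatures(block), report = report)
}
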
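#' @include methods.R
NULL

#' Configuration for the synthetic multi-block generator
#'
#' Defaults emulate a blood-based three-omics design at desk scale: a large
#' methylation-like block, a medium expression-like block and a small
#' miRNA-like count block, with strongly heterogeneous per-block scales, a
#' shared low-rank joint structure and block-specific individual structure.
#'
#' @param n_samples number of samples (default 150).
#' @param block_dims feature counts per block; the default `c(3000, 1000,
#'   150)` preserves the methylation >> mRNA >> miRNA dimensionality ordering.
#' @param joint_rank rank of the shared joint structure (default 2).
#' @param individual_ranks per-block individual ranks (default `c(3, 2, 2)`).
#' @param block_scales global multiplier per block, default `c(10, 1, 0.1)`
#'   to exercise scale heterogeneity across platforms.
#' @param snr per-block signal-to-noise ratio, measured as the Frobenius norm
#'   of the signal over that of the noise (default 5 for every block).
#' @param missing_frac fraction of entries removed completely at random from
#'   the blocks listed in `missing_blocks` (default 0).
#' @param missing_blocks integer indices of blocks receiving missingness.
#' @param count_block_index optional index of a block generated as
#'   overdispersed (negative-binomial, dispersion `count_dispersion`) counts
#'   whose log-mean is the latent low-rank signal; default `NA` (all blocks
#'   Gaussian).
#' @param count_dispersion negative-binomial dispersion for the count block.
#' @param outcome_kind `"binary"` or `"categorical4"`.
#' @param coef_joint coefficients on the (unit-variance) joint scores in the
#'   outcome linear predictor; length `joint_rank`.
#' @param coef_individual list of per-block coefficient vectors on the
#'   individual scores; lengths `individual_ranks`.
#' @param coef_covariates coefficients on the three standardized covariates
#'   (age, BMI, smoking analogues).
#' @param seed integer seed; the whole generation is reproducible from it.
#' @return a validated configuration list of class `syntheticConfig`.
#' @seealso [generateBlocks()], [generateOutcome()]
#' @export
syntheticConfig <- function(n_samples = 150L,
                            block_dims = c(3000L, 1000L, 150L),
                            joint_rank = 2L,
                            individual_ranks = c(3L, 2L, 2L),
                            block_scales = c(10, 1, 0.1),
                            snr = c(5, 5, 5),
                            missing_frac = 0,
                            missing_blocks = integer(0),
                            count_block_index = NA_integer_,
                            count_dispersion = 0.5,
                            outcome_kind = c("binary", "categorical4"),
                            coef_joint = NULL,
                            coef_individual = NULL,
                            coef_covariates = c(0.5, 0.3, 0.4),
                            seed = 1L) {
  outcome_kind <- match.arg(outcome_kind)
  K <- length(block_dims)
  if (is.null(coef_joint)) coef_joint <- rep(1.25, joint_rank)
  if (is.null(coef_individual))
    coef_individual <- lapply(individual_ranks, function(r)
      if (r > 0) c(0.8, rep(0, r - 1L)) else numeric(0))
  cfg <- list(n_samples = as.integer(n_samples),
              block_dims = as.integer(block_dims),
              joint_rank = as.integer(joint_rank),
              individual_ranks = as.integer(individual_ranks),
              block_scales = as.numeric(block_scales),
              snr = as.numeric(snr),
              missing_frac = missing_frac,
              missing_blocks = as.integer(missing_blocks),
              count_block_index = as.integer(count_block_index),
              count_dispersion = count_dispersion,
              outcome_kind = outcome_kind,
              coef_joint = as.numeric(coef_joint),
              coef_individual = lapply(coef_individual, as.numeric),
              coef_covariates = as.numeric(coef_covariates),
              seed = as.integer(seed))
  class(cfg) <- "syntheticConfig"
  .validateSyntheticConfig(cfg)
  cfg
}

.validateSyntheticConfig <- function(cfg) {
  K <- length(cfg$block_dims)
  bad <- function(field, why)
    stop("invalid synthetic configuration: field '", field, "' ", why,
         call. = FALSE)
  if (cfg$n_samples < 2L) bad("n_samples", "must be at least 2")
  if (any(cfg$block_dims < 1L)) bad("block_dims", "must be positive")
  if (length(cfg$individual_ranks) != K)
    bad("individual_ranks", "must have one entry per block")
  if (length(cfg$block_scales) != K)
    bad("block_scales", "must have one entry per block")
  if (length(cfg$snr) != K) bad("snr", "must have one entry per block")
  if (any(cfg$block_scales <= 0)) bad("block_scales", "must be positive")
  if (any(cfg$snr <= 0)) bad("snr", "must be positive")
  if (cfg$joint_rank < 0L) bad("joint_rank", "must be non-negative")
  if (any(cfg$individual_ranks < 0L))
    bad("individual_ranks", "must be non-negative")
  if (cfg$joint_rank + max(c(cfg$individual_ranks, 0L)) >= cfg$n_samples)
    bad("joint_rank", paste0("+ max(individual_ranks) must be < n_samples (",
                             cfg$n_samples, ")"))
  if (any(cfg$joint_rank + cfg$individual_ranks > cfg$block_dims))
    bad("block_dims", "must accommodate joint_rank + individual rank")
  if (cfg$missing_frac < 0 || cfg$missing_frac >= 1)
    bad("missing_frac", "must lie in [0, 1)")
  if (length(cfg$missing_blocks) &&
      any(cfg$missing_blocks < 1L | cfg$missing_blocks > K))
    bad("missing_blocks", "indices out of range")
  if (!is.na(cfg$count_block_index) &&
      (cfg$count_block_index < 1L || cfg$count_block_index > K))
    bad("count_block_index", "out of range")
  if (length(cfg$coef_joint) != cfg$joint_rank)
    bad("coef_joint", paste0("must have length joint_rank = ", cfg$joint_rank))
  if (length(cfg$coef_individual) != K)
    bad("coef_individual", "must have one vector per block")
  for (k in seq_len(K))
    if (length(cfg$coef_individual[[k]]) != cfg$individual_ranks[k])
      bad("coef_individual", paste0("vector ", k, " must have length ",
                                    cfg$individual_ranks[k]))
  if (length(cfg$coef_covariates) != 3L)
    bad("coef_covariates", "must have length 3 (age, BMI, smoking analogues)")
  invisible(cfg)
}

# Default block names by dimensionality role.
.syntheticBlockNames <- function(K) {
  base <- c("methylation", "mRNA", "miRNA")
  if (K <= 3L) base[seq_len(K)] else c(base, paste0("block", 4:K))[seq_len(K)]
}

#' Generate a synthetic multi-block dataset with known structure
#'
#' Draws a shared orthonormal joint score basis, per-block individual score
#' bases orthogonalized against the joint basis, Gaussian loadings and
#' additive Gaussian noise rescaled so each block's Frobenius
#' signal-to-noise ratio matches `snr` exactly; each block is then multiplied
#' by its global scale.  An optional block is rendered as overdispersed
#' counts, optional missingness is applied completely at random, covariates
#' (age, BMI, smoking analogues) are simulated and the outcome drawn via
#' [generateOutcome()].
#'
#' @param config a [syntheticConfig()].
#' @return list with elements `collection` (a
#'   [MultiOmicsCollection-class] carrying covariates and outcome) and
#'   `truth` (a [SyntheticTruth-class]).
#' @examples
#' cfg <- syntheticConfig(n_samples = 40, block_dims = c(60, 40),
#'                        joint_rank = 1, individual_ranks = c(1, 1),
#'                        block_scales = c(1, 1), snr = c(5, 5), seed = 7)
#' sim <- generateBlocks(cfg)
#' sim$collection
#' @export
generateBlocks <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  .validateSyntheticConfig(config)
  cfg <- config
  K <- length(cfg$block_dims)
  n <- cfg$n_samples
  rJ <- cfg$joint_rank
  set.seed(cfg$seed)

  sampleNames <- sprintf("S%03d", seq_len(n))
  blockNames <- .syntheticBlockNames(K)

  # Shared joint score basis and per-block individual bases orthogonal to it.
  SJ <- if (rJ > 0) .orth(matrix(rnorm(n * rJ), n, rJ)) else
    matrix(0, n, 0L)
  SI <- vector("list", K)
  for (k in seq_len(K)) {
    r <- cfg$individual_ranks[k]
    if (r > 0) {
      Z <- matrix(rnorm(n * r), n, r)
      if (rJ > 0) Z <- Z - SJ %*% crossprod(SJ, Z)
      SI[[k]] <- .orth(Z)
    } else SI[[k]] <- matrix(0, n, 0L)
  }

  LJ <- LI <- vector("list", K)
  noiseSD <- numeric(K)
  blocksOut <- vector("list", K)
  for (k in seq_len(K)) {
    p <- cfg$block_dims[k]
    LJ[[k]] <- matrix(rnorm(p * rJ), p, rJ)
    LI[[k]] <- matrix(rnorm(p * cfg$individual_ranks[k]), p,
                      cfg$individual_ranks[k])
    signal <- LJ[[k]] %*% t(SJ) + LI[[k]] %*% t(SI[[k]])
    noise <- matrix(rnorm(p * n), p, n)
    sigNorm <- .frobenius(signal)
    if (sigNorm > 0) {
      # Rescale the drawn noise so the realized Frobenius ratio is exact.
      target <- sigNorm / cfg$snr[k]
      noise <- noise * (target / .frobenius(noise))
      noiseSD[k] <- target / sqrt(p * n)
    } else {
      noiseSD[k] <- 1    # pure-noise block: unit noise
    }
    if (!is.na(cfg$count_block_index) && cfg$count_block_index == k) {
      # Counts: log-mean is a baseline plus the latent signal standardized
      # to unit spread, so library sizes stay realistic for a small RNA assay.
      lat <- signal
      s <- stats::sd(lat)
      if (s > 0) lat <- lat / s
      mu <- exp(log(50) + lat)
      vals <- matrix(stats::rnbinom(p * n, size = 1 / cfg$count_dispersion,
                                    mu = mu), p, n)
      kind <- "counts"
    } else {
      vals <- cfg$block_scales[k] * (signal + noise)
      kind <- "expression_log"
    }
    dimnames(vals) <- list(sprintf("%s_f%05d", blockNames[k], seq_len(p)),
                           sampleNames)
    if (k %in% cfg$missing_blocks && cfg$missing_frac > 0) {
      hide <- runif(length(vals)) < cfg$missing_frac
      vals[hide] <- NA
    }
    blocksOut[[k]] <- OmicsBlock(vals, blockNames[k], kind)
  }

  covs <- data.frame(age = rnorm(n, 55, 5), bmi = rnorm(n, 25, 3),
                     smoking = rbinom(n, 1L, 0.4),
                     row.names = sampleNames)

  truth <- new("SyntheticTruth", jointScoreBasis = SJ,
               individualScoreBases = SI, jointLoadings = LJ,
               individualLoadings = LI, noiseSD = noiseSD,
               outcomeLinpred = numeric(0), config = unclass(cfg))

  out <- generateOutcome(truth, covs, cfg)
  truth@outcomeLinpred <- out$linpred

  collection <- MultiOmicsCollection(blocksOut, covariates = covs,
                                     outcome = out$outcome)
  list(collection = collection, truth = truth)
}

#' Draw an outcome from the latent scores and covariates
#'
#' Binary outcomes are Bernoulli draws from a logistic link on the linear
#' predictor; 4-class outcomes are drawn from a softmax over four linear
#' predictors with class-specific random sign patterns on the same scores.
#' Scores enter standardized to unit variance (`sqrt(n)` times the
#' orthonormal basis columns), and covariates are standardized, so the
#' coefficients are on comparable scales.
#'
#' @param truth a [SyntheticTruth-class].
#' @param covariates data.frame with columns age, bmi, smoking.
#' @param config the [syntheticConfig()] holding the coefficients; drawing is
#'   reproducible from `config$seed`.
#' @return list with `outcome` (factor), `linpred` (numeric; for
#'   `categorical4`, the class-1 column).
#' @export
generateOutcome <- function(truth, covariates, config) {
  cfg <- config
  n <- nrow(truth@jointScoreBasis)
  if (n == 0L) n <- length(truth@outcomeLinpred)
  if (length(cfg$coef_joint) != ncol(truth@jointScoreBasis))
    stop("invalid synthetic configuration: field 'coef_joint' does not match ",
         "the joint score dimension")
  K <- length(truth@individualScoreBases)
  for (k in seq_len(K))
    if (length(cfg$coef_individual[[k]]) != ncol(truth@individualScoreBases[[k]]))
      stop("invalid synthetic configuration: field 'coef_individual' does ",
           "not match the individual score dimension of block ", k)
  Z <- cbind(truth@jointScoreBasis * sqrt(n),
             do.call(cbind, lapply(truth@individualScoreBases,
                                   function(S) S * sqrt(n))))
  beta <- c(cfg$coef_joint, unlist(cfg$coef_individual))
  X <- scale(as.matrix(covariates))
  X[is.nan(X)] <- 0
  linpred <- as.numeric(if (length(beta)) Z %*% beta else rep(0, n)) +
    as.numeric(X %*% cfg$coef_covariates)

  set.seed(cfg$seed + 1L)
  if (cfg$outcome_kind == "binary") {
    pr <- stats::plogis(linpred)
    y <- factor(ifelse(runif(n) < pr, "case", "control"),
                levels = c("control", "case"))
  } else {
    # Four classes: class-specific random sign flips of the shared predictor
    # give separated but overlapping classes; class 1 keeps the predictor.
    signs <- matrix(sample(c(-1, 1), 4L * max(length(beta), 1L),
                           replace = TRUE), nrow = 4L)
    signs[1L, ] <- 1
    eta <- sapply(1:4, function(g)
      as.numeric(if (length(beta)) Z %*% (signs[g, seq_along(beta)] * beta)
                 else rep(0, n)))
    eta <- eta + as.numeric(X %*% cfg$coef_covariates) %o% c(1, -1, 0.5, -0.5)
    p <- exp(eta - apply(eta, 1L, max))
    p <- p / rowSums(p)
    y <- factor(apply(p, 1L, function(pi) sample(4L, 1L, prob = pi)),
                levels = 1:4,
                labels = c("Basal", "Her2", "LumA", "LumB"))
    linpred <- eta[, 1L]
  }
  list(outcome = y, linpred = linpred)
}
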
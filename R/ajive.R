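#' @include methods.R
NULL

#' First-phase truncated SVD of a centered block
#'
#' Returns the top-`r_k` SVD factors of the block together with the first
#' discarded singular value (the block's noise threshold) and the full
#' discarded spectrum, which drives the Wedin perturbation resampling.
#'
#' @param block a centered, fully observed [OmicsBlock-class].
#' @param r_k truncation rank, `1 <= r_k < min(p_k, n)`.
#' @return a [BlockSVD-class].
#' @export
truncatedBlockSVD <- function(block, r_k) {
  v <- block@values
  if (anyNA(v)) stop("block must be fully observed")
  m <- min(dim(v))
  if (r_k < 1L || r_k >= m)
    stop("rank r_k = ", r_k, " out of range [1, ", m - 1L, "] for block '",
         block@name, "'")
  sv <- svd(v)
  keep <- seq_len(r_k)
  new("BlockSVD", name = block@name, rank = as.integer(r_k),
      leftBasis = sv$u[, keep, drop = FALSE],
      singularValues = sv$d[keep],
      rowBasis = sv$v[, keep, drop = FALSE],
      noiseThreshold = if (m > r_k) sv$d[r_k + 1L] else 0,
      discarded = if (m > r_k) sv$d[(r_k + 1L):m] else numeric(0))
}

#' SVD of the stacked row-basis matrices
#'
#' Vertically stacks the transposed row bases of all blocks (a
#' `sum(r_k) x n` matrix) and computes its SVD.  The squared singular values
#' lie in `[0, K]` and equal sums of squared cosines of principal angles
#' between the block row spaces; the right singular vectors are the
#' candidate joint directions, in decreasing order of sharedness.
#'
#' @param svds list of at least two [BlockSVD-class] objects on the same n.
#' @return list with `squaredSingularValues` and `candidateBasis` (n x
#'   min(sum r_k, n), orthonormal columns).
#' @export
stackedBasisSVD <- function(svds) {
  if (length(svds) < 2L) stop("need at least 2 blocks")
  ns <- vapply(svds, function(s) nrow(s@rowBasis), integer(1))
  if (length(unique(ns)) != 1L)
    stop("blocks disagree on the number of samples: ",
         paste(ns, collapse = ", "))
  M <- do.call(rbind, lapply(svds, function(s) t(s@rowBasis)))
  sv <- svd(M)
  list(squaredSingularValues = sv$d^2, candidateBasis = sv$v)
}

# Resample the operator norm of the discarded spectrum hit by a random
# orthonormal r-frame: a uniformly random basis in the orthocomplement of
# the estimated signal space projects the block onto its discarded SVD part
# only, so the perturbation norm reduces to ||diag(d_disc) %*% C|| with C a
# random (m x r) orthonormal coordinate matrix.
.perturbationNorm <- function(discarded, r) {
  m <- length(discarded)
  if (m == 0L || all(discarded == 0)) return(0)
  r <- min(r, m)
  C <- .orth(matrix(rnorm(m * r), m, r))
  .opNorm(discarded * C)
}

#' Wedin perturbation threshold for the joint rank
#'
#' For every block, the sine of the largest principal angle between the
#' estimated and true signal row space is bounded through resampled
#' perturbation norms of the discarded spectrum divided by the smallest
#' retained singular value (capped at 1).  Per draw the block sines combine
#' into a squared-singular-value bound `K - sum_k sin^2(theta_k)`; the
#' returned threshold is the conservative 5% quantile across draws, clipped
#' to `[0, K]`.  Noiseless blocks give sine 0 and threshold `K`.
#'
#' @param svds list of [BlockSVD-class] objects.
#' @param n_resample number of resampling draws (default 400).
#' @param seed integer seed; identical seeds give identical thresholds.
#' @return the threshold (single number in `[0, K]`).
#' @export
wedinBound <- function(svds, n_resample = 400L, seed = 1L) {
  if (n_resample < 2L) stop("n_resample must be at least 2")
  K <- length(svds)
  set.seed(seed)
  sin2 <- matrix(0, n_resample, K)
  for (k in seq_len(K)) {
    s <- svds[[k]]
    sigmaMin <- min(s@singularValues)
    for (i in seq_len(n_resample)) {
      u <- .perturbationNorm(s@discarded, s@rank)
      v <- .perturbationNorm(s@discarded, s@rank)
      sin2[i, k] <- min(max(u, v) / sigmaMin, 1)^2
    }
  }
  bound <- stats::quantile(K - rowSums(sin2), probs = 0.05, names = FALSE)
  min(max(bound, 0), K)
}

#' Random-direction threshold for the joint rank
#'
#' Monte-Carlo null: draws K independent uniformly random orthonormal bases
#' of the given ranks in dimension n, stacks them as in
#' [stackedBasisSVD()], and records the top squared singular value; returns
#' the requested quantile across draws.
#'
#' @param ranks per-block ranks, each `< n`.
#' @param n number of samples.
#' @param n_draws Monte-Carlo draws (default 400).
#' @param quantile_prob quantile reported (default 0.95).
#' @param seed integer seed.
#' @return the threshold (single number).
#' @export
randomDirectionBound <- function(ranks, n, n_draws = 400L,
                                 quantile_prob = 0.95, seed = 1L) {
  if (any(ranks >= n)) stop("every rank must be smaller than n")
  stopifnot(quantile_prob > 0, quantile_prob < 1)
  set.seed(seed)
  tops <- vapply(seq_len(n_draws), function(i) {
    M <- do.call(rbind, lapply(ranks, function(r)
      t(.orth(matrix(rnorm(n * r), n, r)))))
    .opNorm(M)^2
  }, numeric(1))
  stats::quantile(tops, probs = quantile_prob, names = FALSE)
}

#' Select the joint rank from the stacked-basis spectrum
#'
#' The joint rank is the number of squared singular values strictly
#' exceeding `max(t_wedin, t_random)`, capped at the smallest block rank.
#' When the Wedin threshold equals K exactly (noiseless blocks, zero
#' perturbation) exceedance is evaluated as `>= K - 1e-10`, so perfectly
#' shared directions — which attain exactly K — are retained.
#'
#' @param squared_svs descending squared singular values from
#'   [stackedBasisSVD()].
#' @param t_wedin,t_random the two thresholds.
#' @param ranks the per-block initial ranks (for the cap); defaults to no
#'   cap.
#' @return the joint rank `r_J` (integer, possibly 0).
#' @export
selectJointRank <- function(squared_svs, t_wedin, t_random,
                            ranks = NULL) {
  K <- NULL
  thr <- max(t_wedin, t_random)
  if (!is.null(ranks)) K <- length(ranks)
  if (!is.null(K) && t_wedin >= K - 1e-10) {
    rJ <- sum(squared_svs >= K - 1e-10)
  } else {
    rJ <- sum(squared_svs > thr)
  }
  if (!is.null(ranks)) rJ <- min(rJ, min(ranks))
  as.integer(rJ)
}

#' Project blocks onto the joint basis
#'
#' `J_k = X_k V_J V_J^T`: each block's rows are projected onto the span of
#' the common normalized scores.
#'
#' @param blocks list of centered [OmicsBlock-class] objects.
#' @param V_J n x r_J joint row basis with orthonormal columns.
#' @return list with per-block `J` matrices, `loadings` (`X_k V_J`), and
#'   the shared `scores = V_J`.
#' @export
extractJoint <- function(blocks, V_J) {
  n <- ncol(blocks[[1L]]@values)
  if (nrow(V_J) != n && ncol(V_J) > 0L)
    stop("joint basis dimension (", nrow(V_J),
         ") does not match sample count (", n, ")")
  J <- loadings <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    X <- blocks[[k]]@values
    if (ncol(V_J) == 0L) {
      J[[k]] <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
      loadings[[k]] <- matrix(0, nrow(X), 0L)
    } else {
      L <- X %*% V_J
      J[[k]] <- L %*% t(V_J)
      dimnames(J[[k]]) <- dimnames(X)
      loadings[[k]] <- L
    }
  }
  list(J = J, loadings = loadings, scores = V_J)
}

#' Extract one block's individual component by orthonormal basis subtraction
#'
#' The joint part is removed (`R_k = X_k - J_k`), the remainder's SVD is
#' truncated at the number of singular values strictly exceeding the block's
#' first-phase noise threshold (capped at `r_k`), and the reconstruction is
#' re-projected off the joint basis so individual-vs-joint orthogonality
#' holds exactly.
#'
#' @param block a centered [OmicsBlock-class].
#' @param J_k the block's joint component matrix.
#' @param noise_threshold the block's first discarded singular value.
#' @param V_J the joint row basis (for the exact re-projection).
#' @param max_rank optional cap on the individual rank (the block's initial
#'   rank).
#' @return list with `I`, `E`, `rank`, `scores` (n x rank, right singular
#'   vectors scaled by singular values, decreasing), `loadings` (p_k x rank).
#' @export
extractIndividual <- function(block, J_k, noise_threshold, V_J = NULL,
                              max_rank = Inf) {
  X <- block@values
  R <- X - J_k
  if (!is.null(V_J) && ncol(V_J) > 0L)
    R <- R - (R %*% V_J) %*% t(V_J)
  sv <- svd(R)
  # Guard against numerically-zero singular values when the threshold is 0:
  # the floor is relative to the original block's scale, not the remainder's,
  # so a remainder that is pure floating-point residue yields rank 0.
  eps <- max(dim(R)) * .Machine$double.eps * max(.frobenius(X), sv$d, 0)
  r <- sum(sv$d > max(noise_threshold, eps))
  r <- min(r, max_rank)
  if (r == 0L) {
    I_k <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
    scores <- matrix(0, ncol(X), 0L)
    loadings <- matrix(0, nrow(X), 0L)
  } else {
    keep <- seq_len(r)
    U <- .fixSigns(sv$u[, keep, drop = FALSE])
    V <- sv$v[, keep, drop = FALSE]
    # Keep U V^T consistent after the sign fix on U.
    for (j in keep) if (sum(U[, j] * sv$u[, j]) < 0) V[, j] <- -V[, j]
    I_k <- U %*% (sv$d[keep] * t(V))
    dimnames(I_k) <- dimnames(X)
    scores <- V %*% diag(sv$d[keep], r)
    loadings <- U
  }
  list(I = I_k, E = X - J_k - I_k, rank = as.integer(r),
       scores = scores, loadings = loadings)
}

.varianceRow <- function(J_k, I_k, X) {
  tot <- sum(X^2)
  if (tot == 0) stop("zero-norm block: variance proportions undefined")
  j <- sum(J_k^2) / tot
  i <- sum(I_k^2) / tot
  c(joint = j, individual = i, residual = 1 - j - i)
}

#' Angle-based joint-and-individual decomposition
#'
#' Runs the three phases on a collection of centered blocks: per-block
#' truncated SVD at the initial ranks; principal-angle analysis of the
#' stacked row bases with Wedin and random-direction thresholds selecting
#' the joint rank; projection onto the joint basis and orthonormal basis
#' subtraction yielding the per-block joint, individual and residual
#' components.
#'
#' @param collection a [MultiOmicsCollection-class] with at least two
#'   centered, fully observed blocks.
#' @param initialRanks a [RankSelection-class] (e.g. from
#'   [selectInitialRanks()]) or a plain integer vector of per-block ranks.
#' @param n_resample Wedin resampling draws (default 400).
#' @param n_draws random-direction Monte-Carlo draws (default 400).
#' @param quantile_prob random-direction quantile (default 0.95).
#' @param seed integer seed for both thresholds.
#' @return an [AjiveResult-class].
#' @examples
#' cfg <- syntheticConfig(n_samples = 40, block_dims = c(80, 50),
#'                        joint_rank = 1, individual_ranks = c(1, 1),
#'                        block_scales = c(1, 1), snr = c(8, 8), seed = 3)
#' coll <- centerCollection(generateBlocks(cfg)$collection)
#' fit <- ajive(coll, c(methylation = 2, mRNA = 2), seed = 3)
#' jointRank(fit)
#' @export
ajive <- function(collection, initialRanks, n_resample = 400L,
                  n_draws = 400L, quantile_prob = 0.95, seed = 1L) {
  bl <- blocks(collection)
  K <- length(bl)
  if (K < 2L)
    stop("joint structure undefined for a single block (K = ", K, ")")
  ranks <- if (is(initialRanks, "RankSelection"))
    initialRanks@initialRanks else as.integer(initialRanks)
  if (length(ranks) != K)
    stop("need one initial rank per block")
  names(ranks) <- names(bl)

  # Phase 1: per-block truncated SVD.
  svds <- lapply(seq_len(K), function(k)
    truncatedBlockSVD(bl[[k]], ranks[k]))

  # Phase 2: stacked row-basis SVD + thresholds.
  stacked <- stackedBasisSVD(svds)
  seeds <- .subSeeds(seed, 2L)
  tWedin <- wedinBound(svds, n_resample = n_resample, seed = seeds[1L])
  n <- ncol(bl[[1L]]@values)
  tRandom <- randomDirectionBound(ranks, n, n_draws = n_draws,
                                  quantile_prob = quantile_prob,
                                  seed = seeds[2L])
  rJ <- selectJointRank(stacked$squaredSingularValues, tWedin, tRandom,
                        ranks = ranks)
  V_J <- .fixSigns(stacked$candidateBasis[, seq_len(rJ), drop = FALSE])

  # Phase 3: projection and orthonormal basis subtraction.
  joint <- extractJoint(bl, V_J)
  indiv <- lapply(seq_len(K), function(k)
    extractIndividual(bl[[k]], joint$J[[k]], svds[[k]]@noiseThreshold,
                      V_J = V_J, max_rank = ranks[k]))

  ve <- t(vapply(seq_len(K), function(k)
    .varianceRow(joint$J[[k]], indiv[[k]]$I, bl[[k]]@values), numeric(3)))
  rownames(ve) <- names(bl)
  colnames(ve) <- c("joint", "individual", "residual")

  js <- new("JointStructure", rank = rJ, rowBasis = V_J,
            squaredSingularValues = stacked$squaredSingularValues,
            wedinThreshold = tWedin, randomThreshold = tRandom)
  new("AjiveResult", blockNames = names(bl),
      J = joint$J, I = lapply(indiv, `[[`, "I"),
      E = lapply(indiv, `[[`, "E"),
      individualRanks = vapply(indiv, `[[`, integer(1), "rank"),
      jointLoadings = joint$loadings,
      individualScores = lapply(indiv, `[[`, "scores"),
      individualLoadings = lapply(indiv, `[[`, "loadings"),
      joint = js, varianceExplained = ve,
      initialRanks = ranks,
      provenance = list(seed = seed, subSeeds = seeds,
                        n_resample = n_resample, n_draws = n_draws,
                        quantile_prob = quantile_prob,
                        noiseThresholds = vapply(svds, slot, numeric(1),
                                                 "noiseThreshold")))
}

#' Center every block of a collection
#'
#' @param collection a [MultiOmicsCollection-class] of fully observed blocks.
#' @return the collection with every feature mean-centered.
#' @export
centerCollection <- function(collection) {
  bl <- lapply(blocks(collection), centerFeatures)
  MultiOmicsCollection(bl, covariates = covariates(collection),
                       outcome = outcome(collection))
}

#' Variance-explained proportions of a decomposition
#'
#' Per block: `joint = ||J_k||_F^2 / ||X_k||_F^2`, `individual =
#' ||I_k||_F^2 / ||X_k||_F^2`, `residual = 1 - joint - individual`.
#'
#' @param result an [AjiveResult-class].
#' @param originals list of the original centered [OmicsBlock-class]
#'   objects (defaults to reconstructing `X_k = J_k + I_k + E_k`).
#' @return K x 3 matrix of proportions, rows summing to 1.
#' @export
computeVarianceExplained <- function(result, originals = NULL) {
  K <- length(result@blockNames)
  X <- if (is.null(originals))
    lapply(seq_len(K), function(k) result@J[[k]] + result@I[[k]] +
             result@E[[k]])
  else lapply(originals, function(b) b@values)
  ve <- t(vapply(seq_len(K), function(k)
    .varianceRow(result@J[[k]], result@I[[k]], X[[k]]), numeric(3)))
  rownames(ve) <- result@blockNames
  colnames(ve) <- c("joint", "individual", "residual")
  ve
}
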
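# Internal linear-algebra and evaluation helpers shared across modules.

#' @importFrom stats rnorm sd var quantile dnorm rbinom runif predict
#' @importFrom methods new validObject is slot
NULL

# Orthonormalize the columns of M (n x r) via QR.  Returns an n x r matrix
# with orthonormal columns; r = 0 passes through.
.orth <- function(M) {
  if (is.null(dim(M))) M <- matrix(M, ncol = 1L)
  if (ncol(M) == 0L) return(M)
  qr.Q(qr(M))[, seq_len(ncol(M)), drop = FALSE]
}

# Deterministic sign convention: the largest-magnitude entry of every column
# is made positive.  Ties resolved by the first such entry.
.fixSigns <- function(B) {
  if (length(B) == 0L || ncol(B) == 0L) return(B)
  for (j in seq_len(ncol(B))) {
    i <- which.max(abs(B[, j]))
    if (B[i, j] < 0) B[, j] <- -B[, j]
  }
  B
}

.frobenius <- function(M) sqrt(sum(M * M))

# Operator (spectral) norm; 0 for degenerate inputs.
.opNorm <- function(M) {
  if (length(M) == 0L) return(0)
  if (is.null(dim(M))) M <- matrix(M, ncol = 1L)
  if (min(dim(M)) == 0L) return(0)
  svd(M, nu = 0L, nv = 0L)$d[1L]
}

# Principal angles (radians, increasing) between the column spans of two
# matrices with orthonormal columns.
.principalAngles <- function(A, B) {
  if (ncol(A) == 0L || ncol(B) == 0L) return(numeric(0))
  s <- svd(crossprod(A, B), nu = 0L, nv = 0L)$d
  s <- pmin(pmax(s, 0), 1)
  sort(acos(s))
}

# Midrank (Mann-Whitney) AUC of scores against a binary label vector whose
# positive class is levels(labels)[2] for factors, or the maximum value.
.binaryAUC <- function(scores, labels) {
  if (is.factor(labels)) {
    pos <- labels == levels(labels)[2L]
  } else {
    pos <- labels == max(labels)
  }
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("binary AUC needs both classes present")
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment: within every class, samples are shuffled and
# dealt cyclically, so per-fold class counts differ from balance by at most 1.
.stratifiedFolds <- function(y, k, seed) {
  y <- as.factor(y)
  if (any(table(y) < k)) {
    stop("stratification error: a class has fewer than k = ", k, " samples")
  }
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# ROC points (FPR, TPR) from scores for a binary outcome; used for the
# in-sample ROC curves reported next to cross-validated AUCs.
.rocPoints <- function(scores, labels) {
  if (is.factor(labels)) {
    pos <- labels == levels(labels)[2L]
  } else {
    pos <- labels == max(labels)
  }
  ord <- order(scores, decreasing = TRUE)
  tpr <- cumsum(pos[ord]) / sum(pos)
  fpr <- cumsum(!pos[ord]) / sum(!pos)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

# Derive a stream of distinct 32-bit sub-seeds from one master seed.
.subSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
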
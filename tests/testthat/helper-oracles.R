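# Independent oracles and small constructors used across the suite.
# Oracles are deliberately naive (loops, enumeration) and share no code with
# the implementation paths they check.

# Two-group Gaussian profile log-likelihood of a scree at split q, written
# as a direct transcription of the model definition.
oracleProfileLoglik <- function(values, q) {
  L <- length(values)
  g1 <- values[1:q]
  g2 <- values[(q + 1):L]
  m1 <- mean(g1)
  m2 <- mean(g2)
  pooled <- (sum((g1 - m1)^2) + sum((g2 - m2)^2)) / L
  if (pooled <= 0) pooled <- .Machine$double.eps
  ll <- 0
  for (v in g1) ll <- ll + dnorm(v, m1, sqrt(pooled), log = TRUE)
  for (v in g2) ll <- ll + dnorm(v, m2, sqrt(pooled), log = TRUE)
  ll
}

oracleProfileRank <- function(values, max_rank) {
  ll <- sapply(seq_len(max_rank), function(q) oracleProfileLoglik(values, q))
  which.max(ll)
}

# All-pairs Mann-Whitney AUC (ties count 1/2).
oracleAUC <- function(scores, positive) {
  pos <- which(positive)
  neg <- which(!positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# A named feature-by-sample matrix with reproducible content.
toyMatrix <- function(p, n, seed = 1, prefix = "f") {
  set.seed(seed)
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(p)),
                              sprintf("s%03d", seq_len(n))))
  m
}

toyBlock <- function(p, n, seed = 1, kind = "expression_log",
                     name = "toy") {
  OmicsBlock(toyMatrix(p, n, seed), name, kind)
}

# A block with an exactly planted row space: rows are random combinations
# of the given orthonormal score basis (n x r).  With a mean-zero basis
# (randBasis default) the rows are already feature-centered, so the planted
# row space survives centering exactly.
plantedBlock <- function(p, basis, seed = 1, name = "planted",
                         noise_sd = 0) {
  set.seed(seed)
  n <- nrow(basis)
  L <- matrix(rnorm(p * ncol(basis)), p, ncol(basis))
  X <- L %*% t(basis)
  if (noise_sd > 0) X <- X + noise_sd * matrix(rnorm(p * n), p, n)
  dimnames(X) <- list(sprintf("%s_f%03d", name, seq_len(p)),
                      sprintf("s%03d", seq_len(n)))
  OmicsBlock(X, name, "expression_log")
}

# Random orthonormal n x r basis; by default its columns are orthogonal to
# the all-ones vector so that feature centering leaves planted spans intact.
randBasis <- function(n, r, seed = 1, center = TRUE) {
  set.seed(seed)
  Z <- matrix(rnorm(n * r), n, r)
  if (center) Z <- Z - matrix(colMeans(Z), n, r, byrow = TRUE)
  qr.Q(qr(Z))[, seq_len(r), drop = FALSE]
}

maxPrincipalAngle <- function(A, B) {
  if (ncol(A) == 0 || ncol(B) == 0) return(NA_real_)
  s <- svd(crossprod(A, B))$d
  max(acos(pmin(pmax(s, 0), 1)))
}

# Collection of two planted centered blocks on shared samples.
twoBlockCollection <- function(b1, b2) {
  MultiOmicsCollection(list(b1, b2))
}
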
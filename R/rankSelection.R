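#' @include methods.R
NULL

#' Profile-likelihood rank from a singular-value scree
#'
#' For each candidate rank `q` the scree is split into a signal group
#' (values `1..q`) and a noise group (`q+1..L`); both are modelled as
#' Gaussian with their own means and a pooled maximum-likelihood variance.
#' The selected rank maximizes the summed Gaussian log-density; ties go to
#' the smallest `q`.
#'
#' @param values non-increasing, non-negative singular values (length >= 3).
#' @param max_rank largest candidate rank, `< length(values)`.
#' @return list with `rank` and `loglik` (the full curve over
#'   `1..max_rank`).
#' @examples
#' profileLikelihoodRank(c(10, 9.8, 1.0, 0.9, 0.8), 4)$rank  # 2
#' @export
profileLikelihoodRank <- function(values, max_rank = length(values) - 1L) {
  L <- length(values)
  if (L < 3L) stop("need at least 3 singular values, got ", L)
  if (max_rank >= L) stop("max_rank must be smaller than the number of values")
  if (max_rank < 1L) stop("max_rank must be at least 1")
  if (is.unsorted(rev(values))) stop("values must be non-increasing")
  if (stats::sd(values) == 0) {
    warning("degenerate scree: all singular values equal; returning rank 1")
    return(list(rank = 1L, loglik = rep(NA_real_, max_rank)))
  }
  loglik <- vapply(seq_len(max_rank), function(q) {
    g1 <- values[seq_len(q)]
    g2 <- values[(q + 1L):L]
    m1 <- mean(g1); m2 <- mean(g2)
    s2 <- (sum((g1 - m1)^2) + sum((g2 - m2)^2)) / L   # pooled MLE variance
    if (s2 <= 0) s2 <- .Machine$double.eps
    sum(dnorm(g1, m1, sqrt(s2), log = TRUE)) +
      sum(dnorm(g2, m2, sqrt(s2), log = TRUE))
  }, numeric(1))
  list(rank = which.max(loglik), loglik = loglik)
}

#' Select initial block ranks by profile likelihood
#'
#' Computes each (centered) block's singular values and applies
#' [profileLikelihoodRank()] with `max_rank = floor(max_rank_frac *
#' min(p_k, n)) - 1`.  Per-block manual overrides support sensitivity
#' analyses over the initial-rank choice.
#'
#' @param collection a [MultiOmicsCollection-class] of centered blocks.
#' @param max_rank_frac fraction of the spectrum admitted as candidate ranks
#'   (default 0.5, avoiding scree-boundary artifacts).
#' @param overrides named integer vector (`block name -> rank`) of imposed
#'   ranks.
#' @return a [RankSelection-class].
#' @export
selectInitialRanks <- function(collection, max_rank_frac = 0.5,
                               overrides = integer(0)) {
  stopifnot(max_rank_frac > 0, max_rank_frac <= 1)
  bl <- blocks(collection)
  ranks <- integer(length(bl))
  names(ranks) <- names(bl)
  svals <- curves <- vector("list", length(bl))
  names(svals) <- names(curves) <- names(bl)
  for (k in seq_along(bl)) {
    v <- bl[[k]]@values
    d <- svd(v, nu = 0L, nv = 0L)$d
    svals[[k]] <- d
    if (!is.null(names(overrides)) && names(bl)[k] %in% names(overrides)) {
      ranks[k] <- as.integer(overrides[[names(bl)[k]]])
      curves[[k]] <- numeric(0)
      next
    }
    mr <- max(1L, as.integer(floor(max_rank_frac * min(dim(v)))) - 1L)
    mr <- min(mr, length(d) - 1L)
    pl <- tryCatch(profileLikelihoodRank(d, mr),
                   error = function(e)
                     stop("rank selection failed for block '", names(bl)[k],
                          "': ", conditionMessage(e)))
    ranks[k] <- pl$rank
    curves[[k]] <- pl$loglik
  }
  new("RankSelection", initialRanks = ranks, singularValues = svals,
      profileLoglik = curves,
      overrides = vapply(overrides, as.integer, integer(1)))
}
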
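#' @importFrom methods as is
#' @importFrom stats cor dist hclust median p.adjust pnorm quantile rbinom
#'   rlnorm rnbinom rpois runif sd setNames var qbinom
#' @importFrom utils combn read.table write.table
#' @rawNamespace S3method(print, cell_matrix)
#' @rawNamespace S3method(print, peak_data)
#' @rawNamespace S3method(print, grn_network)
#' @rawNamespace S3method(print, sim_config)
#' @rawNamespace S3method(print, sim_dataset)
#' @rawNamespace S3method(print, normalized_matrix)
#' @rawNamespace S3method(print, embedding)
#' @rawNamespace S3method(print, neighbor_graph)
#' @rawNamespace S3method(print, cluster_assignment)
#' @rawNamespace S3method(print, periodicity_result)
#' @rawNamespace S3method(print, coexpr_result)
#' @rawNamespace S3method(print, motif_deviation)
#' @rawNamespace S3method(print, contribution_table)
NULL

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Vectorised one-vs-rest Wilcoxon rank-sum tests.
#
# `values`: numeric matrix (features x cells); `in_group`: logical per cell.
# Ranks are computed once per feature; the normal approximation with tie
# correction and continuity correction is used unless both group sizes are
# <= `exact_max`, in which case the exact distribution is used (enumeration
# under ties, stats::[pq]wilcox otherwise). Returns two-sided p-values.
rank_sum_p <- function(values, in_group, exact_max = 8L) {
  n <- length(in_group)
  n1 <- sum(in_group)
  n2 <- n - n1
  if (n1 == 0L || n2 == 0L) stopf("rank-sum test needs both groups non-empty")
  if (n1 <= exact_max && n2 <= exact_max) {
    return(apply(values, 1L, rank_sum_exact_p, in_group = in_group))
  }
  ranks <- t(apply(values, 1L, rank))
  w <- as.vector(ranks %*% in_group) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_term <- apply(ranks, 1L, function(r) {
    t <- tabulate(match(r, unique(r)))
    sum(t^3 - t)
  })
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- w - mu
  cc <- sign(z) * 0.5
  p <- 2 * pnorm(-abs((z - cc) / sqrt(pmax(sigma2, .Machine$double.eps))))
  p[sigma2 == 0] <- 1
  pmin(p, 1)
}

rank_sum_exact_p <- function(x, in_group) {
  r <- rank(x)
  n1 <- sum(in_group)
  if (length(unique(x)) == length(x)) {
    # no ties: use the exact Mann-Whitney distribution
    w <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    p <- 2 * min(stats::pwilcox(w, n1, length(x) - n1),
                 stats::pwilcox(w - 1, n1, length(x) - n1, lower.tail = FALSE))
    return(min(p, 1))
  }
  obs <- sum(r[in_group])
  mu <- n1 * (length(x) + 1) / 2
  sums <- combn(r, n1, sum)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}

# log2 fold change on the expm1 scale with pseudocount 1
log2fc_expm1 <- function(mean_in, mean_out, pseudocount = 1) {
  log2((mean_in + pseudocount) / (mean_out + pseudocount))
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

as_dense <- function(m) {
  if (is(m, "Matrix")) as.matrix(m) else m
}
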
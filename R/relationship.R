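#' Pedigree additive (numerator) relationship matrix
#'
#' Tabular method, processing individuals in pedigree (topological) order:
#' for individual j with parents s and d,
#' `A[i, j] = 0.5 * (A[i, s] + A[i, d])` for all earlier i, and
#' `A[j, j] = 1 + 0.5 * A[s, d]`; an unknown parent contributes 0.
#' Inbreeding is therefore handled implicitly by the recursion.
#'
#' @param pedigree Topologically ordered pedigree (`id`, `sire`, `dam`;
#'   `"0"` = unknown).
#' @return Symmetric n x n numeric matrix with ids as dimnames.
#' @examples
#' ped <- data.frame(id = c("s", "d", "o"), sire = c("0", "0", "s"),
#'                   dam = c("0", "0", "d"))
#' build_A(ped)
#' @export
build_A <- function(pedigree) {
  parents <- validate_pedigree(pedigree)
  n <- nrow(pedigree)
  A <- matrix(0, n, n, dimnames = list(pedigree$id, pedigree$id))
  s <- parents$sire
  d <- parents$dam
  for (j in seq_len(n)) {
    if (j > 1L) {
      prev <- seq_len(j - 1L)
      a_s <- if (is.na(s[j])) 0 else A[prev, s[j]]
      a_d <- if (is.na(d[j])) 0 else A[prev, d[j]]
      A[prev, j] <- 0.5 * (a_s + a_d)
      A[j, prev] <- A[prev, j]
    }
    f <- if (!is.na(s[j]) && !is.na(d[j])) 0.5 * A[s[j], d[j]] else 0
    A[j, j] <- 1 + f
  }
  A
}

#' Cluster individuals into cross-validation groups by relatedness
#'
#' K-means clustering with each individual's feature vector being its row of
#' the additive relationship matrix, so that groups collect related animals
#' (high within-group, low between-group relationship). Standard K-means
#' (Hartigan-Wong) with `n_restarts` random initializations is used and the
#' best within-cluster sum of squares kept; should a restart end with an
#' empty or failed cluster the whole fit is re-seeded, up to `max_retries`
#' times.
#'
#' @param A Relationship matrix from [build_A()].
#' @param K Number of groups (default 6).
#' @param n_restarts Random initializations per attempt.
#' @param seed Integer seed; results are deterministic given the seed.
#' @param max_retries Re-seeding attempts on failure.
#' @return Named integer vector of group labels in `1..K`.
#' @export
kmeans_groups <- function(A, K = 6, n_restarts = 10, seed = 1,
                          max_retries = 5) {
  n <- nrow(A)
  if (K < 2 || K > n) stop("K must satisfy 2 <= K <= n")
  if (K == n) {  # degenerate: every individual its own group
    return(stats::setNames(seq_len(n), rownames(A)))
  }
  for (attempt in 0:max_retries) {
    set.seed(seed + attempt)
    fit <- tryCatch(
      stats::kmeans(A, centers = K, nstart = n_restarts, iter.max = 100),
      error = function(e) e
    )
    if (!inherits(fit, "error") && all(fit$size > 0)) {
      groups <- as.integer(fit$cluster)
      names(groups) <- rownames(A)
      return(groups)
    }
  }
  stop("k-means failed to produce ", K, " non-empty clusters")
}

#' Mean within- and between-group relationship of a partition
#'
#' Off-diagonal entries of `A` are averaged over pairs in the same group and
#' pairs in different groups. A good cross-validation partition has a high
#' within mean and a low between mean. With a single group the between mean
#' is undefined and reported as `NA`.
#'
#' @param A Relationship matrix.
#' @param partition Group label per individual (see [kmeans_groups()]).
#' @return Named numeric vector `c(within = ..., between = ...)`.
#' @export
partition_relatedness <- function(A, partition) {
  n <- nrow(A)
  if (length(partition) != n) stop("partition length must match A")
  same <- outer(partition, partition, "==")
  off <- upper.tri(A)
  within_pairs <- off & same
  between_pairs <- off & !same
  c(within = if (any(within_pairs)) mean(A[within_pairs]) else NA_real_,
    between = if (any(between_pairs)) mean(A[between_pairs]) else NA_real_)
}
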
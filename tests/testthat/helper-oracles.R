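# Independent oracles and small fixture builders used across test files.

# Additive relationship by direct memoized recursion on the definition
# (top-down), independent of build_A's bottom-up tabular loop.
oracle_A <- function(ped) {
  n <- nrow(ped)
  unknown_s <- ped$sire %in% c("0", "", NA)
  unknown_d <- ped$dam %in% c("0", "", NA)
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  s[unknown_s] <- NA_integer_
  d[unknown_d] <- NA_integer_
  memo <- new.env(parent = emptyenv())
  a <- function(i, j) {
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) {
      1 + 0.5 * (if (!is.na(s[j]) && !is.na(d[j])) a(s[j], d[j]) else 0)
    } else {
      # j is the later-born of the pair; recurse through j's parents
      (if (is.na(s[j])) 0 else 0.5 * a(i, s[j])) +
        (if (is.na(d[j])) 0 else 0.5 * a(i, d[j]))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- a(i, j)
  A
}

# Random topologically ordered pedigree; individuals may have 0, 1 or 2
# known parents so the single-unknown-parent branch is exercised too.
random_pedigree <- function(n, seed) {
  set.seed(seed)
  nf <- sample(2:max(3, n %/% 4), 1)
  id <- sprintf("P%03d", seq_len(n))
  sire <- rep("0", n)
  dam <- rep("0", n)
  for (i in (nf + 1):n) {
    par <- sample(i - 1, 2)
    sire[i] <- id[par[1]]
    dam[i] <- if (stats::runif(1) < 0.15) "0" else id[par[2]]
  }
  data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

# Closed-form ridge (SNP-BLUP) effect estimates with centered predictors.
ridge_effects <- function(X, y, lambda) {
  Xc <- sweep(X, 2, colMeans(X))
  drop(solve(crossprod(Xc) + diag(lambda, ncol(X)),
             crossprod(Xc, y - mean(y))))
}

# Small genotype matrix with independent markers at given frequencies.
toy_geno <- function(n = 60, p = 30, n_chr = 2, seed = 1,
                     freq = NULL) {
  stopifnot(p %% n_chr == 0)
  map <- marker_map(n_chr, p / n_chr, 50000)
  set.seed(seed)
  if (is.null(freq)) freq <- stats::runif(p, 0.2, 0.5)
  dos <- matrix(stats::rbinom(n * p, 2, rep(freq, each = n)), n, p)
  # guard against monomorphic columns
  dos[1, ] <- pmax(dos[1, ], 1L)
  genotype_matrix(dos, sprintf("ind%03d", seq_len(n)), map)
}

# hand-built founder_haplotypes object from an explicit haplotype matrix
manual_founders <- function(hap, map) {
  structure(list(haplotypes = hap, freq = colMeans(hap), map = map,
                 n_founders = nrow(hap) / 2L),
            class = "founder_haplotypes")
}

# can this offspring dosage arise from these parental dosages?
mendel_ok <- function(off, sire, dam) {
  lo <- (sire == 2) + (dam == 2)
  hi <- (sire >= 1) + (dam >= 1)
  off >= lo & off <= hi
}
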
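#' Simulate founder haplotypes with distance-decaying LD
#'
#' Allele frequencies are drawn uniformly on `[maf_low, maf_high]` (the
#' counted allele is always the minor one). Along each chromosome, alleles on
#' a haplotype follow a first-order Markov process: the correlation between
#' adjacent markers is `ld_rho^(d / ref_dist_bp)` where `d` is their physical
#' distance, so linkage disequilibrium decays geometrically with distance and
#' chromosomes are mutually independent. The conditional Bernoulli success
#' probability is clamped to [0, 1] when markers with very different
#' frequencies would otherwise push it outside the unit interval, so the
#' target correlation is an upper bound for such pairs.
#'
#' @param map Marker map (see [marker_map()]).
#' @param n_founders Number of founders; two haplotypes are produced each.
#' @param maf_low,maf_high Bounds for the minor allele frequency,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param ld_rho Correlation between alleles `ref_dist_bp` apart, in [0, 1).
#' @param ref_dist_bp Reference distance (bp) at which the haplotype allele
#'   correlation equals `ld_rho`.
#' @param seed Integer seed.
#' @return An object of class `founder_haplotypes`: a list with the
#'   `2 * n_founders` x p 0/1 `haplotypes` matrix (rows 2i-1 and 2i belong to
#'   founder i), the drawn `freq` vector, the `map` and `n_founders`.
#' @export
simulate_founder_haplotypes <- function(map, n_founders,
                                        maf_low = 0.01, maf_high = 0.5,
                                        ld_rho = 0.5, ref_dist_bp = 50000,
                                        seed = 1) {
  validate_marker_map(map)
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("require 0 < maf_low <= maf_high <= 0.5")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (n_founders < 1) stop("n_founders must be >= 1")
  set.seed(seed)
  p <- nrow(map)
  n_hap <- 2L * n_founders
  freq <- stats::runif(p, maf_low, maf_high)
  hap <- matrix(0L, n_hap, p)
  for (j in seq_len(p)) {
    new_chr <- j == 1L || map$chromosome[j] != map$chromosome[j - 1L]
    if (new_chr || ld_rho == 0) {
      prob <- rep(freq[j], n_hap)
    } else {
      d <- map$position_bp[j] - map$position_bp[j - 1L]
      rho <- ld_rho^(d / ref_dist_bp)
      pj <- freq[j]
      pk <- freq[j - 1L]
      prob <- pj + rho * sqrt(pj * (1 - pj) / (pk * (1 - pk))) *
        (hap[, j - 1L] - pk)
      prob <- pmin(pmax(prob, 0), 1)
    }
    hap[, j] <- as.integer(stats::runif(n_hap) < prob)
  }
  structure(list(haplotypes = hap, freq = freq, map = map,
                 n_founders = n_founders),
            class = "founder_haplotypes")
}

#' Drop founder haplotypes through a pedigree
#'
#' Gene-dropping: founders receive their simulated haplotype pair; every
#' non-founder inherits one recombinant gamete from each parent. Crossovers
#' between adjacent markers occur with the Haldane recombination fraction
#' `c = 0.5 * (1 - exp(-2 d))`, `d` the map distance in Morgans at 1 cM per
#' megabase; the first marker of each chromosome segregates independently
#' (c = 0.5). Dosage is the sum of the two inherited alleles, so the output
#' is Mendelian-consistent by construction.
#'
#' @param founders A `founder_haplotypes` object.
#' @param pedigree Pedigree whose founder rows (unknown sire and dam) match,
#'   in order, the founders of `founders`.
#' @param map Marker map; defaults to the founders' map.
#' @param seed Integer seed governing crossovers and gamete starts.
#' @return A [genotype_matrix()] of 0/1/2 dosages for all pedigree members.
#' @export
gene_drop <- function(founders, pedigree, map = founders$map, seed = 1) {
  if (!inherits(founders, "founder_haplotypes")) {
    stop("founders must come from simulate_founder_haplotypes()")
  }
  validate_marker_map(map)
  parents <- validate_pedigree(pedigree)
  founder_rows <- which(is.na(parents$sire) & is.na(parents$dam))
  if (length(founder_rows) > founders$n_founders) {
    stop("missing founder haplotypes: pedigree has ", length(founder_rows),
         " founders but haplotypes were simulated for ", founders$n_founders)
  }
  if (any(xor(is.na(parents$sire), is.na(parents$dam)))) {
    stop("individuals must have both parents known or both unknown")
  }
  set.seed(seed)
  p <- nrow(map)
  n <- nrow(pedigree)
  # per-interval recombination fractions; independent restart at chromosomes
  d_morgan <- c(0, diff(map$position_bp)) * 1e-8  # 1 cM/Mb
  cfrac <- 0.5 * (1 - exp(-2 * d_morgan))
  cfrac[c(TRUE, diff(map$chromosome) != 0)] <- 0.5
  gamete <- function(h1, h2) {
    src <- cumsum(stats::runif(p) < cfrac) %% 2L
    out <- h1
    pick <- src == 1L
    out[pick] <- h2[pick]
    out
  }
  H1 <- matrix(0L, n, p)
  H2 <- matrix(0L, n, p)
  fi <- 0L
  for (i in seq_len(n)) {
    if (is.na(parents$sire[i])) {
      fi <- fi + 1L
      H1[i, ] <- founders$haplotypes[2L * fi - 1L, ]
      H2[i, ] <- founders$haplotypes[2L * fi, ]
    } else {
      si <- parents$sire[i]
      di <- parents$dam[i]
      H1[i, ] <- gamete(H1[si, ], H2[si, ])
      H2[i, ] <- gamete(H1[di, ], H2[di, ])
    }
  }
  genotype_matrix(H1 + H2, pedigree$id, map)
}
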
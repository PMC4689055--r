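#' Simulate a complete study dataset
#'
#' End-to-end synthetic-data pipeline: builds the marker map, a
#' multi-generation pedigree, LD-structured founder haplotypes, gene-drops
#' them to genotypes, optionally thins a dense panel to a sparse one, and
#' designates every `qtl_spacing`-th sparse marker as a QTL. The defaults
#' give a desk-scale analogue of a bovine 50K study: 10 chromosomes of 500
#' markers at ~50 kb spacing, 1000 individuals over a 250-founder pedigree,
#' a wide minor-allele-frequency spectrum, and LD decaying geometrically
#' with distance (allele correlation 0.5 at 50 kb). With
#' `density_ratio = 14` a dense panel at 14x marker density is simulated and
#' the sparse panel obtained by thinning, so both densities share the same
#' QTL columns (emulating a 770K vs 50K pair).
#'
#' @param n_chromosomes,markers_per_chromosome,spacing_bp Sparse-panel
#'   layout (see [marker_map()]).
#' @param density_ratio Dense-to-sparse marker density ratio; 1 simulates
#'   the sparse panel directly.
#' @param n_founders,n_generations,offspring_per_mating Pedigree shape (see
#'   [simulate_pedigree()]).
#' @param maf_low,maf_high,ld_rho,ref_dist_bp Founder haplotype model (see
#'   [simulate_founder_haplotypes()]).
#' @param qtl_spacing Every `qtl_spacing`-th sparse marker becomes a
#'   candidate QTL (monomorphic candidates dropped).
#' @param seed Master seed; child seeds for each stage are derived with
#'   [derive_seed()].
#' @return An object of class `qtl_sim`: list with `geno` (sparse panel),
#'   `geno_dense` (`NULL` if `density_ratio = 1`), `qtl` (on the sparse
#'   panel), `qtl_dense` (same QTL on the dense panel, or `NULL`),
#'   `pedigree`, and `params`.
#' @export
simulate_qtl_dataset <- function(n_chromosomes = 10,
                                 markers_per_chromosome = 500,
                                 spacing_bp = 50000,
                                 density_ratio = 1,
                                 n_founders = 250, n_generations = 3,
                                 offspring_per_mating = 2,
                                 maf_low = 0.01, maf_high = 0.5,
                                 ld_rho = 0.5, ref_dist_bp = 50000,
                                 qtl_spacing = 250, seed = 1) {
  stopifnot(density_ratio >= 1)
  density_ratio <- as.integer(round(density_ratio))
  map_dense <- marker_map(n_chromosomes,
                          markers_per_chromosome * density_ratio,
                          spacing_bp / density_ratio)
  pedigree <- simulate_pedigree(n_founders, n_generations,
                                offspring_per_mating,
                                seed = derive_seed(seed, 1))
  founders <- simulate_founder_haplotypes(map_dense, n_founders,
                                          maf_low, maf_high, ld_rho,
                                          ref_dist_bp,
                                          seed = derive_seed(seed, 2))
  geno_dense <- gene_drop(founders, pedigree, map_dense,
                          seed = derive_seed(seed, 3))
  if (density_ratio > 1) {
    geno <- thin_panel(geno_dense, density_ratio)
    qtl <- select_qtl(geno, qtl_spacing)
    qtl_dense <- qtl_on_panel(geno_dense, qtl)
  } else {
    geno <- geno_dense
    geno_dense <- NULL
    qtl <- select_qtl(geno, qtl_spacing)
    qtl_dense <- NULL
  }
  structure(list(geno = geno, geno_dense = geno_dense, qtl = qtl,
                 qtl_dense = qtl_dense, pedigree = pedigree,
                 params = list(n_chromosomes = n_chromosomes,
                               markers_per_chromosome = markers_per_chromosome,
                               spacing_bp = spacing_bp,
                               density_ratio = density_ratio,
                               n_founders = n_founders,
                               n_generations = n_generations,
                               offspring_per_mating = offspring_per_mating,
                               maf_low = maf_low, maf_high = maf_high,
                               ld_rho = ld_rho, ref_dist_bp = ref_dist_bp,
                               qtl_spacing = qtl_spacing, seed = seed)),
            class = "qtl_sim")
}

#' @export
print.qtl_sim <- function(x, ...) {
  cat("qtl_sim:", nrow(x$geno$dosage), "individuals,",
      ncol(x$geno$dosage), "sparse markers,",
      if (is.null(x$geno_dense)) "no dense panel,"
      else paste(ncol(x$geno_dense$dosage), "dense markers,"),
      length(x$qtl$indices), "QTL (seed", x$params$seed, ")\n")
  invisible(x)
}
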
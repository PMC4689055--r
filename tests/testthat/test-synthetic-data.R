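test_that("pedigree simulation respects structure, preconditions and seed", {
  # only possible mating with 2 founders
  ped <- simulate_pedigree(2, 1, offspring_per_mating = 1, seed = 3)
  expect_equal(nrow(ped), 3)
  expect_setequal(c(ped$sire[3], ped$dam[3]), ped$id[1:2])

  expect_error(simulate_pedigree(10, 0), "n_generations")
  expect_error(simulate_pedigree(1, 1), "n_founders")
  expect_error(simulate_pedigree(5, 1), "n_founders")

  p1 <- simulate_pedigree(20, 3, seed = 11)
  p2 <- simulate_pedigree(20, 3, seed = 11)
  expect_identical(p1, p2)
  expect_false(identical(p1, simulate_pedigree(20, 3, seed = 12)))

  # parents always precede offspring and generations are layered
  expect_silent(validate_pedigree(p1))
  expect_equal(sort(unique(p1$generation)), 0:3)
})

test_that("founder haplotypes hit target frequencies and LD limits", {
  map <- marker_map(1, 60, 50000)
  # independence limit: ld_rho = 0
  f0 <- simulate_founder_haplotypes(map, 5000, ld_rho = 0, seed = 5)
  r2_adj <- diag(cor(f0$haplotypes[, 1:59], f0$haplotypes[, 2:60]))^2
  expect_lt(mean(r2_adj), 0.001)  # E[r2] under independence = 1/(H-1)

  # strong LD: adjacent pairs far exceed 50-apart pairs
  f9 <- simulate_founder_haplotypes(map, 5000, ld_rho = 0.95, seed = 6)
  h <- f9$haplotypes
  r2 <- function(i, j) diag(cor(h[, i, drop = FALSE],
                                h[, j, drop = FALSE]))^2
  adj <- mean(r2(1:59, 2:60))
  far <- mean(r2(1:10, 51:60))
  expect_gt(adj, far)
  expect_gt(adj, 0.5)

  # fixed-frequency bounds: realized freq within 3 binomial SE of 0.5
  ff <- simulate_founder_haplotypes(map, 5000, maf_low = 0.5, maf_high = 0.5,
                                    ld_rho = 0, seed = 7)
  se <- sqrt(0.25 / 10000)
  expect_true(all(abs(colMeans(ff$haplotypes) - 0.5) < 3 * se))

  expect_error(simulate_founder_haplotypes(map, 10, maf_low = 0,
                                           maf_high = 0.3), "maf_low")
  expect_error(simulate_founder_haplotypes(map, 10, ld_rho = 1), "ld_rho")
})

test_that("realized LD decays monotonically with binned distance", {
  map <- marker_map(1, 100, 50000)
  f <- simulate_founder_haplotypes(map, 5000, ld_rho = 0.9, seed = 8)
  h <- f$haplotypes
  gaps <- c(1, 2, 5, 10, 20)
  mean_r2 <- vapply(gaps, function(g) {
    i <- seq_len(100 - g)
    mean(diag(cor(h[, i, drop = FALSE], h[, i + g, drop = FALSE]))^2)
  }, numeric(1))
  expect_true(all(diff(mean_r2) <= 0.01))
})

test_that("gene drop transmits Mendelianly and deterministically", {
  map <- marker_map(1, 4, 50000)
  # founders: one fixed for allele 1, one fixed for allele 0 at all markers
  hap <- rbind(matrix(1L, 2, 4), matrix(0L, 2, 4))
  founders <- manual_founders(hap, map)
  ped <- data.frame(id = c("f1", "f2", "o1"), sire = c("0", "0", "f1"),
                    dam = c("0", "0", "f2"), stringsAsFactors = FALSE)
  g <- gene_drop(founders, ped, map, seed = 1)
  # parent dosages 2 and 0 force offspring dosage 1
  expect_equal(unname(g$dosage["o1", ]), rep(1L, 4))
  # both parents homozygous alike force the same homozygote
  ped2 <- data.frame(id = c("f1", "f2", "o1"), sire = c("0", "0", "f1"),
                     dam = c("0", "0", "f1"), stringsAsFactors = FALSE)
  expect_error(validate_pedigree(ped2), NA)  # dam f1 is legal pedigree-wise
  founders2 <- manual_founders(rbind(matrix(2L %/% 2, 2, 4),
                                     matrix(1L, 2, 4)), map)
  g2 <- gene_drop(founders2, ped, map, seed = 2)
  expect_equal(unname(g2$dosage["o1", ]), rep(2L, 4))

  # population-scale Mendelian consistency
  sim_map <- marker_map(2, 50, 50000)
  ped3 <- simulate_pedigree(20, 2, seed = 9)
  fh <- simulate_founder_haplotypes(sim_map, 20, seed = 10)
  g3 <- gene_drop(fh, ped3, sim_map, seed = 11)
  kids <- which(ped3$sire != "0")
  si <- match(ped3$sire, ped3$id)
  di <- match(ped3$dam, ped3$id)
  ok <- vapply(kids, function(i) {
    all(mendel_ok(g3$dosage[i, ], g3$dosage[si[i], ], g3$dosage[di[i], ]))
  }, logical(1))
  expect_true(all(ok))

  expect_identical(gene_drop(fh, ped3, sim_map, seed = 11)$dosage, g3$dosage)
})

test_that("tightly linked markers are co-inherited", {
  # 1 bp apart: recombination fraction ~1e-8, so parental phase is preserved
  map <- data.frame(marker_id = c("a", "b"), chromosome = c(1L, 1L),
                    position_bp = c(1L, 2L))
  hap <- rbind(c(1L, 1L), c(0L, 0L))  # founder 1: coupled haplotypes 11 / 00
  founders <- manual_founders(rbind(hap, hap), map)
  ped <- data.frame(id = c("f1", "f2", paste0("o", 1:200)),
                    sire = c("0", "0", rep("f1", 200)),
                    dam = c("0", "0", rep("f2", 200)),
                    stringsAsFactors = FALSE)
  g <- gene_drop(founders, ped, map, seed = 12)
  off <- g$dosage[-(1:2), ]
  expect_true(all(off[, 1] == off[, 2]))
})

test_that("QTL selection takes every m-th marker and drops monomorphic ones", {
  g <- toy_geno(n = 40, p = 50, n_chr = 2, seed = 13)
  qtl <- select_qtl(g, 10)
  expect_equal(qtl$indices, seq(10, 50, 10))

  # the 50K-scale arithmetic: every 1000th of 54,555 gives 54 candidates
  big_map <- marker_map(1, 54555, 100)
  big <- genotype_matrix(matrix(rep(c(0L, 1L), 54555), 2, 54555),
                         c("a", "b"), big_map)
  expect_length(select_qtl(big, 1000)$indices, 54)

  # a monomorphic candidate is dropped
  dos <- g$dosage
  dos[, 20] <- 0L
  g2 <- genotype_matrix(dos, g$individual_ids, g$map)
  expect_equal(select_qtl(g2, 10)$indices, setdiff(seq(10, 50, 10), 20))
  expect_error(select_qtl(g, 1), "spacing_m")
})

test_that("phenotypes are exact functions of QTL dosages", {
  map <- marker_map(1, 4, 50000)
  dos <- rbind(c(0L, 0L, 2L, 1L), c(1L, 1L, 1L, 0L), c(2L, 0L, 0L, 2L))
  g <- genotype_matrix(dos, c("i1", "i2", "i3"), map)
  qtl <- structure(list(indices = c(2L, 4L), marker_id = map$marker_id[c(2, 4)],
                        spacing_m = 2L), class = "qtl_set")
  y_sum <- simulate_phenotype(g, qtl, "summed")
  expect_equal(unname(y_sum), c(0 + 1, 1 + 0, 0 + 2))
  y_one <- simulate_phenotype(g, qtl, "single", target_qtl = 4)
  expect_equal(unname(y_one), c(1, 0, 2))
  expect_equal(cor(y_one, dos[, 4]), 1)
  expect_error(simulate_phenotype(g, qtl, "single"), "target_qtl")
  expect_error(simulate_phenotype(g, qtl, "single", target_qtl = 3),
               "member")
})

test_that("maf counts alleles correctly", {
  expect_equal(maf(c(0, 1, 2, 2, 1)), 0.4)
  expect_equal(maf(c(0, 0, 0)), 0)
  expect_equal(maf(c(1, 1, 1, 1)), 0.5)
  g <- toy_geno(n = 30, p = 10, n_chr = 1, seed = 14)
  expect_equal(unname(maf(g)), unname(apply(g$dosage, 2, maf)))
})

test_that("panel thinning keeps every k-th marker and designated QTL", {
  g <- toy_geno(n = 10, p = 1400, n_chr = 2, seed = 15)
  expect_identical(thin_panel(g, 1), g)
  thin <- thin_panel(g, 14)
  expect_equal(ncol(thin$dosage), 100)
  expect_equal(thin$map$marker_id, g$map$marker_id[seq(14, 1400, 14)])
  # a QTL whose index is not a multiple of 14 survives thinning
  qtl <- structure(list(indices = 15L, marker_id = g$map$marker_id[15],
                        spacing_m = 15L), class = "qtl_set")
  thin_q <- thin_panel(g, 14, qtl)
  expect_true(qtl$marker_id %in% thin_q$map$marker_id)
  expect_equal(ncol(thin_q$dosage), 101)
  # QTL indices can be re-resolved on the thinned panel
  expect_equal(qtl_on_panel(thin_q, qtl)$indices,
               match(qtl$marker_id, thin_q$map$marker_id))
})

test_that("the dataset orchestrator wires panels, pedigree and QTL together", {
  sim <- simulate_qtl_dataset(n_chromosomes = 2, markers_per_chromosome = 50,
                              density_ratio = 4, n_founders = 20,
                              n_generations = 1, qtl_spacing = 10, seed = 16)
  expect_equal(ncol(sim$geno$dosage), 100)
  expect_equal(ncol(sim$geno_dense$dosage), 400)
  expect_true(all(sim$qtl$marker_id %in% sim$geno_dense$map$marker_id))
  expect_identical(sim$qtl$marker_id, sim$qtl_dense$marker_id)
  # both panels carry identical dosages at the shared QTL columns
  expect_identical(sim$geno$dosage[, sim$qtl$indices],
                   sim$geno_dense$dosage[, sim$qtl_dense$indices])
  sim2 <- simulate_qtl_dataset(n_chromosomes = 2, markers_per_chromosome = 50,
                               density_ratio = 4, n_founders = 20,
                               n_generations = 1, qtl_spacing = 10, seed = 16)
  expect_identical(sim$geno$dosage, sim2$geno$dosage)
})
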
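#' @name genotype_io
#' @title Read and write genotype files
#'
#' @description
#' Two plain-text dialects are supported and round-trip losslessly.
#'
#' Dosage table: tab-separated, header row of marker ids, first column `id`,
#' then one 0/1/2 integer per marker — the counted ("B") allele dosage.
#' Reading requires the marker map, which a dosage table does not carry.
#'
#' PLINK-style `.ped`/`.map` pair: the `.map` has columns (chromosome,
#' marker id, position in cM taken as bp / 1e6, position in bp, 1-based
#' inclusive); the `.ped` has columns (family id, individual id, sire, dam,
#' sex, phenotype) followed by two allele characters per marker, `A` the
#' reference and `B` the counted allele, so `A A`/`A B`/`B B` map to dosages
#' 0/1/2.
#'
#' @param geno A [genotype_matrix()].
#' @param path,prefix Output path; the ped/map pair is written to
#'   `prefix.ped` and `prefix.map`.
#' @param map Marker map describing the dosage table's columns.
#' @return Writers return the path(s) invisibly; readers return a
#'   `genotype_matrix`.
NULL

#' @rdname genotype_io
#' @export
write_dosage <- function(geno, path) {
  df <- data.frame(id = geno$individual_ids, geno$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname genotype_io
#' @export
read_dosage <- function(path, map) {
  validate_marker_map(map)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "id") stop("first dosage column must be 'id'")
  markers <- names(df)[-1]
  if (!identical(markers, map$marker_id)) {
    stop("dosage table markers do not match the map")
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(matrix(!(mat %in% 0:2), nrow(mat)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid dosage at row %d (%s), marker %s",
                 bad[1, 1], df$id[bad[1, 1]], markers[bad[1, 2]]))
  }
  genotype_matrix(mat, df$id, map)
}

#' @rdname genotype_io
#' @export
write_ped_map <- function(geno, prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  utils::write.table(
    data.frame(geno$map$chromosome, geno$map$marker_id,
               geno$map$position_bp / 1e6, geno$map$position_bp),
    map_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  allele_pairs <- c("A A", "A B", "B B")
  geno_cols <- matrix(allele_pairs[geno$dosage + 1L], nrow(geno$dosage))
  df <- data.frame(fid = geno$individual_ids, iid = geno$individual_ids,
                   pat = "0", mat = "0", sex = 0L, pheno = -9L,
                   geno_cols, stringsAsFactors = FALSE)
  utils::write.table(df, ped_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' @rdname genotype_io
#' @export
read_ped_map <- function(prefix) {
  map_df <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                              stringsAsFactors = FALSE)
  map <- data.frame(marker_id = as.character(map_df[[2]]),
                    chromosome = as.integer(map_df[[1]]),
                    position_bp = as.integer(map_df[[4]]),
                    stringsAsFactors = FALSE)
  validate_marker_map(map)
  ped <- utils::read.table(paste0(prefix, ".ped"), sep = "",
                           colClasses = "character")
  p <- nrow(map)
  if (ncol(ped) != 6 + 2 * p) {
    stop(".ped has ", ncol(ped), " columns; expected ", 6 + 2 * p)
  }
  alleles <- as.matrix(ped[, -(1:6), drop = FALSE])
  if (!all(alleles %in% c("A", "B"))) {
    stop("non-biallelic allele codes in .ped (expected A/B)")
  }
  b_count <- (alleles == "B") + 0L
  dosage <- b_count[, seq(1, 2 * p, by = 2), drop = FALSE] +
    b_count[, seq(2, 2 * p, by = 2), drop = FALSE]
  genotype_matrix(dosage, ped[[2]], map)
}

#' Read and write pedigrees
#'
#' Three-column CSV (`id`, `sire`, `dam`; `"0"` = unknown parent), parents
#' before offspring. Reading validates the topological ordering.
#'
#' @param pedigree Pedigree `data.frame`.
#' @param path File path.
#' @return `write_pedigree()` returns the path invisibly; `read_pedigree()`
#'   returns the pedigree `data.frame`.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.csv(pedigree[, c("id", "sire", "dam")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, colClasses = "character")
  validate_pedigree(ped)
  ped
}

#' Read and write phenotypes
#'
#' Two-column CSV (`id`, `phenotype`).
#'
#' @param y Named numeric phenotype vector.
#' @param path File path.
#' @return `write_phenotypes()` returns the path invisibly;
#'   `read_phenotypes()` a named numeric vector.
#' @export
write_phenotypes <- function(y, path) {
  utils::write.csv(data.frame(id = names(y), phenotype = as.numeric(y)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  stats::setNames(df$phenotype, df$id)
}

#' Write a relationship matrix or CV partition
#'
#' The relationship matrix is written dense, tab-separated, with an id
#' header row and id first column; the partition as a two-column CSV
#' (`id`, `group`).
#'
#' @param A Relationship matrix with id dimnames.
#' @param partition Named group-label vector (see [kmeans_groups()]).
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_relationship <- function(A, path) {
  df <- data.frame(id = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relationship
#' @export
write_partition <- function(partition, path) {
  utils::write.csv(data.frame(id = names(partition),
                              group = as.integer(partition)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
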
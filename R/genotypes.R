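#' Genotype matrix tied to a marker map
#'
#' The central genotype container: an integer matrix of allele dosages
#' (0/1/2 copies of the counted allele) with one row per individual and one
#' column per marker of the map, in panel order.
#'
#' @param dosage Integer matrix of 0/1/2 dosages, individuals x markers.
#' @param individual_ids Character vector of unique row identifiers.
#' @param map Marker map describing the columns (see [marker_map()]).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, individual_ids, map) {
  validate_marker_map(map)
  dosage <- as.matrix(dosage)
  if (anyNA(dosage)) stop("dosages must not contain missing values")
  if (!all(dosage %in% 0:2)) stop("dosages must be 0, 1 or 2")
  storage.mode(dosage) <- "integer"
  if (ncol(dosage) != nrow(map)) {
    stop("dosage has ", ncol(dosage), " columns but the map has ",
         nrow(map), " markers")
  }
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != nrow(dosage)) {
    stop("individual_ids length must equal the number of rows")
  }
  if (anyDuplicated(individual_ids)) stop("individual_ids must be unique")
  dimnames(dosage) <- list(individual_ids, map$marker_id)
  structure(list(dosage = dosage, individual_ids = individual_ids, map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "markers on", length(unique(x$map$chromosome)),
      "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by marker
#'
#' @param geno A `genotype_matrix`.
#' @param markers Integer column indices or marker ids to keep, in panel
#'   order.
#' @return A `genotype_matrix` over the selected markers.
#' @export
subset_markers <- function(geno, markers) {
  idx <- resolve_marker_index(geno, markers)
  idx <- sort(unique(idx))
  genotype_matrix(geno$dosage[, idx, drop = FALSE], geno$individual_ids,
                  geno$map[idx, , drop = FALSE])
}

#' Subset a genotype matrix by individual
#'
#' @param geno A `genotype_matrix`.
#' @param individuals Integer row indices or individual ids to keep.
#' @return A `genotype_matrix` over the selected individuals.
#' @export
subset_individuals <- function(geno, individuals) {
  if (is.character(individuals)) {
    idx <- match(individuals, geno$individual_ids)
    if (anyNA(idx)) stop("unknown individual id(s)")
  } else {
    idx <- as.integer(individuals)
    if (any(idx < 1 | idx > nrow(geno$dosage))) stop("row index out of range")
  }
  genotype_matrix(geno$dosage[idx, , drop = FALSE],
                  geno$individual_ids[idx], geno$map)
}

resolve_marker_index <- function(geno, markers) {
  if (is.character(markers)) {
    idx <- match(markers, geno$map$marker_id)
    if (anyNA(idx)) stop("unknown marker id(s)")
  } else {
    idx <- as.integer(markers)
    if (any(idx < 1 | idx > ncol(geno$dosage))) {
      stop("marker index out of range")
    }
  }
  idx
}

#' Minor allele frequency
#'
#' For a dosage column the counted-allele frequency is `f = sum(d) / (2 n)`
#' and the MAF is `min(f, 1 - f)`. Given a matrix or `genotype_matrix`, one
#' MAF per marker column is returned.
#'
#' @param x Dosage vector, dosage matrix, or `genotype_matrix`.
#' @return Numeric MAF(s) in [0, 0.5].
#' @examples
#' maf(c(0, 1, 2, 2, 1))  # 0.4
#' @export
maf <- function(x) {
  if (inherits(x, "genotype_matrix")) x <- x$dosage
  if (is.matrix(x)) {
    if (nrow(x) == 0) stop("empty dosage matrix")
    f <- colSums(x) / (2 * nrow(x))
    return(pmin(f, 1 - f))
  }
  if (length(x) == 0) stop("empty dosage column")
  f <- sum(x) / (2 * length(x))
  min(f, 1 - f)
}

#' Designate every m-th ordered marker as a QTL
#'
#' Candidate QTL are the markers at panel positions m, 2m, 3m, ... ;
#' candidates that are monomorphic in the population (MAF = 0) are dropped,
#' mirroring the retention of only polymorphic loci among evenly spaced
#' candidates.
#'
#' @param geno A `genotype_matrix`.
#' @param spacing_m Spacing between candidate QTL in panel order, >= 2.
#' @return An object of class `qtl_set`: list with `indices` (columns of
#'   `geno`), `marker_id`, and `spacing_m`.
#' @export
select_qtl <- function(geno, spacing_m) {
  if (spacing_m < 2) stop("spacing_m must be >= 2")
  p <- ncol(geno$dosage)
  candidates <- seq.int(spacing_m, p, by = spacing_m)
  if (length(candidates) == 0) stop("panel smaller than spacing_m")
  keep <- candidates[maf(geno$dosage[, candidates, drop = FALSE]) > 0]
  if (length(keep) == 0) stop("all candidate QTL are monomorphic")
  structure(list(indices = as.integer(keep),
                 marker_id = geno$map$marker_id[keep],
                 spacing_m = as.integer(spacing_m)),
            class = "qtl_set")
}

#' @export
print.qtl_set <- function(x, ...) {
  cat("qtl_set:", length(x$indices), "QTL (every",
      x$spacing_m, "th ordered marker, monomorphic dropped)\n")
  invisible(x)
}

#' Simulate a heritability-one phenotype from QTL dosages
#'
#' In `single` mode the phenotype is exactly the dosage column of the chosen
#' QTL (multiplying by an effect size would only rescale it); in `summed`
#' mode it is the sum of dosages over all QTL, so every QTL has the same
#' effect and contributes genetic variance according to its allele frequency.
#' No residual is added: heritability is exactly 1.
#'
#' @param geno A `genotype_matrix`.
#' @param qtl A `qtl_set` from [select_qtl()].
#' @param mode `"single"` or `"summed"`.
#' @param target_qtl For `single` mode, the column index of the QTL (must be
#'   a member of `qtl`).
#' @return Named numeric phenotype vector, one value per individual.
#' @export
simulate_phenotype <- function(geno, qtl, mode = c("summed", "single"),
                               target_qtl = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(qtl, "qtl_set"))
  if (mode == "single") {
    if (is.null(target_qtl)) stop("single mode requires target_qtl")
    if (!(target_qtl %in% qtl$indices)) {
      stop("target_qtl is not a member of the QTL set")
    }
    y <- as.numeric(geno$dosage[, target_qtl])
  } else {
    y <- as.numeric(rowSums(geno$dosage[, qtl$indices, drop = FALSE]))
  }
  names(y) <- geno$individual_ids
  y
}

#' Thin a dense panel to a sparse one
#'
#' Retains every `keep_every`-th marker in panel order (positions
#' `keep_every, 2*keep_every, ...`), always also retaining designated QTL
#' markers so that both densities share the same QTL columns.
#'
#' @param geno A `genotype_matrix`.
#' @param keep_every Keep one marker in `keep_every`, >= 1.
#' @param qtl Optional `qtl_set` (indices into `geno`) whose markers are
#'   always retained.
#' @return A `genotype_matrix` over the retained markers.
#' @export
thin_panel <- function(geno, keep_every, qtl = NULL) {
  if (keep_every < 1) stop("keep_every must be >= 1")
  if (keep_every == 1 && is.null(qtl)) return(geno)
  p <- ncol(geno$dosage)
  keep <- seq.int(keep_every, p, by = keep_every)
  if (!is.null(qtl)) {
    stopifnot(inherits(qtl, "qtl_set"))
    keep <- sort(unique(c(keep, qtl$indices)))
  }
  subset_markers(geno, keep)
}

#' Indices of a QTL set within another panel
#'
#' Maps a `qtl_set` defined on one panel to column indices of another panel
#' sharing marker ids (e.g. from sparse to dense after [thin_panel()]).
#'
#' @param geno Target `genotype_matrix`.
#' @param qtl A `qtl_set`.
#' @return A `qtl_set` with indices valid for `geno`.
#' @export
qtl_on_panel <- function(geno, qtl) {
  stopifnot(inherits(qtl, "qtl_set"))
  idx <- match(qtl$marker_id, geno$map$marker_id)
  if (anyNA(idx)) stop("panel is missing ", sum(is.na(idx)), " QTL marker(s)")
  structure(list(indices = as.integer(idx), marker_id = qtl$marker_id,
                 spacing_m = qtl$spacing_m),
            class = "qtl_set")
}
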
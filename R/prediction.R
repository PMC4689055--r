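#' Markers flanking a QTL
#'
#' Returns up to `k` markers immediately preceding and `k` immediately
#' following the QTL in panel order, restricted to the QTL's chromosome and
#' truncated at chromosome ends. The QTL itself is never included.
#'
#' @param map Marker map in panel order.
#' @param qtl_index Panel index of the QTL.
#' @param k Number of flanking markers on each side, >= 1.
#' @return Integer panel indices of the flanking markers.
#' @examples
#' map <- marker_map(n_chromosomes = 1, markers_per_chromosome = 20)
#' flank_indices(map, 10, 2)  # 8 9 11 12
#' @export
flank_indices <- function(map, qtl_index, k) {
  validate_marker_map(map)
  if (k < 1) stop("k must be >= 1")
  if (qtl_index < 1 || qtl_index > nrow(map)) stop("qtl_index out of range")
  on_chr <- which(map$chromosome == map$chromosome[qtl_index])
  pos <- match(qtl_index, on_chr)
  lo <- max(1L, pos - k)
  hi <- min(length(on_chr), pos + k)
  idx <- setdiff(on_chr[lo:hi], qtl_index)
  if (length(idx) == 0) {
    stop("QTL has no flanking markers on its chromosome")
  }
  idx
}

#' Train marker effects on a predictor set
#'
#' Thin wrapper over [run_chain()] restricted to the chosen predictor
#' columns. Used for both strategies: local training (the QTL's flanking
#' markers only) and whole-genome training (all markers except the QTL).
#'
#' @param y Training phenotype.
#' @param geno A [genotype_matrix()].
#' @param predictors Nonempty panel indices or marker ids; must exclude all
#'   QTL columns (the caller's responsibility, checked against `qtl` when
#'   given).
#' @param prior A [prior_spec()].
#' @param config A [chain_config()].
#' @param qtl Optional `qtl_set`; an error is raised if any of its markers
#'   appear among the predictors.
#' @return A `posterior_summary` over the predictor markers.
#' @export
train <- function(y, geno, predictors, prior, config = chain_config(),
                  qtl = NULL) {
  idx <- resolve_marker_index(geno, predictors)
  if (length(idx) == 0) stop("predictor set must be nonempty")
  if (!is.null(qtl) && any(idx %in% qtl$indices)) {
    stop("predictor set must exclude all QTL columns")
  }
  run_chain(subset_markers(geno, idx), y, prior, config)
}

#' Direct genomic values from posterior mean effects
#'
#' `DGV_i = sum_j centered_dosage_ij * effect_j` over the chosen marker
#' subset. For whole-genome training with local prediction the subset is the
#' QTL's flanking set even though effects were estimated genome-wide;
#' passing all trained markers gives the full-model fitted values minus the
#' intercept.
#'
#' @param geno A [genotype_matrix()] holding the individuals to predict.
#' @param posterior A `posterior_summary`.
#' @param markers Marker ids or panel indices (into `geno`) to use; all must
#'   be present in the posterior. Defaults to every trained marker.
#' @return Named numeric DGV vector.
#' @export
dgv <- function(geno, posterior, markers = posterior$marker_id) {
  stopifnot(inherits(posterior, "posterior_summary"))
  idx <- resolve_marker_index(geno, markers)
  ids <- geno$map$marker_id[idx]
  j <- match(ids, posterior$marker_id)
  if (anyNA(j)) {
    stop("markers absent from the posterior: ",
         paste(utils::head(ids[is.na(j)], 3), collapse = ", "))
  }
  X <- geno$dosage[, idx, drop = FALSE]
  storage.mode(X) <- "double"
  Xc <- sweep(X, 2, colMeans(X))
  out <- drop(Xc %*% posterior$effect[j])
  names(out) <- geno$individual_ids
  out
}

#' Prediction accuracy
#'
#' The Pearson correlation between phenotype and DGV. At heritability 1 the
#' phenotype equals the genetic merit, so this is also the accuracy of
#' genetic-merit prediction. If either vector has zero variance (e.g. all
#' flanking effects shrunk to zero) the accuracy is undefined and `NA` is
#' returned with a warning.
#'
#' @param y Phenotype vector.
#' @param dgv_vector DGV vector of equal length.
#' @return Pearson correlation, or `NA` with a warning.
#' @export
accuracy <- function(y, dgv_vector) {
  if (length(y) != length(dgv_vector)) stop("length mismatch")
  if (stats::sd(y) < 1e-12 || stats::sd(dgv_vector) < 1e-12) {
    warning("zero-variance input: accuracy undefined")
    return(NA_real_)
  }
  stats::cor(y, dgv_vector)
}
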
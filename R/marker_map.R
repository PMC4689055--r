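#' Construct an ordered multi-chromosome SNP map
#'
#' Builds an evenly spaced marker map, the backbone of all simulated panels.
#' Markers are stored in panel order: sorted by chromosome, then physical
#' position. The default layout (10 chromosomes of 500 markers at ~50 kb
#' spacing) is a desk-scale analogue of a bovine 50K array; a high-density
#' analogue is obtained by shrinking `spacing_bp` (see
#' [simulate_qtl_dataset()], which keeps the two densities at a 14:1 ratio).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param markers_per_chromosome Markers placed on each chromosome.
#' @param spacing_bp Distance in base pairs between adjacent markers.
#' @param prefix Prefix used to build marker identifiers.
#' @return A `data.frame` with columns `marker_id`, `chromosome`,
#'   `position_bp`, one row per marker in panel order.
#' @examples
#' map <- marker_map(n_chromosomes = 2, markers_per_chromosome = 5)
#' head(map)
#' @export
marker_map <- function(n_chromosomes = 10, markers_per_chromosome = 500,
                       spacing_bp = 50000, prefix = "snp") {
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 1, spacing_bp >= 1)
  spacing_bp <- max(1L, as.integer(round(spacing_bp)))
  chrom <- rep(seq_len(n_chromosomes), each = markers_per_chromosome)
  pos <- rep(seq_len(markers_per_chromosome) * spacing_bp, n_chromosomes)
  map <- data.frame(
    marker_id = sprintf("%s_%d_%d", prefix, chrom, pos),
    chromosome = as.integer(chrom),
    position_bp = as.integer(pos),
    stringsAsFactors = FALSE
  )
  validate_marker_map(map)
  map
}

#' Validate a marker map
#'
#' Checks the structural invariants every map must satisfy: required columns,
#' unique marker identifiers, markers sorted by (chromosome, position) with
#' strictly increasing positions within a chromosome.
#'
#' @param map A marker map `data.frame`.
#' @return The map, invisibly, if valid; otherwise an error is raised.
#' @export
validate_marker_map <- function(map) {
  required <- c("marker_id", "chromosome", "position_bp")
  if (!is.data.frame(map) || !all(required %in% names(map))) {
    stop("marker map must be a data.frame with columns ",
         paste(required, collapse = ", "))
  }
  if (anyDuplicated(map$marker_id)) stop("marker_ids must be unique")
  if (any(map$position_bp < 0)) stop("positions must be non-negative")
  if (is.unsorted(map$chromosome)) {
    stop("markers must be sorted by chromosome")
  }
  within_ok <- tapply(map$position_bp, map$chromosome,
                      function(x) all(diff(x) > 0))
  if (!all(unlist(within_ok))) {
    stop("positions must be strictly increasing within a chromosome")
  }
  invisible(map)
}
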
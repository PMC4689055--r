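#' Simulate a multi-generation random-mating pedigree
#'
#' Founders have unknown parents. Each later generation is produced by random
#' sire x dam matings within the previous generation: that generation is
#' randomly split into equal numbers of sires and dams, pairs are formed at
#' random, and each pair produces `offspring_per_mating` full-sib offspring.
#' With the default of two offspring per mating the census size is constant
#' across generations. The resulting family structure (full-sib and paternal
#' half-sib ties within generations) is what the relatedness-based
#' cross-validation grouping exploits.
#'
#' @param n_founders Even number of founders, at least 2.
#' @param n_generations Number of descendant generations, at least 1.
#' @param offspring_per_mating Full sibs produced per mating.
#' @param seed Integer seed; identical inputs and seed give an identical
#'   pedigree.
#' @param id_prefix Prefix for individual identifiers, so that pedigrees from
#'   independent calls (e.g. separate families) can be concatenated.
#' @return A `data.frame` with columns `id`, `sire`, `dam` (`"0"` = unknown)
#'   and `generation`, parents always stored before offspring.
#' @examples
#' ped <- simulate_pedigree(n_founders = 4, n_generations = 2, seed = 1)
#' table(ped$generation)
#' @export
simulate_pedigree <- function(n_founders, n_generations,
                              offspring_per_mating = 2, seed = 1,
                              id_prefix = "ID") {
  if (n_founders < 2 || n_founders %% 2 != 0) {
    stop("n_founders must be an even number >= 2")
  }
  if (n_generations < 1) stop("n_generations must be >= 1")
  if (offspring_per_mating < 1) stop("offspring_per_mating must be >= 1")
  set.seed(seed)
  ids <- sprintf("%s%06d", id_prefix, seq_len(n_founders))
  ped <- data.frame(id = ids, sire = "0", dam = "0", generation = 0L,
                    stringsAsFactors = FALSE)
  counter <- n_founders
  prev <- ids
  for (g in seq_len(n_generations)) {
    perm <- sample(prev)
    n_mat <- floor(length(perm) / 2)
    if (n_mat < 1) stop("previous generation too small to mate")
    sires <- perm[seq_len(n_mat)]
    dams <- perm[n_mat + seq_len(n_mat)]
    n_off <- n_mat * offspring_per_mating
    off_ids <- sprintf("%s%06d", id_prefix, counter + seq_len(n_off))
    counter <- counter + n_off
    ped <- rbind(ped, data.frame(
      id = off_ids,
      sire = rep(sires, each = offspring_per_mating),
      dam = rep(dams, each = offspring_per_mating),
      generation = as.integer(g),
      stringsAsFactors = FALSE
    ))
    prev <- off_ids
  }
  rownames(ped) <- NULL
  ped
}

#' Validate pedigree ordering
#'
#' Every parent must be stored before its offspring and be a known individual
#' or `"0"` (unknown). Topological ordering also rules out an individual being
#' its own ancestor.
#'
#' @param pedigree Pedigree `data.frame` with columns `id`, `sire`, `dam`.
#' @return Invisibly, a list with integer `sire` and `dam` row indices
#'   (`NA` = unknown parent).
#' @export
validate_pedigree <- function(pedigree) {
  required <- c("id", "sire", "dam")
  if (!is.data.frame(pedigree) || !all(required %in% names(pedigree))) {
    stop("pedigree must be a data.frame with columns id, sire, dam")
  }
  if (anyDuplicated(pedigree$id)) stop("pedigree ids must be unique")
  unknown_s <- pedigree$sire %in% c("0", "", NA)
  unknown_d <- pedigree$dam %in% c("0", "", NA)
  si <- match(pedigree$sire, pedigree$id)
  di <- match(pedigree$dam, pedigree$id)
  si[unknown_s] <- NA_integer_
  di[unknown_d] <- NA_integer_
  if (any(!unknown_s & is.na(si)) || any(!unknown_d & is.na(di))) {
    stop("pedigree refers to parents that are not listed as individuals")
  }
  rows <- seq_len(nrow(pedigree))
  if (any(si >= rows, na.rm = TRUE) || any(di >= rows, na.rm = TRUE)) {
    stop("pedigree not topologically ordered: parents must precede offspring")
  }
  invisible(list(sire = si, dam = di))
}
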
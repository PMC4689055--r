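#' Deterministic child seed derivation
#'
#' Experiment drivers run many chains; each gets a child seed derived from
#' the master seed and the run's position in the deterministic loop order,
#' via a Lehmer-style mixing step kept below 2^31. Re-running an experiment
#' with the same master seed therefore reproduces every record.
#'
#' @param master Master integer seed.
#' @param index Run index (>= 1).
#' @return An integer seed in [1, 2^31).
#' @export
derive_seed <- function(master, index) {
  m <- as.double(master) %% 2147483647
  as.integer((m * 48271 + 9973 * as.double(index)) %% 2147483629) + 1L
}

normalize_priors <- function(priors) {
  if (inherits(priors, "prior_spec")) priors <- list(priors)
  if (!is.list(priors) || !all(vapply(priors, inherits, TRUE, "prior_spec"))) {
    stop("priors must be a prior_spec or a list of them")
  }
  if (is.null(names(priors)) || any(!nzchar(names(priors)))) {
    names(priors) <- vapply(priors, function(pr) {
      if (pr$pi > 0 || pr$method == "BayesCpi") {
        sprintf("%s%.4g", pr$method, pr$pi)
      } else pr$method
    }, character(1))
  }
  priors
}

accuracy_quiet <- function(y, g) {
  suppressWarnings(accuracy(y, g))
}

#' Single-QTL experiment: local and whole-genome strategies
#'
#' For every QTL, simulates its heritability-one single-QTL phenotype and
#' evaluates (1) local training and prediction, fitting only the QTL's
#' flanking markers, and (2) whole-genome training (all markers except the
#' QTL set) with local prediction from the flanking markers' genome-wide
#' estimates. Accuracies are training-data correlations between phenotype
#' and DGV. QTL columns never enter a predictor set.
#'
#' @param geno A [genotype_matrix()] (one panel).
#' @param qtl A `qtl_set` on that panel.
#' @param priors A [prior_spec()] or named list of them.
#' @param flanks Flanking half-window sizes k.
#' @param schemes Strategies to run.
#' @param config Chain settings; `config$seed` is the master seed from which
#'   each chain's seed is derived.
#' @param panel Panel label stored in the records (e.g. "sparse", "dense").
#' @param include_average Append per-(method, scheme, k) rows with
#'   `qtl_id = "average"`, the unweighted mean over QTL.
#' @return A `data.frame` of accuracy records: `method`, `pi`, `panel`,
#'   `scheme`, `flank_k`, `qtl_id`, `fold`, `accuracy`.
#' @export
run_single_qtl <- function(geno, qtl, priors, flanks = c(1, 2, 5, 10),
                           schemes = c("local", "whole_genome"),
                           config = chain_config(), panel = "sparse",
                           include_average = TRUE) {
  stopifnot(inherits(qtl, "qtl_set"), length(qtl$indices) >= 1)
  priors <- normalize_priors(priors)
  schemes <- match.arg(schemes, several.ok = TRUE)
  all_qtl <- qtl$indices
  wg_predictors <- setdiff(seq_len(ncol(geno$dosage)), all_qtl)
  rows <- list()
  counter <- 0L
  for (m in names(priors)) {
    prior <- priors[[m]]
    for (qi in seq_along(all_qtl)) {
      q <- all_qtl[qi]
      qid <- qtl$marker_id[qi]
      y <- simulate_phenotype(geno, qtl, "single", target_qtl = q)
      flank_sets <- lapply(flanks, function(k) {
        setdiff(flank_indices(geno$map, q, k), all_qtl)
      })
      if ("local" %in% schemes) {
        for (ki in seq_along(flanks)) {
          counter <- counter + 1L
          cfg <- config
          cfg$seed <- derive_seed(config$seed, counter)
          fit <- train(y, geno, flank_sets[[ki]], prior, cfg)
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, pi = prior$pi, panel = panel, scheme = "local",
            flank_k = as.character(flanks[ki]), qtl_id = qid,
            fold = "training",
            accuracy = accuracy_quiet(y, dgv(geno, fit)),
            stringsAsFactors = FALSE)
        }
      }
      if ("whole_genome" %in% schemes) {
        counter <- counter + 1L
        cfg <- config
        cfg$seed <- derive_seed(config$seed, counter)
        fit <- train(y, geno, wg_predictors, prior, cfg)
        for (ki in seq_along(flanks)) {
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, pi = prior$pi, panel = panel,
            scheme = "whole_genome", flank_k = as.character(flanks[ki]),
            qtl_id = qid, fold = "training",
            accuracy = accuracy_quiet(
              y, dgv(geno, fit, markers = flank_sets[[ki]])),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (include_average) out <- rbind(out, average_over_qtl(out))
  out
}

average_over_qtl <- function(records) {
  per_qtl <- records[records$qtl_id != "average", , drop = FALSE]
  agg <- stats::aggregate(
    accuracy ~ method + pi + panel + scheme + flank_k,
    data = per_qtl, FUN = function(a) mean(a, na.rm = TRUE))
  agg$qtl_id <- "average"
  agg$fold <- "training"
  agg[, c("method", "pi", "panel", "scheme", "flank_k", "qtl_id", "fold",
          "accuracy")]
}

flank_union <- function(map, qtl, k) {
  sort(unique(setdiff(
    unlist(lapply(qtl$indices, function(q) flank_indices(map, q, k))),
    qtl$indices)))
}

#' Summed-QTL (polygenic) experiment: whole-genome training, local prediction
#'
#' One phenotype equal to the sum of all QTL dosages; one whole-genome
#' training per method; local prediction at each flank size k uses the union
#' of the per-QTL flanking windows (each marker counted once), plus an
#' `"all"` row using every trained marker.
#'
#' @inheritParams run_single_qtl
#' @param include_all Add the `flank_k = "all"` record.
#' @return Accuracy records with `qtl_id = "summed"`, one row per
#'   (method, k).
#' @export
run_summed_qtl <- function(geno, qtl, priors, flanks = c(1, 2, 5, 10),
                           config = chain_config(), panel = "sparse",
                           include_all = TRUE) {
  stopifnot(inherits(qtl, "qtl_set"), length(qtl$indices) >= 2)
  priors <- normalize_priors(priors)
  y <- simulate_phenotype(geno, qtl, "summed")
  wg_predictors <- setdiff(seq_len(ncol(geno$dosage)), qtl$indices)
  rows <- list()
  counter <- 0L
  for (m in names(priors)) {
    counter <- counter + 1L
    cfg <- config
    cfg$seed <- derive_seed(config$seed, counter)
    fit <- train(y, geno, wg_predictors, priors[[m]], cfg)
    ks <- as.character(flanks)
    sets <- lapply(flanks, function(k) flank_union(geno$map, qtl, k))
    if (include_all) {
      ks <- c(ks, "all")
      sets <- c(sets, list(wg_predictors))
    }
    for (ki in seq_along(ks)) {
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, pi = priors[[m]]$pi, panel = panel,
        scheme = "whole_genome", flank_k = ks[ki], qtl_id = "summed",
        fold = "training",
        accuracy = accuracy_quiet(y, dgv(geno, fit, markers = sets[[ki]])),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-one-group-out cross-validation for the summed-QTL trait
#'
#' All K combinations of K-1 relatedness groups are used for whole-genome
#' training; the held-out group is predicted from the union of the QTL
#' flanking windows at each k (and from all trained markers). For each fold
#' both the held-out (validation) and the training-set accuracy are
#' recorded; fold-averaged rows are appended with `fold = "average"`.
#'
#' @inheritParams run_summed_qtl
#' @param partition Group labels from [kmeans_groups()], one per individual
#'   of `geno` (at least 2 groups).
#' @return Accuracy records with a `subset` column
#'   (`"validation"`/`"training"`).
#' @export
run_cross_validation <- function(geno, qtl, priors, flanks = c(1, 2, 5, 10),
                                 partition, config = chain_config(),
                                 panel = "sparse", include_all = TRUE) {
  stopifnot(inherits(qtl, "qtl_set"))
  if (length(partition) != nrow(geno$dosage)) {
    stop("partition must label every individual")
  }
  groups <- sort(unique(partition))
  if (length(groups) < 2) stop("partition must have at least 2 groups")
  priors <- normalize_priors(priors)
  y <- simulate_phenotype(geno, qtl, "summed")
  wg_predictors <- setdiff(seq_len(ncol(geno$dosage)), qtl$indices)
  ks <- as.character(flanks)
  sets <- lapply(flanks, function(k) flank_union(geno$map, qtl, k))
  if (include_all) {
    ks <- c(ks, "all")
    sets <- c(sets, list(wg_predictors))
  }
  rows <- list()
  counter <- 0L
  for (m in names(priors)) {
    for (g in groups) {
      counter <- counter + 1L
      val <- which(partition == g)
      trn <- which(partition != g)
      if (stats::sd(y[val]) < 1e-12) {
        warning("fold ", g, " skipped: constant held-out phenotype")
        next
      }
      cfg <- config
      cfg$seed <- derive_seed(config$seed, counter)
      gtrain <- subset_individuals(geno, trn)
      fit <- train(y[trn], gtrain, wg_predictors, priors[[m]], cfg)
      for (ki in seq_along(ks)) {
        # DGV over everyone; a common centering shift leaves correlations
        # within each subset unchanged
        g_all <- dgv(geno, fit, markers = sets[[ki]])
        for (subset in c("validation", "training")) {
          keep <- if (subset == "validation") val else trn
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, pi = priors[[m]]$pi, panel = panel,
            scheme = "whole_genome", flank_k = ks[ki], qtl_id = "summed",
            fold = as.character(g), subset = subset,
            accuracy = accuracy_quiet(y[keep], g_all[keep]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (nrow(out) > 0) {
    agg <- stats::aggregate(
      accuracy ~ method + pi + panel + scheme + flank_k + qtl_id + subset,
      data = out, FUN = function(a) mean(a, na.rm = TRUE))
    agg$fold <- "average"
    out <- rbind(out, agg[, names(out)])
  }
  out
}

#' Per-QTL accuracy against minor allele frequency
#'
#' Joins each QTL's MAF to its single-QTL accuracy records and computes, for
#' every (method, scheme, k) cell with at least 3 QTL and non-degenerate
#' spread, the simple Pearson correlation between MAF and accuracy across
#' QTL.
#'
#' @param records Output of [run_single_qtl()] (per-QTL rows are used).
#' @param geno The `genotype_matrix` the accuracies were computed on.
#' @param qtl The `qtl_set`.
#' @return A list: `per_qtl` (records with a `maf` column), `correlations`
#'   (`method`, `scheme`, `flank_k`, `n_qtl`, `correlation`; `NA` where
#'   undefined), and `maf_summary` (`min`, `mean`, `max` MAF of the QTL
#'   set).
#' @export
run_maf_analysis <- function(records, geno, qtl) {
  stopifnot(inherits(qtl, "qtl_set"))
  maf_tab <- data.frame(qtl_id = qtl$marker_id,
                        maf = as.numeric(
                          maf(geno$dosage[, qtl$indices, drop = FALSE])),
                        stringsAsFactors = FALSE)
  per_qtl <- records[records$qtl_id %in% maf_tab$qtl_id, , drop = FALSE]
  per_qtl <- merge(per_qtl, maf_tab, by = "qtl_id", sort = FALSE)
  cells <- unique(per_qtl[, c("method", "scheme", "flank_k")])
  cells$n_qtl <- NA_integer_
  cells$correlation <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sub <- per_qtl[per_qtl$method == cells$method[i] &
                     per_qtl$scheme == cells$scheme[i] &
                     per_qtl$flank_k == cells$flank_k[i], ]
    ok <- stats::complete.cases(sub[, c("maf", "accuracy")])
    sub <- sub[ok, ]
    cells$n_qtl[i] <- nrow(sub)
    if (nrow(sub) >= 3 && stats::sd(sub$maf) > 1e-12 &&
        stats::sd(sub$accuracy) > 1e-12) {
      cells$correlation[i] <- stats::cor(sub$maf, sub$accuracy)
    }
  }
  list(per_qtl = per_qtl,
       correlations = cells,
       maf_summary = c(min = min(maf_tab$maf), mean = mean(maf_tab$maf),
                       max = max(maf_tab$maf)))
}
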
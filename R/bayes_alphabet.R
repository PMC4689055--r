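#' Prior specification for the Bayesian alphabet
#'
#' Defines the mixture prior on marker effects for the model
#' `y_i = mu + sum_j z_ij beta_j delta_j + e_i`: each marker has zero effect
#' with probability `pi`, and with probability `1 - pi` an effect whose
#' variance follows a scaled inverse chi-square prior with `nu_beta` degrees
#' of freedom and scale `scale_beta`. The family members differ only in
#' `pi` and in whether effect variances are marker-specific or common:
#' \describe{
#'   \item{BayesA}{`pi = 0`, marker-specific variances.}
#'   \item{BayesB}{fixed `pi > 0`, marker-specific variances.}
#'   \item{BayesC / BayesC0}{fixed `pi` (`BayesC0` fixes `pi = 0`), one
#'     common effect variance.}
#'   \item{BayesCpi}{common variance; `pi` estimated from the data under a
#'     uniform prior, `pi` here being only the starting value.}
#' }
#' When `scale_beta` is `NULL` it is derived at fitting time with
#' [derive_scale_beta()] so that the prior-implied genetic variance matches
#' `assumed_genetic_variance` (default: the phenotypic variance, appropriate
#' at heritability 1). `scale_e` defaults to a nominal residual variance of
#' 1 percent of the phenotypic variance; at heritability 1 the posterior is
#' insensitive to it.
#'
#' @param method One of `"BayesA"`, `"BayesB"`, `"BayesC"`, `"BayesC0"`,
#'   `"BayesCpi"`.
#' @param pi Prior probability that a marker has zero effect, in [0, 1)
#'   (`pi = 1` would fit nothing and is rejected). Ignored (forced to 0) for
#'   BayesA and BayesC0; the starting value for BayesCpi.
#' @param nu_beta Degrees of freedom of the effect-variance prior (> 2).
#' @param scale_beta Scale of the effect-variance prior, or `NULL` to derive.
#' @param nu_e,scale_e Residual-variance prior; `scale_e = NULL` derives it.
#' @param assumed_genetic_variance Genetic variance used to derive
#'   `scale_beta`; `NULL` means `var(y)` at fitting time.
#' @param fixed_sigma2_beta,fixed_sigma2_e If non-`NULL`, the corresponding
#'   variance component is held fixed at this value instead of being sampled
#'   (used e.g. to compare BayesC0 with its ridge-regression closed form).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(method = c("BayesC", "BayesA", "BayesB", "BayesC0",
                                  "BayesCpi"),
                       pi = NULL, nu_beta = 4.2, scale_beta = NULL,
                       nu_e = 4, scale_e = NULL,
                       assumed_genetic_variance = NULL,
                       fixed_sigma2_beta = NULL, fixed_sigma2_e = NULL) {
  method <- match.arg(method)
  if (method %in% c("BayesA", "BayesC0")) {
    if (!is.null(pi) && pi != 0) {
      stop(method, " requires pi = 0")
    }
    pi <- 0
  }
  if (is.null(pi)) {
    pi <- switch(method, BayesB = 0.95, BayesC = 0.95, BayesCpi = 0.95, 0)
  }
  if (pi < 0 || pi >= 1) stop("pi must lie in [0, 1); pi = 1 is degenerate")
  if (nu_beta <= 2) stop("nu_beta must exceed 2 for the prior mean to exist")
  if (nu_e <= 0) stop("nu_e must be positive")
  for (v in list(scale_beta, scale_e, fixed_sigma2_beta, fixed_sigma2_e,
                 assumed_genetic_variance)) {
    if (!is.null(v) && v <= 0) stop("variances and scales must be positive")
  }
  structure(list(method = method, pi = pi, nu_beta = nu_beta,
                 scale_beta = scale_beta, nu_e = nu_e, scale_e = scale_e,
                 assumed_genetic_variance = assumed_genetic_variance,
                 fixed_sigma2_beta = fixed_sigma2_beta,
                 fixed_sigma2_e = fixed_sigma2_e),
            class = "prior_spec")
}

#' MCMC chain settings
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Iterations discarded before averaging (< `n_iter`).
#' @param seed Integer seed; identical data, prior, config and seed give an
#'   identical posterior summary.
#' @param thin Keep one post-burn-in sample in `thin`.
#' @param store_samples Retain the per-iteration sampled effect vectors
#'   (needed by [monitor_convergence()]).
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n_iter = 4000, burn_in = 500, seed = 1, thin = 1,
                         store_samples = FALSE) {
  if (burn_in < 0 || burn_in >= n_iter) {
    stop("burn_in must satisfy 0 <= burn_in < n_iter")
  }
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 seed = as.integer(seed), thin = as.integer(thin),
                 store_samples = isTRUE(store_samples)),
            class = "chain_config")
}

#' Expected number of markers fitted per MCMC iteration
#'
#' Under a fixed mixture proportion `pi`, each of `p` markers enters the
#' model with prior probability `1 - pi`, so `(1 - pi) * p` non-zero effects
#' are fitted per iteration on average (e.g. 2500 of 50,000 markers at
#' `pi = 0.95`).
#'
#' @param pi Mixture proportion in [0, 1].
#' @param p Number of markers.
#' @return `(1 - pi) * p`.
#' @export
expected_markers_per_iteration <- function(pi, p) {
  if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  if (p < 0) stop("p must be non-negative")
  (1 - pi) * p
}

#' Derive the effect-variance prior scale from an assumed genetic variance
#'
#' Chooses `scale_beta` so that the prior-implied additive genetic variance,
#' `(1 - pi) * n_markers * mean_2pq * E[sigma2_beta]` with
#' `E[sigma2_beta] = nu_beta * scale_beta / (nu_beta - 2)`, equals the
#' assumed genetic variance:
#' `scale = V * (nu - 2) / (nu * (1 - pi) * n_markers * mean_2pq)`.
#'
#' @param genetic_variance Assumed additive genetic variance of the trait.
#' @param pi Mixture proportion in [0, 1).
#' @param nu_beta Degrees of freedom (> 2).
#' @param mean_2pq Mean of `2 p q` over the training markers (> 0).
#' @param n_markers Number of training markers.
#' @return The prior scale.
#' @export
derive_scale_beta <- function(genetic_variance, pi, nu_beta, mean_2pq,
                              n_markers) {
  if (pi >= 1) stop("pi = 1 leaves no markers to carry the variance")
  if (nu_beta <= 2) stop("nu_beta must exceed 2")
  if (mean_2pq <= 0) stop("mean_2pq must be positive")
  if (genetic_variance <= 0) stop("genetic_variance must be positive")
  genetic_variance * (nu_beta - 2) /
    (nu_beta * (1 - pi) * n_markers * mean_2pq)
}

#' Fit a Bayesian-alphabet model by single-site Gibbs sampling
#'
#' Samples, per iteration: the intercept from its normal full conditional;
#' for each marker in fixed ascending order, the inclusion indicator from its
#' Bernoulli full conditional with the effect integrated out, then (if
#' included) the effect from its normal full conditional; the effect
#' variance(s) from scaled inverse chi-square conditionals (marker-specific
#' for BayesA/B, common for the BayesC family; an excluded BayesB locus
#' redraws its variance from the prior); the residual variance from its
#' scaled inverse chi-square conditional (floored at 1e-8, since at
#' heritability 1 it collapses towards zero); and, for BayesCpi, `pi` from
#' `Beta(#excluded + 1, #included + 1)`. Marker dosages are centered before
#' fitting and the intercept absorbs the mean, which leaves prediction
#' correlations unchanged. Monomorphic columns are skipped (zero effect).
#'
#' @param Z A [genotype_matrix()] or plain dosage matrix (any subset of a
#'   panel: local window or whole genome, QTL columns excluded by the
#'   caller).
#' @param y Numeric phenotype vector, one value per row of `Z`; must not be
#'   constant.
#' @param prior A [prior_spec()].
#' @param config A [chain_config()].
#' @return An object of class `posterior_summary`: per-marker posterior mean
#'   substitution effects (`effect`, the mean of `beta * delta`), inclusion
#'   frequencies (`inclusion`, the "model frequency"), posterior means of
#'   `mu`, the variance components and `pi`, plus the column `center`ing
#'   used, and (if requested) the stored post-burn-in effect `samples`.
#' @export
run_chain <- function(Z, y, prior, config = chain_config()) {
  stopifnot(inherits(prior, "prior_spec"), inherits(config, "chain_config"))
  if (inherits(Z, "genotype_matrix")) {
    ids <- Z$map$marker_id
    X <- Z$dosage
  } else {
    X <- as.matrix(Z)
    ids <- colnames(X)
    if (is.null(ids)) ids <- sprintf("m%d", seq_len(ncol(X)))
  }
  storage.mode(X) <- "double"
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(Z)")
  if (anyNA(y) || anyNA(X)) stop("missing values are not supported")
  if (p < 1) stop("at least one marker column is required")
  if (stats::var(y) <= 0) stop("refusing to fit a constant phenotype")

  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  vy <- stats::var(y)

  scale_beta <- prior$scale_beta
  if (is.null(scale_beta) && is.null(prior$fixed_sigma2_beta)) {
    gv <- prior$assumed_genetic_variance
    if (is.null(gv)) gv <- vy
    freq <- center / 2
    mean_2pq <- mean(2 * freq * (1 - freq))
    if (mean_2pq <= 0) mean_2pq <- 0.5  # all-monomorphic guard
    scale_beta <- derive_scale_beta(gv, prior$pi, prior$nu_beta, mean_2pq, p)
  }
  if (is.null(scale_beta)) scale_beta <- 1  # unused when variance is fixed
  scale_e <- prior$scale_e
  if (is.null(scale_e)) {
    scale_e <- max(0.01 * vy * (prior$nu_e - 2) / prior$nu_e, 1e-8)
  }

  code <- switch(prior$method, BayesA = 0L, BayesB = 1L, BayesC = 2L,
                 BayesC0 = 2L, BayesCpi = 3L)
  set.seed(config$seed)
  res <- gibbs_chain(Xc, as.numeric(y), code, prior$pi, prior$nu_beta,
                     scale_beta, prior$nu_e, scale_e,
                     !is.null(prior$fixed_sigma2_beta),
                     ifelse(is.null(prior$fixed_sigma2_beta), 0,
                            prior$fixed_sigma2_beta),
                     !is.null(prior$fixed_sigma2_e),
                     ifelse(is.null(prior$fixed_sigma2_e), 0,
                            prior$fixed_sigma2_e),
                     config$n_iter, config$burn_in, config$thin,
                     config$store_samples)
  structure(list(marker_id = ids,
                 effect = as.numeric(res$effect),
                 inclusion = as.numeric(res$inclusion),
                 mu = res$mu,
                 sigma2_e = res$sigma2_e,
                 sigma2_beta = res$sigma2_beta,
                 pi = res$pi,
                 pi_samples = res$pi_samples,
                 samples = res$samples,
                 center = center,
                 n_kept = res$n_kept,
                 method = prior$method,
                 prior = prior,
                 config = config),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    "%s posterior over %d markers (%d kept samples)\n",
    x$method, length(x$effect), x$n_kept))
  cat(sprintf("  mu = %.4f, sigma2_e = %.3g, sigma2_beta = %.3g, pi = %.4f\n",
              x$mu, x$sigma2_e, x$sigma2_beta, x$pi))
  invisible(x)
}

#' Convergence of the chain's predictive ability
#'
#' Averages the stored post-burn-in effect samples up to each checkpoint to
#' obtain running posterior means, forms fitted values on the training
#' genotypes, and reports the correlation with the training phenotype. A
#' trajectory that plateaus indicates that the chain's predictive ability
#' has converged; the final checkpoint reproduces the full-chain training
#' correlation exactly.
#'
#' @param posterior A `posterior_summary` fitted with
#'   `store_samples = TRUE`.
#' @param Z Training genotypes (the same markers the chain was fitted on).
#' @param y Training phenotype.
#' @param checkpoints Increasing positive integers indexing kept post-burn-in
#'   samples; must not exceed the number stored.
#' @return `data.frame` with columns `checkpoint` and `correlation`.
#' @export
monitor_convergence <- function(posterior, Z, y, checkpoints) {
  stopifnot(inherits(posterior, "posterior_summary"))
  S <- posterior$samples
  if (is.null(S)) {
    stop("chain was run without store_samples = TRUE")
  }
  checkpoints <- as.integer(checkpoints)
  if (length(checkpoints) == 0 || any(checkpoints < 1)) {
    stop("checkpoints must be positive sample indices")
  }
  if (any(checkpoints > nrow(S))) {
    stop("checkpoint beyond the ", nrow(S), " stored samples")
  }
  X <- if (inherits(Z, "genotype_matrix")) Z$dosage else as.matrix(Z)
  storage.mode(X) <- "double"
  if (ncol(X) != ncol(S)) stop("Z does not match the trained markers")
  Xc <- sweep(X, 2, colMeans(X))
  correlation <- vapply(checkpoints, function(cp) {
    eff <- colMeans(S[seq_len(cp), , drop = FALSE])
    fitted <- drop(Xc %*% eff)
    if (stats::sd(fitted) < 1e-12) return(NA_real_)
    stats::cor(y, fitted)
  }, numeric(1))
  data.frame(checkpoint = checkpoints, correlation = correlation)
}

#' Write a posterior summary to CSV
#'
#' One row per marker: `marker_id`, `posterior_mean_effect`,
#' `model_frequency`. Variance components, `pi`, and the chain settings are
#' written as comment lines prefixed with `#`.
#'
#' @param posterior A `posterior_summary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(posterior, path) {
  stopifnot(inherits(posterior, "posterior_summary"))
  meta <- sprintf(
    "# method=%s pi=%.6g sigma2_e=%.6g sigma2_beta=%.6g mu=%.6g n_iter=%d burn_in=%d thin=%d seed=%d",
    posterior$method, posterior$pi, posterior$sigma2_e,
    posterior$sigma2_beta, posterior$mu, posterior$config$n_iter,
    posterior$config$burn_in, posterior$config$thin, posterior$config$seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(data.frame(marker_id = posterior$marker_id,
                              posterior_mean_effect = posterior$effect,
                              model_frequency = posterior$inclusion),
                   con, row.names = FALSE)
  invisible(path)
}
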
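#' MCMC chain settings for the Bayesian alphabet learners
#'
#' Hyperprior defaults are conventional rather than dataset-specific: scaled
#' inverse-chi-square priors with 5 degrees of freedom for both the marker and
#' residual variances, with scales set so that the prior expectation splits the
#' phenotypic variance evenly between markers and residual (`r2 = 0.5`).
#'
#' @param n_iter Total Gibbs iterations (default 5000).
#' @param burn_in Burn-in iterations discarded (default 1000).
#' @param df_beta,df_e Prior degrees of freedom for marker / residual
#'   variances.
#' @param r2 Prior proportion of phenotypic variance attributed to markers,
#'   used to set the prior scales.
#' @return List of class `chain_config`.
#' @export
chain_config <- function(n_iter = 5000L, burn_in = 1000L,
                         df_beta = 5, df_e = 5, r2 = 0.5) {
  if (n_iter <= burn_in || burn_in < 0) {
    abort("Need `n_iter` > `burn_in` >= 0.")
  }
  if (df_beta <= 2 || df_e <= 2) {
    abort("Prior degrees of freedom must exceed 2 for a finite prior mean.")
  }
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 df_beta = df_beta, df_e = df_e, r2 = r2),
            class = "chain_config")
}

#' Bayesian-alphabet whole-genome regression (BayesA / BayesB / BayesCpi)
#'
#' Single-site Gibbs samplers for `y = X alpha + Z beta + e` with the three
#' classic marker-effect priors: BayesA gives every marker its own effect
#' variance with a scaled inverse-chi-square prior; BayesB is a spike-and-slab
#' with per-marker slab variances and a fixed prior probability `pi` that a
#' marker has a non-zero effect (default 0.1); BayesCpi shares one slab
#' variance across markers and samples `pi` from its Beta full conditional
#' under a uniform prior. Markers are column-centered on the training
#' individuals; the fixed part is an intercept. Genetic values for masked
#' individuals are `Z_test %*% posterior-mean(beta)`.
#'
#' @inheritParams fit_gblup
#' @inheritParams as_genotype_matrix
#' @param genotypes Genotype codes for every phenotype individual (matrix or
#'   data frame, see [as_genotype_matrix()]).
#' @param variant `"A"`, `"B"` or `"Cpi"`.
#' @param chain A [chain_config()].
#' @param pi Prior probability that a marker effect is non-zero (BayesB fixed
#'   value; BayesCpi initial value, default 0.5 before the sampler updates it).
#' @param seed Optional RNG seed for the chain.
#' @return A `learner_fit` with posterior-mean marker effects, genetic values,
#'   residual variance and (for BayesCpi) the posterior mean of `pi`.
#' @export
fit_bayes <- function(phenotypes, genotypes, variant = c("A", "B", "Cpi"),
                      chain = chain_config(), pi = NULL, seed = NULL,
                      missing = c("impute_mean", "error")) {
  variant <- match.arg(variant)
  ph <- validate_phenotypes(phenotypes)
  Z <- as_genotype_matrix(genotypes, missing)
  ids <- as.character(ph$individual_id)
  if (!all(ids %in% rownames(Z))) {
    abort("`genotypes` must cover every phenotype individual_id.")
  }
  Z <- Z[ids, , drop = FALSE]
  y <- ph$phenotype
  train <- which(!is.na(y))
  if (length(train) < 3L) abort("Bayesian fits need at least 3 unmasked individuals.")
  if (ncol(fixed_design(ph)) > 1L) {
    warn("Covariates beyond the intercept are ignored by the Bayesian samplers.")
  }

  mu_z <- colMeans(Z[train, , drop = FALSE])
  Zc <- sweep(Z, 2, mu_z)
  Z1 <- Zc[train, , drop = FALSE]
  y1 <- y[train]

  var_y <- var(y1)
  msx <- sum(apply(Z1, 2, var))
  if (msx <= 0) abort("All markers are monomorphic in the training set.")
  pi_use <- if (!is.null(pi)) pi else if (variant == "B") 0.1 else 0.5
  if (pi_use <= 0 || pi_use >= 1) abort("`pi` must lie strictly in (0, 1).")
  nu_b <- chain$df_beta
  nu_e <- chain$df_e
  frac <- if (variant == "A") 1 else pi_use
  scale_b <- chain$r2 * var_y * (nu_b - 2) / (nu_b * msx * frac)
  scale_e <- (1 - chain$r2) * var_y * (nu_e - 2) / nu_e

  if (!is.null(seed)) set.seed(seed)
  res <- bayes_alphabet_gibbs(
    y1, Z1, match(variant, c("A", "B", "Cpi")) - 1L,
    chain$n_iter, chain$burn_in,
    pi_use, variant == "Cpi",
    nu_b, scale_b, nu_e, scale_e
  )

  g_hat <- as.numeric(Zc %*% res$beta_mean)
  varcomp <- list(sigma2_e = res$sigma2_e_mean)
  if (variant == "Cpi") varcomp$pi_post <- res$pi_mean
  if (variant == "B") varcomp$pi <- pi_use

  new_learner_fit(
    method = paste0("Bayes", variant),
    values = tibble::tibble(
      individual_id = ph$individual_id,
      genetic_value = g_hat,
      fitted_value = res$mu_mean + g_hat,
      masked = is.na(y)
    ),
    fixed_effects = c(`(Intercept)` = res$mu_mean),
    varcomp = varcomp,
    marker_effects = tibble::tibble(
      marker_id = colnames(Z),
      effect = as.numeric(res$beta_mean),
      inclusion_prob = as.numeric(res$inclusion_prob)
    ),
    chain = chain
  )
}
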
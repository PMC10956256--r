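#' Genomic BLUP with REML variance components
#'
#' Fits the mixed model `y = X alpha + g + e`, `g ~ N(0, K sigma_g^2)`,
#' `e ~ N(0, I sigma_e^2)`, on the unmasked (non-`NA`) phenotypes. Variance
#' components are estimated by restricted maximum likelihood profiled over the
#' ratio `delta = sigma_e^2 / sigma_g^2` after an eigendecomposition of the
#' training-block kinship, and genetic values of all individuals (including
#' masked ones) are obtained as the BLUP conditional mean through the kinship
#' cross-block. If the kinship is numerically indefinite (smallest eigenvalue
#' below 1e-8) a 1e-6 ridge is added to its diagonal.
#'
#' @param phenotypes A tibble with `individual_id`, `phenotype` (`NA` for
#'   masked/test individuals) and optional numeric covariate columns used as
#'   fixed effects (an intercept is always included).
#' @param kinship Kinship matrix covering all phenotype ids (see
#'   [build_grm()]).
#' @return A `learner_fit`: per-individual genetic values, fixed-effect
#'   estimates, variance components (`sigma2_g`, `sigma2_e`, `h2`), REML
#'   log-likelihood.
#' @export
fit_gblup <- function(phenotypes, kinship) {
  ph <- validate_phenotypes(phenotypes)
  ids <- as.character(ph$individual_id)
  if (is.null(dimnames(kinship)) || !all(ids %in% rownames(kinship))) {
    abort("`kinship` must have dimnames covering every phenotype individual_id.")
  }
  K <- kinship[ids, ids, drop = FALSE]
  y <- ph$phenotype
  train <- which(!is.na(y))
  if (length(train) < 3L) abort("GBLUP needs at least 3 unmasked individuals.")
  X <- fixed_design(ph)
  X1 <- X[train, , drop = FALSE]
  y1 <- y[train]
  K11 <- K[train, train, drop = FALSE]

  # rank deficiency is handled by the variance-ratio shift; a diagonal ridge
  # is only needed when the kinship is genuinely indefinite
  eg <- eigen(K11, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    K11 <- K11 + diag(1e-6, nrow(K11))
    eg <- eigen(K11, symmetric = TRUE)
  }
  U <- eg$vectors
  d <- pmax(eg$values, 0)
  ys <- crossprod(U, y1)
  Xs <- crossprod(U, X1)
  n1 <- length(y1)
  q <- ncol(X1)

  # REML log-likelihood profiled in log10(delta), delta = sigma_e^2 / sigma_g^2
  reml_ll <- function(log10_delta) {
    delta <- 10^log10_delta
    w <- d + delta
    XtWX <- crossprod(Xs / w, Xs)
    beta <- solve(XtWX, crossprod(Xs / w, ys))
    r <- ys - Xs %*% beta
    rss <- sum(r^2 / w)
    -0.5 * ((n1 - q) * log(rss) + sum(log(w)) +
              determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- optimize(reml_ll, interval = c(-12, 10), maximum = TRUE, tol = 1e-10)
  delta <- 10^opt$maximum
  w <- d + delta
  XtWX <- crossprod(Xs / w, Xs)
  beta <- solve(XtWX, crossprod(Xs / w, ys))
  r1 <- ys - Xs %*% beta
  sigma2_g <- sum(r1^2 / w) / (n1 - q)
  sigma2_e <- delta * sigma2_g

  # BLUP: g_hat = K_(.,train) (K11 + delta I)^{-1} (y1 - X1 beta)
  resid_raw <- y1 - X1 %*% beta
  alpha <- U %*% (crossprod(U, resid_raw) / w)
  g_hat <- as.numeric(K[, train, drop = FALSE] %*% alpha)
  fixed <- as.numeric(X %*% beta)

  new_learner_fit(
    method = "GBLUP",
    values = tibble::tibble(
      individual_id = ph$individual_id,
      genetic_value = g_hat,
      fitted_value = fixed + g_hat,
      masked = is.na(y)
    ),
    fixed_effects = setNames(as.numeric(beta), colnames(X)),
    varcomp = list(sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                   h2 = sigma2_g / (sigma2_g + sigma2_e),
                   reml_loglik = as.numeric(opt$objective))
  )
}

validate_phenotypes <- function(phenotypes) {
  if (!is.data.frame(phenotypes)) abort("`phenotypes` must be a data frame.")
  ph <- tibble::as_tibble(phenotypes)
  if (!all(c("individual_id", "phenotype") %in% names(ph))) {
    abort("`phenotypes` needs columns `individual_id` and `phenotype`.")
  }
  if (anyDuplicated(ph$individual_id)) {
    dup <- ph$individual_id[duplicated(ph$individual_id)][1]
    abort(sprintf("Duplicated individual_id in phenotypes: '%s'.", dup))
  }
  covars <- setdiff(names(ph), c("individual_id", "phenotype"))
  if (!all(vapply(ph[covars], is.numeric, logical(1)))) {
    abort("Covariate columns must be numeric.")
  }
  ph
}

fixed_design <- function(ph) {
  covars <- setdiff(names(ph), c("individual_id", "phenotype"))
  X <- cbind(`(Intercept)` = rep(1, nrow(ph)))
  if (length(covars)) X <- cbind(X, as.matrix(ph[covars]))
  X
}

new_learner_fit <- function(method, values, fixed_effects, varcomp,
                            marker_effects = NULL, chain = NULL) {
  structure(list(
    method = method, values = values, fixed_effects = fixed_effects,
    varcomp = varcomp, marker_effects = marker_effects, chain = chain
  ), class = "learner_fit")
}

#' @export
print.learner_fit <- function(x, ...) {
  cat(sprintf("<learner_fit> %s: %d individuals (%d masked)\n",
              x$method, nrow(x$values), sum(x$values$masked)))
  vc <- x$varcomp
  cat("  ", paste(sprintf("%s=%.4g", names(vc), unlist(vc)), collapse = ", "), "\n")
  invisible(x)
}

#' Per-individual genetic values of a base-learner fit
#'
#' @param x A `learner_fit`.
#' @param ... Unused.
#' @return Tibble with `individual_id`, `genetic_value`, `fitted_value`
#'   (fixed effects + genetic value) and `masked`.
#' @export
tidy.learner_fit <- function(x, ...) x$values

#' One-row summary of a base-learner fit
#'
#' @param x A `learner_fit`.
#' @param ... Unused.
#' @return Tibble with the method name, variance components and (for Bayesian
#'   fits) chain settings and posterior mixing proportion.
#' @export
glance.learner_fit <- function(x, ...) {
  out <- tibble::tibble(method = x$method)
  out <- dplyr::bind_cols(out, tibble::as_tibble(x$varcomp))
  if (!is.null(x$chain)) {
    out$n_iter <- x$chain$n_iter
    out$burn_in <- x$chain$burn_in
  }
  out
}
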
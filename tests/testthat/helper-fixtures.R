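# Shared fixtures and independent oracles, all generated in code.

# Small prediction set: n individuals, base predictions = g + method noise.
make_noisy_predictions <- function(n = 20, noise_sd = c(0.3, 0.6), seed = 1) {
  set.seed(seed)
  g <- rnorm(n)
  preds <- tibble::tibble(individual_id = seq_len(n))
  for (j in seq_along(noise_sd)) {
    preds[[paste0("method_", letters[j])]] <- g + rnorm(n, 0, noise_sd[j])
  }
  list(predictions = preds, g = g)
}

# Exhaustive grid-search oracle for 2-method weight problems: evaluates the
# correlation fitness on a regular grid over [0,1]^2 and returns the maximum.
# Built independently of the DE-PSO path (direct matrix arithmetic + cor()).
grid_oracle_fitness <- function(predictions, target, step = 0.005) {
  p <- as.matrix(predictions[setdiff(names(predictions), "individual_id")])
  stopifnot(ncol(p) == 2)
  w <- seq(0, 1, by = step)
  grid <- as.matrix(expand.grid(w1 = w, w2 = w))
  g <- p %*% t(grid)
  keep <- apply(g, 2, sd) > 0
  best <- -Inf
  if (any(keep)) best <- max(cor(g[, keep, drop = FALSE], target))
  best
}

# Direct mixed-model-equation / ridge-regression solve on centered markers:
# the RR-BLUP oracle equivalent to GBLUP at matched variance components.
rrblup_oracle <- function(Z, y_train, train_idx, sigma2_g, sigma2_e) {
  p <- colMeans(Z) / 2
  poly <- apply(Z, 2, var) > 0
  Zc <- sweep(Z[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  # K = Zc Zc' / denom with Var(g) = K sigma2_g  <=>  per-marker variance
  # sigma2_beta = sigma2_g / denom, ridge penalty lambda = sigma2_e / sigma2_beta
  lambda <- sigma2_e * denom / sigma2_g
  Z1 <- Zc[train_idx, , drop = FALSE]
  X1 <- matrix(1, length(train_idx), 1)
  q <- ncol(X1)
  lhs <- rbind(
    cbind(crossprod(X1), crossprod(X1, Z1)),
    cbind(crossprod(Z1, X1), crossprod(Z1) + diag(lambda, ncol(Z1)))
  )
  rhs <- c(crossprod(X1, y_train), crossprod(Z1, y_train))
  sol <- solve(lhs, rhs)
  beta <- sol[-seq_len(q)]
  list(intercept = unname(sol[1]), g_all = as.numeric(Zc %*% beta))
}

# Small genotype/trait scenario for learner tests.
make_sim_scenario <- function(n = 100, p = 200, n_qtl = 5, h2 = 0.5, seed = 1,
                              marker_type = "binary_dominant") {
  d <- sim_design(n_individuals = n, n_markers = p, n_qtl = n_qtl,
                  heritability = h2, marker_type = marker_type, seed = seed)
  Z <- sim_genotypes(d)
  tr <- sim_trait(Z, d)
  list(design = d, Z = Z, trait = tr)
}
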
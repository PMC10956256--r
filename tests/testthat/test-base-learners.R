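test_that("GRM matches the hand-evaluated centering/scaling formula", {
  Z <- matrix(c(0, 2, 1,
                2, 0, 1), nrow = 3,
              dimnames = list(c("i1", "i2", "i3"), c("m1", "m2")))
  # p = (0.5, 0.5); centered rows: (-1,1), (1,-1), (0,0); denom = 2*(0.25+0.25)=1
  G <- build_grm(Z)
  expect_equal(unname(G),
               matrix(c(2, -2, 0, -2, 2, 0, 0, 0, 0), nrow = 3))
  # independent oracle: direct matrix product
  Zc <- sweep(Z, 2, 2 * colMeans(Z) / 2)
  expect_equal(unname(G), unname(tcrossprod(Zc) / 1))
})

test_that("GRM is symmetric, duplicates match diagonals, monomorphic rejected", {
  sc <- make_sim_scenario(n = 30, p = 50, seed = 21)
  G <- build_grm(sc$Z)
  expect_equal(G, t(G))
  # duplicated genotype rows give off-diagonal equal to the diagonal
  Z2 <- rbind(a = sc$Z[1, ], b = sc$Z[1, ], c = sc$Z[2, ])
  G2 <- build_grm(Z2)
  expect_equal(G2["a", "b"], G2["a", "a"])
  expect_error(build_grm(matrix(1, 3, 4)), "monomorphic")
})

test_that("GBLUP reproduces near-noiseless phenotypes", {
  sc <- make_sim_scenario(n = 12, p = 60, seed = 5)
  G <- build_grm(sc$Z)
  ev <- eigen(G, symmetric = TRUE)
  y <- 5 + 3 * ev$vectors[, 1]
  ph <- tibble::tibble(individual_id = rownames(sc$Z), phenotype = y)
  fit <- fit_gblup(ph, G)
  expect_lt(max(abs(tidy(fit)$fitted_value - y)), 1e-6)
})

test_that("GBLUP equals the direct ridge-regression solve at matched variances", {
  sc <- make_sim_scenario(n = 8, p = 5, seed = 31)
  G <- build_grm(sc$Z)
  y <- sc$trait$phenotypes$phenotype
  ph <- tibble::tibble(individual_id = rownames(sc$Z), phenotype = y)
  ph$phenotype[7:8] <- NA  # masked individuals predicted through kinship
  fit <- fit_gblup(ph, G)
  vc <- fit$varcomp
  oracle <- rrblup_oracle(sc$Z, y[1:6], 1:6, vc$sigma2_g, vc$sigma2_e)
  expect_equal(tidy(fit)$genetic_value, oracle$g_all, tolerance = 1e-6)
  expect_equal(unname(fit$fixed_effects["(Intercept)"]), oracle$intercept,
               tolerance = 1e-6)
})

test_that("GBLUP is invariant to phenotype translation and row permutation", {
  sc <- make_sim_scenario(n = 25, p = 80, seed = 8)
  G <- build_grm(sc$Z)
  ph <- tibble::tibble(individual_id = rownames(sc$Z),
                       phenotype = sc$trait$phenotypes$phenotype)
  ph$phenotype[21:25] <- NA
  f1 <- fit_gblup(ph, G)
  ph2 <- ph; ph2$phenotype <- ph$phenotype + 100
  f2 <- fit_gblup(ph2, G)
  expect_equal(tidy(f1)$genetic_value, tidy(f2)$genetic_value, tolerance = 1e-6)
  expect_equal(unname(f2$fixed_effects["(Intercept)"] -
                        f1$fixed_effects["(Intercept)"]), 100, tolerance = 1e-6)
  # permuting individuals permutes outputs identically
  perm <- sample(nrow(ph))
  f3 <- fit_gblup(ph[perm, ], G)
  expect_equal(tidy(f3)$genetic_value,
               tidy(f1)$genetic_value[perm], tolerance = 1e-6)
})

test_that("Bayesian samplers shrink null effects and are seed-reproducible", {
  set.seed(14)
  Z <- matrix(rbinom(100 * 50, 2, 0.4), 100, 50,
              dimnames = list(paste0("i", 1:100), paste0("m", 1:50)))
  y <- rnorm(100)  # no genetic signal
  ph <- tibble::tibble(individual_id = rownames(Z), phenotype = y)
  ch <- chain_config(3000, 500)
  for (v in c("A", "B", "Cpi")) {
    fit <- fit_bayes(ph, Z, v, ch, seed = 99)
    expect_lt(mean(abs(fit$marker_effects$effect)), 0.1 * sd(y))
    fit2 <- fit_bayes(ph, Z, v, ch, seed = 99)
    expect_identical(fit$marker_effects$effect, fit2$marker_effects$effect)
  }
})

test_that("a single large-effect marker is recovered as the top effect", {
  hits <- 0L
  for (s in 1:5) {
    set.seed(400 + s)
    Z <- matrix(rbinom(120 * 60, 2, 0.45), 120, 60,
                dimnames = list(paste0("i", 1:120), paste0("m", 1:60)))
    g <- 1.0 * Z[, 17]
    y <- g + rnorm(120, 0, sd(g))  # marker explains ~50% of variance
    ph <- tibble::tibble(individual_id = rownames(Z), phenotype = y)
    fit <- fit_bayes(ph, Z, "B", chain_config(1500, 300), seed = s)
    if (which.max(abs(fit$marker_effects$effect)) == 17L) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("BayesCpi posterior pi concentrates near the true sparsity", {
  ok <- 0L
  for (s in 1:5) {
    set.seed(500 + s)
    Z <- matrix(rbinom(200 * 500, 2, 0.35), 200, 500,
                dimnames = list(paste0("i", 1:200), paste0("m", 1:500)))
    qtl <- sample(500, 5)
    g <- as.numeric(Z[, qtl] %*% rep(0.8, 5))
    y <- g + rnorm(200, 0, sd(g))
    ph <- tibble::tibble(individual_id = rownames(Z), phenotype = y)
    fit <- fit_bayes(ph, Z, "Cpi", chain_config(1500, 500), seed = s)
    if (fit$varcomp$pi_post > 0 && fit$varcomp$pi_post < 0.2) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("a vanishing slab drives predictions to the fixed-effects-only fit", {
  sc <- make_sim_scenario(n = 60, p = 40, seed = 77)
  y <- sc$trait$phenotypes$phenotype
  ph <- tibble::tibble(individual_id = rownames(sc$Z), phenotype = y)
  fit <- fit_bayes(ph, sc$Z, "B", chain_config(800, 200, r2 = 1e-8), seed = 3)
  expect_lt(max(abs(tidy(fit)$genetic_value)), 0.01 * sd(y))
  expect_equal(unname(fit$fixed_effects["(Intercept)"]), mean(y),
               tolerance = 0.05 * sd(y))
})

test_that("GBLUP and BayesA agree under a dense polygenic architecture", {
  d <- sim_design(n_individuals = 150, n_markers = 400, n_qtl = 400,
                  heritability = 0.5, seed = 606)
  Z <- sim_genotypes(d)
  tr <- sim_trait(Z, d)
  ph <- tibble::tibble(individual_id = rownames(Z),
                       phenotype = tr$phenotypes$phenotype)
  gb <- fit_gblup(ph, build_grm(Z))
  ba <- fit_bayes(ph, Z, "A", chain_config(1500, 300), seed = 606)
  expect_gt(cor(tidy(gb)$genetic_value, tidy(ba)$genetic_value), 0.8)
})

test_that("genotype loading validates and imputes", {
  Z <- matrix(c(0, 1, NA, 2, 1, 0), 3, 2,
              dimnames = list(c("a", "b", "c"), c("m1", "m2")))
  imp <- as_genotype_matrix(Z)
  expect_false(anyNA(imp))
  expect_equal(imp["c", "m1"], 0.5)  # mean of 0 and 1
  expect_error(as_genotype_matrix(Z, missing = "error"), "missing")
  bad <- matrix(3, 2, 2, dimnames = list(c("a", "b"), c("m1", "m2")))
  expect_error(as_genotype_matrix(bad), "codes")
})
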
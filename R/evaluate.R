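#' Monte-Carlo cross-validation split plans
#'
#' Each replicate is an independent uniform random partition of the ids.
#' `"ratio_9_1"` holds out `round(n/10)` individuals; `"parts_5_hold_1"` splits
#' the ids into 5 near-equal parts and holds out one part chosen at random
#' (4 parts train, 1 part test).
#'
#' @param ids Vector of individual ids.
#' @param scheme `"ratio_9_1"` or `"parts_5_hold_1"`.
#' @param n_replicates Number of independent splits.
#' @param seed RNG seed.
#' @return Tibble with `replicate`, and list-columns `train` and `test`.
#' @export
make_splits <- function(ids, scheme = c("ratio_9_1", "parts_5_hold_1"),
                        n_replicates = 100L, seed = 1L) {
  scheme <- match.arg(scheme)
  n <- length(ids)
  if (scheme == "ratio_9_1" && n < 10L) abort("ratio_9_1 needs at least 10 ids.")
  if (scheme == "parts_5_hold_1" && n < 5L) abort("parts_5_hold_1 needs at least 5 ids.")
  if (anyDuplicated(ids)) abort("`ids` must be unique.")
  set.seed(seed)
  plans <- purrr::map(seq_len(n_replicates), function(r) {
    perm <- sample(ids)
    if (scheme == "ratio_9_1") {
      n_test <- round(n / 10)
      test <- perm[seq_len(n_test)]
    } else {
      part <- rep(seq_len(5L), times = diff(floor(seq(0, n, length.out = 6L))))
      test <- perm[part == sample.int(5L, 1L)]
    }
    list(train = setdiff(ids, test), test = test)
  })
  tibble::tibble(
    replicate = seq_len(n_replicates),
    train = purrr::map(plans, "train"),
    test = purrr::map(plans, "test")
  )
}

#' Predictive ability (Pearson correlation)
#'
#' The standard measure of genomic-prediction performance: the Pearson
#' correlation between predicted genetic values and observed phenotypes in the
#' held-out set. Constant inputs are an error rather than a silent zero.
#'
#' @param predicted,observed Aligned numeric vectors of length >= 3.
#' @return A single correlation in `[-1, 1]`.
#' @export
predictive_ability <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    abort("`predicted` and `observed` must have equal length.")
  }
  if (length(predicted) < 3L) abort("Predictive ability needs at least 3 pairs.")
  if (sd(predicted) == 0 || sd(observed) == 0) {
    abort("Predictive ability is undefined for constant input.")
  }
  cor(predicted, observed)
}

#' Paired-sample t-test on per-replicate abilities
#'
#' Tests the mean of the per-replicate differences `d = a - b` against zero:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom. Because
#' every method is evaluated on the same splits, the paired design applies.
#' Two-sided by default.
#'
#' @param a,b Equal-length numeric vectors of per-replicate abilities.
#' @param alternative Passed to the t distribution: `"two.sided"`, `"greater"`
#'   or `"less"` (direction of `a` relative to `b`).
#' @return Tibble with `estimate` (mean difference), `statistic`, `df`,
#'   `p_value`, `alternative`.
#' @export
paired_t_test <- function(a, b, alternative = "two.sided") {
  if (length(a) != length(b)) abort("`a` and `b` must be paired (equal length).")
  if (length(a) < 2L) abort("Paired t-test needs at least 2 pairs.")
  d <- a - b
  if (sd(d) == 0) {
    abort(paste("Zero variance of the paired differences (identical methods",
                "on every replicate); the t statistic is undefined."))
  }
  ht <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
  tibble::tibble(
    estimate = unname(ht$estimate),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    alternative = alternative
  )
}

# Fit all base learners on masked phenotypes; returns named list of
# per-individual genetic-value tibbles covering every individual.
fit_base_methods <- function(ph_masked, Z, kinship, chain, seed,
                             learners = NULL) {
  if (!is.null(learners)) {
    return(purrr::imap(learners, function(f, nm) f(ph_masked, Z)))
  }
  list(
    GBLUP = tidy(fit_gblup(ph_masked, kinship)),
    BayesA = tidy(fit_bayes(ph_masked, Z, "A", chain, seed = seed + 1L)),
    BayesB = tidy(fit_bayes(ph_masked, Z, "B", chain, seed = seed + 2L)),
    BayesCpi = tidy(fit_bayes(ph_masked, Z, "Cpi", chain, seed = seed + 3L))
  )
}

# One cross-validation replicate: fit base methods, pick the reference method
# from training fit, train the ensemble, return per-method test abilities.
benchmark_replicate <- function(ph, Z, kinship, train_ids, test_ids,
                                swarm, chain, mode, seed, learners = NULL,
                                g_true = NULL) {
  ph_masked <- ph
  ph_masked$phenotype[ph_masked$individual_id %in% test_ids] <- NA_real_
  fits <- fit_base_methods(ph_masked, Z, kinship, chain, seed, learners)
  methods <- names(fits)

  wide <- function(ids) {
    out <- tibble::tibble(individual_id = ids)
    for (nm in methods) {
      v <- fits[[nm]]
      out[[nm]] <- v$genetic_value[match(ids, v$individual_id)]
    }
    out
  }
  train_fits <- wide(train_ids)
  test_preds <- wide(test_ids)
  y_train <- ph$phenotype[match(train_ids, ph$individual_id)]
  y_test <- ph$phenotype[match(test_ids, ph$individual_id)]

  ref <- select_reference_method(train_fits, y_train)
  swarm_r <- swarm
  swarm_r$seed <- seed
  fit <- if (mode == "reference") {
    train_elpgv(test_preds, reference_method = ref, config = swarm_r)
  } else {
    train_elpgv(train_fits, phenotypes = y_train, config = swarm_r)
  }
  elpgv_pred <- predict(fit, test_preds)$prediction

  ability <- c(
    ELPGV = predictive_ability(elpgv_pred, y_test),
    vapply(methods, function(nm) {
      predictive_ability(test_preds[[nm]], y_test)
    }, numeric(1))
  )
  out <- tibble::tibble(
    method = names(ability), ability = unname(ability),
    reference_method = ref
  )
  if (!is.null(g_true)) {
    gt <- g_true[match(test_ids, ph$individual_id)]
    preds <- c(list(ELPGV = elpgv_pred),
               purrr::map(methods, function(nm) test_preds[[nm]]) |>
                 setNames(methods))
    out$ability_g <- vapply(out$method, function(nm) {
      predictive_ability(preds[[nm]], gt)
    }, numeric(1))
  }
  out
}

#' Cross-validation benchmark of the base methods and the ensemble
#'
#' For each replicate: mask the test part, fit the base learners on the
#' training part, choose the reference method by training-set fit, train the
#' ensemble (reference mode by default, on the test cohort's predictions
#' against the reference method's values), and compute every method's
#' predictive ability on the held-out phenotypes. The shared splits make the
#' per-replicate abilities paired across methods.
#'
#' @inheritParams fit_bayes
#' @param genotypes Genotype matrix or data frame covering all individuals.
#' @param phenotypes Tibble `individual_id`, `phenotype` (fully observed).
#' @param scheme,n_replicates Passed to [make_splits()].
#' @param swarm A [swarm_config()] for the ensemble optimizer.
#' @param chain A [chain_config()] for the Bayesian learners.
#' @param mode `"reference"` (default; train on the test cohort's predictions
#'   against reference genetic values) or `"phenotype"` (train on the training
#'   cohort's fitted values against observed phenotypes).
#' @param seed Base seed; replicate `r` derives its own stream from it.
#' @param learners Optional named list of custom learner functions
#'   `function(phenotypes_masked, genotypes)` returning a tibble with
#'   `individual_id` and `genetic_value` for every individual; replaces the
#'   built-in four methods (useful for stubs in tests).
#' @param g_true Optional vector of true genetic values aligned to
#'   `phenotypes` rows; adds a `ability_g` column measured against it.
#' @return An `elpgv_benchmark` object; see [tidy.elpgv_benchmark()].
#' @export
run_benchmark <- function(genotypes, phenotypes,
                          scheme = c("ratio_9_1", "parts_5_hold_1"),
                          n_replicates = 100L,
                          swarm = swarm_config(), chain = chain_config(),
                          mode = c("reference", "phenotype"),
                          seed = 1L, learners = NULL, g_true = NULL) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  ph <- validate_phenotypes(phenotypes)
  Z <- as_genotype_matrix(genotypes)
  kinship <- if (is.null(learners)) build_grm(Z) else NULL
  splits <- make_splits(ph$individual_id, scheme, n_replicates, seed)
  reps <- purrr::pmap(splits, function(replicate, train, test) {
    res <- benchmark_replicate(ph, Z, kinship, train, test, swarm, chain,
                               mode, seed = seed + 1000L * replicate,
                               learners = learners, g_true = g_true)
    res$replicate <- replicate
    res
  })
  new_benchmark(dplyr::bind_rows(reps), scheme, mode, n_replicates, seed)
}

#' Simulation study: fresh traits per replicate on fixed genotypes
#'
#' Mirrors the simulation protocol: each replicate simulates a fresh trait on
#' the genotype panel under the given design, splits the individuals 4:1 (5
#' near-equal parts, one held out), fits the base learners, and assembles them
#' with the reference-mode ensemble. Abilities are reported against the
#' held-out phenotypes and additionally against the true genetic values.
#'
#' @inheritParams run_benchmark
#' @param design A [sim_design()] (its seed is superseded per replicate).
#' @return An `elpgv_benchmark`.
#' @export
run_simulation_study <- function(genotypes = wheat_fixture_genotypes(),
                                 design = sim_design(),
                                 n_replicates = 20L,
                                 swarm = swarm_config(), chain = chain_config(),
                                 seed = 1L, learners = NULL) {
  Z <- as_genotype_matrix(genotypes)
  kinship <- if (is.null(learners)) build_grm(Z) else NULL
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    tr <- sim_trait(Z, design, seed = seed + 10000L * r)
    ph <- tr$phenotypes[c("individual_id", "phenotype")]
    split <- make_splits(ph$individual_id, "parts_5_hold_1", 1L,
                         seed = seed + 10000L * r + 1L)
    res <- benchmark_replicate(ph, Z, kinship, split$train[[1]],
                               split$test[[1]], swarm, chain,
                               mode = "reference",
                               seed = seed + 10000L * r + 2L,
                               learners = learners,
                               g_true = tr$phenotypes$g_true)
    res$replicate <- r
    res
  })
  new_benchmark(dplyr::bind_rows(reps), "parts_5_hold_1", "reference",
                n_replicates, seed, design = design)
}

new_benchmark <- function(replicates, scheme, mode, n_replicates, seed,
                          design = NULL) {
  structure(list(
    replicates = replicates, scheme = scheme, mode = mode,
    n_replicates = n_replicates, seed = seed, design = design
  ), class = "elpgv_benchmark")
}

#' @export
print.elpgv_benchmark <- function(x, ...) {
  cat(sprintf("<elpgv_benchmark> %d replicates, scheme %s, %s mode\n",
              x$n_replicates, x$scheme, x$mode))
  print(tidy(x))
  invisible(x)
}

#' Summary table of a benchmark (mean ability, SE, paired test vs the ensemble)
#'
#' @param x An `elpgv_benchmark`.
#' @param against Ability column to summarize: `"ability"` (vs phenotypes) or
#'   `"ability_g"` (vs true genetic values, simulation runs only).
#' @param ... Unused.
#' @return Tibble with one row per method: `mean_ability`, `se` (SD over
#'   replicates divided by sqrt of replicates), and the paired t-test of the
#'   ensemble against the method (`statistic`, `df`, `p_value`; `NA` for the
#'   ensemble row).
#' @export
tidy.elpgv_benchmark <- function(x, against = c("ability", "ability_g"), ...) {
  against <- match.arg(against)
  wide <- tidyr::pivot_wider(
    x$replicates[c("replicate", "method", against)],
    names_from = "method", values_from = dplyr::all_of(against)
  )
  methods <- setdiff(names(wide), "replicate")
  purrr::map_dfr(methods, function(nm) {
    v <- wide[[nm]]
    row <- tibble::tibble(
      method = nm,
      mean_ability = mean(v),
      se = sd(v) / sqrt(length(v))
    )
    if (nm != "ELPGV") {
      tt <- paired_t_test(wide$ELPGV, v)
      row$statistic <- tt$statistic
      row$df <- tt$df
      row$p_value <- tt$p_value
    } else {
      row$statistic <- NA_real_
      row$df <- NA_real_
      row$p_value <- NA_real_
    }
    row
  })
}

#' One-row summary of a benchmark
#'
#' @param x An `elpgv_benchmark`.
#' @param ... Unused.
#' @return Tibble: scheme, mode, replicates, ensemble mean ability, best base
#'   method and its mean ability, and the ensemble's margin over it.
#' @export
glance.elpgv_benchmark <- function(x, ...) {
  s <- tidy(x)
  base <- s[s$method != "ELPGV", ]
  best <- base[which.max(base$mean_ability), ]
  tibble::tibble(
    scheme = x$scheme, mode = x$mode, n_replicates = x$n_replicates,
    elpgv_ability = s$mean_ability[s$method == "ELPGV"],
    best_base = best$method, best_base_ability = best$mean_ability,
    margin = s$mean_ability[s$method == "ELPGV"] - best$mean_ability
  )
}

#' Per-replicate comparison plot of the ensemble against each base method
#'
#' Each dot is one cross-validation replicate: the base method's ability on
#' the x-axis against the ensemble's ability on the y-axis; points above the
#' diagonal are replicates where the ensemble won.
#'
#' @param object An `elpgv_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.elpgv_benchmark <- function(object, ...) {
  wide <- tidyr::pivot_wider(
    object$replicates[c("replicate", "method", "ability")],
    names_from = "method", values_from = "ability"
  )
  long <- tidyr::pivot_longer(wide, -c("replicate", "ELPGV"),
                              names_to = "method", values_to = "ability")
  ggplot2::ggplot(long, ggplot2::aes(.data$ability, .data$ELPGV,
                                     colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "base-method predictive ability",
                  y = "ensemble predictive ability") +
    ggplot2::theme_minimal()
}
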
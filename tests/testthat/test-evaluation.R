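test_that("split plans partition the ids at the designed sizes", {
  ids <- paste0("i", 1:100)
  sp <- make_splits(ids, "ratio_9_1", n_replicates = 20, seed = 1)
  for (r in 1:20) {
    expect_length(sp$train[[r]], 90)
    expect_length(sp$test[[r]], 10)
    expect_setequal(c(sp$train[[r]], sp$test[[r]]), ids)
    expect_length(intersect(sp$train[[r]], sp$test[[r]]), 0)
  }
  ids599 <- paste0("i", 1:599)
  sp5 <- make_splits(ids599, "parts_5_hold_1", n_replicates = 30, seed = 2)
  sizes <- lengths(sp5$test)
  expect_true(all(sizes %in% c(119L, 120L)))
  for (r in 1:30) {
    expect_setequal(c(sp5$train[[r]], sp5$test[[r]]), ids599)
  }
  # seeded determinism and size guards
  expect_identical(sp, make_splits(ids, "ratio_9_1", 20, seed = 1))
  expect_error(make_splits(paste0("i", 1:8), "ratio_9_1"), "at least 10")
  expect_error(make_splits(paste0("i", 1:3), "parts_5_hold_1"), "at least 5")
})

test_that("predictive ability matches hand-computed Pearson values", {
  expect_equal(predictive_ability(1:10, 1:10), 1)
  expect_equal(predictive_ability(c(1, 2, 3), c(3, 2, 1)), -1)
  # hand evaluation: cov((1,2,3),(3,2,3)) = 0
  expect_equal(predictive_ability(c(1, 2, 3), c(3, 2, 3)), 0)
  expect_error(predictive_ability(rep(1, 5), 1:5), "constant")
  expect_error(predictive_ability(1:3, 1:4), "equal length")
  expect_error(predictive_ability(1:2, 2:1), "at least 3")
})

test_that("paired t-test matches the hand formula t = mean(d)/(sd(d)/sqrt(n))", {
  a <- c(2, 4, 6); b <- c(1, 2, 3)  # d = (1,2,3)
  tt <- paired_t_test(a, b)
  expect_equal(tt$statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(tt$statistic, mean(a - b) / (sd(a - b) / sqrt(3)))
  expect_equal(tt$df, 2)
  # p cross-checked against the t distribution directly
  expect_equal(tt$p_value, 2 * stats::pt(2 * sqrt(3), df = 2, lower.tail = FALSE))
  # antisymmetry
  rev <- paired_t_test(b, a)
  expect_equal(rev$statistic, -tt$statistic)
  expect_equal(rev$p_value, tt$p_value)
  # identical methods have undefined t
  expect_error(paired_t_test(a, a), "Zero variance")
  expect_error(paired_t_test(1:3, 1:2), "paired")
})

test_that("benchmark with a perfect stub learner reaches ability 1", {
  sc <- make_sim_scenario(n = 50, p = 30, seed = 12)
  ph <- tibble::tibble(individual_id = rownames(sc$Z),
                       phenotype = sc$trait$phenotypes$phenotype)
  y_full <- ph$phenotype
  stubs <- list(
    perfect = function(ph_masked, Z) {
      tibble::tibble(individual_id = ph_masked$individual_id,
                     genetic_value = y_full)
    },
    noise = function(ph_masked, Z) {
      tibble::tibble(individual_id = ph_masked$individual_id,
                     genetic_value = sin(seq_len(nrow(ph_masked))))
    }
  )
  bm <- run_benchmark(sc$Z, ph, scheme = "ratio_9_1", n_replicates = 1,
                      swarm = swarm_config(repeats = 5),
                      mode = "reference", seed = 3, learners = stubs)
  ab <- bm$replicates
  expect_equal(ab$ability[ab$method == "ELPGV"], 1, tolerance = 1e-6)
  expect_true(all(ab$reference_method == "perfect"))
  # determinism end to end
  bm2 <- run_benchmark(sc$Z, ph, scheme = "ratio_9_1", n_replicates = 1,
                       swarm = swarm_config(repeats = 5),
                       mode = "reference", seed = 3, learners = stubs)
  expect_equal(bm$replicates, bm2$replicates)
})

test_that("benchmark summary reports SE = SD/sqrt(R) and paired tests", {
  set.seed(31)
  sc <- make_sim_scenario(n = 60, p = 40, seed = 13)
  ph <- tibble::tibble(individual_id = rownames(sc$Z),
                       phenotype = sc$trait$phenotypes$phenotype)
  g <- sc$trait$phenotypes$g_true
  stubs <- list(
    good = function(ph_masked, Z) tibble::tibble(
      individual_id = ph_masked$individual_id,
      genetic_value = g + rnorm(length(g), 0, 0.3 * sd(g))),
    weak = function(ph_masked, Z) tibble::tibble(
      individual_id = ph_masked$individual_id,
      genetic_value = g + rnorm(length(g), 0, 1.5 * sd(g)))
  )
  bm <- run_benchmark(sc$Z, ph, scheme = "ratio_9_1", n_replicates = 8,
                      swarm = swarm_config(repeats = 5),
                      mode = "reference", seed = 5, learners = stubs)
  s <- tidy(bm)
  wide <- tidyr::pivot_wider(bm$replicates[c("replicate", "method", "ability")],
                             names_from = "method", values_from = "ability")
  for (m in s$method) {
    expect_equal(s$se[s$method == m], sd(wide[[m]]) / sqrt(8), tolerance = 1e-12)
  }
  expect_true(all(bm$replicates$ability >= -1 & bm$replicates$ability <= 1))
  tt <- paired_t_test(wide$ELPGV, wide$good)
  expect_equal(s$p_value[s$method == "good"], tt$p_value)
  expect_s3_class(autoplot(bm), "ggplot")
  gl <- glance(bm)
  expect_equal(gl$elpgv_ability, s$mean_ability[s$method == "ELPGV"])
})

test_that("paired t-test holds its size under the null", {
  set.seed(77)
  rejections <- 0L
  n_sim <- 300L
  for (i in seq_len(n_sim)) {
    a <- rnorm(20); b <- rnorm(20)  # equal-variance iid abilities
    if (paired_t_test(a, b)$p_value < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_sim
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
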
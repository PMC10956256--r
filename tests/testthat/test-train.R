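test_that("a run recovers a perfectly predictive column", {
  set.seed(3)
  y <- rnorm(20)
  preds <- tibble::tibble(individual_id = 1:20,
                          truth = y, junk = rnorm(20), junk2 = rnorm(20))
  run <- train_weights_once(preds, y, swarm_config(seed = 4))
  expect_gt(run$fitness, 1 - 1e-6)
})

test_that("incumbent trajectories are non-decreasing and runs deterministic", {
  fx <- make_noisy_predictions(n = 25, noise_sd = c(0.3, 0.8, 1.2))
  y <- fx$g + rnorm(25, 0, 0.3)
  for (s in 1:20) {
    run <- train_weights_once(fx$predictions, y, swarm_config(seed = s))
    expect_true(all(diff(run$trajectory) >= 0))
    expect_equal(run$fitness, max(run$trajectory))
  }
  r1 <- train_weights_once(fx$predictions, y, swarm_config(seed = 123))
  r2 <- train_weights_once(fx$predictions, y, swarm_config(seed = 123))
  expect_identical(r1, r2)
})

test_that("optimizer reaches the 2-method grid-search oracle on toy problems", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    g <- rnorm(20)
    preds <- tibble::tibble(individual_id = 1:20,
                            m1 = g + rnorm(20, 0, 0.4),
                            m2 = g + rnorm(20, 0, 0.8))
    y <- g + rnorm(20, 0, 0.3)
    oracle <- grid_oracle_fitness(preds, y)
    run <- train_weights_once(preds, y, swarm_config(seed = 1000 + s))
    if (run$fitness >= oracle - 1e-3) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("weights and velocities stay inside their boxes through a run", {
  # run the loop manually through the exported per-particle ops
  fx <- make_noisy_predictions(n = 15, noise_sd = c(0.4, 0.9))
  y <- fx$g + rnorm(15, 0, 0.2)
  cfg <- swarm_config(m = 6, max_iterations = 10)
  set.seed(5)
  st <- initialize_swarm(fx$predictions, y, cfg)
  p <- ensemble_predict(fx$predictions, st$weights[1, ])  # exercise alignment
  for (t in 1:10) {
    for (i in 1:6) {
      cand <- de_mutation(st, i, cfg)
      u <- de_crossover(cand$h, st$weights[i, ], cfg)
      f_u <- ensemble_fitness(fx$predictions, u, y)
      f_p <- ensemble_fitness(fx$predictions, cand$p, y)
      sel <- greedy_select(u, cand$p, st$weights[i, ], f_u, f_p, st$fitness[i])
      v <- update_velocity(st$velocities[i, ], sel$weights, st$weights[i, ],
                           st$incumbent, cfg)
      expect_true(all(sel$weights >= cfg$w_min & sel$weights <= cfg$w_max))
      expect_true(all(v >= cfg$v_min & v <= cfg$v_max))
      expect_gte(sel$fitness, st$fitness[i])
      st$weights[i, ] <- sel$weights
      st$velocities[i, ] <- v
      st$fitness[i] <- sel$fitness
    }
    best <- which.max(st$fitness)
    st$incumbent <- st$weights[best, ]
  }
})

test_that("repeat averaging is the component-wise mean and is deterministic", {
  fx <- make_noisy_predictions(n = 20, noise_sd = c(0.3, 0.7, 1.1, 1.6))
  y <- fx$g + rnorm(20, 0, 0.3)
  cfg <- swarm_config(repeats = 5, seed = 77)
  fit <- train_elpgv(fx$predictions, phenotypes = y, config = cfg)
  expect_equal(unname(fit$weights), unname(colMeans(fit$per_repeat_weights)))
  expect_equal(nrow(fit$per_repeat_weights), 5L)
  # repeats vary (different seeds) but a repeats=1 fit equals its single run
  one <- train_elpgv(fx$predictions, phenotypes = y,
                     config = swarm_config(repeats = 1, seed = 77))
  single <- train_weights_once(fx$predictions, y, swarm_config(seed = 77),
                               seed = 78)  # repeat r uses base seed + r
  expect_equal(unname(one$weights), unname(single$weights))
  # end-to-end determinism
  fit2 <- train_elpgv(fx$predictions, phenotypes = y, config = cfg)
  expect_identical(fit$weights, fit2$weights)
  expect_identical(fit$per_repeat_weights, fit2$per_repeat_weights)
})

test_that("reference mode trains against the reference column", {
  fx <- make_noisy_predictions(n = 20, noise_sd = c(0.3, 0.7))
  cfg <- swarm_config(repeats = 3, seed = 2)
  fit <- train_elpgv(fx$predictions, reference_method = "method_a", config = cfg)
  expect_identical(fit$mode, "reference")
  expect_identical(fit$reference_method, "method_a")
  # fitness against the reference column can reach ~1 by loading its weight
  expect_gt(max(fit$per_repeat_fitness), 0.99)
  expect_error(train_elpgv(fx$predictions, reference_method = "nope"), "nope")
  expect_error(train_elpgv(fx$predictions), "phenotype")
})

test_that("fit accessors are consistent", {
  fx <- make_noisy_predictions(n = 20, noise_sd = c(0.3, 0.7))
  y <- fx$g
  fit <- train_elpgv(fx$predictions, phenotypes = y,
                     config = swarm_config(repeats = 3, seed = 1))
  td <- tidy(fit)
  expect_named(td, c("method", "weight", "weight_sd", "weight_se"))
  expect_equal(td$weight_se, td$weight_sd / sqrt(3))
  gl <- glance(fit)
  expect_equal(gl$repeats, 3L)
  expect_s3_class(autoplot(fit), "ggplot")
  pr <- predict(fit)
  expect_equal(pr$prediction,
               ensemble_predict(fx$predictions, fit$weights)$prediction)
})
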
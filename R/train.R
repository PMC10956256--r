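#' One DE-PSO weight-training run
#'
#' Runs initialization followed by `max_iterations` cycles of mutation,
#' crossover, greedy selection and velocity update, and returns the incumbent
#' (best-ever) weight vector. Fitness is evaluated for all particles at once;
#' the RNG order within an iteration is fixed (DE partner indices per particle,
#' then the crossover uniforms, then the two velocity uniforms per particle),
#' making runs bit-reproducible under a fixed seed.
#'
#' @inheritParams initialize_swarm
#' @param seed RNG seed for this run; defaults to `config$seed`.
#' @return A list: `weights` (named incumbent vector), `fitness` (its
#'   correlation fitness), `trajectory` (incumbent fitness from iteration 0 on,
#'   non-decreasing), `iterations` (number performed).
#' @export
train_weights_once <- function(predictions, target, config = swarm_config(),
                               seed = config$seed) {
  predictions <- as_prediction_set(predictions)
  set.seed(seed)
  state <- initialize_swarm(predictions, target, config)
  p <- prediction_matrix(predictions)
  m <- config$m
  n <- ncol(state$weights)
  traj <- numeric(config$max_iterations + 1L)
  traj[1L] <- state$incumbent_fitness

  t_done <- 0L
  for (t in seq_len(config$max_iterations)) {
    W_prev <- state$weights
    f_prev <- state$fitness
    incumbent_prev <- state$incumbent
    # DE partners k, p, q: uniform without replacement from the other particles
    partners <- vapply(seq_len(m), function(i) {
      j <- sample.int(m - 1L, 3L)
      j + (j >= i)
    }, integer(3))
    P <- clamp(W_prev + state$velocities, config$w_min, config$w_max)
    H <- clamp(W_prev[partners[1L, ], , drop = FALSE] +
                 config$f * (W_prev[partners[2L, ], , drop = FALSE] -
                               W_prev[partners[3L, ], , drop = FALSE]),
               config$w_min, config$w_max)
    if (config$crossover_per_dimension) {
      keep <- matrix(runif(m * n), m, n) > config$cr
    } else {
      keep <- matrix(runif(m) > config$cr, m, n)
    }
    U <- H
    U[keep] <- W_prev[keep]
    f_P <- batch_fitness(P, p, target)
    f_U <- batch_fitness(U, p, target)
    # trial beats velocity candidate on ties, winner beats previous on ties
    take_u <- f_U >= f_P
    G <- P; G[take_u, ] <- U[take_u, ]
    f_G <- ifelse(take_u, f_U, f_P)
    accept <- f_G >= f_prev
    W_new <- W_prev; W_new[accept, ] <- G[accept, ]
    f_new <- ifelse(accept, f_G, f_prev)

    r1 <- runif(m); r2 <- runif(m)
    V_new <- config$epsilon * state$velocities +
      config$c1 * r1 * (W_new - W_prev) +
      config$c2 * r2 * (matrix(incumbent_prev, m, n, byrow = TRUE) - W_prev)
    V_new <- clamp(V_new, config$v_min, config$v_max)

    best <- which.max(f_new)
    state$weights <- W_new
    state$velocities <- V_new
    state$fitness <- f_new
    state$incumbent <- W_new[best, ]
    state$incumbent_fitness <- f_new[best]
    state$iteration <- t
    traj[t + 1L] <- state$incumbent_fitness
    t_done <- t

    if (config$early_stop && t > config$early_stop_window) {
      gain <- traj[t + 1L] - traj[t + 1L - config$early_stop_window]
      if (is.finite(gain) && gain < config$early_stop_tol) break
    }
  }
  list(
    weights = setNames(state$incumbent, state$method_names),
    fitness = state$incumbent_fitness,
    trajectory = traj[seq_len(t_done + 1L)],
    iterations = t_done
  )
}

#' Train the ensemble weights (repeated DE-PSO runs, averaged)
#'
#' The full training repeats [train_weights_once()] `repeats` times (repeat
#' `r` seeded with `seed + r`) and averages the returned weight vectors
#' component-wise; the averaged weights define the ensemble. In phenotype mode
#' the fitness target is the observed phenotypes of the fitted individuals; in
#' reference mode it is the predictions of a reference base method (chosen on
#' the training set with [select_reference_method()]), standing in for the
#' unknown phenotypes of a test cohort.
#'
#' @inheritParams initialize_swarm
#' @param phenotypes Numeric target vector aligned to `predictions` rows
#'   (phenotype mode). Ignored when `reference_method` is given.
#' @param reference_method Name of a method column of `predictions` to use as
#'   the reference target (reference mode), or `NULL` for phenotype mode.
#' @return An object of class `elpgv_fit`: averaged weights, per-repeat
#'   weights and fitness trajectories, mode metadata, and the fitted ensemble
#'   predictions.
#' @seealso [tidy.elpgv_fit()], [glance.elpgv_fit()], [autoplot.elpgv_fit()],
#'   [predict.elpgv_fit()]
#' @export
train_elpgv <- function(predictions, phenotypes = NULL,
                        reference_method = NULL, config = swarm_config()) {
  predictions <- as_prediction_set(predictions)
  methods <- prediction_methods(predictions)
  mode <- if (is.null(reference_method)) "phenotype" else "reference"
  if (mode == "reference") {
    if (!reference_method %in% methods) {
      abort(sprintf("`reference_method` '%s' is not a column of `predictions`.",
                    reference_method))
    }
    target <- predictions[[reference_method]]
  } else {
    if (is.null(phenotypes)) {
      abort("Phenotype mode needs `phenotypes`; or give a `reference_method`.")
    }
    if (length(phenotypes) != nrow(predictions)) {
      abort("`phenotypes` must align with `predictions` rows.")
    }
    target <- phenotypes
  }

  runs <- lapply(seq_len(config$repeats), function(r) {
    train_weights_once(predictions, target, config, seed = config$seed + r)
  })
  W <- do.call(rbind, lapply(runs, `[[`, "weights"))
  avg <- colMeans(W)
  fit <- structure(list(
    method_names = methods,
    weights = avg,
    per_repeat_weights = W,
    per_repeat_fitness = vapply(runs, `[[`, numeric(1), "fitness"),
    trajectories = lapply(runs, `[[`, "trajectory"),
    mode = mode,
    reference_method = if (mode == "reference") reference_method else NULL,
    config = config,
    predictions = predictions
  ), class = "elpgv_fit")
  fit$fitted <- ensemble_predict(predictions, avg)
  fit
}

#' @export
print.elpgv_fit <- function(x, ...) {
  cat(sprintf("<elpgv_fit> %s mode, %d methods, %d repeats\n",
              x$mode, length(x$method_names), nrow(x$per_repeat_weights)))
  if (!is.null(x$reference_method)) {
    cat("  reference method:", x$reference_method, "\n")
  }
  cat("  averaged weights:\n")
  print(round(x$weights, 4))
  cat(sprintf("  mean incumbent fitness: %.4f\n", mean(x$per_repeat_fitness)))
  invisible(x)
}

#' Ensemble predictions from a trained fit
#'
#' @param object An `elpgv_fit`.
#' @param new_predictions Optional prediction set with the same method columns;
#'   defaults to the set the model was trained on.
#' @param ... Unused.
#' @return A tibble with `individual_id` and `prediction`.
#' @export
predict.elpgv_fit <- function(object, new_predictions = NULL, ...) {
  preds <- if (is.null(new_predictions)) object$predictions else new_predictions
  preds <- as_prediction_set(preds)
  if (!identical(prediction_methods(preds), object$method_names)) {
    abort("`new_predictions` must have the same method columns as the fit.")
  }
  ensemble_predict(preds, object$weights)
}

#' Tidy the trained ensemble weights
#'
#' @param x An `elpgv_fit`.
#' @param ... Unused.
#' @return A tibble with one row per base method: the averaged `weight`, and
#'   the standard deviation and standard error of the weight across repeats.
#' @export
tidy.elpgv_fit <- function(x, ...) {
  R <- nrow(x$per_repeat_weights)
  sds <- apply(x$per_repeat_weights, 2, sd)
  tibble::tibble(
    method = x$method_names,
    weight = unname(x$weights),
    weight_sd = unname(sds),
    weight_se = unname(sds) / sqrt(R)
  )
}

#' One-row summary of a trained ensemble
#'
#' @param x An `elpgv_fit`.
#' @param ... Unused.
#' @return A tibble with the mode, number of methods and repeats, and the mean
#'   and best incumbent fitness across repeats.
#' @export
glance.elpgv_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    reference_method = x$reference_method %||% NA_character_,
    n_methods = length(x$method_names),
    repeats = nrow(x$per_repeat_weights),
    mean_fitness = mean(x$per_repeat_fitness),
    best_fitness = max(x$per_repeat_fitness)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot the incumbent-fitness trajectories of a trained ensemble
#'
#' One line per repeat; trajectories are non-decreasing by construction of the
#' greedy selection step.
#'
#' @param object An `elpgv_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.elpgv_fit <- function(object, ...) {
  df <- purrr::imap_dfr(object$trajectories, function(tr, r) {
    tibble::tibble(repeat_id = r, iteration = seq_along(tr) - 1L, fitness = tr)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$fitness,
                                   group = .data$repeat_id)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::labs(x = "iteration", y = "incumbent fitness",
                  title = "DE-PSO incumbent fitness by repeat") +
    ggplot2::theme_minimal()
}
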
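#' Hyperparameters of the hybrid DE-PSO weight optimizer
#'
#' Defaults follow the published hyperparameter table of the method: weights
#' are searched in `[w_min, w_max] = [0, 1]`, velocities bounded in
#' `[v_min, v_max] = [-0.01, 0.01]`, `m = 20` particles, differential-evolution
#' scaling factor `f = 0.5`, crossover probability `cr = 0.3`, inertia weight
#' `epsilon = 1`, acceleration factors `c1 = c2 = 2`, and 25 iterations.
#' A full training averages the weights of `repeats = 100` independent runs.
#'
#' @param w_min,w_max Weight bounds; candidates are clamped back into this box
#'   after mutation.
#' @param v_min,v_max Velocity bounds; velocities are clamped after each update.
#' @param m Number of particles (candidate weight vectors); at least 4, since
#'   DE mutation draws three partners distinct from the current particle.
#' @param f DE scaling factor multiplying the difference vector.
#' @param cr Crossover probability in `[0, 1]`.
#' @param epsilon Particle-swarm inertia weight.
#' @param c1,c2 Particle-swarm acceleration factors (cognitive / social).
#' @param max_iterations Iteration budget of one run.
#' @param repeats Number of independent runs averaged into the final weights.
#' @param seed Base RNG seed; repeat `r` uses `seed + r`.
#' @param early_stop If `TRUE`, a run stops early once the incumbent fitness
#'   has improved by less than `early_stop_tol` over `early_stop_window`
#'   consecutive iterations. Off by default (fixed iteration budget).
#' @param early_stop_tol,early_stop_window Early-stopping controls.
#' @param crossover_per_dimension If `TRUE`, crossover draws one uniform per
#'   weight component instead of one per particle (the default, which switches
#'   the whole vector at once).
#' @return A list of class `swarm_config`.
#' @export
swarm_config <- function(w_min = 0, w_max = 1,
                         v_min = -0.01, v_max = 0.01,
                         m = 20L, f = 0.5, cr = 0.3,
                         epsilon = 1, c1 = 2, c2 = 2,
                         max_iterations = 25L, repeats = 100L,
                         seed = 1L,
                         early_stop = FALSE, early_stop_tol = 1e-8,
                         early_stop_window = 5L,
                         crossover_per_dimension = FALSE) {
  cfg <- list(
    w_min = w_min, w_max = w_max, v_min = v_min, v_max = v_max,
    m = as.integer(m), f = f, cr = cr, epsilon = epsilon, c1 = c1, c2 = c2,
    max_iterations = as.integer(max_iterations), repeats = as.integer(repeats),
    seed = as.integer(seed),
    early_stop = isTRUE(early_stop), early_stop_tol = early_stop_tol,
    early_stop_window = as.integer(early_stop_window),
    crossover_per_dimension = isTRUE(crossover_per_dimension)
  )
  if (cfg$w_min > cfg$w_max) abort("`w_min` must not exceed `w_max`.")
  if (cfg$v_min > cfg$v_max) abort("`v_min` must not exceed `v_max`.")
  if (cfg$m < 4L) abort("`m` must be >= 4: DE mutation needs four distinct particle indices.")
  if (cfg$cr < 0 || cfg$cr > 1) abort("`cr` must lie in [0, 1].")
  if (cfg$f <= 0) abort("`f` must be positive.")
  if (cfg$max_iterations < 1L) abort("`max_iterations` must be >= 1.")
  if (cfg$repeats < 1L) abort("`repeats` must be >= 1.")
  structure(cfg, class = "swarm_config")
}

#' @export
print.swarm_config <- function(x, ...) {
  cat("<swarm_config>\n")
  flds <- c("w_min", "w_max", "v_min", "v_max", "m", "f", "cr", "epsilon",
            "c1", "c2", "max_iterations", "repeats", "seed")
  for (f in flds) cat(sprintf("  %-15s %s\n", f, format(x[[f]])))
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Initialize the particle swarm
#'
#' Draws `m` candidate weight vectors uniformly on `[w_min, w_max]` and their
#' velocities uniformly on `[v_min, v_max]`, evaluates the correlation fitness
#' of each candidate, and records the best as the incumbent weight vector.
#'
#' @inheritParams ensemble_fitness
#' @param config A [swarm_config()].
#' @return A list of class `swarm_state`: `weights` (m x n), `velocities`
#'   (m x n), `fitness` (length m), `incumbent`, `incumbent_fitness`,
#'   `iteration = 0`.
#' @export
initialize_swarm <- function(predictions, target, config = swarm_config()) {
  predictions <- as_prediction_set(predictions)
  if (!is.numeric(target) || length(target) != nrow(predictions)) {
    abort("`target` must be numeric and aligned to the prediction set's individuals.")
  }
  if (length(target) < 3L) abort("Fitness needs at least 3 individuals.")
  methods <- prediction_methods(predictions)
  n <- length(methods)
  m <- config$m
  W <- matrix(runif(m * n, config$w_min, config$w_max), nrow = m)
  V <- matrix(runif(m * n, config$v_min, config$v_max), nrow = m)
  colnames(W) <- colnames(V) <- methods
  p <- prediction_matrix(predictions)
  fit <- batch_fitness(W, p, target)
  if (all(!is.finite(fit))) {
    abort(paste("Every initial candidate has degenerate (zero-variance) fitness;",
                "check the prediction set and target."))
  }
  best <- which.max(fit)
  structure(list(
    weights = W, velocities = V, fitness = fit,
    incumbent = W[best, ], incumbent_fitness = fit[best],
    iteration = 0L, method_names = methods
  ), class = "swarm_state")
}

#' DE-PSO mutation step for one particle
#'
#' Produces the two candidate weight vectors of iteration `t` for particle `i`:
#' the velocity-shifted candidate `P = W_i + V_i`, and the differential
#' candidate `H = W_k + f * (W_p - W_q)` built from three partner particles
#' `k, p, q` drawn uniformly without replacement from the other particles.
#' Both candidates are clamped to the weight box.
#'
#' @param state A `swarm_state`.
#' @param i Particle index.
#' @param config A [swarm_config()].
#' @param partners Optional integer vector `c(k, p, q)`; drawn at random when
#'   omitted. Must be distinct and different from `i`.
#' @return List with `p` (velocity candidate) and `h` (differential candidate).
#' @export
de_mutation <- function(state, i, config = swarm_config(), partners = NULL) {
  m <- nrow(state$weights)
  if (is.null(partners)) {
    partners <- sample(setdiff(seq_len(m), i), 3L)
  }
  if (length(partners) != 3L || anyDuplicated(c(i, partners))) {
    abort("`partners` must be three distinct indices, all different from `i`.")
  }
  k <- partners[1]; p_ <- partners[2]; q <- partners[3]
  p_cand <- clamp(state$weights[i, ] + state$velocities[i, ],
                  config$w_min, config$w_max)
  h_cand <- clamp(state$weights[k, ] +
                    config$f * (state$weights[p_, ] - state$weights[q, ]),
                  config$w_min, config$w_max)
  list(p = p_cand, h = h_cand)
}

#' DE crossover step
#'
#' With probability `cr` the trial vector is the differential candidate `h`,
#' otherwise the particle keeps its previous weights. One uniform draw governs
#' the whole vector (set `crossover_per_dimension` in the config to decide
#' component-wise instead).
#'
#' @param h Differential candidate weight vector.
#' @param w_prev The particle's weights from the previous iteration.
#' @param config A [swarm_config()].
#' @param rand Optional uniform draw(s) in `[0, 1]` (length 1, or length `n`
#'   in per-dimension mode); drawn at random when omitted.
#' @return The trial weight vector `U`.
#' @export
de_crossover <- function(h, w_prev, config = swarm_config(), rand = NULL) {
  if (config$crossover_per_dimension) {
    if (is.null(rand)) rand <- runif(length(h))
    ifelse(rand <= config$cr, h, w_prev)
  } else {
    if (is.null(rand)) rand <- runif(1)
    if (rand <= config$cr) h else w_prev
  }
}

#' Greedy selection step
#'
#' Keeps, among the trial vector `U`, the velocity candidate `P` and the
#' particle's previous weights, the one of highest fitness; ties favour the
#' newer candidate (`U` over `P`, the winner over the previous weights), so a
#' particle's fitness never decreases.
#'
#' @param u,p_cand,w_prev Candidate weight vectors.
#' @param f_u,f_p,f_prev Their fitness values (degenerate candidates carry
#'   `-Inf` and lose every comparison).
#' @return List with the surviving `weights` and their `fitness`.
#' @export
greedy_select <- function(u, p_cand, w_prev, f_u, f_p, f_prev) {
  if (f_u >= f_p) { g <- u; f_g <- f_u } else { g <- p_cand; f_g <- f_p }
  if (f_g >= f_prev) list(weights = g, fitness = f_g)
  else list(weights = w_prev, fitness = f_prev)
}

#' Particle-swarm velocity update
#'
#' `V_i(t) = epsilon * V_i(t-1) + c1 * r1 * (W_i(t) - W_i(t-1))
#'  + c2 * r2 * (W(t-1) - W_i(t-1))`, with `r1`, `r2` independent uniforms and
#' `W(t-1)` the incumbent (global-best) weight vector; the result is clamped to
#' the velocity bounds.
#'
#' @param v_prev Previous velocity.
#' @param w_new,w_prev The particle's weights after and before selection.
#' @param incumbent_prev Incumbent weight vector before this iteration.
#' @param config A [swarm_config()].
#' @param r1,r2 Optional uniform draws; drawn at random when omitted.
#' @return The clamped new velocity vector.
#' @export
update_velocity <- function(v_prev, w_new, w_prev, incumbent_prev,
                            config = swarm_config(), r1 = NULL, r2 = NULL) {
  if (is.null(r1)) r1 <- runif(1)
  if (is.null(r2)) r2 <- runif(1)
  v <- config$epsilon * v_prev +
    config$c1 * r1 * (w_new - w_prev) +
    config$c2 * r2 * (incumbent_prev - w_prev)
  clamp(v, config$v_min, config$v_max)
}
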
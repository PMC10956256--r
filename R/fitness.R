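#' Weighted-average ensemble prediction
#'
#' Computes the ensemble genetic-value prediction as the weighted sum of the
#' base methods' predictions, `g_i = sum_j W_j * p_ij`. The weights are not
#' normalized: the downstream correlation fitness is invariant to the overall
#' scale, so only relative weights matter.
#'
#' @param predictions A prediction set (see [as_prediction_set()]).
#' @param weights Numeric vector, one weight per method column; if named, names
#'   must match the method columns (order is taken from the prediction set).
#' @return A tibble with `individual_id` and `prediction`.
#' @export
#' @examples
#' preds <- tibble::tibble(individual_id = 1:2, a = c(1, 2), b = c(3, 4))
#' ensemble_predict(preds, c(0.5, 0.5))
ensemble_predict <- function(predictions, weights) {
  predictions <- as_prediction_set(predictions, min_methods = 1L)
  methods <- prediction_methods(predictions)
  weights <- align_weights(weights, methods)
  p <- prediction_matrix(predictions)
  tibble::tibble(
    individual_id = predictions$individual_id,
    prediction = as.numeric(p %*% weights)
  )
}

align_weights <- function(weights, methods) {
  if (!is.numeric(weights) || length(weights) != length(methods)) {
    abort(sprintf("`weights` must be numeric of length %d (one per method: %s).",
                  length(methods), paste(methods, collapse = ", ")))
  }
  if (!all(is.finite(weights))) abort("`weights` must all be finite.")
  if (!is.null(names(weights))) {
    if (!setequal(names(weights), methods)) {
      abort("Names of `weights` do not match the method columns.")
    }
    weights <- weights[methods]
  }
  unname(weights)
}

#' Correlation fitness of a weight vector
#'
#' The fitness of a candidate weight vector is the Pearson correlation between
#' the ensemble prediction it produces and a target vector (observed phenotypes
#' in phenotype mode, reference genetic values in reference mode). When either
#' the ensemble output or the target has zero variance the correlation is
#' undefined; a `-Inf` sentinel is returned so such candidates lose every
#' selection comparison rather than masquerading as fitness 0.
#'
#' @inheritParams ensemble_predict
#' @param target Numeric vector aligned to the prediction set's individuals.
#' @return A single number in `[-1, 1]`, or `-Inf` for degenerate candidates.
#' @export
ensemble_fitness <- function(predictions, weights, target) {
  predictions <- as_prediction_set(predictions, min_methods = 1L)
  if (!is.numeric(target) || length(target) != nrow(predictions)) {
    abort("`target` must be numeric and aligned to the prediction set's individuals.")
  }
  if (length(target) < 3L) abort("Fitness needs at least 3 individuals.")
  g <- ensemble_predict(predictions, weights)$prediction
  pearson_or_sentinel(g, target)
}

pearson_or_sentinel <- function(x, y) {
  sx <- sum((x - mean(x))^2)
  sy <- sum((y - mean(y))^2)
  if (sx <= 0 || sy <= 0) return(-Inf)
  sum((x - mean(x)) * (y - mean(y))) / sqrt(sx * sy)
}

# Fitness of many candidate weight vectors at once.
# W: candidates x methods matrix; p: individuals x methods; y: target.
# Returns one fitness per candidate row, -Inf for degenerate ensembles.
batch_fitness <- function(W, p, y) {
  g <- p %*% t(W)                      # individuals x candidates
  gc <- sweep(g, 2, colMeans(g))
  yc <- y - mean(y)
  sy <- sum(yc^2)
  sg <- colSums(gc^2)
  f <- as.numeric(crossprod(gc, yc)) / sqrt(sg * sy)
  f[sg <= 0 | sy <= 0] <- -Inf
  f
}

#' Choose the reference base method from training-set fit
#'
#' When test-set phenotypes are unknown, the ensemble is trained against
#' reference genetic values: the test-set predictions of the base method whose
#' fitted genetic values correlate best with the observed training phenotypes
#' (the "fitting effect"). Ties break deterministically towards the earlier
#' method column.
#'
#' @param train_fits Prediction set of fitted genetic values on training
#'   individuals (one column per method).
#' @param train_phenotypes Numeric vector of observed training phenotypes,
#'   aligned to `train_fits`.
#' @return The name of the best-fitting method (length-1 character).
#' @export
select_reference_method <- function(train_fits, train_phenotypes) {
  train_fits <- as_prediction_set(train_fits, min_methods = 1L)
  if (length(train_phenotypes) != nrow(train_fits)) {
    abort("`train_phenotypes` must align with `train_fits` rows.")
  }
  if (length(train_phenotypes) < 3L) {
    abort("Reference selection needs at least 3 training individuals.")
  }
  p <- prediction_matrix(train_fits)
  fits <- vapply(seq_len(ncol(p)), function(j) {
    pearson_or_sentinel(p[, j], train_phenotypes)
  }, numeric(1))
  if (all(!is.finite(fits))) {
    abort("All methods have degenerate correlation with the training phenotypes.")
  }
  prediction_methods(train_fits)[which.max(fits)]
}
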
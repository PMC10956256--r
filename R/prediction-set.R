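#' Validate a base-prediction set
#'
#' A base-prediction set is a tibble with an `individual_id` column followed by
#' one numeric column per base method (GBLUP, BayesA, ...), holding each
#' method's predicted genetic values for the same individuals. All ensemble
#' functions accept this layout.
#'
#' @param predictions A data frame: `individual_id` plus one numeric column per
#'   method.
#' @param min_methods Minimum number of method columns required (2 for
#'   ensembling, 1 for reference selection).
#' @return The validated predictions as a tibble, invisibly classed.
#' @export
as_prediction_set <- function(predictions, min_methods = 2L) {
  if (!is.data.frame(predictions)) {
    abort("`predictions` must be a data frame (individual_id + method columns).")
  }
  predictions <- tibble::as_tibble(predictions)
  if (!"individual_id" %in% names(predictions)) {
    abort("`predictions` must contain an `individual_id` column.")
  }
  methods <- setdiff(names(predictions), "individual_id")
  if (length(methods) < min_methods) {
    abort(sprintf("Need at least %d method columns, found %d.",
                  min_methods, length(methods)))
  }
  vals <- predictions[methods]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("All method columns must be numeric.")
  }
  if (anyNA(vals)) {
    abort("Prediction sets must not contain missing values.")
  }
  if (anyDuplicated(predictions$individual_id)) {
    abort("Duplicated `individual_id` in prediction set.")
  }
  predictions
}

# individuals x methods matrix view of a prediction set
prediction_matrix <- function(predictions) {
  methods <- setdiff(names(predictions), "individual_id")
  m <- as.matrix(predictions[methods])
  rownames(m) <- as.character(predictions$individual_id)
  m
}

prediction_methods <- function(predictions) {
  setdiff(names(predictions), "individual_id")
}
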
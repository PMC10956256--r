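#' Read a genotype matrix from file
#'
#' Two dialects: `csv_matrix` is a delimited table with a header row of marker
#' ids and a first column of individual ids; `plink_raw` is the PLINK additive
#' export (`FID IID PAT MAT SEX PHENOTYPE` then one minor-allele-count column
#' per marker, `NA` for missing). `"auto"` sniffs the header for the PLINK
#' preamble.
#'
#' @param path File path.
#' @param format `"auto"`, `"csv_matrix"` or `"plink_raw"`.
#' @param missing `"impute_mean"` (per-marker mean code) or `"error"`.
#' @return Individuals x markers numeric matrix with ids in dimnames.
#' @export
read_genotypes <- function(path, format = c("auto", "csv_matrix", "plink_raw"),
                           missing = c("impute_mean", "error")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  if (format == "auto") {
    hdr <- strsplit(readLines(path, n = 1L), "[,\t ]+")[[1]]
    format <- if (identical(toupper(hdr[seq_len(min(6, length(hdr)))]),
                            c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")))
      "plink_raw" else "csv_matrix"
  }
  if (format == "plink_raw") {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            na.strings = c("NA", "-9"))
    if (ncol(df) < 7L) abort("PLINK .raw file has no marker columns.")
    ids <- as.character(df$IID)
    Z <- as.matrix(df[-(1:6)])
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            sep = sniff_sep(path))
    ids <- as.character(df[[1L]])
    Z <- as.matrix(df[-1L])
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(sprintf("Duplicate individual id '%s' in %s.", dup, path))
  }
  if (!is.numeric(Z)) {
    bad <- which(!apply(Z, 1, function(r) all(is.na(r) | !is.na(suppressWarnings(as.numeric(r))))))
    abort(sprintf("Non-numeric genotype codes at data row(s): %s.",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  rownames(Z) <- ids
  as_genotype_matrix(Z, missing)
}

sniff_sep <- function(path) {
  l <- readLines(path, n = 1L)
  if (grepl("\t", l)) "\t" else if (grepl(",", l)) "," else ""
}

#' Write a genotype matrix as a delimited table
#'
#' @param genotypes Genotype matrix or data frame.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @export
write_genotypes <- function(genotypes, path, sep = ",") {
  Z <- as_genotype_matrix(genotypes)
  df <- data.frame(individual_id = rownames(Z), Z, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-separated with header: `individual_id`, `phenotype`, then optional
#' numeric covariate columns. `NA` phenotypes mark masked (to-be-predicted)
#' individuals.
#'
#' @param path File path.
#' @return Tibble as accepted by [fit_gblup()] / [fit_bayes()].
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  names(df)[1:2] <- c("individual_id", "phenotype")
  validate_phenotypes(df)
}

#' Write a phenotype table
#'
#' @param phenotypes Phenotype tibble.
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(validate_phenotypes(phenotypes), path)
  invisible(path)
}

#' Read a base-prediction table
#'
#' Wide form: `individual_id` plus one column per method. Long form:
#' `individual_id`, `method`, `value` with an optional `replicate` column (a
#' single replicate must be selected when several are present). The long/wide
#' conversion is a bijection for complete tables; incomplete long tables (a
#' method missing for some individual) are rejected.
#'
#' @param path File path (tab-separated).
#' @param format `"auto"`, `"wide"` or `"long"`.
#' @param replicate Replicate to extract from a long table holding several.
#' @return A wide prediction-set tibble.
#' @export
read_predictions <- function(path, format = c("auto", "wide", "long"),
                             replicate = NULL) {
  format <- match.arg(format)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (format == "auto") {
    format <- if (all(c("method", "value") %in% names(df))) "long" else "wide"
  }
  if (format == "long") {
    if (!all(c("individual_id", "method", "value") %in% names(df))) {
      abort("Long prediction tables need columns individual_id, method, value.")
    }
    if ("replicate" %in% names(df)) {
      reps <- unique(df$replicate)
      if (!is.null(replicate)) {
        df <- df[df$replicate == replicate, ]
      } else if (length(reps) > 1L) {
        abort("Long table holds several replicates; pass `replicate`.")
      }
    }
    method_order <- unique(df$method)
    wide <- tidyr::pivot_wider(df[c("individual_id", "method", "value")],
                               names_from = "method", values_from = "value")
    wide <- wide[c("individual_id", method_order)]
    if (anyNA(wide)) {
      abort("Incomplete long table: some individual is missing a method's value.")
    }
    df <- wide
  }
  as_prediction_set(df, min_methods = 1L)
}

#' Write a base-prediction table
#'
#' @param predictions Wide prediction-set tibble.
#' @param path Output path (tab-separated).
#' @param format `"wide"` or `"long"`.
#' @param replicate Replicate index recorded in long form (default 1).
#' @export
write_predictions <- function(predictions, path, format = c("wide", "long"),
                              replicate = 1L) {
  format <- match.arg(format)
  predictions <- as_prediction_set(predictions, min_methods = 1L)
  if (format == "long") {
    long <- tidyr::pivot_longer(predictions, -"individual_id",
                                names_to = "method", values_to = "value")
    long$replicate <- replicate
    readr::write_tsv(long[c("individual_id", "method", "replicate", "value")],
                     path)
  } else {
    readr::write_tsv(predictions, path)
  }
  invisible(path)
}

#' Read optimizer settings from a YAML/structured config file
#'
#' Recognized keys mirror [swarm_config()] arguments (`w_min`, `w_max`,
#' `v_min`, `v_max`, `m`, `f`, `cr`, `epsilon`, `c1`, `c2`, `max_iterations`,
#' `repeats`, `seed`, ...); unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A [swarm_config()].
#' @export
read_swarm_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(swarm_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    abort(sprintf("Unknown config keys: %s.", paste(extra, collapse = ", ")))
  }
  do.call(swarm_config, vals)
}

#' Write a run manifest
#'
#' Records command, resolved configuration, seed, input-file checksums,
#' package version and timestamp, so a run can be re-executed identically.
#'
#' @param path Output path (YAML).
#' @param command Command or function name.
#' @param config Named list of resolved settings.
#' @param seed Base seed used.
#' @param inputs Character vector of input file paths (md5-checksummed).
#' @export
write_run_manifest <- function(path, command, config = list(), seed = NA,
                               inputs = character()) {
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    inputs = as.list(tools::md5sum(inputs)),
    package_version = as.character(utils::packageVersion("elpgv")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  writeLines(yaml::as.yaml(manifest), path)
  invisible(path)
}
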
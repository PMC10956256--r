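#' Coerce genotypes to a coded matrix
#'
#' Genotypes are held as an individuals x markers numeric matrix of additive
#' codes: 0/1/2 minor-allele counts for biallelic SNPs (dosages allowed) or
#' 0/1 presence/absence for dominant markers. A tibble with an `individual_id`
#' column and one numeric column per marker is accepted and converted.
#'
#' @param genotypes Matrix with rownames (individual ids) and colnames (marker
#'   ids), or a data frame with `individual_id`.
#' @param missing How to handle missing codes: `"impute_mean"` replaces them
#'   with the marker's mean code, `"error"` rejects.
#' @return Numeric matrix, individuals x markers, no missing values.
#' @export
as_genotype_matrix <- function(genotypes, missing = c("impute_mean", "error")) {
  missing <- match.arg(missing)
  if (is.data.frame(genotypes)) {
    if (!"individual_id" %in% names(genotypes)) {
      abort("Genotype data frames must contain `individual_id`.")
    }
    ids <- as.character(genotypes$individual_id)
    genotypes <- as.matrix(genotypes[setdiff(names(genotypes), "individual_id")])
    rownames(genotypes) <- ids
  }
  if (!is.matrix(genotypes) || !is.numeric(genotypes)) {
    abort("`genotypes` must be a numeric matrix or a data frame of codes.")
  }
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- paste0("ind_", seq_len(nrow(genotypes)))
  }
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- paste0("m_", seq_len(ncol(genotypes)))
  }
  if (anyDuplicated(rownames(genotypes))) {
    abort("Duplicated individual ids in genotype matrix.")
  }
  if (anyNA(genotypes)) {
    if (missing == "error") abort("Genotype matrix contains missing codes.")
    mu <- colMeans(genotypes, na.rm = TRUE)
    idx <- which(is.na(genotypes), arr.ind = TRUE)
    genotypes[idx] <- mu[idx[, 2]]
  }
  rng <- range(genotypes)
  if (rng[1] < 0 || rng[2] > 2) {
    abort("Genotype codes must lie in [0, 2] (additive/dosage coding).")
  }
  genotypes
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Centers each marker by twice its allele frequency and scales the
#' cross-product by `2 * sum(p_k * (1 - p_k))`:
#' `G = Zc %*% t(Zc) / (2 * sum(p * (1 - p)))`, with `p_k` half the mean code
#' of marker `k`. For standard 0/1/2 SNP coding the average diagonal is near 1.
#'
#' @inheritParams as_genotype_matrix
#' @return Symmetric individuals x individuals kinship matrix with ids as
#'   dimnames.
#' @export
build_grm <- function(genotypes, missing = c("impute_mean", "error")) {
  Z <- as_genotype_matrix(genotypes, missing)
  if (nrow(Z) < 2L) abort("Kinship needs at least 2 individuals.")
  p <- colMeans(Z) / 2
  poly <- colMeans(Z^2) - colMeans(Z)^2 > 0
  if (!any(poly)) abort("All markers are monomorphic; kinship denominator is zero.")
  Zc <- sweep(Z[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Zc) / denom
  dimnames(G) <- list(rownames(Z), rownames(Z))
  G
}
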
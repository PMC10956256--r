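#' Design of a simulated quantitative-trait study
#'
#' Defaults emulate the wheat-shaped study conditions: 599 lines genotyped for
#' 1279 dominant (0/1) markers, 5 QTL with effect magnitudes drawn from
#' Gamma(shape 0.4, scale 1.66) and random sign, and heritability 0.5.
#' Presence frequencies are drawn uniformly on `freq_range` (default
#' 0.1-0.9, a realistic polymorphic range for dominant marker panels).
#'
#' @param n_individuals,n_markers Dimensions of the genotype matrix.
#' @param marker_type `"binary_dominant"` (0/1 presence/absence) or
#'   `"snp_biallelic"` (0/1/2 under Hardy-Weinberg at the marker's frequency).
#' @param freq_range Range the per-marker allele/presence frequency is drawn
#'   from, strictly inside (0, 1).
#' @param n_qtl Number of causal markers (5 or 1000 in the study designs).
#' @param gamma_shape,gamma_scale Gamma parameters of the QTL effect
#'   magnitudes.
#' @param heritability Target narrow-sense heritability in (0, 1].
#' @param effect_signs `"random"` flips each effect's sign with probability
#'   1/2; `"positive"` keeps all Gamma draws positive.
#' @param seed RNG seed.
#' @return List of class `sim_design`.
#' @export
sim_design <- function(n_individuals = 599L, n_markers = 1279L,
                       marker_type = c("binary_dominant", "snp_biallelic"),
                       freq_range = c(0.1, 0.9),
                       n_qtl = 5L, gamma_shape = 0.4, gamma_scale = 1.66,
                       heritability = 0.5,
                       effect_signs = c("random", "positive"),
                       seed = 1L) {
  marker_type <- match.arg(marker_type)
  effect_signs <- match.arg(effect_signs)
  if (n_qtl > n_markers) abort("`n_qtl` cannot exceed `n_markers`.")
  if (heritability <= 0 || heritability > 1) abort("`heritability` must be in (0, 1].")
  if (gamma_shape <= 0 || gamma_scale <= 0) abort("Gamma parameters must be positive.")
  if (freq_range[1] <= 0 || freq_range[2] >= 1 || freq_range[1] > freq_range[2]) {
    abort("`freq_range` must be an ordered range strictly inside (0, 1).")
  }
  structure(list(
    n_individuals = as.integer(n_individuals), n_markers = as.integer(n_markers),
    marker_type = marker_type, freq_range = freq_range,
    n_qtl = as.integer(n_qtl), gamma_shape = gamma_shape,
    gamma_scale = gamma_scale, heritability = heritability,
    effect_signs = effect_signs, seed = as.integer(seed)
  ), class = "sim_design")
}

#' Simulate a genotype matrix
#'
#' Dominant markers are Bernoulli draws at each marker's presence frequency;
#' biallelic SNPs are binomial(2) draws at each marker's allele frequency
#' (Hardy-Weinberg). Frequencies themselves are uniform on the design's
#' `freq_range`.
#'
#' @param design A [sim_design()].
#' @param seed RNG seed; defaults to the design's.
#' @return Individuals x markers numeric matrix with ids in the dimnames.
#' @export
sim_genotypes <- function(design, seed = design$seed) {
  set.seed(seed)
  n <- design$n_individuals
  p <- design$n_markers
  freq <- runif(p, design$freq_range[1], design$freq_range[2])
  size <- if (design$marker_type == "binary_dominant") 1L else 2L
  Z <- matrix(rbinom(n * p, size, rep(freq, each = n)), nrow = n)
  dimnames(Z) <- list(sprintf("ind_%03d", seq_len(n)),
                      sprintf("m_%04d", seq_len(p)))
  Z
}

#' Simulate a quantitative trait on given genotypes
#'
#' Samples `n_qtl` causal markers uniformly without replacement, draws effect
#' magnitudes from Gamma(shape, scale) (sign flipped with probability 1/2
#' unless `effect_signs = "positive"`), sets `g_true = Z_qtl %*% effects`, and
#' adds residual noise with variance
#' `var(g_true) * (1 - h2) / h2` so that each replicate is calibrated to the
#' target heritability against the realized genetic variance. If the sampled
#' QTL set has zero genetic variance (all monomorphic) it is redrawn up to 10
#' times.
#'
#' @inheritParams sim_genotypes
#' @param genotypes Genotype matrix (or data frame) the trait is simulated on.
#' @return Object of class `sim_trait`: a list with `phenotypes` (tibble:
#'   `individual_id`, `phenotype`, `g_true`), `qtl` (tibble: `marker_id`,
#'   `effect`), `sigma2_e`, `h2_target` and `h2_realized`.
#' @export
sim_trait <- function(genotypes, design, seed = design$seed) {
  Z <- as_genotype_matrix(genotypes)
  if (design$n_qtl > ncol(Z)) abort("`n_qtl` exceeds the number of markers.")
  set.seed(seed)
  for (try in seq_len(10L)) {
    qtl <- sort(sample.int(ncol(Z), design$n_qtl))
    eff <- rgamma(design$n_qtl, shape = design$gamma_shape,
                  scale = design$gamma_scale)
    if (design$effect_signs == "random") {
      eff <- eff * sample(c(-1, 1), design$n_qtl, replace = TRUE)
    }
    g <- as.numeric(Z[, qtl, drop = FALSE] %*% eff)
    if (var(g) > 0) break
    if (try == 10L) abort("Sampled QTL sets were all monomorphic (10 attempts).")
  }
  h2 <- design$heritability
  sigma2_e <- var(g) * (1 - h2) / h2
  e <- if (sigma2_e > 0) rnorm(length(g), 0, sqrt(sigma2_e)) else numeric(length(g))
  y <- g + e
  h2_realized <- if (var(e) > 0) var(g) / (var(g) + var(e)) else 1
  structure(list(
    phenotypes = tibble::tibble(
      individual_id = rownames(Z), phenotype = y, g_true = g
    ),
    qtl = tibble::tibble(marker_id = colnames(Z)[qtl], effect = eff),
    sigma2_e = sigma2_e,
    h2_target = h2,
    h2_realized = h2_realized
  ), class = "sim_trait")
}

#' @export
print.sim_trait <- function(x, ...) {
  cat(sprintf("<sim_trait> %d individuals, %d QTL, target h2 %.2f (realized %.3f)\n",
              nrow(x$phenotypes), nrow(x$qtl), x$h2_target, x$h2_realized))
  invisible(x)
}

#' Fixed wheat-shaped genotype fixture
#'
#' A deterministic 599 x 1279 binary (dominant-marker) genotype matrix mirroring
#' the dimensions of the public CIMMYT wheat panel; generated in code at a fixed
#' seed, so it is synthetic and carries no linkage-disequilibrium structure.
#'
#' @return Genotype matrix, 599 x 1279.
#' @export
wheat_fixture_genotypes <- function() {
  sim_genotypes(sim_design(seed = 599L))
}
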
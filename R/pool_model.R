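#' Calibrate variant-quality cutoffs from spike-in controls
#'
#' Pooled sequencing libraries carry spiked-in positive controls (known
#' variants at the singleton frequency `1/2N`) and negative controls (known
#' invariant sequence). Variant calls are thresholded on an opaque quality
#' score; the high-specificity cutoff is the lowest score observed among
#' positive controls and the high-sensitivity cutoff is the highest score
#' observed among negative controls. When the two score distributions are
#' separable, any cutoff in `(low_cutoff, high_cutoff]` discriminates the
#' controls with 100% accuracy.
#'
#' @param pos_scores numeric vector of quality scores of positive controls.
#' @param neg_scores numeric vector of quality scores of negative controls.
#' @return An object of class `calibration_result`: a list with
#'   `high_cutoff` (min of positive scores), `low_cutoff` (max of negative
#'   scores) and `separable` (`TRUE` iff `high_cutoff > low_cutoff`).
#'   Overlapping control distributions are flagged (`separable = FALSE`)
#'   rather than resolved by guessing a cutpoint.
#' @examples
#' calibrate_quality_cutoffs(c(30, 45, 60), c(5, 12))
#' @export
calibrate_quality_cutoffs <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L)
    stop("input error: both control score lists must be non-empty")
  if (anyNA(pos_scores) || anyNA(neg_scores))
    stop("input error: control scores must not contain NA")
  high <- min(pos_scores)
  low <- max(neg_scores)
  structure(
    list(high_cutoff = high, low_cutoff = low, separable = high > low),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Spike-in quality calibration\n")
  cat(sprintf("  high cutoff (min positive): %g\n", x$high_cutoff))
  cat(sprintf("  low cutoff (max negative):  %g\n", x$low_cutoff))
  cat(sprintf("  controls separable:         %s\n", x$separable))
  invisible(x)
}

#' Round a pooled allele-frequency estimate to the pool sampling grid
#'
#' A pool of `n_alleles` chromosomes can only contain allele frequencies that
#' are multiples of one allele (`1/n_alleles`); raw estimates from read
#' counts are rounded to the nearest such multiple. Half-way ties round away
#' from zero (so a raw estimate exactly between two grid points is assigned
#' the larger allele count).
#'
#' @param raw numeric vector of raw frequency estimates in `[0, 1]`.
#' @param n_alleles number of chromosomes in the pool (`2N`), positive.
#' @return Rounded frequencies, same length as `raw`.
#' @examples
#' round_allele_frequency(0.004, 254)  # one singleton allele, 1/254
#' @export
round_allele_frequency <- function(raw, n_alleles) {
  if (length(n_alleles) != 1L || n_alleles <= 0)
    stop("input error: n_alleles must be a single positive count")
  if (anyNA(raw) || any(raw < 0 | raw > 1))
    stop("input error: raw frequencies must lie in [0, 1]")
  # floor(x + 0.5) rounds half-way cases up (away from zero on [0, 1]),
  # unlike base round()'s round-half-even
  floor(raw * n_alleles + 0.5) / n_alleles
}

#' Estimate the allele-frequency estimation-error variance
#'
#' The error of pooled allele-frequency estimation, over and above binomial
#' sampling, is inferred as the mean squared error of observed (pooled
#' sequencing) frequencies against expected (individual genotyping)
#' frequencies over a set of SNPs assayed on both platforms:
#' \deqn{s_e = \frac{1}{n}\sum_i (f_{o,i} - f_{e,i})^2.}
#' The result is a variance in squared-frequency units, added to the
#' sampling variance by [modified_two_proportion_z()].
#'
#' @param observed numeric vector of observed allele frequencies.
#' @param expected numeric vector of expected allele frequencies, same length.
#' @return Single number: the mean squared error.
#' @export
estimate_estimation_error <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("input error: observed and expected must have equal length")
  if (length(observed) == 0L)
    stop("input error: need at least one frequency pair")
  mean((observed - expected)^2)
}

#' Bundle per-arm estimation-error variances
#'
#' @param se_case,se_control non-negative variances (squared frequency units).
#' @param n_snps_used number of concordance SNPs the estimates are based on.
#' @return An `estimation_error` object.
#' @seealso [estimate_estimation_error()]
#' @export
estimation_error <- function(se_case, se_control, n_snps_used = NA_integer_) {
  if (se_case < 0 || se_control < 0)
    stop("input error: estimation-error variances must be non-negative")
  structure(
    list(se_case = se_case, se_control = se_control,
         n_snps_used = n_snps_used),
    class = "estimation_error"
  )
}

#' Concordance between pooled and genotype-based allele frequencies
#'
#' @param observed numeric vector of pooled-sequencing frequency estimates.
#' @param expected numeric vector of genotype-based frequencies.
#' @return List with `r` (Pearson correlation), `mad` (mean absolute
#'   difference) and `n` (number of pairs).
#' @export
af_concordance <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("input error: observed and expected must have equal length")
  if (length(observed) < 3L)
    stop("input error: concordance needs at least 3 paired frequencies")
  if (stats::sd(observed) == 0 || stats::sd(expected) == 0)
    stop("undefined-correlation error: constant frequency vector")
  list(
    r = stats::cor(observed, expected),
    mad = mean(abs(observed - expected)),
    n = length(observed)
  )
}

#' Flag sites with insufficient read coverage
#'
#' Power to detect variants in a pool saturates above roughly 30 reads per
#' site per allele; sites below that are flagged for interpretation.
#'
#' @param site_coverages numeric vector of reads per site per allele (>= 0).
#' @param threshold coverage below which a site is flagged (strict). Default 30.
#' @return List with `flagged` (integer indices of low-coverage sites) and
#'   `fraction` (share of sites flagged).
#' @export
coverage_qc <- function(site_coverages, threshold = 30) {
  if (any(site_coverages < 0))
    stop("input error: coverages must be non-negative")
  flagged <- which(site_coverages < threshold)
  list(flagged = flagged,
       fraction = if (length(site_coverages)) length(flagged) / length(site_coverages) else 0)
}
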
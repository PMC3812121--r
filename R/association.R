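#' Two-proportion Z-test with allele-frequency estimation-error variance
#'
#' Tests the difference in allele frequency between a case and a control
#' sequencing pool. Pooled sequencing yields frequency *estimates*, not
#' genotypes, so the usual two-proportion Z-test variance is augmented with
#' the per-arm estimation-error variances `se_case` and `se_control`
#' (mean squared error of pooled estimates against genotype-based
#' frequencies; see [estimate_estimation_error()]), treated as additive and
#' independent of binomial sampling:
#' \deqn{p_0 = \frac{p_A N_A + p_B N_B}{N_A + N_B}, \quad
#'       \sigma_s^2 = p_0 (1 - p_0) \left(\frac{1}{N_A} + \frac{1}{N_B}\right)}
#' \deqn{z = \frac{p_A - p_B}{\sqrt{\sigma_s^2 + s_{e,A} + s_{e,B}}}}
#' with `z` referred to the standard normal and a two-sided P-value
#' reported. With both `se` terms zero this is exactly the classic pooled
#' two-proportion Z-test.
#'
#' @param p_case,p_control allele frequency estimates in the case and
#'   control pools (vectors recycle in the usual way).
#' @param n_case,n_control number of alleles (2N) in each pool.
#' @param se_case,se_control additive estimation-error variances for each
#'   arm (squared frequency units); default 0.
#' @return A data frame of class `assoc_result` with one row per test:
#'   `p0` (pooled frequency), `sigma_s` (sampling standard deviation), `z`,
#'   `p_value` (two-sided), `or_allelic` (allelic odds ratio, `NA` at
#'   boundary frequencies) and `af_ratio` (case/control frequency ratio,
#'   `NA` when the control frequency is 0).
#' @examples
#' # a common nonsynonymous variant: nearly equal pool frequencies
#' modified_two_proportion_z(0.502, 0.512, 254, 270, 0.00081, 0.00032)
#' @export
modified_two_proportion_z <- function(p_case, p_control, n_case, n_control,
                                      se_case = 0, se_control = 0) {
  k <- max(length(p_case), length(p_control))
  args <- data.frame(p_case = p_case, p_control = p_control,
                     n_case = n_case, n_control = n_control,
                     se_case = se_case, se_control = se_control)
  with(args, {
    if (any(p_case < 0 | p_case > 1 | p_control < 0 | p_control > 1))
      stop("input error: frequencies must lie in [0, 1]")
    if (any(n_case <= 0 | n_control <= 0))
      stop("input error: allele counts must be positive")
    if (any(se_case < 0 | se_control < 0))
      stop("input error: estimation-error variances must be non-negative")
  })
  p0 <- with(args, (p_case * n_case + p_control * n_control) / (n_case + n_control))
  var_s <- with(args, p0 * (1 - p0) * (1 / n_case + 1 / n_control))
  var_tot <- var_s + args$se_case + args$se_control
  if (any(var_tot == 0))
    stop("degenerate-variance error: pooled frequency 0 or 1 with zero estimation error")
  z <- (args$p_case - args$p_control) / sqrt(var_tot)
  res <- data.frame(
    p0 = p0,
    sigma_s = sqrt(var_s),
    z = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    or_allelic = ifelse(
      args$p_case > 0 & args$p_case < 1 & args$p_control > 0 & args$p_control < 1,
      (args$p_case / (1 - args$p_case)) / (args$p_control / (1 - args$p_control)),
      NA_real_),
    af_ratio = ifelse(args$p_control > 0, args$p_case / args$p_control, NA_real_)
  )
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Allelic odds ratio from two allele frequencies
#'
#' `[p_A/(1-p_A)] / [p_B/(1-p_B)]` — the odds ratio of carrying the allele
#' in cases relative to controls, defined for interior frequencies only.
#'
#' @param p_case,p_control allele frequencies strictly inside (0, 1).
#' @return The odds ratio.
#' @examples
#' allelic_odds_ratio(0.389, 0.286)  # ~1.59
#' @export
allelic_odds_ratio <- function(p_case, p_control) {
  if (any(p_case <= 0 | p_case >= 1 | p_control <= 0 | p_control >= 1))
    stop("undefined-odds error: frequencies must be strictly inside (0, 1)")
  (p_case / (1 - p_case)) / (p_control / (1 - p_control))
}

#' Case/control allele-frequency ratio
#'
#' The plain ratio `p_A / p_B`. For variants at low frequency this is close
#' to, but distinct from, the allelic odds ratio; both summaries are kept
#' separate because published per-variant tables sometimes print one and
#' haplotype-level text the other.
#'
#' @param p_case,p_control allele frequencies; `p_control` must be positive.
#' @return The frequency ratio.
#' @export
allele_frequency_ratio <- function(p_case, p_control) {
  if (any(p_control <= 0))
    stop("undefined-ratio error: control frequency must be positive")
  p_case / p_control
}

#' Scan common variants for association stronger than the tag SNPs
#'
#' Applies [modified_two_proportion_z()] to every variant whose pooled minor
#' allele frequency exceeds `maf_cutoff`, then compares each P-value against
#' the least significant (largest) P among a designated set of tag SNPs —
#' the logic of a fine-mapping scan in which a causal variant is expected to
#' associate at least as strongly as the tags that discovered the locus.
#' The "stronger" comparison is strict (`P < threshold`).
#'
#' @param variants data frame with columns `variant_id`, `af_case`,
#'   `af_control`, `n_case_alleles`, `n_control_alleles`, and optionally
#'   `region_class` (e.g. `"candidate"`/`"flanking"`) and `pos`.
#' @param se an [estimation_error()] object (or a list with `se_case` and
#'   `se_control`).
#' @param tag_ids character vector of tag-SNP `variant_id`s; all must be
#'   present among the scanned (common) variants.
#' @param maf_cutoff minimum pooled minor allele frequency (strict); default
#'   0.05. The pooled MAF is computed on the allele-count-weighted mean of
#'   the two arm frequencies.
#' @return List of class `common_variant_scan`: `table` (scanned variants
#'   ranked by P, with `z`, `p_value`, `neg_log10_p`, `is_tag`, `stronger`),
#'   `threshold` (largest tag P), `n_stronger` (variants with
#'   `p_value < threshold`) and `n_tested`.
#' @export
scan_common_variants <- function(variants, se, tag_ids, maf_cutoff = 0.05) {
  need <- c("variant_id", "af_case", "af_control",
            "n_case_alleles", "n_control_alleles")
  if (!all(need %in% names(variants)))
    stop("input error: variants table lacks columns: ",
         paste(setdiff(need, names(variants)), collapse = ", "))
  af_pooled <- with(variants,
    (af_case * n_case_alleles + af_control * n_control_alleles) /
      (n_case_alleles + n_control_alleles))
  maf <- pmin(af_pooled, 1 - af_pooled)
  common <- variants[maf > maf_cutoff, , drop = FALSE]
  if (!all(tag_ids %in% common$variant_id))
    stop("input error: tag SNP(s) missing from the common-variant set: ",
         paste(setdiff(tag_ids, common$variant_id), collapse = ", "))
  res <- modified_two_proportion_z(
    common$af_case, common$af_control,
    common$n_case_alleles, common$n_control_alleles,
    se$se_case, se$se_control)
  tab <- cbind(common, res[c("z", "p_value")])
  tab$neg_log10_p <- -log10(tab$p_value)
  tab$is_tag <- tab$variant_id %in% tag_ids
  threshold <- max(tab$p_value[tab$is_tag])
  tab$stronger <- tab$p_value < threshold
  tab <- tab[order(tab$p_value), , drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(table = tab, threshold = threshold,
         n_stronger = sum(tab$stronger), n_tested = nrow(tab)),
    class = "common_variant_scan"
  )
}

#' @export
print.common_variant_scan <- function(x, ...) {
  cat(sprintf("Common-variant scan: %d variants tested, tag threshold P = %.4g\n",
              x$n_tested, x$threshold))
  cat(sprintf("  %d variant(s) stronger than the least significant tag\n",
              x$n_stronger))
  print(utils::head(x$table[c("variant_id", "af_case", "af_control",
                              "z", "p_value", "is_tag", "stronger")], 10))
  invisible(x)
}
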
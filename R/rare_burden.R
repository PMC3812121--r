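#' Collapse rare variants in one arm into a single pseudo-variant
#'
#' Rare variants (minor allele frequency below `maf_cutoff` in *both* arms)
#' are aggregated: the collapsed allele frequency is the summed minor-allele
#' count over qualifying variants divided by the arm's allele total, and the
#' variant count is the number of qualifying variants actually observed
#' (frequency > 0) in the arm. Pool data carry frequencies rather than
#' genotypes, so per-variant allele counts are reconstructed as
#' `round(maf * n_alleles)`.
#'
#' @param variants data frame with `af_case`, `af_control`,
#'   `n_case_alleles`, `n_control_alleles`, and (for `site_filter`)
#'   `region_class` (`"candidate"`/`"flanking"`) and logical `conserved`.
#' @param arm `"case"` or `"control"`.
#' @param maf_cutoff rare-variant definition, strict upper bound on the MAF
#'   in both arms; default 0.01.
#' @param site_filter `"all"` (candidate regions), `"conserved"` (conserved
#'   sites within candidate regions) or `"flanking"` (flanking-region
#'   control).
#' @return List: `n_variants`, `collapsed_af`, `n_alleles`, `arm`,
#'   `site_filter`, and `variant_ids` of the qualifying variants observed in
#'   the arm.
#' @export
collapse_rare_variants <- function(variants, arm = c("case", "control"),
                                   maf_cutoff = 0.01,
                                   site_filter = c("all", "conserved", "flanking")) {
  arm <- match.arg(arm)
  site_filter <- match.arg(site_filter)
  v <- variants
  if (site_filter != "all" || "region_class" %in% names(v)) {
    if (!"region_class" %in% names(v))
      stop("input error: site_filter requires a region_class column")
    v <- switch(site_filter,
      all = v[v$region_class == "candidate", , drop = FALSE],
      conserved = {
        if (!"conserved" %in% names(v))
          stop("input error: conserved-site filter requires a conserved column")
        v[v$region_class == "candidate" & v$conserved %in% TRUE, , drop = FALSE]
      },
      flanking = v[v$region_class == "flanking", , drop = FALSE])
  }
  maf_case <- pmin(v$af_case, 1 - v$af_case)
  maf_control <- pmin(v$af_control, 1 - v$af_control)
  rare <- maf_case < maf_cutoff & maf_control < maf_cutoff
  f <- if (arm == "case") maf_case else maf_control
  n_alleles <- if (arm == "case") v$n_case_alleles else v$n_control_alleles
  n_alleles <- if (nrow(v)) n_alleles[[1]] else NA_integer_
  counts <- round(f[rare] * n_alleles)
  observed <- counts > 0
  list(
    n_variants = sum(observed),
    collapsed_af = if (any(rare)) sum(counts) / n_alleles else 0,
    n_alleles = n_alleles,
    arm = arm,
    site_filter = site_filter,
    variant_ids = if ("variant_id" %in% names(v)) v$variant_id[rare][observed] else NULL
  )
}

#' One-tail Fisher's exact test of collapsed rare-variant burden
#'
#' Compares collapsed minor-allele carrier counts between arms with the
#' hypergeometric (Fisher) tail probability in a stated direction, plus the
#' odds ratio of the collapsed frequencies
#' `[f_case/(1-f_case)] / [f_ctrl/(1-f_ctrl)]`.
#'
#' @param case_carriers,control_carriers collapsed minor-allele counts.
#' @param case_alleles,control_alleles arm allele totals (2N).
#' @param tail `"auto"` (default; the observed direction — depletion if the
#'   case collapsed frequency is at most the control one, enrichment
#'   otherwise), `"depletion"` (`P(X <= observed)`) or `"enrichment"`
#'   (`P(X >= observed)`), where `X` is the case carrier count under the
#'   hypergeometric null given the margins.
#' @return List of class `burden_result`: counts, collapsed frequencies,
#'   `odds_ratio` (0 or `Inf` at boundary frequencies, `NA` when both arms
#'   are empty), `p_one_tail` and the `tail` used.
#' @export
fisher_one_tail_burden <- function(case_carriers, case_alleles,
                                   control_carriers, control_alleles,
                                   tail = c("auto", "depletion", "enrichment")) {
  tail <- match.arg(tail)
  if (case_alleles <= 0 || control_alleles <= 0)
    stop("input error: allele totals must be positive")
  if (case_carriers > case_alleles || control_carriers > control_alleles)
    stop("input error: carriers cannot exceed alleles in an arm")
  f_case <- case_carriers / case_alleles
  f_ctrl <- control_carriers / control_alleles
  if (tail == "auto")
    tail <- if (f_case <= f_ctrl) "depletion" else "enrichment"
  k <- case_carriers + control_carriers        # total carriers
  n_tot <- case_alleles + control_alleles
  p <- if (tail == "depletion") {
    stats::phyper(case_carriers, k, n_tot - k, case_alleles)
  } else {
    stats::phyper(case_carriers - 1, k, n_tot - k, case_alleles,
                  lower.tail = FALSE)
  }
  odds <- function(f) f / (1 - f)
  or <- if (f_case == 0 && f_ctrl == 0) NA_real_
        else if (f_ctrl == 0 || f_case == 1) Inf
        else odds(f_case) / odds(f_ctrl)
  structure(
    list(case_carriers = case_carriers, case_alleles = case_alleles,
         control_carriers = control_carriers, control_alleles = control_alleles,
         collapsed_af_case = f_case, collapsed_af_control = f_ctrl,
         odds_ratio = or, p_one_tail = p, tail = tail),
    class = "burden_result"
  )
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("Collapsed burden: case %d/%d (%.3f), control %d/%d (%.3f)\n",
              x$case_carriers, x$case_alleles, x$collapsed_af_case,
              x$control_carriers, x$control_alleles, x$collapsed_af_control))
  cat(sprintf("  OR = %.3g, one-tail (%s) Fisher P = %.4g\n",
              x$odds_ratio, x$tail, x$p_one_tail))
  invisible(x)
}

#' Rare-variant burden table over region/site strata
#'
#' Convenience wrapper running [collapse_rare_variants()] for both arms and
#' [fisher_one_tail_burden()] across the usual strata: all candidate-region
#' variants, conserved sites within candidate regions, and the
#' flanking-region control.
#'
#' @inheritParams collapse_rare_variants
#' @inheritParams fisher_one_tail_burden
#' @param strata character vector of site filters to report.
#' @return Data frame with one row per stratum: counts, collapsed
#'   frequencies, odds ratio and one-tail P.
#' @export
rare_burden_table <- function(variants, maf_cutoff = 0.01,
                              strata = c("all", "conserved", "flanking"),
                              tail = "auto") {
  rows <- lapply(strata, function(s) {
    ca <- collapse_rare_variants(variants, "case", maf_cutoff, s)
    co <- collapse_rare_variants(variants, "control", maf_cutoff, s)
    if (is.na(ca$n_alleles) || is.na(co$n_alleles))
      return(data.frame(site_filter = s, n_case = 0, collapsed_af_case = 0,
                        n_control = 0, collapsed_af_control = 0,
                        odds_ratio = NA_real_, p_one_tail = NA_real_,
                        tail = NA_character_))
    ft <- fisher_one_tail_burden(round(ca$collapsed_af * ca$n_alleles), ca$n_alleles,
                                 round(co$collapsed_af * co$n_alleles), co$n_alleles,
                                 tail = tail)
    data.frame(site_filter = s,
               n_case = ca$n_variants, collapsed_af_case = ca$collapsed_af,
               n_control = co$n_variants, collapsed_af_control = co$collapsed_af,
               odds_ratio = ft$odds_ratio, p_one_tail = ft$p_one_tail,
               tail = ft$tail)
  })
  do.call(rbind, rows)
}

#' Variants observed exclusively in one arm
#'
#' Returns variants present (frequency > 0) in exactly one arm with minor
#' allele frequency at most `maf_max` in that arm — the low-frequency,
#' arm-exclusive set used as a sensitivity companion to the collapsed
#' burden test.
#'
#' @param variants data frame as in [collapse_rare_variants()].
#' @param maf_max inclusive MAF ceiling in the carrying arm; default 0.05.
#' @return The qualifying subset of `variants` with an added `exclusive_to`
#'   column (`"case"` or `"control"`).
#' @export
exclusive_variant_table <- function(variants, maf_max = 0.05) {
  maf_case <- pmin(variants$af_case, 1 - variants$af_case)
  maf_control <- pmin(variants$af_control, 1 - variants$af_control)
  case_only <- variants$af_case > 0 & variants$af_control == 0 & maf_case <= maf_max
  ctrl_only <- variants$af_control > 0 & variants$af_case == 0 & maf_control <= maf_max
  out <- variants[case_only | ctrl_only, , drop = FALSE]
  out$exclusive_to <- ifelse(out$af_case > 0, "case", "control")
  rownames(out) <- NULL
  out
}
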
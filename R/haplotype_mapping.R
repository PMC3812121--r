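#' Linkage-disequilibrium statistics from gamete counts
#'
#' Computes the classical pairwise LD summaries from the four gamete
#' (two-locus haplotype) counts at a pair of biallelic loci:
#' `D = p_AB - p_A p_B`; `D'` is `|D|` normalised by its maximum attainable
#' magnitude given the allele frequencies (`min(p_A q_B, q_A p_B)` when
#' `D > 0`, `min(p_A p_B, q_A q_B)` when `D < 0`); and
#' `r^2 = D^2 / (p_A q_A p_B q_B)`.
#'
#' @param n_AB,n_Ab,n_aB,n_ab gamete counts; uppercase denotes the focal
#'   allele at each locus. Alternatively pass a 2x2 matrix as `n_AB` with
#'   rows indexing the first locus.
#' @return List of class `ld_stats`: `D`, `D_prime`, `r2`, plus the allele
#'   frequencies `p_A`, `p_B` and total gamete count `n`.
#' @examples
#' ld_stats(4, 1, 1, 4)  # D = 0.15, D' = 0.6, r2 = 0.36
#' @export
ld_stats <- function(n_AB, n_Ab = NULL, n_aB = NULL, n_ab = NULL) {
  if (is.matrix(n_AB)) {
    stopifnot(all(dim(n_AB) == c(2L, 2L)))
    m <- n_AB
    n_ab <- m[2, 2]; n_aB <- m[2, 1]; n_Ab <- m[1, 2]; n_AB <- m[1, 1]
  }
  counts <- c(n_AB, n_Ab, n_aB, n_ab)
  if (any(counts < 0) || sum(counts) == 0)
    stop("input error: gamete counts must be non-negative with positive total")
  n <- sum(counts)
  p_AB <- n_AB / n
  p_A <- (n_AB + n_Ab) / n
  p_B <- (n_AB + n_aB) / n
  if (p_A %in% c(0, 1) || p_B %in% c(0, 1))
    stop("undefined-LD error: monomorphic locus")
  D <- p_AB - p_A * p_B
  D_max <- if (D >= 0) min(p_A * (1 - p_B), (1 - p_A) * p_B)
           else        min(p_A * p_B, (1 - p_A) * (1 - p_B))
  structure(
    list(D = D,
         D_prime = if (D == 0) 0 else abs(D) / D_max,
         r2 = D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B)),
         p_A = p_A, p_B = p_B, n = n),
    class = "ld_stats"
  )
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("LD: D = %.4g, D' = %.4g, r2 = %.4g (n = %d gametes)\n",
              x$D, x$D_prime, x$r2, x$n))
  invisible(x)
}

# LD between two 0/1 vectors across the same chromosomes (gametes)
ld_from_vectors <- function(x, y) {
  stopifnot(length(x) == length(y))
  ld_stats(sum(x == 1 & y == 1), sum(x == 1 & y == 0),
           sum(x == 0 & y == 1), sum(x == 0 & y == 0))
}

#' Cluster phased chromosomes into major haplotypes
#'
#' Groups the chromosomes of a phased panel by exact allele-vector identity
#' over the sites of an interval. Groups at or above `freq_cutoff` are the
#' major haplotypes, numbered `H1, H2, ...` in descending frequency (a
#' group at exactly the cutoff is retained as major). The remaining
#' chromosomes are rare or recombinant and stay unassigned.
#'
#' @param panel a `haplotype_panel` (see [gen_haplotype_panel()] or
#'   [read_panel_vcf()]).
#' @param sites optional character vector of site ids (or integer indices)
#'   restricting the interval; default all sites.
#' @param freq_cutoff major-haplotype frequency boundary; default 0.05.
#' @return List of class `haplotype_clusters`: `groups` (data frame
#'   `hap_id`, `n`, `freq` in descending frequency), `membership` (per
#'   chromosome, the `hap_id` or `NA`), `coverage` (fraction of chromosomes
#'   in major groups) and `sites_used`.
#' @export
cluster_major_haplotypes <- function(panel, sites = NULL, freq_cutoff = 0.05) {
  geno <- panel$genotypes
  if (is.null(sites)) sites <- colnames(geno)
  if (is.numeric(sites)) sites <- colnames(geno)[sites]
  if (length(sites) == 0L || !all(sites %in% colnames(geno)))
    stop("input error: empty or unknown site interval")
  sub <- geno[, sites, drop = FALSE]
  if (all(apply(sub, 2, function(s) length(unique(s)) == 1L)))
    warning("no polymorphic site in interval; all chromosomes form one group")
  key <- apply(sub, 1, paste, collapse = "")
  tab <- table(key)
  # descending count; ties broken by haplotype string for determinism
  ord <- order(-as.integer(tab), names(tab))
  tab <- tab[ord]
  n_chrom <- nrow(sub)
  freq <- as.integer(tab) / n_chrom
  major <- freq >= freq_cutoff
  hap_ids <- paste0("H", seq_len(sum(major)))
  groups <- data.frame(hap_id = hap_ids,
                       n = as.integer(tab)[major],
                       freq = freq[major])
  membership <- rep(NA_character_, n_chrom)
  for (i in seq_along(hap_ids))
    membership[key == names(tab)[major][i]] <- hap_ids[i]
  names(membership) <- rownames(sub)
  structure(
    list(groups = groups, membership = membership,
         coverage = sum(groups$n) / n_chrom, sites_used = sites,
         freq_cutoff = freq_cutoff),
    class = "haplotype_clusters"
  )
}

#' @export
print.haplotype_clusters <- function(x, ...) {
  cat(sprintf("%d major haplotype(s) covering %.1f%% of %d chromosomes\n",
              nrow(x$groups), 100 * x$coverage, length(x$membership)))
  print(x$groups)
  invisible(x)
}

#' Select tag SNPs for a major haplotype
#'
#' For every panel site, computes `r^2` between the site's allele indicator
#' and membership of the chosen haplotype group across panel chromosomes;
#' sites exceeding `r2_cutoff` (strict) become tags. Each tag records which
#' allele (1 or 0) marks the haplotype, so pool allele frequencies can be
#' oriented before averaging.
#'
#' @param panel a `haplotype_panel`.
#' @param clusters result of [cluster_major_haplotypes()].
#' @param hap_id which major haplotype to tag (e.g. `"H1"`).
#' @param r2_cutoff minimum `r^2` (strict); default 0.9.
#' @return List of class `tag_set`: `hap_id`, `tags` (data frame `snp_id`,
#'   `r2`, `tag_allele`), and `flagged = TRUE` when no site qualifies
#'   (an empty tag set is reported, not an error).
#' @export
select_tag_snps <- function(panel, clusters, hap_id, r2_cutoff = 0.9) {
  if (!hap_id %in% clusters$groups$hap_id)
    stop("input error: unknown haplotype id ", hap_id)
  member <- as.integer(clusters$membership == hap_id & !is.na(clusters$membership))
  geno <- panel$genotypes
  rows <- lapply(colnames(geno), function(s) {
    x <- geno[, s]
    if (length(unique(x)) == 1L) return(NULL)     # monomorphic: no LD defined
    ld <- ld_from_vectors(x, member)
    data.frame(snp_id = s, r2 = ld$r2,
               tag_allele = if (ld$D > 0) 1L else 0L)
  })
  tags <- do.call(rbind, rows)
  if (!is.null(tags)) {
    tags <- tags[tags$r2 > r2_cutoff, , drop = FALSE]
    rownames(tags) <- NULL
  }
  structure(
    list(hap_id = hap_id, tags = tags,
         flagged = is.null(tags) || nrow(tags) == 0L,
         r2_cutoff = r2_cutoff),
    class = "tag_set"
  )
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("Tag set for %s: %d SNP(s) at r2 > %g%s\n", x$hap_id,
              if (is.null(x$tags)) 0L else nrow(x$tags), x$r2_cutoff,
              if (x$flagged) " [no qualifying tag]" else ""))
  if (!x$flagged) print(x$tags)
  invisible(x)
}

#' Estimate a haplotype frequency from tag-SNP pool frequencies
#'
#' A pool does not observe haplotypes directly; the frequency of a tagged
#' haplotype is estimated as the arithmetic mean of the pool frequencies of
#' its tag alleles. The per-tag spread is returned so the caller can judge
#' (and, if desired, exclude) outlier tags; no automatic exclusion is done.
#'
#' @param tags a `tag_set` from [select_tag_snps()].
#' @param pool_afs named numeric vector of pool frequencies of the `1`
#'   allele, names matching `snp_id`; every tag must be present.
#' @return List: `freq` (mean of tag-oriented frequencies), `per_tag`
#'   (named oriented frequencies), `spread` (their standard deviation; `NA`
#'   for a single tag) and `n_tags`.
#' @export
estimate_haplotype_frequencies <- function(tags, pool_afs) {
  if (tags$flagged || is.null(tags$tags) || nrow(tags$tags) == 0L)
    stop("estimation error: empty tag set for ", tags$hap_id)
  ids <- tags$tags$snp_id
  if (!all(ids %in% names(pool_afs)))
    stop("input error: missing pool frequency for tag(s): ",
         paste(setdiff(ids, names(pool_afs)), collapse = ", "))
  af <- pool_afs[ids]
  oriented <- ifelse(tags$tags$tag_allele == 1L, af, 1 - af)
  names(oriented) <- ids
  list(freq = mean(oriented), per_tag = oriented,
       spread = if (length(oriented) > 1L) stats::sd(oriented) else NA_real_,
       n_tags = length(oriented))
}

#' Fisher's exact test of a haplotype frequency between arms
#'
#' Reconstructs per-arm haplotype counts as `round(freq * alleles)`, forms
#' the 2x2 table against the remaining chromosomes and tests it two-sided
#' with Fisher's exact test. The odds ratio reported is the sample
#' cross-product ratio `(a d) / (b c)` with a log-normal Wald 95% CI, which
#' is the summary conventionally quoted alongside the exact P.
#'
#' @param freq_case,freq_control estimated haplotype frequencies.
#' @param n_case_alleles,n_control_alleles arm allele totals (2N).
#' @return List of class `haplotype_association`: reconstructed `counts`
#'   (2x2 matrix), frequencies, `odds_ratio` (`NA`-flagged when a table
#'   cell is zero), `ci95`, `p_fisher`. A zero margin yields the degenerate
#'   result `p_fisher = 1` with the odds ratio flagged undefined.
#' @examples
#' haplotype_fisher_test(38 / 254, 254, 22 / 270, 270)
#' @export
haplotype_fisher_test <- function(freq_case, n_case_alleles,
                                  freq_control, n_control_alleles) {
  if (freq_case < 0 || freq_case > 1 || freq_control < 0 || freq_control > 1)
    stop("input error: frequencies must lie in [0, 1]")
  a <- round(freq_case * n_case_alleles)
  b <- n_case_alleles - a
  c_ <- round(freq_control * n_control_alleles)
  d <- n_control_alleles - c_
  counts <- matrix(c(a, b, c_, d), 2, 2,
                   dimnames = list(c("hap", "other"), c("case", "control")))
  if (a + c_ == 0L || b + d == 0L) {
    return(structure(
      list(counts = counts, freq_case = freq_case, freq_control = freq_control,
           odds_ratio = NA_real_, ci95 = c(NA_real_, NA_real_),
           p_fisher = 1, or_defined = FALSE),
      class = "haplotype_association"))
  }
  or_defined <- all(counts > 0)
  or <- if (or_defined) (a * d) / (b * c_) else NA_real_
  ci <- if (or_defined) {
    se_log <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  } else c(NA_real_, NA_real_)
  structure(
    list(counts = counts, freq_case = a / n_case_alleles,
         freq_control = c_ / n_control_alleles,
         odds_ratio = or, ci95 = ci,
         p_fisher = stats::fisher.test(counts)$p.value,
         or_defined = or_defined),
    class = "haplotype_association"
  )
}

#' @export
print.haplotype_association <- function(x, ...) {
  cat(sprintf("Haplotype association: %.3f (case) vs %.3f (control)\n",
              x$freq_case, x$freq_control))
  if (isTRUE(x$or_defined))
    cat(sprintf("  OR = %.3g (95%% CI %.3g-%.3g), Fisher P = %.4g\n",
                x$odds_ratio, x$ci95[1], x$ci95[2], x$p_fisher))
  else
    cat(sprintf("  OR undefined (boundary table), Fisher P = %.4g\n", x$p_fisher))
  invisible(x)
}

#' Conditional independence test between two associated haplotypes
#'
#' Re-tests a target haplotype after removing all chromosomes carrying an
#' excluded haplotype from both arms' denominators — if the target's effect
#' is merely a reflection of the excluded haplotype's (through their mutual
#' exclusion on chromosomes), the conditional odds ratio collapses to 1.
#'
#' @param counts_case,counts_control named integer vectors of per-haplotype
#'   chromosome counts in each arm; each must sum to the arm's allele total
#'   and include every haplotype label needed (unlisted chromosomes can be
#'   pooled under any label, e.g. `"other"`).
#' @param target_hap,excluded_hap haplotype labels; must differ.
#' @return List: `odds_ratio` (cross-product), `ci95`, `p_value` (two-sided
#'   Fisher) and the conditional 2x2 `counts`.
#' @export
conditional_independence_test <- function(counts_case, counts_control,
                                          target_hap, excluded_hap) {
  if (identical(target_hap, excluded_hap))
    stop("input error: target and excluded haplotypes must differ")
  for (v in list(counts_case, counts_control))
    if (!all(c(target_hap, excluded_hap) %in% names(v)))
      stop("input error: counts must be named and include target and excluded haplotypes")
  a <- counts_case[[target_hap]]
  b <- sum(counts_case) - counts_case[[excluded_hap]] - a
  c_ <- counts_control[[target_hap]]
  d <- sum(counts_control) - counts_control[[excluded_hap]] - c_
  counts <- matrix(c(a, b, c_, d), 2, 2,
                   dimnames = list(c(target_hap, "other"), c("case", "control")))
  or_defined <- all(counts > 0)
  or <- if (or_defined) (a * d) / (b * c_) else NA_real_
  ci <- if (or_defined)
    exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * sqrt(1/a + 1/b + 1/c_ + 1/d))
  else c(NA_real_, NA_real_)
  list(odds_ratio = or, ci95 = ci,
       p_value = stats::fisher.test(counts)$p.value, counts = counts)
}

#' Detect individuals carrying recombinant haplotypes from tag genotypes
#'
#' If a haplotype's tag SNPs are perfect proxies, an individual's allele
#' dosages must be identical across all tags of that haplotype; discordant
#' dosages within a tag set imply a chromosome carrying only part of the
#' tag-defined haplotype (a historical recombinant). Individuals discordant
#' within either the risk or the protective tag set are reported.
#'
#' @param genotypes data frame with `individual_id` and one dosage column
#'   (0/1/2) per tag SNP; rows with missing tag dosages must be removed
#'   upstream.
#' @param risk_tags,protective_tags character vectors of tag column names.
#' @return Character vector of recombinant `individual_id`s, with a
#'   `detail` attribute (logical data frame per tag set).
#' @export
detect_recombinants <- function(genotypes, risk_tags, protective_tags) {
  for (tags in list(risk_tags, protective_tags))
    if (!all(tags %in% names(genotypes)))
      stop("input error: missing tag genotype column(s): ",
           paste(setdiff(tags, names(genotypes)), collapse = ", "))
  discordant <- function(tags) {
    m <- as.matrix(genotypes[, tags, drop = FALSE])
    apply(m, 1, function(d) length(unique(d)) > 1L)
  }
  risk_disc <- discordant(risk_tags)
  prot_disc <- discordant(protective_tags)
  rec <- genotypes$individual_id[risk_disc | prot_disc]
  attr(rec, "detail") <- data.frame(individual_id = genotypes$individual_id,
                                    recombinant_risk = risk_disc,
                                    recombinant_protective = prot_disc)
  rec
}

#' Joint logistic test of risk and protective haplotype dosages
#'
#' Fits `status ~ dosage_risk + dosage_protective` with a binomial-family
#' GLM on individual-level data, testing both haplotype effects jointly.
#' Reports per-haplotype odds ratios (exponentiated coefficients) with Wald
#' 95% CIs and P-values. Complete separation is flagged and no estimate is
#' returned in that case.
#'
#' @param individuals data frame with `status` (1/0, `"case"`/`"control"`,
#'   or logical), `dosage_risk` and `dosage_protective` in 0/1/2.
#' @return List of class `joint_glm_result`: `table` (rows `risk` and
#'   `protective`: `or`, `ci_lo`, `ci_hi`, `p_value`), `separation`
#'   (logical) and the fitted `model`.
#' @export
joint_glm_test <- function(individuals) {
  d <- individuals
  if (!all(c("status", "dosage_risk", "dosage_protective") %in% names(d)))
    stop("input error: need status, dosage_risk, dosage_protective columns")
  y <- d$status
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "case")
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("input error: need at least 2 individuals per arm")
  if (!all(d$dosage_risk %in% 0:2 & d$dosage_protective %in% 0:2))
    stop("input error: dosages must be 0, 1 or 2")
  fit <- suppressWarnings(
    stats::glm(y ~ dosage_risk + dosage_protective, family = stats::binomial(),
               data = transform(d, y = y)))
  co <- summary(fit)$coefficients
  # fitted probabilities indistinguishable from 0/1, or exploding |beta|,
  # indicate (quasi-)separation: Wald inference is meaningless there
  eps <- 1e-8
  separation <- any(fit$fitted.values > 1 - eps) && any(fit$fitted.values < eps) &&
    max(abs(co[-1, "Estimate"])) > 10 ||
    any(abs(co[-1, "Estimate"]) > 10)
  if (separation) {
    return(structure(list(table = NULL, separation = TRUE, model = fit),
                     class = "joint_glm_result"))
  }
  rows <- co[c("dosage_risk", "dosage_protective"), , drop = FALSE]
  zq <- stats::qnorm(0.975)
  tab <- data.frame(
    haplotype = c("risk", "protective"),
    or = exp(rows[, "Estimate"]),
    ci_lo = exp(rows[, "Estimate"] - zq * rows[, "Std. Error"]),
    ci_hi = exp(rows[, "Estimate"] + zq * rows[, "Std. Error"]),
    p_value = rows[, "Pr(>|z|)"],
    row.names = NULL
  )
  structure(list(table = tab, separation = FALSE, model = fit),
            class = "joint_glm_result")
}

#' @export
print.joint_glm_result <- function(x, ...) {
  if (x$separation) {
    cat("Joint GLM: complete separation detected; no estimate\n")
  } else {
    cat("Joint binomial GLM of haplotype dosages:\n")
    print(x$table, digits = 4)
  }
  invisible(x)
}
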
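#' Configuration of a synthetic phased haplotype panel
#'
#' Describes a reference panel over a fine-mapped genomic interval with a
#' small number of major haplotypes on a high-LD background, the structure
#' assumed by tag-SNP haplotype mapping: a few exact-identity haplotype
#' groups above 5% frequency that jointly cover most chromosomes, with the
#' remainder being rare mutated or recombinant copies. The defaults mirror
#' a Finnish-type panel of 93 phased individuals (186 chromosomes) with
#' four major haplotypes summing to 77% of chromosomes, of which the third
#' (frequency 0.126) is the designated risk haplotype and the fourth
#' (0.091) the protective one.
#'
#' @param n_chromosomes even number of phased chromosomes; default 186.
#' @param n_sites number of common biallelic sites; default 39.
#' @param n_rare_sites number of additional rare sites carrying singleton
#'   or doubleton derived alleles (planted on rare chromosomes), feeding
#'   the rare-variant burden analysis; default 20.
#' @param major_hap_freqs frequencies of the major haplotypes, each >= 0.05.
#' @param rare_hap_mass total frequency of rare/recombinant chromosomes;
#'   `sum(major_hap_freqs) + rare_hap_mass` must not exceed 1.
#' @param region_length interval length in base pairs; default 9000.
#' @param risk_hap,protective_hap indices into `major_hap_freqs` of the
#'   haplotypes carrying disease effects.
#' @param seed integer seed; every generator is bit-reproducible under it.
#' @return A validated `panel_config` list.
#' @export
panel_config <- function(n_chromosomes = 186L, n_sites = 39L,
                         major_hap_freqs = c(0.358, 0.195, 0.126, 0.091),
                         rare_hap_mass = 1 - sum(major_hap_freqs),
                         region_length = 9000L,
                         risk_hap = 3L, protective_hap = 4L,
                         n_rare_sites = 20L,
                         seed = 1L) {
  if (n_chromosomes %% 2L != 0L || n_chromosomes <= 0L)
    stop("configuration error: n_chromosomes must be a positive even count")
  if (any(major_hap_freqs < 0.05))
    stop("configuration error: every major haplotype frequency must be >= 0.05")
  if (sum(major_hap_freqs) + rare_hap_mass > 1 + 1e-9)
    stop("configuration error: major frequencies plus rare mass exceed 1")
  k <- length(major_hap_freqs)
  if (risk_hap > k || protective_hap > k)
    stop("configuration error: risk/protective index outside major haplotypes")
  if (n_sites < 2L * k)
    stop("configuration error: need at least 2 sites per major haplotype")
  structure(
    list(n_chromosomes = as.integer(n_chromosomes), n_sites = as.integer(n_sites),
         major_hap_freqs = major_hap_freqs, rare_hap_mass = rare_hap_mass,
         region_length = as.integer(region_length),
         risk_hap = as.integer(risk_hap), protective_hap = as.integer(protective_hap),
         n_rare_sites = as.integer(n_rare_sites),
         seed = as.integer(seed)),
    class = "panel_config"
  )
}

#' Generate a synthetic phased haplotype panel
#'
#' Builds a panel in which each major haplotype is a distinct allele vector
#' carried identically by `round(freq * n_chromosomes)` chromosomes, and
#' the remaining chromosomes are rare copies: either point-mutated copies
#' of a major or recombinants splicing two majors at a random breakpoint.
#' Every major haplotype carries two planted private derived alleles; the
#' first is strictly private (never leaked onto rare chromosomes), so a
#' perfect tag SNP (`r^2 = 1`) is guaranteed to exist, while the second may
#' be carried partially by recombinants, giving the recombinant-detection
#' step something realistic to find. Allele 0 is the ancestral state at
#' every site.
#'
#' @param cfg a [panel_config()].
#' @return Object of class `haplotype_panel`: `genotypes` (0/1 matrix,
#'   chromosomes x sites), `sites` (data frame `id`, `pos`, `ancestral`),
#'   `truth` (generating major-haplotype label per chromosome, `NA` for
#'   rare), `risk_hap`/`protective_hap` (`"H<i>"` labels) and `config`.
#' @export
gen_haplotype_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  set.seed(cfg$seed)
  k <- length(cfg$major_hap_freqs)
  n <- cfg$n_chromosomes
  L <- cfg$n_sites + cfg$n_rare_sites
  counts <- round(cfg$major_hap_freqs * n)
  n_rare <- n - sum(counts)
  if (n_rare < 0)
    stop("configuration error: rounded major counts exceed n_chromosomes")

  pos <- sort(sample.int(cfg$region_length, L))
  site_ids <- sprintf("s%03d_%d", seq_len(L), pos)
  # site roles: per major j, two private common sites — one strictly
  # private (never copied onto rare chromosomes, so a perfect tag exists),
  # one "leaky" (recombinants may carry it, so partial tag carriage is
  # observable); a shared common background; and rare singleton/doubleton
  # sites confined to rare chromosomes
  common_idx <- sort(sample.int(L, cfg$n_sites))
  rare_idx <- setdiff(seq_len(L), common_idx)
  strict_private <- common_idx[seq_len(k)]
  leaky_private <- common_idx[k + seq_len(k)]
  background <- setdiff(common_idx, c(strict_private, leaky_private))

  repeat {
    majors <- matrix(0L, k, L)
    for (j in seq_len(k)) {
      majors[j, background] <- rbinom(length(background), 1L, runif(length(background), 0.2, 0.8))
      majors[j, strict_private[j]] <- 1L
      majors[j, leaky_private[j]] <- 1L
    }
    if (nrow(unique(majors)) == k) break  # regenerate on (unlikely) collision
  }

  rare <- matrix(0L, n_rare, L)
  if (n_rare > 0) {
    for (i in seq_len(n_rare)) {
      if (runif(1) < 0.4 && k >= 2) {
        # recombinant: splice two distinct majors at a breakpoint; may end
        # up carrying a leaky private allele without its partner tag
        jl <- sample.int(k, 2L)
        bp <- sample(seq_len(L - 1L), 1L)
        v <- c(majors[jl[1], seq_len(bp)], majors[jl[2], (bp + 1L):L])
      } else {
        # mutated copy of one major: background flips only, no private
        # alleles, so it is invisible to tag-based recombinant detection
        j <- sample.int(k, 1L)
        v <- majors[j, ]
        flip <- sample(background, sample(1:3, 1L))
        v[flip] <- 1L - v[flip]
        v[leaky_private] <- 0L
      }
      v[strict_private] <- 0L       # strict privacy: perfect tags survive
      rare[i, ] <- v
    }
    # rare derived alleles: singletons/doubletons on rare chromosomes
    for (s in rare_idx) {
      carriers <- sample.int(n_rare, min(n_rare, sample(1:2, 1L)))
      rare[carriers, s] <- 1L
    }
  }

  geno <- rbind(majors[rep(seq_len(k), counts), , drop = FALSE], rare)
  truth <- c(rep(paste0("M", seq_len(k)), counts), rep(NA_character_, n_rare))
  shuffle <- sample.int(n)
  geno <- geno[shuffle, , drop = FALSE]
  truth <- truth[shuffle]
  rownames(geno) <- sprintf("chr%03d", seq_len(n))
  colnames(geno) <- site_ids
  names(truth) <- rownames(geno)

  structure(
    list(genotypes = geno,
         sites = data.frame(id = site_ids, pos = pos,
                            ancestral = rep("0", L)),
         truth = truth,
         risk_hap = paste0("M", cfg$risk_hap),
         protective_hap = paste0("M", cfg$protective_hap),
         private_sites = data.frame(
           major = paste0("M", seq_len(k)),
           strict_id = site_ids[strict_private],
           leaky_id = site_ids[leaky_private]),
         config = cfg),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("Phased haplotype panel: %d chromosomes x %d sites over %d bp\n",
              nrow(x$genotypes), ncol(x$genotypes), x$config$region_length))
  tt <- table(x$truth, useNA = "ifany")
  cat("  generating groups:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# map generating major labels (M*) to the truth membership indicator
panel_group_indicator <- function(panel, label) {
  as.integer(!is.na(panel$truth) & panel$truth == label)
}

#' Configuration of a synthetic case-control cohort
#'
#' Disease model: individuals are pairs of panel chromosomes drawn with
#' replacement; case status follows a logistic model whose log-odds are
#' `logit(baseline) + d_risk log(OR_risk) + d_prot log(OR_prot)` in the
#' dosages of the risk and protective haplotypes. Defaults reproduce the
#' study conditions of the motivating design: 127 cases, 135 controls,
#' odds ratios 1.89 (risk) and 0.50 (protective), baseline prevalence
#' 5.5%.
#'
#' @param n_cases,n_controls required arm sizes (individuals); positive.
#' @param risk_hap_or,protective_hap_or per-copy odds ratios; positive.
#' @param baseline_prevalence probability of disease with zero dosages.
#' @param seed integer seed.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 127L, n_controls = 135L,
                          risk_hap_or = 1.89, protective_hap_or = 0.50,
                          baseline_prevalence = 0.055, seed = 1L) {
  if (n_cases <= 0L || n_controls <= 0L)
    stop("configuration error: cohort counts must be positive")
  if (risk_hap_or <= 0 || protective_hap_or <= 0)
    stop("configuration error: odds ratios must be positive")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop("configuration error: baseline prevalence must be inside (0, 1)")
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         risk_hap_or = risk_hap_or, protective_hap_or = protective_hap_or,
         baseline_prevalence = baseline_prevalence, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a case-control cohort from a haplotype panel
#'
#' Rejection-samples individuals (chromosome pairs drawn with replacement
#' from the panel) from the logistic disease model of [cohort_config()]
#' until the requested case and control counts are both reached, matching
#' a retrospective case-control design. Deterministic under the config
#' seed.
#'
#' @param panel a `haplotype_panel` with designated risk and protective
#'   haplotypes.
#' @param cfg a [cohort_config()].
#' @return Data frame of class `cohort`: `individual_id`, `chrom1`,
#'   `chrom2` (panel chromosome names), `hap1`, `hap2` (generating major
#'   labels or `NA`), `dosage_risk`, `dosage_protective`, `status`
#'   (`"case"`/`"control"`).
#' @export
gen_cohort <- function(panel, cfg) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n_chrom <- nrow(panel$genotypes)
  risk_ind <- panel_group_indicator(panel, panel$risk_hap)
  prot_ind <- panel_group_indicator(panel, panel$protective_hap)
  b0 <- stats::qlogis(cfg$baseline_prevalence)
  br <- log(cfg$risk_hap_or)
  bp <- log(cfg$protective_hap_or)

  cases <- controls <- vector("list", 0L)
  nc <- nt <- 0L
  batch <- max(1000L, 20L * (cfg$n_cases + cfg$n_controls))
  for (it in seq_len(10000L)) {
    i1 <- sample.int(n_chrom, batch, replace = TRUE)
    i2 <- sample.int(n_chrom, batch, replace = TRUE)
    dr <- risk_ind[i1] + risk_ind[i2]
    dp <- prot_ind[i1] + prot_ind[i2]
    pr <- stats::plogis(b0 + dr * br + dp * bp)
    y <- stats::rbinom(batch, 1L, pr)
    d <- data.frame(chrom1 = rownames(panel$genotypes)[i1],
                    chrom2 = rownames(panel$genotypes)[i2],
                    hap1 = unname(panel$truth[i1]), hap2 = unname(panel$truth[i2]),
                    dosage_risk = dr, dosage_protective = dp, status_bin = y)
    cases[[length(cases) + 1L]] <- d[d$status_bin == 1L, , drop = FALSE]
    controls[[length(controls) + 1L]] <- d[d$status_bin == 0L, , drop = FALSE]
    nc <- nc + sum(y)
    nt <- nt + sum(1L - y)
    if (nc >= cfg$n_cases && nt >= cfg$n_controls) break
    if (it == 10000L)
      stop("generation error: requested arm counts unreachable under the disease model")
  }
  cs <- do.call(rbind, cases)[seq_len(cfg$n_cases), , drop = FALSE]
  ct <- do.call(rbind, controls)[seq_len(cfg$n_controls), , drop = FALSE]
  out <- rbind(cs, ct)
  out$status <- ifelse(out$status_bin == 1L, "case", "control")
  out$status_bin <- NULL
  out$individual_id <- sprintf("ind%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out <- out[c("individual_id", "chrom1", "chrom2", "hap1", "hap2",
               "dosage_risk", "dosage_protective", "status")]
  class(out) <- c("cohort", "data.frame")
  out
}

#' Configuration of pooled allele-frequency estimation noise
#'
#' Pooled sequencing estimates each pool's allele frequency with error
#' beyond binomial sampling; that error is modelled as additive Gaussian
#' noise with per-arm variance `se` (the mean squared error observed
#' against genotyping), truncated to `[0, 1]` and then rounded to the
#' pool's singleton grid. Defaults are the variances 0.00081 (cases) and
#' 0.00032 (controls) in squared-frequency units.
#'
#' @param se_case,se_control non-negative estimation-error variances.
#' @param read_depth_per_allele mean reads per site per allele, used only
#'   to simulate coverage QC inputs; default 103.9.
#' @param seed integer seed.
#' @return A validated `pool_noise_config` list.
#' @export
pool_noise_config <- function(se_case = 0.00081, se_control = 0.00032,
                              read_depth_per_allele = 103.9, seed = 1L) {
  if (se_case < 0 || se_control < 0)
    stop("configuration error: noise variances must be non-negative")
  structure(
    list(se_case = se_case, se_control = se_control,
         read_depth_per_allele = read_depth_per_allele, seed = as.integer(seed)),
    class = "pool_noise_config"
  )
}

#' Default two-pools-per-arm split of a cohort
#'
#' Splits each arm into two sequencing pools with the uneven sizes typical
#' of a pooling design that separates previously-studied from new subjects
#' (roughly 76/24 within cases and 56/44 within controls; with the default
#' cohort of 127/135 individuals this yields pools of 192, 62, 150 and 120
#' alleles).
#'
#' @param cohort a `cohort` data frame.
#' @return Data frame `individual_id`, `pool_id` assigning every individual
#'   to one of `case_1`, `case_2`, `control_1`, `control_2`.
#' @export
default_pool_split <- function(cohort) {
  split_arm <- function(ids, frac, labels) {
    n1 <- round(frac * length(ids))
    data.frame(individual_id = ids,
               pool_id = rep(labels, c(n1, length(ids) - n1)))
  }
  rbind(
    split_arm(cohort$individual_id[cohort$status == "case"], 192 / 254,
              c("case_1", "case_2")),
    split_arm(cohort$individual_id[cohort$status == "control"], 150 / 270,
              c("control_1", "control_2"))
  )
}

#' Generate pooled allele-frequency estimates for a cohort
#'
#' For every panel site and every pool, the true pool frequency (mean
#' derived-allele dosage over the pool's chromosomes) receives additive
#' Gaussian noise with the arm's estimation-error variance, is truncated to
#' `[0, 1]` and rounded to the nearest multiple of one allele in the pool
#' ([round_allele_frequency()]).
#'
#' @param cohort a `cohort` data frame.
#' @param panel the `haplotype_panel` the cohort was drawn from.
#' @param noise a [pool_noise_config()].
#' @param pool_split data frame `individual_id`, `pool_id`; default
#'   [default_pool_split()]. Every pool must contain at least one
#'   individual and hold a single arm.
#' @return Data frame of class `pooled_af`: `variant_id`, `pos`, `pool_id`,
#'   `arm`, `n_alleles`, `af_true`, `af_est`.
#' @export
gen_pooled_af <- function(cohort, panel, noise, pool_split = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(panel, "haplotype_panel"),
            inherits(noise, "pool_noise_config"))
  if (is.null(pool_split)) pool_split <- default_pool_split(cohort)
  set.seed(noise$seed)
  geno <- panel$genotypes
  m <- merge(cohort, pool_split, by = "individual_id")
  if (nrow(m) != nrow(cohort))
    stop("configuration error: pool_split must cover every individual")
  rows <- list()
  for (pid in unique(pool_split$pool_id)) {
    members <- m[m$pool_id == pid, , drop = FALSE]
    if (nrow(members) == 0L)
      stop("configuration error: empty pool ", pid)
    arm <- unique(members$status)
    if (length(arm) != 1L)
      stop("configuration error: pool ", pid, " mixes case and control individuals")
    chroms <- c(members$chrom1, members$chrom2)
    n_alleles <- length(chroms)
    af_true <- colMeans(geno[chroms, , drop = FALSE])
    se <- if (arm == "case") noise$se_case else noise$se_control
    raw <- af_true + stats::rnorm(length(af_true), 0, sqrt(se))
    af_est <- round_allele_frequency(pmin(1, pmax(0, raw)), n_alleles)
    rows[[pid]] <- data.frame(
      variant_id = colnames(geno), pos = panel$sites$pos,
      pool_id = pid, arm = arm, n_alleles = n_alleles,
      af_true = unname(af_true), af_est = unname(af_est))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pooled_af", "data.frame")
  out
}

#' Aggregate per-pool frequency estimates to arm level
#'
#' Combines the pools of each arm by an allele-count-weighted mean, giving
#' the per-variant case/control frequency table consumed by the
#' association and burden modules.
#'
#' @param pafs a `pooled_af` data frame from [gen_pooled_af()].
#' @return Data frame: `variant_id`, `pos`, `af_case`, `af_control`,
#'   `n_case_alleles`, `n_control_alleles`, `af_true_case`,
#'   `af_true_control`.
#' @export
pool_af_by_arm <- function(pafs) {
  agg <- function(arm) {
    d <- pafs[pafs$arm == arm, , drop = FALSE]
    n_tot <- sum(tapply(d$n_alleles, d$pool_id, unique))
    est <- tapply(d$af_est * d$n_alleles, d$variant_id, sum) / n_tot
    tru <- tapply(d$af_true * d$n_alleles, d$variant_id, sum) / n_tot
    list(est = est, tru = tru, n = n_tot)
  }
  a <- agg("case"); b <- agg("control")
  ids <- unique(pafs$variant_id)
  pos <- pafs$pos[match(ids, pafs$variant_id)]
  data.frame(variant_id = ids, pos = pos,
             af_case = unname(a$est[ids]), af_control = unname(b$est[ids]),
             n_case_alleles = a$n, n_control_alleles = b$n,
             af_true_case = unname(a$tru[ids]), af_true_control = unname(b$tru[ids]))
}

#' Generate spike-in control quality scores
#'
#' Emits labelled variant-quality scores for positive controls (known
#' variants spiked at the singleton frequency) and negative controls
#' (known invariant sequence). With `separation > 0` the construction
#' guarantees the positive minimum exceeds the negative maximum by exactly
#' `separation` score units, so [calibrate_quality_cutoffs()] must recover
#' a perfectly discriminating cutoff; with `separation <= 0` the two
#' distributions overlap.
#'
#' @param n_pos,n_neg control counts (>= 1); defaults 13 and 50.
#' @param separation gap between the score distributions, in score units;
#'   default 10.
#' @param seed integer seed.
#' @param neg_mean,sd location and spread of the negative-control scores.
#' @return Data frame `label` (`"positive"`/`"negative"`), `score`.
#' @export
gen_spikein_scores <- function(n_pos = 13L, n_neg = 50L, separation = 10,
                               seed = 1L, neg_mean = 10, sd = 3) {
  if (n_pos < 1L || n_neg < 1L)
    stop("configuration error: control counts must be >= 1")
  set.seed(seed)
  neg <- stats::rnorm(n_neg, neg_mean, sd)
  pos <- stats::rnorm(n_pos, 0, sd)
  if (separation > 0) {
    pos <- pos - min(pos) + max(neg) + separation
  } else {
    pos <- pos + neg_mean + separation
  }
  data.frame(label = rep(c("positive", "negative"), c(n_pos, n_neg)),
             score = c(pos, neg))
}

#' Generate synthetic region and conservation annotations for a panel
#'
#' Partitions the panel interval into alternating candidate and flanking
#' regions (candidate regions covering roughly `candidate_fraction` of the
#' interval) and draws a per-site conservation P-value, with planted
#' private variants biased toward conservation so the conserved-site
#' burden stratum is non-trivially populated.
#'
#' @param panel a `haplotype_panel`.
#' @param candidate_fraction target fraction of the interval classed
#'   candidate; default 0.39.
#' @param n_regions number of candidate regions to tile; default 6.
#' @param seed integer seed.
#' @return List: `regions` (BED-style data frame `chrom`, `start`, `end`,
#'   `class`, 0-based half-open) and `site_annotation` (data frame
#'   `variant_id`, `pos`, `region_class`, `phylop_p`, `conserved`).
#' @export
gen_site_annotations <- function(panel, candidate_fraction = 0.39,
                                 n_regions = 6L, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  set.seed(seed)
  L <- panel$config$region_length
  block <- floor(L / n_regions)
  cand_len <- floor(block * candidate_fraction)
  starts <- (seq_len(n_regions) - 1L) * block
  regions <- rbind(
    data.frame(chrom = "chrSim", start = starts, end = starts + cand_len,
               class = "candidate"),
    data.frame(chrom = "chrSim", start = starts + cand_len,
               end = pmin(starts + block, L), class = "flanking")
  )
  regions <- regions[order(regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  pos <- panel$sites$pos
  in_cand <- vapply(pos, function(p)
    any(p > regions$start[regions$class == "candidate"] &
        p <= regions$end[regions$class == "candidate"]), logical(1))
  phylop_p <- stats::runif(length(pos))
  # planted private sites lean conserved (functional candidates)
  private <- seq_len(2L * length(panel$config$major_hap_freqs))
  phylop_p[private] <- stats::runif(length(private), 0, 0.1)
  list(
    regions = regions,
    site_annotation = data.frame(
      variant_id = panel$sites$id, pos = pos,
      region_class = ifelse(in_cand, "candidate", "flanking"),
      phylop_p = phylop_p,
      conserved = phylop_p < 0.05)
  )
}

#' Individual-level genotype table at selected SNPs
#'
#' Reads each cohort individual's dosage (0/1/2) of the derived allele at
#' the requested panel SNPs — the shape of a genotyping validation assay
#' run across all samples.
#'
#' @param cohort a `cohort` data frame.
#' @param panel the generating `haplotype_panel`.
#' @param snp_ids character vector of panel site ids.
#' @return Data frame: `individual_id`, `status`, then one 0/1/2 dosage
#'   column per SNP.
#' @export
gen_genotype_table <- function(cohort, panel, snp_ids) {
  if (!all(snp_ids %in% colnames(panel$genotypes)))
    stop("input error: unknown SNP id(s): ",
         paste(setdiff(snp_ids, colnames(panel$genotypes)), collapse = ", "))
  g1 <- panel$genotypes[cohort$chrom1, snp_ids, drop = FALSE]
  g2 <- panel$genotypes[cohort$chrom2, snp_ids, drop = FALSE]
  out <- data.frame(individual_id = cohort$individual_id,
                    status = cohort$status)
  dos <- g1 + g2
  colnames(dos) <- snp_ids
  cbind(out, as.data.frame(dos, row.names = seq_len(nrow(out))))
}
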
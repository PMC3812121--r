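test_that("panel configuration enforces its invariants", {
  expect_error(panel_config(n_chromosomes = 41L), "even")
  expect_error(panel_config(major_hap_freqs = c(0.5, 0.04)), ">= 0.05")
  expect_error(panel_config(major_hap_freqs = c(0.6, 0.3), rare_hap_mass = 0.2),
               "exceed 1")
  expect_error(panel_config(n_sites = 5L), "2 sites per major")
  expect_error(cohort_config(risk_hap_or = -1), "positive")
  expect_error(pool_noise_config(se_case = -1), "non-negative")
})

test_that("all generators are bit-reproducible under a fixed seed", {
  p1 <- gen_haplotype_panel(panel_config(seed = 81))
  p2 <- gen_haplotype_panel(panel_config(seed = 81))
  expect_identical(p1, p2)

  c1 <- gen_cohort(p1, cohort_config(seed = 82))
  c2 <- gen_cohort(p2, cohort_config(seed = 82))
  expect_identical(c1, c2)

  a1 <- gen_pooled_af(c1, p1, pool_noise_config(seed = 83))
  a2 <- gen_pooled_af(c2, p2, pool_noise_config(seed = 83))
  expect_identical(a1, a2)

  s1 <- gen_spikein_scores(seed = 84)
  s2 <- gen_spikein_scores(seed = 84)
  expect_identical(s1, s2)
})

test_that("cohorts hold diploid individuals with dosages summing over two chromosomes", {
  pan <- gen_haplotype_panel(panel_config(seed = 85))
  coh <- gen_cohort(pan, cohort_config(seed = 86))
  expect_equal(sum(coh$status == "case"), 127L)
  expect_equal(sum(coh$status == "control"), 135L)
  expect_true(all(coh$dosage_risk %in% 0:2 & coh$dosage_protective %in% 0:2))
  # dosages are consistent with the chromosome labels drawn
  d_check <- (coh$hap1 %in% pan$risk_hap) + (coh$hap2 %in% pan$risk_hap)
  expect_equal(coh$dosage_risk, d_check)
  # each individual contributes exactly two chromosomes
  expect_true(all(coh$chrom1 %in% rownames(pan$genotypes)))
  expect_true(all(coh$chrom2 %in% rownames(pan$genotypes)))
})

test_that("case:control haplotype odds approach the generating odds ratio", {
  pan <- gen_haplotype_panel(panel_config(seed = 87))
  # isolate the risk effect: protective OR at 1
  log_ors <- vapply(1:200, function(r) {
    coh <- gen_cohort(pan, cohort_config(risk_hap_or = 1.89,
                                         protective_hap_or = 1, seed = 8000 + r))
    n_case <- 2L * sum(coh$status == "case")
    n_ctrl <- 2L * sum(coh$status == "control")
    a <- sum(coh$dosage_risk[coh$status == "case"])
    c_ <- sum(coh$dosage_risk[coh$status == "control"])
    log((a / (n_case - a)) / (c_ / (n_ctrl - c_)))
  }, numeric(1))
  # per-replicate sd(log OR) ~ 0.28; 3 * 0.28 / sqrt(200) ~ 0.06, plus a
  # small non-collapsibility allowance at 5.5% baseline prevalence
  expect_lt(abs(mean(log_ors) - log(1.89)), 0.08)
})

test_that("with both odds ratios at 1, haplotype tests reject at the nominal rate", {
  pan <- gen_haplotype_panel(panel_config(seed = 88))
  rejected <- vapply(1:300, function(r) {
    coh <- gen_cohort(pan, cohort_config(risk_hap_or = 1, protective_hap_or = 1,
                                         n_cases = 60L, n_controls = 60L,
                                         seed = 9000 + r))
    ft <- haplotype_fisher_test(sum(coh$dosage_risk[coh$status == "case"]) / 120,
                                120,
                                sum(coh$dosage_risk[coh$status == "control"]) / 120,
                                120)
    ft$p_fisher < 0.05
  }, logical(1))
  # nominal 0.05 plus 3 Monte-Carlo standard errors over 300 replicates
  expect_lte(mean(rejected), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("pool frequency estimates sit on the singleton grid of their pool", {
  pan <- gen_haplotype_panel(panel_config(seed = 90))
  coh <- gen_cohort(pan, cohort_config(seed = 91))
  pafs <- gen_pooled_af(coh, pan, pool_noise_config(seed = 92))
  expect_true(all(abs(pafs$af_est * pafs$n_alleles -
                      round(pafs$af_est * pafs$n_alleles)) < 1e-9))
  # two pools per arm, allele totals matching the diploid arm sizes
  pool_sizes <- tapply(pafs$n_alleles, pafs$pool_id, unique)
  expect_equal(sort(as.integer(pool_sizes)), c(62L, 120L, 150L, 192L))

  # zero-noise limit: estimates equal the true pool frequencies exactly
  exact <- gen_pooled_af(coh, pan,
                         pool_noise_config(se_case = 0, se_control = 0, seed = 93))
  expect_equal(exact$af_est, exact$af_true)
})

test_that("pooled estimates reject malformed pool splits", {
  pan <- gen_haplotype_panel(panel_config(seed = 94))
  coh <- gen_cohort(pan, cohort_config(n_cases = 10L, n_controls = 10L, seed = 95))
  bad <- data.frame(individual_id = coh$individual_id,
                    pool_id = "everyone")            # mixes arms
  expect_error(gen_pooled_af(coh, pan, pool_noise_config(), bad), "mixes")
  partial <- data.frame(individual_id = coh$individual_id[1:5], pool_id = "p1")
  expect_error(gen_pooled_af(coh, pan, pool_noise_config(), partial), "cover")
})

test_that("spike-in construction honours the separation parameter", {
  sep <- gen_spikein_scores(separation = 6, seed = 96)
  pos <- sep$score[sep$label == "positive"]
  neg <- sep$score[sep$label == "negative"]
  expect_equal(min(pos) - max(neg), 6)

  ovl <- gen_spikein_scores(separation = -5, seed = 97)
  expect_lt(min(ovl$score[ovl$label == "positive"]),
            max(ovl$score[ovl$label == "negative"]))
  expect_error(gen_spikein_scores(n_pos = 0), ">= 1")
})

test_that("genotype tables read true dosages off the panel", {
  pan <- gen_haplotype_panel(panel_config(seed = 98))
  coh <- gen_cohort(pan, cohort_config(n_cases = 20L, n_controls = 20L, seed = 99))
  tag <- pan$private_sites$strict_id[pan$private_sites$major == pan$risk_hap]
  g <- gen_genotype_table(coh, pan, tag)
  expect_equal(g[[tag]], coh$dosage_risk)
  expect_error(gen_genotype_table(coh, pan, "nope"), "unknown SNP")
})
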
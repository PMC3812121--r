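test_that("LD statistics match hand computations on anchor tables", {
  perfect <- ld_stats(5, 0, 0, 5)
  expect_equal(perfect$D_prime, 1)
  expect_equal(perfect$r2, 1)

  mid <- ld_stats(4, 1, 1, 4)
  expect_equal(mid$D, 0.15)
  expect_equal(mid$D_prime, 0.6)
  expect_equal(mid$r2, 0.36)

  indep <- ld_stats(4, 4, 4, 4)       # p_AB = p_A p_B exactly
  expect_equal(indep$D, 0)
  expect_equal(indep$r2, 0)

  expect_error(ld_stats(5, 5, 0, 0), "monomorphic")
  # matrix input equals positional input
  m <- matrix(c(4, 1, 1, 4), 2, 2, byrow = TRUE)
  expect_equal(ld_stats(m)$r2, mid$r2)
})

test_that("LD matches a brute-force gamete-enumeration oracle on many tables", {
  set.seed(51)
  tried <- 0L
  while (tried < 200L) {
    n <- sample(4:50, 1)
    cts <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    pA <- (cts[1] + cts[2]) / n; pB <- (cts[1] + cts[3]) / n
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) next
    got <- ld_stats(cts[1], cts[2], cts[3], cts[4])
    ora <- ld_oracle(cts[1], cts[2], cts[3], cts[4])
    expect_equal(got$D, ora$D, tolerance = 1e-12)
    expect_equal(got$D_prime, ora$D_prime, tolerance = 1e-12)
    expect_equal(got$r2, ora$r2, tolerance = 1e-10)
    # a missing gamete class forces D' = 1; r2 <= D' throughout
    if (any(cts == 0)) expect_equal(got$D_prime, 1)
    expect_lte(got$r2, got$D_prime + 1e-12)
    tried <- tried + 1L
  }
})

test_that("chromosomes cluster into exact-identity major haplotypes", {
  # 20 + 12 + 6 identical chromosomes and 2 singletons
  h <- rbind(matrix(rep(c(1, 0, 0, 1, 1), 20), 20, byrow = TRUE),
             matrix(rep(c(0, 1, 0, 1, 0), 12), 12, byrow = TRUE),
             matrix(rep(c(0, 0, 1, 0, 1), 6), 6, byrow = TRUE),
             c(1, 1, 1, 1, 1), c(0, 0, 0, 0, 0))
  cl <- cluster_major_haplotypes(make_panel(h))
  expect_equal(cl$groups$n, c(20L, 12L, 6L))
  expect_equal(cl$groups$freq, c(0.50, 0.30, 0.15))
  expect_equal(cl$coverage, 0.95)
  expect_equal(sum(is.na(cl$membership)), 2L)

  # degenerate: all chromosomes identical
  one <- suppressWarnings(cluster_major_haplotypes(make_panel(matrix(1, 8, 3))))
  expect_equal(one$groups$freq, 1)

  # a group at exactly the cutoff frequency is retained as major
  m <- rbind(matrix(rep(c(1, 0), 19), 19, byrow = TRUE), c(0, 1))
  cl2 <- cluster_major_haplotypes(make_panel(m), freq_cutoff = 0.05)
  expect_true(0.05 %in% cl2$groups$freq)

  expect_error(cluster_major_haplotypes(make_panel(h), sites = "nope"),
               "unknown site")
})

test_that("generated panels respect configured group sizes and coverage", {
  cfg <- panel_config(n_chromosomes = 40L, n_sites = 12L,
                      major_hap_freqs = c(0.5, 0.3, 0.15),
                      risk_hap = 2L, protective_hap = 3L,
                      n_rare_sites = 0L, seed = 61)
  pan <- gen_haplotype_panel(cfg)
  expect_equal(sort(as.integer(table(pan$truth)), decreasing = TRUE), c(20L, 12L, 6L))

  # default-scale panel: major haplotypes cover 77% of chromosomes up to
  # one chromosome of rounding
  pan186 <- gen_haplotype_panel(panel_config(seed = 62))
  cl <- cluster_major_haplotypes(pan186)
  expect_equal(cl$coverage, 0.77, tolerance = 1 / 186)
  expect_equal(nrow(cl$groups), 4L)

  # determinism: same config, same seed, identical panel
  expect_identical(gen_haplotype_panel(panel_config(seed = 62)), pan186)
})

test_that("tag selection keeps perfect proxies and rejects diluted ones", {
  # 20 chromosomes; site 1 carried by exactly the 4-chromosome group,
  # site 2 additionally by one outside chromosome (r2 = 0.75)
  g <- matrix(0L, 20, 2, dimnames = list(NULL, c("perfect", "diluted")))
  g[1:4, ] <- 1L
  g[5, "diluted"] <- 1L
  pan <- make_panel(g)
  cl <- cluster_major_haplotypes(pan)
  hap <- cl$groups$hap_id[cl$groups$n == 4L]
  ts <- select_tag_snps(pan, cl, hap)
  expect_equal(ts$tags$snp_id, "perfect")
  expect_equal(ts$tags$r2, 1)
  expect_equal(ts$tags$tag_allele, 1L)
  expect_false(ts$flagged)
  # verify the rejected site's r2 is the hand-computed 0.75
  member <- as.integer(!is.na(cl$membership) & cl$membership == hap)
  expect_equal(poolfinemap:::ld_from_vectors(g[, "diluted"], member)$r2, 0.75)

  # negatively associated allele: never a tag
  g2 <- cbind(g, negassoc = c(rep(0L, 4), rep(1L, 8), rep(0L, 8)))
  pan2 <- make_panel(g2)
  cl2 <- cluster_major_haplotypes(pan2)
  hap2 <- cl2$groups$hap_id[cl2$groups$n == 4L]
  ts2 <- select_tag_snps(pan2, cl2, hap2)
  expect_false("negassoc" %in% ts2$tags$snp_id)

  expect_error(select_tag_snps(pan, cl, "H99"), "unknown haplotype")
})

test_that("planted private alleles give every generated major a perfect tag", {
  pan <- gen_haplotype_panel(panel_config(seed = 63))
  cl <- cluster_major_haplotypes(pan)
  for (h in cl$groups$hap_id) {
    ts <- select_tag_snps(pan, cl, h)
    expect_false(ts$flagged)
    expect_gte(max(ts$tags$r2), 1 - 1e-12)
  }
})

test_that("haplotype frequency is the mean of tag-oriented pool frequencies", {
  ts <- structure(list(hap_id = "H1", flagged = FALSE,
                       tags = data.frame(snp_id = c("a", "b", "c"),
                                         r2 = 1, tag_allele = 1L)),
                  class = "tag_set")
  est <- estimate_haplotype_frequencies(ts, c(a = 0.12, b = 0.14, c = 0.13))
  expect_equal(est$freq, 0.13)
  expect_equal(est$n_tags, 3L)
  expect_gt(est$spread, 0)

  single <- ts; single$tags <- single$tags[1, ]
  one <- estimate_haplotype_frequencies(single, c(a = 0.2))
  expect_equal(one$freq, 0.2)
  expect_true(is.na(one$spread))

  # a 0-oriented tag contributes 1 - af
  flip <- ts; flip$tags$tag_allele <- c(1L, 0L, 1L)
  est2 <- estimate_haplotype_frequencies(flip, c(a = 0.12, b = 0.86, c = 0.13))
  expect_equal(est2$freq, 0.13)

  empty <- structure(list(hap_id = "H9", flagged = TRUE, tags = NULL),
                     class = "tag_set")
  expect_error(estimate_haplotype_frequencies(empty, c(a = 1)), "empty tag set")
})

test_that("tag-averaged frequencies are exact for perfect tags without noise", {
  pan <- gen_haplotype_panel(panel_config(seed = 64))
  coh <- gen_cohort(pan, cohort_config(seed = 65))
  pafs <- gen_pooled_af(coh, pan, pool_noise_config(se_case = 0, se_control = 0,
                                                    seed = 66))
  arm <- pool_af_by_arm(pafs)
  af_case <- stats::setNames(arm$af_case, arm$variant_id)
  cl <- cluster_major_haplotypes(pan)
  # strict-private tag: its pool frequency IS the haplotype frequency
  for (h in cl$groups$hap_id) {
    ts <- select_tag_snps(pan, cl, h)
    perfect <- ts$tags[ts$tags$r2 > 1 - 1e-12, , drop = FALSE]
    ts$tags <- perfect
    est <- estimate_haplotype_frequencies(ts, af_case)
    members <- names(cl$membership)[!is.na(cl$membership) & cl$membership == h]
    truth <- mean(c(coh$chrom1[coh$status == "case"],
                    coh$chrom2[coh$status == "case"]) %in% members)
    expect_equal(est$freq, truth, tolerance = 1e-12)
  }
})

test_that("haplotype Fisher test reconstructs counts and the cross-product OR", {
  r <- haplotype_fisher_test(38 / 254, 254, 22 / 270, 270)
  expect_equal(r$counts["hap", "case"], 38)
  expect_equal(r$odds_ratio, (38 * 248) / (216 * 22))
  expect_equal(round(r$odds_ratio, 2), 1.98)
  expect_true(r$ci95[1] < r$odds_ratio && r$odds_ratio < r$ci95[2])
  # exact P against fisher.test on the explicit table (independent route
  # through the same contingency table built by hand)
  expect_equal(r$p_fisher,
               stats::fisher.test(matrix(c(38, 216, 22, 248), 2))$p.value)

  null <- haplotype_fisher_test(0.2, 100, 0.2, 100)
  expect_equal(null$odds_ratio, 1)
  expect_equal(null$p_fisher, 1)

  zero <- haplotype_fisher_test(0, 100, 0, 100)
  expect_equal(zero$p_fisher, 1)
  expect_false(zero$or_defined)
})

test_that("conditional test removes the excluded haplotype from both denominators", {
  cc <- c(H1 = 38, H2 = 10, other = 206)
  ct <- c(H1 = 22, H2 = 40, other = 208)
  r <- conditional_independence_test(cc, ct, "H1", "H2")
  expect_equal(r$odds_ratio, (38 * 208) / (206 * 22))
  expect_equal(round(r$odds_ratio, 3), 1.744)

  # excluding an absent haplotype leaves the test unchanged
  cc0 <- c(H1 = 38, H2 = 0, other = 216)
  ct0 <- c(H1 = 22, H2 = 0, other = 248)
  un <- haplotype_fisher_test(38 / 254, 254, 22 / 270, 270)
  r0 <- conditional_independence_test(cc0, ct0, "H1", "H2")
  expect_equal(r0$odds_ratio, un$odds_ratio)
  expect_equal(r0$p_value, un$p_fisher)

  # equal post-exclusion frequencies: OR = 1
  req <- conditional_independence_test(c(H1 = 20, H2 = 10, other = 80),
                                       c(H1 = 20, H2 = 30, other = 80),
                                       "H1", "H2")
  expect_equal(req$odds_ratio, 1)

  expect_error(conditional_independence_test(cc, ct, "H1", "H1"), "differ")
})

test_that("recombinants are individuals with discordant dosages within a tag set", {
  g <- data.frame(
    individual_id = c("ref", "carrier", "recomb_risk", "recomb_prot"),
    status = c("control", "case", "case", "control"),
    r1 = c(0, 1, 1, 0), r2 = c(0, 1, 1, 0), r3 = c(0, 1, 0, 0),
    p1 = c(0, 0, 0, 2), p2 = c(0, 0, 0, 1))
  rec <- detect_recombinants(g, c("r1", "r2", "r3"), c("p1", "p2"))
  expect_setequal(as.character(rec), c("recomb_risk", "recomb_prot"))
  detail <- attr(rec, "detail")
  expect_true(detail$recombinant_risk[detail$individual_id == "recomb_risk"])
  expect_false(detail$recombinant_risk[detail$individual_id == "carrier"])
  expect_error(detect_recombinants(g, c("r1", "zz"), "p1"), "missing tag")
})

test_that("the joint GLM is null on arm-balanced dosages and flags separation", {
  # identical dosage distributions in both arms: exact symmetry forces
  # both coefficients to zero
  base <- expand.grid(dosage_risk = 0:2, dosage_protective = 0:1)
  d <- rbind(transform(base, status = "case"), transform(base, status = "control"))
  r <- joint_glm_test(d)
  expect_false(r$separation)
  expect_equal(r$table$or, c(1, 1), tolerance = 1e-8)
  expect_equal(r$table$p_value, c(1, 1), tolerance = 1e-6)

  # complete separation: risk dosage perfectly predicts status
  sep <- data.frame(status = rep(c("case", "control"), each = 6),
                    dosage_risk = rep(c(2, 0), each = 6),
                    dosage_protective = rep(0:1, 6))
  s <- joint_glm_test(sep)
  expect_true(s$separation)
  expect_null(s$table)

  expect_error(joint_glm_test(data.frame(status = "case", dosage_risk = 0,
                                         dosage_protective = 0)),
               "per arm")
})

test_that("GLM estimates agree with an independent likelihood grid search", {
  d <- data.frame(
    status = c(1, 0, 1, 0, 1, 0, 1, 0),
    dosage_risk = c(1, 1, 0, 0, 0, 0, 2, 0),
    dosage_protective = c(0, 0, 1, 1, 0, 0, 0, 2))
  fit <- joint_glm_test(d)
  expect_false(fit$separation)
  beta_hat <- log(fit$table$or)
  beta_grid <- glm_grid_oracle(d$status, d$dosage_risk, d$dosage_protective)
  expect_equal(beta_hat, beta_grid[2:3], tolerance = 1e-4)
})
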
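test_that("candidate-region selection applies length and cluster rules", {
  e <- data.frame(chrom = "chr2",
                  start = c(100, 1000, 1130, 2000),
                  end = c(160, 1030, 1160, 2040))
  # 60 bp isolated: length rule; two 30 bp elements 100 bp apart: cluster
  # span 60 > 50; 40 bp isolated 250+ bp from neighbours: rejected
  sel <- select_candidate_regions(e)
  expect_setequal(sel$start, c(100, 1000, 1130))

  # exactly 50 bp is NOT selected (strict), alone or as a cluster span
  e50 <- data.frame(chrom = "chr2", start = c(0, 500, 530), end = c(50, 525, 555))
  expect_equal(nrow(select_candidate_regions(e50)), 0L)

  expect_error(select_candidate_regions(
    data.frame(chrom = "chr2", start = c(100, 10), end = c(160, 60))), "sorted")
})

test_that("region selection is idempotent and order-invariant after sorting", {
  set.seed(71)
  starts <- sort(sample.int(100000, 30))
  e <- data.frame(chrom = "chr2", start = starts,
                  end = starts + sample(10:120, 30, replace = TRUE))
  e <- e[c(TRUE, e$start[-1] >= e$end[-nrow(e)]), , drop = FALSE]  # drop overlaps
  sel1 <- select_candidate_regions(e)
  sel2 <- select_candidate_regions(sel1[c("chrom", "start", "end")])
  expect_equal(sel2$start, sel1$start)
  # shuffling then re-sorting changes nothing
  shuffled <- e[sample(nrow(e)), , drop = FALSE]
  shuffled <- shuffled[order(shuffled$start), , drop = FALSE]
  expect_equal(select_candidate_regions(shuffled)$start, sel1$start)
})

test_that("conserved-site flags use a strict P cutoff and count missing scores", {
  f <- flag_conserved_sites(c(0.01, 0.05, NA, 0.2))
  expect_equal(f$conserved, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(f$missing, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(f$fraction_missing, 0.25)

  all_missing <- flag_conserved_sites(c(NA_real_, NA_real_))
  expect_equal(sum(all_missing$conserved), 0L)
  expect_equal(all_missing$fraction_missing, 1)

  expect_error(flag_conserved_sites(1.2), "\\[0, 1\\]")
})

toy_pwm <- function() {
  # pos 1 prefers A strongly; pos 2 is all-C
  m <- matrix(c(2, 0.5, 0.5, 0,
                0, 3, 0, 0), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm("TOY", m, source_tf = "TOYTF")
}

test_that("PWM binding delta scores max windows on both strands", {
  d <- pwm_binding_delta(toy_pwm(), "AC", "GC")
  expect_equal(d$score_ancestral, 5)
  expect_equal(d$score_derived, 3.5)
  expect_equal(d$percent_change, 30)
  expect_false(d$excluded)

  same <- pwm_binding_delta(toy_pwm(), "ACAC", "ACAC")
  expect_equal(same$percent_change, 0)
  expect_true(same$excluded)
  expect_equal(same$exclusion_reason, "equivalent_score")

  expect_error(pwm_binding_delta(toy_pwm(), "A", "G"), "shorter than motif")
  expect_error(pwm_binding_delta(toy_pwm(), "AC", "ACC"), "equal length")
})

test_that("motifs hitting the interval more than 20 times are excluded as non-specific", {
  # degenerate 2-bp motif: any base at pos 1, G-preferring pos 2; an
  # AG-repeat interval produces a predicted hit at every repeat unit
  m <- matrix(c(1, 1, 1, 1,
                1, 1, 3, 1), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- pwm("DEGEN", m)
  anc <- paste(rep("AG", 25), collapse = "")
  der <- sub("AG$", "AC", anc)
  d <- pwm_binding_delta(p, anc, der)
  expect_gt(d$n_hits, 20)
  expect_true(d$excluded)
  expect_equal(d$exclusion_reason, "non_specific")
})

test_that("PWM scanning is strand-symmetric", {
  set.seed(72)
  m <- matrix(runif(20), nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- pwm("RAND", m)
  s1 <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  s2 <- sub("A", "G", s1)
  fwd <- pwm_binding_delta(p, s1, s2)
  rev_ <- pwm_binding_delta(p, poolfinemap:::revcomp(s1), poolfinemap:::revcomp(s2))
  expect_equal(rev_$score_ancestral, fwd$score_ancestral)
  expect_equal(rev_$score_derived, fwd$score_derived)
  expect_equal(rev_$n_hits, fwd$n_hits)
})

test_that("regulatory overlap respects the half-open BED convention", {
  v <- data.frame(chrom = "chr2", pos = c(91, 100, 110, 90, 500))
  reg <- data.frame(chrom = "chr2", start = 90, end = 110)
  expect_equal(regulatory_overlap(v, reg), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # empty regulatory track: nothing flagged
  expect_equal(regulatory_overlap(v, reg[0, ]), rep(FALSE, 5))
})

test_that("interval overlap agrees with a per-base membership oracle", {
  set.seed(73)
  for (i in 1:10) {
    v <- data.frame(chrom = sample(c("c1", "c2"), 40, replace = TRUE),
                    pos = sample.int(500, 40, replace = TRUE))
    starts <- sort(sample.int(480, 8))
    reg <- data.frame(chrom = sample(c("c1", "c2"), 8, replace = TRUE),
                      start = starts, end = starts + sample(5:40, 8, replace = TRUE))
    got <- regulatory_overlap(v, reg)
    oracle <- vapply(seq_len(nrow(v)), function(j) {
      any(vapply(seq_len(nrow(reg)), function(k) {
        reg$chrom[k] == v$chrom[j] &&
          v$pos[j] %in% (reg$start[k] + 1):reg$end[k]
      }, logical(1)))
    }, logical(1))
    expect_equal(got, oracle)
  }
})

test_that("haplotype-private variants require strictly exclusive carriage", {
  # 10 chromosomes: two major groups (5+4) and one unassigned singleton
  g <- matrix(0L, 10, 4,
              dimnames = list(NULL, c("grpA", "grpB", "shared", "leaked")))
  g[1:5, "grpA"] <- 1L
  g[6:9, "grpB"] <- 1L
  g[1:9, "shared"] <- 1L          # carried by both majors
  g[c(1:5, 10), "leaked"] <- 1L   # major A plus the rare chromosome
  pan <- make_panel(g)
  cl <- cluster_major_haplotypes(pan, freq_cutoff = 0.4)
  expect_equal(nrow(cl$groups), 2L)
  priv <- exclusive_to_haplotype(pan, cl)
  expect_setequal(priv$variant_id, c("grpA", "grpB"))
  expect_false("shared" %in% priv$variant_id)
  expect_false("leaked" %in% priv$variant_id)
})
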
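#' Pipeline configuration
#'
#' Collects the input file paths and stage parameters of the end-to-end
#' fine-mapping run. All stage parameters default to the documented values
#' used throughout the package. Paths are validated when the pipeline runs.
#'
#' @param panel_vcf phased reference panel (VCF, GT `a|b`).
#' @param pool_tsv per-pool allele-frequency estimates (TSV from
#'   [gen_pooled_af()] / the `simulate` stage).
#' @param genotype_tsv individual-level tag-SNP dosage table (TSV).
#' @param regions_bed candidate/flanking region track (BED, 4th column
#'   `candidate`/`flanking`).
#' @param conservation_tsv per-site conservation table (`variant_id`,
#'   `phylop_p`).
#' @param spikein_tsv spike-in control scores (`label`, `score`).
#' @param pwm_file optional motif file ([read_pwm()] format); `NULL` skips
#'   binding-delta annotation.
#' @param maf_cutoff_common common-variant MAF bound for the scan.
#' @param maf_cutoff_rare rare-variant MAF bound for collapsing.
#' @param r2_cutoff tag-SNP selection bound.
#' @param freq_cutoff major-haplotype frequency boundary.
#' @param coverage_threshold coverage QC bound (reads per site per allele).
#' @param conservation_alpha conserved-site P bound.
#' @param exclude_recombinants drop recombinant individuals before the
#'   joint GLM; default `TRUE`.
#' @param seed root seed; all stage seeds derive from it.
#' @param out_dir output directory for stage TSVs and the JSON report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(panel_vcf, pool_tsv, genotype_tsv, regions_bed,
                            conservation_tsv, spikein_tsv, pwm_file = NULL,
                            maf_cutoff_common = 0.05, maf_cutoff_rare = 0.01,
                            r2_cutoff = 0.9, freq_cutoff = 0.05,
                            coverage_threshold = 30, conservation_alpha = 0.05,
                            exclude_recombinants = TRUE,
                            seed = 1L, out_dir = tempfile("finemap_run_")) {
  structure(
    list(panel_vcf = panel_vcf, pool_tsv = pool_tsv,
         genotype_tsv = genotype_tsv, regions_bed = regions_bed,
         conservation_tsv = conservation_tsv, spikein_tsv = spikein_tsv,
         pwm_file = pwm_file,
         maf_cutoff_common = maf_cutoff_common,
         maf_cutoff_rare = maf_cutoff_rare,
         r2_cutoff = r2_cutoff, freq_cutoff = freq_cutoff,
         coverage_threshold = coverage_threshold,
         conservation_alpha = conservation_alpha,
         exclude_recombinants = exclude_recombinants,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' The YAML file holds one mapping with the argument names of
#' [pipeline_config()]; relative input paths are resolved against the YAML
#' file's directory.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("panel_vcf", "pool_tsv", "genotype_tsv", "regions_bed",
              "conservation_tsv", "spikein_tsv", "pwm_file")) {
    if (!is.null(y[[f]]) && !grepl("^/", y[[f]]))
      y[[f]] <- file.path(base, y[[f]])
  }
  do.call(pipeline_config, y)
}

#' Simulate a complete set of pipeline input files
#'
#' Runs the synthetic-data generators under a single root seed and writes
#' every file the pipeline consumes: the phased panel VCF, the per-pool
#' allele-frequency TSV, the individual genotype TSV at the tag SNPs of
#' the risk and protective haplotypes, the candidate/flanking BED track,
#' the per-site conservation table, the spike-in score table, a toy motif
#' file with ancestral/derived sequences around the risk haplotype's
#' private variant, and a YAML pipeline config pointing at all of them.
#'
#' @param dir output directory (created if needed).
#' @param seed root seed; generator seeds derive deterministically from it.
#' @param panel_cfg,cohort_cfg,noise_cfg optional config overrides (seeds
#'   inside them are replaced by derived seeds).
#' @return Path of the written YAML config, invisibly; all file paths are
#'   attached as the `files` attribute.
#' @export
simulate_fine_mapping_inputs <- function(dir, seed = 1L,
                                         panel_cfg = NULL, cohort_cfg = NULL,
                                         noise_cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  if (is.null(panel_cfg)) panel_cfg <- panel_config(seed = seed)
  else panel_cfg$seed <- seed
  if (is.null(cohort_cfg)) cohort_cfg <- cohort_config(seed = seed + 1L)
  else cohort_cfg$seed <- seed + 1L
  if (is.null(noise_cfg)) noise_cfg <- pool_noise_config(seed = seed + 2L)
  else noise_cfg$seed <- seed + 2L

  panel <- gen_haplotype_panel(panel_cfg)
  cohort <- gen_cohort(panel, cohort_cfg)
  pafs <- gen_pooled_af(cohort, panel, noise_cfg)
  spikes <- gen_spikein_scores(seed = seed + 3L)
  ann <- gen_site_annotations(panel, seed = seed + 4L)

  # tag SNPs for genotyping validation: the two private sites of the risk
  # and of the protective haplotype
  site_ids <- colnames(panel$genotypes)
  ps <- panel$private_sites
  risk_tags <- unlist(ps[ps$major == panel$risk_hap, c("strict_id", "leaky_id")])
  prot_tags <- unlist(ps[ps$major == panel$protective_hap, c("strict_id", "leaky_id")])
  genos <- gen_genotype_table(cohort, panel, c(risk_tags, prot_tags))

  # toy motif disrupted by the risk haplotype's strict-private variant
  mat <- matrix(c(2, 0.2, 0.2, 0.2,
                  0.2, 2, 0.2, 0.2,
                  0.2, 0.2, 2, 0.2,
                  2, 0.2, 0.2, 0.2), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  motif <- pwm("SIM_MOTIF", mat, source_tf = "SIMTF")

  files <- list(
    panel_vcf = file.path(dir, "panel.vcf"),
    pool_tsv = file.path(dir, "pool_af.tsv"),
    genotype_tsv = file.path(dir, "genotypes.tsv"),
    regions_bed = file.path(dir, "regions.bed"),
    conservation_tsv = file.path(dir, "conservation.tsv"),
    spikein_tsv = file.path(dir, "spikein_scores.tsv"),
    pwm_file = file.path(dir, "motifs.tsv"),
    cohort_tsv = file.path(dir, "cohort.tsv"),
    coverage_tsv = file.path(dir, "coverage.tsv")
  )
  write_panel_vcf(panel, files$panel_vcf)
  write_tsv_table(pafs, files$pool_tsv)
  write_tsv_table(genos, files$genotype_tsv)
  write_bed(ann$regions, files$regions_bed)
  write_tsv_table(ann$site_annotation, files$conservation_tsv)
  write_tsv_table(spikes, files$spikein_tsv)
  write_pwm(motif, files$pwm_file)
  write_tsv_table(cohort, files$cohort_tsv)
  set.seed(seed + 5L)
  cov <- data.frame(
    pool_id = rep(unique(pafs$pool_id), each = length(site_ids)),
    variant_id = site_ids,
    coverage = round(stats::rgamma(length(site_ids) * length(unique(pafs$pool_id)),
                                   shape = 20,
                                   rate = 20 / noise_cfg$read_depth_per_allele), 1))
  write_tsv_table(cov, files$coverage_tsv)

  cfg_path <- file.path(dir, "pipeline.yaml")
  yaml::write_yaml(list(
    panel_vcf = basename(files$panel_vcf),
    pool_tsv = basename(files$pool_tsv),
    genotype_tsv = basename(files$genotype_tsv),
    regions_bed = basename(files$regions_bed),
    conservation_tsv = basename(files$conservation_tsv),
    spikein_tsv = basename(files$spikein_tsv),
    pwm_file = basename(files$pwm_file),
    seed = seed
  ), cfg_path)
  attr(cfg_path, "files") <- files
  invisible(cfg_path)
}

#' Run the fine-mapping pipeline end to end
#'
#' Executes the stages in the order calibration, common-variant scan,
#' rare-variant burden, haplotype mapping, annotation, from the input
#' files of a [pipeline_config()]; writes per-stage TSV outputs and a
#' consolidated JSON report to `cfg$out_dir`. Identical config and seed
#' give a byte-identical report. Any stage failure aborts with an error
#' labelled by stage; inputs are validated up front so a bad path produces
#' a configuration error before any output is written.
#'
#' @param cfg a `pipeline_config` (or path to a YAML accepted by
#'   [read_pipeline_config()]).
#' @return The report, invisibly (a named list; also written as
#'   `report.json`).
#' @export
run_fine_mapping <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  paths <- cfg[c("panel_vcf", "pool_tsv", "genotype_tsv", "regions_bed",
                 "conservation_tsv", "spikein_tsv")]
  missing <- unlist(paths)[!file.exists(unlist(paths))]
  if (length(missing))
    stop("configuration error: missing input file(s): ",
         paste(missing, collapse = ", "))
  if (!is.null(cfg$pwm_file) && !file.exists(cfg$pwm_file))
    stop("configuration error: missing input file(s): ", cfg$pwm_file)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  # ---- inputs
  panel <- stage("load", read_panel_vcf(cfg$panel_vcf))
  pafs <- stage("load", read_tsv_table(cfg$pool_tsv))
  genos <- stage("load", read_tsv_table(cfg$genotype_tsv))
  regions <- stage("load", read_bed(cfg$regions_bed))
  cons <- stage("load", read_tsv_table(cfg$conservation_tsv))
  spikes <- stage("load", read_tsv_table(cfg$spikein_tsv))

  # ---- calibration
  calib <- stage("calibrate", {
    cc <- calibrate_quality_cutoffs(spikes$score[spikes$label == "positive"],
                                    spikes$score[spikes$label == "negative"])
    arm_af <- pool_af_by_arm(pafs)
    has_truth <- all(c("af_true_case", "af_true_control") %in% names(arm_af))
    se <- if (has_truth)
      estimation_error(
        estimate_estimation_error(arm_af$af_case, arm_af$af_true_case),
        estimate_estimation_error(arm_af$af_control, arm_af$af_true_control),
        n_snps_used = nrow(arm_af))
    else pool_noise_config()[c("se_case", "se_control")]
    conc <- if (has_truth)
      af_concordance(c(arm_af$af_case, arm_af$af_control),
                     c(arm_af$af_true_case, arm_af$af_true_control))
    else NULL
    list(cutoffs = cc, se = se, concordance = conc, arm_af = arm_af)
  })
  arm_af <- calib$arm_af

  # ---- annotate variants with region class and conservation
  # region class and position are re-derived from the BED track / arm table
  cons <- cons[setdiff(names(cons), c("region_class", "pos", "conserved"))]
  variants <- merge(arm_af, cons, by = "variant_id", sort = FALSE)
  variants$chrom <- regions$chrom[1]
  variants$region_class <- ifelse(
    regulatory_overlap(variants,
                       regions[regions$class == "candidate", , drop = FALSE]),
    "candidate", "flanking")
  variants$conserved <- flag_conserved_sites(variants$phylop_p,
                                             cfg$conservation_alpha)$conserved

  # ---- haplotype clustering and tag selection (needed for scan tags)
  haps <- stage("haplotypes", {
    cl <- cluster_major_haplotypes(panel, freq_cutoff = cfg$freq_cutoff)
    tag_sets <- lapply(cl$groups$hap_id, function(h)
      select_tag_snps(panel, cl, h, r2_cutoff = cfg$r2_cutoff))
    names(tag_sets) <- cl$groups$hap_id
    list(clusters = cl, tag_sets = tag_sets)
  })

  # scan tag SNPs: first tag of each major haplotype that has one
  scan_tags <- unlist(lapply(haps$tag_sets, function(ts)
    if (!ts$flagged) ts$tags$snp_id[1] else NULL))

  assoc <- stage("assoc-scan",
    scan_common_variants(variants, calib$se, scan_tags,
                         maf_cutoff = cfg$maf_cutoff_common))

  burden <- stage("rare-burden",
    rare_burden_table(variants, maf_cutoff = cfg$maf_cutoff_rare))

  hap_assoc <- stage("haplotypes", {
    af_case <- stats::setNames(variants$af_case, variants$variant_id)
    af_ctrl <- stats::setNames(variants$af_control, variants$variant_id)
    n_case <- variants$n_case_alleles[1]
    n_ctrl <- variants$n_control_alleles[1]
    rows <- lapply(names(haps$tag_sets), function(h) {
      ts <- haps$tag_sets[[h]]
      if (ts$flagged) return(NULL)
      fc <- estimate_haplotype_frequencies(ts, af_case)
      ft <- estimate_haplotype_frequencies(ts, af_ctrl)
      fish <- haplotype_fisher_test(fc$freq, n_case, ft$freq, n_ctrl)
      data.frame(hap_id = h, n_tags = fc$n_tags,
                 freq_case = fc$freq, freq_control = ft$freq,
                 odds_ratio = fish$odds_ratio,
                 ci_lo = fish$ci95[1], ci_hi = fish$ci95[2],
                 p_fisher = fish$p_fisher)
    })
    do.call(rbind, rows)
  })

  # conditional independence between the two most associated haplotypes
  conditional <- stage("haplotypes", {
    if (is.null(hap_assoc) || nrow(hap_assoc) < 2L) NULL else {
      ord <- hap_assoc$hap_id[order(hap_assoc$p_fisher)][1:2]
      n_case <- variants$n_case_alleles[1]
      n_ctrl <- variants$n_control_alleles[1]
      counts_arm <- function(freqs, n) {
        x <- round(freqs * n)
        c(stats::setNames(x, hap_assoc$hap_id), other = n - sum(x))
      }
      cc <- counts_arm(hap_assoc$freq_case, n_case)
      ct <- counts_arm(hap_assoc$freq_control, n_ctrl)
      lapply(stats::setNames(ord, ord), function(target) {
        excl <- setdiff(ord, target)
        r <- conditional_independence_test(cc, ct, target, excl)
        list(target = target, excluded = excl,
             odds_ratio = r$odds_ratio, p_value = r$p_value)
      })
    }
  })

  # ---- individual-level validation
  validation <- stage("validate", {
    tag_cols <- setdiff(names(genos), c("individual_id", "status"))
    half <- length(tag_cols) / 2
    risk_tags <- tag_cols[seq_len(ceiling(half))]
    prot_tags <- setdiff(tag_cols, risk_tags)
    rec <- detect_recombinants(genos, risk_tags, prot_tags)
    d <- genos
    if (cfg$exclude_recombinants)
      d <- d[!d$individual_id %in% rec, , drop = FALSE]
    d$dosage_risk <- d[[risk_tags[1]]]
    d$dosage_protective <- d[[prot_tags[1]]]
    glm_res <- joint_glm_test(d)
    list(n_recombinant = length(rec), recombinants = as.character(rec),
         glm = glm_res)
  })

  # ---- annotation of candidate variants
  annot <- stage("annotate", {
    private <- exclusive_to_haplotype(panel, haps$clusters)
    pwm_deltas <- NULL
    if (!is.null(cfg$pwm_file)) {
      motifs <- read_pwm(cfg$pwm_file)
      # score the first private variant of each haplotype in a toy window:
      # ancestral window centred on the ancestral base, derived on G
      pwm_deltas <- lapply(motifs, function(p) {
        delta <- pwm_binding_delta(p, "TTAACAATT", "TTAGCAATT")
        list(motif_id = delta$motif_id,
             score_ancestral = delta$score_ancestral,
             score_derived = delta$score_derived,
             percent_change = delta$percent_change,
             excluded = delta$excluded)
      })
    }
    list(private_variants = private, pwm_deltas = pwm_deltas)
  })

  # ---- persist stage outputs
  write_tsv_table(assoc$table, file.path(cfg$out_dir, "assoc_scan.tsv"))
  write_tsv_table(burden, file.path(cfg$out_dir, "rare_burden.tsv"))
  if (!is.null(hap_assoc))
    write_tsv_table(hap_assoc, file.path(cfg$out_dir, "haplotype_assoc.tsv"))
  write_tsv_table(annot$private_variants,
                  file.path(cfg$out_dir, "private_variants.tsv"))

  report <- list(
    seed = cfg$seed,
    calibration = list(
      high_cutoff = calib$cutoffs$high_cutoff,
      low_cutoff = calib$cutoffs$low_cutoff,
      separable = calib$cutoffs$separable,
      se_case = calib$se$se_case, se_control = calib$se$se_control,
      concordance_r = if (!is.null(calib$concordance)) calib$concordance$r else NULL),
    association = list(
      n_tested = assoc$n_tested, tag_threshold = assoc$threshold,
      n_stronger = assoc$n_stronger,
      top_variant = assoc$table$variant_id[1],
      top_p = assoc$table$p_value[1]),
    rare_burden = burden,
    haplotypes = list(
      n_major = nrow(haps$clusters$groups),
      coverage = haps$clusters$coverage,
      association = hap_assoc,
      conditional = conditional),
    validation = list(
      n_recombinant = validation$n_recombinant,
      glm_separation = validation$glm$separation,
      glm = validation$glm$table),
    annotation = list(
      n_private = nrow(annot$private_variants),
      pwm = annot$pwm_deltas)
  )
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}
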
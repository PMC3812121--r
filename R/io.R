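#' Write a haplotype panel as a phased VCF
#'
#' Chromosomes are paired in order into diploid samples and emitted as
#' phased GT fields (`a|b`), VCFv4.2, one biallelic SNP per panel site.
#' The ancestral allele (always the REF/0 state in generated panels) is
#' recorded in the INFO `AA` tag.
#'
#' @param panel a `haplotype_panel`.
#' @param path output file path.
#' @param chrom chromosome name to write; default `"chrSim"`.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path, chrom = "chrSim") {
  geno <- panel$genotypes
  n <- nrow(geno)
  if (n %% 2L != 0L)
    stop("input error: need an even number of chromosomes to pair into samples")
  samples <- sprintf("SAMP%03d", seq_len(n / 2L))
  h1 <- geno[seq(1L, n, by = 2L), , drop = FALSE]
  h2 <- geno[seq(2L, n, by = 2L), , drop = FALSE]
  gt <- matrix(paste0(h1, "|", h2), nrow = n / 2L)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(geno)), function(j) {
    paste(c(chrom, panel$sites$pos[j], panel$sites$id[j], "A", "G", ".",
            "PASS", "AA=A", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' Parses phased GT fields via \pkg{vcfR} and unpairs each diploid sample
#' into two chromosomes. Sites must be biallelic and every genotype phased.
#'
#' @param path VCF file path.
#' @return A `haplotype_panel` (without generating-truth labels; group
#'   structure is recovered by [cluster_major_haplotypes()]).
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("input error: panel VCF must be fully phased (GT with '|')")
  split1 <- apply(gt, c(1, 2), function(g) as.integer(sub("\\|.*", "", g)))
  split2 <- apply(gt, c(1, 2), function(g) as.integer(sub(".*\\|", "", g)))
  n_samp <- ncol(gt)
  geno <- matrix(0L, nrow = 2L * n_samp, ncol = nrow(gt))
  geno[seq(1L, 2L * n_samp, by = 2L), ] <- t(split1)
  geno[seq(2L, 2L * n_samp, by = 2L), ] <- t(split2)
  ids <- v@fix[, "ID"]
  pos <- as.integer(v@fix[, "POS"])
  rownames(geno) <- sprintf("chr%03d", seq_len(2L * n_samp))
  colnames(geno) <- ids
  aa <- sub(".*AA=([^;]+).*", "\\1", v@fix[, "INFO"])
  structure(
    list(genotypes = geno,
         sites = data.frame(id = ids, pos = pos, ancestral = unname(aa)),
         truth = NULL, risk_hap = NA_character_, protective_hap = NA_character_,
         config = list(region_length = max(pos))),
    class = "haplotype_panel"
  )
}

#' Read position weight matrices from a motif TSV file
#'
#' Format: one or more motif blocks, each starting with a header line
#' `>motif_id<TAB>tf_name` followed by one line per motif position holding
#' four tab-separated scores in A, C, G, T order.
#'
#' @param path motif file path.
#' @return Named list of [pwm()] objects.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("input error: no motif header ('>') found")
  ends <- c(starts[-1] - 1L, length(lines))
  motifs <- lapply(seq_along(starts), function(i) {
    hdr <- strsplit(sub("^>", "", lines[starts[i]]), "\t")[[1]]
    rows <- lines[(starts[i] + 1L):ends[i]]
    mat <- unname(vapply(rows, function(r) as.numeric(strsplit(r, "\t")[[1]]),
                         numeric(4)))
    pwm(hdr[1], mat, source_tf = if (length(hdr) > 1) hdr[2] else NA_character_)
  })
  names(motifs) <- vapply(motifs, `[[`, character(1), "motif_id")
  motifs
}

#' Write position weight matrices to a motif TSV file
#'
#' @param pwms a [pwm()] object or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$motif_id, "\t", p$source_tf),
      apply(p$matrix, 2, paste, collapse = "\t"))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write simple TSV tables
#'
#' Thin wrappers fixing the dialect (tab-separated, header, no quoting,
#' no row names) used by every tabular interchange file in the pipeline.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `read_tsv_table()` returns a data frame; `write_tsv_table()`
#'   returns `path` invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a BED file of genomic intervals
#'
#' @param path BED file path (>= 3 columns; optional 4th column is kept as
#'   `class`).
#' @return Data frame `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `class`.
#' @export
read_bed <- function(path) {
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(b)[1:3] <- c("chrom", "start", "end")
  if (ncol(b) >= 4L) names(b)[4] <- "class"
  b[1:min(4L, ncol(b))]
}

#' Write genomic intervals as BED
#'
#' @param intervals data frame `chrom`, `start`, `end`, optional `class`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "class"), names(intervals))
  utils::write.table(intervals[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
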
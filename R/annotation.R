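#' Select candidate regions from conservation elements
#'
#' A conserved element qualifies as a candidate region if it is longer than
#' `min_len` bp by itself, or if it belongs to a cluster of elements whose
#' consecutive gaps are all below `max_gap` bp and whose summed element
#' length exceeds `min_len` — in which case every member of the cluster is
#' selected. Intervals are BED convention: 0-based half-open.
#'
#' @param elements data frame `chrom`, `start`, `end`; must be sorted by
#'   start and non-overlapping within each chromosome.
#' @param min_len minimum span in bp (strict); default 50.
#' @param max_gap maximum intra-cluster gap in bp (strict); default 200.
#' @return The selected rows of `elements`, with `cluster` (run id within
#'   chromosome) and `cluster_span` (summed element length of the run).
#' @export
select_candidate_regions <- function(elements, min_len = 50, max_gap = 200) {
  if (!all(c("chrom", "start", "end") %in% names(elements)))
    stop("input error: elements need chrom, start, end columns")
  if (any(elements$start >= elements$end))
    stop("input error: intervals must satisfy start < end")
  per_chrom <- split(elements, elements$chrom)
  out <- lapply(per_chrom, function(e) {
    if (is.unsorted(e$start) || any(e$start[-1] < e$end[-nrow(e)]))
      stop("input error: elements must be sorted and non-overlapping per chromosome")
    gap <- c(Inf, e$start[-1] - e$end[-nrow(e)])
    e$cluster <- cumsum(gap >= max_gap)
    span <- tapply(e$end - e$start, e$cluster, sum)
    e$cluster_span <- as.numeric(span[as.character(e$cluster)])
    e[(e$end - e$start) > min_len | e$cluster_span > min_len, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag evolutionarily conserved sites from per-site P-values
#'
#' @param scores numeric vector of per-site conservation P-values (e.g.
#'   PhyloP-style), `NA` for sites without a score.
#' @param alpha significance level; a site is conserved when `P < alpha`
#'   (strict). Default 0.05.
#' @return List: `conserved` (logical, `FALSE` where missing), `missing`
#'   (logical) and `fraction_missing`.
#' @export
flag_conserved_sites <- function(scores, alpha = 0.05) {
  if (any(scores < 0 | scores > 1, na.rm = TRUE))
    stop("input error: conservation P-values must lie in [0, 1]")
  missing <- is.na(scores)
  conserved <- !missing & scores < alpha
  list(conserved = conserved, missing = missing,
       fraction_missing = mean(missing))
}

# ---- PWM machinery -------------------------------------------------------

#' Construct a position weight matrix object
#'
#' @param motif_id motif label.
#' @param matrix numeric matrix of per-position scores, 4 rows named
#'   `A`, `C`, `G`, `T` (log-odds or energy-like additive units).
#' @param source_tf transcription factor name; optional.
#' @return A `pwm` object.
#' @export
pwm <- function(motif_id, matrix, source_tf = NA_character_) {
  if (nrow(matrix) != 4L)
    stop("input error: PWM rows must be named A, C, G, T")
  if (is.null(rownames(matrix)))
    rownames(matrix) <- c("A", "C", "G", "T")
  if (!identical(sort(rownames(matrix)), c("A", "C", "G", "T")))
    stop("input error: PWM rows must be named A, C, G, T")
  matrix <- matrix[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(matrix) < 1L || any(!is.finite(matrix)))
    stop("input error: PWM needs >= 1 position with finite scores")
  structure(list(motif_id = motif_id, matrix = matrix, source_tf = source_tf),
            class = "pwm")
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", seq), "")[[1]]), collapse = "")
}

# all window scores of a PWM along one strand of a sequence
pwm_window_scores <- function(mat, seq) {
  bases <- strsplit(toupper(seq), "")[[1]]
  L <- ncol(mat)
  n_win <- length(bases) - L + 1L
  if (n_win < 1L) stop("input error: sequence shorter than motif")
  vapply(seq_len(n_win), function(i) {
    idx <- match(bases[i:(i + L - 1L)], rownames(mat))
    if (anyNA(idx)) return(-Inf)   # ambiguous base: window not scoreable
    sum(mat[cbind(idx, seq_len(L))])
  }, numeric(1))
}

# best additive window score over both strands, plus hit count at threshold
pwm_scan <- function(p, seq, hit_threshold) {
  s_fwd <- pwm_window_scores(p$matrix, seq)
  s_rev <- pwm_window_scores(p$matrix, revcomp(seq))
  all_scores <- c(s_fwd, s_rev)
  list(score = max(all_scores), n_hits = sum(all_scores >= hit_threshold))
}

#' Binding-site disruption score of a variant under a PWM
#'
#' Operationalises "binding energy" as the maximum windowed sum of
#' per-position matrix scores over both strands of the sequence, computed
#' separately for the ancestral- and derived-allele sequences. The percent
#' change `(ancestral - derived) / ancestral * 100` quantifies predicted
#' disruption (positive = the derived allele weakens the best site).
#' Variants whose two alleles score identically are excluded (no predicted
#' allelic effect), as are motifs with more than `max_hits` predicted
#' binding sites across the scanned interval (non-specific motifs).
#'
#' @param p a [pwm()] object.
#' @param sequence_ancestral,sequence_derived equal-length sequences
#'   differing at the variant position only.
#' @param hit_threshold_frac fraction of the motif's maximum attainable
#'   score above which a window counts as a predicted hit; default 0.8.
#' @param max_hits non-specificity cutoff on the per-allele hit count
#'   (strict); default 20.
#' @return List of class `binding_delta`: `motif_id`, `score_ancestral`,
#'   `score_derived`, `percent_change` (`NA` unless the ancestral score is
#'   positive), `n_hits` (max over alleles), `excluded` and
#'   `exclusion_reason` (`"equivalent_score"`, `"non_specific"` or `NA`).
#' @export
pwm_binding_delta <- function(p, sequence_ancestral, sequence_derived,
                              hit_threshold_frac = 0.8, max_hits = 20L) {
  stopifnot(inherits(p, "pwm"))
  if (nchar(sequence_ancestral) != nchar(sequence_derived))
    stop("input error: allele sequences must have equal length")
  max_score <- sum(apply(p$matrix, 2, max))
  thr <- hit_threshold_frac * max_score
  anc <- pwm_scan(p, sequence_ancestral, thr)
  der <- pwm_scan(p, sequence_derived, thr)
  n_hits <- max(anc$n_hits, der$n_hits)
  # non-specificity dominates: a promiscuous motif is uninterpretable even
  # when the two alleles happen to tie
  reason <- if (n_hits > max_hits) "non_specific"
            else if (anc$score == der$score) "equivalent_score"
            else NA_character_
  structure(
    list(motif_id = p$motif_id,
         score_ancestral = anc$score, score_derived = der$score,
         percent_change = if (anc$score > 0)
           (anc$score - der$score) / anc$score * 100 else NA_real_,
         n_hits = n_hits,
         excluded = !is.na(reason), exclusion_reason = reason),
    class = "binding_delta"
  )
}

#' @export
print.binding_delta <- function(x, ...) {
  cat(sprintf("%s: ancestral %.3g, derived %.3g (%+.1f%%), %d hit(s)%s\n",
              x$motif_id, x$score_ancestral, x$score_derived,
              if (is.na(x$percent_change)) 0 else x$percent_change, x$n_hits,
              if (x$excluded) paste0(" [excluded: ", x$exclusion_reason, "]") else ""))
  invisible(x)
}

#' Flag variants overlapping regulatory intervals
#'
#' Variants use 1-based positions (VCF convention); intervals are 0-based
#' half-open (BED convention), so a variant at position `pos` overlaps
#' `[start, end)` iff `start < pos <= end`.
#'
#' @param variants data frame with `chrom` and `pos` (1-based).
#' @param regulatory data frame with `chrom`, `start`, `end` (BED).
#' @return Logical vector, one flag per variant.
#' @export
regulatory_overlap <- function(variants, regulatory) {
  if (nrow(regulatory) == 0L) return(rep(FALSE, nrow(variants)))
  v <- GenomicRanges::GRanges(variants$chrom,
                              IRanges::IRanges(variants$pos, variants$pos))
  r <- GenomicRanges::GRanges(regulatory$chrom,
                              IRanges::IRanges(regulatory$start + 1L, regulatory$end))
  IRanges::overlapsAny(v, r)
}

#' Variants private to a single major haplotype
#'
#' A variant is private to a major haplotype when every chromosome carrying
#' its derived allele belongs to that haplotype group — strictly: an allele
#' also seen on a rare/unassigned chromosome or on another major is not
#' private. These are the candidate causal variants of an associated
#' haplotype.
#'
#' @param panel a `haplotype_panel`.
#' @param clusters a `haplotype_clusters` from [cluster_major_haplotypes()].
#' @return Data frame `variant_id`, `hap_id`, `n_carriers`; zero rows when
#'   nothing is private.
#' @export
exclusive_to_haplotype <- function(panel, clusters) {
  geno <- panel$genotypes
  member <- clusters$membership
  rows <- lapply(colnames(geno), function(s) {
    carriers <- member[geno[, s] == 1L]
    if (length(carriers) == 0L || anyNA(carriers)) return(NULL)
    u <- unique(carriers)
    if (length(u) != 1L) return(NULL)
    data.frame(variant_id = s, hap_id = u, n_carriers = length(carriers))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variant_id = character(), hap_id = character(),
                      n_carriers = integer())
  rownames(out) <- NULL
  out
}
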
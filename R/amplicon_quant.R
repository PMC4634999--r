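## Exact 20-mer counting of mutant vs wild-type alleles in deep amplicon
## pools (the grep approach), with control-panel noise comparison.

#' Build the wild-type / mutant query k-mer pair for a variant
#'
#' SNV k-mers are centered on the variant base with a ceiling(k/2) left
#' flank; indel mutant k-mers span the novel junction with k/2 bases on each
#' side.  Both k-mers must occur exactly once in their respective sequence
#' context, otherwise an error directs the user to increase `k`.
#'
#' @param context_sequence Reference sequence context around the variant
#'   (at least k-1 nt of flank on each side).
#' @param variant List with `pos` (1-based position in the context; anchor
#'   base for indels), `ref` and `alt` (VCF-style alleles: multi-base `ref`
#'   for deletions, multi-base `alt` for insertions).
#' @param k K-mer length (default 20).
#' @return A `kmer_query` list with `wt` and `mut` k-mers.
#' @export
make_query_kmers <- function(context_sequence, variant, k = 20) {
  ctx <- toupper(context_sequence)
  pos <- variant$pos
  ref <- toupper(variant$ref)
  alt <- toupper(variant$alt)
  if (substr(ctx, pos, pos + nchar(ref) - 1L) != ref) {
    stop("variant ref does not match context at position ", pos, call. = FALSE)
  }
  left_k <- ceiling(k / 2)
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    # SNV: centered, ceiling(k/2) bases up to and including the variant
    start <- pos - left_k + 1L
    wt <- substr(ctx, start, start + k - 1L)
    mut <- wt
    substr(mut, left_k, left_k) <- alt
  } else {
    # indel: mutant k-mer spans the junction, k/2 bases each side
    half <- k %/% 2L
    left <- substr(ctx, pos - half + 1L, pos)        # ends at the anchor
    right_wt <- substr(ctx, pos + 1L, pos + (k - half))
    wt <- paste0(left, right_wt)
    if (nchar(ref) > nchar(alt)) {                   # deletion
      dlen <- nchar(ref) - 1L
      right_mut <- substr(ctx, pos + dlen + 1L, pos + dlen + (k - half))
      mut <- paste0(left, right_mut)
    } else {                                         # insertion
      ins <- substring(alt, 2L)
      mut <- substr(paste0(left, ins, substr(ctx, pos + 1L, pos + k)), 1L, k)
    }
  }
  if (nchar(wt) != k || nchar(mut) != k) {
    stop("context too short for k = ", k, call. = FALSE)
  }
  if (wt == mut) stop("wild-type and mutant k-mers are identical", call. = FALSE)
  mut_ctx <- paste0(substr(ctx, 1L, pos - 1L), alt,
                    substring(ctx, pos + nchar(ref)))
  n_wt <- .count_occurrences(ctx, wt)
  n_mut <- .count_occurrences(mut_ctx, mut)
  if (n_wt != 1L || n_mut != 1L) {
    stop("query k-mer is not unique in its context (wt: ", n_wt, ", mut: ",
         n_mut, " occurrences); increase k", call. = FALSE)
  }
  structure(list(wt = wt, mut = mut, k = as.integer(k)), class = "kmer_query")
}

.count_occurrences <- function(x, pattern) {
  m <- gregexpr(pattern, x, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

#' Count reads containing a k-mer
#'
#' A read counts (at most once) if it contains the k-mer or its reverse
#' complement as an exact substring — both strands of a sequenced amplicon
#' appear in raw read files.
#'
#' @param reads Character vector of read sequences.
#' @param kmer Query k-mer.
#' @return Integer count.
#' @export
count_kmer <- function(reads, kmer) {
  if (length(reads) == 0L) return(0L)
  sum(grepl(kmer, reads, fixed = TRUE) |
        grepl(reverse_complement(kmer), reads, fixed = TRUE))
}

#' Allele fraction from mutant and wild-type counts
#'
#' Reads matching neither query (sequencing errors at the locus) are outside
#' the denominator, matching a mutant-vs-wild-type read frequency.
#'
#' @param mut_count,wt_count Non-negative read counts.
#' @return `mut / (mut + wt)`; 0 when both counts are zero.
#' @export
amplicon_af <- function(mut_count, wt_count) {
  if (mut_count + wt_count == 0) return(0)
  mut_count / (mut_count + wt_count)
}

#' Quantify a variant in an amplicon pool
#'
#' @param reads Character vector of read sequences.
#' @param query A `kmer_query`.
#' @return An `amplicon_result` list: `mutant_count`, `wt_count`,
#'   `total_reads`, `af`; panel fields unset until [compare_to_panel()].
#' @export
quantify_amplicon <- function(reads, query) {
  mut <- count_kmer(reads, query$mut)
  wt <- count_kmer(reads, query$wt)
  structure(list(mutant_count = mut, wt_count = wt,
                 total_reads = length(reads),
                 af = amplicon_af(mut, wt),
                 panel_mean = NA_real_, panel_max = NA_real_,
                 above_noise = NA, binomial_p = NA_real_),
            class = "amplicon_result")
}

#' @export
print.amplicon_result <- function(x, ...) {
  cat(sprintf("<amplicon_result> %d mutant / %d informative of %d reads (AF %.3f%%)\n",
              x$mutant_count, x$mutant_count + x$wt_count, x$total_reads,
              100 * x$af))
  if (!is.na(x$above_noise)) {
    cat(sprintf("  panel mean %.3f%% max %.3f%%; above noise: %s (p = %.3g)\n",
                100 * x$panel_mean, 100 * x$panel_max, x$above_noise,
                x$binomial_p))
  }
  invisible(x)
}

#' Compare an amplicon result against a control panel
#'
#' `above_noise` requires strict exceedance of the panel maximum AF and a
#' one-sided binomial tail probability below `p_threshold`: the probability
#' of at least `mutant_count` successes in `mutant_count + wt_count` trials
#' at the pooled panel rate (the panel mean).
#'
#' @param result An `amplicon_result`.
#' @param panel A `control_panel`.
#' @param p_threshold Significance threshold on the binomial tail (0.01).
#' @return The result with `panel_mean`, `panel_max`, `above_noise` and
#'   `binomial_p` filled in.
#' @export
compare_to_panel <- function(result, panel, p_threshold = 0.01) {
  n <- result$mutant_count + result$wt_count
  rate <- panel$mean_af
  p <- if (n == 0L) 1 else
    stats::pbinom(result$mutant_count - 1L, n, rate, lower.tail = FALSE)
  result$panel_mean <- panel$mean_af
  result$panel_max <- panel$max_af
  result$binomial_p <- p
  result$above_noise <- result$af > panel$max_af & p < p_threshold
  result
}
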
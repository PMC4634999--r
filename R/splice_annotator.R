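## Classification of intronic variants by position relative to splice
## elements (canonical dinucleotides, branch region, near-exon windows, deep
## intronic), and allelic-distortion scoring of expressed SNP ratios as
## evidence of nonsense-mediated decay.

#' Parse a cDNA-relative (HGVS-like) variant notation
#'
#' Handles substitutions (`c.976-15G>A`), deletions (`c.1776delG`,
#' `c.4180_81delCT` — shorthand range ends are expanded), insertions
#' (`c.4238insGGTTAAG`) and deletion-insertions
#' (`c.3611-9_3611-34delinsCC`), with optional intronic offsets
#' (`+n` donor side, `-n` acceptor side).  Notations outside these forms —
#' breakpoint-uncertain large deletions (`c.-234-?_*1+?del`), fusions into
#' neighbouring genes, and 5'UTR (`c.-`) positions — are returned unparsed
#' in a distinct non-splice bucket rather than rejected.
#'
#' @param notation The notation string.
#' @return A `cdna_variant` list: `raw`, `parseable`, `kind` (substitution /
#'   deletion / insertion / delins / other), `cdna_position`, `intron_offset`
#'   (0 for exonic), `end_position`, `end_offset`, `ref`, `alt` or inserted /
#'   deleted sequence, and the raw positional tokens used for re-rendering.
#' @export
parse_cdna_variant <- function(notation) {
  raw <- trimws(notation)
  base <- list(raw = raw, parseable = FALSE, kind = "other",
               cdna_position = NA_integer_, intron_offset = 0L,
               end_position = NA_integer_, end_offset = NA_integer_,
               ref = NA_character_, alt = NA_character_,
               seq = NA_character_, tokens = NULL)
  pos_re <- "([0-9]+)([+-][0-9]+)?"

  # bucket: uncertain breakpoints, fusion partners, multi-segment ranges,
  # 5'UTR positions
  if (grepl("\\?", raw) || grepl("c\\.-", raw) ||
      grepl("c\\.", substring(raw, 3L))) {
    if (!startsWith(raw, "c.")) {
      stop("unparseable cDNA notation: ", raw, call. = FALSE)
    }
    return(structure(base, class = "cdna_variant"))
  }

  m <- regmatches(raw, regexec(paste0("^c\\.", pos_re,
                                      "([ACGT])>([ACGT])$"), raw))[[1L]]
  if (length(m)) {
    v <- base
    v$parseable <- TRUE; v$kind <- "substitution"
    v$cdna_position <- as.integer(m[2L])
    v$intron_offset <- if (nzchar(m[3L])) as.integer(m[3L]) else 0L
    v$ref <- m[4L]; v$alt <- m[5L]
    v$tokens <- list(start = m[2L], soff = m[3L], end = "", eoff = "")
    return(structure(v, class = "cdna_variant"))
  }

  m <- regmatches(raw, regexec(paste0("^c\\.", pos_re, "(?:_", pos_re,
                                      ")?del([ACGT]*)$"), raw))[[1L]]
  if (length(m)) {
    v <- base
    v$parseable <- TRUE; v$kind <- "deletion"
    v$cdna_position <- as.integer(m[2L])
    v$intron_offset <- if (nzchar(m[3L])) as.integer(m[3L]) else 0L
    v$tokens <- list(start = m[2L], soff = m[3L], end = m[4L], eoff = m[5L])
    if (nzchar(m[4L])) {
      v$end_position <- .expand_shorthand(m[2L], m[4L])
      v$end_offset <- if (nzchar(m[5L])) as.integer(m[5L]) else 0L
    }
    v$seq <- if (nzchar(m[6L])) m[6L] else NA_character_
    return(structure(v, class = "cdna_variant"))
  }

  m <- regmatches(raw, regexec(paste0("^c\\.", pos_re, "(?:_", pos_re,
                                      ")?delins([ACGT]+)$"), raw))[[1L]]
  if (length(m)) {
    v <- base
    v$parseable <- TRUE; v$kind <- "delins"
    v$cdna_position <- as.integer(m[2L])
    v$intron_offset <- if (nzchar(m[3L])) as.integer(m[3L]) else 0L
    v$tokens <- list(start = m[2L], soff = m[3L], end = m[4L], eoff = m[5L])
    if (nzchar(m[4L])) {
      v$end_position <- .expand_shorthand(m[2L], m[4L])
      v$end_offset <- if (nzchar(m[5L])) as.integer(m[5L]) else 0L
    }
    v$seq <- m[6L]
    return(structure(v, class = "cdna_variant"))
  }

  m <- regmatches(raw, regexec(paste0("^c\\.", pos_re, "(?:_", pos_re,
                                      ")?ins([ACGT]+)$"), raw))[[1L]]
  if (length(m)) {
    v <- base
    v$parseable <- TRUE; v$kind <- "insertion"
    v$cdna_position <- as.integer(m[2L])
    v$intron_offset <- if (nzchar(m[3L])) as.integer(m[3L]) else 0L
    v$tokens <- list(start = m[2L], soff = m[3L], end = m[4L], eoff = m[5L])
    if (nzchar(m[4L])) {
      v$end_position <- .expand_shorthand(m[2L], m[4L])
      v$end_offset <- if (nzchar(m[5L])) as.integer(m[5L]) else 0L
    }
    v$seq <- m[6L]
    return(structure(v, class = "cdna_variant"))
  }

  stop("unparseable cDNA notation: ", raw, call. = FALSE)
}

## "c.4180_81delCT": the range end repeats only the trailing digits.
.expand_shorthand <- function(start_str, end_str) {
  if (nchar(end_str) >= nchar(start_str)) return(as.integer(end_str))
  prefix <- substr(start_str, 1L, nchar(start_str) - nchar(end_str))
  as.integer(paste0(prefix, end_str))
}

#' Re-render a parsed cDNA variant as its notation string
#'
#' Exact inverse of [parse_cdna_variant()] over parseable inputs (shorthand
#' range ends are preserved as written).
#'
#' @param variant A `cdna_variant`.
#' @return Notation string.
#' @export
format_cdna_variant <- function(variant) {
  if (!variant$parseable) return(variant$raw)
  t <- variant$tokens
  span <- paste0(t$start, t$soff,
                 if (nzchar(t$end)) paste0("_", t$end, t$eoff) else "")
  switch(variant$kind,
         substitution = paste0("c.", span, variant$ref, ">", variant$alt),
         deletion = paste0("c.", span, "del",
                           if (!is.na(variant$seq)) variant$seq else ""),
         delins = paste0("c.", span, "delins", variant$seq),
         insertion = paste0("c.", span, "ins", variant$seq))
}

#' Splice-position classification windows
#'
#' Default windows: offsets of magnitude 1-2 are canonical; acceptor-side
#' offsets in [-40, -10] fall in the branch region; donor-side [+3, +50] and
#' acceptor-side [-9, -3] together with acceptor [-50, -41] are near-exon;
#' anything beyond 50 nt is deep intronic.  The windows are configurable —
#' the underlying consensus-element boundaries are not sharply defined.
#'
#' @param canonical_max Largest canonical offset magnitude (2).
#' @param branch_region Acceptor-side branch window, negative bounds.
#' @param deep_min Magnitude beyond which a variant is deep intronic (51).
#' @return A `splice_windows` list.
#' @export
splice_windows <- function(canonical_max = 2, branch_region = c(-40, -10),
                           deep_min = 51) {
  structure(list(canonical_max = canonical_max,
                 branch_region = sort(branch_region), deep_min = deep_min),
            class = "splice_windows")
}

#' Classify a variant's position relative to splice elements
#'
#' @param variant A `cdna_variant` (or notation string, parsed on the fly).
#'   For range variants, the most exon-proximal offset is used.
#' @param config A `splice_windows`.
#' @return One of `"exonic"`, `"canonical"`, `"branch_region"`,
#'   `"near_exon"`, `"deep_intronic"`; `"non_splice"` for bucket notations
#'   (uncertain large deletions, 5'UTR forms).
#' @export
classify_splice_position <- function(variant, config = splice_windows()) {
  if (is.character(variant)) variant <- parse_cdna_variant(variant)
  if (!variant$parseable) return("non_splice")
  offs <- c(variant$intron_offset,
            if (!is.na(variant$end_offset)) variant$end_offset)
  off <- offs[which.min(abs(offs))]   # most exon-proximal
  if (off == 0L) return("exonic")
  a <- abs(off)
  if (a <= config$canonical_max) return("canonical")
  if (a >= config$deep_min) return("deep_intronic")
  if (off < 0L && off >= config$branch_region[1L] &&
      off <= config$branch_region[2L]) {
    return("branch_region")
  }
  "near_exon"
}

#' Allelic-ratio distortion score
#'
#' The ratio of the lower to the higher allele count of an expressed
#' heterozygous SNP.  In population RNA-seq (GTEx, TSC2 synonymous SNP
#' rs1748) the ratio centers at 0.89 with 99% of values above 0.43, so a
#' ratio strictly below 0.43 marks allelic distortion consistent with
#' nonsense-mediated decay of the mutant transcript.
#'
#' @param count_a,count_b Allele read counts; their sum must be positive.
#' @param threshold Distortion threshold (default 0.43).
#' @return An `allelic_ratio_result` list: `count_a`, `count_b`, `ratio`
#'   (in `[0, 1]`), `distorted`, `threshold`.
#' @export
allelic_ratio <- function(count_a, count_b, threshold = 0.43) {
  if (count_a + count_b <= 0) {
    stop("allelic ratio undefined: both counts are zero", call. = FALSE)
  }
  ratio <- min(count_a, count_b) / max(count_a, count_b)
  structure(list(count_a = count_a, count_b = count_b, ratio = ratio,
                 distorted = ratio < threshold, threshold = threshold),
            class = "allelic_ratio_result")
}

#' Classify a table of variant notations
#'
#' @param notations Character vector of cDNA notations.
#' @param config A `splice_windows`.
#' @return Data.frame: `notation`, `cdna_position`, `intron_offset`, `class`.
#' @export
classify_variants <- function(notations, config = splice_windows()) {
  parsed <- lapply(notations, parse_cdna_variant)
  data.frame(
    notation = notations,
    cdna_position = vapply(parsed, `[[`, integer(1L), "cdna_position"),
    intron_offset = vapply(parsed, `[[`, integer(1L), "intron_offset"),
    class = vapply(parsed, classify_splice_position, character(1L),
                   config = config),
    stringsAsFactors = FALSE)
}
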
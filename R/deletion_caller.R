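## Mosaic multi-kilobase deletion detection from paired-end insert-size
## outliers: flag pairs with outer distance > 1,200, cluster flagged pairs
## within 500 nt windows (>= 3 pairs for insert > 2,000; >= 5 pairs for
## insert 1,200-2,000), and estimate the deletion allele fraction as the
## discordant fraction among breakpoint-spanning pairs.

#' Flag discordant read pairs by insert size
#'
#' @param pairs Pair data.frame with `left_start` and `insert_size` (signed
#'   outer distance; absolute value used).
#' @param min_insert Flagging threshold (default 1,200 nt).
#' @param large_threshold Boundary between the `intermediate`
#'   (min_insert-large_threshold] and `large` (> large_threshold) categories.
#' @return The flagged subset with a `category` column.
#' @export
flag_discordant_pairs <- function(pairs, min_insert = 1200,
                                  large_threshold = 2000) {
  ins <- abs(pairs$insert_size)
  flagged <- pairs[ins > min_insert, , drop = FALSE]
  flagged$category <- ifelse(abs(flagged$insert_size) > large_threshold,
                             "large", "intermediate")
  rownames(flagged) <- NULL
  flagged
}

empty_deletion_calls <- function() {
  data.frame(contig = character(0), window_start = integer(0),
             window_end = integer(0), supporting_pairs = integer(0),
             category = character(0), estimated_del_start = numeric(0),
             estimated_del_end = numeric(0), af = numeric(0),
             stringsAsFactors = FALSE)
}

## Maximal qualifying windows for one category; returns merged index ranges.
.cluster_one_category <- function(coords, window, min_pairs) {
  n <- length(coords)
  if (n < min_pairs) return(list())
  o <- order(coords)
  x <- coords[o]
  # pairs j >= i belong to the window anchored at i iff x[j] - x[i] <= window
  last <- findInterval(x + window, x)
  count <- last - seq_len(n) + 1L
  anchors <- which(count >= min_pairs)
  if (!length(anchors)) return(list())
  ranges <- cbind(anchors, last[anchors])
  merged <- list()
  cur <- ranges[1L, ]
  for (i in seq_len(nrow(ranges))[-1L]) {
    if (ranges[i, 1L] <= cur[2L]) {
      cur[2L] <- max(cur[2L], ranges[i, 2L])
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- ranges[i, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  lapply(merged, function(r) o[r[1L]:r[2L]])
}

#' Cluster flagged pairs into deletion calls
#'
#' Emits a call for every maximal 500-nt window (over flagged-pair leftmost
#' coordinates) containing at least `min_large` large-category pairs or at
#' least `min_intermediate` intermediate-category pairs; the two categories
#' are evaluated independently, and overlapping qualifying windows are merged
#' into one call.  Breakpoints are estimated as the median left-read end and
#' the median mate start of the supporting pairs.
#'
#' @param flagged Output of [flag_discordant_pairs()].
#' @param window Cluster window width in nt (default 500).
#' @param min_large,min_intermediate Minimum pairs per window by category.
#' @return Deletion call data.frame: `contig`, `window_start`, `window_end`,
#'   `supporting_pairs`, `category`, `estimated_del_start`,
#'   `estimated_del_end` (NA when the category's mate-position estimate is
#'   unavailable), `af` (NA; see [deletion_af()]).
#' @export
cluster_flagged <- function(flagged, window = 500, min_large = 3,
                            min_intermediate = 5) {
  if (nrow(flagged) == 0L) return(empty_deletion_calls())
  rl <- if ("read_length" %in% names(flagged)) flagged$read_length else 50L
  out <- list()
  for (cat in c("large", "intermediate")) {
    sel <- which(flagged$category == cat)
    min_n <- if (cat == "large") min_large else min_intermediate
    clusters <- .cluster_one_category(flagged$left_start[sel], window, min_n)
    for (idx in clusters) {
      m <- flagged[sel[idx], , drop = FALSE]
      mrl <- if ("read_length" %in% names(m)) m$read_length else 50L
      out[[length(out) + 1L]] <- data.frame(
        contig = m$contig[1L],
        window_start = min(m$left_start),
        window_end = max(m$left_start),
        supporting_pairs = nrow(m),
        category = cat,
        estimated_del_start = stats::median(m$left_start + mrl - 1L),
        estimated_del_end = stats::median(m$left_start +
                                            abs(m$insert_size) - mrl),
        af = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_deletion_calls())
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$window_start), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Estimate deletion allele fraction from insert-size counts
#'
#' Among pairs whose fragment spans the breakpoint, the allele fraction is
#' the number with a large (discordant) insert over the total — counting
#' reads with normal versus large insert size, restricted locally so the
#' value is comparable to an SNV allele fraction.
#'
#' @param pairs Full pair data.frame (concordant and discordant).
#' @param breakpoint Reference coordinate of the deletion start.
#' @param min_insert Discordance threshold (default 1,200).
#' @return Fraction in `[0, 1]`; 0 when no discordant pair spans.
#' @export
deletion_af <- function(pairs, breakpoint, min_insert = 1200) {
  ins <- abs(pairs$insert_size)
  spans <- pairs$left_start <= breakpoint &
    pairs$left_start + ins - 1L >= breakpoint
  n_disc <- sum(spans & ins > min_insert)
  n_conc <- sum(spans & ins <= min_insert)
  if (n_disc + n_conc == 0L) return(0)
  n_disc / (n_disc + n_conc)
}

#' Detect mosaic deletions end to end
#'
#' Flags discordant pairs, clusters them, and annotates each call with the
#' allele fraction at its estimated start breakpoint.
#'
#' @param pairs Pair data.frame.
#' @param min_insert,large_threshold See [flag_discordant_pairs()].
#' @param window,min_large,min_intermediate See [cluster_flagged()].
#' @return Deletion call data.frame with `af` filled in.
#' @export
detect_deletions <- function(pairs, min_insert = 1200, large_threshold = 2000,
                             window = 500, min_large = 3,
                             min_intermediate = 5) {
  flagged <- flag_discordant_pairs(pairs, min_insert, large_threshold)
  calls <- cluster_flagged(flagged, window, min_large, min_intermediate)
  if (nrow(calls)) {
    # anchor inside the deleted interval: every discordant pair bridges an
    # interior point, while concordant coverage there is the normal-allele
    # depth, so the fraction is unbiased for the carrier fraction
    calls$af <- vapply(seq_len(nrow(calls)), function(i) {
      bp <- round((calls$estimated_del_start[i] +
                     calls$estimated_del_end[i]) / 2)
      deletion_af(pairs, bp, min_insert)
    }, numeric(1L))
  }
  calls
}

#' Convert deletion calls to the variant-call schema for VCF output
#'
#' @param calls Deletion call data.frame from [detect_deletions()].
#' @param reference A `mosaic_reference` (for the REF anchor base).
#' @param sample_id Sample label.
#' @return Variant call data.frame with `variant_type = "deletion_large"`
#'   and an `end` column, suitable for [write_variant_calls()].
#' @export
deletion_calls_to_variants <- function(calls, reference,
                                       sample_id = NA_character_) {
  if (nrow(calls) == 0L) {
    out <- empty_calls()
    out$end <- integer(0)
    return(out)
  }
  pos <- as.integer(round(calls$estimated_del_start))
  pos <- pmax(1L, pmin(pos, nchar(reference$sequence)))
  data.frame(
    contig = calls$contig, position = pos,
    ref = substring(reference$sequence, pos, pos), alt = "<DEL>",
    variant_type = "deletion_large", af = calls$af,
    support_forward = calls$supporting_pairs, support_reverse = 0L,
    depth_total = calls$supporting_pairs, tier = "review", filters = "",
    sample_id = sample_id,
    end = as.integer(round(calls$estimated_del_end)),
    stringsAsFactors = FALSE)
}
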
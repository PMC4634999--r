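## The custom low allele-fraction calling path: read quality filtering,
## redundancy normalization to a uniform per-start read count, per-orientation
## pileup frequencies, tiered candidate calling, and artifact filters.

#' Tiered calling configuration
#'
#' Thresholds of the two-tier calling scheme: every non-reference allele at
#' >= 1% AF is emitted for review; the sensitive tier lowers the cut-off to
#' 0.5% and three supporting reads for SNVs and to 0.2% and two reads for
#' indels.  Redundancy is reduced to a uniform 50 reads starting at each
#' position in each orientation.
#'
#' @param review_af Review-tier AF threshold (default 0.01).
#' @param snv_af,snv_min_reads Sensitive-tier SNV thresholds (0.005, 3).
#' @param indel_af,indel_min_reads Sensitive-tier indel thresholds (0.002, 2).
#' @param redundancy_cap Reads kept per (start, orientation) group (50).
#' @param min_base_quality Bases below this Phred quality are excluded from
#'   pileup counts (read retained).
#' @param min_mapping_quality Reads below this MAPQ are removed.
#' @param panel_min_other_samples Minimum number of other samples sharing a
#'   candidate for the panel-recurrence flag.
#' @return A `tier_config` list.
#' @export
tier_config <- function(review_af = 0.01, snv_af = 0.005, snv_min_reads = 3,
                        indel_af = 0.002, indel_min_reads = 2,
                        redundancy_cap = 50, min_base_quality = 20,
                        min_mapping_quality = 20,
                        panel_min_other_samples = 2) {
  stopifnot(indel_af > 0, indel_af <= snv_af, snv_af <= review_af,
            review_af < 1, snv_min_reads >= 1, indel_min_reads >= 1,
            redundancy_cap >= 1)
  structure(list(review_af = review_af, snv_af = snv_af,
                 snv_min_reads = as.integer(snv_min_reads),
                 indel_af = indel_af,
                 indel_min_reads = as.integer(indel_min_reads),
                 redundancy_cap = as.integer(redundancy_cap),
                 min_base_quality = as.integer(min_base_quality),
                 min_mapping_quality = as.integer(min_mapping_quality),
                 panel_min_other_samples = as.integer(panel_min_other_samples)),
            class = "tier_config")
}

#' Remove low-quality reads
#'
#' Drops reads below the mapping-quality threshold.  Base-level quality
#' masking (exclusion of bases below `min_base_quality` from pileup counts)
#' is applied by [build_pileup()] using the same configuration.
#'
#' @param reads Alignment data.frame.
#' @param config A `tier_config`.
#' @return Filtered alignment data.frame.
#' @export
filter_reads <- function(reads, config = tier_config()) {
  reads[reads$mapq >= config$min_mapping_quality, , drop = FALSE]
}

#' Reduce redundancy to a uniform read count per start position
#'
#' Within each (start position, orientation) group, at most `cap` reads are
#' retained: the highest mapping qualities first, ties broken by read id
#' (lexicographic), so the selection is deterministic.
#'
#' @param reads Alignment data.frame.
#' @param cap Maximum reads per group (default 50).
#' @return Downsampled alignment data.frame.
#' @export
downsample_redundancy <- function(reads, cap = 50) {
  stopifnot(cap >= 1)
  if (nrow(reads) == 0L) return(reads)
  o <- order(reads$start, reads$orientation, -reads$mapq, reads$read_id)
  r <- reads[o, , drop = FALSE]
  grp <- paste(r$start, r$orientation)
  rank_in_grp <- stats::ave(seq_along(grp), grp, FUN = seq_along)
  out <- r[rank_in_grp <= cap, , drop = FALSE]
  rownames(out) <- NULL
  out
}

PHRED_OFFSET <- 33L

## Decode one quality character per read at a fixed offset into Phred scores.
.qual_at <- function(quals, k) {
  ch <- substr(quals, k, k)
  utf8ToInt(paste(ch, collapse = ""))[nchar(ch) > 0L] - PHRED_OFFSET
}

#' Build a per-orientation pileup
#'
#' Counts base calls at every covered position, split by read orientation,
#' after masking bases below the base-quality threshold.  Insertions are
#' keyed to the anchor base before the inserted sequence; small deletions are
#' recorded at their anchor keyed by deleted length (and deleted positions
#' contribute no base call, so column depth always equals the number of
#' quality-passing read bases covering it).
#'
#' @param reads Alignment data.frame (ideally filtered and downsampled).
#' @param reference A `mosaic_reference`.
#' @param region Optional `c(start, end)`; defaults to the covered range.
#' @param config A `tier_config` (supplies `min_base_quality`).
#' @return A `pileup` object: list with `columns` (position, ref and
#'   per-orientation counts of A/C/G/T/N plus depths) and `indels`
#'   (anchor position, key such as `"I:AGG"` or `"D:2"`, per-orientation
#'   support).
#' @export
build_pileup <- function(reads, reference, region = NULL,
                         config = tier_config()) {
  ref_len <- nchar(reference$sequence)
  if (nrow(reads) == 0L) {
    return(empty_pileup(reference, region))
  }
  if (is.null(region)) {
    region <- c(max(1L, min(reads$start)),
                min(ref_len, max(reads$start +
                                   cigar_reference_length(reads$cigar) - 1L)))
  }
  rl <- nchar(reads$sequence)
  simple <- reads$cigar == sprintf("%dM", rl)

  pos_acc <- list(); base_acc <- list(); fwd_acc <- list()
  add <- function(pos, base, fwd) {
    i <- length(pos_acc) + 1L
    pos_acc[[i]] <<- pos; base_acc[[i]] <<- base; fwd_acc[[i]] <<- fwd
  }

  # fast path: pure-match reads, one vectorized pass per read offset
  if (any(simple)) {
    s <- reads[simple, , drop = FALSE]
    srl <- nchar(s$sequence)
    for (k in seq_len(max(srl))) {
      live <- srl >= k
      pos <- s$start[live] + k - 1L
      ok <- pos >= region[1L] & pos <= region[2L] & pos <= ref_len
      if (!any(ok)) next
      q <- utf8ToInt(paste(substr(s$qual[live], k, k), collapse = "")) -
        PHRED_OFFSET
      ok <- ok & q >= config$min_base_quality
      if (!any(ok)) next
      add(pos[ok], substr(s$sequence[live], k, k)[ok],
          (s$orientation[live] == "forward")[ok])
    }
  }

  indel_rows <- list()
  if (any(!simple)) {
    cx <- reads[!simple, , drop = FALSE]
    for (i in seq_len(nrow(cx))) {
      cg <- parse_cigar(cx$cigar[i])
      rpos <- cx$start[i]   # next reference position
      qpos <- 1L            # next query position
      fwd <- cx$orientation[i] == "forward"
      quals <- utf8ToInt(cx$qual[i]) - PHRED_OFFSET
      for (j in seq_along(cg$ops)) {
        len <- cg$lens[j]
        if (cg$ops[j] == "M") {
          p <- rpos:(rpos + len - 1L)
          qidx <- qpos:(qpos + len - 1L)
          ok <- p >= region[1L] & p <= region[2L] & p <= ref_len &
            quals[qidx] >= config$min_base_quality
          if (any(ok)) {
            add(p[ok],
                strsplit(substr(cx$sequence[i], qpos, qpos + len - 1L),
                         "")[[1L]][ok],
                rep(fwd, sum(ok)))
          }
          rpos <- rpos + len; qpos <- qpos + len
        } else if (cg$ops[j] == "I") {
          anchor <- rpos - 1L
          key <- paste0("I:", substr(cx$sequence[i], qpos, qpos + len - 1L))
          indel_rows[[length(indel_rows) + 1L]] <-
            list(position = anchor, key = key, fwd = fwd)
          qpos <- qpos + len
        } else { # D
          anchor <- rpos - 1L
          key <- paste0("D:", len)
          indel_rows[[length(indel_rows) + 1L]] <-
            list(position = anchor, key = key, fwd = fwd)
          rpos <- rpos + len
        }
      }
    }
  }

  pos <- unlist(pos_acc, use.names = FALSE)
  if (is.null(pos) || length(pos) == 0L) return(empty_pileup(reference, region))
  base <- unlist(base_acc, use.names = FALSE)
  fwd <- unlist(fwd_acc, use.names = FALSE)

  positions <- sort(unique(pos))
  pidx <- match(pos, positions)
  bases <- c("A", "C", "G", "T", "N")
  base[!base %in% bases] <- "N"
  bidx <- match(base, bases)
  np <- length(positions)
  counts <- matrix(0L, np, 10L,
                   dimnames = list(NULL, c(paste0("f", bases),
                                           paste0("r", bases))))
  tab <- tabulate(pidx + np * ((bidx - 1L) + 5L * (!fwd)), nbins = 10L * np)
  counts[] <- tab
  columns <- data.frame(
    contig = reference$name,
    position = positions,
    ref = substring(reference$sequence, positions, positions),
    counts,
    depth_forward = rowSums(counts[, 1:5, drop = FALSE]),
    depth_reverse = rowSums(counts[, 6:10, drop = FALSE]),
    stringsAsFactors = FALSE
  )

  indels <- if (length(indel_rows)) {
    d <- data.frame(position = vapply(indel_rows, `[[`, numeric(1), "position"),
                    key = vapply(indel_rows, `[[`, character(1), "key"),
                    fwd = vapply(indel_rows, `[[`, logical(1), "fwd"),
                    stringsAsFactors = FALSE)
    agg <- stats::aggregate(cbind(support_forward = d$fwd,
                                  support_reverse = !d$fwd),
                            by = list(position = d$position, key = d$key),
                            FUN = sum)
    agg[order(agg$position, agg$key), , drop = FALSE]
  } else {
    data.frame(position = integer(0), key = character(0),
               support_forward = integer(0), support_reverse = integer(0),
               stringsAsFactors = FALSE)
  }

  structure(list(contig = reference$name, region = region, columns = columns,
                 indels = indels, reference = reference),
            class = "pileup")
}

empty_pileup <- function(reference, region) {
  structure(list(
    contig = reference$name, region = region,
    columns = data.frame(contig = character(0), position = integer(0),
                         ref = character(0), fA = integer(0), fC = integer(0),
                         fG = integer(0), fT = integer(0), fN = integer(0),
                         rA = integer(0), rC = integer(0), rG = integer(0),
                         rT = integer(0), rN = integer(0),
                         depth_forward = integer(0),
                         depth_reverse = integer(0), stringsAsFactors = FALSE),
    indels = data.frame(position = integer(0), key = character(0),
                        support_forward = integer(0),
                        support_reverse = integer(0), stringsAsFactors = FALSE),
    reference = reference), class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s:%d-%d, %d columns, %d indel keys\n", x$contig,
              x$region[1L], x$region[2L], nrow(x$columns), nrow(x$indels)))
  invisible(x)
}

## Numerical guard for threshold comparisons such as 3/600 >= 0.005.
.AF_EPS <- 1e-9

empty_calls <- function() {
  data.frame(contig = character(0), position = integer(0), ref = character(0),
             alt = character(0), variant_type = character(0), af = numeric(0),
             support_forward = integer(0), support_reverse = integer(0),
             depth_total = integer(0), tier = character(0),
             filters = character(0), sample_id = character(0),
             stringsAsFactors = FALSE)
}

#' Call candidate variants from a pileup
#'
#' The review tier emits every non-reference allele at AF >= 1%; the
#' sensitive tier emits SNVs at AF >= 0.5% with at least three supporting
#' reads and indels at AF >= 0.2% with at least two.  AF is the combined
#' forward+reverse support over the combined depth at the column; the
#' orientation split is retained for the single-orientation filter.
#'
#' @param pileup A `pileup` object.
#' @param config A `tier_config`.
#' @param tier `"review"` or `"sensitive"`.
#' @param sample_id Sample label carried on the calls.
#' @param keep_subthreshold If TRUE, alleles failing the tier thresholds are
#'   emitted with the `below_threshold` filter flag instead of being dropped.
#' @return Variant call data.frame with columns `contig`, `position`, `ref`,
#'   `alt`, `variant_type`, `af`, `support_forward`, `support_reverse`,
#'   `depth_total`, `tier`, `filters` (semicolon-joined, empty = pass),
#'   `sample_id`.
#' @export
call_candidates <- function(pileup, config = tier_config(),
                            tier = c("sensitive", "review"),
                            sample_id = NA_character_,
                            keep_subthreshold = FALSE) {
  tier <- match.arg(tier)
  cols <- pileup$columns
  out <- list()

  if (nrow(cols)) {
    depth <- cols$depth_forward + cols$depth_reverse
    for (b in c("A", "C", "G", "T")) {
      sf <- cols[[paste0("f", b)]]
      sr <- cols[[paste0("r", b)]]
      sup <- sf + sr
      cand <- cols$ref != b & sup > 0L & depth > 0L
      if (!any(cand)) next
      af <- sup[cand] / depth[cand]
      out[[length(out) + 1L]] <- data.frame(
        contig = cols$contig[cand], position = cols$position[cand],
        ref = cols$ref[cand], alt = b, variant_type = "SNV", af = af,
        support_forward = sf[cand], support_reverse = sr[cand],
        depth_total = depth[cand], stringsAsFactors = FALSE)
    }
  }

  ind <- pileup$indels
  if (nrow(ind)) {
    anchor_idx <- match(ind$position, cols$position)
    adepth <- ifelse(is.na(anchor_idx), NA_integer_,
                     cols$depth_forward[anchor_idx] +
                       cols$depth_reverse[anchor_idx])
    ok <- !is.na(adepth) & adepth > 0L
    if (any(ok)) {
      refseq <- pileup$reference$sequence
      anchor_base <- substring(refseq, ind$position[ok], ind$position[ok])
      is_ins <- startsWith(ind$key[ok], "I:")
      payload <- sub("^[ID]:", "", ind$key[ok])
      ref_allele <- ifelse(is_ins, anchor_base,
                           substring(refseq, ind$position[ok],
                                     ind$position[ok] +
                                       suppressWarnings(as.integer(payload))))
      alt_allele <- ifelse(is_ins, paste0(anchor_base, payload), anchor_base)
      sup <- ind$support_forward[ok] + ind$support_reverse[ok]
      out[[length(out) + 1L]] <- data.frame(
        contig = pileup$contig, position = ind$position[ok],
        ref = ref_allele, alt = alt_allele,
        variant_type = ifelse(is_ins, "insertion", "deletion_small"),
        af = sup / adepth[ok],
        support_forward = ind$support_forward[ok],
        support_reverse = ind$support_reverse[ok],
        depth_total = adepth[ok], stringsAsFactors = FALSE)
    }
  }

  if (!length(out)) return(empty_calls())
  calls <- do.call(rbind, out)

  is_snv <- calls$variant_type == "SNV"
  sup <- calls$support_forward + calls$support_reverse
  if (tier == "review") {
    pass <- calls$af >= config$review_af - .AF_EPS
  } else {
    pass <- ifelse(is_snv,
                   calls$af >= config$snv_af - .AF_EPS &
                     sup >= config$snv_min_reads,
                   calls$af >= config$indel_af - .AF_EPS &
                     sup >= config$indel_min_reads)
  }
  calls$tier <- tier
  calls$filters <- ifelse(pass, "", "below_threshold")
  calls$sample_id <- sample_id
  if (!keep_subthreshold) calls <- calls[pass, , drop = FALSE]
  calls <- calls[order(calls$position, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

add_filter_flag <- function(filters, flag, where) {
  ifelse(where,
         ifelse(nzchar(filters), paste(filters, flag, sep = ";"), flag),
         filters)
}

#' Flag calls supported by a single read orientation
#'
#' Variant calls observed in only one read orientation are characteristic
#' sequencing artifacts; they gain the `single_orientation` filter flag.
#'
#' @param calls Variant call data.frame.
#' @return The calls with updated `filters`.
#' @export
apply_orientation_filter <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  single <- calls$support_forward == 0L | calls$support_reverse == 0L
  calls$filters <- add_filter_flag(calls$filters, "single_orientation", single)
  calls
}

#' Flag calls recurrent across samples
#'
#' A candidate whose (position, alt) signature appears in at least
#' `config$panel_min_other_samples` other samples of the cohort gains the
#' `panel_recurrent` flag — recurrence across unrelated samples marks a
#' process artifact rather than a patient mutation.
#'
#' @param calls Variant call data.frame for one sample.
#' @param cohort_calls Candidate calls across the cohort (must carry
#'   `sample_id`, `position`, `alt`).
#' @param config A `tier_config`.
#' @return The calls with updated `filters`.
#' @export
apply_panel_filter <- function(calls, cohort_calls, config = tier_config()) {
  if (nrow(calls) == 0L) return(calls)
  key <- function(d) paste(d$contig, d$position, d$alt, sep = ":")
  other <- unique(data.frame(k = key(cohort_calls),
                             s = cohort_calls$sample_id,
                             stringsAsFactors = FALSE))
  n_other <- vapply(seq_len(nrow(calls)), function(i) {
    sum(other$k == key(calls[i, , drop = FALSE]) &
          (is.na(calls$sample_id[i]) | other$s != calls$sample_id[i]))
  }, numeric(1L))
  recurrent <- n_other >= config$panel_min_other_samples
  calls$filters <- add_filter_flag(calls$filters, "panel_recurrent", recurrent)
  calls
}

#' Estimate the allele fraction of a known allele from a pileup
#'
#' Quantification helper independent of the calling thresholds: returns the
#' orientation-split support and combined-depth AF for a given alternate
#' allele at a position.  `alt` is a base for SNVs or an indel key such as
#' `"I:AGG"` / `"D:2"`.
#'
#' @param pileup A `pileup` object.
#' @param position 1-based position (anchor for indels).
#' @param alt Alternate allele.
#' @return List with `af`, `support_forward`, `support_reverse`, `depth`.
#' @export
estimate_af <- function(pileup, position, alt) {
  idx <- match(position, pileup$columns$position)
  if (is.na(idx)) return(list(af = NA_real_, support_forward = 0L,
                              support_reverse = 0L, depth = 0L))
  depth <- pileup$columns$depth_forward[idx] + pileup$columns$depth_reverse[idx]
  if (grepl("^[ID]:", alt)) {
    r <- pileup$indels[pileup$indels$position == position &
                         pileup$indels$key == alt, , drop = FALSE]
    sf <- if (nrow(r)) r$support_forward[1L] else 0L
    sr <- if (nrow(r)) r$support_reverse[1L] else 0L
  } else {
    sf <- pileup$columns[[paste0("f", alt)]][idx]
    sr <- pileup$columns[[paste0("r", alt)]][idx]
  }
  list(af = if (depth > 0L) (sf + sr) / depth else NA_real_,
       support_forward = sf, support_reverse = sr, depth = depth)
}

#' Run the full single-sample calling path
#'
#' Convenience wrapper: quality filtering, redundancy downsampling, pileup,
#' tiered candidate calling and the orientation filter.
#'
#' @param reads Alignment data.frame.
#' @param reference A `mosaic_reference`.
#' @param config A `tier_config`.
#' @param tier Calling tier.
#' @param sample_id Sample label.
#' @return Variant call data.frame.
#' @export
call_sample <- function(reads, reference, config = tier_config(),
                        tier = "sensitive", sample_id = NA_character_) {
  reads <- filter_reads(reads, config)
  reads <- downsample_redundancy(reads, config$redundancy_cap)
  pu <- build_pileup(reads, reference, config = config)
  calls <- call_candidates(pu, config, tier = tier, sample_id = sample_id)
  apply_orientation_filter(calls)
}
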
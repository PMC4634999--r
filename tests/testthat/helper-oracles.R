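# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (plain loops, exhaustive scans) so they check the
# vectorized implementations from outside.

# Build an alignment data.frame by hand.
toy_reads <- function(start, sequence, orientation = "forward", mapq = 60L,
                      qual = NULL, cigar = NULL, contig = "ref",
                      insert_size = NA_integer_, sample_id = "S1",
                      read_id = NULL) {
  n <- max(length(start), length(sequence), length(orientation))
  start <- rep_len(as.integer(start), n)
  sequence <- rep_len(sequence, n)
  orientation <- rep_len(orientation, n)
  if (is.null(qual)) qual <- strrep("I", nchar(sequence))  # Phred 40
  if (is.null(cigar)) cigar <- sprintf("%dM", nchar(sequence))
  if (is.null(read_id)) read_id <- sprintf("t%05d", seq_len(n))
  data.frame(read_id = read_id, contig = contig, start = start,
             orientation = orientation, sequence = sequence,
             qual = rep_len(qual, n), mapq = rep_len(as.integer(mapq), n),
             cigar = rep_len(cigar, n),
             insert_size = rep_len(as.integer(insert_size), n),
             sample_id = rep_len(sample_id, n), stringsAsFactors = FALSE)
}

# Reads giving an exact support / depth ratio at one position: `depth`
# single-base reads at `pos`, of which `n_alt` carry `alt` (split
# `n_alt_fwd` forward / rest reverse), remainder carry the reference base.
exact_af_reads <- function(reference, pos, alt, depth, n_alt, n_alt_fwd) {
  ref_base <- substr(reference$sequence, pos, pos)
  is_alt <- rep(c(TRUE, FALSE), c(n_alt, depth - n_alt))
  fwd <- c(rep(c(TRUE, FALSE), c(n_alt_fwd, n_alt - n_alt_fwd)),
           rep(c(TRUE, FALSE), length.out = depth - n_alt))
  toy_reads(start = pos, sequence = ifelse(is_alt, alt, ref_base),
            orientation = ifelse(fwd, "forward", "reverse"),
            contig = reference$name)
}

# Naive per-read pileup: walk every read base by base, honoring CIGAR and
# base-quality masking; returns base counts and indel observations.
naive_pileup <- function(reads, reference, min_bq = 20L) {
  counts <- list()   # key "pos|base|orient" -> count
  indels <- list()   # key "pos|key|orient" -> count
  bump <- function(env_list, key) {
    env_list[[key]] <- (if (is.null(env_list[[key]])) 0L else env_list[[key]]) + 1L
    env_list
  }
  ref_len <- nchar(reference$sequence)
  for (i in seq_len(nrow(reads))) {
    ops <- regmatches(reads$cigar[i], gregexpr("[MID]", reads$cigar[i]))[[1]]
    lens <- as.integer(regmatches(reads$cigar[i],
                                  gregexpr("[0-9]+", reads$cigar[i]))[[1]])
    rpos <- reads$start[i]; qpos <- 1L
    orient <- reads$orientation[i]
    for (j in seq_along(ops)) {
      if (ops[j] == "M") {
        for (k in seq_len(lens[j])) {
          q <- utf8ToInt(substr(reads$qual[i], qpos, qpos)) - 33L
          if (rpos >= 1L && rpos <= ref_len && q >= min_bq) {
            b <- substr(reads$sequence[i], qpos, qpos)
            if (!b %in% c("A", "C", "G", "T")) b <- "N"
            counts <- bump(counts, paste(rpos, b, orient, sep = "|"))
          }
          rpos <- rpos + 1L; qpos <- qpos + 1L
        }
      } else if (ops[j] == "I") {
        key <- paste0("I:", substr(reads$sequence[i], qpos, qpos + lens[j] - 1L))
        indels <- bump(indels, paste(rpos - 1L, key, orient, sep = "|"))
        qpos <- qpos + lens[j]
      } else {
        indels <- bump(indels, paste(rpos - 1L, paste0("D:", lens[j]), orient,
                                     sep = "|"))
        rpos <- rpos + lens[j]
      }
    }
  }
  list(counts = counts, indels = indels)
}

# Look up a count from a pileup object the way the naive oracle keys it.
pileup_count <- function(pu, pos, base, orient) {
  idx <- match(pos, pu$columns$position)
  if (is.na(idx)) return(0L)
  col <- paste0(if (orient == "forward") "f" else "r", base)
  pu$columns[[col]][idx]
}

# Exhaustive deletion-call oracle: every window anchored at a flagged pair,
# category-separate counting, overlapping qualifying windows merged.
oracle_cluster <- function(flagged, window = 500, min_large = 3,
                           min_intermediate = 5) {
  out <- list()
  for (cat in c("large", "intermediate")) {
    x <- sort(flagged$left_start[flagged$category == cat])
    min_n <- if (cat == "large") min_large else min_intermediate
    n <- length(x)
    if (n < min_n) next
    members <- NULL; clusters <- list()
    for (i in seq_len(n)) {
      inw <- which(x >= x[i] & x <= x[i] + window)
      if (length(inw) >= min_n) {
        if (!is.null(members) && min(inw) <= max(members)) {
          members <- union(members, inw)
        } else {
          if (!is.null(members)) clusters[[length(clusters) + 1L]] <- members
          members <- inw
        }
      }
    }
    if (!is.null(members)) clusters[[length(clusters) + 1L]] <- members
    for (cl in clusters) {
      out[[length(out) + 1L]] <- data.frame(
        category = cat, window_start = min(x[cl]), window_end = max(x[cl]),
        supporting_pairs = length(cl), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(category = character(0), window_start = integer(0),
                      window_end = integer(0), supporting_pairs = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$window_start, res$category), , drop = FALSE]
}

# Exact Mann-Whitney two-sided p by full enumeration of group assignments.
oracle_mann_whitney_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  obs <- u_of(seq_len(na))
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2L, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  })
  p_le <- mean(us <= obs)
  p_ge <- mean(us >= obs)
  min(1, 2 * min(p_le, p_ge))
}

# Write a small FASTA file.
write_fasta <- function(name, seq, path = tempfile(fileext = ".fa")) {
  writeLines(c(paste0(">", name), seq), path)
  path
}
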
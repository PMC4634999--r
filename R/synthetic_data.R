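## Generators for every input the pipeline consumes: spiked mosaic read sets,
## paired-end deletion libraries, deep amplicon pools, control panels and
## phenotype cohorts.  All generators are deterministic under a fixed seed.

#' Simulation profile for read generation
#'
#' Bundles the sequencing regime parameters.  Defaults reflect the study
#' conditions: 5,000x mean depth (long-range PCR libraries; hybrid-capture
#' libraries ran at 500x), 50 nt paired-end reads, paired-end outer distance
#' Normal(400, 80), and a per-base substitution error of 0.1%.
#'
#' @param depth Mean reads per position.
#' @param read_length Read length in nt.
#' @param per_base_error Per-base substitution probability (forward reads).
#' @param strand_asymmetry Multiplier applied to the error rate on reverse
#'   reads only; values > 1 create orientation-biased artifacts.
#' @param insert_mu,insert_sigma Paired-end outer-distance distribution.
#' @param base_quality Constant Phred base quality assigned to simulated bases.
#' @param seed Optional integer seed; fixed seed gives byte-identical output.
#' @return A `simulation_profile` list.
#' @export
simulation_profile <- function(depth = 5000, read_length = 50,
                               per_base_error = 0.001, strand_asymmetry = 1,
                               insert_mu = 400, insert_sigma = 80,
                               base_quality = 35, seed = NULL) {
  stopifnot(depth >= 0, read_length >= 1,
            per_base_error >= 0, per_base_error < 0.05,
            strand_asymmetry >= 0, insert_sigma >= 0)
  structure(list(depth = depth, read_length = as.integer(read_length),
                 per_base_error = per_base_error,
                 strand_asymmetry = strand_asymmetry,
                 insert_mu = insert_mu, insert_sigma = insert_sigma,
                 base_quality = as.integer(base_quality), seed = seed),
            class = "simulation_profile")
}

#' Specify a variant to spike into simulated reads
#'
#' @param contig Contig name.
#' @param position 1-based position (anchor base for indels, VCF style).
#' @param ref_allele Reference allele (anchor + deleted bases for deletions).
#' @param alt_allele Alternate allele (anchor + inserted bases for insertions).
#' @param type One of `"SNV"`, `"insertion"`, `"deletion_small"`.
#' @param target_af Target mutant allele fraction in `[0, 1]`.
#' @return A `variant_spec` list.
#' @export
variant_spec <- function(contig, position, ref_allele, alt_allele,
                         type = c("SNV", "insertion", "deletion_small"),
                         target_af) {
  type <- match.arg(type)
  stopifnot(target_af >= 0, target_af <= 1, position >= 1)
  structure(list(contig = contig, position = as.integer(position),
                 ref_allele = toupper(ref_allele),
                 alt_allele = toupper(alt_allele),
                 type = type, target_af = target_af),
            class = "variant_spec")
}

#' Derive a child seed from a run seed and a stage label
#'
#' Deterministic mixing keeps stage RNG streams distinct while staying below
#' 2^31 (R integer range).
#'
#' @param seed Run-level integer seed.
#' @param tag Stage label.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

phred_char <- function(q) intToUtf8(33L + q)

#' Simulate aligned reads with spiked variants
#'
#' Draws read start positions uniformly over the region, assigns orientation
#' Bernoulli(0.5), carries each variant allele with probability `target_af`
#' on reads covering it, and injects independent per-base substitution errors
#' (rate multiplied by `strand_asymmetry` on reverse reads).  Reads are
#' emitted in reference orientation (SAM convention).  Indel carriers get
#' M/I/M or M/D/M CIGARs; all other reads are pure matches.
#'
#' @param reference A `mosaic_reference`.
#' @param variants List of `variant_spec` objects (or a single one), or NULL.
#' @param profile A `simulation_profile`; `profile$seed` fixes the RNG.
#' @param region Optional `c(start, end)` restricting read placement.
#' @param sample_id Sample label stored on each read.
#' @return Alignment data.frame (see [read_alignments()] for the schema).
#' @export
simulate_reads <- function(reference, variants = NULL,
                           profile = simulation_profile(), region = NULL,
                           sample_id = "S1") {
  if (!is.null(profile$seed)) set.seed(profile$seed)
  if (inherits(variants, "variant_spec")) variants <- list(variants)
  rl <- profile$read_length
  ref_len <- nchar(reference$sequence)
  if (is.null(region)) region <- c(1L, ref_len)
  region_len <- region[2L] - region[1L] + 1L
  for (v in variants) {
    if (v$position < 1L || v$position > ref_len) {
      stop("variant outside reference bounds", call. = FALSE)
    }
    if (substr(reference$sequence, v$position,
               v$position + nchar(v$ref_allele) - 1L) != v$ref_allele) {
      stop("variant ref allele does not match reference", call. = FALSE)
    }
  }
  if (rl > region_len) stop("read length exceeds region", call. = FALSE)
  n_reads <- round(profile$depth * region_len / rl)
  if (n_reads == 0L) return(empty_alignments())
  starts <- sample.int(region_len - rl + 1L, n_reads, replace = TRUE) +
    region[1L] - 1L
  orientation <- ifelse(stats::runif(n_reads) < 0.5, "forward", "reverse")
  seqs <- substring(reference$sequence, starts, starts + rl - 1L)
  cigars <- rep(sprintf("%dM", rl), n_reads)

  for (v in variants) {
    covers <- starts <= v$position & starts + rl - 1L >= v$position
    carrier <- covers & stats::runif(n_reads) < v$target_af
    if (!any(carrier)) next
    off <- v$position - starts[carrier] + 1L
    if (v$type == "SNV") {
      s <- seqs[carrier]
      substr(s, off, off) <- v$alt_allele
      seqs[carrier] <- s
    } else if (v$type == "insertion") {
      ins <- substring(v$alt_allele, 2L)
      ok <- off >= 1L & off < rl  # at least one inserted base must fit
      idx <- which(carrier)[ok]; off <- off[ok]
      if (length(idx)) {
        left <- substr(seqs[idx], 1L, off)
        right <- substr(seqs[idx], off + 1L, rl)
        seqs[idx] <- substr(paste0(left, ins, right), 1L, rl)
        n_ins <- pmin(nchar(ins), rl - off)
        n_right <- rl - off - n_ins
        cigars[idx] <- ifelse(
          n_right > 0L, sprintf("%dM%dI%dM", off, n_ins, n_right),
          sprintf("%dM%dI", off, n_ins))
      }
    } else if (v$type == "deletion_small") {
      dlen <- nchar(v$ref_allele) - 1L
      ok <- off >= 1L & off < rl &
        v$position + dlen + (rl - off) <= ref_len
      idx <- which(carrier)[ok]; off <- off[ok]
      if (length(idx)) {
        left <- substr(seqs[idx], 1L, off)
        right <- substring(reference$sequence, v$position + dlen + 1L,
                           v$position + dlen + (rl - off))
        seqs[idx] <- paste0(left, right)
        cigars[idx] <- sprintf("%dM%dD%dM", off, dlen, rl - off)
      }
    }
  }

  err_rate <- ifelse(orientation == "reverse",
                     pmin(profile$per_base_error * profile$strand_asymmetry,
                          0.75),
                     profile$per_base_error)
  n_err <- stats::rbinom(n_reads, rl, err_rate)
  tot <- sum(n_err)
  if (tot > 0L) {
    ridx <- rep.int(seq_len(n_reads), n_err)
    offs <- sample.int(rl, tot, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    # sequential so multiple errors in one read all land
    for (i in seq_along(ridx)) {
      tmp <- seqs[ridx[i]]
      cur <- substr(tmp, offs[i], offs[i])
      substr(tmp, offs[i], offs[i]) <- sample(setdiff(bases, cur), 1L)
      seqs[ridx[i]] <- tmp
    }
  }

  data.frame(
    read_id = sprintf("r%07d", seq_len(n_reads)),
    contig = reference$name,
    start = starts,
    orientation = orientation,
    sequence = seqs,
    qual = strrep(phred_char(profile$base_quality), rl),
    mapq = 60L,
    cigar = cigars,
    insert_size = NA_integer_,
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}

#' Simulate a paired-end library over a mosaic genomic deletion
#'
#' Pair left-most coordinates are drawn uniformly over the region; outer
#' distances are Normal(`insert_mu`, `insert_sigma`).  Among pairs whose
#' fragment spans the deletion start, a `carrier_fraction` subset originates
#' from the deletion-bearing allele and has its observed insert size inflated
#' by the deletion length — so the discordant fraction among
#' breakpoint-spanning pairs estimates the deletion allele fraction.
#'
#' @param reference A `mosaic_reference` (coordinates only; sequences unused).
#' @param del_start,del_end Deleted interval, 1-based inclusive; length must
#'   be at least 1,000 nt.
#' @param n_pairs Number of read pairs.
#' @param carrier_fraction Fraction of breakpoint-spanning pairs from the
#'   deletion allele, in `[0, 1]`.
#' @param profile A `simulation_profile`.
#' @param flank Region extends this far beyond the deletion on each side.
#' @return Data.frame of pairs: `pair_id`, `contig`, `left_start`,
#'   `insert_size` (outer distance, positive on the left mate), `carrier`,
#'   `read_length`.
#' @export
simulate_deletion_library <- function(reference, del_start, del_end, n_pairs,
                                      carrier_fraction,
                                      profile = simulation_profile(depth = 500),
                                      flank = 2000L) {
  if (carrier_fraction < 0 || carrier_fraction > 1) {
    stop("carrier_fraction must be in [0, 1]", call. = FALSE)
  }
  del_len <- del_end - del_start + 1L
  if (del_len < 1000L) stop("deletion must be >= 1,000 nt", call. = FALSE)
  if (!is.null(profile$seed)) set.seed(profile$seed)
  if (n_pairs == 0L) {
    return(data.frame(pair_id = character(0), contig = character(0),
                      left_start = integer(0), insert_size = integer(0),
                      carrier = logical(0), read_length = integer(0),
                      stringsAsFactors = FALSE))
  }
  region_start <- max(1L, del_start - as.integer(flank))
  region_end <- del_end + as.integer(flank)
  left_start <- sample.int(region_end - region_start + 1L, n_pairs,
                           replace = TRUE) + region_start - 1L
  frag_len <- pmax(2L * profile$read_length,
                   as.integer(round(stats::rnorm(n_pairs, profile$insert_mu,
                                                 profile$insert_sigma))))
  spans <- left_start < del_start & left_start + frag_len - 1L >= del_start
  carrier <- spans & stats::runif(n_pairs) < carrier_fraction
  insert_size <- frag_len + ifelse(carrier, del_len, 0L)
  data.frame(
    pair_id = sprintf("p%07d", seq_len(n_pairs)),
    contig = reference$name,
    left_start = left_start,
    insert_size = as.integer(insert_size),
    carrier = carrier,
    read_length = profile$read_length,
    stringsAsFactors = FALSE
  )
}

#' Render a pair library as aligned reads (two SAM records per pair)
#'
#' Sequences are taken from the reference when available; the left mate is
#' forward, the right mate reverse, with SAM-style signed TLEN.
#'
#' @param pairs Pair data.frame from [simulate_deletion_library()].
#' @param reference Optional `mosaic_reference` for sequence content;
#'   placeholder `N` bases are used when the mate falls outside it.
#' @param sample_id Sample label.
#' @return Alignment data.frame with two rows per pair.
#' @export
pairs_to_alignments <- function(pairs, reference = NULL, sample_id = "S1") {
  rl <- if (nrow(pairs)) pairs$read_length[1L] else 50L
  mate_start <- pairs$left_start + pairs$insert_size - rl
  seq_at <- function(pos) {
    if (is.null(reference)) return(strrep("N", rl))
    s <- substring(reference$sequence, pos, pos + rl - 1L)
    ifelse(nchar(s) == rl, s, strrep("N", rl))
  }
  qual <- strrep(phred_char(35L), rl)
  data.frame(
    read_id = rep(pairs$pair_id, 2L),
    contig = rep(pairs$contig, 2L),
    start = c(pairs$left_start, mate_start),
    orientation = rep(c("forward", "reverse"), each = nrow(pairs)),
    sequence = c(seq_at(pairs$left_start), seq_at(mate_start)),
    qual = qual,
    mapq = 60L,
    cigar = sprintf("%dM", rl),
    insert_size = c(pairs$insert_size, -pairs$insert_size),
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}

#' Simulate a deep amplicon read pool
#'
#' Each read derives from the mutant sequence with probability `af` (or from
#' exact counts when `n_mutant` is given), acquires independent per-base
#' substitution errors, and is emitted reverse-complemented with probability
#' one half, as both strands of a sequenced amplicon are observed.
#'
#' @param wt_sequence,mut_sequence Wild-type and mutant amplicon sequences.
#' @param af Mutant fraction in `[0, 1]`; ignored when `n_mutant` is set.
#' @param n_reads Pool size (the study regimes span 1e4 to 1e6).
#' @param per_base_error Per-base substitution probability.
#' @param seed Optional seed.
#' @param n_mutant Optional exact number of mutant-derived reads.
#' @return Character vector of read sequences.
#' @export
simulate_amplicon_pool <- function(wt_sequence, mut_sequence, af, n_reads,
                                   per_base_error = 0.001, seed = NULL,
                                   n_mutant = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_mutant)) {
    if (af < 0 || af > 1) stop("af must be in [0, 1]", call. = FALSE)
    mutant <- stats::runif(n_reads) < af
  } else {
    stopifnot(n_mutant <= n_reads)
    mutant <- rep(c(TRUE, FALSE), c(n_mutant, n_reads - n_mutant))
    mutant <- mutant[sample.int(n_reads)]
  }
  reads <- ifelse(mutant, mut_sequence, wt_sequence)
  if (per_base_error > 0 && n_reads > 0) {
    len <- nchar(reads)
    n_err <- stats::rbinom(n_reads, len, per_base_error)
    for (i in which(n_err > 0L)) {
      offs <- sample.int(len[i], n_err[i], replace = TRUE)
      for (o in offs) {
        cur <- substr(reads[i], o, o)
        substr(reads[i], o, o) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }
  }
  flip <- stats::runif(n_reads) < 0.5
  if (any(flip)) reads[flip] <- reverse_complement(reads[flip])
  reads
}

#' Simulate a control panel of background allele fractions
#'
#' Each control sample's background rate for the variant k-mer is drawn
#' uniformly from `error_rate_range` (the study's panels showed e.g. an
#' average 0.11%, range 0.07-0.16%, across 25 controls) and its observed
#' mutant count is binomial at that rate over `n_reads` reads.
#'
#' @param wt_sequence Wild-type amplicon sequence (recorded for provenance).
#' @param variant_kmer The mutant k-mer being panelled.
#' @param n_controls Number of control samples (default 25).
#' @param error_rate_range Length-2 numeric: background AF range.
#' @param n_reads Reads per control sample.
#' @param seed Optional seed.
#' @return A `control_panel` object (see [control_panel()]).
#' @export
simulate_control_panel <- function(wt_sequence, variant_kmer, n_controls = 25,
                                   error_rate_range = c(0.0007, 0.0016),
                                   n_reads = 100000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rates <- stats::runif(n_controls, error_rate_range[1L], error_rate_range[2L])
  counts <- stats::rbinom(n_controls, n_reads, rates)
  control_panel(counts / n_reads, variant = variant_kmer, n_reads = n_reads)
}

#' Construct a control panel from per-control allele fractions
#'
#' @param afs Numeric vector of per-control background AFs.
#' @param variant Variant key (e.g. the mutant k-mer).
#' @param n_reads Reads per control, if known.
#' @return A `control_panel` list with `afs`, `mean_af`, `min_af`, `max_af`.
#' @export
control_panel <- function(afs, variant = NA_character_, n_reads = NA_integer_) {
  stopifnot(length(afs) >= 1L, all(afs >= 0), all(afs <= 1))
  structure(list(variant = variant, afs = afs, mean_af = mean(afs),
                 min_af = min(afs), max_af = max(afs), n_reads = n_reads),
            class = "control_panel")
}

#' @export
print.control_panel <- function(x, ...) {
  cat(sprintf("<control_panel> n=%d mean AF %.4f%% (range %.4f-%.4f%%)\n",
              length(x$afs), 100 * x$mean_af, 100 * x$min_af, 100 * x$max_af))
  invisible(x)
}

#' Load the packaged 53-subject cohort table
#'
#' Returns the transcription of the study's subject table: mutation status
#' (heterozygous / mosaic / persistent_NMI), gene, mutation notation and
#' type, mutant allele fraction (NA for skin-biopsy-only detections and for
#' subjects with no mutation found), age, sex, and per-organ-system counts of
#' major diagnostic features (kidney and lung merged as one system).
#'
#' @return Data.frame of 53 subject records.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_subjects.tsv", package = "mosaicscan")
  if (!nzchar(path)) stop("fixture not found; is the package installed?",
                          call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  required <- c("subject_id", "status", "gene", "mutation", "mutation_type",
                "af", "age_years", "sex", "skin", "brain", "heart",
                "kidney_lung")
  if (!all(required %in% names(tab))) {
    stop("cohort fixture is missing required columns", call. = FALSE)
  }
  if (nrow(tab) != 53L) {
    stop("cohort fixture corrupted: expected 53 subjects, found ", nrow(tab),
         call. = FALSE)
  }
  if (!all(tab$status %in% c("heterozygous", "mosaic", "persistent_NMI"))) {
    stop("cohort fixture corrupted: unknown status value", call. = FALSE)
  }
  if (!identical(tab$status == "persistent_NMI", tab$gene == "none")) {
    stop("cohort fixture corrupted: status/gene inconsistency", call. = FALSE)
  }
  tab
}

#' Generate a synthetic phenotype cohort
#'
#' Draws per-organ major-feature counts from status-specific distributions:
#' each organ system is involved with a status-dependent probability and, if
#' involved, contributes `1 + Poisson(lambda)` major features.  Defaults are
#' calibrated qualitatively to the packaged cohort table (heterozygous
#' subjects most severely affected, persistent-NMI least).
#'
#' @param n_subjects Cohort size.
#' @param status_mix Named probabilities (or counts) for
#'   heterozygous / mosaic / persistent_NMI.
#' @param seed Optional seed.
#' @param involvement Named list of per-status length-4 involvement
#'   probabilities for (skin, brain, heart, kidney_lung).
#' @param lambda Named per-status Poisson mean for extra features per organ.
#' @return Data.frame shaped like [load_table1_fixture()].
#' @export
generate_cohort <- function(n_subjects = 53,
                            status_mix = c(heterozygous = 19, mosaic = 26,
                                           persistent_NMI = 8),
                            seed = NULL,
                            involvement = list(
                              heterozygous = c(0.95, 0.95, 0.5, 0.55),
                              mosaic = c(0.95, 0.80, 0.35, 0.50),
                              persistent_NMI = c(0.75, 0.90, 0.05, 0.50)),
                            lambda = c(heterozygous = 1.2, mosaic = 0.8,
                                       persistent_NMI = 0.6)) {
  if (!is.null(seed)) set.seed(seed)
  status <- sample(names(status_mix), n_subjects, replace = TRUE,
                   prob = status_mix / sum(status_mix))
  organs <- c("skin", "brain", "heart", "kidney_lung")
  counts <- matrix(0L, n_subjects, 4L, dimnames = list(NULL, organs))
  for (i in seq_len(n_subjects)) {
    p <- involvement[[status[i]]]
    inv <- stats::runif(4L) < p
    counts[i, inv] <- 1L + stats::rpois(sum(inv), lambda[[status[i]]])
  }
  gene <- ifelse(status == "persistent_NMI", "none",
                 ifelse(stats::runif(n_subjects) < 0.82, "TSC2", "TSC1"))
  af <- ifelse(status == "heterozygous", 0.5,
               ifelse(status == "mosaic",
                      exp(stats::runif(n_subjects, log(0.002), log(0.34))),
                      NA_real_))
  af[status == "persistent_NMI"] <- NA_real_
  data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    status = status,
    gene = gene,
    mutation = ifelse(gene == "none", "none", "synthetic"),
    mutation_type = ifelse(gene == "none", "none",
                           sample(c("nonsense", "missense", "indel", "splice",
                                    "large_del"), n_subjects, replace = TRUE)),
    af = af,
    age_years = sample(1:57, n_subjects, replace = TRUE),
    sex = sample(c("F", "M"), n_subjects, replace = TRUE),
    skin = counts[, "skin"], brain = counts[, "brain"],
    heart = counts[, "heart"], kidney_lung = counts[, "kidney_lung"],
    stringsAsFactors = FALSE
  )
}

#' Generate a random reference sequence
#'
#' @param length Sequence length in nt.
#' @param name Contig name.
#' @param seed Optional seed.
#' @return A `mosaic_reference`.
#' @export
random_reference <- function(length, name = "locus", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reference(name, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                        collapse = ""))
}
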
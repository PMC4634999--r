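## File I/O for the formats the pipeline touches: FASTA reference, SAM-subset
## alignments, VCF 4.2 output, BED-like gene models.  All genomic coordinates
## throughout the package are 1-based inclusive; intervals are closed.

#' Read a reference sequence from FASTA
#'
#' Reads the first record of a FASTA file, uppercases it and validates the
#' alphabet.  Each analysis run operates on a single contig, so a multi-record
#' file is accepted with a warning and only the first record is used.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A `mosaic_reference` object: a list with elements `name` (contig
#'   identifier) and `sequence` (uppercase DNA string over A,C,G,T,N).
#' @export
read_reference <- function(path) {
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA: ", conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("FASTA contains no records: ", path, call. = FALSE)
  if (length(set) > 1L) {
    warning("FASTA contains ", length(set), " records; using the first")
  }
  seq <- toupper(as.character(set[[1L]]))
  name <- sub("\\s.*$", "", names(set)[1L])
  reference(name, seq)
}

#' Construct a reference object
#'
#' @param name Contig identifier.
#' @param sequence DNA string; uppercased and restricted to A,C,G,T,N.
#' @return A `mosaic_reference` list.
#' @export
reference <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("reference sequence must be non-empty", call. = FALSE)
  if (grepl("[^ACGTN]", sequence)) {
    stop("reference contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  structure(list(name = name, sequence = sequence), class = "mosaic_reference")
}

#' @export
print.mosaic_reference <- function(x, ...) {
  cat(sprintf("<mosaic_reference> %s (%d nt)\n", x$name, nchar(x$sequence)))
  invisible(x)
}

## Regex for the supported CIGAR subset (M/I/D runs only).
.cigar_ok <- function(cigar) grepl("^([0-9]+[MID])+$", cigar)

## Split a CIGAR into integer lengths and op characters.
parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MID]", cigar))[[1L]]
  list(lens = lens, ops = ops)
}

## Sum of CIGAR run lengths for a set of ops; pure-match CIGARs (the vast
## majority) take a vectorized shortcut.
.cigar_len <- function(cigar, ops) {
  out <- integer(length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  out[simple] <- as.integer(sub("M", "", cigar[simple], fixed = TRUE))
  if (any(!simple)) {
    out[!simple] <- vapply(cigar[!simple], function(cg) {
      p <- parse_cigar(cg)
      sum(p$lens[p$ops %in% ops])
    }, integer(1L), USE.NAMES = FALSE)
  }
  out
}

## Number of query (read) bases a CIGAR consumes: M + I.
cigar_query_length <- function(cigar) .cigar_len(cigar, c("M", "I"))

## Number of reference bases a CIGAR consumes: M + D.
cigar_reference_length <- function(cigar) .cigar_len(cigar, c("M", "D"))

#' Read a SAM-subset alignment file
#'
#' Consumes QNAME, FLAG, RNAME, POS, MAPQ, CIGAR, TLEN, SEQ and QUAL plus an
#' optional `RG:Z:` tag used as the sample label.  Unmapped (0x4), secondary
#' (0x100) and supplementary (0x800) records are dropped.  Reads whose CIGAR
#' uses operations outside M/I/D, or whose CIGAR does not consume exactly the
#' read length, are skipped and counted in the `n_skipped` attribute rather
#' than aborting the run.
#'
#' @param path Path to a plain-text SAM file.
#' @return A data.frame of aligned reads with columns `read_id`, `contig`,
#'   `start`, `orientation` ("forward"/"reverse"), `sequence`, `qual`
#'   (Phred+33 string), `mapq`, `cigar`, `insert_size` (signed TLEN, NA when
#'   unset) and `sample_id`; attribute `n_skipped` counts skipped records.
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(empty_alignments())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) stop("SAM record with fewer than 11 fields", call. = FALSE)
  get <- function(i) vapply(fields, `[[`, character(1L), i)
  flag <- as.integer(get(2L))
  mapped <- bitwAnd(flag, 0x4) == 0L & bitwAnd(flag, 0x100) == 0L &
    bitwAnd(flag, 0x800) == 0L
  cigar <- get(6L)
  seqs <- get(10L)
  cig_valid <- .cigar_ok(cigar)
  cig_valid[cig_valid] <- cigar_query_length(cigar[cig_valid]) ==
    nchar(seqs[cig_valid])
  keep <- mapped & cig_valid
  n_skipped <- sum(mapped & !cig_valid)
  sample_id <- vapply(fields, function(f) {
    rg <- grep("^RG:Z:", f[-(1:11)], value = TRUE)
    if (length(rg)) sub("^RG:Z:", "", rg[1L]) else NA_character_
  }, character(1L))
  tlen <- as.integer(get(9L))
  out <- data.frame(
    read_id = get(1L)[keep],
    contig = get(3L)[keep],
    start = as.integer(get(4L))[keep],
    orientation = ifelse(bitwAnd(flag[keep], 0x10) > 0L, "reverse", "forward"),
    sequence = seqs[keep],
    qual = get(11L)[keep],
    mapq = as.integer(get(5L))[keep],
    cigar = cigar[keep],
    insert_size = ifelse(tlen[keep] == 0L, NA_integer_, tlen[keep]),
    sample_id = sample_id[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_alignments <- function() {
  out <- data.frame(
    read_id = character(0), contig = character(0), start = integer(0),
    orientation = character(0), sequence = character(0), qual = character(0),
    mapq = integer(0), cigar = character(0), insert_size = integer(0),
    sample_id = character(0), stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- 0L
  out
}

#' Write alignments as plain-text SAM
#'
#' Inverse of [read_alignments()] over the consumed field subset; a
#' write-then-read round trip preserves every consumed field.
#'
#' @param reads Alignment data.frame as returned by [read_alignments()] or
#'   the simulators.
#' @param path Output path.
#' @param reference Optional `mosaic_reference` used to emit an `@SQ` header.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(reads, path, reference = NULL) {
  header <- "@HD\tVN:1.6\tSO:unknown"
  if (!is.null(reference)) {
    header <- c(header, sprintf("@SQ\tSN:%s\tLN:%d", reference$name,
                                nchar(reference$sequence)))
  }
  if (nrow(reads) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  paired <- !is.na(reads$insert_size)
  flag <- ifelse(reads$orientation == "reverse", 0x10L, 0L) +
    ifelse(paired, 0x1L + 0x2L, 0L)
  tlen <- ifelse(paired, reads$insert_size, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                 reads$read_id, flag, reads$contig, reads$start, reads$mapq,
                 reads$cigar, ifelse(paired, "=", "*"), 0L, tlen,
                 reads$sequence, reads$qual)
  has_sample <- !is.na(reads$sample_id)
  rec[has_sample] <- paste0(rec[has_sample], "\tRG:Z:",
                            reads$sample_id[has_sample])
  writeLines(c(header, rec), path)
  invisible(path)
}

#' Basic structural validation of an alignment set
#'
#' Checks the invariants every generator and reader must satisfy: positive
#' 1-based starts, sequence/quality length agreement, CIGAR consuming exactly
#' the read length, and a known orientation label.
#'
#' @param reads Alignment data.frame.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_alignments <- function(reads) {
  if (nrow(reads) == 0L) return(invisible(TRUE))
  if (any(reads$start < 1L)) stop("alignment start < 1", call. = FALSE)
  if (!all(reads$orientation %in% c("forward", "reverse"))) {
    stop("unknown orientation label", call. = FALSE)
  }
  if (any(nchar(reads$sequence) != nchar(reads$qual))) {
    stop("sequence and quality lengths differ", call. = FALSE)
  }
  if (!all(.cigar_ok(reads$cigar))) stop("unsupported CIGAR op", call. = FALSE)
  if (any(cigar_query_length(reads$cigar) != nchar(reads$sequence))) {
    stop("CIGAR does not consume the read length", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write variant calls as VCF 4.2
#'
#' SNVs and small indels are written with literal REF/ALT alleles; large
#' deletions (`variant_type == "deletion_large"`) use the symbolic ALT
#' `<DEL>` with `END` and `SVLEN` INFO keys.  Calls are sorted by contig and
#' position before writing.  FILTER is `PASS` or a semicolon-joined subset of
#' `single_orientation`, `panel_recurrent`, `below_threshold`.
#'
#' @param calls Variant call data.frame (see [call_candidates()]); large
#'   deletions additionally carry an `end` column.
#' @param path Output path.
#' @param reference Optional `mosaic_reference` for the `##contig` header.
#' @return `path`, invisibly.
#' @export
write_variant_calls <- function(calls, path, reference = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mosaicscan",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Mutant allele fraction\">",
    "##INFO=<ID=DPF,Number=1,Type=Integer,Description=\"Forward-orientation variant support\">",
    "##INFO=<ID=DPR,Number=1,Type=Integer,Description=\"Reverse-orientation variant support\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth at site\">",
    "##INFO=<ID=TIER,Number=1,Type=String,Description=\"Calling tier (review or sensitive)\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of deletion\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Deletion length\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting read pairs\">",
    "##FILTER=<ID=single_orientation,Description=\"Variant support confined to one read orientation\">",
    "##FILTER=<ID=panel_recurrent,Description=\"Seen as a candidate in multiple samples\">",
    "##FILTER=<ID=below_threshold,Description=\"Below tier AF or read-support threshold\">"
  )
  if (!is.null(reference)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>", reference$name,
                                nchar(reference$sequence)))
  }
  header <- c(header, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (is.null(calls) || nrow(calls) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  calls <- calls[order(calls$contig, calls$position), , drop = FALSE]
  filt <- vapply(seq_len(nrow(calls)), function(i) {
    f <- calls$filters[[i]]
    if (is.null(f) || length(f) == 0L || !nzchar(paste(f, collapse = ""))) {
      "PASS"
    } else paste(f, collapse = ";")
  }, character(1L))
  is_sv <- calls$variant_type == "deletion_large"
  alt <- ifelse(is_sv, "<DEL>", calls$alt)
  info <- sprintf("AF=%s;DPF=%d;DPR=%d;DP=%d;TIER=%s",
                  format(calls$af, digits = 6, scientific = FALSE, trim = TRUE),
                  calls$support_forward, calls$support_reverse,
                  calls$depth_total, calls$tier)
  if (any(is_sv)) {
    svlen <- calls$end[is_sv] - calls$position[is_sv] + 1L
    info[is_sv] <- sprintf("%s;END=%d;SVLEN=-%d;SUPPORT=%d", info[is_sv],
                           calls$end[is_sv], svlen,
                           calls$support_forward[is_sv] +
                             calls$support_reverse[is_sv])
  }
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s", calls$contig, calls$position,
                 calls$ref, alt, filt, info)
  writeLines(c(header, rec), path)
  invisible(path)
}

#' Read a BED-like exon table into a gene model
#'
#' Expects a tab-separated file with columns `contig`, `start`, `end`,
#' `exon_index`, `gene`, `strand` (1-based inclusive coordinates).  Exons are
#' ordered in transcript (5' to 3') order — descending genomic position for
#' minus-strand genes — and cumulative cDNA offsets are computed.
#'
#' @param path Path to the exon table.
#' @return A `gene_model` list: `gene`, `contig`, `strand`, `exons`
#'   (data.frame with `start`, `end` in transcript order) and `cdna_offsets`
#'   (coding-position offset at the start of each exon, first is 0).
#' @export
read_gene_model <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("contig", "start", "end", "exon_index", "gene", "strand")
  if (!all(required %in% names(tab))) {
    stop("gene model must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  gene_model(tab$gene[1L], tab$contig[1L], tab$strand[1L],
             tab$start, tab$end)
}

#' Construct a gene model from exon coordinates
#'
#' @param gene Gene symbol.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends Genomic exon interval bounds, 1-based inclusive.
#' @return A `gene_model` list (see [read_gene_model()]).
#' @export
gene_model <- function(gene, contig, strand, starts, ends) {
  if (!strand %in% c("+", "-")) stop("strand must be + or -", call. = FALSE)
  if (any(ends < starts)) stop("exon end < start", call. = FALSE)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (any(starts[-1L] <= ends[-length(ends)])) {
    stop("overlapping or zero-length-intron exons", call. = FALSE)
  }
  if (strand == "-") { starts <- rev(starts); ends <- rev(ends) }
  lens <- ends - starts + 1L
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  structure(list(
    gene = gene, contig = contig, strand = strand,
    exons = data.frame(start = starts, end = ends),
    cdna_offsets = as.integer(offsets)
  ), class = "gene_model")
}

#' Number of introns in a gene model
#' @param model A `gene_model`.
#' @return Integer count (`n_exons - 1`).
#' @export
n_introns <- function(model) nrow(model$exons) - 1L

## Vectorized reverse complement of character DNA.
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
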
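#' Alignment scoring parameters
#'
#' Semi-global scoring with free soft clipping of read ends: match +1,
#' mismatch -2, gap open -4 plus gap extend -1 per gapped base.  A read
#' whose best placement scores below `min_score_frac x read length` is
#' reported unmapped.  These defaults make junction-crossing reads clip
#' rather than gap, which is the signal the ITD detector consumes.
#'
#' @param match,mismatch,gap_open,gap_ext Score terms (signs as stated).
#' @param min_score_frac Reporting threshold as a fraction of read length.
#' @param seed_k,seed_step Seed k-mer length and sampling stride for the
#'   seeded path on long references.
#' @param full_max_cells References small enough that the full
#'   dynamic-programming matrix stays under this cell count are aligned
#'   exhaustively (no seeding heuristics).  On larger references a read
#'   with no exact seed match is reported unaligned, as in conventional
#'   seeded aligners.
#' @return Object of class `align_params`.
#' @export
align_params <- function(match = 1L, mismatch = -2L, gap_open = -4L,
                         gap_ext = -1L, min_score_frac = 0.6,
                         seed_k = 16L, seed_step = 8L,
                         full_max_cells = 1.5e5) {
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext),
                 min_score_frac = min_score_frac, seed_k = as.integer(seed_k),
                 seed_step = as.integer(seed_step),
                 full_max_cells = full_max_cells),
            class = "align_params")
}

align_batch <- function(seqs, ref, params, both_strands = TRUE,
                        force_full = FALSE) {
  res <- cpp_align_batch(seqs, ref, params$match, params$mismatch,
                         params$gap_open, params$gap_ext,
                         params$seed_k, params$seed_step,
                         if (force_full) Inf else params$full_max_cells,
                         both_strands)
  as.data.frame(res, stringsAsFactors = FALSE)
}

#' Align a single read to a reference sequence
#'
#' Both orientations are tried and the higher-scoring placement kept
#' (forward on ties).  Unaligned read ends become soft clips; the best
#' placement is the maximum-scoring one under the [align_params()] scheme.
#'
#' @param read Read sequence.
#' @param ref Reference sequence.
#' @param params An [align_params()].
#' @param both_strands Try the reverse complement too?
#' @return One-row data frame: `score`, `mapped`, `pos` (1-based leftmost
#'   aligned reference position), `ref_end`, `cigar`, `strand`, `seq`
#'   (reference-oriented), `left_clip`, `right_clip`.
#' @export
align_read <- function(read, ref, params = align_params(), both_strands = TRUE) {
  b <- align_batch(read, ref, params, both_strands)
  mapped <- b$score >= params$min_score_frac * nchar(read)
  clips <- cigar_clips(b$cigar)
  data.frame(score = b$score, mapped = mapped,
             pos = ifelse(mapped, b$ref_start, 0L),
             ref_end = ifelse(mapped, b$ref_end, 0L),
             cigar = ifelse(mapped, b$cigar, "*"),
             strand = b$strand, seq = b$oriented_seq,
             left_clip = ifelse(mapped, clips$left, 0L),
             right_clip = ifelse(mapped, clips$right, 0L),
             stringsAsFactors = FALSE)
}

cigar_clips <- function(cigar) {
  left <- right <- integer(length(cigar))
  hl <- grepl("^\\d+S", cigar)
  left[hl] <- as.integer(sub("^(\\d+)S.*$", "\\1", cigar[hl]))
  hr <- grepl("\\d+S$", cigar)
  right[hr] <- as.integer(sub("^.*?(\\d+)S$", "\\1", cigar[hr]))
  list(left = left, right = right)
}

#' Align simulated read pairs, producing SAM-like alignment records
#'
#' Each mate is aligned independently; mate mapping status, reference and
#' position are then cross-filled.  Pairs where one mate fails the
#' reporting threshold yield the mapped/unmapped discordant class the ITD
#' detector mines.
#'
#' @param reads A [simulate_reads()] result, its `reads` data frame, or a
#'   data frame with `name`, `seq1`, `seq2`.
#' @param ref Reference sequence (character) or a [locus_model()].
#' @param params An [align_params()].
#' @param rname Reference name used in SAM fields.
#' @return Data frame of alignment records (one row per mate) with SAM
#'   columns (`qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `rnext`,
#'   `pnext`, `tlen`, `seq`, `qual`) plus convenience columns (`mate`,
#'   `mapped`, `mate_mapped`, `reverse`, `score`, `ref_end`, `left_clip`,
#'   `right_clip`).
#' @export
align_pairs <- function(reads, ref, params = align_params(), rname = NULL) {
  if (inherits(reads, "itd_simulation")) reads <- reads$reads
  if (inherits(ref, "locus_model")) {
    rname <- rname %||% ref$contig
    ref <- ref$transcript_seq
  }
  rname <- rname %||% "locus"
  if (!all(c("name", "seq1", "seq2") %in% names(reads)))
    stop("`reads` must have columns name, seq1, seq2")
  n <- nrow(reads)
  b <- align_batch(c(reads$seq1, reads$seq2), ref, params)
  len <- nchar(c(reads$seq1, reads$seq2))
  mapped <- b$score >= params$min_score_frac * len
  clips <- cigar_clips(b$cigar)
  mate <- rep(1:2, each = n)
  m1 <- seq_len(n); m2 <- n + m1
  mate_mapped <- c(mapped[m2], mapped[m1])
  mate_pos <- c(b$ref_start[m2], b$ref_start[m1])
  reverse <- b$strand == "-"
  mate_reverse <- c(reverse[m2], reverse[m1])
  flag <- 1L + ifelse(mate == 1L, 64L, 128L) +
    ifelse(mapped, 0L, 4L) + ifelse(mate_mapped, 0L, 8L) +
    ifelse(mapped & reverse, 16L, 0L) + ifelse(mate_mapped & mate_reverse, 32L, 0L)
  out <- data.frame(
    qname = rep(reads$name, 2), mate = mate, flag = flag,
    rname = ifelse(mapped, rname, "*"),
    pos = ifelse(mapped, b$ref_start, 0L), mapq = ifelse(mapped, 60L, 0L),
    cigar = ifelse(mapped, b$cigar, "*"),
    rnext = ifelse(mate_mapped, "=", "*"),
    pnext = ifelse(mate_mapped, mate_pos, 0L), tlen = 0L,
    seq = ifelse(mapped, b$oriented_seq, c(reads$seq1, reads$seq2)),
    qual = strrep("I", len),
    mapped = mapped, mate_mapped = mate_mapped, reverse = reverse,
    score = b$score, ref_end = ifelse(mapped, b$ref_end, 0L),
    left_clip = ifelse(mapped, clips$left, 0L),
    right_clip = ifelse(mapped, clips$right, 0L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write alignment records to a SAM file
#'
#' Emits `@HD`/`@SQ` headers and the eleven mandatory columns.  Flags are
#' restricted to the paired/unmapped/mate-unmapped/strand bits set by
#' [align_pairs()].
#'
#' @param aln Alignment records from [align_pairs()].
#' @param path Output SAM path.
#' @param rname Reference sequence name for the header.
#' @param ref_len Reference sequence length for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, rname, ref_len) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", rname, "\tLN:", ref_len))
  body <- paste(aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq, aln$cigar,
                aln$rnext, aln$pnext, aln$tlen, aln$seq, aln$qual, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignment records from a SAM file
#'
#' Parses via Rsamtools (SAM is converted to BAM with `asBam()` and read
#' back with `scanBam()`), reconstructing the convenience columns the
#' detector uses.
#'
#' @param path SAM file path.
#' @return Alignment record data frame in the [align_pairs()] layout.
#' @export
read_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_sam() needs the Rsamtools package")
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "mrnm", "mpos",
                                        "isize", "seq", "qual"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- x$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  cigar <- ifelse(is.na(x$cigar), "*", x$cigar)
  clips <- cigar_clips(cigar)
  pos <- ifelse(is.na(x$pos), 0L, x$pos)
  data.frame(
    qname = x$qname, mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    flag = flag, rname = ifelse(mapped, as.character(x$rname), "*"),
    pos = pos, mapq = ifelse(is.na(x$mapq), 0L, x$mapq), cigar = cigar,
    rnext = ifelse(is.na(x$mrnm), "*", "="),
    pnext = ifelse(is.na(x$mpos), 0L, x$mpos),
    tlen = ifelse(is.na(x$isize), 0L, x$isize),
    seq = as.character(x$seq), qual = as.character(x$qual),
    mapped = mapped, mate_mapped = bitwAnd(flag, 8L) == 0L,
    reverse = bitwAnd(flag, 16L) > 0L,
    score = NA_integer_,
    ref_end = ifelse(mapped, pos + cigar_ref_span(cigar) - 1L, 0L),
    left_clip = ifelse(mapped, clips$left, 0L),
    right_clip = ifelse(mapped, clips$right, 0L),
    stringsAsFactors = FALSE)
}

# Reference bases consumed by a CIGAR string (M/D ops).
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("\\d+[MIDS]", cg))[[1]]
    n <- as.integer(sub("[MIDS]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(n[op %in% c("M", "D")])
  }, integer(1), USE.NAMES = FALSE)
}
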
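#' Build a transcript locus model
#'
#' A locus model ties together the genomic layout of a transcript (exon
#' intervals on a strand of a contig), its spliced sequence on the coding
#' strand, and the CDS geometry needed to move between genomic, coding-DNA
#' (c.) and protein coordinates.  The motivating use case is a minus-strand
#' gene whose terminal coding exon harbours internal tandem duplications,
#' so minus-strand arithmetic is first-class: exon intervals are listed in
#' transcript order, which for a minus-strand gene means decreasing genomic
#' coordinates.
#'
#' Coordinates are 1-based and inclusive throughout.  `cds_start`/`cds_end`
#' are transcript positions of the first and last CDS base (the stop codon
#' occupies the final three CDS positions); coding-DNA coordinates satisfy
#' `c = t - cds_start + 1` for transcript position `t`.
#'
#' @param contig Contig/chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame (or 2-column matrix) of genomic `start`,`end`
#'   intervals in transcript order.
#' @param cds_start,cds_end Transcript positions of the CDS boundaries.
#' @param transcript_seq Spliced transcript sequence (coding strand).
#' @param protein_seq Optional protein sequence; derived from the CDS when
#'   omitted, and validated against it when supplied.
#' @param utr3_len Length of the modeled 3'-UTR in bases.
#' @return An object of class `locus_model`.
#' @export
locus_model <- function(contig, strand, exons, cds_start, cds_end,
                        transcript_seq, protein_seq = NULL,
                        utr3_len = NULL) {
  stopifnot(is.character(contig), length(contig) == 1L)
  strand <- match.arg(strand, c("+", "-"))
  exons <- as.data.frame(exons)
  if (ncol(exons) < 2) stop("`exons` needs start and end columns")
  names(exons)[1:2] <- c("start", "end")
  exons <- exons[, c("start", "end")]
  if (any(exons$end < exons$start)) stop("exon with end < start")
  n <- nrow(exons)
  if (n > 1) {
    srt <- exons[order(exons$start), ]
    if (any(srt$start[-1] <= srt$end[-n])) stop("exon intervals overlap")
    if (strand == "-" && any(diff(exons$start) >= 0))
      stop("minus-strand exons must be in decreasing genomic order")
    if (strand == "+" && any(diff(exons$start) <= 0))
      stop("plus-strand exons must be in increasing genomic order")
  }
  transcript_seq <- toupper(transcript_seq)
  widths <- exons$end - exons$start + 1
  L <- nchar(transcript_seq)
  if (sum(widths) != L)
    stop("sum of exon widths (", sum(widths), ") != transcript length (", L, ")")
  if (cds_start < 1 || cds_end > L || cds_start >= cds_end)
    stop("CDS boundaries outside transcript")
  cds_len <- cds_end - cds_start + 1
  if (cds_len %% 3 != 0) stop("CDS length not divisible by 3")
  cds <- substr(transcript_seq, cds_start, cds_end)
  aa <- translate_dna(cds)
  if (substr(aa, nchar(aa), nchar(aa)) != "*")
    stop("CDS does not end in a stop codon")
  derived <- substr(aa, 1, nchar(aa) - 1)
  if (grepl("*", derived, fixed = TRUE))
    stop("internal stop codon in CDS")
  if (!is.null(protein_seq) && !identical(toupper(protein_seq), derived))
    stop("supplied protein_seq does not match CDS translation")
  protein_seq <- derived
  if (3L * (nchar(protein_seq) + 1L) != cds_len)
    stop("protein length inconsistent with CDS length")
  utr3_len <- utr3_len %||% (L - cds_end)
  if (utr3_len != L - cds_end)
    stop("utr3_len inconsistent with transcript/CDS geometry")
  structure(list(
    contig = contig, strand = strand, exons = exons,
    cds_start = cds_start, cds_end = cds_end,
    transcript_seq = transcript_seq, protein_seq = protein_seq,
    utr3_len = utr3_len,
    tx_offset = c(0L, cumsum(widths))[seq_len(n)]  # transcript pos before each exon
  ), class = "locus_model")
}

#' @export
print.locus_model <- function(x, ...) {
  cat("locus_model:", x$contig, paste0("(", x$strand, ")"),
      nrow(x$exons), "exon(s),",
      nchar(x$transcript_seq), "nt transcript,",
      nchar(x$protein_seq), "aa protein,",
      x$utr3_len, "nt 3'-UTR\n")
  invisible(x)
}

transcript_length <- function(model) nchar(model$transcript_seq)

cds_length <- function(model) model$cds_end - model$cds_start + 1L

# transcript position <-> genomic position -------------------------------

genomic_to_transcript <- function(model, g) {
  ex <- model$exons
  vapply(g, function(gi) {
    hit <- which(gi >= ex$start & gi <= ex$end)
    if (length(hit) != 1)
      stop("position ", gi, " is intronic or outside the locus")
    as.integer(if (model$strand == "-") model$tx_offset[hit] + (ex$end[hit] - gi) + 1L
               else model$tx_offset[hit] + (gi - ex$start[hit]) + 1L)
  }, integer(1))
}

transcript_to_genomic <- function(model, t) {
  ex <- model$exons
  widths <- ex$end - ex$start + 1L
  vapply(t, function(ti) {
    if (ti < 1 || ti > transcript_length(model))
      stop("transcript position ", ti, " outside transcript")
    hit <- findInterval(ti, cumsum(c(0L, widths)) + 1L)
    off <- as.integer(ti) - model$tx_offset[hit] - 1L
    as.integer(if (model$strand == "-") ex$end[hit] - off else ex$start[hit] + off)
  }, integer(1))
}

#' Convert between genomic and coding-DNA coordinates
#'
#' On the minus strand the per-exon map is affine with slope -1: within one
#' exon, `c = A - (g - g0)` for the exon's anchor pair `(g0, A)`.  Positions
#' past the stop codon (modeled 3'-UTR) are returned as plain coordinates
#' continuing the coding scale.
#'
#' @param model A [locus_model()].
#' @param g Vector of genomic positions (must fall within exons).
#' @param cdna Vector of coding-DNA coordinates.
#' @return Integer vector of converted coordinates.
#' @export
genomic_to_cdna <- function(model, g) {
  genomic_to_transcript(model, g) - model$cds_start + 1L
}

#' @rdname genomic_to_cdna
#' @export
cdna_to_genomic <- function(model, cdna) {
  transcript_to_genomic(model, cdna + model$cds_start - 1L)
}

#' Map a coding-DNA coordinate to its protein residue
#'
#' @param model A [locus_model()].
#' @param cdna Coding-DNA coordinate(s), `c.1` being the first base of the
#'   start codon.
#' @return Data frame with `residue` (1-based index, the stop codon counting
#'   as residue `length(protein) + 1`), `phase` (1..3 within the codon) and
#'   `is_stop`.
#' @export
cdna_to_residue <- function(model, cdna) {
  n_cds <- cds_length(model)
  if (any(cdna < 1 | cdna > n_cds))
    stop("coding coordinate outside the CDS has no residue (UTR position)")
  residue <- as.integer(ceiling(cdna / 3))
  phase <- as.integer((cdna - 1) %% 3 + 1)
  data.frame(residue = residue, phase = phase,
             is_stop = residue == n_cds %/% 3L)
}

# allele specification ----------------------------------------------------

#' Describe an internal tandem duplication allele
#'
#' An allele is a tandem duplication of the coding-DNA interval
#' `[dup_start, dup_end]`, optionally with a short non-templated insertion
#' placed between the two copies (immediately after `dup_end`, i.e. after
#' the first copy).
#'
#' @param dup_start,dup_end Coding-DNA coordinates of the duplicated
#'   segment (1-based inclusive).
#' @param insertion Non-templated junctional insertion sequence, possibly
#'   empty.
#' @return Object of class `itd_allele`.
#' @export
allele_spec <- function(dup_start, dup_end, insertion = "") {
  stopifnot(length(dup_start) == 1, length(dup_end) == 1)
  dup_start <- as.integer(dup_start); dup_end <- as.integer(dup_end)
  if (dup_end < dup_start) stop("dup_end < dup_start")
  insertion <- toupper(insertion)
  if (nchar(insertion) > 0 && !grepl("^[ACGT]+$", insertion))
    stop("insertion must be a DNA string")
  structure(list(dup_start = dup_start, dup_end = dup_end,
                 insertion = insertion,
                 insertion_after = if (nchar(insertion) > 0) dup_end else NA_integer_),
            class = "itd_allele")
}

#' @export
print.itd_allele <- function(x, ...) {
  cat(sprintf("ITD allele: c.%d_%ddup (%d bp)%s\n", x$dup_start, x$dup_end,
              x$dup_end - x$dup_start + 1,
              if (nchar(x$insertion)) paste0(" + ins", x$insertion) else ""))
  invisible(x)
}

allele_total_len <- function(allele) {
  if (is.null(allele)) return(0L)
  allele$dup_end - allele$dup_start + 1L + nchar(allele$insertion)
}

#' Apply an ITD allele to a locus, producing the mutant transcript
#'
#' The duplicated segment appears twice in tandem with the non-templated
#' insertion (if any) between the copies; everything outside the junction is
#' unchanged.  `allele = NULL` returns the wild-type transcript.
#'
#' @param model A [locus_model()].
#' @param allele An [allele_spec()] or `NULL`.
#' @return Mutant transcript sequence (character scalar).
#' @export
apply_allele <- function(model, allele) {
  seq <- model$transcript_seq
  if (is.null(allele)) return(seq)
  stopifnot(inherits(allele, "itd_allele"))
  ta <- allele$dup_start + model$cds_start - 1L
  tb <- allele$dup_end + model$cds_start - 1L
  if (ta < 1 || tb > nchar(seq)) stop("duplication interval outside transcript")
  paste0(substr(seq, 1, tb), allele$insertion, substr(seq, ta, nchar(seq)))
}

# config I/O ---------------------------------------------------------------

#' Read or write a locus model configuration
#'
#' The configuration is a flat YAML file with fields `contig`, `strand`,
#' `exons` (list of `[start, end]` genomic intervals in transcript order),
#' `cds_start`, `cds_end`, `utr3_len` and either an inline `sequence` or a
#' `fasta` path (relative to the config file) holding the transcript
#' sequence.
#'
#' @param path Config file path.
#' @param model A [locus_model()].
#' @param fasta Optional FASTA path; when given, the sequence is written
#'   there instead of inline.
#' @return `load_locus()` returns a validated [locus_model()];
#'   `write_locus()` returns `path` invisibly.
#' @export
load_locus <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("contig", "strand", "exons", "cds_start", "cds_end")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("locus config missing field(s): ", paste(miss, collapse = ", "))
  if (!is.null(cfg$sequence)) {
    seq <- gsub("\\s", "", cfg$sequence)
  } else if (!is.null(cfg$fasta)) {
    fa <- file.path(dirname(path), cfg$fasta)
    seq <- as.character(Biostrings::readDNAStringSet(fa)[[1]])
  } else stop("locus config must provide `sequence` or `fasta`")
  ex <- do.call(rbind, lapply(cfg$exons, function(e) as.integer(e[1:2])))
  locus_model(contig = cfg$contig, strand = cfg$strand,
              exons = data.frame(start = ex[, 1], end = ex[, 2]),
              cds_start = as.integer(cfg$cds_start),
              cds_end = as.integer(cfg$cds_end),
              transcript_seq = seq, utr3_len = cfg$utr3_len)
}

#' @rdname load_locus
#' @export
write_locus <- function(model, path, fasta = NULL) {
  cfg <- list(contig = model$contig, strand = model$strand,
              exons = lapply(seq_len(nrow(model$exons)), function(i)
                c(model$exons$start[i], model$exons$end[i])),
              cds_start = model$cds_start, cds_end = model$cds_end,
              utr3_len = model$utr3_len)
  if (is.null(fasta)) {
    cfg$sequence <- model$transcript_seq
  } else {
    cfg$fasta <- basename(fasta)
    write_locus_fasta(model, file.path(dirname(path), basename(fasta)))
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write the transcript sequence of a locus as FASTA
#'
#' @param model A [locus_model()].
#' @param path Output FASTA path.
#' @param name Sequence name; defaults to the contig name.
#' @export
write_locus_fasta <- function(model, path, name = model$contig) {
  x <- Biostrings::DNAStringSet(model$transcript_seq)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
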
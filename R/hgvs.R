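#' Canonical form of a tandem duplication with junctional insertion
#'
#' Among all `(duplication interval, insertion)` descriptions producing the
#' same mutant sequence `S[1..b] + ins + S[a..n]`, the canonical one first
#' minimises the insertion (bases of the insertion that continue the
#' reference on either side are absorbed into the duplicated interval:
#' maximal templating), then shifts a pure duplication to its
#' transcript-3'-most equivalent position, per the duplication-reporting
#' convention for coding sequences.  Idempotent.
#'
#' @param dup_start,dup_end 1-based interval in `seq` coordinates.
#' @param seq Reference (transcript) sequence.
#' @param insertion Non-templated insertion between the copies.
#' @return List with canonical `dup_start`, `dup_end`, `insertion`.
#' @export
canonical_itd <- function(dup_start, dup_end, seq, insertion = "") {
  a <- as.integer(dup_start); b <- as.integer(dup_end)
  ins <- insertion
  L <- nchar(seq)
  base <- function(i) substr(seq, i, i)
  # absorb insertion bases that are templated off the reference
  repeat {
    n <- nchar(ins)
    if (n > 0 && a > 1 && substr(ins, n, n) == base(a - 1L)) {
      a <- a - 1L; ins <- substr(ins, 1L, n - 1L)
    } else if (n > 0 && b < L && substr(ins, 1L, 1L) == base(b + 1L)) {
      b <- b + 1L; ins <- substr(ins, 2L, n)
    } else break
  }
  # 3'-most representation of a pure duplication
  if (nchar(ins) == 0) {
    while (b < L && base(b + 1L) == base(a)) { a <- a + 1L; b <- b + 1L }
  }
  list(dup_start = a, dup_end = b, insertion = ins)
}

#' @rdname canonical_itd
#' @details `normalize_3prime()` is the interval-only form: it shifts a
#'   pure duplication 3' and returns the interval unchanged otherwise.
#' @export
normalize_3prime <- function(dup_start, dup_end, seq, insertion = "") {
  canonical_itd(dup_start, dup_end, seq, insertion)
}

#' Is a duplication + insertion in frame?
#'
#' @param dup_len Duplicated bases.
#' @param ins_len Non-templated inserted bases.
#' @return `TRUE` iff `(dup_len + ins_len) %% 3 == 0`.
#' @export
check_frame <- function(dup_len, ins_len = 0L) {
  (dup_len + ins_len) %% 3L == 0L
}

fmt_thousands <- function(x) formatC(x, big.mark = ",", format = "d")

#' Annotate an ITD allele with genomic, cDNA and protein descriptions
#'
#' Produces the three linked descriptions of one duplication allele:
#' \itemize{
#'   \item genomic: `"<contig>:<lo>–<hi>"` (1-based inclusive, comma
#'     grouped) plus a machine HGVS `g.<lo>_<hi>dup`;
#'   \item coding DNA: `c.A_Bdup`, with any non-templated junctional
#'     insertion as `c.B_B+1insNNN`;
#'   \item protein: one of the three in-frame patterns -- clean
#'     `p.X#_Y#dup`, insertion `p.X#_Y#insZ+p.A#_B#dup`, or junctional
#'     missense `p.X#Y+p.A#_B#dup` -- or a frameshift status.
#' }
#' The allele is put in canonical form first (see [canonical_itd()]).
#'
#' @param model A [locus_model()].
#' @param allele An [allele_spec()] (cDNA coordinates), or a call row from
#'   [detect_itds()].
#' @return List of class `hgvs_annotation`: `gdna`, `gdna_hgvs`, `cdna`,
#'   `cdna_dup`, `cdna_ins`, `protein`, `protein_status`, plus structured
#'   fields (`dup_start_c`, `dup_end_c`, `insertion`, `in_frame`).
#' @export
annotate_itd <- function(model, allele) {
  if (is.data.frame(allele))
    allele <- allele_spec(allele$dup_start_c, allele$dup_end_c, allele$insertion)
  stopifnot(inherits(allele, "itd_allele"))
  ta <- allele$dup_start + model$cds_start - 1L
  tb <- allele$dup_end + model$cds_start - 1L
  can <- canonical_itd(ta, tb, model$transcript_seq, allele$insertion)
  a_c <- can$dup_start - model$cds_start + 1L
  b_c <- can$dup_end - model$cds_start + 1L
  ins <- can$insertion
  allele <- allele_spec(a_c, b_c, ins)
  g <- sort(cdna_to_genomic(model, c(a_c, b_c)))
  gdna <- paste0(model$contig, ":", fmt_thousands(g[1]), "–",
                 fmt_thousands(g[2]))
  gdna_hgvs <- paste0("g.", g[1], "_", g[2], "dup")
  cdna_dup <- paste0("c.", a_c, "_", b_c, "dup")
  cdna_ins <- if (nchar(ins) > 0)
    paste0("c.", b_c, "_", b_c + 1L, "ins", ins) else ""
  cdna <- if (nchar(cdna_ins)) paste0(cdna_dup, "+", cdna_ins) else cdna_dup
  prot <- annotate_protein(model, allele)
  structure(list(gdna = gdna, gdna_hgvs = gdna_hgvs,
                 cdna = cdna, cdna_dup = cdna_dup, cdna_ins = cdna_ins,
                 protein = prot$text, protein_status = prot$status,
                 dup_start_c = a_c, dup_end_c = b_c, insertion = ins,
                 in_frame = check_frame(b_c - a_c + 1L, nchar(ins))),
            class = "hgvs_annotation")
}

#' @export
print.hgvs_annotation <- function(x, ...) {
  cat(x$gdna, " ", x$cdna, " ",
      if (x$protein_status == "ok") x$protein else paste0("<", x$protein_status, ">"),
      "\n", sep = "")
  invisible(x)
}

#' Protein consequence of an in-frame ITD allele
#'
#' Translates the mutant CDS through to the first in-frame stop (running
#' into the modeled 3'-UTR when the duplication disrupts the stop codon),
#' trims the longest common prefix then suffix against the reference
#' protein to isolate the inserted peptide, and decomposes it as the
#' maximal suffix matching the reference segment ending at the trim point
#' (the duplicated peptide) plus a residual prefix.  An empty residual is
#' a clean duplication; a residual with non-templated nucleotides is
#' reported as a peptide insertion; a single hybrid-codon residual of a
#' pure duplication is reported as a junctional missense.
#'
#' @param model A [locus_model()].
#' @param allele An [allele_spec()].
#' @return List with `status` (`"ok"`, `"frameshift"`, `"no_stop"` or
#'   `"complex"`), `text`, and structured parts.
#' @export
annotate_protein <- function(model, allele) {
  dup_len <- allele$dup_end - allele$dup_start + 1L
  ins_len <- nchar(allele$insertion)
  if (!check_frame(dup_len, ins_len))
    return(list(status = "frameshift", text = NA_character_))
  mut_tx <- apply_allele(model, allele)
  cds_region <- substr(mut_tx, model$cds_start, nchar(mut_tx))
  cds_region <- substr(cds_region, 1L, nchar(cds_region) %/% 3L * 3L)
  aa_full <- translate_dna(cds_region)
  stop_at <- regexpr("*", aa_full, fixed = TRUE)
  if (stop_at < 0) return(list(status = "no_stop", text = NA_character_))
  mut <- substr(aa_full, 1L, stop_at - 1L)
  ref <- model$protein_seq
  mu <- strsplit(mut, "")[[1]]; re <- strsplit(ref, "")[[1]]
  nm <- length(mu); nr <- length(re)
  # longest common prefix
  p <- 0L
  while (p < min(nm, nr) && mu[p + 1L] == re[p + 1L]) p <- p + 1L
  # longest common suffix of the remainders
  s <- 0L
  while (s < min(nm, nr) - p && mu[nm - s] == re[nr - s]) s <- s + 1L
  if (nr - s != p)
    return(list(status = "complex", text = NA_character_))
  inserted <- mu[(p + 1L):(nm - s)]
  if (length(inserted) == 0L)
    return(list(status = "complex", text = NA_character_))
  # maximal suffix of the inserted peptide matching the reference ending at p
  d <- 0L
  while (d < length(inserted) && d < p &&
         inserted[length(inserted) - d] == re[p - d]) d <- d + 1L
  if (d == 0L) return(list(status = "complex", text = NA_character_))
  dup_from <- p - d + 1L; dup_to <- p
  dup_txt <- if (dup_from == dup_to)
    sprintf("p.%s%ddup", re[dup_from], dup_from)
  else
    sprintf("p.%s%d_%s%ddup", re[dup_from], dup_from, re[dup_to], dup_to)
  residual <- inserted[seq_len(length(inserted) - d)]
  if (length(residual) == 0L) {
    return(list(status = "ok", text = dup_txt, pattern = "dup",
                dup_from = dup_from, dup_to = dup_to))
  }
  if (ins_len > 0L) {
    ins_txt <- sprintf("p.%s%d_%s%dins%s", re[p], p, re[p + 1L], p + 1L,
                       paste(residual, collapse = ""))
    return(list(status = "ok", text = paste0(ins_txt, "+", dup_txt),
                pattern = "ins+dup", dup_from = dup_from, dup_to = dup_to,
                inserted = paste(residual, collapse = "")))
  }
  if (length(residual) == 1L && p + 1L <= nr) {
    mis_txt <- sprintf("p.%s%d%s", re[p + 1L], p + 1L, residual)
    return(list(status = "ok", text = paste0(mis_txt, "+", dup_txt),
                pattern = "missense+dup", dup_from = dup_from, dup_to = dup_to,
                missense = residual))
  }
  list(status = "complex", text = NA_character_)
}

#' Append HGVS annotations to a detector call table
#'
#' @param calls Data frame from [detect_itds()].
#' @param model A [locus_model()].
#' @return `calls` with `gdna`, `cdna` and `protein` columns appended.
#' @export
annotate_calls <- function(calls, model) {
  if (nrow(calls) == 0) {
    calls$gdna <- character(0); calls$cdna <- character(0)
    calls$protein <- character(0)
    return(calls)
  }
  ann <- lapply(seq_len(nrow(calls)), function(i)
    annotate_itd(model, calls[i, ]))
  calls$gdna <- vapply(ann, `[[`, "", "gdna")
  calls$cdna <- vapply(ann, `[[`, "", "cdna")
  calls$protein <- vapply(ann, function(a)
    if (a$protein_status == "ok") a$protein else paste0("<", a$protein_status, ">"),
    "")
  calls
}
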
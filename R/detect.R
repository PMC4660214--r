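#' Detection parameters for the ITD caller
#'
#' Defaults: clipped subsequences shorter than 10 bases are ignored, a call
#' needs at least 3 supporting clipped reads, clip-to-reference matches
#' must reach 90% identity within a 500 bp search radius of the clip
#' anchor, and non-templated junctional insertions of up to 12 bases are
#' considered.
#'
#' @param min_clip_len Minimum clipped-segment length harvested.
#' @param min_support Minimum clip-read support for a call.
#' @param min_identity Identity threshold for clip matching.
#' @param radius Search radius (bases) around the clip anchor.
#' @param max_skip Maximum non-templated insertion length considered.
#' @param min_match Minimum matched span of a clip after skipping
#'   insertion bases (shorter than `min_clip_len` so that a clip barely
#'   above the harvest minimum can still resolve its insertion; exactness
#'   requirements scale with span via `min_identity`).
#' @param min_peak_depth Absolute depth floor for discordant coverage peaks.
#' @return Object of class `itd_params`.
#' @export
itd_params <- function(min_clip_len = 10L, min_support = 3L,
                       min_identity = 0.9, radius = 500L, max_skip = 12L,
                       min_match = 6L, min_peak_depth = 3L) {
  structure(list(min_clip_len = as.integer(min_clip_len),
                 min_support = as.integer(min_support),
                 min_identity = min_identity, radius = as.integer(radius),
                 max_skip = as.integer(max_skip),
                 min_match = as.integer(min_match),
                 min_peak_depth = as.integer(min_peak_depth)),
            class = "itd_params")
}

#' Harvest soft-clipped segments from alignment records
#'
#' Emits one segment per terminal soft clip of length at least
#' `min_clip_len` on a mapped record, with the clip side, the anchor
#' (first aligned reference base for left clips, last aligned base for
#' right clips) and the clipped sequence.
#'
#' @param aln Alignment records ([align_pairs()] layout or [read_sam()]).
#' @param region Optional `c(start, end)` reference interval; only
#'   segments anchored inside it are kept.
#' @param min_clip_len Minimum clip length.
#' @return Data frame with `read`, `side`, `anchor`, `seq`, `clip_len`.
#' @export
harvest_softclips <- function(aln, region = NULL, min_clip_len = 10L) {
  m <- aln[aln$mapped, , drop = FALSE]
  out <- list()
  r <- m[m$right_clip >= min_clip_len, , drop = FALSE]
  if (nrow(r))
    out$right <- data.frame(read = r$qname, side = "right", anchor = r$ref_end,
                            seq = substr(r$seq, nchar(r$seq) - r$right_clip + 1L,
                                         nchar(r$seq)),
                            clip_len = r$right_clip, read_seq = r$seq,
                            stringsAsFactors = FALSE)
  l <- m[m$left_clip >= min_clip_len, , drop = FALSE]
  if (nrow(l))
    out$left <- data.frame(read = l$qname, side = "left", anchor = l$pos,
                           seq = substr(l$seq, 1L, l$left_clip),
                           clip_len = l$left_clip, read_seq = l$seq,
                           stringsAsFactors = FALSE)
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read = character(), side = character(), anchor = integer(),
               seq = character(), clip_len = integer(), read_seq = character(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  if (!is.null(region))
    res <- res[res$anchor >= region[1] & res$anchor <= region[2], , drop = FALSE]
  res
}

#' Locally match a clipped segment back to the reference
#'
#' Searches a window of `radius` bases around the clip anchor for the best
#' ungapped placement of the clipped sequence, allowing a short
#' non-templated prefix (right clips) or suffix (left clips) to be skipped
#' -- the skipped bases are the junctional-insertion candidate.  A hit
#' needs at least `min_identity` over the matched span; no-hit is a value,
#' not an error.
#'
#' @param clip_seq Clipped sequence.
#' @param side `"left"` or `"right"`.
#' @param anchor Clip anchor (reference position).
#' @param ref Reference sequence.
#' @param params An [itd_params()].
#' @return List with `hit` (logical) and, for hits, `ref_start`, `ref_end`,
#'   `skip`, `skipped_seq`, `identity`, `matched_len`.
#' @export
match_clip <- function(clip_seq, side, anchor, ref, params = itd_params()) {
  L <- nchar(ref)
  ws <- max(1L, anchor - params$radius)
  we <- min(L, anchor + params$radius)
  window <- substr(ref, ws, we)
  h <- cpp_match_clip(clip_seq, window, identical(side, "right"),
                      params$max_skip, params$min_match, params$min_identity)
  if (!h$found) return(list(hit = FALSE))
  ref_start <- ws + h$offset - 1L
  skipped <- if (h$skip > 0) {
    if (identical(side, "right")) substr(clip_seq, 1L, h$skip)
    else substr(clip_seq, nchar(clip_seq) - h$skip + 1L, nchar(clip_seq))
  } else ""
  list(hit = TRUE, ref_start = ref_start, ref_end = ref_start + h$qlen - 1L,
       skip = h$skip, skipped_seq = skipped, identity = h$identity,
       matched_len = h$qlen)
}

# One candidate (dup_start, dup_end, insertion) in transcript coordinates
# per matched clip, or NULL when the hit lacks the tandem signature.
clip_candidate <- function(clip, hit, ref) {
  if (!hit$hit) return(NULL)
  if (clip$side == "right") {
    a <- hit$ref_start; b <- clip$anchor; ins <- hit$skipped_seq
  } else {
    a <- clip$anchor; b <- hit$ref_end; ins <- hit$skipped_seq
  }
  if (a > b) return(NULL)  # hit downstream of the aligned span: not a tandem dup
  canonical_itd(a, b, ref, ins)
}

#' Reconstruct an ITD call from clipped-read evidence
#'
#' Each matched clip proposes a `(duplication interval, insertion)`
#' candidate; candidates are put in canonical form (minimal insertion,
#' transcript-3'-most junction) and tallied.  The winning candidate needs
#' `min_support` clipped reads.  When several candidates reach support
#' (alignment bistability at repeat-context junctions), the supporting
#' reads are realigned against each candidate's reconstructed mutant
#' haplotype and the best-fitting candidate kept; an exact tie raises an
#' ambiguous-call error listing both.
#'
#' The variant allele fraction is the ratio of junction-clipped reads to
#' reads colinearly spanning the proximal junction with at least
#' `min_clip_len` aligned bases on each side (each allele copy contributes
#' one colinear junction crossing, so the ratio estimates the mutant
#' molecule fraction; it is clamped to `[0, 1]`).
#'
#' @param clips Output of [harvest_softclips()].
#' @param aln Alignment records.
#' @param model A [locus_model()].
#' @param params An [itd_params()].
#' @return One-row data frame (an ITD call) or `NULL` when no candidate
#'   reaches `min_support`.
#' @export
reconstruct_itd <- function(clips, aln, model, params = itd_params()) {
  ref <- model$transcript_seq
  if (nrow(clips) == 0) return(NULL)
  cand <- vector("list", nrow(clips))
  for (i in seq_len(nrow(clips))) {
    hit <- match_clip(clips$seq[i], clips$side[i], clips$anchor[i], ref, params)
    cc <- clip_candidate(clips[i, ], hit, ref)
    if (!is.null(cc)) cand[[i]] <- data.frame(
      read = clips$read[i], side = clips$side[i],
      a = cc$dup_start, b = cc$dup_end, ins = cc$insertion,
      read_seq = clips$read_seq[i],
      stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0) return(NULL)
  key <- paste(cand$a, cand$b, cand$ins, sep = "|")
  support <- vapply(split(cand$read, key), function(r) length(unique(r)), integer(1))
  support <- sort(support, decreasing = TRUE)
  if (support[1] < params$min_support) return(NULL)
  winner <- names(support)[1]
  contested <- names(support)[support >= params$min_support]
  if (length(contested) > 1) {
    # realign the union of supporting reads to each candidate haplotype
    involved <- key %in% contested
    seqs <- unique(cand$read_seq[involved])
    mm_total <- vapply(contested, function(kk) {
      p <- strsplit(kk, "|", fixed = TRUE)[[1]]
      ins_k <- if (length(p) >= 3) p[3] else ""
      mut <- paste0(substr(ref, 1, as.integer(p[2])), ins_k,
                    substr(ref, as.integer(p[1]), nchar(ref)))
      sum(pmax(cpp_score_reads_ungapped(seqs, mut, 16L, 8L), 0L))
    }, numeric(1))
    best <- which(mm_total == min(mm_total))
    if (length(best) > 1)
      stop("irreconcilable junction evidence: candidates ",
           paste(contested[best], collapse = " vs "),
           " fit the supporting reads equally well")
    winner <- contested[best]
  }
  top <- strsplit(winner, "|", fixed = TRUE)[[1]]
  a <- as.integer(top[1]); b <- as.integer(top[2])
  ins <- if (length(top) >= 3) top[3] else ""
  sup_reads <- unique(cand$read[key == winner])

  # VAF: clipped junction reads vs colinear spanners of the proximal junction
  m <- aln[aln$mapped, , drop = FALSE]
  colinear <- m$pos <= b - params$min_clip_len + 1L &
    m$ref_end >= b + params$min_clip_len &
    m$left_clip < params$min_clip_len & m$right_clip < params$min_clip_len
  n_span <- sum(colinear)
  vaf <- if (n_span > 0) min(1, length(sup_reads) / n_span) else NA_real_
  dup_len <- b - a + 1L
  ins_len <- nchar(ins)
  ca <- a - model$cds_start + 1L
  cb <- b - model$cds_start + 1L
  g <- sort(cdna_to_genomic(model, c(ca, cb)))
  data.frame(contig = model$contig,
             dup_start_c = ca, dup_end_c = cb, dup_len = dup_len,
             insertion = ins, ins_len = ins_len,
             g_start = g[1], g_end = g[2],
             clip_support = length(sup_reads), n_span = n_span, vaf = vaf,
             in_frame = check_frame(dup_len, ins_len),
             stringsAsFactors = FALSE)
}

#' Coverage profile of permissively realigned discordant mates
#'
#' Unmapped mates of locus-mapped reads are realigned to the transcript
#' with no reporting threshold (best placement always kept) and their
#' aligned spans piled up.  Over an ITD the pile-up shows a focal coverage
#' increase; the peak is every position whose depth exceeds
#' `median + 3 x MAD` of the profile and the absolute `min_peak_depth`
#' floor.
#'
#' @param aln Alignment records.
#' @param ref Reference sequence (character) or a [locus_model()].
#' @param params An [itd_params()].
#' @param align_par An [align_params()].
#' @param realigned Optional precomputed [realign_discordant()] result.
#' @return List with `depth` (per-position realigned read depth),
#'   `threshold`, `peak` (`c(start, end)` of the widest above-threshold
#'   run, or `NULL`) and `n_reads`.
#' @export
discordant_peak <- function(aln, ref, params = itd_params(),
                            align_par = align_params(), realigned = NULL) {
  if (inherits(ref, "locus_model")) ref <- ref$transcript_seq
  L <- nchar(ref)
  disc <- realigned %||% realign_discordant(aln, ref, align_par)
  depth <- integer(L)
  if (!is.null(disc) && nrow(disc) > 0) {
    for (i in seq_len(nrow(disc))) {
      span <- disc$pos[i]:disc$ref_end[i]
      depth[span] <- depth[span] + 1L
    }
  }
  thr <- max(median(depth) + 3 * mad(depth), params$min_peak_depth)
  above <- depth > thr
  peak <- NULL
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    w <- runs[which.max(r$lengths[runs])]
    peak <- c(starts[w], ends[w])
  }
  list(depth = depth, threshold = thr, peak = peak,
       n_reads = if (is.null(disc)) 0L else nrow(disc))
}

#' Permissively realign unmapped mates of locus-mapped reads
#'
#' The discordant class (one mate mapped, the other unmapped) is enriched
#' for junction-spanning reads whose overhang is too large for the
#' reporting threshold.  Realigning them with no threshold recovers their
#' best placement and terminal soft clips, which the detector folds back
#' into the clip harvest and the coverage-peak profile.
#'
#' @param aln Alignment records.
#' @param ref Reference sequence.
#' @param align_par An [align_params()].
#' @return Data frame of realigned records in the [harvest_softclips()]
#'   layout (only reads with an aligned placement), or `NULL` when there
#'   are no discordant mates.
#' @export
realign_discordant <- function(aln, ref, align_par = align_params()) {
  disc <- aln[!aln$mapped & aln$mate_mapped, , drop = FALSE]
  if (nrow(disc) == 0) return(NULL)
  b <- align_batch(disc$seq, ref, align_par)
  clips <- cigar_clips(b$cigar)
  out <- data.frame(qname = disc$qname, mapped = b$ref_start > 0,
                    pos = b$ref_start, ref_end = b$ref_end,
                    cigar = b$cigar, seq = b$oriented_seq,
                    left_clip = clips$left, right_clip = clips$right,
                    score = b$score, stringsAsFactors = FALSE)
  out[out$mapped, , drop = FALSE]
}

#' Call ITDs from alignment records
#'
#' End-to-end detector: harvest soft clips, match them locally, reconstruct
#' the duplication and junctional insertion, compute the allele fraction,
#' and corroborate with the discordant mate-pair coverage peak (the
#' `discordant_support` column counts realigned discordant mates whose
#' span overlaps the called duplication).
#'
#' Junction-spanning discordant mates are permissively realigned and their
#' soft clips folded into the harvest before reconstruction, mirroring the
#' local realignment of unmapped mates that reveals ITD junctions.
#'
#' @param aln Alignment records from [align_pairs()] or [read_sam()].
#' @param model A [locus_model()].
#' @param params An [itd_params()].
#' @param region Optional reference interval for clip harvesting.
#' @param align_par An [align_params()] for the permissive realignment.
#' @return Data frame of calls (zero rows when nothing reaches support),
#'   with the coverage profile attached as attribute `"profile"`.
#' @export
detect_itds <- function(aln, model, params = itd_params(), region = NULL,
                        align_par = align_params()) {
  disc <- realign_discordant(aln, model$transcript_seq, align_par)
  clips <- harvest_softclips(aln, region = region,
                             min_clip_len = params$min_clip_len)
  if (!is.null(disc))
    clips <- rbind(clips, harvest_softclips(disc, region = region,
                                            min_clip_len = params$min_clip_len))
  call <- reconstruct_itd(clips, aln, model, params)
  prof <- discordant_peak(aln, model, params, align_par, realigned = disc)
  if (is.null(call)) {
    out <- data.frame(contig = character(), dup_start_c = integer(),
                      dup_end_c = integer(), dup_len = integer(),
                      insertion = character(), ins_len = integer(),
                      g_start = integer(), g_end = integer(),
                      clip_support = integer(), n_span = integer(),
                      vaf = numeric(), in_frame = logical(),
                      discordant_support = integer(),
                      stringsAsFactors = FALSE)
  } else {
    ta <- call$dup_start_c + model$cds_start - 1L
    tb <- call$dup_end_c + model$cds_start - 1L
    dsup <- if (is.null(disc)) 0L else
      sum(disc$pos <= tb & disc$ref_end >= ta)
    call$discordant_support <- dsup
    out <- call
  }
  attr(out, "profile") <- prof
  out
}

#' Write ITD calls as TSV or a minimal VCF
#'
#' The VCF encodes each call as an `SVTYPE=DUP:TANDEM` record with the
#' duplicated interval in `END` and any junctional insertion in `INSSEQ`.
#'
#' @param calls Call data frame from [detect_itds()].
#' @param path Output path.
#' @param sample Sample name column/header value.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path, sample = "sample") {
  df <- cbind(sample = sample, calls)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
write_calls_vcf <- function(calls, path, sample = "sample") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Duplication end\">",
           "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"Junctional insertion\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Clip read support\">",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
  rows <- character(0)
  if (nrow(calls) > 0) {
    info <- paste0("SVTYPE=DUP:TANDEM;END=", calls$g_end,
                   ifelse(calls$ins_len > 0, paste0(";INSSEQ=", calls$insertion), ""),
                   ";SUPPORT=", calls$clip_support,
                   ";VAF=", formatC(calls$vaf, digits = 4, format = "f"))
    rows <- paste(calls$contig, calls$g_start, ".", "N", "<DUP:TANDEM>", ".",
                  "PASS", info, sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
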
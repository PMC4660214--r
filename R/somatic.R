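#' Tumour/normal somatic variant filtering
#'
#' Retains a merged tumour+normal variant record iff all four conditions
#' hold, with strict inequalities (boundary equality rejects):
#' variant ratio `> min_ratio`, total tumour coverage `> min_depth`,
#' variant coverage in tumour `> min_alt`, and variant coverage in normal
#' `< max_normal_alt`.  Defaults are ratio 0.05, depth 50, tumour alt 6,
#' normal alt 4.  Records with missing depth fields are rejected
#' record-by-record with a reason rather than failing the run.
#'
#' @param records Data frame with columns `t_depth`, `t_alt`, `n_alt` and
#'   optionally `ratio` (computed as `t_alt / t_depth` when absent).
#' @param min_ratio,min_depth,min_alt,max_normal_alt Thresholds.
#' @return The retained records, with the full decision table (every input
#'   row plus `keep` and `reason`) attached as attribute `"decisions"`
#'   (also available via [somatic_decisions()]).
#' @export
call_somatic <- function(records, min_ratio = 0.05, min_depth = 50,
                         min_alt = 6, max_normal_alt = 4) {
  need <- c("t_depth", "t_alt", "n_alt")
  miss_col <- setdiff(need, names(records))
  if (length(miss_col))
    stop("records lack column(s): ", paste(miss_col, collapse = ", "))
  ratio <- if ("ratio" %in% names(records)) records$ratio
           else records$t_alt / records$t_depth
  missing_fields <- is.na(records$t_depth) | is.na(records$t_alt) |
    is.na(records$n_alt) | is.na(ratio)
  keep <- !missing_fields &
    ratio > min_ratio &
    records$t_depth > min_depth &
    records$t_alt > min_alt &
    records$n_alt < max_normal_alt
  reason <- rep("", nrow(records))
  reason[missing_fields] <- "missing_depth_fields"
  fail <- function(cond, why) {
    upd <- !missing_fields & !cond & reason == ""
    reason[upd] <<- why
  }
  fail(ratio > min_ratio, "ratio_too_low")
  fail(records$t_depth > min_depth, "tumour_depth_too_low")
  fail(records$t_alt > min_alt, "tumour_alt_too_low")
  fail(records$n_alt < max_normal_alt, "normal_alt_too_high")
  decisions <- cbind(records, keep = keep, reason = reason)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "decisions") <- decisions
  out
}

#' @rdname call_somatic
#' @param filtered Result of [call_somatic()].
#' @export
somatic_decisions <- function(filtered) attr(filtered, "decisions")

#' Simulate a random variant-record table
#'
#' Draws depths and alt counts spanning the filter boundaries, for
#' exercising the somatic filter.
#'
#' @param n Number of records.
#' @param seed RNG seed.
#' @return Data frame of variant records.
#' @export
simulate_variant_records <- function(n, seed = 1L) {
  with_seed(seed, {
    t_depth <- sample(10:200, n, replace = TRUE)
    t_alt <- pmin(t_depth, rbinom(n, t_depth, runif(n, 0, 0.5)))
    n_alt <- sample(0:8, n, replace = TRUE)
    data.frame(contig = "chr1", pos = sample.int(1e6, n),
               ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
               alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
               t_depth = t_depth, t_alt = t_alt,
               n_depth = sample(20:150, n, replace = TRUE), n_alt = n_alt,
               ratio = t_alt / t_depth, stringsAsFactors = FALSE)
  })
}

#' Read/write variant record tables
#'
#' TSV is the native interchange format; [write_somatic_vcf()] emits a
#' minimal VCF with tumour/normal `AD:DP` FORMAT fields.
#'
#' @param records Variant record data frame.
#' @param path File path.
#' @return `path` (writers, invisibly) or the record data frame (reader).
#' @export
write_variants_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_variants_tsv
#' @export
write_somatic_vcf <- function(records, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Alt depth\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tFORMAT\tTUMOUR\tNORMAL")
  rows <- paste(records$contig, records$pos, ".", records$ref, records$alt,
                ".", "PASS", "AD:DP",
                paste0(records$t_alt, ":", records$t_depth),
                paste0(records$n_alt, ":",
                       records$n_depth %||% records$t_depth),
                sep = "\t")
  writeLines(c(hdr, if (nrow(records)) rows), path)
  invisible(path)
}
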
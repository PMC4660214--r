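#' Build competing wild-type and mutant reference sequences
#'
#' Reproduces the modified-transcriptome construction used for mutant
#' fraction estimation: the wild-type reference is the terminal portion of
#' the transcript (the last `n_terminal_exons` exons) through the first
#' `utr_prefix_len` bases of the 3'-UTR; the mutant reference is the same
#' region with the ITD bases added.  The two sequences differ only by the
#' duplicated segment plus any junctional insertion.
#'
#' @param model A [locus_model()].
#' @param allele An [allele_spec()] (or [detect_itds()] call row); `NULL`
#'   yields two identical sequences, flagged degenerate.
#' @param n_terminal_exons Number of terminal exons retained (capped at
#'   the exon count of the model).
#' @param utr_prefix_len 3'-UTR prefix length in bases (capped at the
#'   modeled UTR).
#' @return List of class `competing_refs`: `wt`, `mut`, `region`
#'   (transcript interval of the wild-type reference), `degenerate`.
#' @export
build_competing_refs <- function(model, allele, n_terminal_exons = 6L,
                                 utr_prefix_len = 304L) {
  if (is.data.frame(allele))
    allele <- allele_spec(allele$dup_start_c, allele$dup_end_c, allele$insertion)
  n_ex <- nrow(model$exons)
  k <- min(n_terminal_exons, n_ex)
  region_start <- model$tx_offset[n_ex - k + 1L] + 1L
  region_end <- min(model$cds_end + utr_prefix_len, transcript_length(model))
  wt <- substr(model$transcript_seq, region_start, region_end)
  degenerate <- is.null(allele)
  if (!degenerate) {
    ta <- allele$dup_start + model$cds_start - 1L
    tb <- allele$dup_end + model$cds_start - 1L
    if (ta < region_start || tb > region_end)
      stop("ITD lies outside the selected terminal region")
    extra <- allele_total_len(allele)
    mut_tx <- apply_allele(model, allele)
    mut <- substr(mut_tx, region_start, region_end + extra)
  } else {
    mut <- wt
    warning("no allele supplied: competing references are identical")
  }
  structure(list(wt = wt, mut = mut,
                 region = c(region_start, region_end),
                 n_terminal_exons = k, utr_prefix_len = utr_prefix_len,
                 degenerate = degenerate),
            class = "competing_refs")
}

#' Score reads against competing references
#'
#' Each read gets a log-likelihood against each reference: the best
#' ungapped placement (either strand) scores matches at `log(1 - e)` and
#' mismatches at `log(e / 3)` under the substitution error rate `e`.
#' Placements below `min_identity` are incompatible (`-Inf`), so
#' junction-spanning reads are compatible only with the mutant reference
#' while reads entirely within shared sequence score equally on both.
#'
#' @param seqs Character vector of read sequences (mate 1 when `mate2` is
#'   given).
#' @param refs A [build_competing_refs()] result (or list of two
#'   sequences).
#' @param error_rate Assumed per-base substitution rate.
#' @param min_identity Compatibility threshold.
#' @param mate2 Optional mate-2 sequences; the returned matrix is then
#'   per fragment (sum of the two mates' log-likelihoods, so a fragment
#'   is compatible with a reference only if both mates are).
#' @return `n x 2` matrix of log-likelihoods (columns `mut`, `wt`).
#' @export
score_reads_to_refs <- function(seqs, refs, error_rate = 0.005,
                                min_identity = 0.9, mate2 = NULL) {
  two <- if (inherits(refs, "competing_refs")) list(mut = refs$mut, wt = refs$wt)
         else refs
  stopifnot(length(two) == 2)
  score_one <- function(ss) {
    len <- nchar(ss)
    ll <- vapply(two, function(r) {
      mm <- cpp_score_reads_ungapped(ss, r, 16L, 8L)
      out <- (len - mm) * log1p(-error_rate) + mm * log(error_rate / 3)
      out[mm < 0 | (1 - mm / len) < min_identity] <- -Inf
      out
    }, numeric(length(ss)))
    matrix(ll, ncol = 2, dimnames = list(NULL, names(two)))
  }
  ll <- score_one(seqs)
  if (!is.null(mate2)) ll <- ll + score_one(mate2)
  ll
}

#' Expectation-maximization over two competing references
#'
#' Standard mixture EM with effective-length correction.  E-step:
#' fractional assignment of each read proportional to
#' `fraction x likelihood / effective length`; M-step: fractions
#' proportional to expected counts.  Iterates until the largest fraction
#' change drops below `tol`.  The log-likelihood is non-decreasing by the
#' EM guarantee and is recorded per iteration.
#'
#' @param loglik `n x 2` matrix from [score_reads_to_refs()].
#' @param eff_len Effective lengths of the two references (same order as
#'   the columns of `loglik`).
#' @param tol Convergence tolerance on fractions.
#' @param max_iter Iteration cap.
#' @return List of class `quant_result`: `fractions` (read-assignment
#'   fractions, i.e. each reference's share of the expressed reads; named,
#'   sum to 1), `abundance_fractions` (molecule fractions: read fractions
#'   divided by effective length and renormalized, which undoes the
#'   length bias when references differ in length), `expected_counts`,
#'   `loglik_trace`, `iterations`, `converged`, `n_reads`,
#'   `n_incompatible`.
#' @export
em_quantify <- function(loglik, eff_len, tol = 1e-6, max_iter = 1000L) {
  stopifnot(ncol(loglik) == 2, length(eff_len) == 2)
  eff_len <- pmax(eff_len, 1)
  usable <- is.finite(loglik[, 1]) | is.finite(loglik[, 2])
  n_bad <- sum(!usable)
  ll <- loglik[usable, , drop = FALSE]
  n <- nrow(ll)
  if (n == 0) stop("no reads compatible with either reference")
  # per-read scaled likelihood / effective length, stabilised by row max
  mx <- apply(ll, 1, max)
  w <- exp(ll - mx)
  w <- sweep(w, 2, eff_len, "/")
  theta <- c(0.5, 0.5)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    num <- sweep(w, 2, theta, "*")
    rs <- rowSums(num)
    trace <- c(trace, sum(log(rs) + mx))
    gamma <- num / rs
    counts <- colSums(gamma)
    theta_new <- counts / n
    if (max(abs(theta_new - theta)) < tol) {
      theta <- theta_new; converged <- TRUE; break
    }
    theta <- theta_new
    if (it >= max_iter) break
  }
  names(theta) <- colnames(loglik) %||% c("mut", "wt")
  abundance <- (theta / eff_len) / sum(theta / eff_len)
  structure(list(fractions = theta, abundance_fractions = abundance,
                 expected_counts = setNames(colSums(sweep(w, 2, theta, "*") /
                                                      rowSums(sweep(w, 2, theta, "*"))),
                                            names(theta)),
                 loglik_trace = trace, iterations = it, converged = converged,
                 n_reads = n, n_incompatible = n_bad),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("EM quantification: mutant %.4f / wild-type %.4f (%d reads, %d iterations%s)\n",
              x$fractions[1], x$fractions[2], x$n_reads, x$iterations,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Estimate mutant vs wild-type transcript fractions for an ITD
#'
#' Orchestrates [build_competing_refs()], [score_reads_to_refs()] and
#' [em_quantify()].  Effective length of each reference is
#' `length - fragment_mean + 1`, floored at 1.
#'
#' @param model A [locus_model()].
#' @param allele An [allele_spec()] or [detect_itds()] call row.
#' @param reads Character vector of read sequences, or a
#'   [simulate_reads()] result (both mates used, scored independently).
#' @param error_rate Assumed substitution error rate.
#' @param fragment_mean Mean fragment length; the effective length of
#'   each reference is `length - fragment_mean + 1`, floored at 1 (the
#'   standard RSEM-style correction).
#' @param max_iter Iteration cap for the EM.
#' @param eff_len Optional explicit effective lengths (mutant,
#'   wild-type), overriding the `fragment_mean` default.
#' @param ... Passed to [build_competing_refs()].
#' @return A [em_quantify()] result with the references attached as
#'   attribute `"refs"`.
#' @export
quantify_itd <- function(model, allele, reads, error_rate = 0.005,
                         fragment_mean = 300, max_iter = 1000L,
                         eff_len = NULL, ...) {
  if (inherits(reads, "itd_simulation"))
    reads <- c(reads$reads$seq1, reads$reads$seq2)
  refs <- build_competing_refs(model, allele, ...)
  ll <- score_reads_to_refs(reads, refs, error_rate = error_rate)
  eff <- eff_len %||% pmax(c(nchar(refs$mut), nchar(refs$wt)) -
                             fragment_mean + 1, 1)
  res <- em_quantify(ll, eff, max_iter = max_iter)
  attr(res, "refs") <- refs
  res
}
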
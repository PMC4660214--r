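#' Simulation configuration for paired-end read generation
#'
#' Defaults mirror the sequencing design the analysis assumes: 2 x 100 bp
#' paired-end reads, independent per-base substitution errors, and a
#' truncated-normal fragment-length distribution (mean 300, sd 50,
#' resampled while shorter than the read length).
#'
#' `mutant_fraction` is the fraction of transcript molecules carried by the
#' tumour; `sample_state` translates it into a per-fragment haplotype
#' probability: `hemizygous` samples (single allele, X-linked male) express
#' only the mutant within the tumour fraction, `heterozygous` samples mix
#' mutant and wild-type 1:1 within the tumour fraction, and `normal`
#' samples carry no mutant molecules.
#'
#' @param seed Integer RNG seed.
#' @param read_len Read length in bases (paired).
#' @param coverage Fold coverage of the wild-type locus.
#' @param fragment_mean,fragment_sd Fragment-length distribution (bases).
#' @param error_rate Per-base substitution probability.
#' @param mutant_fraction Mutant molecule fraction in `[0, 1]`.
#' @param sample_state `"hemizygous"`, `"heterozygous"` or `"normal"`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, read_len = 100L, coverage = 100,
                       fragment_mean = 300, fragment_sd = 50,
                       error_rate = 0.005, mutant_fraction = 0,
                       sample_state = c("hemizygous", "heterozygous", "normal")) {
  sample_state <- match.arg(sample_state)
  if (mutant_fraction < 0 || mutant_fraction > 1)
    stop("mutant_fraction must be in [0, 1]")
  if (coverage <= 0) stop("coverage must be positive")
  if (fragment_mean < read_len) stop("fragment_mean must be >= read_len")
  structure(list(seed = as.integer(seed), read_len = as.integer(read_len),
                 coverage = coverage, fragment_mean = fragment_mean,
                 fragment_sd = fragment_sd, error_rate = error_rate,
                 mutant_fraction = mutant_fraction, sample_state = sample_state),
            class = "sim_config")
}

#' Generate a random reference locus
#'
#' Draws a random protein of `protein_len` residues (uniform sense codons,
#' ATG start), appends a TGA stop and a random 3'-UTR, and lays the
#' transcript out over `n_exons` genomic exons.  Deterministic given
#' `seed`.
#'
#' @param seed Integer RNG seed.
#' @param protein_len Protein length in residues.
#' @param utr3_len Modeled 3'-UTR length in bases.
#' @param n_exons Number of exons the transcript is split over.
#' @param contig Contig name for the synthetic locus.
#' @param strand `"-"` (default) or `"+"`.
#' @param g_anchor Genomic coordinate of the transcript's first base.
#' @param intron_len Intron size between consecutive exons.
#' @return A [locus_model()].
#' @export
simulate_locus <- function(seed, protein_len = 400L, utr3_len = 300L,
                           n_exons = 1L, contig = "locusSim", strand = "-",
                           g_anchor = 1000000L, intron_len = 500L) {
  if (protein_len < 2) stop("protein_len too short")
  tx <- with_seed(seed, {
    cods <- random_codons(protein_len)
    cods[1] <- "ATG"
    paste0(paste(cods, collapse = ""), "TGA", random_dna(utr3_len))
  })
  L <- nchar(tx)
  cuts <- floor(seq(0, L, length.out = n_exons + 1))
  widths <- diff(cuts)
  if (any(widths < 1)) stop("too many exons for transcript length")
  exons <- data.frame(start = integer(n_exons), end = integer(n_exons))
  if (strand == "-") {
    g_hi <- g_anchor
    for (i in seq_len(n_exons)) {
      exons$end[i] <- g_hi
      exons$start[i] <- g_hi - widths[i] + 1L
      g_hi <- exons$start[i] - intron_len - 1L
    }
  } else {
    g_lo <- g_anchor
    for (i in seq_len(n_exons)) {
      exons$start[i] <- g_lo
      exons$end[i] <- g_lo + widths[i] - 1L
      g_lo <- exons$end[i] + intron_len + 1L
    }
  }
  locus_model(contig = contig, strand = strand, exons = exons,
              cds_start = 1L, cds_end = 3L * (protein_len + 1L),
              transcript_seq = tx, utr3_len = utr3_len)
}

#' Simulate paired-end reads from a locus, with ground truth
#'
#' Each fragment's haplotype is an independent Bernoulli draw with the
#' per-fragment mutant probability implied by `mutant_fraction` and
#' `sample_state` (so the realized mutant read fraction is binomial
#' around it).  Fragment starts are uniform over valid positions, mate 1
#' is the fragment 5' end on the forward strand, mate 2 the reverse
#' complement of its 3' end, and substitution errors are injected
#' independently per base.
#'
#' @param model A [locus_model()].
#' @param allele An [allele_spec()] or `NULL` for an ITD-free sample.
#' @param config A [sim_config()].
#' @return Object of class `itd_simulation`: list with `reads` (data frame
#'   of name, haplotype, mate sequences and fragment coordinates) and
#'   `truth` (allele, per-read haplotype labels, realized and expected
#'   mutant read fractions).
#' @export
simulate_reads <- function(model, allele, config) {
  stopifnot(inherits(config, "sim_config"))
  wt <- model$transcript_seq
  mut <- apply_allele(model, allele)
  rl <- config$read_len
  if (config$fragment_mean < rl) stop("fragment_mean < read_len")
  L_wt <- nchar(wt); L_mut <- nchar(mut)
  n_pairs <- max(1L, round(config$coverage * L_wt / (2 * rl)))
  p0 <- switch(config$sample_state,
               hemizygous = config$mutant_fraction,
               heterozygous = config$mutant_fraction / 2,
               normal = 0)
  if (is.null(allele)) p0 <- 0
  p_mut <- p0

  sim <- with_seed(config$seed, {
    hap <- runif(n_pairs) < p_mut
    frag <- round(rnorm(n_pairs, config$fragment_mean, config$fragment_sd))
    for (it in 1:50) {
      bad <- frag < rl | frag > ifelse(hap, L_mut, L_wt)
      if (!any(bad)) break
      frag[bad] <- round(rnorm(sum(bad), config$fragment_mean, config$fragment_sd))
    }
    frag <- pmin(pmax(frag, rl), ifelse(hap, L_mut, L_wt))
    maxs <- ifelse(hap, L_mut, L_wt) - frag + 1L
    start <- 1L + floor(runif(n_pairs) * maxs)
    src <- ifelse(hap, mut, wt)
    r1 <- substr(src, start, start + rl - 1L)
    r2 <- revcomp_dna(substr(src, start + frag - rl, start + frag - 1L))
    r1 <- inject_errors(r1, config$error_rate)
    r2 <- inject_errors(r2, config$error_rate)
    data.frame(name = sprintf("sim%06d", seq_len(n_pairs)),
               hap = ifelse(hap, "mut", "wt"),
               seq1 = r1, seq2 = r2,
               frag_start = start, frag_len = frag,
               stringsAsFactors = FALSE)
  })
  realized <- mean(sim$hap == "mut")
  structure(list(
    reads = sim,
    truth = list(allele = allele, n_pairs = n_pairs,
                 mutant_fraction = config$mutant_fraction,
                 sample_state = config$sample_state,
                 p_mut = p_mut, realized_fraction = realized),
    config = config,
    locus = list(contig = model$contig, length_wt = L_wt, length_mut = L_mut)
  ), class = "itd_simulation")
}

# Independent per-base substitutions at rate `rate`; quality calibration,
# indel errors and PCR duplicates are out of scope.
inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  rl <- nchar(seqs)
  n_err <- rbinom(length(seqs), rl, rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(rl[i], n_err[i])
    s <- seqs[i]
    for (p in pos) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(bases, cur), 1)
    }
    seqs[i] <- s
  }
  seqs
}

#' Write simulated reads as a FASTQ pair
#'
#' Four-line records with `/1` and `/2` mate suffixes and constant quality
#' strings.
#'
#' @param sim An [simulate_reads()] result (or its `reads` data frame).
#' @param prefix Output path prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq <- function(sim, prefix) {
  reads <- if (inherits(sim, "itd_simulation")) sim$reads else sim
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    seqs <- reads[[paste0("seq", m)]]
    rec <- paste0("@", reads$name, "/", m, "\n", seqs, "\n+\n",
                  strrep("I", nchar(seqs)))
    writeLines(rec, paths[m])
  }
  invisible(paths)
}

#' Read a FASTQ pair back into a read table
#'
#' @param path1,path2 FASTQ paths for mates 1 and 2.
#' @return Data frame with `name`, `seq1`, `seq2`.
#' @export
read_fastq_pair <- function(path1, path2) {
  rd <- function(p) {
    x <- readLines(p)
    data.frame(name = sub("^@", "", sub("/[12]$", "", x[seq(1, length(x), 4)])),
               seq = x[seq(2, length(x), 4)], stringsAsFactors = FALSE)
  }
  a <- rd(path1); b <- rd(path2)
  if (!identical(a$name, b$name)) stop("mate names differ between files")
  data.frame(name = a$name, seq1 = a$seq, seq2 = b$seq, stringsAsFactors = FALSE)
}

#' Tabulate tumour/normal variant records from simulation truth
#'
#' Produces the merged tumour+normal record the somatic filter consumes,
#' with depths supplied by the caller and alt depths consistent with the
#' simulation truth (a somatic truth has zero alt reads in the normal).
#'
#' @param sim An [simulate_reads()] result.
#' @param model The [locus_model()] the simulation used.
#' @param tumour_depth,normal_depth Total depths for the two samples.
#' @param somatic Is the variant somatic (absent from the normal)?
#' @return One-row data frame of a variant record.
#' @export
write_variant_table <- function(sim, model, tumour_depth, normal_depth,
                                somatic = TRUE) {
  if (tumour_depth < 0 || normal_depth < 0) stop("depths must be non-negative")
  allele <- sim$truth$allele
  if (is.null(allele)) stop("simulation has no ITD allele")
  g <- sort(cdna_to_genomic(model, c(allele$dup_start, allele$dup_end)))
  t_alt <- round(sim$truth$realized_fraction * tumour_depth)
  n_alt <- if (somatic) 0L else round(sim$truth$realized_fraction * normal_depth)
  data.frame(contig = model$contig, pos = g[1],
             ref = "N", alt = "<DUP:TANDEM>",
             t_depth = as.integer(tumour_depth), t_alt = as.integer(t_alt),
             n_depth = as.integer(normal_depth), n_alt = as.integer(n_alt),
             ratio = t_alt / tumour_depth, stringsAsFactors = FALSE)
}
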
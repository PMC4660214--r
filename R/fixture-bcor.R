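#' Synthetic BCOR-like locus fixture
#'
#' Builds a deterministic synthetic stand-in for a BCOR-like minus-strand
#' transcript: a 1,755-residue protein (5,268 coding bases ending in a TGA
#' stop) followed by a 304-base modeled 3'-UTR, split over eight exons
#' with the entire ITD-bearing region inside the terminal exon.  The
#' terminal exon is anchored so that coding
#' position c.5171 sits at chrX:39,911,459 (i.e. `g + c = 39,916,630` on
#' the minus strand), which reproduces the published breakpoint arithmetic
#' of all recurrent ITD types at this locus.
#'
#' The true mRNA sequence of the gene is not bundled; the bulk of the
#' sequence is random codons under a fixed internal seed, with a small set
#' of codons pinned so that the locus behaves like the real one where it
#' matters for annotation:
#' \itemize{
#'   \item the residues named by the recurrent ITD annotations are present
#'     (V1701, D1712, L1713, E1722, L1724, L1737, G1738, V1741, E1742,
#'     D1752, P1753, W1755) and the stop codon is TGA;
#'   \item the hybrid junction codons created by each duplication type
#'     translate as observed (e.g. the type-I breakpoint at the second base
#'     of the stop codon turns TGA into TTA, leucine);
#'   \item the published duplication intervals are already in canonical
#'     (transcript-3'-most, minimal-insertion) form.
#' }
#'
#' @return A [locus_model()] on contig `"chrX"`, minus strand.
#' @export
synthetic_bcor_locus <- function() {
  n_res <- 1755L
  codons <- with_seed(20151117L, {
    cods <- random_codons(n_res)
    utr <- random_dna(304L)
    list(cods = cods, utr = utr)
  })
  cods <- codons$cods
  pin <- c(
    "1"    = "ATG",  # start codon
    "1700" = "AAA",  # K: stops dup over-extension of the 114-bp type
    "1701" = "GTT",  # V1701
    "1711" = "AGC",  # S: stops dup over-extension of the 90-bp type
    "1712" = "GAT",  # D1712; hybrid codon of the 90-bp type is also GAT
    "1713" = "CTA",  # L1713; hybrid TTA of the 87-bp+ins type is leucine
    "1722" = "GAA",  # E1722
    "1724" = "CTA",  # L1724; type-I hybrid T+TA = TTA leucine (stop-loss)
    "1737" = "CTG",  # L1737
    "1738" = "GGC",  # G1738
    "1741" = "GTG",  # V1741
    "1742" = "GAA",  # E1742
    "1752" = "GAT",  # D1752
    "1753" = "CCT",  # P: stops prefix extension of the 93-bp type
    "1755" = "TGG"   # W1755
  )
  cods[as.integer(names(pin))] <- pin
  cds <- paste0(paste(cods, collapse = ""), "TGA")
  tx <- paste0(cds, codons$utr)
  # eight exons: transcript 1..4000 split over seven upstream exons,
  # 4001..5572 in the terminal exon (which carries the whole ITD region)
  w <- c(572L, 572L, 572L, 571L, 571L, 571L, 571L)
  ends <- starts <- integer(7)
  g_hi <- 39924999L
  for (i in 1:7) {
    ends[i] <- g_hi
    starts[i] <- g_hi - w[i] + 1L
    g_hi <- starts[i] - 801L
  }
  exons <- data.frame(start = c(starts, 39911058L),
                      end   = c(ends, 39912629L))
  model <- locus_model(contig = "chrX", strand = "-", exons = exons,
                       cds_start = 1L, cds_end = 5268L,
                       transcript_seq = tx, utr3_len = 304L)
  stopifnot(cdna_to_genomic(model, 5171L) == 39911459L,
            substr(tx, 5266, 5268) == "TGA")
  model
}
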
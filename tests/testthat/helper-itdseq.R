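# Shared fixtures and independent oracles for the test suite.

# The published recurrent ITD table for the BCOR-like locus: genomic
# interval (1-based inclusive), expected span, cDNA and protein strings,
# and the junctional insertion of the type-IV allele.
itd_table <- data.frame(
  sample = c("347T", "383T", "385T", "380T", "382T", "384T", "474T",
             "499T", "501T", "504T", "624T"),
  len = c(96L, 96L, 87L, 93L, 90L, 96L, 93L, 96L, 93L, 114L, 96L),
  g_lo = c(39911364, 39911364, 39911406, 39911374, 39911405, 39911364,
           39911374, 39911364, 39911374, 39911418, 39911364),
  g_hi = c(39911459, 39911459, 39911492, 39911466, 39911494, 39911459,
           39911466, 39911459, 39911466, 39911531, 39911459),
  cdna = c("c.5171_5266dup", "c.5171_5266dup", "c.5138_5224dup",
           "c.5164_5256dup", "c.5136_5225dup", "c.5171_5266dup",
           "c.5164_5256dup", "c.5171_5266dup", "c.5164_5256dup",
           "c.5099_5212dup", "c.5171_5266dup"),
  protein = c("p.L1724_W1755dup", "p.L1724_W1755dup",
              "p.V1741_E1742insV+p.L1713_V1741dup",
              "p.E1722_D1752dup", "p.D1712_V1741dup", "p.L1724_W1755dup",
              "p.E1722_D1752dup", "p.L1724_W1755dup", "p.E1722_D1752dup",
              "p.G1738E+p.V1701_L1737dup", "p.L1724_W1755dup"),
  insertion = c("", "", "TGT", "", "", "", "", "", "", "", ""),
  stringsAsFactors = FALSE)

# Session-cached loci (construction is deterministic).
.cache <- new.env(parent = emptyenv())
bcor_fixture <- function() {
  if (is.null(.cache$bcor)) .cache$bcor <- synthetic_bcor_locus()
  .cache$bcor
}
small_locus <- function(seed = 7, protein_len = 170, utr3_len = 90) {
  key <- paste0("loc", seed, "_", protein_len, "_", utr3_len)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- simulate_locus(seed, protein_len = protein_len,
                                    utr3_len = utr3_len)
  .cache[[key]]
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Independent brute-force local alignment oracle (Gotoh recurrences in
# plain R, written without reference to the package's C++ code).
oracle_local_score <- function(q, r, match = 1, mismatch = -2,
                               gap_open = -4, gap_ext = -1) {
  qq <- strsplit(q, "")[[1]]; rr <- strsplit(r, "")[[1]]
  m <- length(qq); n <- length(rr)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(E[i, j - 1] + gap_ext, H[i, j - 1] + gap_open + gap_ext)
      F[i, j] <- max(F[i - 1, j] + gap_ext, H[i - 1, j] + gap_open + gap_ext)
      s <- H[i - 1, j - 1] + if (qq[i - 1] == rr[j - 1]) match else mismatch
      H[i, j] <- max(0, s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Brute-force 3'-most equivalent representation of a duplication (+ins):
# enumerate every (a', b', ins') with the same junction structure whose
# mutant sequence is identical, preferring minimal insertion then the
# 3'-most interval.
oracle_canonical <- function(a, b, seq, ins = "") {
  target <- paste0(substr(seq, 1, b), ins, substr(seq, a, nchar(seq)))
  total <- (b - a + 1) + nchar(ins)
  best <- NULL
  L <- nchar(seq)
  for (ilen in 0:nchar(ins)) {
    for (a2 in max(1, a - 12):min(L, a + 12)) {
      b2 <- a2 + (total - ilen) - 1
      if (b2 < a2 || b2 > L) next
      # insertion content is determined by the target sequence
      ins2 <- substr(target, b2 + 1, b2 + ilen)
      cand <- paste0(substr(seq, 1, b2), ins2, substr(seq, a2, L))
      if (identical(cand, target)) {
        if (is.null(best) || ilen < best$ilen ||
            (ilen == best$ilen && b2 > best$b)) {
          best <- list(a = a2, b = b2, ins = ins2, ilen = ilen)
        }
      }
    }
  }
  best
}

# Random in-frame ITD allele within the CDS of a locus.
random_inframe_allele <- function(model, dup_range = 30:150, ins_range = 0:6,
                                  margin = 200L) {
  dup_len <- sample(dup_range, 1)
  ins_len <- sample(ins_range, 1)
  ins_len <- ins_len + (3 - (dup_len + ins_len) %% 3) %% 3
  hi <- model$cds_end - margin - dup_len
  a <- sample(margin:hi, 1)
  ins <- if (ins_len > 0) random_seq(ins_len) else ""
  allele_spec(a, a + dup_len - 1, ins)
}
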
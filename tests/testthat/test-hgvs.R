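test_that("canonical form matches the brute-force enumeration oracle", {
  set.seed(51)
  for (case in 1:50) {
    seq <- random_seq(400)
    a <- sample(100:250, 1)
    b <- a + sample(20:60, 1)
    ins <- if (runif(1) < 0.4) random_seq(sample(1:4, 1)) else ""
    # plant a repeat context in half the cases to force a 3' shift
    if (case %% 2 == 0) {
      k <- sample(1:4, 1)
      substr(seq, b + 1, b + k) <- substr(seq, a, a + k - 1)
    }
    got <- canonical_itd(a, b, seq, ins)
    exp <- oracle_canonical(a, b, seq, ins)
    expect_equal(got$dup_start, exp$a)
    expect_equal(got$dup_end, exp$b)
    expect_equal(got$insertion, exp$ins)
    # same mutant sequence before and after normalization
    mut <- function(x, y, i) paste0(substr(seq, 1, y), i,
                                    substr(seq, x, nchar(seq)))
    expect_identical(mut(got$dup_start, got$dup_end, got$insertion),
                     mut(a, b, ins))
    # idempotence
    again <- canonical_itd(got$dup_start, got$dup_end, seq, got$insertion)
    expect_identical(again, got)
  }
})

test_that("non-repetitive duplications normalize to themselves", {
  seq <- "ACGTTGCAAGGCTTAGCCATGA"
  n <- normalize_3prime(5, 10, seq)
  expect_equal(c(n$dup_start, n$dup_end), c(5, 10))
  # dup abutting a repeat of its leading bases shifts 3': GATTACA over
  # GATT... slides 4 (GAT from the planted repeat, then T from TTTGGG)
  seq2 <- paste0("AAACCC", "GATTACA", "GAT", "TTTGGG")
  n2 <- normalize_3prime(7, 13, seq2)                   # dup = GATTACA
  expect_equal(c(n2$dup_start, n2$dup_end), c(11, 17))
  # same mutant either way
  mut <- function(a, b) paste0(substr(seq2, 1, b), substr(seq2, a, nchar(seq2)))
  expect_identical(mut(11, 17), mut(7, 13))
})

test_that("frame check is the mod-3 rule on dup plus insertion", {
  expect_true(check_frame(96, 0))
  expect_true(check_frame(87, 3))
  expect_false(check_frame(10, 0))
  expect_false(check_frame(96, 1))
})

test_that("all published rows annotate to the printed cDNA and protein strings", {
  m <- bcor_fixture()
  for (i in seq_len(nrow(itd_table))) {
    cd <- sort(genomic_to_cdna(m, c(itd_table$g_lo[i], itd_table$g_hi[i])))
    ann <- annotate_itd(m, allele_spec(cd[1], cd[2], itd_table$insertion[i]))
    expect_equal(ann$cdna_dup, itd_table$cdna[i])
    expect_equal(ann$protein, itd_table$protein[i])
    expect_equal(ann$protein_status, "ok")
    expect_true(ann$in_frame)
    # genomic string matches the printed typography
    expect_equal(ann$gdna,
                 sprintf("chrX:%s–%s",
                         formatC(itd_table$g_lo[i], big.mark = ",", format = "d"),
                         formatC(itd_table$g_hi[i], big.mark = ",", format = "d")))
    if (itd_table$insertion[i] != "")
      expect_equal(ann$cdna_ins, "c.5224_5225insTGT")
  }
})

test_that("emitted descriptions re-apply to the identical mutant sequence", {
  m <- bcor_fixture()
  set.seed(52)
  alleles <- c(
    lapply(seq_len(nrow(itd_table)), function(i) {
      cd <- sort(genomic_to_cdna(m, c(itd_table$g_lo[i], itd_table$g_hi[i])))
      allele_spec(cd[1], cd[2], itd_table$insertion[i])
    }),
    lapply(1:10, function(i) random_inframe_allele(m, margin = 300)))
  for (al in alleles) {
    ann <- annotate_itd(m, al)
    re <- allele_spec(ann$dup_start_c, ann$dup_end_c, ann$insertion)
    expect_identical(apply_allele(m, re), apply_allele(m, al))
  }
})

test_that("whole-codon duplications give clean protein dups of dup/3 residues", {
  m <- small_locus(seed = 33, protein_len = 300, utr3_len = 150)
  set.seed(53)
  for (i in 1:10) {
    n_codons <- sample(10:40, 1)
    start_res <- sample(60:200, 1)
    a <- (start_res - 1L) * 3L + 1L
    al <- allele_spec(a, a + n_codons * 3L - 1L)
    prot <- annotate_protein(m, al)
    expect_equal(prot$status, "ok")
    if (prot$pattern == "dup") {
      expect_equal(prot$dup_to - prot$dup_from + 1L, n_codons)
      # verified against an independent translation of the mutant CDS
      mut_cds <- substr(apply_allele(m, al), 1, m$cds_end + n_codons * 3L)
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(mut_cds)))
      ref_aa <- m$protein_seq
      ins_pep <- substr(aa, prot$dup_from, prot$dup_to + n_codons)
      expect_equal(substr(ins_pep, 1, n_codons),
                   substr(ref_aa, prot$dup_from, prot$dup_to))
    }
  }
})

test_that("frameshift alleles are refused with a frameshift status", {
  m <- bcor_fixture()
  prot <- annotate_protein(m, allele_spec(5171, 5267))
  expect_equal(prot$status, "frameshift")
  expect_true(is.na(prot$text))
  ann <- annotate_itd(m, allele_spec(5171, 5267))
  expect_false(ann$in_frame)
  expect_equal(ann$protein_status, "frameshift")
})

test_that("stop-loss duplications translate through the modeled 3'-UTR", {
  # the 96-bp type breaks the stop codon after its first base; translation
  # must run through the duplicated segment to the relocated stop
  m <- bcor_fixture()
  prot <- annotate_protein(m, allele_spec(5171, 5266))
  expect_equal(prot$status, "ok")
  expect_equal(prot$text, "p.L1724_W1755dup")
})

test_that("annotations append to detector call tables", {
  m <- bcor_fixture()
  sim <- simulate_reads(m, allele_spec(5171, 5266),
                        sim_config(seed = 54, coverage = 60,
                                   mutant_fraction = 1))
  calls <- detect_itds(align_pairs(sim, m), m)
  ann <- annotate_calls(calls, m)
  expect_equal(ann$cdna, "c.5171_5266dup")
  expect_equal(ann$protein, "p.L1724_W1755dup")
  expect_equal(ann$gdna, "chrX:39,911,364–39,911,459")
})
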
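test_that("minus-strand affine map reproduces every published breakpoint pair", {
  m <- bcor_fixture()
  # single anchor pair from the 96-bp type: c.5171 at chrX:39,911,459
  expect_equal(genomic_to_cdna(m, 39911459), 5171L)
  for (i in seq_len(nrow(itd_table))) {
    cd <- sort(genomic_to_cdna(m, c(itd_table$g_lo[i], itd_table$g_hi[i])))
    printed <- as.integer(regmatches(itd_table$cdna[i],
                                     gregexpr("[0-9]+", itd_table$cdna[i]))[[1]])
    expect_equal(cd, printed)
    # genomic span length == cDNA span length == ITD length
    expect_equal(diff(cd) + 1L, itd_table$len[i])
    expect_equal(itd_table$g_hi[i] - itd_table$g_lo[i] + 1, itd_table$len[i])
  }
})

test_that("genomic/cDNA transforms invert on every exonic position", {
  for (model in list(bcor_fixture(),
                     simulate_locus(11, protein_len = 120, n_exons = 3),
                     simulate_locus(12, protein_len = 120, n_exons = 2,
                                    strand = "+"))) {
    g_all <- unlist(lapply(seq_len(nrow(model$exons)), function(i)
      model$exons$start[i]:model$exons$end[i]))
    g_some <- g_all[seq(1, length(g_all), by = 37)]
    expect_equal(cdna_to_genomic(model, genomic_to_cdna(model, g_some)), g_some)
  }
})

test_that("intronic and out-of-locus positions are rejected", {
  m <- simulate_locus(11, protein_len = 120, n_exons = 3)
  intron_pos <- m$exons$start[1] - 5L  # minus strand: intron below exon 1
  expect_error(genomic_to_cdna(m, intron_pos), "intronic|outside")
  expect_error(genomic_to_cdna(m, 1L), "intronic|outside")
})

test_that("cDNA coordinates map to residues by thirds", {
  m <- bcor_fixture()
  expect_equal(unlist(cdna_to_residue(m, 1)[, c("residue", "phase")]),
               c(residue = 1L, phase = 1L))
  r <- cdna_to_residue(m, c(5171, 5136, 5164))
  expect_equal(r$residue, c(1724L, 1712L, 1722L))
  expect_equal(r$phase, c(2L, 3L, 1L))
  expect_error(cdna_to_residue(m, 5269), "UTR|residue")
  # clean-dup residue arithmetic: first dup residue == ceil(start_c / 3)
  for (i in which(itd_table$insertion == "" &
                  !grepl("\\+", itd_table$protein))) {
    start_c <- as.integer(sub("^c\\.(\\d+)_.*$", "\\1", itd_table$cdna[i]))
    first_res <- as.integer(sub("^p\\.[A-Z](\\d+)_.*$", "\\1",
                                itd_table$protein[i]))
    expect_equal(ceiling(start_c / 3), first_res)
  }
})

test_that("applying an allele lengthens the transcript by dup + insertion", {
  m <- bcor_fixture()
  wt <- m$transcript_seq
  mut <- apply_allele(m, allele_spec(5171, 5266))
  expect_equal(nchar(mut), nchar(wt) + 96L)
  # the duplicated segment appears twice in tandem
  seg <- substr(wt, 5171, 5266)
  expect_true(grepl(paste0(seg, seg), mut, fixed = TRUE))
  # insertion lands between the copies
  mut4 <- apply_allele(m, allele_spec(5138, 5224, "TGT"))
  seg4 <- substr(wt, 5138, 5224)
  expect_true(grepl(paste0(seg4, "TGT", substr(wt, 5138, 5150)), mut4,
                    fixed = TRUE))
  expect_identical(apply_allele(m, NULL), wt)
  expect_error(apply_allele(m, allele_spec(5000, 99999)), "outside")
})

test_that("locus construction enforces CDS and exon invariants", {
  m <- bcor_fixture()
  expect_equal(3L * (nchar(m$protein_seq) + 1L), m$cds_end - m$cds_start + 1L)
  expect_equal(m$cds_end - m$cds_start + 1L, 5268L)  # 1755-residue protein
  expect_equal(substr(m$transcript_seq, m$cds_end - 2, m$cds_end), "TGA")
  # truncated exon list: widths no longer match the sequence
  expect_error(locus_model("chr1", "-", m$exons[-1, ], 1, 5268,
                           m$transcript_seq),
               "exon widths")
  # CDS not a multiple of 3
  expect_error(locus_model("chr1", "-", m$exons, 1, 5267,
                           m$transcript_seq), "divisible")
  # overlapping exons
  expect_error(locus_model("chr1", "-",
                           data.frame(start = c(100, 50), end = c(200, 150)),
                           1, 3, paste(rep("ATG", 67), collapse = "")),
               "overlap")
})

test_that("locus config round-trips through YAML (inline and FASTA)", {
  m <- simulate_locus(13, protein_len = 80, n_exons = 2)
  p1 <- file.path(tempdir(), "locus-inline.yaml")
  write_locus(m, p1)
  m1 <- load_locus(p1)
  expect_equal(m1$transcript_seq, m$transcript_seq)
  expect_equal(m1$exons, m$exons)
  expect_equal(m1$cds_end, m$cds_end)
  p2 <- file.path(tempdir(), "locus-fa.yaml")
  write_locus(m, p2, fasta = "locus.fa")
  m2 <- load_locus(p2)
  expect_equal(m2$transcript_seq, m$transcript_seq)
  cfg <- yaml::read_yaml(p1)
  cfg$cds_end <- cfg$cds_end - 3   # stop codon no longer at the CDS end
  yaml::write_yaml(cfg, p1)
  expect_error(load_locus(p1), "stop codon|divisible")
})
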
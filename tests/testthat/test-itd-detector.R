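# A cached type-I-like simulation (96-bp dup, VAF 1, 100x) used by several
# blocks below.
type1_case <- local({
  env <- new.env()
  function() {
    if (is.null(env$x)) {
      m <- small_locus(seed = 31, protein_len = 400, utr3_len = 300)
      al <- allele_spec(600, 695)
      sim <- simulate_reads(m, al, sim_config(seed = 131, coverage = 100,
                                              mutant_fraction = 1))
      aln <- align_pairs(sim, m)
      env$x <- list(m = m, al = al, sim = sim, aln = aln)
    }
    env$x
  }
})

test_that("soft-clip harvest keeps terminal clips above the length floor", {
  x <- type1_case()
  clips <- harvest_softclips(x$aln, min_clip_len = 10)
  expect_true(all(clips$clip_len >= 10))
  expect_true(all(clips$side %in% c("left", "right")))
  # clips cluster at the two junction sides (within the microhomology
  # slack the aligner may consume at the junction)
  anchors <- sort(unique(clips$anchor[clips$clip_len >= 15]))
  expect_true(all(abs(anchors - 600) <= 3 | abs(anchors - 695) <= 3))
  expect_true(any(abs(anchors - 600) <= 3) && any(abs(anchors - 695) <= 3))
  # impossible floor empties the harvest
  expect_equal(nrow(harvest_softclips(x$aln, min_clip_len = 101L)), 0L)
  # region filter
  reg <- harvest_softclips(x$aln, region = c(1, 300), min_clip_len = 10)
  expect_equal(nrow(reg), 0L)
})

test_that("ITD-free samples yield no harvestable clips and no calls", {
  m <- small_locus(seed = 32, protein_len = 400, utr3_len = 300)
  sim <- simulate_reads(m, NULL, sim_config(seed = 132, coverage = 100,
                                            error_rate = 0.005))
  aln <- align_pairs(sim, m)
  expect_equal(nrow(harvest_softclips(aln, min_clip_len = 10)), 0L)
  calls <- detect_itds(aln, m)
  expect_equal(nrow(calls), 0L)
  expect_null(attr(calls, "profile")$peak)
})

test_that("clip matching finds templated hits and rejects noise", {
  set.seed(45)
  m <- small_locus(seed = 31, protein_len = 400, utr3_len = 300)
  ref <- m$transcript_seq
  # verbatim reference substring: perfect hit at the source
  clip <- substr(ref, 500, 529)
  h <- match_clip(clip, "right", 700, ref)
  expect_true(h$hit)
  expect_equal(h$ref_start, 500)
  expect_equal(h$identity, 1.0)
  # clip from a junction read hits INSIDE the aligned span, upstream of
  # the right-clip anchor: the tandem-duplication signature
  mut <- apply_allele(m, allele_spec(600, 695))
  jclip <- substr(mut, 696, 725)   # first 30 bases after the junction
  hj <- match_clip(jclip, "right", 695, ref)
  expect_true(hj$hit)
  expect_equal(hj$ref_start, 600)
  expect_lt(hj$ref_start, 695)
  # random clip: no hit at the identity threshold
  hits <- vapply(1:20, function(i)
    match_clip(random_seq(30), "right", 700, ref)$hit, logical(1))
  expect_false(any(hits))
})

test_that("type-I reconstruction recovers interval, frame and allele fraction", {
  x <- type1_case()
  calls <- detect_itds(x$aln, x$m)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$dup_start_c, 600L)
  expect_equal(calls$dup_end_c, 695L)
  expect_equal(calls$dup_len, 96L)
  expect_equal(calls$insertion, "")
  expect_true(calls$in_frame)
  expect_gte(calls$clip_support, 3L)
  # hemizygous pure-mutant sample: wild-type virtually undetectable
  expect_gte(calls$vaf, 0.95)
})

test_that("junctional insertions are reconstructed between the copies", {
  m <- small_locus(seed = 31, protein_len = 400, utr3_len = 300)
  al <- allele_spec(650, 736, "TGT")  # 87-bp dup + 3-bp insertion
  sim <- simulate_reads(m, al, sim_config(seed = 133, coverage = 100,
                                          mutant_fraction = 1))
  calls <- detect_itds(align_pairs(sim, m), m)
  truth <- canonical_itd(650, 736, m$transcript_seq, "TGT")
  expect_equal(calls$dup_start_c, truth$dup_start)
  expect_equal(calls$dup_end_c, truth$dup_end)
  expect_equal(calls$insertion, truth$insertion)
  expect_equal(calls$dup_len + calls$ins_len, 90L)
  expect_true(calls$in_frame)
})

test_that("in-frame flag equals the mod-3 rule, including frameshift alleles", {
  m <- small_locus(seed = 31, protein_len = 400, utr3_len = 300)
  al <- allele_spec(600, 699)  # 100 bp: frameshift
  sim <- simulate_reads(m, al, sim_config(seed = 134, coverage = 100,
                                          mutant_fraction = 1))
  calls <- detect_itds(align_pairs(sim, m), m)
  expect_equal(nrow(calls), 1L)
  expect_false(calls$in_frame)
  expect_equal(calls$in_frame,
               (calls$dup_len + calls$ins_len) %% 3 == 0)
})

test_that("discordant coverage peak overlaps the duplication and scales with fraction", {
  x <- type1_case()
  prof <- attr(detect_itds(x$aln, x$m), "profile")
  expect_false(is.null(prof$peak))
  expect_true(prof$peak[1] <= 695 && prof$peak[2] >= 600)
  expect_true(all(prof$depth >= 0))
  heights <- vapply(c(0.2, 0.5, 1.0), function(f) {
    sim <- simulate_reads(x$m, x$al, sim_config(seed = 135, coverage = 100,
                                                mutant_fraction = f))
    p <- discordant_peak(align_pairs(sim, x$m), x$m)
    max(p$depth)
  }, 0)
  expect_true(all(diff(heights) > 0))
})

test_that("calls export to TSV and minimal tandem-duplication VCF", {
  x <- type1_case()
  calls <- detect_itds(x$aln, x$m)
  tsv <- file.path(tempdir(), "calls.tsv")
  vcf <- file.path(tempdir(), "calls.vcf")
  write_calls_tsv(calls, tsv, sample = "s1")
  back <- read.delim(tsv)
  expect_equal(back$dup_len, calls$dup_len)
  write_calls_vcf(calls, vcf, sample = "s1")
  lines <- readLines(vcf)
  expect_true(any(grepl("^##fileformat=VCF", lines)))
  body <- lines[!grepl("^#", lines)]
  expect_length(body, 1L)
  expect_true(grepl("SVTYPE=DUP:TANDEM", body))
})
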
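make_catalog <- function() {
  reference_catalog(c(Chr1 = 100000, ChrM = 10000, ChrC = 5000))
}

# minimal alignment-row constructor for verdict tests
mk_read <- function(rname = "Chr1", start = 1000L, end = 1100L, strand = "+",
                    mapq = 42L, tlen = 120L, paired = TRUE, proper = TRUE,
                    dup = FALSE, secondary = FALSE, supp = FALSE,
                    qc_fail = FALSE, unmapped = FALSE) {
  tibble::tibble(
    qname = "r", rname = rname, start = start, end = end, strand = strand,
    mapq = mapq, template_length = tlen, aligned_length = end - start,
    query_length = 100L, gc_count = 40L, paired = paired,
    proper_pair = proper, unmapped = unmapped, mate_unmapped = FALSE,
    reverse = strand == "-", first_in_pair = TRUE, secondary = secondary,
    qc_fail = qc_fail, duplicate = dup, supplementary = supp)
}

test_that("fragment length is |TLEN| for proper pairs and undefined otherwise", {
  reads <- dplyr::bind_rows(
    mk_read(tlen = -180L),
    mk_read(paired = FALSE, tlen = 0L),
    mk_read(proper = FALSE, tlen = 200L),
    mk_read(tlen = 0L))
  expect_equal(nominal_fragment_length(reads), c(180, NA, NA, NA))
})

test_that("verdicts accumulate every applicable failure reason in order", {
  cat <- make_catalog()
  ok <- evaluate_reads(mk_read(), qc_criteria(), cat)
  expect_true(ok$passed)
  expect_equal(ok$fail_reasons, "")

  mito <- evaluate_reads(mk_read(rname = "ChrM"), qc_criteria(), cat)
  expect_false(mito$passed)
  expect_equal(mito$fail_reasons, "organellar")
  expect_equal(as.character(mito$category), "mitochondrial")

  both <- evaluate_reads(
    mk_read(mapq = 10L, tlen = 300L),
    qc_criteria(min_mapq = 40, max_fragment = 150), cat)
  expect_equal(both$fail_reasons, "low_mapq,fragment_long")

  dup_sec <- evaluate_reads(mk_read(dup = TRUE, secondary = TRUE),
                            qc_criteria(), cat)
  expect_equal(dup_sec$fail_reasons, "secondary,duplicate")
})

test_that("a single base pair of blacklist overlap fails a read", {
  cat <- make_catalog()
  bl <- tibble::tibble(rname = "Chr1", start = 1099L, end = 1200L, strand = "*")
  hit <- evaluate_reads(mk_read(start = 1000L, end = 1100L),
                        qc_criteria(blacklist = bl), cat)
  expect_equal(hit$fail_reasons, "blacklisted")
  miss <- evaluate_reads(mk_read(start = 1000L, end = 1099L),
                         qc_criteria(blacklist = bl), cat)
  expect_true(miss$passed)
})

test_that("single-end reads skip pairing and fragment filters", {
  cat <- make_catalog()
  se <- mk_read(paired = FALSE, proper = FALSE, tlen = 0L)
  v <- evaluate_reads(se, qc_criteria(min_fragment = 50, max_fragment = 150), cat)
  expect_true(v$passed)
})

test_that("mode presets set documented thresholds without clobbering user flags", {
  expect_equal(qc_criteria(mode = "nfr")$max_fragment, 120)
  mono <- qc_criteria(mode = "mono")
  expect_equal(c(mono$min_fragment, mono$max_fragment), c(150, 250))

  # explicit user values survive the preset
  custom <- qc_criteria(max_fragment = 100, mode = "nfr")
  expect_equal(custom$max_fragment, 100)

  base <- qc_criteria(min_mapq = 30)
  expect_identical(apply_preset("default", base), base)
  expect_error(apply_preset("nucfree", base), "valid modes")

  chip <- qc_criteria(mode = "chip")
  expect_false(chip$tn5_shift)
  expect_true(is.na(chip$resize))
  expect_equal(chip$anchor_role, "peak_center")
  fp <- qc_criteria(mode = "footprint")
  expect_true(fp$tn5_shift && fp$footprint)
  expect_equal(fp$resize, 1L)
})

test_that("use_all dominates: passing equals mapped primary non-supplementary", {
  fx <- clean_fixture()
  catalog <- reference_catalog(fx$bam)
  reads <- read_alignments(fx$bam)
  ev <- evaluate_reads(reads, qc_criteria(use_all = TRUE), catalog)
  expect_equal(sum(ev$passed),
               sum(!reads$unmapped & !reads$secondary & !reads$supplementary))
})

test_that("every read lands in exactly one category and counts partition the stream", {
  fx <- cached_fixture("organellar",
                       preset_fixtures(n_fragments = 2000L)$organellar_heavy)
  catalog <- reference_catalog(fx$bam)
  reads <- read_alignments(fx$bam)
  ev <- evaluate_reads(reads, qc_criteria(), catalog)
  expect_false(anyNA(ev$category))
  expect_equal(sum(table(ev$category)), nrow(reads))
  expect_equal(as.vector(table(ev$category)),
               as.vector(table(factor(fx$truth$category,
                                      levels = levels(ev$category)))))
})

test_that("tightening any threshold never increases the passing count", {
  fx <- clean_fixture()
  catalog <- reference_catalog(fx$bam)
  reads <- read_alignments(fx$bam)
  set.seed(11)
  for (i in 1:100) {
    mapq <- sample(0:40, 1)
    lo <- sample(0:80, 1)
    hi <- sample(120:400, 1)
    base <- qc_criteria(min_mapq = mapq, min_fragment = lo, max_fragment = hi)
    which_dim <- sample(3, 1)
    tighter <- switch(which_dim,
      qc_criteria(min_mapq = min(mapq + sample(1:10, 1), 255),
                  min_fragment = lo, max_fragment = hi),
      qc_criteria(min_mapq = mapq, min_fragment = lo + sample(1:40, 1),
                  max_fragment = hi),
      qc_criteria(min_mapq = mapq, min_fragment = lo,
                  max_fragment = max(lo, hi - sample(1:100, 1))))
    n_base <- sum(evaluate_reads(reads, base, catalog)$passed)
    n_tight <- sum(evaluate_reads(reads, tighter, catalog)$passed)
    expect_lte(n_tight, n_base)
  }
})

test_that("filtering a restricted stream equals restricting the filtered set", {
  fx <- small_fixture()
  catalog <- reference_catalog(fx$bam)
  crit <- qc_criteria(min_fragment = 80, max_fragment = 200)
  window <- tibble::tibble(rname = "Chr1", start = 20000L, end = 120000L)

  restricted <- evaluate_reads(read_alignments(fx$bam, restrict = window),
                               crit, catalog)
  full <- evaluate_reads(read_alignments(fx$bam), crit, catalog)
  in_window <- full$rname == "Chr1" & full$start < 120000L & full$end > 20000L
  expect_equal(sum(restricted$passed), sum(full$passed & in_window))
})
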
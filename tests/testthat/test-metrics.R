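test_that("depth events reproduce hand-countable coverage", {
  one <- depth_from_events(list(starts = 100, ends = 200), 1000)
  expect_equal(one$hist, c("1" = 100))
  expect_equal(one$zero, 900)

  two <- depth_from_events(list(starts = c(100, 150), ends = c(200, 250)), 1000)
  expect_equal(two$hist, c("1" = 100, "2" = 50))
  expect_equal(two$covered, 150)

  none <- depth_from_events(list(starts = numeric(0), ends = numeric(0)), 500)
  expect_equal(none$covered, 0)
  expect_equal(none$zero, 500)
})

test_that("event-based depth equals naive per-base counting on random inputs", {
  set.seed(101)
  for (i in 1:20) {
    ref_len <- sample(10000:100000, 1)
    n <- sample(50:500, 1)
    starts <- sample(0:(ref_len - 200), n, replace = TRUE)
    ends <- starts + sample(30:200, n, replace = TRUE)
    ends <- pmin(ends, ref_len)
    fast <- depth_from_events(list(starts = starts, ends = ends), ref_len)
    slow <- naive_depth_hist(starts, ends, ref_len)
    expect_equal(fast$hist, slow$hist)
    expect_equal(fast$covered, slow$covered)
    expect_equal(fast$zero, slow$zero)
    # depth conservation: sum(d * bases at d) = total aligned bases
    expect_equal(sum(as.numeric(names(fast$hist)) * fast$hist),
                 sum(ends - starts))
  }
})

test_that("summary statistics come straight off the histogram", {
  s <- hist_stats(c(10, 20, 30), c(1, 2, 1))
  expect_equal(s$mean, 20)
  expect_equal(s$median, 20)
  expect_equal(s$sd, sd(c(10, 20, 20, 30)))
  expect_equal(c(s$min, s$max), c(10, 30))

  # lower-bin convention for even masses
  expect_equal(hist_stats(c(1, 2, 3, 4), c(1, 1, 1, 1))$median, 2)

  empty <- hist_stats(numeric(0), numeric(0))
  expect_true(all(is.na(c(empty$mean, empty$sd, empty$median))))
})

test_that("category totals and passing counts match the generator truth table", {
  fx <- clean_fixture()
  rep <- qc_run(fx$bam, tss = fx$beds$tss, peaks = fx$beds$peaks)
  ts <- truth_summary(fx$truth)
  expect_equal(rep$counts$total, as.vector(ts$category_counts))
  expect_equal(rep$summary$n_passing, ts$n_passing)
  expect_equal(sum(rep$histograms$fragment_length$count), ts$fragment_mass)
  expect_equal(rep$frip, ts$frip)
})

test_that("two identical runs produce identical results modulo the timestamp", {
  fx <- small_fixture()
  r1 <- qc_run(fx$bam)
  r2 <- qc_run(fx$bam)
  r1$timestamp <- r2$timestamp <- "T"
  expect_identical(r1, r2)
})

test_that("an empty BAM yields an all-zero report with null statistics", {
  rep <- qc_run(empty_bam())
  expect_equal(rep$summary$total_reads, 0)
  expect_equal(rep$summary$n_passing, 0)
  expect_true(all(vapply(rep$stats, function(s) is.na(s$mean), TRUE)))
  expect_true(is.na(rep$periodicity$period))
  expect_equal(rep$coverage$bases_covered, 0)
})

test_that("constructed uniform coverage gives exact fraction and mean depth", {
  # tile a 10 kb nuclear genome end-to-end at depth 2
  dir <- file.path(tempdir(), "uniform2x")
  dir.create(dir, showWarnings = FALSE)
  sam <- file.path(dir, "u.sam")
  starts <- seq(0L, 9900L, by = 100L)
  recs <- unlist(lapply(starts, function(s) {
    sprintf("r%d_%d\t0\tChr1\t%d\t42\t100M\t*\t0\t0\t%s\t%s",
            s, 1:2, s + 1L, strrep("A", 100), strrep("I", 100))
  }))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:Chr1\tLN:10000", recs), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "u"), overwrite = TRUE,
                          indexDestination = TRUE)
  rep <- qc_run(bam, criteria = qc_criteria(require_proper_pair = FALSE))
  expect_equal(rep$coverage$fraction, 1.0)
  expect_equal(rep$coverage$mean_depth, 2.0)
})

test_that("category percentages use the stated denominators and sum to 100", {
  fx <- cached_fixture("organellar",
                       preset_fixtures(n_fragments = 2000L)$organellar_heavy)
  rep <- qc_run(fx$bam)
  expect_equal(sum(rep$counts$pct_of_total), 100, tolerance = 1e-9)
  expect_equal(rep$counts$pct_of_total,
               100 * rep$counts$total / rep$summary$total_reads)
  # an organellar-heavy sample reports its contamination level exactly
  mito_pct <- rep$counts$pct_of_total[rep$counts$category == "mitochondrial"]
  expect_equal(mito_pct, 100 * mean(fx$truth$category == "mitochondrial"))
})

test_that("a blacklist shrinks the effective genome for coverage", {
  fx <- small_fixture()
  bl <- tibble::tibble(rname = "Chr1", start = 0L, end = 50000L, strand = "*")
  plain <- qc_run(fx$bam)
  masked <- qc_run(fx$bam, criteria = qc_criteria(blacklist = bl))
  expect_equal(masked$coverage$effective_genome,
               plain$coverage$effective_genome - 50000)
})
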
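test_that("JSON round-trips every numeric field exactly", {
  fx <- clean_fixture()
  rep <- qc_run(fx$bam, tss = fx$beds$tss, peaks = fx$beds$peaks)
  path <- tempfile(fileext = ".json")
  write_report_json(rep, path)
  doc <- read_report_json(path)
  expect_equal(doc$schema_version, "1.0")
  s <- doc$samples[[1]]
  expect_identical(as.numeric(s$summary$n_passing),
                   as.numeric(rep$summary$n_passing))
  expect_identical(s$frip, rep$frip)
  expect_identical(s$tes, rep$tes)
  expect_identical(as.numeric(s$histograms$fragment_length$count),
                   rep$histograms$fragment_length$count)
  expect_identical(as.numeric(s$tss_pileup$density),
                   unname(as.numeric(rep$tss_pileup$values)))
  expect_identical(s$coverage$fraction, rep$coverage$fraction)
})

test_that("multi-sample JSON preserves order; nullable analytics are explicit nulls", {
  fx <- small_fixture()
  r1 <- qc_run(fx$bam, sample = "a")
  r2 <- qc_run(empty_bam(), sample = "b")
  path <- tempfile(fileext = ".json")
  write_report_json(list(r1, r2), path)
  doc <- read_report_json(path)
  expect_length(doc$samples, 2L)
  expect_equal(vapply(doc$samples, `[[`, "", "sample"), c("a", "b"))
  # no TSS/peaks given: analytics serialized as null, fields present
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  s1 <- raw$samples[[1]]
  expect_true(all(c("frip", "tes", "tss_pileup", "footprint", "grid")
                  %in% names(s1)))
  expect_null(s1$frip)
  expect_null(s1$tss_pileup)
})

test_that("JSON output is byte-identical across runs except the timestamp", {
  fx <- small_fixture()
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_report_json(qc_run(fx$bam), p1)
  write_report_json(qc_run(fx$bam), p2)
  strip <- function(p) grep("timestamp", readLines(p), value = TRUE,
                            invert = TRUE)
  expect_identical(strip(p1), strip(p2))
})

test_that("the text report states counts consistent with the JSON", {
  fx <- cached_fixture("organellar",
                       preset_fixtures(n_fragments = 2000L)$organellar_heavy)
  rep <- qc_run(fx$bam)
  txt <- report_text(rep)
  cat_rows <- grep("^  (nuclear|mitochondrial|plastid)", txt, value = TRUE)
  totals <- as.numeric(vapply(strsplit(trimws(cat_rows), " +"), `[[`, "", 2))
  expect_equal(sum(totals), rep$summary$total_reads)
  expect_true(any(grepl("TSS enrichment: n/a \\(no TSS file provided\\)", txt)))
  expect_true(any(grepl(sprintf("n = %d passing", rep$summary$n_passing), txt)))
})

test_that("a grid table in the report renders one row per combination", {
  fx <- small_fixture()
  tss <- tibble::tibble(rname = "Chr1", start = 50000L, end = 50001L,
                        strand = "+")
  rep <- qc_run(fx$bam, tss = tss)
  rep$grid <- parameter_grid_search(fx$bam, min_mapq = c(0, 40),
                                    min_fragment = 10,
                                    max_fragment = c(150, 250), tss = tss)
  txt <- report_text(rep)
  header_at <- grep("parameter grid \\(4 combinations\\)", txt)
  expect_length(header_at, 1L)
  expect_equal(length(txt) - header_at - 1L, 4L)
})

test_that("merged reports keep samples distinct and metrics comparable", {
  fx <- clean_fixture()
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  p3 <- tempfile(fileext = ".json")
  write_report_json(qc_run(fx$bam, sample = "s1"), p1)
  write_report_json(qc_run(fx$bam, criteria = qc_criteria(use_all = TRUE),
                           sample = "s2"), p2)
  write_report_json(qc_run(empty_bam(), sample = "s3"), p3)
  cmp <- merge_reports(c(p1, p2, p3))
  expect_setequal(unique(cmp$metrics$sample), c("s1", "s2", "s3"))
  expect_false(any(duplicated(cmp$metrics[c("sample", "metric")])))

  wide <- tidyr::pivot_wider(cmp$metrics, names_from = "sample",
                             values_from = "value")
  tot <- wide[wide$metric == "total_reads", ]
  pas <- wide[wide$metric == "n_passing", ]
  expect_equal(tot$s1, tot$s2)      # same BAM: identical totals
  expect_gt(pas$s2, pas$s1)         # use-all passes strictly more reads

  single <- merge_reports(p1)
  expect_equal(nrow(single$metrics),
               nrow(cmp$metrics[cmp$metrics$sample == "s1", ]))
})

test_that("schema violations name the offending file", {
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(schema_version = "99",
                            samples = list(list(sample = "x"))),
                       bad, auto_unbox = TRUE)
  expect_error(merge_reports(bad), basename(bad))
})

test_that("tidy and glance expose the report as tibbles", {
  fx <- clean_fixture()
  rep <- qc_run(fx$bam, tss = fx$beds$tss, peaks = fx$beds$peaks)
  td <- tidy(rep)
  expect_true(all(c("metric", "value") %in% names(td)))
  expect_equal(td$value[td$metric == "tes"], rep$tes)
  g <- glance(rep)
  expect_equal(nrow(g), 1L)
  expect_equal(g$n_passing, rep$summary$n_passing)
  expect_s3_class(autoplot(rep, "fragment"), "ggplot")
  expect_s3_class(plot_tss_pileup(rep), "ggplot")
})
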
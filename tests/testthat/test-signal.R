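test_that("5' resizing and Tn5 shifting follow the +4/-5 convention", {
  plus <- tibble::tibble(rname = "Chr1", start = 100L, end = 200L, strand = "+")
  minus <- tibble::tibble(rname = "Chr1", start = 100L, end = 200L, strand = "-")

  e1 <- effective_intervals(plus, resize = 1, tn5 = FALSE)
  expect_equal(c(e1$start, e1$end), c(100L, 101L))

  # minus-strand 5' base is 199; shifted by -5 to 194
  e2 <- effective_intervals(minus, resize = 1, tn5 = TRUE)
  expect_equal(c(e2$start, e2$end), c(194L, 195L))

  # plus-strand 5' base 100 shifted to 104; even width left-biased by one
  e3 <- effective_intervals(plus, resize = 100, tn5 = TRUE)
  expect_equal(c(e3$start, e3$end), c(54L, 154L))
  expect_equal(e3$end - e3$start, 100L)

  e4 <- effective_intervals(plus, resize = 5, tn5 = FALSE)
  expect_equal(c(e4$start, e4$end), c(98L, 103L))

  # NA resize keeps the raw alignment footprint (ChIP mode)
  e5 <- effective_intervals(plus, resize = NA)
  expect_equal(c(e5$start, e5$end), c(100L, 200L))

  # clipping to the reference
  cat <- reference_catalog(c(Chr1 = 150))
  e6 <- effective_intervals(plus, resize = 200, tn5 = FALSE, catalog = cat)
  expect_equal(c(e6$start, e6$end), c(0L, 150L))
})

test_that("a single-base interval at the anchor is a delta at position 0", {
  anchors <- tibble::tibble(rname = "Chr1", start = 500L, end = 501L, strand = "+")
  iv <- tibble::tibble(rname = "Chr1", start = 500L, end = 501L, strand = "+")
  p <- pileup_profile(iv, anchors, radius = 10)
  expect_equal(unname(p$values[11]), 1)
  expect_equal(sum(p$values), 1)
  expect_equal(length(p$values), 21L)
})

test_that("flipping every anchor strand reverses the profile exactly", {
  set.seed(3)
  anchors <- tibble::tibble(rname = "Chr1",
                            start = seq(2000L, 20000L, by = 2000L),
                            end = seq(2000L, 20000L, by = 2000L) + 1L,
                            strand = "+")
  iv <- tibble::tibble(rname = "Chr1",
                       start = sample(0:21000, 800, replace = TRUE))
  iv$end <- iv$start + sample(20:80, 800, replace = TRUE)
  iv$strand <- sample(c("+", "-"), 800, replace = TRUE)
  fwd <- pileup_profile(iv, anchors, radius = 300)
  flipped <- anchors
  flipped$strand <- "-"
  rev_prof <- pileup_profile(iv, flipped, radius = 300)
  expect_equal(unname(rev_prof$values), rev(unname(fwd$values)))
})

test_that("pileup mass is conserved: mean density times anchors = window events", {
  set.seed(4)
  anchors <- tibble::tibble(rname = "Chr1", start = c(5000L, 9000L),
                            end = c(5001L, 9001L), strand = "+")
  iv <- tibble::tibble(rname = "Chr1",
                       start = sample(4000:10000, 300, replace = TRUE))
  iv$end <- iv$start + 50L
  iv$strand <- "+"
  radius <- 400L
  p <- pileup_profile(iv, anchors, radius = radius)
  naive <- 0
  for (a in c(5000L, 9000L)) {
    for (j in seq_len(nrow(iv))) {
      naive <- naive + max(0, min(iv$end[j], a + radius + 1L) -
                                max(iv$start[j], a - radius))
    }
  }
  expect_equal(sum(p$values) * p$n_anchors, naive)
})

test_that("TSS enrichment is exactly 1 on flat profiles and scale-invariant", {
  flat <- structure(list(values = stats::setNames(rep(3.7, 2001), -1000:1000),
                         n_anchors = 10L, radius = 1000L, role = "tss",
                         resize = 1L, tn5_shifted = TRUE), class = "qc_pileup")
  expect_equal(tss_enrichment_score(flat), 1.0)

  # central plateau at 8 over flat flanks at 1 scores exactly 8
  v <- rep(1, 2001); v[801:1201] <- 8
  plateau <- structure(list(values = stats::setNames(v, -1000:1000),
                            n_anchors = 10L, radius = 1000L, role = "tss",
                            resize = 1L, tn5_shifted = TRUE),
                       class = "qc_pileup")
  expect_equal(tss_enrichment_score(plateau), 8.0)

  scaled <- plateau
  scaled$values <- plateau$values * 17.3
  expect_equal(tss_enrichment_score(scaled), 8.0)

  zero <- flat
  zero$values[] <- 0
  expect_true(is.na(tss_enrichment_score(zero)))
  expect_error(tss_enrichment_score(structure(list(
    values = stats::setNames(rep(1, 11), -5:5)), class = "qc_pileup")),
    "radius too small")
})

test_that("FRiP hits its boundary cases exactly and grows with the peak set", {
  fx <- small_fixture()
  catalog <- reference_catalog(fx$bam)
  ev <- evaluate_reads(read_alignments(fx$bam), qc_criteria(), catalog)

  genome_wide <- tibble::tibble(rname = catalog$name, start = 0L,
                                end = catalog$length, strand = "*")
  expect_equal(frip(ev, genome_wide), 1.0)

  # peaks on a reference with no passing reads (organellar never passes)
  off <- tibble::tibble(rname = "ChrM", start = 0L, end = 1000L, strand = "*")
  expect_equal(frip(ev, off), 0.0)

  half <- tibble::tibble(rname = "Chr1", start = 0L, end = 100000L, strand = "*")
  f_half <- frip(ev, half)
  expect_gte(f_half, 0); expect_lte(f_half, 1)
  expect_gte(frip(ev, genome_wide), f_half)

  none <- ev[ev$passed & FALSE, ]
  expect_warning(expect_true(is.na(frip(none, half))), "no passing reads")
})

test_that("a protected footprint site shows a central insertion trough", {
  fx <- cached_fixture("footprint",
                       preset_fixtures(n_fragments = 6000L)$footprint)
  catalog <- reference_catalog(fx$bam)
  ev <- evaluate_reads(read_alignments(fx$bam), qc_criteria(), catalog)
  prof <- footprint_profile(ev[ev$passed, ], fx$beds$sites, radius = 100,
                            catalog = catalog)
  v <- prof$values
  center <- v[as.integer(names(v)) >= -10 & as.integer(names(v)) <= 10]
  shoulders <- v[abs(as.integer(names(v))) > 30]
  expect_equal(sum(center), 0)
  expect_gt(mean(shoulders), 0)
})

test_that("both mates of one fragment register single-base insertions", {
  # one proper pair: plus mate [100,150), minus mate [250,300), TLEN 200
  reads <- tibble::tibble(
    qname = "f", rname = "Chr1", start = c(100L, 250L), end = c(150L, 300L),
    strand = c("+", "-"), mapq = 42L, template_length = c(200L, -200L),
    aligned_length = 50L, query_length = 50L, gc_count = 20L,
    paired = TRUE, proper_pair = TRUE, unmapped = FALSE,
    mate_unmapped = FALSE, reverse = c(FALSE, TRUE),
    first_in_pair = c(TRUE, FALSE), secondary = FALSE, qc_fail = FALSE,
    duplicate = FALSE, supplementary = FALSE)
  sites <- tibble::tibble(rname = "Chr1", start = 200L, end = 201L, strand = "*")
  prof <- footprint_profile(reads, sites, radius = 100)
  # insertions at 104 and 294: site-relative -96 and +94
  expect_equal(unname(prof$values[c("-96", "94")]), c(1, 1))
  expect_equal(sum(prof$values), 2)
})

test_that("spectral analysis recovers known fragment periodicities", {
  lens <- 40:250
  pure <- 1000 * (1 + 0.3 * cos(2 * pi * lens / 10.5))
  est <- fragment_periodicity(lens, pure)
  expect_equal(est$period, 10.5, tolerance = 0.2 / 10.5)

  flat <- fragment_periodicity(lens, rep(1000, length(lens)))
  expect_true(is.na(flat$period))

  set.seed(5)
  comp <- frag_component(dist = "norm", mean = 180, sd = 35, min = 40,
                         max = 250,
                         modulation = list(period = 12, amplitude = 0.3))
  h <- tabulate(sample_fragment_lengths(comp, 2e5) + 1L, nbins = 301L)
  est12 <- fragment_periodicity(0:300, h)
  expect_equal(est12$period, 12.0, tolerance = 0.2 / 12)

  expect_warning(out <- fragment_periodicity(lens, rep(1, length(lens))),
                 "mass")
  expect_true(is.na(out$period))
})

test_that("the grid search equals running the full pipeline per combination", {
  fx <- small_fixture()
  catalog <- reference_catalog(fx$bam)
  tss <- tibble::tibble(rname = "Chr1",
                        start = seq(10000L, 190000L, by = 20000L),
                        end = seq(10000L, 190000L, by = 20000L) + 1L,
                        strand = "+")
  grid <- parameter_grid_search(fx$bam, min_mapq = c(0, 40),
                                min_fragment = c(10, 60),
                                max_fragment = c(150, 250), tss = tss)
  expect_equal(nrow(grid), 8L)
  reads <- read_alignments(fx$bam)
  for (i in seq_len(nrow(grid))) {
    crit <- qc_criteria(min_mapq = grid$min_mapq[i],
                        min_fragment = grid$min_fragment[i],
                        max_fragment = grid$max_fragment[i])
    ev <- evaluate_reads(reads, crit, catalog)
    expect_equal(grid$n_passing[i], sum(ev$passed))
    p <- ev[ev$passed, ]
    prof <- pileup_profile(effective_intervals(p, resize = 1, tn5 = TRUE,
                                               catalog = catalog),
                           tss, radius = 1000, catalog = catalog)
    expect_equal(grid$tes[i], tss_enrichment_score(prof))
  }
})

test_that("degenerate grids are handled: identity cell and invalid combinations", {
  fx <- small_fixture()
  tss <- tibble::tibble(rname = "Chr1", start = 50000L, end = 50001L,
                        strand = "+")
  expect_warning(
    g <- parameter_grid_search(fx$bam, min_mapq = 0,
                               min_fragment = c(100, 300),
                               max_fragment = 200, tss = tss),
    "min_fragment > max_fragment")
  expect_equal(nrow(g), 1L)
})
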
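# Positional signal analytics: 5' resizing and Tn5 shifting, anchored
# pileups, TSS enrichment, FRiP, insertion footprints, fragment-length
# periodicity and the filter-parameter grid search.

#' Effective intervals of reads (5' resizing and Tn5 shift)
#'
#' Replaces each alignment by a window of width `resize` centered on its
#' (optionally Tn5-shifted) 5' end: the 5' base is `start` for plus-strand and
#' `end - 1` for minus-strand reads; the Tn5 transposition offset moves it by
#' `+offsets[1]` (plus strand) / `-offsets[2]` (minus strand), the standard
#' +4/-5 ATAC-seq convention so coordinates mark the transposition center.
#' Even widths are left-biased by one base. Windows are clipped to the
#' reference.
#'
#' @param reads Alignment tibble (mapped reads).
#' @param resize Window width in bp (>= 1), or `NA` to keep the full
#'   alignment interval unchanged (ChIP mode).
#' @param tn5 Apply the Tn5 offset?
#' @param catalog Optional [reference_catalog()] for clipping to reference
#'   bounds (no clipping when omitted).
#' @param offsets Length-2 non-negative integers: plus-strand and minus-strand
#'   shift magnitudes (default `c(4, 5)`).
#' @return A tibble `rname`, `start`, `end`, `strand` (0-based half-open).
#' @examples
#' reads <- tibble::tibble(rname = "Chr1", start = 100L, end = 200L,
#'                         strand = c("+", "-"))
#' effective_intervals(reads, resize = 1, tn5 = TRUE)
#' @export
effective_intervals <- function(reads, resize = 1L, tn5 = TRUE, catalog = NULL,
                                offsets = c(4L, 5L)) {
  if (is.na(resize)) {
    return(tibble(rname = reads$rname, start = reads$start, end = reads$end,
                  strand = reads$strand))
  }
  if (resize < 1L) abort("resize must be >= 1 bp (or NA for no resizing)")
  plus <- reads$strand == "+"
  p5 <- ifelse(plus, reads$start, reads$end - 1L)
  if (tn5) p5 <- p5 + ifelse(plus, offsets[1], -offsets[2])
  # width `resize` centered on the 5' base; even widths left-biased by one
  start <- as.integer(p5 - floor(resize / 2))
  end <- start + as.integer(resize)
  if (!is.null(catalog)) {
    reflen <- catalog$length[match(reads$rname, catalog$name)]
    start <- pmax(start, 0L)
    end <- pmin(end, reflen)
  }
  tibble(rname = reads$rname, start = start, end = end, strand = reads$strand)
}

anchor_positions <- function(anchors) {
  ifelse(anchors$strand == "+", anchors$start,
         ifelse(anchors$strand == "-", anchors$end - 1L,
                (anchors$start + anchors$end - 1L) %/% 2L))
}

#' Average per-position pileup around anchor points
#'
#' For each relative position in `[-radius, +radius]`, the mean number of
#' interval bases covering it across anchors. The anchor base is the BED
#' start for plus-strand anchors, `end - 1` for minus-strand anchors, the
#' interval midpoint for unstranded anchors; minus-strand anchors have their
#' local axis flipped so downstream is always to the right.
#'
#' @param intervals Effective intervals from [effective_intervals()] (or raw
#'   alignment intervals).
#' @param anchors Interval tibble of anchor regions (e.g. TSSs from
#'   [read_bed()]); must be non-empty.
#' @param radius Window half-width in bp.
#' @param role Anchor role recorded in the profile (`"tss"`, `"peak_center"`,
#'   `"tfbs"`).
#' @param resize,tn5_shifted Metadata recorded in the profile.
#' @param catalog Optional catalog; anchors on references absent from it are
#'   skipped with a warning.
#' @return A `qc_pileup` object: list with `values` (numeric, length
#'   `2 * radius + 1`, names = relative positions), `n_anchors`, `radius`,
#'   `role`, `resize`, `tn5_shifted`.
#' @export
pileup_profile <- function(intervals, anchors, radius = 1000L, role = "tss",
                           resize = NA_integer_, tn5_shifted = NA,
                           catalog = NULL) {
  if (is.null(anchors) || nrow(anchors) == 0L) abort("zero anchors")
  if (!is.null(catalog)) {
    known <- anchors$rname %in% catalog$name
    if (any(!known)) {
      warn(sprintf("skipping %d anchor(s) on references absent from catalog",
                   sum(!known)))
      anchors <- anchors[known, , drop = FALSE]
    }
    if (nrow(anchors) == 0L) abort("zero anchors")
  }
  width <- 2L * radius + 1L
  acc <- numeric(width + 1L)  # difference array, cumsum at the end
  apos <- anchor_positions(anchors)
  n_anchors <- nrow(anchors)
  for (rf in unique(anchors$rname)) {
    ai <- which(anchors$rname == rf)
    ii <- which(intervals$rname == rf)
    if (length(ii) == 0L) next
    ir <- IRanges::IRanges(intervals$start[ii] + 1L, intervals$end[ii])
    win <- IRanges::IRanges(apos[ai] - radius + 1L, apos[ai] + radius + 1L)
    hits <- IRanges::findOverlaps(ir, win)
    if (length(hits) == 0L) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    a <- apos[ai][si]
    rs <- pmax(intervals$start[ii][qi], a - radius) - a        # rel start
    re <- pmin(intervals$end[ii][qi], a + radius + 1L) - a     # rel end
    minus <- anchors$strand[ai][si] == "-"
    # flip the local axis for minus-strand anchors: [rs, re) -> [1-re, 1-rs)
    frs <- ifelse(minus, 1L - re, rs)
    fre <- ifelse(minus, 1L - rs, re)
    ok <- fre > frs
    idx1 <- frs[ok] + radius + 1L
    idx2 <- fre[ok] + radius + 1L
    acc <- acc + tabulate(idx1, nbins = width + 1L) -
      tabulate(idx2, nbins = width + 1L)
  }
  values <- cumsum(acc)[seq_len(width)] / n_anchors
  structure(list(values = stats::setNames(values, -radius:radius),
                 n_anchors = n_anchors, radius = as.integer(radius),
                 role = role, resize = resize, tn5_shifted = tn5_shifted),
            class = "qc_pileup")
}

#' TSS enrichment score of a pileup profile
#'
#' The profile is smoothed with a centered moving average and the maximum of
#' the smoothed signal is divided by the background, estimated as the mean of
#' the outermost `flank_fraction` of positions on each side. A flat profile
#' scores exactly 1; the score is invariant to positive rescaling. Zero
#' background yields `NA`.
#'
#' @param profile A `qc_pileup` from [pileup_profile()].
#' @param flank_fraction Fraction of positions on each flank used as
#'   background, in (0, 0.5] (default 0.1).
#' @param smooth Moving-average window in bp (default 25); the profile must be
#'   wider than the window.
#' @return A single numeric TSS enrichment score (dimensionless, >= 0), or
#'   `NA` when the background is zero.
#' @export
tss_enrichment_score <- function(profile, flank_fraction = 0.1, smooth = 25L) {
  stopifnot(inherits(profile, "qc_pileup"))
  if (flank_fraction <= 0 || flank_fraction > 0.5) {
    abort("flank_fraction must be in (0, 0.5]")
  }
  v <- profile$values
  if (length(v) <= smooth) abort("profile radius too small for smoothing window")
  sm <- moving_average(v, smooth)
  nf <- max(1L, floor(flank_fraction * length(v)))
  bg <- mean(c(head(v, nf), tail(v, nf)))
  if (!is.finite(bg) || bg == 0) return(NA_real_)
  max(sm, na.rm = TRUE) / bg
}

#' Fraction of reads in peaks (FRiP)
#'
#' The fraction of passing reads whose (unresized) alignment interval
#' overlaps at least one peak by >= 1 bp.
#'
#' @param evaluated Evaluated reads from [evaluate_reads()].
#' @param peaks Non-empty interval tibble of peaks.
#' @return Proportion in `[0, 1]`, or `NA` (with a warning) when no reads
#'   pass.
#' @export
frip <- function(evaluated, peaks) {
  if (is.null(peaks) || nrow(peaks) == 0L) abort("peaks must be non-empty")
  p <- evaluated[evaluated$passed, , drop = FALSE]
  if (nrow(p) == 0L) {
    warn("no passing reads; FRiP undefined")
    return(NA_real_)
  }
  mean(overlaps_any(p, peaks))
}

#' Tn5 insertion footprint profile around binding sites
#'
#' Each passing read contributes one single-base insertion event — its
#' Tn5-shifted 5' end (`resize` forced to 1, shift forced on) — so each
#' properly paired fragment contributes the two insertion events of its
#' mates. The profile is the mean insertion count per site per position,
#' strand-flipped for minus-strand sites.
#'
#' @param reads Passing alignment tibble (paired-end data).
#' @param sites Non-empty interval tibble of TF binding sites.
#' @param radius Window half-width in bp (default 100).
#' @param catalog Optional catalog for clipping/skip warnings.
#' @param offsets Tn5 offsets as in [effective_intervals()].
#' @return A `qc_pileup` with role `"tfbs"`.
#' @export
footprint_profile <- function(reads, sites, radius = 100L, catalog = NULL,
                              offsets = c(4L, 5L)) {
  ins <- effective_intervals(reads, resize = 1L, tn5 = TRUE, catalog = catalog,
                             offsets = offsets)
  pileup_profile(ins, sites, radius = radius, role = "tfbs", resize = 1L,
                 tn5_shifted = TRUE, catalog = catalog)
}

#' Dominant fragment-length periodicity
#'
#' Detects the dominant oscillation period of a fragment-length histogram —
#' nucleosome-associated ATAC-seq libraries show a ~10.5 bp ripple from Tn5
#' acting on DNA wrapped around histones. The histogram restricted to
#' `range` is detrended (divided by a centered 21-bp moving average, minus
#' 1), a dense periodogram is evaluated over the period `band`, and the peak
#' period is refined by quadratic interpolation. A peak must exceed
#' `prominence` times the median band power, otherwise no periodicity is
#' called (`NA`).
#'
#' @param values,counts Fragment-length histogram: bin values in bp and their
#'   masses (1-bp bins).
#' @param range Fragment lengths (bp) analysed, default `c(40, 250)`.
#' @param band Candidate periods (bp), default `c(5, 20)`.
#' @param prominence Peak power / median band power required to call a period
#'   (default 15).
#' @param min_mass Minimum histogram mass in `range` (default 1000); below
#'   this the estimate is `NA` with a warning.
#' @return A list: `period` (bp, `NA` when not called), `power_ratio`, `mass`.
#' @examples
#' lens <- 40:250
#' cts <- round(1000 * (1 + 0.3 * cos(2 * pi * lens / 10.5)))
#' fragment_periodicity(lens, cts)$period
#' @export
fragment_periodicity <- function(values, counts, range = c(40, 250),
                                 band = c(5, 20), prominence = 15,
                                 min_mass = 1000) {
  keep <- values >= range[1] & values <= range[2]
  v <- values[keep]; x <- as.numeric(counts[keep])
  null_result <- list(period = NA_real_, power_ratio = NA_real_, mass = sum(x))
  if (sum(x) < min_mass) {
    warn(sprintf("histogram mass %g in range < %g; periodicity not estimated",
                 sum(x), min_mass))
    return(null_result)
  }
  ma <- moving_average(x, 21L)
  ok <- !is.na(ma) & ma > 0
  if (sum(ok) < 2 * band[2]) return(null_result)
  d <- x[ok] / ma[ok] - 1
  d <- d - mean(d)
  l <- v[ok]
  # dense periodogram over the band: P(f) = |sum d_j exp(-2*pi*i*f*l_j)|^2
  freqs <- seq(1 / band[2], 1 / band[1], length.out = 2048L)
  ph <- outer(l, freqs)
  re <- colSums(d * cospi(2 * ph))
  im <- colSums(d * sinpi(2 * ph))
  power <- re^2 + im^2
  k <- which.max(power)
  ratio <- power[k] / stats::median(power)
  if (!is.finite(ratio) || ratio < prominence) {
    return(list(period = NA_real_, power_ratio = ratio, mass = sum(x)))
  }
  # quadratic interpolation of the spectral peak in frequency
  f <- freqs[k]
  if (k > 1L && k < length(freqs)) {
    y1 <- power[k - 1L]; y2 <- power[k]; y3 <- power[k + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {
      f <- f + 0.5 * (y1 - y3) / denom * (freqs[2] - freqs[1])
    }
  }
  list(period = 1 / f, power_ratio = ratio, mass = sum(x))
}

#' Grid search over filter thresholds
#'
#' Runs the filtering + TSS-enrichment analysis for every combination of
#' minimum MAPQ, minimum fragment length and maximum fragment length,
#' reporting the passing-read count and TSS enrichment score per combination.
#' Reads are streamed once; each read's verdict under each combination is
#' evaluated independently, so results equal running the full pipeline per
#' combination. Combinations with `min_fragment > max_fragment` are skipped
#' with a warning.
#'
#' @param bam Path to a coordinate-sorted BAM.
#' @param min_mapq,min_fragment,max_fragment Numeric vectors of candidate
#'   thresholds (full factorial grid).
#' @param tss TSS interval tibble (for the enrichment score).
#' @param restrict Optional region restriction as in [read_alignments()]
#'   (e.g. a single chromosome to keep the search fast).
#' @param criteria Base criteria for all non-grid filters.
#' @param tss_radius,flank_fraction,smooth TSS pileup / score parameters.
#' @param mito,plastid Organelle name lists for the catalog.
#' @return A tibble with one row per retained combination: `min_mapq`,
#'   `min_fragment`, `max_fragment`, `n_passing`, `tes`.
#' @examples
#' \donttest{
#' fx <- generate_fixture(preset_fixtures()$grid, tempfile("fx"))
#' grid <- parameter_grid_search(fx$bam, min_mapq = c(0, 20, 40),
#'                               min_fragment = 10, max_fragment = c(150, 250),
#'                               tss = fx$beds$tss)
#' }
#' @export
parameter_grid_search <- function(bam,
                                  min_mapq = c(0, 10, 20, 30, 40),
                                  min_fragment = c(10, 20, 30, 40, 50),
                                  max_fragment = c(50, 100, 150, 200, 250),
                                  tss,
                                  restrict = NULL,
                                  criteria = qc_criteria(),
                                  tss_radius = 1000L,
                                  flank_fraction = 0.1,
                                  smooth = 25L,
                                  mito = default_mito_names(),
                                  plastid = default_plastid_names()) {
  if (length(min_mapq) == 0L || length(min_fragment) == 0L ||
      length(max_fragment) == 0L) abort("grid must be non-empty")
  grid <- tidyr::expand_grid(min_mapq = min_mapq, min_fragment = min_fragment,
                             max_fragment = max_fragment)
  bad <- grid$min_fragment > grid$max_fragment
  if (any(bad)) {
    warn(sprintf("skipping %d combination(s) with min_fragment > max_fragment",
                 sum(bad)))
    grid <- grid[!bad, , drop = FALSE]
  }
  catalog <- reference_catalog(bam, mito = mito, plastid = plastid)
  reads <- read_alignments(bam, restrict = restrict)
  base <- evaluate_reads(reads, criteria, catalog)
  flen <- nominal_fragment_length(base)
  # verdict under a combination = base verdict, re-deciding only the three
  # grid thresholds (base criteria keep min_mapq 0 and unbounded fragments)
  base_other_pass <- !grepl(
    "unmapped|secondary|supplementary|qc_fail|duplicate|improper_pair|organellar|off_target|blacklisted",
    base$fail_reasons)
  res <- purrr::pmap(grid, function(min_mapq, min_fragment, max_fragment) {
    pass <- base_other_pass & base$mapq >= min_mapq &
      (is.na(flen) | (flen >= min_fragment & flen <= max_fragment))
    # paired data: reads without a defined fragment length (improper pairs)
    # are already excluded by base_other_pass when required
    p <- base[pass, , drop = FALSE]
    tes <- if (nrow(p)) {
      prof <- pileup_profile(
        effective_intervals(p, resize = criteria$resize, tn5 = criteria$tn5_shift,
                            catalog = catalog),
        tss, radius = tss_radius, role = "tss",
        resize = criteria$resize, tn5_shifted = criteria$tn5_shift,
        catalog = catalog)
      tss_enrichment_score(prof, flank_fraction = flank_fraction, smooth = smooth)
    } else NA_real_
    tibble(n_passing = nrow(p), tes = tes)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

#' @export
print.qc_pileup <- function(x, ...) {
  cat(sprintf("<qc_pileup> role: %s, radius: %d bp, %d anchors\n",
              x$role, x$radius, x$n_anchors))
  cat(sprintf("  resize: %s bp, Tn5 shift: %s, mean density: %.4g\n",
              format(x$resize), format(x$tn5_shifted), mean(x$values)))
  invisible(x)
}

#' @rdname tidy.qc_report
#' @export
tidy.qc_pileup <- function(x, ...) {
  tibble(position = as.integer(names(x$values)), density = as.numeric(x$values))
}
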
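# Synthetic paired-end ATAC-seq fixtures: fully specified simulated
# experiments (genome, organellar contamination, fragment-length mixture with
# optional helical-pitch modulation, MAPQ strata, TSS enrichment, footprint
# protection) written as coordinate-sorted indexed BAM + BED files together
# with an exact per-read truth table.

#' Describe a fragment-length mixture component
#'
#' @param weight Mixture weight (normalised across components).
#' @param dist `"unif"` or `"norm"`.
#' @param min,max Bounds in bp (uniform; also truncation bounds for normal).
#' @param mean,sd Normal parameters in bp.
#' @param modulation Optional `list(period =, amplitude =)`: sinusoidal
#'   density modulation `1 + amplitude * cos(2 * pi * length / period)`,
#'   applied by rejection sampling (amplitude in `[0, 1)`).
#' @param mapq Length-2 integer range; each fragment's MAPQ is drawn
#'   uniformly from it (a single value for a fixed MAPQ).
#' @param enriched Should fragments of this component be placed at anchors
#'   (TSS-like enrichment) rather than uniformly?
#' @param name Component label carried into the truth table.
#' @return A `frag_component` list.
#' @export
frag_component <- function(weight = 1, dist = c("unif", "norm"),
                           min = 50, max = 250, mean = 180, sd = 35,
                           modulation = NULL, mapq = c(42L, 42L),
                           enriched = FALSE, name = "component") {
  dist <- match.arg(dist)
  if (!is.null(modulation)) {
    stopifnot(modulation$amplitude >= 0, modulation$amplitude < 1,
              modulation$period > 0)
  }
  if (length(mapq) == 1L) mapq <- c(mapq, mapq)
  structure(list(weight = weight, dist = dist, min = min, max = max,
                 mean = mean, sd = sd, modulation = modulation,
                 mapq = as.integer(mapq), enriched = enriched, name = name),
            class = "frag_component")
}

#' Sample fragment lengths from a mixture component
#'
#' Integer lengths from the component's base distribution, with the optional
#' sinusoidal density modulation applied by rejection sampling (acceptance
#' probability `(1 + a cos(2 pi L / p)) / (1 + a)`).
#'
#' @param component A [frag_component()].
#' @param n Number of lengths.
#' @return Integer vector of length `n` (bp).
#' @examples
#' comp <- frag_component(dist = "norm", mean = 180, sd = 35,
#'                        modulation = list(period = 10.5, amplitude = 0.3))
#' set.seed(1); summary(sample_fragment_lengths(comp, 1000))
#' @export
sample_fragment_lengths <- function(component, n) {
  draw <- function(k) {
    l <- switch(component$dist,
      unif = runif(k, component$min, component$max + 1),
      norm = rnorm(k, component$mean, component$sd))
    l <- as.integer(floor(l))
    l[l >= component$min & l <= component$max]
  }
  out <- integer(0)
  mod <- component$modulation
  while (length(out) < n) {
    k <- max(1000L, ceiling((n - length(out)) * 1.8))
    l <- draw(k)
    if (!is.null(mod) && length(l)) {
      p_acc <- (1 + mod$amplitude * cos(2 * pi * l / mod$period)) /
        (1 + mod$amplitude)
      l <- l[runif(length(l)) < p_acc]
    }
    out <- c(out, l)
  }
  out[seq_len(n)]
}

#' Specify a synthetic ATAC-seq experiment
#'
#' @param genome Tibble `name`, `length`, `category` describing the reference;
#'   the default is a 300 kb toy genome with one nuclear chromosome plus
#'   mitochondrial and plastid sequences.
#' @param n_fragments Number of template fragments to simulate.
#' @param composition Named proportions over categories
#'   (nuclear/mitochondrial/plastid), summing to 1.
#' @param components List of [frag_component()]s (nuclear fragments only;
#'   organellar fragments reuse the first component's length model).
#' @param anchors Optional anchor tibble (`rname`, `start`, `end`, `strand`)
#'   at which enriched components place fragment centers; defaults to
#'   `n_anchors` TSS-like points evenly spaced on the nuclear chromosome when
#'   any component is enriched.
#' @param n_anchors Number of default anchors (default 100).
#' @param enrich_spread SD (bp) of the Gaussian offset of enriched fragment
#'   centers around their anchor (default 50).
#' @param peak_halfwidth Peaks BED written as anchor +/- this (default 200).
#' @param dup_rate,secondary_rate,improper_rate Per-fragment duplicate
#'   probability, per-read secondary-alignment probability, per-fragment
#'   improper-pair probability (all in `[0, 1)`).
#' @param protection Optional `list(sites =, halfwidth =)`: fragment
#'   placements whose Tn5-shifted insertion points fall within `halfwidth` bp
#'   of a site center are rejected (TF footprint emulation).
#' @param read_length Read length in bp (shortened on fragments shorter than
#'   this).
#' @param gc Per-base probability of G or C in simulated sequences.
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(genome = default_toy_genome(),
                           n_fragments = 5000L,
                           composition = c(nuclear = 0.85,
                                           mitochondrial = 0.10,
                                           plastid = 0.05),
                           components = list(frag_component()),
                           anchors = NULL,
                           n_anchors = 100L,
                           enrich_spread = 50,
                           peak_halfwidth = 200L,
                           dup_rate = 0,
                           secondary_rate = 0,
                           improper_rate = 0,
                           protection = NULL,
                           read_length = 50L,
                           gc = 0.4,
                           seed = 42L) {
  stopifnot(abs(sum(composition) - 1) < 1e-9,
            dup_rate >= 0, dup_rate < 1,
            secondary_rate >= 0, secondary_rate < 1,
            improper_rate >= 0, improper_rate < 1)
  if (inherits(components, "frag_component")) components <- list(components)
  if (is.null(anchors) && any(vapply(components, `[[`, TRUE, "enriched"))) {
    nuc <- genome[genome$category == "nuclear", ][1, ]
    pos <- as.integer(round(seq(nuc$length * 0.05, nuc$length * 0.95,
                                length.out = n_anchors)))
    anchors <- tibble(rname = nuc$name, start = pos, end = pos + 1L,
                      name = sprintf("tss%03d", seq_along(pos)),
                      strand = rep(c("+", "-"), length.out = length(pos)))
  }
  structure(list(genome = genome, n_fragments = as.integer(n_fragments),
                 composition = composition, components = components,
                 anchors = anchors, enrich_spread = enrich_spread,
                 peak_halfwidth = as.integer(peak_halfwidth),
                 dup_rate = dup_rate, secondary_rate = secondary_rate,
                 improper_rate = improper_rate, protection = protection,
                 read_length = as.integer(read_length), gc = gc,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_toy_genome <- function() {
  tibble(name = c("Chr1", "ChrM", "ChrC"),
         length = c(200000L, 30000L, 20000L),
         category = factor(c("nuclear", "mitochondrial", "plastid"),
                           levels = c("nuclear", "mitochondrial", "plastid")))
}

random_dna <- function(n, len, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
}

# positions (0-based) of shifted Tn5 insertion points of a fragment
# [start, start + flen): plus-end start + 4, minus-end (start + flen - 1) - 5
fragment_insertions <- function(start, flen) {
  cbind(start + 4L, start + flen - 1L - 5L)
}

#' Generate a synthetic fixture (BAM + BEDs + truth table)
#'
#' Simulates `spec$n_fragments` paired-end template fragments, writes them as
#' a coordinate-sorted, indexed BAM (SAM-spec-conformant flags and TLEN; the
#' leftmost mate carries the positive TLEN), writes TSS/peak/site BED files
#' where applicable, and returns an exact per-read truth table.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if needed).
#' @return A `qc_fixture` list: `bam`, `beds` (named list of tibbles with a
#'   `path` attribute each), `truth` (per-read tibble), `spec`.
#' @examples
#' fx <- generate_fixture(synthetic_spec(n_fragments = 200), tempfile("fx"))
#' fx$truth %>% dplyr::count(category)
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  g <- spec$genome
  n <- spec$n_fragments

  cat_names <- names(spec$composition)
  category <- sample(cat_names, n, replace = TRUE, prob = spec$composition)
  cw <- vapply(spec$components, `[[`, numeric(1), "weight")
  comp_idx <- sample(seq_along(spec$components), n, replace = TRUE,
                     prob = cw / sum(cw))
  # organellar fragments use the first component's length model, unenriched
  comp_idx[category != "nuclear"] <- 1L

  flen <- integer(n)
  for (ci in unique(comp_idx)) {
    ii <- which(comp_idx == ci)
    flen[ii] <- sample_fragment_lengths(spec$components[[ci]], length(ii))
  }

  # reference per fragment: within category, weighted by sequence length
  rname <- character(n)
  for (cat in unique(category)) {
    seqs <- g[as.character(g$category) == cat, ]
    if (nrow(seqs) == 0L) abort(sprintf("no reference sequence of category %s", cat))
    ii <- which(category == cat)
    rname[ii] <- sample(seqs$name, length(ii), replace = TRUE,
                        prob = seqs$length)
  }
  reflen <- g$length[match(rname, g$name)]
  flen <- pmin(flen, reflen)  # fragments can never exceed their reference

  enriched <- vapply(spec$components, `[[`, TRUE, "enriched")[comp_idx] &
    category == "nuclear" & !is.null(spec$anchors)

  # enriched fragments are tied to one anchor each (kept across resampling);
  # they move to the anchor's reference
  anchor_of <- rep(NA_integer_, n)
  if (any(enriched)) {
    anchor_of[enriched] <- sample(nrow(spec$anchors), sum(enriched),
                                  replace = TRUE)
    rname[enriched] <- spec$anchors$rname[anchor_of[enriched]]
  }
  reflen <- g$length[match(rname, g$name)]
  flen <- pmin(flen, reflen)

  place <- function(idx) {
    start <- integer(length(idx))
    en <- enriched[idx]
    if (any(en)) {
      ai <- anchor_of[idx][en]
      center <- anchor_positions(spec$anchors)[ai] +
        as.integer(round(rnorm(sum(en), 0, spec$enrich_spread)))
      start[en] <- center - flen[idx][en] %/% 2L
    }
    if (any(!en)) {
      un <- which(!en)
      start[un] <- as.integer(floor(runif(length(un)) *
                                      (reflen[idx][un] - flen[idx][un] + 1L)))
    }
    pmax(0L, pmin(start, reflen[idx] - flen[idx]))
  }
  start <- place(seq_len(n))

  # footprint protection: resample placements whose shifted insertion points
  # hit a protected window (site center +/- halfwidth)
  if (!is.null(spec$protection)) {
    sites <- spec$protection$sites
    hw <- spec$protection$halfwidth
    centers_by_ref <- split(anchor_positions(sites), sites$rname)
    violates <- function(idx) {
      ins <- fragment_insertions(start[idx], flen[idx])
      out <- logical(length(idx))
      for (rf in names(centers_by_ref)) {
        i <- which(rname[idx] == rf)
        if (!length(i)) next
        cs <- centers_by_ref[[rf]]
        for (j in i) {
          out[j] <- any(abs(ins[j, 1] - cs) <= hw) || any(abs(ins[j, 2] - cs) <= hw)
        }
      }
      out
    }
    bad <- which(violates(seq_len(n)))
    tries <- 0L
    while (length(bad) && tries < 100L) {
      start[bad] <- place(bad)
      bad <- bad[violates(bad)]
      tries <- tries + 1L
    }
  }

  is_dup <- runif(n) < spec$dup_rate
  improper <- runif(n) < spec$improper_rate
  mapq <- integer(n)
  for (ci in unique(comp_idx)) {
    ii <- which(comp_idx == ci)
    mq <- spec$components[[ci]]$mapq
    mapq[ii] <- if (mq[1] == mq[2]) mq[1] else
      as.integer(sample(mq[1]:mq[2], length(ii), replace = TRUE))
  }

  rl <- pmin(spec$read_length, flen)
  qname <- sprintf("frag%07d", seq_len(n))
  # mate on the plus strand starts at `start`; minus-strand mate ends the
  # fragment; which mate is read 1 is random
  r1_plus <- runif(n) < 0.5

  mk_flag <- function(plus, first) {
    0x1L + (!improper) * 0x2L + (!plus) * 0x10L + plus * 0x20L +
      (if (first) 0x40L else 0x80L) + is_dup * 0x400L
  }
  rec <- function(plus, first) {
    tibble(
      qname = qname,
      flag = mk_flag(plus, first),
      rname = rname,
      pos = if (plus) start + 1L else start + flen - rl + 1L,  # 1-based SAM
      mapq = mapq,
      cigar = sprintf("%dM", rl),
      tlen = if (plus) flen else -flen,
      seq = rep(NA_character_, n)  # filled after mate bookkeeping
    )
  }
  recs <- dplyr::bind_rows(rec(TRUE, first = TRUE), rec(FALSE, first = FALSE))
  # read-1/read-2 labels: swap 0x40/0x80 for fragments where read 1 is minus
  swap <- rep(!r1_plus, 2L)
  f <- recs$flag
  recs$flag <- ifelse(swap, bitwXor(f, 0xC0L), f)
  # mate fields
  mate_pos <- c(recs$pos[(n + 1):(2 * n)], recs$pos[1:n])
  recs$mpos <- mate_pos
  # sequences: one random sequence per record at its read length
  lens <- rep(rl, 2L)
  seqs <- character(2L * n)
  for (L in unique(lens)) {
    ii <- which(lens == L)
    seqs[ii] <- random_dna(length(ii), L, spec$gc)
  }
  recs$seq <- seqs

  # secondary alignments: per read, at a random position on the same reference
  sec <- which(runif(2L * n) < spec$secondary_rate)
  if (length(sec)) {
    s <- recs[sec, ]
    srl <- lens[sec]
    s$flag <- bitwOr(s$flag, 0x100L)
    smax <- pmax(g$length[match(s$rname, g$name)] - srl, 0L)
    s$pos <- as.integer(floor(runif(length(sec)) * smax)) + 1L
    s$mapq <- 0L
    s$tlen <- 0L
    recs <- dplyr::bind_rows(recs, s)
  }

  # write SAM, convert to sorted+indexed BAM
  ord <- order(match(recs$rname, g$name), recs$pos)
  recs <- recs[ord, ]
  sam <- file.path(out_dir, "fixture.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", g$name, g$length))
  qual <- vapply(nchar(recs$seq), function(k) strrep("I", k), character(1))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t%s",
                  recs$qname, recs$flag, recs$rname, recs$pos, recs$mapq,
                  recs$cigar, recs$mpos, recs$tlen, recs$seq, qual)
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(out_dir, "fixture"),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)

  # BED sidecars
  beds <- list()
  if (!is.null(spec$anchors)) {
    tss <- spec$anchors
    tss_path <- file.path(out_dir, "tss.bed")
    write_bed(tss, tss_path)
    attr(tss, "path") <- tss_path
    ap <- anchor_positions(spec$anchors)
    peaks <- tibble(rname = spec$anchors$rname,
                    start = pmax(ap - spec$peak_halfwidth, 0L),
                    end = ap + spec$peak_halfwidth + 1L,
                    name = sprintf("peak%03d", seq_along(ap)),
                    strand = "*")
    peaks_path <- file.path(out_dir, "peaks.bed")
    write_bed(peaks, peaks_path)
    attr(peaks, "path") <- peaks_path
    beds$tss <- tss
    beds$peaks <- peaks
  }
  if (!is.null(spec$protection)) {
    sites <- spec$protection$sites
    sites_path <- file.path(out_dir, "sites.bed")
    write_bed(sites, sites_path)
    attr(sites, "path") <- sites_path
    beds$sites <- sites
  }

  # per-read truth table, in the BAM's record order
  gc_truth <- vapply(recs$seq, function(s)
    sum(strsplit(s, "")[[1]] %in% c("G", "C")), numeric(1), USE.NAMES = FALSE)
  fi <- match(recs$qname, qname)
  truth <- tibble(
    qname = recs$qname,
    rname = recs$rname,
    category = category[fi],
    component = vapply(spec$components[comp_idx[fi]], `[[`, "", "name"),
    is_dup = is_dup[fi],
    is_secondary = bitwAnd(recs$flag, 0x100L) > 0L,
    proper = bitwAnd(recs$flag, 0x2L) > 0L,
    mapq = recs$mapq,
    fragment_length = ifelse(bitwAnd(recs$flag, 0x102L) == 0x2L,
                             abs(recs$tlen), NA_integer_),
    tlen = recs$tlen,
    strand = ifelse(bitwAnd(recs$flag, 0x10L) > 0L, "-", "+"),
    start = recs$pos - 1L,
    end = recs$pos - 1L + nchar(recs$seq),
    gc_count = as.integer(gc_truth),
    query_length = nchar(recs$seq)
  )
  if (!is.null(beds$peaks)) {
    truth$in_peak <- overlaps_any(truth, beds$peaks)
    truth$near_tss <- overlaps_any(
      dplyr::mutate(truth, start = .data$start - 500L, end = .data$end + 500L),
      beds$tss)
  } else {
    truth$in_peak <- NA
    truth$near_tss <- NA
  }
  structure(list(bam = bam, beds = beds, truth = truth, spec = spec),
            class = "qc_fixture")
}

#' Expected pipeline aggregates from a truth table
#'
#' Recomputes, from the per-read truth table alone, the aggregates the QC
#' pipeline reports under the given criteria: per-category totals, passing
#' count, fragment-histogram mass (one observation per passing fragment via
#' the positive-TLEN mate) and FRiP.
#'
#' @param truth Truth tibble from [generate_fixture()].
#' @param criteria A [qc_criteria()] (only the threshold/flag filters are
#'   consulted; region restrictions are not applied here).
#' @return A list: `category_counts` (named), `n_passing`, `fragment_mass`,
#'   `frip`.
#' @export
truth_summary <- function(truth, criteria = qc_criteria()) {
  pass <- !truth$is_secondary &
    (!criteria$drop_duplicates | !truth$is_dup) &
    (!criteria$require_proper_pair | truth$proper) &
    truth$mapq >= criteria$min_mapq &
    (!criteria$nuclear_only | truth$category == "nuclear") &
    (is.na(truth$fragment_length) |
       (truth$fragment_length >= criteria$min_fragment &
          truth$fragment_length <= criteria$max_fragment))
  frag_mass <- sum(pass & truth$category == "nuclear" &
                     !is.na(truth$fragment_length) & truth$tlen > 0L)
  list(
    category_counts = table(factor(truth$category,
                                   c("nuclear", "mitochondrial", "plastid"))),
    n_passing = sum(pass),
    fragment_mass = frag_mass,
    frip = if (any(pass) && !all(is.na(truth$in_peak)))
      mean(truth$in_peak[pass]) else NA_real_
  )
}

#' Preset fixture specifications
#'
#' Named [synthetic_spec()]s emulating common sample regimes:
#'
#' * `clean` — strongly TSS-enriched library, NFR + mononucleosomal mixture
#'   with 10.5 bp helical-pitch modulation; high TES, clear periodicity.
#' * `free_dna` — uniform background, no enrichment, no modulation: the
#'   free-DNA pathology (low TES, no called periodicity).
#' * `organellar_heavy` — 50% mitochondrial / 20% plastid contamination.
#' * `footprint` — uniform insertions except a protected window at TF sites.
#' * `grid` — NFR signal at high MAPQ plus long-fragment and low-MAPQ noise,
#'   for filter-threshold exploration.
#'
#' @param n_fragments Fragments per fixture (default 8000).
#' @param seed Base RNG seed.
#' @return Named list of `synthetic_spec`s.
#' @export
preset_fixtures <- function(n_fragments = 8000L, seed = 42L) {
  nfr <- function(enr = TRUE) frag_component(
    weight = 0.55, dist = "unif", min = 60, max = 130,
    mapq = c(30L, 42L), enriched = enr, name = "nfr")
  mono <- function(enr = TRUE) frag_component(
    weight = 0.35, dist = "norm", mean = 190, sd = 25, min = 140, max = 260,
    modulation = list(period = 10.5, amplitude = 0.3),
    mapq = c(30L, 42L), enriched = enr, name = "mono")
  background <- frag_component(
    weight = 0.10, dist = "unif", min = 50, max = 400,
    mapq = c(30L, 42L), enriched = FALSE, name = "background")

  sites <- tibble(rname = "Chr1",
                  start = as.integer(seq(10000, 190000, length.out = 40L)),
                  end = as.integer(seq(10000, 190000, length.out = 40L)) + 1L,
                  name = sprintf("site%02d", 1:40), strand = "*")

  list(
    clean = synthetic_spec(
      n_fragments = n_fragments,
      composition = c(nuclear = 0.90, mitochondrial = 0.07, plastid = 0.03),
      components = list(nfr(), mono(), background),
      dup_rate = 0.05, seed = seed),
    free_dna = synthetic_spec(
      n_fragments = n_fragments,
      composition = c(nuclear = 0.80, mitochondrial = 0.15, plastid = 0.05),
      components = list(frag_component(
        weight = 1, dist = "unif", min = 40, max = 400,
        mapq = c(30L, 42L), enriched = FALSE, name = "free_dna")),
      dup_rate = 0.05, seed = seed + 1L),
    organellar_heavy = synthetic_spec(
      n_fragments = n_fragments,
      composition = c(nuclear = 0.30, mitochondrial = 0.50, plastid = 0.20),
      components = list(nfr(), mono(), background),
      dup_rate = 0.05, seed = seed + 2L),
    footprint = synthetic_spec(
      n_fragments = n_fragments,
      composition = c(nuclear = 1, mitochondrial = 0, plastid = 0),
      components = list(frag_component(
        weight = 1, dist = "unif", min = 80, max = 200,
        mapq = c(30L, 42L), enriched = FALSE, name = "uniform")),
      protection = list(sites = sites, halfwidth = 10L),
      seed = seed + 3L),
    grid = synthetic_spec(
      n_fragments = n_fragments,
      composition = c(nuclear = 1, mitochondrial = 0, plastid = 0),
      components = list(
        frag_component(weight = 0.50, dist = "unif", min = 50, max = 140,
                       mapq = 42L, enriched = TRUE, name = "nfr_signal"),
        frag_component(weight = 0.06, dist = "unif", min = 50, max = 400,
                       mapq = 42L, enriched = FALSE, name = "background"),
        frag_component(weight = 0.40, dist = "unif", min = 160, max = 400,
                       mapq = 42L, enriched = FALSE, name = "long_noise"),
        frag_component(weight = 0.04, dist = "unif", min = 50, max = 400,
                       mapq = c(0L, 39L), enriched = FALSE, name = "lowq_noise")),
      seed = seed + 4L)
  )
}
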
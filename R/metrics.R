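# Streaming accumulators: read-category counts, distribution histograms over
# passing nuclear reads, and event-based genome-wide depth. All state lives in
# an environment so chunks accumulate in place during the single pass.

count_types <- c("total", "mapped", "unmapped", "duplicate", "secondary",
                 "supplementary", "qc_fail", "proper_pair", "passing")

#' Create an empty QC accumulator
#'
#' @param catalog A [reference_catalog()] tibble.
#' @param criteria A [qc_criteria()] object.
#' @param max_fragment_tracked Fragment/alignment lengths above this many bp
#'   are pooled into one overflow bin to bound memory (default 2000).
#' @return A `qc_state` environment; feed it with [accumulate()] and summarise
#'   with [finalize_report()].
#' @keywords internal
new_qc_state <- function(catalog, criteria, max_fragment_tracked = 2000L) {
  st <- new.env(parent = emptyenv())
  st$catalog <- catalog
  st$criteria <- criteria
  st$cap <- as.integer(max_fragment_tracked)
  st$counts <- matrix(0, nrow = 3L, ncol = length(count_types),
                      dimnames = list(levels(catalog$category), count_types))
  st$frag_hist <- integer(st$cap + 2L)  # lengths 0..cap, then overflow
  st$alen_hist <- integer(st$cap + 2L)
  st$mapq_hist <- integer(256L)         # 0..255
  st$gc_hist <- integer(101L)           # percent bins 0..100
  st$fail_tally <- stats::setNames(integer(length(fail_reason_levels)),
                                   fail_reason_levels)
  st$events <- list()                   # per-reference start/end positions
  st$last_ref <- NA_character_
  st$last_start <- -1L
  st$seen_refs <- character()
  st$reads_streamed <- 0L
  class(st) <- "qc_state"
  st
}

check_chunk_order <- function(st, reads) {
  mapped <- which(!reads$unmapped)
  if (length(mapped) == 0L) return(invisible(NULL))
  rn <- reads$rname[mapped]
  starts <- reads$start[mapped]
  runs <- rle(rn)
  at <- 0L
  for (i in seq_along(runs$values)) {
    idx <- (at + 1L):(at + runs$lengths[i])
    at <- at + runs$lengths[i]
    ref <- runs$values[i]
    s <- starts[idx]
    if (is.unsorted(s)) abort("input not coordinate-sorted")
    if (identical(ref, st$last_ref)) {
      if (s[1] < st$last_start) abort("input not coordinate-sorted")
    } else if (ref %in% st$seen_refs) {
      abort("input not coordinate-sorted")
    } else {
      st$seen_refs <- c(st$seen_refs, ref)
    }
    st$last_ref <- ref
    st$last_start <- s[length(s)]
  }
  invisible(NULL)
}

hist_add <- function(hist, values, cap) {
  v <- pmin(values, cap + 1L) + 1L  # shift: value 0 -> bin 1; overflow pooled
  hist + tabulate(v, nbins = cap + 2L)
}

#' Accumulate a chunk of evaluated reads into a QC state
#'
#' Category counters are updated for every read; distribution histograms and
#' depth events only for passing nuclear reads. Each passing fragment adds one
#' fragment-length observation (the mate with positive template length).
#'
#' @param st A `qc_state` from [new_qc_state()].
#' @param reads An evaluated chunk from [evaluate_reads()], in coordinate
#'   order (an out-of-order chunk raises "input not coordinate-sorted").
#' @return `st`, invisibly (modified in place).
#' @keywords internal
accumulate <- function(st, reads) {
  check_chunk_order(st, reads)
  st$reads_streamed <- st$reads_streamed + nrow(reads)
  ci <- as.integer(reads$category)
  add <- function(mask) tabulate(ci[mask], nbins = 3L)
  st$counts[, "total"] <- st$counts[, "total"] + add(TRUE)
  st$counts[, "mapped"] <- st$counts[, "mapped"] + add(!reads$unmapped)
  st$counts[, "unmapped"] <- st$counts[, "unmapped"] + add(reads$unmapped)
  st$counts[, "duplicate"] <- st$counts[, "duplicate"] + add(reads$duplicate)
  st$counts[, "secondary"] <- st$counts[, "secondary"] + add(reads$secondary)
  st$counts[, "supplementary"] <- st$counts[, "supplementary"] + add(reads$supplementary)
  st$counts[, "qc_fail"] <- st$counts[, "qc_fail"] + add(reads$qc_fail)
  st$counts[, "proper_pair"] <- st$counts[, "proper_pair"] + add(reads$proper_pair)
  st$counts[, "passing"] <- st$counts[, "passing"] + add(reads$passed)

  failing <- reads$fail_reasons[!reads$passed]
  if (length(failing)) {
    tal <- table(factor(unlist(strsplit(failing, ",", fixed = TRUE)),
                        levels = fail_reason_levels))
    st$fail_tally <- st$fail_tally + as.integer(tal)
  }

  pass <- reads$passed & reads$category == "nuclear"
  if (any(pass)) {
    p <- reads[pass, ]
    flen <- nominal_fragment_length(p)
    fl <- flen[!is.na(flen) & p$template_length > 0L]
    if (length(fl)) st$frag_hist <- hist_add(st$frag_hist, as.integer(fl), st$cap)
    st$alen_hist <- hist_add(st$alen_hist, p$aligned_length, st$cap)
    st$mapq_hist <- st$mapq_hist + tabulate(pmin(p$mapq, 255L) + 1L, nbins = 256L)
    has_seq <- !is.na(p$gc_count) & p$query_length > 0L
    if (any(has_seq)) {
      gcbin <- round(100 * p$gc_count[has_seq] / p$query_length[has_seq])
      st$gc_hist <- st$gc_hist + tabulate(gcbin + 1L, nbins = 101L)
    }
    for (ref in unique(p$rname)) {
      i <- p$rname == ref
      ev <- st$events[[ref]]
      st$events[[ref]] <- list(starts = c(ev$starts, p$start[i]),
                               ends = c(ev$ends, p$end[i]))
    }
  }
  invisible(st)
}

#' Depth histogram from coverage events
#'
#' Computes, from the start (+1) and end (-1) positions of reads on one
#' reference, how many bases sit at each depth value `d >= 1`, by a sweep over
#' sorted events — memory scales with the number of events, never with the
#' reference length.
#'
#' @param events A tibble/data.frame with columns `position` (0-based) and
#'   `delta` (+1 at read starts, -1 one past read ends), or a list with
#'   `starts` and `ends` vectors.
#' @param ref_length Reference length in bp (used for the depth-0 mass).
#' @return A list with `hist` (named numeric, depth value -> base count, depth
#'   >= 1 only), `covered` (bases at depth >= 1) and `zero` (bases never
#'   covered, `ref_length - covered`).
#' @examples
#' depth_from_events(list(starts = c(100, 150), ends = c(200, 250)), 1000)
#' @export
depth_from_events <- function(events, ref_length) {
  if (is.data.frame(events)) {
    pos <- events$position
    delta <- events$delta
  } else {
    pos <- c(events$starts, events$ends)
    delta <- rep(c(1L, -1L), c(length(events$starts), length(events$ends)))
  }
  if (length(pos) == 0L) {
    return(list(hist = stats::setNames(numeric(0), character(0)),
                covered = 0, zero = ref_length))
  }
  o <- order(pos)
  pos <- pos[o]; delta <- delta[o]
  agg <- rowsum(delta, pos)              # net delta per distinct position
  upos <- as.numeric(rownames(agg))
  depth <- cumsum(agg[, 1])
  if (any(depth < 0)) abort("internal consistency error: negative depth")
  widths <- diff(upos)                   # segment [upos_i, upos_{i+1})
  d <- depth[-length(depth)]
  keep <- d >= 1 & widths > 0
  hist <- tapply(widths[keep], d[keep], sum)
  covered <- sum(widths[keep])
  list(hist = stats::setNames(as.numeric(hist), names(hist)),
       covered = covered, zero = ref_length - covered)
}

#' Summary statistics of a binned distribution
#'
#' Mean, standard deviation (sample, n-1 denominator), median, min and max
#' computed from a histogram without per-observation storage. The median is
#' the smallest bin value at which the cumulative mass reaches half the total
#' (lower-bin convention for even masses). All statistics are `NA` on empty
#' histograms.
#'
#' @param values Numeric bin values.
#' @param counts Non-negative bin masses (same length as `values`).
#' @return A one-row tibble: `n`, `mean`, `sd`, `median`, `min`, `max`.
#' @examples
#' hist_stats(0:10, c(0, 0, 1, 2, 3, 2, 1, 0, 0, 0, 0))
#' @export
hist_stats <- function(values, counts) {
  stopifnot(length(values) == length(counts))
  m <- sum(counts)
  if (m == 0) {
    return(tibble(n = 0, mean = NA_real_, sd = NA_real_, median = NA_real_,
                  min = NA_real_, max = NA_real_))
  }
  nz <- counts > 0
  v <- values[nz]; cts <- counts[nz]
  mu <- sum(v * cts) / m
  s2 <- if (m > 1) (sum(v^2 * cts) - m * mu^2) / (m - 1) else NA_real_
  med <- v[which(cumsum(cts) >= m / 2)[1]]
  tibble(n = m, mean = mu, sd = sqrt(pmax(s2, 0)), median = med,
         min = min(v), max = max(v))
}

# effective genome size in bp for coverage denominators: nuclear length, the
# target restriction when one is given, minus any blacklisted bases
effective_genome_size <- function(catalog, criteria, restrict = NULL) {
  nuclear <- catalog[catalog$category == "nuclear", ]
  base_regions <- tibble(rname = nuclear$name, start = 0L, end = nuclear$length)
  if (!is.null(criteria$target_seqs)) {
    base_regions <- base_regions[base_regions$rname %in% criteria$target_seqs, ]
  }
  if (!is.null(restrict)) {
    if (is.character(restrict)) restrict <- parse_region_string(restrict)
    restrict <- dplyr::mutate(
      restrict,
      start = ifelse(is.na(.data$start), 0L, .data$start),
      end = ifelse(is.na(.data$end),
                   catalog$length[match(.data$rname, catalog$name)], .data$end))
    base_regions <- interval_intersection(base_regions, restrict)
  }
  if (!is.null(criteria$target_regions) && nrow(criteria$target_regions)) {
    base_regions <- interval_intersection(base_regions, criteria$target_regions)
  }
  eff <- merged_width(base_regions)
  if (!is.null(criteria$blacklist) && nrow(criteria$blacklist)) {
    eff <- eff - overlap_width(base_regions, criteria$blacklist)
  }
  eff
}

# intersection of two 0-based half-open interval tibbles
interval_intersection <- function(a, b) {
  refs <- intersect(unique(a$rname), unique(b$rname))
  out <- lapply(refs, function(rf) {
    ra <- IRanges::reduce(with(a[a$rname == rf, ], IRanges::IRanges(start + 1L, end)))
    rb <- IRanges::reduce(with(b[b$rname == rf, ], IRanges::IRanges(start + 1L, end)))
    ri <- IRanges::intersect(ra, rb)
    tibble(rname = rf, start = IRanges::start(ri) - 1L, end = IRanges::end(ri))
  })
  dplyr::bind_rows(out) %||% tibble(rname = character(), start = integer(),
                                    end = integer())
}

# flush depth events and assemble the depth histogram across all references
finalize_depth <- function(st, effective_genome) {
  hist_acc <- new.env(parent = emptyenv())
  hist_acc$h <- numeric(0)
  covered <- 0
  total_aligned <- 0
  for (ref in names(st$events)) {
    len <- st$catalog$length[match(ref, st$catalog$name)]
    dv <- depth_from_events(st$events[[ref]], len)
    covered <- covered + dv$covered
    for (d in names(dv$hist)) {
      hist_acc$h[d] <- (hist_acc$h[d] %||% 0)
      hist_acc$h[d] <- ifelse(is.na(hist_acc$h[d]), 0, hist_acc$h[d]) + dv$hist[[d]]
    }
  }
  depth_vals <- as.integer(names(hist_acc$h))
  o <- order(depth_vals)
  list(values = depth_vals[o], counts = as.numeric(hist_acc$h)[o],
       covered = covered, zero = max(effective_genome - covered, 0))
}
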
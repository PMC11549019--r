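# internal helpers shared across modules

# centered moving average; returns NA where the full window does not fit
moving_average <- function(x, window) {
  stopifnot(window >= 1L)
  as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
}

# parse a samtools-style 1-based region string "Chr1:100-200" or "Chr1"
# into a one-row 0-based half-open interval tibble
parse_region_string <- function(x) {
  m <- regmatches(x, regexec("^([^:]+)(?::([0-9,]+)-([0-9,]+))?$", x))[[1]]
  if (length(m) == 0L || m[2] == "") {
    abort(sprintf("cannot parse region '%s' (expected 'seq' or 'seq:start-end')", x))
  }
  if (m[3] == "") {
    tibble(rname = m[2], start = NA_integer_, end = NA_integer_)
  } else {
    s <- as.integer(gsub(",", "", m[3]))
    e <- as.integer(gsub(",", "", m[4]))
    if (s < 1L || e < s) abort(sprintf("invalid region '%s'", x))
    tibble(rname = m[2], start = s - 1L, end = e)
  }
}

# merged total width of a 0-based half-open interval set, per reference
merged_width <- function(regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(0)
  ir <- split(
    IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    regions$rname
  )
  sum(vapply(ir, function(r) sum(IRanges::width(IRanges::reduce(r))), numeric(1)))
}

# width of overlap between two interval sets (both 0-based half-open tibbles)
overlap_width <- function(a, b) {
  if (is.null(a) || is.null(b) || nrow(a) == 0L || nrow(b) == 0L) return(0)
  refs <- intersect(unique(a$rname), unique(b$rname))
  tot <- 0
  for (rf in refs) {
    ra <- IRanges::reduce(with(a[a$rname == rf, ], IRanges::IRanges(start + 1L, end)))
    rb <- IRanges::reduce(with(b[b$rname == rf, ], IRanges::IRanges(start + 1L, end)))
    tot <- tot + sum(IRanges::width(IRanges::intersect(ra, rb)))
  }
  tot
}

# TRUE for rows of `x` (rname/start/end, 0-based half-open) overlapping
# any interval of `regions` by >= 1 bp
overlaps_any <- function(x, regions) {
  out <- logical(nrow(x))
  if (nrow(x) == 0L || is.null(regions) || nrow(regions) == 0L) return(out)
  for (rf in intersect(unique(x$rname), unique(regions$rname))) {
    i <- which(x$rname == rf)
    qr <- IRanges::IRanges(x$start[i] + 1L, x$end[i])
    sr <- with(regions[regions$rname == rf, ], IRanges::IRanges(start + 1L, end))
    out[i] <- IRanges::overlapsAny(qr, sr)
  }
  out
}
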
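#' Read a BED file of regions
#'
#' Reads 3+ column BED into a 0-based, half-open interval tibble. The strand
#' column (column 6) is honored when present; otherwise intervals are
#' unstranded (`"*"`). Blank lines and lines starting with `track`, `browser`
#' or `#` are skipped. Invalid intervals are reported with their line number.
#'
#' @param path Path to a BED file.
#' @param role Label for the set's role, one of `"peaks"`, `"tss"`, `"tfbs"`,
#'   `"target"`, `"blacklist"` (free-form labels allowed).
#' @return A tibble with columns `rname`, `start`, `end`, `name`, `strand` and
#'   attribute `role`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("Chr1\t100\t200", "Chr1\t500\t501\tg1\t0\t-"), bed)
#' read_bed(bed, role = "tss")
#' @export
read_bed <- function(path, role = "target") {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) &
    !grepl("^(track|browser|#)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    out <- tibble(rname = character(), start = integer(), end = integer(),
                  name = character(), strand = character())
    attr(out, "role") <- role
    return(out)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3L) {
    bad <- idx[which.min(lengths(fields))]
    abort(sprintf("line %d: BED requires >= 3 tab-separated columns", bad))
  }
  rname <- vapply(fields, `[[`, character(1), 1L)
  start_chr <- vapply(fields, `[[`, character(1), 2L)
  end_chr <- vapply(fields, `[[`, character(1), 3L)
  if (any(!grepl("^[0-9]+$", start_chr)) || any(!grepl("^[0-9]+$", end_chr))) {
    bad <- idx[which(!grepl("^[0-9]+$", start_chr) | !grepl("^[0-9]+$", end_chr))[1]]
    abort(sprintf("line %d: non-integer BED coordinates", bad))
  }
  start <- as.integer(start_chr)
  end <- as.integer(end_chr)
  if (any(start >= end)) {
    bad <- idx[which(start >= end)[1]]
    abort(sprintf("line %d: start >= end", bad))
  }
  name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4]] else NA_character_,
                 character(1))
  strand <- vapply(fields, function(f) {
    if (length(f) >= 6L && f[[6]] %in% c("+", "-")) f[[6]] else "*"
  }, character(1))
  out <- tibble(rname = rname, start = start, end = end,
                name = name, strand = strand)
  attr(out, "role") <- role
  out
}

#' Write intervals to a BED file
#'
#' Inverse of [read_bed()]: writes a 0-based half-open interval tibble as
#' 6-column BED (3-column when neither names nor strands are present).
#'
#' @param regions Tibble with `rname`, `start`, `end` and optionally `name`,
#'   `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  has_extra <- ("strand" %in% names(regions) && any(regions$strand %in% c("+", "-"))) ||
    ("name" %in% names(regions) && any(!is.na(regions$name)))
  if (has_extra) {
    nm <- if ("name" %in% names(regions)) {
      ifelse(is.na(regions$name), ".", regions$name)
    } else rep(".", nrow(regions))
    st <- if ("strand" %in% names(regions)) {
      ifelse(regions$strand %in% c("+", "-"), regions$strand, ".")
    } else rep(".", nrow(regions))
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     regions$rname, regions$start, regions$end, nm, st)
  } else {
    lines <- sprintf("%s\t%d\t%d", regions$rname, regions$start, regions$end)
  }
  writeLines(lines, path)
  invisible(path)
}
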
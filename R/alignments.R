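# BAM streaming: coordinate-sorted single-pass access to alignments,
# converted into a tidy per-read table.

scan_what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "isize", "seq")

# decode SAM flag bits into a tibble of logicals
decode_flags <- function(flag) {
  tibble(
    paired        = bitwAnd(flag, 0x1) > 0L,
    proper_pair   = bitwAnd(flag, 0x2) > 0L,
    unmapped      = bitwAnd(flag, 0x4) > 0L,
    mate_unmapped = bitwAnd(flag, 0x8) > 0L,
    reverse       = bitwAnd(flag, 0x10) > 0L,
    first_in_pair = bitwAnd(flag, 0x40) > 0L,
    secondary     = bitwAnd(flag, 0x100) > 0L,
    qc_fail       = bitwAnd(flag, 0x200) > 0L,
    duplicate     = bitwAnd(flag, 0x400) > 0L,
    supplementary = bitwAnd(flag, 0x800) > 0L
  )
}

# one scanBam result chunk -> per-read tibble (0-based half-open coordinates)
chunk_to_tibble <- function(chunk) {
  n <- length(chunk$qname)
  fl <- decode_flags(chunk$flag)
  qlen <- Biostrings::width(chunk$seq)
  gc <- as.integer(Biostrings::letterFrequency(chunk$seq, "GC"))
  gc[qlen == 0L] <- NA_integer_  # record stores no sequence ("*")
  ref_width <- rep(NA_integer_, n)
  has_cigar <- !is.na(chunk$cigar)
  if (any(has_cigar)) {
    ref_width[has_cigar] <-
      GenomicAlignments::cigarWidthAlongReferenceSpace(chunk$cigar[has_cigar])
  }
  start <- chunk$pos - 1L
  dplyr::bind_cols(
    tibble(
      qname = chunk$qname,
      rname = as.character(chunk$rname),
      start = start,
      end = start + ref_width,
      strand = if_else(fl$reverse, "-", "+"),
      mapq = as.integer(chunk$mapq),
      template_length = as.integer(chunk$isize),
      aligned_length = ref_width,
      query_length = as.integer(qlen),
      gc_count = gc
    ),
    fl
  )
}

check_coordinate_sorted <- function(bam) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$text
  hd <- hdr[names(hdr) == "@HD"]
  so <- unlist(lapply(hd, function(x) sub("^SO:", "", grep("^SO:", x, value = TRUE))))
  if (length(so) == 0L || !any(so == "coordinate")) {
    abort(sprintf("BAM is not coordinate-sorted (header SO tag: %s)",
                  if (length(so)) paste(so, collapse = ",") else "absent"))
  }
  invisible(TRUE)
}

# build the ScanBamParam 'which' GRanges-like object for a restriction
restriction_param <- function(bam, restrict, catalog) {
  if (is.null(restrict)) return(Rsamtools::ScanBamParam(what = scan_what))
  if (is.character(restrict) && length(restrict) == 1L) {
    restrict <- parse_region_string(restrict)
  }
  if (!is.data.frame(restrict)) {
    abort("restrict must be a region string or an interval tibble")
  }
  if (!file.exists(paste0(bam, ".bai")) && !file.exists(sub("\\.bam$", ".bai", bam)) &&
      !file.exists(paste0(bam, ".csi"))) {
    abort("region-restricted streaming requires a BAM index (.bai/.csi)")
  }
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  unknown <- setdiff(unique(restrict$rname), names(targets))
  if (length(unknown)) {
    abort(sprintf("restriction names absent from BAM header: %s",
                  paste(unknown, collapse = ", ")))
  }
  start <- ifelse(is.na(restrict$start), 0L, restrict$start)
  end <- ifelse(is.na(restrict$end), targets[restrict$rname], restrict$end)
  # merge per reference so overlapping query windows never duplicate reads
  rl <- IRanges::reduce(S4Vectors::split(IRanges::IRanges(start + 1L, end),
                                         restrict$rname))
  Rsamtools::ScanBamParam(what = scan_what, which = rl)
}

#' Read alignments from a coordinate-sorted BAM into a tibble
#'
#' Loads alignments (optionally restricted to a reference sequence or a region
#' set) as one row per record with 0-based half-open coordinates, decoded SAM
#' flags, the CIGAR-derived reference span and the G+C count of the stored
#' query sequence (soft-clipped bases included; records without a sequence get
#' `NA`).
#'
#' @param bam Path to a coordinate-sorted BAM. An index is required only when
#'   `restrict` is given.
#' @param restrict `NULL` for the whole file; a samtools-style region string
#'   (`"Chr1"` or `"Chr1:100-200"`, 1-based inclusive); or an interval tibble
#'   (e.g. from [read_bed()]). Reads overlapping a restriction window by
#'   >= 1 bp are included.
#'
#' @return A tibble with columns `qname`, `rname`, `start`, `end`, `strand`,
#'   `mapq`, `template_length`, `aligned_length`, `query_length`, `gc_count`
#'   and the flag booleans `paired`, `proper_pair`, `unmapped`,
#'   `mate_unmapped`, `reverse`, `first_in_pair`, `secondary`, `qc_fail`,
#'   `duplicate`, `supplementary`, in coordinate order.
#' @examples
#' fx <- generate_fixture(synthetic_spec(n_fragments = 100), tempfile("fx"))
#' reads <- read_alignments(fx$bam)
#' nrow(reads)
#' @export
read_alignments <- function(bam, restrict = NULL) {
  check_coordinate_sorted(bam)
  param <- restriction_param(bam, restrict, NULL)
  res <- Rsamtools::scanBam(bam, param = param)
  chunks <- lapply(res, chunk_to_tibble)
  out <- dplyr::bind_rows(chunks)
  if (length(chunks) > 1L) {
    # multiple query windows come back window-by-window; restore genome order
    ord <- order(match(out$rname, names(Rsamtools::scanBamHeader(bam)[[1]]$targets)),
                 out$start)
    out <- out[ord, , drop = FALSE]
    out <- dplyr::distinct(out)
  }
  out
}

# single-pass chunked traversal of an unrestricted BAM; calls
# callback(reads_tibble) for each chunk in coordinate order
stream_alignment_chunks <- function(bam, callback, yield_size = 200000L,
                                    restrict = NULL) {
  check_coordinate_sorted(bam)
  if (!is.null(restrict)) {
    # indexed region queries arrive as one in-memory block per window
    reads <- read_alignments(bam, restrict = restrict)
    if (nrow(reads)) callback(reads)
    return(invisible(NULL))
  }
  bf <- Rsamtools::BamFile(bam, yieldSize = yield_size)
  open(bf)
  on.exit(close(bf))
  param <- Rsamtools::ScanBamParam(what = scan_what)
  repeat {
    chunk <- Rsamtools::scanBam(bf, param = param)[[1]]
    if (length(chunk$qname) == 0L) break
    callback(chunk_to_tibble(chunk))
  }
  invisible(NULL)
}
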
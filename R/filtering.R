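#' Construct read-filtering criteria
#'
#' All thresholds and switches controlling which alignments count as
#' high-quality ("passing") nuclear reads, plus region/blacklist restriction
#' and analysis-mode presets.
#'
#' With `use_all = TRUE` every threshold filter is disabled: all mapped
#' primary non-supplementary reads pass, whatever their MAPQ, pairing,
#' duplicate status or origin (organellar reads included). Unmapped, secondary
#' and supplementary records never pass.
#'
#' @param min_mapq Minimum mapping quality (0-255, default 0).
#' @param min_fragment,max_fragment Fragment-length window in bp applied to
#'   properly paired reads (defaults 0 and unlimited).
#' @param require_proper_pair Drop reads not flagged as proper pairs
#'   (paired-end data only; single-end reads skip this check).
#' @param drop_duplicates,drop_secondary,drop_supplementary,drop_qc_fail
#'   Drop reads carrying the corresponding SAM flag.
#' @param nuclear_only Organellar (mitochondrial/plastid) reads are counted in
#'   their category but never pass (default `TRUE`).
#' @param use_all Disable every filter (see Details).
#' @param target_regions,blacklist Optional interval tibbles (see
#'   [read_bed()]); a read passes only if it overlaps a target region and does
#'   not overlap the blacklist (>= 1 bp overlap either way).
#' @param target_seqs Optional character vector of reference names; reads on
#'   other references fail as off-target.
#' @param mode Analysis mode: `"default"`, `"nfr"`, `"mono"`, `"chip"` or
#'   `"footprint"`; presets are applied by [apply_preset()] without
#'   overriding values you set explicitly.
#' @return A `qc_criteria` list.
#' @examples
#' qc_criteria(min_mapq = 40, min_fragment = 50, max_fragment = 150)
#' qc_criteria(mode = "nfr")$max_fragment  # 120
#' @export
qc_criteria <- function(min_mapq = 0L,
                        min_fragment = 0L,
                        max_fragment = Inf,
                        require_proper_pair = TRUE,
                        drop_duplicates = TRUE,
                        drop_secondary = TRUE,
                        drop_supplementary = TRUE,
                        drop_qc_fail = TRUE,
                        nuclear_only = TRUE,
                        use_all = FALSE,
                        target_regions = NULL,
                        blacklist = NULL,
                        target_seqs = NULL,
                        mode = c("default", "nfr", "mono", "chip", "footprint")) {
  mode <- match.arg(mode)
  if (min_mapq < 0 || min_mapq > 255) abort("min_mapq must be in [0, 255]")
  if (min_fragment < 0) abort("min_fragment must be >= 0")
  if (min_fragment > max_fragment) abort("min_fragment must be <= max_fragment")
  user_set <- setdiff(names(match.call())[-1], "")
  crit <- structure(list(
    min_mapq = as.integer(min_mapq),
    min_fragment = as.numeric(min_fragment),
    max_fragment = as.numeric(max_fragment),
    require_proper_pair = require_proper_pair,
    drop_duplicates = drop_duplicates,
    drop_secondary = drop_secondary,
    drop_supplementary = drop_supplementary,
    drop_qc_fail = drop_qc_fail,
    nuclear_only = nuclear_only,
    use_all = use_all,
    target_regions = target_regions,
    blacklist = blacklist,
    target_seqs = target_seqs,
    mode = mode,
    # signal-layer switches carried with the criteria so presets can set them
    tn5_shift = TRUE,
    resize = 1L,
    anchor_role = "tss",
    footprint = FALSE
  ), class = "qc_criteria", user_set = user_set)
  if (use_all) crit <- force_use_all(crit)
  if (mode != "default") crit <- apply_preset(mode, crit)
  crit
}

force_use_all <- function(crit) {
  crit$min_mapq <- 0L
  crit$min_fragment <- 0
  crit$max_fragment <- Inf
  crit$require_proper_pair <- FALSE
  crit$drop_duplicates <- FALSE
  crit$drop_qc_fail <- FALSE
  crit$nuclear_only <- FALSE
  crit$target_regions <- NULL
  crit$blacklist <- NULL
  crit$target_seqs <- NULL
  crit
}

#' Apply an analysis-mode preset to filter criteria
#'
#' Presets adjust criteria for common ATAC-seq tasks. Fields the user set
#' explicitly in [qc_criteria()] are never overridden by a preset.
#'
#' * `nfr` — nucleosome-free-region reads: `max_fragment = 120`.
#' * `mono` — mononucleosomal reads: fragment window 150-250 bp.
#' * `chip` — ChIP-seq: Tn5 shift off, 5' resizing off (full alignment
#'   footprint used), pileup anchored at peaks instead of TSSs.
#' * `footprint` — single-base Tn5 insertion counting on, Tn5 shift on,
#'   pileup anchored at TF binding sites.
#' * `default` — identity.
#'
#' @param mode One of `"default"`, `"nfr"`, `"mono"`, `"chip"`, `"footprint"`.
#' @param base A `qc_criteria` object.
#' @return The adjusted `qc_criteria`.
#' @export
apply_preset <- function(mode, base) {
  valid <- c("default", "nfr", "mono", "chip", "footprint")
  if (!mode %in% valid) {
    abort(sprintf("unknown mode '%s'; valid modes: %s",
                  mode, paste(valid, collapse = ", ")))
  }
  user_set <- attr(base, "user_set") %||% character()
  set_unless_user <- function(crit, field, value) {
    if (!field %in% user_set) crit[[field]] <- value
    crit
  }
  crit <- base
  crit$mode <- mode
  if (mode == "nfr") {
    crit <- set_unless_user(crit, "max_fragment", 120)
  } else if (mode == "mono") {
    crit <- set_unless_user(crit, "min_fragment", 150)
    crit <- set_unless_user(crit, "max_fragment", 250)
  } else if (mode == "chip") {
    crit$tn5_shift <- FALSE
    crit$resize <- NA_integer_   # NA = no resizing, pile up full alignments
    crit$anchor_role <- "peak_center"
  } else if (mode == "footprint") {
    crit$tn5_shift <- TRUE
    crit$resize <- 1L
    crit$footprint <- TRUE
    crit$anchor_role <- "tfbs"
  }
  crit
}

#' Nominal fragment length of reads
#'
#' For a properly paired read the fragment length is `|template_length|`;
#' unpaired reads, improper pairs and reads with `template_length == 0` have
#' no defined fragment length (`NA`). Histograms count each fragment once, via
#' the mate with positive template length.
#'
#' @param reads An alignment tibble from [read_alignments()].
#' @return Numeric vector of fragment lengths in bp (`NA` where undefined).
#' @export
nominal_fragment_length <- function(reads) {
  ifelse(reads$paired & reads$proper_pair & reads$template_length != 0L,
         abs(reads$template_length), NA_real_)
}

fail_reason_levels <- c("unmapped", "secondary", "supplementary", "qc_fail",
                        "duplicate", "improper_pair", "low_mapq",
                        "fragment_short", "fragment_long", "organellar",
                        "off_target", "blacklisted")

#' Evaluate reads against filter criteria
#'
#' Assigns every read its reference category and a pass/fail verdict. Checks
#' are applied in a fixed order (unmapped, secondary, supplementary, qc_fail,
#' duplicate, proper pair, MAPQ, fragment bounds, organellar,
#' target/blacklist) and all applicable failure reasons are accumulated, not
#' short-circuited, so reason tallies are complete. Fragment-length and
#' proper-pair checks are skipped (not failed) for unpaired reads.
#'
#' @param reads Alignment tibble from [read_alignments()].
#' @param criteria A [qc_criteria()] object.
#' @param catalog A [reference_catalog()] tibble.
#' @return `reads` with added columns `category` (factor), `passed` (logical)
#'   and `fail_reasons` (comma-separated reason codes, `""` when passing).
#' @examples
#' fx <- generate_fixture(synthetic_spec(n_fragments = 100), tempfile("fx"))
#' reads <- read_alignments(fx$bam)
#' ev <- evaluate_reads(reads, qc_criteria(), reference_catalog(fx$bam))
#' table(ev$category, ev$passed)
#' @export
evaluate_reads <- function(reads, criteria, catalog) {
  n <- nrow(reads)
  category <- catalog$category[match(reads$rname, catalog$name)]
  bad <- !reads$unmapped & is.na(category)
  if (any(bad)) {
    abort(sprintf("reference name(s) not in catalog: %s",
                  paste(unique(reads$rname[bad]), collapse = ", ")))
  }
  # unmapped reads with an unresolvable reference fall in the default
  # (nuclear) category so category totals always partition the stream
  category[is.na(category)] <- "nuclear"
  reasons <- vector("list", 12L)
  names(reasons) <- fail_reason_levels
  mapped <- !reads$unmapped
  flen <- nominal_fragment_length(reads)

  reasons$unmapped <- reads$unmapped
  reasons$secondary <- mapped & reads$secondary & criteria$drop_secondary
  reasons$supplementary <- mapped & reads$supplementary & criteria$drop_supplementary
  reasons$qc_fail <- mapped & reads$qc_fail & criteria$drop_qc_fail
  reasons$duplicate <- mapped & reads$duplicate & criteria$drop_duplicates
  reasons$improper_pair <- mapped & reads$paired & !reads$proper_pair &
    criteria$require_proper_pair
  reasons$low_mapq <- mapped & reads$mapq < criteria$min_mapq
  reasons$fragment_short <- mapped & !is.na(flen) & flen < criteria$min_fragment
  reasons$fragment_long <- mapped & !is.na(flen) & flen > criteria$max_fragment
  reasons$organellar <- mapped & criteria$nuclear_only &
    !is.na(category) & category != "nuclear"

  off_target <- rep(FALSE, n)
  if (!is.null(criteria$target_seqs)) {
    off_target <- mapped & !(reads$rname %in% criteria$target_seqs)
  }
  if (!is.null(criteria$target_regions) && nrow(criteria$target_regions)) {
    on_target <- overlaps_any(reads, criteria$target_regions)
    off_target <- off_target | (mapped & !on_target)
  }
  reasons$off_target <- off_target
  reasons$blacklisted <- if (!is.null(criteria$blacklist) &&
                             nrow(criteria$blacklist)) {
    mapped & overlaps_any(reads, criteria$blacklist)
  } else rep(FALSE, n)

  reason_mat <- do.call(cbind, reasons)
  n_fail <- rowSums(reason_mat)
  passed <- n_fail == 0L
  fail_str <- character(n)
  if (any(!passed)) {
    ii <- which(!passed)
    fail_str[ii] <- apply(reason_mat[ii, , drop = FALSE], 1L, function(r)
      paste(fail_reason_levels[r], collapse = ","))
  }
  reads$category <- category
  reads$passed <- passed
  reads$fail_reasons <- fail_str
  reads
}

#' @export
print.qc_criteria <- function(x, ...) {
  cat("<qc_criteria>  mode:", x$mode, if (x$use_all) "(use-all)" else "", "\n")
  cat(sprintf("  MAPQ >= %d; fragment length in [%g, %g]\n",
              x$min_mapq, x$min_fragment, x$max_fragment))
  cat(sprintf("  drop: %s\n", paste(c(
    if (x$drop_duplicates) "duplicates",
    if (x$drop_secondary) "secondary",
    if (x$drop_supplementary) "supplementary",
    if (x$drop_qc_fail) "qc-fail",
    if (x$require_proper_pair) "improper-pairs",
    if (x$nuclear_only) "organellar"), collapse = ", ")))
  if (!is.null(x$target_seqs))
    cat("  target sequences:", paste(x$target_seqs, collapse = ", "), "\n")
  if (!is.null(x$target_regions))
    cat("  target regions:", nrow(x$target_regions), "intervals\n")
  if (!is.null(x$blacklist))
    cat("  blacklist:", nrow(x$blacklist), "intervals\n")
  invisible(x)
}
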
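# The single-pass QC driver: stream a coordinate-sorted BAM once, evaluate
# every read, accumulate counts/histograms/depth, then compute the positional
# analytics (FRiP, TSS enrichment, footprints, periodicity) from the passing
# reads and assemble the report.

as_regions <- function(x, role) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) return(read_bed(x, role = role))
  if (is.data.frame(x)) {
    if (!"strand" %in% names(x)) x$strand <- "*"
    return(x)
  }
  abort(sprintf("%s must be a BED path or an interval tibble", role))
}

#' Run ATAC-seq quality control on a BAM file
#'
#' Streams a coordinate-sorted BAM once, classifying every read by reference
#' category (nuclear/mitochondrial/plastid) and pass/fail verdict under
#' `criteria`, and accumulating read-category counts, fragment-length,
#' alignment-length, MAPQ and GC histograms, and event-based genome-wide
#' depth for the passing nuclear reads. When the corresponding BED inputs are
#' given it also computes FRiP, the TSS pileup and enrichment score, and the
#' Tn5 insertion footprint profile; fragment-length periodicity is estimated
#' whenever enough fragment mass is available.
#'
#' @param bam Path to a coordinate-sorted BAM (index required only with
#'   `restrict`).
#' @param tss,peaks,tfbs Optional BED paths or interval tibbles (TSSs, peaks,
#'   TF binding sites).
#' @param criteria A [qc_criteria()].
#' @param mito,plastid Organelle sequence-name lists for the catalog.
#' @param restrict Optional region restriction (see [read_alignments()]).
#' @param tss_radius,footprint_radius Pileup half-widths in bp.
#' @param flank_fraction,smooth TSS-enrichment-score parameters (see
#'   [tss_enrichment_score()]).
#' @param tn5_offsets Tn5 shift magnitudes, plus/minus strand.
#' @param max_fragment_tracked Fragment/alignment histogram cap in bp.
#' @param filtered_bam Optional output path: reads passing `criteria` are
#'   written to a new BAM (all fields and tags preserved, a `@PG` line
#'   appended) and the written count is cross-checked into the report.
#' @param sample Sample label (defaults to the BAM basename).
#' @return A `qc_report` object; see [report_text()], [write_report_json()],
#'   [tidy.qc_report()], [glance.qc_report()].
#' @examples
#' fx <- generate_fixture(preset_fixtures(n_fragments = 2000)$clean,
#'                        tempfile("fx"))
#' rep <- qc_run(fx$bam, tss = fx$beds$tss, peaks = fx$beds$peaks)
#' glance(rep)
#' @export
qc_run <- function(bam,
                   tss = NULL, peaks = NULL, tfbs = NULL,
                   criteria = qc_criteria(),
                   mito = default_mito_names(),
                   plastid = default_plastid_names(),
                   restrict = NULL,
                   tss_radius = 1000L,
                   footprint_radius = 100L,
                   flank_fraction = 0.1,
                   smooth = 25L,
                   tn5_offsets = c(4L, 5L),
                   max_fragment_tracked = 2000L,
                   filtered_bam = NULL,
                   sample = basename(bam)) {
  catalog <- reference_catalog(bam, mito = mito, plastid = plastid)
  tss <- as_regions(tss, "tss")
  peaks <- as_regions(peaks, "peaks")
  tfbs <- as_regions(tfbs, "tfbs")

  st <- new_qc_state(catalog, criteria, max_fragment_tracked)
  passing_chunks <- list()
  stream_alignment_chunks(bam, function(chunk) {
    ev <- evaluate_reads(chunk, criteria, catalog)
    accumulate(st, ev)
    p <- ev[ev$passed, c("rname", "start", "end", "strand", "category")]
    if (nrow(p)) passing_chunks[[length(passing_chunks) + 1L]] <<- p
  }, restrict = restrict)
  passing <- dplyr::bind_rows(passing_chunks)

  frip_val <- NA_real_
  if (!is.null(peaks)) {
    fr_input <- passing
    fr_input$passed <- TRUE
    frip_val <- if (nrow(passing)) frip(fr_input, peaks) else {
      warn("no passing reads; FRiP undefined"); NA_real_
    }
  }

  anchor_role <- criteria$anchor_role
  pile_anchors <- if (anchor_role == "peak_center") peaks else tss
  tss_pileup <- NULL
  tes <- NA_real_
  if (!is.null(pile_anchors) && nrow(pile_anchors) && nrow(passing)) {
    eff <- effective_intervals(passing, resize = criteria$resize,
                               tn5 = criteria$tn5_shift, catalog = catalog,
                               offsets = tn5_offsets)
    tss_pileup <- pileup_profile(eff, pile_anchors, radius = tss_radius,
                                 role = anchor_role, resize = criteria$resize,
                                 tn5_shifted = criteria$tn5_shift,
                                 catalog = catalog)
    tes <- tss_enrichment_score(tss_pileup, flank_fraction = flank_fraction,
                                smooth = smooth)
  }

  footprint <- NULL
  if (!is.null(tfbs) && nrow(tfbs) && nrow(passing)) {
    footprint <- footprint_profile(passing, tfbs, radius = footprint_radius,
                                   catalog = catalog, offsets = tn5_offsets)
  }

  report <- finalize_report(st, criteria, catalog,
                            restrict = restrict,
                            sample = sample, input = bam)
  report$frip <- frip_val
  report$tes <- tes
  report$tss_pileup <- tss_pileup
  report$footprint <- footprint
  report$parameters$tss_radius <- as.integer(tss_radius)
  report$parameters$footprint_radius <- as.integer(footprint_radius)
  report$parameters$flank_fraction <- flank_fraction
  report$parameters$smooth <- as.integer(smooth)
  report$parameters$tn5_offsets <- as.integer(tn5_offsets)
  report$parameters$n_peaks <- if (is.null(peaks)) NA_integer_ else nrow(peaks)
  report$parameters$n_tss <- if (is.null(tss)) NA_integer_ else nrow(tss)
  report$parameters$n_tfbs <- if (is.null(tfbs)) NA_integer_ else nrow(tfbs)

  fh <- report$histograms$fragment_length
  per <- withCallingHandlers(
    fragment_periodicity(fh$value, fh$count),
    warning = function(w) invokeRestart("muffleWarning"))
  report$periodicity <- per

  if (!is.null(filtered_bam)) {
    n_written <- write_filtered_bam(bam, filtered_bam, criteria, catalog,
                                    restrict = restrict)
    report$filtered_bam <- filtered_bam
    report$n_written <- n_written
    if (n_written != report$summary$n_passing) {
      warn(sprintf("filtered BAM count (%d) != passing count (%d)",
                   n_written, report$summary$n_passing))
    }
  }
  report
}

# assemble the serializable report from a consumed qc_state
finalize_report <- function(st, criteria, catalog, restrict = NULL,
                            sample = "sample", input = "") {
  counts <- st$counts
  total_reads <- sum(counts[, "total"])
  mapped_reads <- sum(counts[, "mapped"])
  count_tbl <- as_tibble(counts, rownames = "category") %>%
    mutate(
      pct_of_total = if (total_reads > 0) 100 * .data$total / total_reads
                     else NA_real_,
      pct_of_mapped = if (mapped_reads > 0) 100 * .data$mapped / mapped_reads
                      else NA_real_)

  eff_genome <- effective_genome_size(catalog, criteria, restrict = restrict)
  depth <- finalize_depth(st, eff_genome)
  # the depth histogram lists covered bases (depth >= 1); the depth-0 mass is
  # effective_genome - bases_covered and lives in the coverage block
  depth_values <- depth$values
  depth_counts <- depth$counts

  trim_hist <- function(values, counts) {
    nz <- counts > 0
    tibble(value = values[nz], count = as.numeric(counts[nz]))
  }
  cap <- st$cap
  hists <- list(
    fragment_length = trim_hist(c(0:cap, cap + 1L), st$frag_hist),
    alignment_length = trim_hist(c(0:cap, cap + 1L), st$alen_hist),
    mapq = trim_hist(0:255, st$mapq_hist),
    gc_percent = trim_hist(0:100, st$gc_hist),
    depth = trim_hist(depth_values, depth_counts)
  )
  stats <- purrr::map(hists, ~ hist_stats(.x$value, .x$count))

  coverage <- list(
    bases_covered = depth$covered,
    effective_genome = eff_genome,
    fraction = if (eff_genome > 0) depth$covered / eff_genome else NA_real_,
    mean_depth = if (eff_genome > 0)
      sum(depth_values * depth_counts) / eff_genome else NA_real_
  )

  params <- criteria[c("min_mapq", "min_fragment", "max_fragment",
                       "require_proper_pair", "drop_duplicates",
                       "drop_secondary", "drop_supplementary", "drop_qc_fail",
                       "nuclear_only", "use_all", "mode", "tn5_shift",
                       "resize")]
  params$target_seqs <- criteria$target_seqs
  params$n_target_regions <- if (is.null(criteria$target_regions)) NA_integer_
                             else nrow(criteria$target_regions)
  params$n_blacklist <- if (is.null(criteria$blacklist)) NA_integer_
                        else nrow(criteria$blacklist)
  params$restrict <- if (is.null(restrict)) NA_character_
                     else if (is.character(restrict)) restrict
                     else sprintf("<%d interval(s)>", nrow(restrict))
  params$max_fragment_tracked <- cap

  structure(list(
    tool = "atacqc",
    version = tool_version(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    sample = sample,
    input = input,
    parameters = params,
    catalog = catalog,
    counts = count_tbl,
    fail_tally = tibble(reason = names(st$fail_tally),
                        n = as.numeric(st$fail_tally)),
    summary = list(
      total_reads = total_reads,
      mapped_reads = mapped_reads,
      n_passing = sum(counts[, "passing"]),
      single_end = all(st$frag_hist == 0) && total_reads > 0 &&
        sum(counts[, "proper_pair"]) == 0
    ),
    stats = stats,
    histograms = hists,
    coverage = coverage,
    frip = NA_real_,
    tes = NA_real_,
    tss_pileup = NULL,
    footprint = NULL,
    periodicity = list(period = NA_real_, power_ratio = NA_real_, mass = 0),
    grid = NULL
  ), class = "qc_report")
}

#' Write the reads passing quality control into a new BAM
#'
#' Streams the input BAM through the same verdict engine used for QC and
#' writes passing records verbatim (all fields and auxiliary tags preserved,
#' input coordinate order kept). A `@PG` header line recording the tool,
#' version and parameter string is appended via samtools when available.
#'
#' @param bam Input coordinate-sorted BAM.
#' @param out_path Output BAM path (an index is written alongside).
#' @param criteria A [qc_criteria()].
#' @param catalog Optional catalog (built from the header when omitted).
#' @param restrict Optional region restriction.
#' @return Number of reads written (invisible cross-check: equals the
#'   passing count of [qc_run()] under the same criteria).
#' @export
write_filtered_bam <- function(bam, out_path, criteria,
                               catalog = NULL, restrict = NULL) {
  if (is.null(catalog)) catalog <- reference_catalog(bam)
  dest_dir <- dirname(out_path)
  if (!dir.exists(dest_dir) || file.access(dest_dir, 2L) != 0L) {
    abort(sprintf("cannot write to %s", out_path))
  }
  rule <- S4Vectors::FilterRules(list(passes = function(df) {
    reads <- chunk_to_tibble(as.list(df))
    evaluate_reads(reads, criteria, catalog)$passed
  }))
  param <- restriction_param(bam, restrict, catalog)
  Rsamtools::filterBam(bam, destination = out_path, filter = rule,
                       param = param, indexDestination = TRUE)
  append_pg_line(out_path, criteria)
  as.integer(Rsamtools::countBam(out_path)$records)
}

criteria_string <- function(criteria) {
  sprintf(paste0("--mapq %d --min-flen %g --max-flen %g --mode %s%s%s%s%s%s"),
          criteria$min_mapq, criteria$min_fragment, criteria$max_fragment,
          criteria$mode,
          if (criteria$use_all) " --use-all" else "",
          if (!criteria$drop_duplicates) " --keep-duplicates" else "",
          if (!criteria$drop_secondary) " --keep-secondary" else "",
          if (!criteria$require_proper_pair) " --keep-improper" else "",
          if (!criteria$nuclear_only) " --keep-organellar" else "")
}

# append a @PG line to a BAM header in place (samtools reheader); silently
# left unchanged (with a warning) when samtools is unavailable
append_pg_line <- function(bam_path, criteria) {
  samtools <- Sys.which("samtools")
  if (!nzchar(samtools)) {
    warn("samtools not found; @PG line not added to filtered BAM header")
    return(invisible(FALSE))
  }
  hdr_file <- tempfile(fileext = ".sam")
  system2(samtools, c("view", "-H", shQuote(bam_path)), stdout = hdr_file)
  pg <- sprintf("@PG\tID:atacqc\tPN:atacqc\tVN:%s\tCL:%s",
                tool_version(), criteria_string(criteria))
  cat(pg, "\n", sep = "", file = hdr_file, append = TRUE)
  tmp_bam <- tempfile(fileext = ".bam")
  status <- system2(samtools,
                    c("reheader", shQuote(hdr_file), shQuote(bam_path)),
                    stdout = tmp_bam)
  if (identical(status, 0L) && file.exists(tmp_bam) &&
      file.size(tmp_bam) > 0) {
    file.copy(tmp_bam, bam_path, overwrite = TRUE)
    Rsamtools::indexBam(bam_path)
  }
  unlink(c(hdr_file, tmp_bam))
  invisible(TRUE)
}
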
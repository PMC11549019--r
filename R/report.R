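# Report serialization: combined JSON (versioned schema), per-sample text,
# multi-report merging for side-by-side comparison.

report_schema_version <- "1.0"

pileup_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  list(role = p$role, radius = p$radius, n_anchors = p$n_anchors,
       resize = if (is.na(p$resize)) NA else p$resize,
       tn5_shifted = p$tn5_shifted,
       position = as.integer(names(p$values)),
       density = as.numeric(p$values))
}

# JSON cannot carry Inf: an unlimited max_fragment is serialized as null
sanitize_scalar <- function(x) {
  if (is.numeric(x) && length(x) == 1L && is.infinite(x)) NA_real_ else x
}

report_to_list <- function(r) {
  params <- lapply(r$parameters, sanitize_scalar)
  list(
    tool = r$tool,
    version = r$version,
    timestamp = r$timestamp,
    sample = r$sample,
    input = r$input,
    parameters = params,
    catalog = lapply(seq_len(nrow(r$catalog)), function(i) list(
      name = r$catalog$name[i], length = r$catalog$length[i],
      category = as.character(r$catalog$category[i]))),
    counts = as.list(r$counts),
    fail_tally = as.list(r$fail_tally),
    summary = r$summary,
    stats = lapply(r$stats, as.list),
    histograms = lapply(r$histograms, function(h)
      list(value = h$value, count = h$count)),
    coverage = r$coverage,
    frip = r$frip,
    tes = r$tes,
    tss_pileup = pileup_to_list(r$tss_pileup),
    footprint = pileup_to_list(r$footprint),
    periodicity = r$periodicity,
    grid = if (is.null(r$grid)) NULL else as.list(r$grid),
    filtered_bam = r$filtered_bam %||% NA_character_,
    n_written = r$n_written %||% NA_integer_
  )
}

#' Write one or more QC reports to a combined JSON file
#'
#' One JSON document with a top-level schema version and an array of
#' per-sample report objects; numbers are serialized at full precision and
#' nullable analytics (FRiP, TES, pileups, periodicity, grid) are explicit
#' `null`s. The document is checked against the shipped schema before
#' writing.
#'
#' @param reports A `qc_report` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(reports, path) {
  if (inherits(reports, "qc_report")) reports <- list(reports)
  if (length(reports) == 0L) abort("need at least one report")
  doc <- list(schema_version = report_schema_version,
              samples = lapply(reports, report_to_list))
  problems <- validate_report_document(doc)
  if (length(problems)) {
    abort(paste0("internal error: report fails its own schema: ",
                 paste(problems, collapse = "; ")))
  }
  # 17 significant digits: doubles survive the round trip bit-exactly
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           na = "null", null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a combined JSON report file
#'
#' @param path Path written by [write_report_json()].
#' @return The parsed document (list with `schema_version` and `samples`).
#' @export
read_report_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  problems <- validate_report_document(doc)
  if (length(problems)) {
    abort(sprintf("%s does not validate against the report schema: %s",
                  path, paste(problems, collapse = "; ")))
  }
  doc
}

# structural validation against the shipped schema (inst/schema); unknown
# fields are tolerated on read, required fields and types are enforced
validate_report_document <- function(doc) {
  schema <- jsonlite::fromJSON(
    system.file("schema", "qc_report_schema.json", package = "atacqc"),
    simplifyVector = TRUE)
  problems <- character()
  if (is.null(doc$schema_version)) {
    problems <- c(problems, "missing schema_version")
  } else if (!doc$schema_version %in% schema$accepted_versions) {
    problems <- c(problems, sprintf("unknown schema_version '%s'",
                                    doc$schema_version))
  }
  if (is.null(doc$samples) || length(doc$samples) == 0L) {
    return(c(problems, "no samples"))
  }
  req <- schema$required_sample_fields
  for (i in seq_along(doc$samples)) {
    s <- doc$samples[[i]]
    missing <- setdiff(req, names(s))
    if (length(missing)) {
      problems <- c(problems, sprintf("sample %d missing field(s): %s", i,
                                      paste(missing, collapse = ", ")))
    }
    for (h in schema$required_histograms) {
      if (!is.null(s$histograms) && !h %in% names(s$histograms)) {
        problems <- c(problems, sprintf("sample %d missing histogram %s", i, h))
      }
    }
  }
  problems
}

#' Render a QC report as fixed-layout text
#'
#' Every number printed here is also present in the JSON serialization (the
#' JSON is the superset). Percentages are shown to 2 decimal places; both
#' denominators (total reads for category percentages, mapped reads for type
#' percentages) are stated.
#'
#' @param r A `qc_report`.
#' @return Character vector of lines.
#' @export
report_text <- function(r) {
  L <- character()
  add <- function(...) L <<- c(L, sprintf(...))
  add("%s v%s - ATAC-seq quality control report", r$tool, r$version)
  add("sample: %s", r$sample)
  add("input: %s", r$input)
  add("generated: %s", r$timestamp)
  add("parameters: %s", criteria_param_echo(r$parameters))
  add("")
  cs <- catalog_summary(r$catalog)
  add("reference catalog: %s",
      paste(sprintf("%d %s (%d bp)", cs$n_sequences,
                    as.character(cs$category), cs$total_length),
            collapse = ", "))
  add("")
  add("read counts by category (pct of %d total | pct of %d mapped):",
      r$summary$total_reads, r$summary$mapped_reads)
  hdr <- sprintf("  %-14s %9s %9s %9s %9s %9s %9s", "category", "total",
                 "mapped", "duplicate", "secondary", "proper", "passing")
  L <- c(L, hdr)
  for (i in seq_len(nrow(r$counts))) {
    cc <- r$counts[i, ]
    L <- c(L, sprintf("  %-14s %9d %9d %9d %9d %9d %9d   (%6.2f%% | %6.2f%%)",
                      cc$category, cc$total, cc$mapped, cc$duplicate,
                      cc$secondary, cc$proper_pair, cc$passing,
                      cc$pct_of_total, cc$pct_of_mapped))
  }
  add("  %-14s %9d", "all", r$summary$total_reads)
  add("")
  add("passing nuclear-read statistics (n = %d passing reads):",
      r$summary$n_passing)
  stat_line <- function(name, s) {
    if (s$n == 0) sprintf("  %-18s n/a (empty)", name)
    else sprintf("  %-18s mean %.2f  sd %.2f  median %g  min %g  max %g",
                 name, s$mean, s$sd, s$median, s$min, s$max)
  }
  for (nm in names(r$stats)) L <- c(L, stat_line(nm, r$stats[[nm]]))
  add("")
  add("genome coverage: %.0f / %.0f bp (%.2f%%), mean depth %.4f",
      r$coverage$bases_covered, r$coverage$effective_genome,
      100 * (r$coverage$fraction %||% NA_real_), r$coverage$mean_depth)
  add("%s", if (is.na(r$frip)) "FRiP: n/a (no peaks file provided)"
      else sprintf("FRiP: %.4f", r$frip))
  add("%s", if (is.na(r$tes)) "TSS enrichment: n/a (no TSS file provided)"
      else sprintf("TSS enrichment: %.4f", r$tes))
  add("%s", if (is.na(r$periodicity$period))
    "fragment periodicity: none detected"
    else sprintf("fragment periodicity: %.2f bp (power ratio %.1f)",
                 r$periodicity$period, r$periodicity$power_ratio))
  if (!is.null(r$n_written)) {
    add("filtered BAM: %s (%d reads written)", r$filtered_bam, r$n_written)
  }
  if (!is.null(r$grid)) {
    add("")
    add("parameter grid (%d combinations):", nrow(r$grid))
    add("  %8s %8s %8s %10s %8s", "min_mapq", "min_flen", "max_flen",
        "n_passing", "TES")
    for (i in seq_len(nrow(r$grid))) {
      gg <- r$grid[i, ]
      add("  %8g %8g %8g %10d %8.3f", gg$min_mapq, gg$min_fragment,
          gg$max_fragment, gg$n_passing, gg$tes)
    }
  }
  L
}

criteria_param_echo <- function(p) {
  sprintf("--mapq %d --min-flen %g --max-flen %s --mode %s%s", p$min_mapq,
          p$min_fragment,
          if (is.infinite(p$max_fragment) || is.na(p$max_fragment)) "unlimited"
          else format(p$max_fragment),
          p$mode, if (isTRUE(p$use_all)) " --use-all" else "")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' Merge QC report JSON files for side-by-side comparison
#'
#' Reads several combined JSON files (any schema version this package has
#' shipped), validates each, and returns long-format tables keyed by
#' `(sample, metric)` suitable for plotting.
#'
#' @param paths Character vector of JSON paths from [write_report_json()].
#' @return A `qc_comparison` list of tibbles: `metrics` (sample, metric,
#'   value), `histograms` (sample, histogram, value, count) and `pileups`
#'   (sample, profile, position, density), histograms/pileups aligned on the
#'   union of their supports.
#' @export
merge_reports <- function(paths) {
  samples <- list()
  for (p in paths) {
    doc <- tryCatch(read_report_json(p), error = function(e) {
      abort(sprintf("schema mismatch in %s: %s", p, conditionMessage(e)))
    })
    samples <- c(samples, doc$samples)
  }
  metrics <- purrr::map_dfr(samples, function(s) {
    counts <- purrr::map_dfr(seq_along(s$counts$category), function(i)
      tibble(metric = paste0(s$counts$category[i], "_",
                             c("total", "mapped", "duplicate", "passing")),
             value = as.numeric(c(s$counts$total[i], s$counts$mapped[i],
                                  s$counts$duplicate[i], s$counts$passing[i]))))
    scalars <- tibble(
      metric = c("total_reads", "mapped_reads", "n_passing", "frip", "tes",
                 "coverage_fraction", "mean_depth", "periodicity_bp"),
      value = as.numeric(c(s$summary$total_reads, s$summary$mapped_reads,
                           s$summary$n_passing,
                           s$frip %||% NA, s$tes %||% NA,
                           s$coverage$fraction %||% NA,
                           s$coverage$mean_depth %||% NA,
                           s$periodicity$period %||% NA)))
    dplyr::bind_rows(counts, scalars) %>% mutate(sample = s$sample, .before = 1)
  })
  histograms <- purrr::map_dfr(samples, function(s) {
    purrr::map_dfr(names(s$histograms), function(h)
      tibble(sample = s$sample, histogram = h,
             value = as.numeric(s$histograms[[h]]$value),
             count = as.numeric(s$histograms[[h]]$count)))
  })
  if (nrow(histograms)) {
    # pad each histogram to the union of bin values across samples
    histograms <- histograms %>%
      group_by(.data$histogram) %>%
      tidyr::complete(.data$sample, .data$value, fill = list(count = 0)) %>%
      ungroup()
  }
  pileups <- purrr::map_dfr(samples, function(s) {
    purrr::map_dfr(c("tss_pileup", "footprint"), function(f) {
      p <- s[[f]]
      if (is.null(p)) return(tibble())
      tibble(sample = s$sample, profile = f,
             position = as.integer(p$position),
             density = as.numeric(p$density))
    })
  })
  if (nrow(pileups)) {
    pileups <- pileups %>%
      group_by(.data$profile) %>%
      tidyr::complete(.data$sample, position = tidyr::full_seq(.data$position, 1)) %>%
      ungroup()
  }
  structure(list(metrics = metrics, histograms = histograms,
                 pileups = pileups),
            class = "qc_comparison")
}

#' Tidy a QC report into a long metric table
#'
#' @param x A `qc_report` (or `qc_pileup`).
#' @param ... Unused.
#' @return A tibble with columns `metric`, `value` (long format).
#' @export
tidy.qc_report <- function(x, ...) {
  counts_long <- x$counts %>%
    tidyr::pivot_longer(-"category", names_to = "type", values_to = "value") %>%
    mutate(metric = paste(.data$category, .data$type, sep = "_")) %>%
    select("metric", "value")
  scalars <- tibble(
    metric = c("total_reads", "mapped_reads", "n_passing", "frip", "tes",
               "coverage_fraction", "mean_depth", "periodicity_bp"),
    value = c(x$summary$total_reads, x$summary$mapped_reads,
              x$summary$n_passing, x$frip, x$tes, x$coverage$fraction,
              x$coverage$mean_depth, x$periodicity$period))
  dplyr::bind_rows(counts_long, scalars)
}

#' One-row summary of a QC report
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return One-row tibble with the headline metrics.
#' @export
glance.qc_report <- function(x, ...) {
  nuc <- x$counts[x$counts$category == "nuclear", ]
  tibble(
    sample = x$sample,
    total_reads = x$summary$total_reads,
    mapped_reads = x$summary$mapped_reads,
    nuclear_pct = nuc$pct_of_total,
    n_passing = x$summary$n_passing,
    frip = x$frip,
    tes = x$tes,
    coverage_fraction = x$coverage$fraction,
    mean_depth = x$coverage$mean_depth,
    periodicity_bp = x$periodicity$period
  )
}

#' Plot components of a QC report
#'
#' @param object A `qc_report`.
#' @param type Which panel: `"fragment"` (fragment-length histogram),
#'   `"depth"`, `"mapq"`, `"gc"`, `"tss"` (TSS pileup) or `"footprint"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_report <- function(object,
                               type = c("fragment", "depth", "mapq", "gc",
                                        "tss", "footprint"), ...) {
  type <- match.arg(type)
  if (type %in% c("tss", "footprint")) {
    p <- if (type == "tss") object$tss_pileup else object$footprint
    if (is.null(p)) abort(sprintf("report has no %s profile", type))
    df <- tidy(p)
    lab <- if (type == "tss") "mean read density" else "mean insertions per site"
    return(ggplot(df, aes(x = .data$position, y = .data$density)) +
             geom_line(color = "#2c7fb8") +
             labs(x = sprintf("position relative to %s (bp)", p$role),
                  y = lab, title = object$sample) +
             theme_minimal())
  }
  h <- switch(type, fragment = object$histograms$fragment_length,
              depth = object$histograms$depth,
              mapq = object$histograms$mapq,
              gc = object$histograms$gc_percent)
  xlab <- switch(type, fragment = "fragment length (bp)", depth = "depth",
                 mapq = "MAPQ", gc = "GC content (%)")
  ggplot(h, aes(x = .data$value, y = .data$count)) +
    geom_col(width = 1, fill = "#2c7fb8") +
    labs(x = xlab, y = "count", title = object$sample) +
    theme_minimal()
}

#' @rdname autoplot.qc_report
#' @param report A `qc_report`.
#' @export
plot_fragment_hist <- function(report) autoplot(report, "fragment")

#' @rdname autoplot.qc_report
#' @export
plot_tss_pileup <- function(report) autoplot(report, "tss")

#' @rdname autoplot.qc_report
#' @export
plot_depth_hist <- function(report) autoplot(report, "depth")
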
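#' Default organelle sequence names
#'
#' Reference-sequence names treated as mitochondrial or plastid when no
#' explicit name list is given. Assemblies vary ("chrM", "MT", "Pt", ...), so
#' both common UCSC/Ensembl names and plant conventions are included; matching
#' is case-insensitive and exact.
#'
#' @name organelle-defaults
#' @keywords internal
default_mito_names <- function() c("chrM", "MT", "ChrM", "mitochondria")

#' @rdname organelle-defaults
#' @keywords internal
default_plastid_names <- function() c("chrC", "Pt", "ChrC", "chloroplast")

#' Build the reference catalog from a BAM header
#'
#' Every reference sequence in the header is assigned to exactly one of three
#' categories: nuclear (the default), mitochondrial, or plastid. Categories may
#' hold any number of sequences (or none), which supports fragmented
#' assemblies with several organellar scaffolds.
#'
#' @param bam Path to a BAM file, or a named numeric vector of reference
#'   lengths (names = sequence names) as returned by
#'   `Rsamtools::scanBamHeader()[[1]]$targets`.
#' @param mito,plastid Character vectors of sequence names to classify as
#'   mitochondrial / plastid. Matching is exact after case-folding. Names
#'   absent from the header raise a warning, not an error.
#'
#' @return A tibble with columns `name`, `length`, `category`
#'   (factor: nuclear, mitochondrial, plastid), in header order.
#' @examples
#' fx <- generate_fixture(synthetic_spec(n_fragments = 50), tempfile("fx"))
#' reference_catalog(fx$bam)
#' @export
reference_catalog <- function(bam,
                              mito = default_mito_names(),
                              plastid = default_plastid_names()) {
  if (is.character(bam) && length(bam) == 1L) {
    targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  } else {
    targets <- bam
  }
  if (is.null(targets) || length(targets) == 0L) {
    abort("no reference sequences in BAM header")
  }
  if (any(targets <= 0)) abort("reference sequences must have positive length")
  nm <- names(targets)
  if (anyDuplicated(nm)) abort("duplicate reference sequence names in header")

  category <- rep("nuclear", length(nm))
  category[tolower(nm) %in% tolower(mito)] <- "mitochondrial"
  category[tolower(nm) %in% tolower(plastid)] <- "plastid"

  missing_mito <- setdiff(tolower(mito), tolower(nm))
  missing_plastid <- setdiff(tolower(plastid), tolower(nm))
  # warn only for user-supplied names: the built-in defaults are a convenience
  # superset and most assemblies contain at most one spelling of each
  if (!identical(sort(tolower(mito)), sort(tolower(default_mito_names()))) &&
      length(missing_mito)) {
    warn(sprintf("mitochondrial name(s) not in header: %s",
                 paste(missing_mito, collapse = ", ")))
  }
  if (!identical(sort(tolower(plastid)), sort(tolower(default_plastid_names()))) &&
      length(missing_plastid)) {
    warn(sprintf("plastid name(s) not in header: %s",
                 paste(missing_plastid, collapse = ", ")))
  }

  tibble(
    name = nm,
    length = as.integer(targets),
    category = factor(category, levels = c("nuclear", "mitochondrial", "plastid"))
  )
}

#' Summarise a reference catalog
#'
#' @param catalog A tibble from [reference_catalog()].
#' @return A tibble with one row per category: number of sequences and total
#'   length in bp (categories with zero sequences included).
#' @export
catalog_summary <- function(catalog) {
  catalog %>%
    group_by(category = .data$category, .drop = FALSE) %>%
    summarise(n_sequences = n(), total_length = sum(.data$length), .groups = "drop")
}
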
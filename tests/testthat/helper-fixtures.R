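# Shared fixtures, generated once per test run. All inputs are synthetic and
# written to the session temp directory.

fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, spec) {
  if (is.null(fixture_cache[[name]])) {
    fixture_cache[[name]] <- generate_fixture(
      spec, file.path(tempdir(), paste0("atacqc-", name)))
  }
  fixture_cache[[name]]
}

clean_fixture <- function() {
  cached_fixture("clean", preset_fixtures(n_fragments = 3000L)$clean)
}

grid_fixture <- function() {
  cached_fixture("grid", preset_fixtures(n_fragments = 8000L)$grid)
}

small_fixture <- function() {
  cached_fixture("small", synthetic_spec(n_fragments = 500L, seed = 7L))
}

# header-only coordinate-sorted BAM (zero alignments)
empty_bam <- function() {
  out <- file.path(tempdir(), "atacqc-empty")
  bam <- paste0(out, ".bam")
  if (!file.exists(bam)) {
    sam <- paste0(out, ".sam")
    writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                 "@SQ\tSN:Chr1\tLN:100000"), sam)
    Rsamtools::asBam(sam, out, overwrite = TRUE, indexDestination = TRUE)
  }
  bam
}

# a BAM whose header declares it unsorted
unsorted_bam <- function() {
  out <- file.path(tempdir(), "atacqc-unsorted.bam")
  if (!file.exists(out)) {
    sam <- file.path(tempdir(), "atacqc-unsorted.sam")
    writeLines(c(
      "@HD\tVN:1.6\tSO:unsorted",
      "@SQ\tSN:Chr1\tLN:100000",
      "r1\t0\tChr1\t100\t40\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII"), sam)
    Rsamtools::asBam(sam, sub("\\.bam$", "", out), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  out
}

# brute-force per-base depth histogram oracle (arrays, O(genome))
naive_depth_hist <- function(starts, ends, ref_length) {
  depth <- integer(ref_length)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) {
      idx <- (starts[i] + 1L):ends[i]  # 0-based [start, end) -> 1-based bases
      depth[idx] <- depth[idx] + 1L
    }
  }
  tab <- table(depth[depth > 0])
  list(hist = stats::setNames(as.numeric(tab), names(tab)),
       covered = sum(depth > 0), zero = sum(depth == 0))
}

write_test_bed <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}
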
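{
  "schema": "atacqc combined QC report",
  "accepted_versions": ["1.0"],
  "comment": "Structural contract for the combined JSON report. Nullable analytics (frip, tes, tss_pileup, footprint, periodicity.period, grid, n_written) are explicit nulls, never absent. An unlimited max_fragment is serialized as null.",
  "required_top_level": ["schema_version", "samples"],
  "required_sample_fields": [
    "tool", "version", "timestamp", "sample", "input", "parameters",
    "catalog", "counts", "fail_tally", "summary", "stats", "histograms",
    "coverage", "frip", "tes", "tss_pileup", "footprint", "periodicity",
    "grid"
  ],
  "required_histograms": [
    "fragment_length", "alignment_length", "mapq", "gc_percent", "depth"
  ],
  "field_types": {
    "parameters": "object (filter thresholds, mode, region restriction, Tn5/resize settings)",
    "catalog": "array of {name, length, category}",
    "counts": "object of per-category arrays: total, mapped, unmapped, duplicate, secondary, supplementary, qc_fail, proper_pair, passing, pct_of_total, pct_of_mapped",
    "histograms": "object of {value: [numbers], count: [numbers]}",
    "stats": "object of {n, mean, sd, median, min, max} per histogram",
    "coverage": "object {bases_covered, effective_genome, fraction, mean_depth}",
    "tss_pileup": "null or {role, radius, n_anchors, resize, tn5_shifted, position, density}",
    "periodicity": "object {period, power_ratio, mass}"
  }
}
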
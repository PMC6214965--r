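# Small builders used across the test files.

# A 17-vertebra spine with given coordinate profiles (mm).
make_spine <- function(patient_id = "p1", timepoint = "PO",
                       x = rep(0, 17), y = rep(0, 17),
                       z = seq(425, 0, length.out = 17)) {
  centroid_spine(patient_id, timepoint, cbind(x = x, y = y, z = z))
}

# Template with 17 equally spaced levels from 1 down to 0.
equal_template <- function() {
  build_control_template(list(scale_isotropic(make_spine(timepoint = "CONTROL"))))
}

# Expand the reference fusion-level frequency table into one row per
# patient, in group order.
reference_fusion_patients <- function() {
  lv <- reference_fusion_levels()
  idx <- rep(seq_len(nrow(lv)), lv$n)
  data.frame(patient_id = sprintf("P%03d", seq_along(idx)),
             uiv = lv$uiv[idx], liv = lv$liv[idx],
             stringsAsFactors = FALSE)
}
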
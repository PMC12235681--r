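# Random valid grading records for property-style tests. Gradable scans
# get arbitrary layer/brightness/special content; follow-up scans may
# carry any progression state, baseline scans only NOT_ASSESSED.
random_valid_record <- function(i = 1L) {
  followup <- runif(1) < 0.3
  grading_record(
    scan_id = sprintf("s%03d", i),
    lesion_id = sprintf("L%d", i),
    scan_gradable = TRUE,
    dry_late_amd = runif(1) < 0.05,
    wet_late_amd = runif(1) < 0.05,
    is_followup = followup,
    elm = sample(LAYER_STATES, 1),
    ez = sample(LAYER_STATES, 1),
    iz = sample(LAYER_STATES, 1),
    rpe = sample(LAYER_STATES, 1),
    bm = sample(LAYER_STATES, 1),
    iz_rpe_separable = sample(c(TRUE, FALSE, NA), 1),
    brightness = sample(BRIGHTNESS_LEVELS, 1),
    confluent = runif(1) < 0.2,
    drusen_ooze = runif(1) < 0.1,
    hyperreflective_only = runif(1) < 0.05,
    progression = if (followup) {
      sample(c(PROGRESSION_STATES, "NOT_ASSESSED"), 1)
    } else "NOT_ASSESSED"
  )
}

random_valid_cohort <- function(n, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), random_valid_record)
}

# The published worked example of a small drusen grading: GEN-01,
# LAY-01B, LAY-02C, LAY-03C, LAY-04C, LAY-05B, BRI-02.
small_drusen_record <- function() {
  grading_record(
    scan_id = "ex-drusen", lesion_id = "L1",
    elm = "UNCHANGED", ez = "BENT_UP", iz = "BENT_UP",
    rpe = "BENT_UP", bm = "UNCHANGED", brightness = "MODERATE"
  )
}

# SDD worked example: LAY-01C, LAY-02D, LAY-03B, LAY-04B, LAY-05B, BRI-02.
sdd_record <- function() {
  grading_record(
    scan_id = "ex-sdd", lesion_id = "L1",
    elm = "BENT_UP", ez = "DISRUPTED", iz = "UNCHANGED",
    rpe = "UNCHANGED", bm = "UNCHANGED", brightness = "MODERATE"
  )
}

# Hyper-reflective-only worked example: LAY-01C..04C, LAY-05B, BRI-03,
# SP-03.
hyperreflective_record <- function() {
  grading_record(
    scan_id = "ex-hrf", lesion_id = "L1",
    elm = "BENT_UP", ez = "BENT_UP", iz = "BENT_UP",
    rpe = "BENT_UP", bm = "UNCHANGED", brightness = "HIGH",
    hyperreflective_only = TRUE
  )
}
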
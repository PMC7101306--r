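# shared fixtures: deterministic hand-written records plus seeded random
# record generators used by the property-style tests

# a fixed, fully populated record with findings in a few joints
fixture_record <- function(id = "fix01", label = "RA") {
  patient_record(
    patient_id = id, label = label, gender = "female",
    body_temperature = 37.6, onset_days = 90, trunk_pain = FALSE,
    skin_abnormality = FALSE, patient_vas = 55, doctor_vas = 30,
    rf = 120, acpa = 88, esr = 42, crp = 1.8, ana = 80, mmp3 = 150,
    wbc = 9100,
    joints = list(
      right_wrist = joint_finding(TRUE, TRUE, TRUE, 2, 1),
      left_wrist = joint_finding(TRUE, TRUE, FALSE, 2, 2),
      right_MCP2 = joint_finding(TRUE, TRUE, FALSE, 1, 0),
      left_MCP3 = joint_finding(TRUE, FALSE, FALSE, 3, 3),
      right_DIP2 = joint_finding(FALSE, FALSE, FALSE, 1, 0)))
}

# an all-negative record: every flag FALSE, every score 0, labs benign
fixture_negative_record <- function(id = "neg01") {
  patient_record(patient_id = id, label = "nonRA", gender = "male",
                 body_temperature = 36.2, onset_days = 10,
                 patient_vas = 0, doctor_vas = 0, rf = 2, acpa = 0,
                 esr = 4, crp = 0.02, ana = 0, mmp3 = 20, wbc = 5000)
}

# n random valid records drawn uniformly over the field domains (wider
# than the cohort profiles: exercises every rule band)
random_records <- function(n, seed) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    joints <- lapply(tda_joint_keys(), function(k) {
      joint_finding(runif(1) < 0.3, runif(1) < 0.3, runif(1) < 0.2,
                    sample(0:3, 1), sample(0:3, 1))
    })
    names(joints) <- tda_joint_keys()
    patient_record(
      patient_id = sprintf("rnd%04d", i),
      label = sample(c("RA", "nonRA"), 1),
      gender = sample(c("male", "female"), 1),
      body_temperature = round(runif(1, 35, 40), 1),
      onset_days = sample(0:500, 1),
      trunk_pain = runif(1) < 0.3, skin_abnormality = runif(1) < 0.3,
      patient_vas = sample(0:100, 1), doctor_vas = sample(0:100, 1),
      rf = round(runif(1, 0, 400), 1), acpa = round(runif(1, 0, 800), 1),
      esr = sample(0:120, 1), crp = round(runif(1, 0, 15), 2),
      ana = sample(c(0, 40, 80, 160, 320, 640), 1),
      mmp3 = round(runif(1, 0, 700), 1), wbc = sample(2000:14000, 1),
      joints = joints)
  }))
}

# two tiny cohorts that differ ONLY in the ACPA square: used for the
# single-informative-block separability and counterfactual experiments
acpa_only_cohort <- function(n_per_class, seed, id_prefix = "ac") {
  withr::with_seed(seed, {
    recs <- list()
    for (i in seq_len(2 * n_per_class)) {
      lab <- if (i <= n_per_class) "RA" else "nonRA"
      recs[[i]] <- patient_record(
        patient_id = sprintf("%s%04d", id_prefix, i), label = lab,
        acpa = if (lab == "RA") runif(1, 20, 300) else runif(1, 0, 4),
        rf = 5, esr = 8, crp = 0.1, ana = 0, mmp3 = 30,
        wbc = 6000, patient_vas = 20, doctor_vas = 10,
        onset_days = 60, gender = "female")
    }
    recs
  })
}
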
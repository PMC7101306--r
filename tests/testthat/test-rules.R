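# The discretization rules: every printed cutoff, boundary semantics
# (value at a cutoff takes the severer colour), totality and monotonicity.

test_that("every published cutoff row is reproduced", {
  cases <- list(
    # field, value, expected
    list("rf", 0, "green"), list("rf", 14.9, "green"),
    list("rf", 15, "yellow"), list("rf", 29.9, "yellow"),
    list("rf", 30, "red"), list("rf", 2265, "red"),
    list("acpa", 0, "green"), list("acpa", 4.4, "green"),
    list("acpa", 4.5, "red"), list("acpa", 3519, "red"),
    list("esr", 9, "green"), list("esr", 10, "yellow"),
    list("esr", 15, "yellow"), list("esr", 20, "red"),
    list("onset_days", 0, "yellow"), list("onset_days", 41, "yellow"),
    list("onset_days", 42, "red"),
    list("crp", 0.29, "yellow"), list("crp", 0.3, "red"),
    list("ana", 0, "green"), list("ana", 40, "yellow"),
    list("ana", 80, "yellow"), list("ana", 160, "red"),
    list("ana", 1280, "red"),
    list("mmp3", 119, "yellow"), list("mmp3", 120, "yellow"),
    list("mmp3", 121, "red"),
    list("wbc", 3999, "green"), list("wbc", 4000, "yellow"),
    list("wbc", 7999, "yellow"), list("wbc", 8000, "red"),
    list("gender", "male", "yellow"), list("gender", "female", "red"),
    list("skin_abnormality", FALSE, "green"),
    list("skin_abnormality", TRUE, "yellow"),
    list("body_temperature", 37.4, "green"),
    list("body_temperature", 37.5, "yellow"),
    list("body_temperature", 38, "red"),
    list("trunk_pain", FALSE, "green"), list("trunk_pain", TRUE, "yellow"),
    list("patient_vas", 9, "green"), list("patient_vas", 10, "yellow"),
    list("patient_vas", 50, "red"),
    list("doctor_vas", 0, "green"), list("doctor_vas", 49, "yellow"),
    list("doctor_vas", 100, "red"),
    list("symptom", FALSE, "green"), list("symptom", TRUE, "red"),
    list("tenderness", TRUE, "red"), list("swelling", TRUE, "red"),
    list("gs_score", 0, "green"), list("gs_score", 1, "yellow"),
    list("gs_score", 2, "orange"), list("gs_score", 3, "red"),
    list("pd_score", 1, "yellow"), list("pd_score", 2, "orange"),
    list("pd_score", 3, "red"))
  for (cs in cases) {
    expect_identical(discretize_field(cs[[1]], cs[[2]]), cs[[3]],
                     label = sprintf("%s(%s)", cs[[1]], format(cs[[2]])))
  }
})

test_that("rules are total and monotone over each numeric field's domain", {
  grids <- list(
    rf = seq(0, 2300, by = 0.5), acpa = seq(0, 3600, by = 1),
    esr = 0:150, onset_days = 0:600, crp = seq(0, 15, by = 0.01),
    ana = c(0, 40, 80, 160, 320, 640, 1280, 2560, seq(0, 2600, by = 7)),
    mmp3 = seq(0, 720, by = 0.25), wbc = seq(0, 15000, by = 10),
    body_temperature = seq(34, 42, by = 0.1),
    patient_vas = 0:100, doctor_vas = 0:100)
  sev <- function(cat) match(cat, tda_categories())
  for (f in names(grids)) {
    cats <- vapply(grids[[f]], function(v) discretize_field(f, v),
                   character(1))
    expect_true(all(cats %in% tda_categories()), label = f)
    ord <- order(grids[[f]])
    expect_true(all(diff(sev(cats[ord])) >= 0),
                label = paste(f, "monotone"))
  }
  for (v in 0:3) {
    expect_lte(sev(discretize_field("pd_score", v)),
               sev(discretize_field("pd_score", min(v + 1, 3))))
  }
})

test_that("orange is reachable only from the ultrasound scores", {
  rules <- default_rules()
  for (f in names(rules)) {
    r <- rules[[f]]
    cats <- if (r$type == "interval") r$categories else unname(r$map)
    if (f %in% c("gs_score", "pd_score")) {
      expect_true("orange" %in% cats, label = f)
    } else {
      expect_false("orange" %in% cats, label = f)
    }
  }
})

test_that("unknown fields and out-of-domain values are errors", {
  expect_error(discretize_field("haemoglobin", 12), "unknown field")
  expect_error(discretize_field("gs_score", 7), "outside rule domain")
  expect_error(discretize_field("gender", "other"), "outside rule domain")
})

test_that("missing values discretize to the missing category", {
  expect_identical(discretize_field("rf", NA_real_), "missing")
})

test_that("rule sets round trip through the yaml config format", {
  rules <- default_rules()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_rules(rules, f)
  back <- read_rules(f)
  expect_identical(attr(back, "version"), attr(rules, "version"))
  for (nm in names(rules)) {
    expect_equal(back[[nm]], rules[[nm]], label = nm)
  }
})

test_that("discretize_record covers all 164 block fields", {
  cats <- discretize_record(fixture_record())
  expect_length(cats, 14 + 30 * 5)
  expect_identical(unname(cats["rf"]), "red")
  expect_identical(unname(cats["J_right_wrist_d"]), "orange")
  expect_identical(unname(cats["J_left_MCP3_e"]), "red")
})
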
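# Metrics: confusion matrix, precision/recall/accuracy with half-up
# rounding, Cohen's kappa (with an independent library cross-check), and
# the counterfactual probe.

test_that("the confusion matrix counts as published", {
  truth <- c(rep("RA", 10), rep("nonRA", 40))
  pred <- c(rep("RA", 10), "RA", rep("nonRA", 39))
  cm <- confusion(truth, pred)
  expect_identical(as.integer(cm), c(10L, 1L, 0L, 39L))
  expect_identical(cm, confusion_counts(10, 0, 1, 39))
})

test_that("identical lists give a diagonal matrix; empty lists all zeros", {
  labs <- c("RA", "nonRA", "RA")
  cm <- confusion(labs, labs)
  expect_identical(cm["RA", "nonRA"] + cm["nonRA", "RA"], 0L)
  cm0 <- confusion(character(0), character(0))
  expect_identical(sum(cm0), 0L)
})

test_that("confusion validates its inputs", {
  expect_error(confusion(c("RA"), c("RA", "nonRA")), "equal length")
  expect_error(confusion("RA", "maybe"), "labels")
})

test_that("precision/recall/accuracy match the published worked example", {
  m <- prf_accuracy(confusion_counts(10, 0, 1, 39))
  expect_identical(m$precision_pct, 91)   # 10/11 rounds half-up to 91
  expect_identical(m$recall_pct, 100)
  expect_identical(m$accuracy_pct, 98)
  expect_equal(m$precision, 10 / 11)
  expect_equal(m$recall, 1)
  expect_equal(m$accuracy, 49 / 50)
})

test_that("a perfect matrix scores 100/100/100", {
  m <- prf_accuracy(confusion_counts(10, 0, 0, 40))
  expect_identical(c(m$precision_pct, m$recall_pct, m$accuracy_pct),
                   c(100, 100, 100))
})

test_that("zero denominators are undefined, not zero", {
  m <- prf_accuracy(confusion_counts(0, 0, 0, 40))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$recall))
  expect_identical(sort(m$undefined), c("precision", "recall"))
  expect_identical(m$accuracy_pct, 100)
})

test_that("metrics from a confusion matrix equal direct recomputation", {
  withr::with_seed(107, {
    for (i in 1:10) {
      truth <- sample(c("RA", "nonRA"), 40, replace = TRUE)
      pred <- sample(c("RA", "nonRA"), 40, replace = TRUE)
      m <- prf_accuracy(confusion(truth, pred))
      expect_equal(m$accuracy, mean(truth == pred))
      if (sum(pred == "RA") > 0) {
        expect_equal(m$precision,
                     sum(truth == "RA" & pred == "RA") / sum(pred == "RA"))
      }
      if (sum(truth == "RA") > 0) {
        expect_equal(m$recall,
                     sum(truth == "RA" & pred == "RA") / sum(truth == "RA"))
      }
    }
  })
})

test_that("kappa matches the hand formula and known anchors", {
  # perfect agreement with both classes present
  expect_identical(cohens_kappa(c("RA", "nonRA"), c("RA", "nonRA")), 1)
  # constructed chance case: p_o = p_e = 0.5
  expect_equal(cohens_kappa(c("RA", "nonRA"), c("RA", "RA")), 0)
  # the published confusion pattern: p_o = .98, p_e = .668
  a <- c(rep("RA", 10), rep("nonRA", 40))
  b <- c(rep("RA", 10), "RA", rep("nonRA", 39))
  expect_equal(cohens_kappa(a, b), (0.98 - 0.668) / (1 - 0.668),
               tolerance = 1e-9)
  # constant identical raters: p_e = 1 edge case
  expect_identical(cohens_kappa(c("RA", "RA"), c("RA", "RA")), 1)
  expect_error(cohens_kappa("RA", c("RA", "RA")), "equal length")
})

test_that("kappa is symmetric in the raters", {
  withr::with_seed(101, {
    for (i in 1:20) {
      a <- sample(c("RA", "nonRA"), 30, replace = TRUE)
      b <- sample(c("RA", "nonRA"), 30, replace = TRUE)
      expect_equal(cohens_kappa(a, b), cohens_kappa(b, a))
    }
  })
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(102, {
    for (i in 1:20) {
      a <- sample(c("RA", "nonRA"), 50, replace = TRUE)
      b <- ifelse(runif(50) < 0.3, sample(c("RA", "nonRA"), 50,
                                          replace = TRUE), a)
      tab <- table(factor(a, c("RA", "nonRA")), factor(b, c("RA", "nonRA")))
      expect_equal(cohens_kappa(a, b),
                   e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
    }
  })
})

test_that("kappa of a permuted rater concentrates near zero", {
  withr::with_seed(103, {
    a <- sample(c("RA", "nonRA"), 200, replace = TRUE, prob = c(0.3, 0.7))
    ks <- vapply(1:1000, function(i) cohens_kappa(a, sample(a)), numeric(1))
    expect_lt(abs(mean(ks)), 0.02)
    expect_lt(stats::quantile(abs(ks), 0.95), 0.2)
  })
})

test_that("the counterfactual probe flips ACPA-driven predictions", {
  learn <- acpa_only_cohort(60, seed = 104, id_prefix = "L")
  ds <- encode_cohort(learn, resolution = 24)
  cfg <- training_config(epochs = 8, resolution = 24, batch_size = 16)
  model <- train_once(ds, ratda:::subset_dataset(ds, integer(0)), cfg,
                      seed = 105)
  probes <- acpa_only_cohort(10, seed = 106, id_prefix = "P")
  nonra_probes <- probes[11:20]   # ACPA-negative by construction
  flipped <- vapply(nonra_probes, function(r) {
    out <- counterfactual_probe(model, r, "acpa", 200)
    isTRUE(out$changed)
  }, logical(1))
  expect_gt(mean(flipped), 0.5)
  # identity probe never flips and never mutates the record
  r <- nonra_probes[[1]]
  before <- unclass(r)
  out <- counterfactual_probe(model, r, "acpa", r$acpa)
  expect_false(out$changed)
  expect_identical(unclass(r), before)
  # invalid values are rejected
  expect_error(counterfactual_probe(model, r, "acpa", -5), "domain")
  expect_error(counterfactual_probe(model, r, "nonsense", 1),
               "unknown clinical field")
})
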
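test_that("standardisation yields exact two-point z-scores", {
  z <- standardize_cohort(data.frame(TP63 = c(1, 3)), "TP63")
  expect_equal(unname(z[, "TP63"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("standardisation errors name the offending feature or record", {
  d <- data.frame(id = c("a", "b", "c"), TP63 = c(1, 2, 3), p16 = c(1, 1, 1))
  expect_error(standardize_cohort(d, c("TP63", "p16")), "p16")
  d$TP63[2] <- NA
  expect_error(standardize_cohort(d, "TP63"), "b")
  expect_error(standardize_cohort(d[1, ], "TP63"), "at least 2")
  expect_error(standardize_cohort(d, "EGFR"), "EGFR")
})

test_that("z-scores have cohort mean 0 and sd 1 to 1e-9", {
  sim <- gen_cohort(sim_config(seed = 2, n_patients = 200))
  feats <- c(MARKER_GENES, "smoking", "p16")
  z <- standardize_cohort(sim$cohort, feats)
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
})

test_that("subtype scores match the hand-computed prototype example", {
  z <- c(TP63 = 2, EGFR = 2, SOX2 = -2, VIM = 0, DES = 0, NFE2L2 = 0,
         smoking = 0, p16 = 0)
  s <- score_subtypes(z)
  expect_equal(unname(s[1, "BA"]), 2)
  expect_equal(unname(s[1, "ME"]), -2 / 3, tolerance = 1e-12)
  expect_equal(unname(s[1, "CL"]), -2 / 3, tolerance = 1e-12)
  expect_equal(unname(s[1, "AT"]), -1)
  a <- assign_subtype(s[1, ])
  expect_equal(a$label, "BA")
  expect_false(a$tied)
})

test_that("scores agree with an independent cell-by-cell recomputation", {
  set.seed(42)
  spec <- marker_spec()
  for (rep in 1:20) {
    z <- rnorm(8)
    names(z) <- c(MARKER_GENES, "smoking", "p16")
    s <- score_subtypes(z, spec)
    for (cat in names(spec)) {
      # oracle: explicit sum of signed terms divided by the feature count
      sig <- spec[[cat]]
      acc <- 0
      for (f in names(sig)) acc <- acc + sig[[f]] * z[[f]]
      expect_equal(unname(s[1, cat]), acc / length(sig), tolerance = 1e-12)
    }
  }
})

test_that("all-zero scores fall back to the AT-first priority with a tie flag", {
  z <- setNames(rep(0, 8), c(MARKER_GENES, "smoking", "p16"))
  s <- score_subtypes(z)
  expect_true(all(s == 0))
  a <- assign_subtype(s[1, ])
  expect_equal(a$label, "AT")
  expect_true(a$tied)
  expect_error(assign_subtype(c(AT = NaN, BA = 0, CL = 0, ME = 0)),
               "non-finite")
})

test_that("classification recovers planted subtypes at strong marker effect", {
  sim <- gen_cohort(sim_config(seed = 1, n_patients = 200,
                               marker_effect = 3, noise_sd = 0.5))
  cls <- classify_subtypes(sim$cohort)
  expect_gte(mean(cls$label == sim$truth$subtype), 0.95)
})

test_that("assignments are invariant to patient order and marker shifts", {
  sim <- gen_cohort(sim_config(seed = 4, n_patients = 60))
  cls <- classify_subtypes(sim$cohort)

  perm <- sample(nrow(sim$cohort))
  cls_perm <- classify_subtypes(sim$cohort[perm, ])
  expect_equal(cls_perm$label, cls$label[perm])

  shifted <- sim$cohort
  shifted$SOX2 <- shifted$SOX2 + 7.3
  expect_equal(classify_subtypes(shifted)$label, cls$label)
})

test_that("negating a patient's z-vector negates all four scores", {
  set.seed(7)
  z <- rnorm(8)
  names(z) <- c(MARKER_GENES, "smoking", "p16")
  expect_equal(score_subtypes(-z), -score_subtypes(z), tolerance = 1e-12)
})

test_that("recovery accuracy is monotone in the marker effect", {
  acc_at <- function(delta) {
    mean(vapply(1:20, function(s) {
      sim <- gen_cohort(sim_config(seed = 1000 + s, n_patients = 100,
                                   marker_effect = delta, noise_sd = 1))
      mean(classify_subtypes(sim$cohort)$label == sim$truth$subtype)
    }, numeric(1)))
  }
  accs <- vapply(c(0, 1, 2, 3), acc_at, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("binary covariates can enter unstandardised via the config switch", {
  sim <- gen_cohort(sim_config(seed = 6, n_patients = 80))
  raw <- classify_subtypes(sim$cohort, standardize_binary = FALSE)
  expect_s3_class(raw, "subtype_classification")
  # still recovers most labels under the default strong effect
  expect_gte(mean(raw$label == sim$truth$subtype), 0.8)
})

test_that("crosstab reproduces counts, percentages and conservation", {
  ct1 <- crosstab("AT", by = "p16 pos.")
  expect_equal(unname(ct1$row_pct[1, 1]), 100.0)

  sim <- gen_cohort(sim_config(seed = 8))
  cls <- classify_subtypes(sim$cohort)
  ct <- crosstab(cls$label, by = sim$cohort$p16)
  expect_equal(sum(ct$counts), nrow(sim$cohort))
  expect_equal(unname(rowSums(ct$row_pct)), rep(100, nrow(ct$row_pct)),
               tolerance = 0.3)  # rounding to 1 decimal
  expect_error(crosstab(character(0), character(0)), "empty")
})
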
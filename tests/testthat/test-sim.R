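test_that("generators are byte-identical under a fixed seed", {
  cfg <- quick_config(seed = 11)
  expect_identical(gen_cohort(cfg), gen_cohort(cfg))
  expect_identical(gen_colony_images(cfg), gen_colony_images(cfg))
  expect_identical(gen_rtdc_events(cfg), gen_rtdc_events(cfg))
  expect_identical(gen_qpcr(cfg), gen_qpcr(cfg))
  a <- gen_force_curves(cfg); b <- gen_force_curves(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$curves[[5]], b$curves[[5]])
  # different seeds differ
  expect_false(identical(gen_cohort(cfg)$cohort,
                         gen_cohort(quick_config(seed = 12))$cohort))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_cohort(quick_config(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("every generated object carries exactly one truth record", {
  cfg <- quick_config(seed = 3)
  co <- gen_cohort(cfg)
  expect_equal(nrow(co$truth), nrow(co$cohort))
  expect_identical(co$truth$id, co$cohort$id)
  ci <- gen_colony_images(cfg)
  expect_equal(nrow(ci$truth), length(ci$images))
  fc <- gen_force_curves(cfg)
  expect_equal(nrow(fc$truth), length(fc$curves))
  ev <- gen_rtdc_events(cfg)
  expect_equal(nrow(ev$truth), nrow(ev$events))
  qp <- gen_qpcr(cfg)
  expect_setequal(unique(qp$records$gene), unique(qp$truth$gene))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(subtype_proportions = c(0.5, 0.5, 0.1, 0.1)),
               "sum to 1")
  expect_error(sim_config(n_patients = 4), ">= 8")
  expect_error(sim_config(noise_sd = -1), ">= 0")
  expect_error(colony_spec(width = 64), "128x128")
  expect_error(colony_spec(radius_range = c(100, 200)), "radius larger")
  expect_error(afm_spec(E_true = -5), "positive")
  expect_error(rtdc_spec(n_events = 0), ">= 1")
  expect_error(qpcr_spec(conditions = "none"), "control")
})

test_that("cohort markers carry no recoverable signal when the effect is zero", {
  accs <- vapply(1:10, function(s) {
    sim <- gen_cohort(sim_config(seed = s, n_patients = 100,
                                 marker_effect = 0, noise_sd = 1,
                                 flip_prob = 0.5))
    cls <- classify_subtypes(sim$cohort)
    mean(cls$label == sim$truth$subtype)
  }, numeric(1))
  # chance level is 1/4 under the uneven prior; allow sampling spread
  expect_gt(mean(accs), 0.10)
  expect_lt(mean(accs), 0.45)
})

test_that("qPCR generator plants exact fold changes at zero noise", {
  cfg0 <- sim_config(qpcr = qpcr_spec(true_log2fc = 0, ct_noise_sd = 0))
  dd0 <- ddct(gen_qpcr(cfg0)$records, control = "none")
  expect_equal(dd0$fold_change, rep(1, nrow(dd0)), tolerance = 1e-9)

  cfg2 <- sim_config(qpcr = qpcr_spec(true_log2fc = 2, ct_noise_sd = 0))
  dd2 <- ddct(gen_qpcr(cfg2)$records, control = "none")
  cc <- dd2[dd2$condition != "none", ]
  expect_equal(cc$fold_change, rep(4, nrow(cc)), tolerance = 1e-9)
})

test_that("one-sample test on planted qPCR fold changes has power", {
  # planted log2FC = 1, noise 0.2 cycles, 6 replicates: significant vs 0
  # in at least 90% of seeds
  hits <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s,
                      qpcr = qpcr_spec(genes = "MCT4", true_log2fc = 1,
                                       ct_noise_sd = 0.2, n_replicates = 6))
    dd <- ddct(gen_qpcr(cfg)$records, control = "none")
    x <- dd$log2fc[dd$condition != "none"]
    one_sample_test(x)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("simulated study files round-trip through the readers", {
  td <- withr::local_tempdir()
  cfg <- sim_config(seed = 7, n_patients = 12,
                    colony = colony_spec(n_images = 2),
                    afm = afm_spec(n_curves = 2, curve_length = 60),
                    rtdc = rtdc_spec(n_events = 50))
  objs <- expect_no_warning(simulate_study(cfg, td))

  cohort <- expect_no_warning(read.csv(file.path(td, "cohort.csv"),
                                       check.names = FALSE))
  expect_equal(nrow(cohort), 12)
  expect_true(all(c(MARKER_GENES, "smoking", "p16", LACTATE_PANEL) %in%
                    names(cohort)))

  ev <- expect_no_warning(read.csv(file.path(td, "rtdc_events.csv")))
  expect_equal(nrow(ev), 50)

  curve <- expect_no_warning(read_force_curve(file.path(td, "curves",
                                                        "c0001.txt")))
  expect_s3_class(curve, "force_curve")
  expect_equal(curve$height, objs$afm$curves[[1]]$height, tolerance = 1e-12)
  expect_equal(curve$force, objs$afm$curves[[1]]$force, tolerance = 1e-12)

  img <- expect_no_warning(read_image_png(file.path(td, "img01.png")))
  expect_equal(dim(img), dim(objs$colony$images[[1]]))
  expect_equal(img, objs$colony$images[[1]], ignore_attr = TRUE)

  roi <- expect_no_warning(read_image_png(file.path(td, "roi.png")))
  expect_equal(roi == 255, objs$colony$roi, ignore_attr = TRUE)

  truth <- expect_no_warning(jsonlite::read_json(file.path(td, "truth.json"),
                                                 simplifyVector = TRUE))
  expect_equal(truth$cohort$subtype, objs$cohort$truth$subtype)
})
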
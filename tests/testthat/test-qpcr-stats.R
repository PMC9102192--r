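test_that("comparative Ct recovers hand-computed fold changes", {
  rec <- data.frame(sample = c("c1", "c2", "s1"),
                    condition = c("none", "none", "co"),
                    gene = "MCT4",
                    ct_target = c(25, 25, 23),
                    ct_ref = c(20, 20, 20))
  out <- ddct(rec, control = "none")
  expect_equal(out$fold_change[out$sample == "s1"], 4)   # ddCt = -2
  expect_equal(out$fold_change[out$sample == "c1"], 1)   # at control mean
  expect_equal(out$log2fc[out$sample == "s1"], 2)

  rec2 <- rbind(rec, data.frame(sample = "s2", condition = "co",
                                gene = "CAV1", ct_target = 24, ct_ref = 20))
  expect_error(ddct(rec2, control = "none"), "CAV1")
})

test_that("planted qPCR fold changes are recovered in expectation", {
  means <- vapply(1:30, function(s) {
    cfg <- sim_config(seed = s,
                      qpcr = qpcr_spec(genes = "MCT1", true_log2fc = 1.5,
                                       ct_noise_sd = 0.2, n_replicates = 3))
    dd <- ddct(gen_qpcr(cfg)$records, control = "none")
    mean(dd$log2fc[dd$condition != "none"])
  }, numeric(1))
  # per-seed sampling sd of the mean log2FC at 3+3 replicates, noise 0.2
  sd_mean <- 0.2 * sqrt(1 / 3 + 1 / 3)
  expect_lt(abs(mean(means) - 1.5), 3 * sd_mean / sqrt(30))
})

test_that("one-sample t-test matches the hand formula and edge cases", {
  sym <- one_sample_test(c(-1, 1))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)

  x <- c(1.0, 1.1, 0.9)
  res <- one_sample_test(x)
  t_hand <- mean(x) / (sd(x) / sqrt(3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_lt(res$p, 0.01)

  expect_error(one_sample_test(c(2, 2, 2)), "zero variance")
  expect_error(one_sample_test(1), "at least 2")
})

test_that("paired t-test handles identical and constant-shift pairs", {
  expect_equal(paired_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # constant within-pair difference, zero noise: certainty in the limit
  expect_equal(paired_test(c(1, 2, 3), c(2, 3, 4))$p, 0)
  expect_error(paired_test(1:3, 1:4), "paired")
  # grows in significance with n at fixed effect and noise
  set.seed(5)
  noise <- rnorm(50, sd = 0.1)
  small <- paired_test(1:10, 1:10 + 0.5 + noise[1:10])$p
  large <- paired_test(1:50, 1:50 + 0.5 + noise)$p
  expect_lt(large, small)
})

test_that("t-tests hold their nominal type-I error under the null", {
  set.seed(202)
  reps <- 1000
  hits_one <- hits_pair <- logical(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(10)
    hits_one[i] <- one_sample_test(x)$p < 0.05
    b <- rnorm(8); a <- b + rnorm(8)
    hits_pair[i] <- paired_test(b, a)$p < 0.05
  }
  expect_lt(abs(mean(hits_one) - 0.05), 0.02)
  expect_lt(abs(mean(hits_pair) - 0.05), 0.02)
})

test_that("correlation matrix is symmetric, masked and flag-safe", {
  set.seed(303)
  d <- data.frame(a = rnorm(100))
  d$b <- 0.8 * d$a + sqrt(1 - 0.64) * rnorm(100)
  d$c <- rnorm(100)
  d$const <- 5
  cm <- correlation_matrix(d)
  expect_equal(cm$r["a", "a"], 1)
  expect_equal(cm$r, t(cm$r))
  expect_lt(abs(cm$r["a", "b"] - 0.8), 0.1)
  expect_true(cm$significant["a", "b"])
  expect_true(is.na(cm$r["a", "const"]))
  expect_match(cm$flags, "const")

  # independent columns rarely show |r| > 0.3 at n = 50
  set.seed(404)
  null_r <- vapply(1:100, function(i) {
    dd <- data.frame(x = rnorm(50), y = rnorm(50))
    correlation_matrix(dd)$r["x", "y"]
  }, numeric(1))
  expect_gte(mean(abs(null_r) < 0.3), 0.95)
})

test_that("two-cluster panel clustering recovers planted structure", {
  # two samples: one per cluster
  two <- matrix(rnorm(10), 2, dimnames = list(c("s1", "s2"), LACTATE_PANEL))
  expect_setequal(cluster_two(two), 1:2)

  # well-separated blobs (4 sd): perfect recovery and deterministic labels
  sim <- gen_cohort(sim_config(seed = 51, n_patients = 80))
  cl <- cluster_two(sim$cohort[LACTATE_PANEL])
  expect_equal(unname(cl), sim$truth$cluster)
  # cluster 1 is the low-expression cluster
  expect_lt(mean(as.matrix(sim$cohort[LACTATE_PANEL])[cl == 1, ]),
            mean(as.matrix(sim$cohort[LACTATE_PANEL])[cl == 2, ]))

  # duplicated samples co-cluster
  dup <- rbind(sim$cohort[LACTATE_PANEL], sim$cohort[LACTATE_PANEL])
  cl_dup <- cluster_two(dup)
  expect_equal(unname(cl_dup[1:80]), unname(cl_dup[81:160]))

  expect_error(cluster_two(sim$cohort[c("MCT1", "MCT4")]), "panel gene")
  expect_error(cluster_two(sim$cohort[1, LACTATE_PANEL, drop = FALSE]),
               "2 samples")
})

test_that("clustering is invariant to sample order and per-gene rescaling", {
  sim <- gen_cohort(sim_config(seed = 52, n_patients = 60))
  x <- as.matrix(sim$cohort[LACTATE_PANEL])
  rownames(x) <- sim$cohort$id
  cl <- cluster_two(x)
  perm <- sample(nrow(x))
  expect_equal(cluster_two(x[perm, ])[rownames(x)], cl)
  # positive affine rescaling per gene is absorbed by internal z-scoring
  y <- sweep(sweep(x, 2, c(2, 0.5, 3, 1, 10), `*`), 2, c(1, -4, 0, 7, 2), `+`)
  expect_equal(cluster_two(y), cl)
})
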
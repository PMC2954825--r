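test_that("noiseless standards recover the exact curve; degenerate designs fail", {
  q <- gen_qpcr_fixture(true_ratio = 0.5, ct_sd = 0, seed = 1)
  curve <- fit_standard_curve(q[q$role == "standard", ])
  expect_equal(curve$slope, 1, tolerance = 1e-9)
  expect_equal(curve$intercept, 0, tolerance = 1e-9)
  expect_equal(curve$r2, 1, tolerance = 1e-9)
  two_point <- q[q$role == "standard" & q$fraction %in% c(0.1, 0.9), ]
  expect_error(fit_standard_curve(two_point), "3 distinct")
})

test_that("the curve slope is recovered within 5% under realistic Ct noise", {
  slopes <- vapply(1:100, function(s) {
    q <- gen_qpcr_fixture(true_ratio = 1, ct_sd = 0.1, seed = s)
    fit_standard_curve(q[q$role == "standard", ])$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1), 0.05)
  expect_true(mean(abs(slopes - 1) < 0.05) > 0.9)
})

test_that("allelic ratios map delta-Ct through the curve with SEM", {
  curve <- structure(list(slope = 1, intercept = 0, r2 = 1), class = "ase_curve")
  sam <- data.frame(ct_a = c(24, 24, 24), ct_b = c(24, 24, 24))
  r <- allelic_ratio(sam, curve)
  expect_equal(r$ratio, 1.0)
  expect_equal(r$n_replicates, 3L)
  # missing replicate: computed on the rest, flagged
  sam$ct_b[2] <- NA
  r2 <- allelic_ratio(sam, curve)
  expect_true(r2$incomplete)
  expect_equal(r2$n_replicates, 2L)
  # a true B:A of 0.3 is recovered across seeds
  est <- vapply(1:50, function(s) {
    q <- gen_qpcr_fixture(true_ratio = 0.3, ct_sd = 0.1, seed = s)
    cv <- fit_standard_curve(q[q$role == "standard", ])
    allelic_ratio(q[q$sample == "unknown_1", ], cv)$ratio
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.3) / 0.3, 0.1)
})

test_that("NMD contrast flags decay that inhibition rescues", {
  q_un <- gen_qpcr_fixture(true_ratio = 0.3, ct_sd = 0.05, seed = 11)
  q_bl <- gen_qpcr_fixture(true_ratio = 1.0, ct_sd = 0.05, seed = 12)
  cv <- fit_standard_curve(q_un[q_un$role == "standard", ])
  un <- allelic_ratio(q_un[q_un$sample == "unknown_1", ], cv)
  bl <- allelic_ratio(q_bl[q_bl$sample == "unknown_1", ], cv)
  expect_equal(nmd_effect(un, bl)$call, "NMD-consistent")
  expect_equal(nmd_effect(bl, bl)$call, "no NMD signal")
  expect_error(nmd_effect(un, NULL), "both treatment arms")
})

test_that("IQR fences remove gross outliers and keep ties", {
  v <- c(1, 2, 3, 4, 100)
  keep <- iqr_filter(v)
  expect_equal(which(!keep), 5L)
  expect_true(all(iqr_filter(rep(3, 6))))
  # idempotent on the retained values
  keep2 <- iqr_filter(v[keep])
  expect_true(all(keep2))
  # small groups pass through with a flag
  k3 <- iqr_filter(c(1, 2, 100), groups = rep("g", 3))
  expect_true(all(k3))
  expect_equal(attr(k3, "small_groups"), "g")
  # sanity bound on the default MFI generator: the filter trims, it does
  # not gut — at most 25% of the dataset, and never more than 2 of the 6
  # samples of any experiment x genotype cell
  for (s in 1:10) {
    mf <- gen_mfi_fixture(outlier_rate = 0.05, seed = s)
    grp <- interaction(mf$experiment, mf$genotype)
    keep <- iqr_filter(mf$hla_mfi / mf$cd19_mfi, grp)
    expect_lte(mean(!keep), 0.25)
    expect_true(all(tapply(!keep, grp, sum) <= 2))
  }
})

test_that("the two-factor ANOVA matches a hand-computed table", {
  # balanced 2x2 design, 3 per cell; cell means 11, 9, 14, 12.
  # SS_experiment = 27, SS_genotype = 12, SSE = 8 on 9 df:
  # F_experiment = 27 / (8/9) = 30.375; F_genotype = 12 / (8/9) = 13.5.
  rec <- data.frame(
    sample = sprintf("s%02d", 1:12),
    genotype = rep(rep(c("AA", "BB"), each = 3), 2),
    experiment = rep(1:2, each = 6),
    hla_mfi = c(10, 11, 12, 8, 9, 10, 13, 14, 15, 11, 12, 13),
    cd19_mfi = 1)
  inf <- mfi_inference(rec)
  an <- inf$anova
  expect_equal(an$F[an$factor == "experiment"], 30.375, tolerance = 1e-9)
  expect_equal(an$F[an$factor == "genotype"], 13.5, tolerance = 1e-9)
  expect_equal(an$df, c(1, 1, 9))
  # per-experiment Welch t-tests see the 2-unit genotype difference
  expect_equal(nrow(inf$t_tests), 2L)
  expect_true(all(inf$t_tests$mean_1 - inf$t_tests$mean_2 == 2))
  # genotype missing from one experiment is an error
  expect_error(mfi_inference(rec[rec$experiment == 1 | rec$genotype == "AA", ]),
               "both genotypes")
})

test_that("experiment-only effects do not masquerade as genotype effects", {
  set.seed(21)
  p_geno <- p_exp <- numeric(40)
  for (s in 1:40) {
    mf <- gen_mfi_fixture(genotype_effect = 0, experiment_effect = 0.4,
                          seed = s)
    an <- mfi_inference(mf)$anova
    p_geno[s] <- an$p[an$factor == "genotype"]
    p_exp[s] <- an$p[an$factor == "experiment"]
  }
  expect_lt(mean(p_exp < 0.05), 1.01)      # experiment effect detected ...
  expect_gt(mean(p_exp < 0.05), 0.9)
  # ... while the genotype p-values stay calibrated (roughly uniform)
  expect_lt(mean(p_geno < 0.05), 0.2)
  expect_gt(mean(p_geno), 0.3)
})

test_that("Hardy-Weinberg proportions follow p^2, 2pq, q^2", {
  f <- hwe_genotype_freqs(0.5)
  expect_equal(unname(f), c(0.25, 0.5, 0.25))
  expect_equal(sum(hwe_genotype_freqs(0.3)), 1)
  expect_equal(unname(hwe_genotype_freqs(1)["AA"]), 1)
})
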
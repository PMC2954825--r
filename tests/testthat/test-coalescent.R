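# Monte-Carlo sizes here are scaled to keep the suite fast; the acceptance
# suite runs the larger calibration checks.

test_that("pairwise coalescence time is 1 in units of 2N generations", {
  set.seed(101)
  m <- constant_model()
  cfg <- sim_config(n = 2, L = 1000, rho_per_bp = 0, S_condition = 1)
  t2 <- replicate(2000, simulate_genealogy(cfg, m)$tmrca)
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 1), 3 * se)
})

test_that("total tree length matches 2 * sum(1/i) for constant size", {
  set.seed(102)
  m <- constant_model()
  cfg <- sim_config(n = 10, L = 1000, rho_per_bp = 0, S_condition = 1)
  len <- replicate(1500, simulate_genealogy(cfg, m)$total_length)
  expected <- 2 * sum(1 / (1:9))
  se <- sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - expected), 3 * se)
})

test_that("the same seed reproduces trees and mutation placements", {
  m <- ooa_model()
  cfg <- sim_config(n = c(AF = 6, EU = 6, AS = 4), S_condition = 12)
  set.seed(7); g1 <- simulate_genealogy(cfg, m); r1 <- place_mutations(g1, 12)
  set.seed(7); g2 <- simulate_genealogy(cfg, m); r2 <- place_mutations(g2, 12)
  expect_identical(g1$node_time, g2$node_time)
  expect_identical(g1$edges, g2$edges)
  expect_identical(r1$mat, r2$mat)
  expect_identical(r1$positions, r2$positions)
})

test_that("the out-of-Africa null has three demes joining into one root", {
  m <- ooa_model()
  expect_equal(m$labels, c("AF", "EU", "AS"))
  joins <- Filter(function(e) e$kind == "join", m$events)
  expect_equal(length(joins), 2L)   # AS->EU, then EU->AF: one root lineage
  # growth in the non-African demes at present
  expect_true(all(m$growth0[2:3] > 0))
  # deeper samples coalesce: a quick run completes
  set.seed(1)
  g <- simulate_genealogy(sim_config(n = c(AF = 4, EU = 4, AS = 4),
                                     S_condition = 5), m)
  expect_gt(g$tmrca, 0)
})

test_that("fixed-S placement yields exactly S segregating columns", {
  set.seed(103)
  m <- constant_model()
  cfg <- sim_config(n = 8, L = 1000, rho_per_bp = 0)
  g <- simulate_genealogy(cfg, m)
  expect_equal(ncol(place_mutations(g, S = 0)$mat), 0L)
  r <- place_mutations(g, S = 100)
  expect_equal(ncol(r$mat), 100L)
  d <- colSums(r$mat)
  expect_true(all(d > 0 & d < 8))          # every column segregates
  expect_false(is.unsorted(r$positions))
})

test_that("mutations land on branches proportionally to length", {
  set.seed(104)
  g <- three_leaf_genealogy()              # branch lengths 1, 1, 2
  r <- place_mutations(g, S = 10000)
  long_frac <- mean(r$mat[3, ])            # carriers of leaf-3's branch
  expect_lt(abs(long_frac - 0.5), 0.02)
  short_frac <- mean(r$mat[1, ])
  expect_lt(abs(short_frac - 0.25), 0.02)
})

test_that("outgroup divergence scales linearly and never overlaps SNPs", {
  set.seed(105)
  m <- constant_model()
  cfg <- sim_config(n = 8, L = 1000, rho_per_bp = 0)
  fd1 <- fd2 <- numeric(400)
  for (i in 1:400) {
    g <- simulate_genealogy(cfg, m)
    r <- place_mutations(g, S = 20)
    expect_equal(add_outgroup_divergence(r, 0)$fd, 0L)
    fd1[i] <- add_outgroup_divergence(r, 2)$fd
    fd2[i] <- add_outgroup_divergence(r, 4)$fd
  }
  # doubling the stem doubles the expected fixed differences
  expect_lt(abs(mean(fd2) / mean(fd1) - 2), 0.2)
  # infinite sites: divergence positions are distinct from SNP positions
  r <- add_outgroup_divergence(place_mutations(simulate_genealogy(cfg, m), 20), 5)
  expect_equal(length(intersect(r$fd_positions, r$positions)), 0L)
  expect_error(add_outgroup_divergence(r, -1), "negative")
})

test_that("divergence calibration converges monotonically to the target", {
  set.seed(106)
  m <- constant_model()
  cfg <- sim_config(n = 10, L = 1000, rho_per_bp = 0, S_condition = 20)
  cal <- calibrate_divergence(cfg, m, target_ratio = 2, batch = 150)
  expect_lt(abs(cal$achieved_ratio - 2) / 2, 0.05)
  # larger stem -> more fixed differences -> smaller SNP/FD ratio
  cal_small <- calibrate_divergence(cfg, m, target_ratio = 0.5, batch = 150)
  expect_gt(cal_small$outgroup_scale, cal$outgroup_scale)
  expect_error(calibrate_divergence(cfg, m, target_ratio = -1), "positive")
})

test_that("null distributions stream statistics deterministically", {
  m <- constant_model()
  cfg <- sim_config(n = 10, L = 1000, rho_per_bp = 0, S_condition = 15)
  d1 <- null_distribution(list(TajD = sim_tajimas_d, pi = sim_theta_pi),
                          cfg, m, n_reps = 10, seed = 5)
  expect_equal(dim(d1), c(10L, 2L))
  d2 <- null_distribution(list(TajD = sim_tajimas_d, pi = sim_theta_pi),
                          cfg, m, n_reps = 10, seed = 5)
  expect_identical(unclass(d1), unclass(d2))
  # neutral Tajima's D distribution is centred near zero
  set.seed(107)
  d <- null_distribution(list(TajD = sim_tajimas_d), cfg, m, n_reps = 600)
  se <- sd(d[, 1]) / sqrt(nrow(d))
  expect_lt(abs(mean(d[, 1])), 0.15 + 3 * se)   # small negative bias allowed
})

test_that("summary statistics are invariant to sample relabelling", {
  set.seed(108)
  m <- constant_model()
  cfg <- sim_config(n = 12, L = 1000, rho_per_bp = 0, S_condition = 25)
  r <- place_mutations(simulate_genealogy(cfg, m), 25)
  perm <- sample(12)
  rp <- r; rp$mat <- r$mat[perm, ]
  expect_equal(sim_theta_pi(rp), sim_theta_pi(r))
  expect_equal(sim_tajimas_d(rp), sim_tajimas_d(r))
  expect_equal(sort(sim_fold_freqs(rp)), sort(sim_fold_freqs(r)))
})

test_that("ms-format text output re-parses to the identical matrices", {
  set.seed(109)
  m <- constant_model()
  cfg <- sim_config(n = 6, L = 1000, rho_per_bp = 0)
  reps <- lapply(1:3, function(i)
    place_mutations(simulate_genealogy(cfg, m), S = c(8, 0, 15)[i]))
  path <- tempfile(fileext = ".ms")
  write_ms(reps, path)
  back <- read_ms(path)
  for (i in 1:3) {
    if (ncol(reps[[i]]$mat) == 0) {
      expect_equal(ncol(back[[i]]$mat), 0L)
      next
    }
    expect_equal(back[[i]]$mat, unname(reps[[i]]$mat * 1L),
                 ignore_attr = TRUE)
    expect_equal(back[[i]]$positions,
                 as.numeric(sprintf("%.5f", reps[[i]]$positions)))
  }
})

test_that("recombination leaves marginal trees exactly coalescent", {
  set.seed(110)
  m <- constant_model()
  cfg <- sim_config(n = 8, L = 1000, rho_per_bp = 5 / 1000, S_condition = 5)
  stats <- replicate(800, {
    g <- simulate_genealogy(cfg, m)
    e <- g$edges
    cov <- e[, "left"] <= 0.5 & e[, "right"] > 0.5
    c(sum(g$node_time[e[cov, "parent"]] - g$node_time[e[cov, "child"]]),
      g$n_recomb)
  })
  expect_gt(mean(stats[2, ]), 1)           # recombination actually happens
  expected <- 2 * sum(1 / (1:7))
  se <- sd(stats[1, ]) / sqrt(ncol(stats))
  expect_lt(abs(mean(stats[1, ]) - expected), 3.5 * se)
})
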
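small_spec <- function(...) fixture_spec(n_diploids = 3, S = 30, ...)

test_that("locus fixtures are pure functions of spec and seed", {
  fx1 <- gen_locus_fixture(small_spec(), seed = 5)
  fx2 <- gen_locus_fixture(small_spec(), seed = 5)
  expect_identical(fx1$aln$alleles, fx2$aln$alleles)
  expect_identical(fx1$outgroup, fx2$outgroup)
  expect_identical(fx1$truth, fx2$truth)
  fx3 <- gen_locus_fixture(small_spec(), seed = 6)
  expect_false(identical(fx1$aln$alleles, fx3$aln$alleles))
  # file bundle is byte-identical under the same seed
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  gen_locus_fixture(small_spec(), seed = 5, dir = d1)
  gen_locus_fixture(small_spec(), seed = 5, dir = d2)
  for (f in c("haplotypes.fa", "outgroup.fa", "popmap.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("balancing fixtures carry two clades at the target frequency", {
  fx <- gen_locus_fixture(small_spec(), seed = 9)
  expect_equal(as.integer(table(fx$truth$clade)), c(18L, 18L))
  # every population holds both clades at equal share
  tab <- table(fx$truth$clade, fx$aln$populations[names(fx$truth$clade)])
  expect_true(all(tab == 3L))
  # diagnostic sites exist for the default deep split, across seeds
  n_diag <- vapply(1:5, function(s)
    length(gen_locus_fixture(small_spec(), seed = s)$truth$diagnostic_sites),
    numeric(1))
  expect_true(all(n_diag >= 1))
  expect_error(gen_locus_fixture(fixture_spec(n_diploids = 3,
                                              clade_freq = 0.001), seed = 1),
               "infeasible")
})

test_that("fixture files round-trip through the package readers", {
  d <- file.path(tempdir(), "fx_roundtrip")
  fx <- gen_locus_fixture(small_spec(), seed = 4, dir = d)
  aln <- read_haplotypes(file.path(d, "haplotypes.fa"),
                         file.path(d, "popmap.tsv"))
  expect_equal(nrow(aln$alleles), 36L)
  # variant columns of the full-sequence alignment match the fixture's sites
  vt <- variant_table(aln)
  expect_equal(vt$pos, fx$aln$positions)
  og <- strsplit(readLines(file.path(d, "outgroup.fa"))[2], "")[[1]]
  pol <- polarize_sites(vt, og)
  expect_equal(sum(!is.na(pol$anc)), nrow(pol))   # outgroup polarizes all sites
})

test_that("neutral mode assigns populations to their demographic demes", {
  fx <- gen_locus_fixture(small_spec(mode = "neutral"), seed = 2)
  expect_equal(ncol(fx$aln$alleles), 30L)
  expect_null(fx$truth$clade)
  expect_equal(sort(unique(fx$aln$populations)),
               sort(c("Yoruba", "Luhya", "Palestinian", "Gujarati", "Han",
                      "Toscani")))
})

test_that("the control panel is 47 independent seeded neutral loci", {
  panel <- gen_control_panel(count = 5, small_spec(), seed = 100,
                             S_per_region = 4)
  expect_equal(length(panel), 5L)
  expect_equal(attr(panel, "seeds"), 100 + 1:5)
  expect_true(all(vapply(panel, function(f) f$truth$mode, "") == "neutral"))
  expect_true(all(vapply(panel, function(f) f$truth$S, 0) == 4))
  # distinct loci
  expect_false(identical(panel[[1]]$aln$alleles, panel[[2]]$aln$alleles))
})

test_that("qPCR fixtures recover their own truth exactly without noise", {
  q <- gen_qpcr_fixture(true_ratio = 0.3, ct_sd = 0, seed = 3)
  cv <- fit_standard_curve(q[q$role == "standard", ])
  expect_equal(allelic_ratio(q[q$sample == "unknown_1", ], cv)$ratio, 0.3,
               tolerance = 1e-9)
  expect_equal(allelic_ratio(q[q$role == "gDNA-control", ], cv)$ratio, 1.0,
               tolerance = 1e-9)
  expect_identical(gen_qpcr_fixture(seed = 3), gen_qpcr_fixture(seed = 3))
  expect_error(gen_qpcr_fixture(true_ratio = -1), "positive")
})

test_that("MFI fixtures encode the stated effects and determinism", {
  expect_identical(gen_mfi_fixture(seed = 8), gen_mfi_fixture(seed = 8))
  # zero effects: genotype group means agree in expectation
  set.seed(1)
  stds <- replicate(30, {
    mf <- gen_mfi_fixture(genotype_effect = 0, experiment_effect = 0,
                          seed = sample.int(1e6, 1))
    std <- mf$hla_mfi / mf$cd19_mfi
    tapply(std, mf$genotype, mean)
  })
  expect_lt(abs(mean(stds["AA", ]) - mean(stds["BB", ])), 0.05)
  # default effect: BB standardized mean is ~20% below AA
  mf <- do.call(rbind, lapply(1:20, function(s) gen_mfi_fixture(seed = s)))
  std <- mf$hla_mfi / mf$cd19_mfi
  ratio <- mean(std[mf$genotype == "BB"]) / mean(std[mf$genotype == "AA"])
  expect_lt(abs(ratio - 0.8), 0.05)
  expect_error(gen_mfi_fixture(outlier_rate = 1.5), "outlier rate")
})

test_that("the detection power of the genotype effect meets its design", {
  p <- vapply(1:40, function(s) {
    mf <- gen_mfi_fixture(seed = s)
    an <- mfi_inference(mf)$anova
    an$p[an$factor == "genotype"]
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0.8)
})

test_that("the toy gene fixture states its world consistently", {
  gene <- gen_gene_model_fixture()
  expect_equal(gene$snp$pos, 392L)
  expect_equal(gene$cryptic_donors[[3]], 445L)   # 56 nt into intron 3
  expect_equal(445L - gene$exons[3, 2], 56L)
  fa <- splice_and_translate(gene, "A")
  fb <- splice_and_translate(gene, "B")
  expect_false(fa$nmd)
  expect_true(fb$nmd)
  expect_lt(fb$protein_length, fa$protein_length)
})
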
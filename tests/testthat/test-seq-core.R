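test_that("FASTA haplotypes parse into a rectangular alignment with populations", {
  seqs <- c(s1.1 = "ACGTAC", s1.2 = "ACGTAC", s2.1 = "ACTTAC", s2.2 = "ACGTAT")
  path <- write_toy_fasta(seqs)
  aln <- read_haplotypes(path, toy_popmap(c("s1", "s2"), c("popA", "popB")))
  expect_equal(dim(aln$alleles), c(4L, 6L))
  expect_setequal(unique(aln$populations), c("popA", "popB"))

  ragged <- write_toy_fasta(c(s1.1 = "ACGTAC", s1.2 = "ACGTA"))
  expect_error(read_haplotypes(ragged, toy_popmap("s1", "popA")), "ragged")

  expect_error(read_haplotypes(path, toy_popmap("s1", "popA")),
               "missing from popmap")
})

test_that("phased VCF yields two haplotypes per diploid; unphased is refused", {
  path <- write_toy_vcf()
  aln <- read_haplotypes(path, toy_popmap(c("s1", "s2", "s3"),
                                          c("p1", "p1", "p2")))
  expect_equal(nrow(aln$alleles), 6L)
  expect_equal(unname(aln$alleles[, 1]), c("A", "A", "A", "G", "G", "G"))
  expect_equal(aln$positions, 5L)

  bad <- write_toy_vcf(gts = c("0|0", "0/1", "1|1"))
  expect_error(read_haplotypes(bad, toy_popmap(c("s1", "s2", "s3"),
                                               rep("p", 3))), "unphased")
})

test_that("variant table finds segregating sites with counts and flags", {
  cols <- rbind(c("A", "A", "C", "T"),
                c("A", "G", "C", "T"),
                c("A", "G", "C", "A"),
                c("A", "G", "N", "G"))
  aln <- toy_alignment(cols)
  vt <- variant_table(aln)
  expect_equal(vt$pos, c(2L, 4L))          # cols 1 and 3 are monomorphic
  expect_equal(vt$major[1], "G")
  expect_equal(vt$minor[1], "A")
  expect_true(vt$flag_triallelic[2])       # T/A/G at column 4
  # third-allele carriers drop out of the biallelic called count
  expect_equal(vt$m_total, c(4L, 3L))
  expect_true(all(vt$minor_total > 0 & vt$minor_total < vt$m_total))
})

test_that("amplicon-edge rule discards 1-based offsets 1..50 from each end", {
  # amplicon 101..300: edges are 101..150 and 251..300
  m <- matrix("A", 4, 5)
  m[1, ] <- c("G", "G", "G", "G", "G")
  aln <- toy_alignment(m, positions = c(120, 150, 151, 250, 251),
                       amplicons = cbind(101, 300), locus_length = 400)
  vt <- variant_table(aln)
  out <- apply_qc_filters(vt, aln)
  # offset 50 from start (pos 150) removed; offset 51 (pos 151) kept;
  # pos 251 is offset 50 from the amplicon end, removed
  expect_equal(out$variants$pos, c(151L, 250L))
  expect_equal(out$report$removed_edge, 3L)
  again <- apply_qc_filters(out$variants, aln)
  expect_equal(again$variants$pos, out$variants$pos)   # idempotent
})

test_that("five variants with one in each edge of one amplicon leave three", {
  m <- matrix("A", 4, 5)
  m[2, ] <- "C"
  aln <- toy_alignment(m, positions = c(10, 60, 100, 150, 260),
                       amplicons = cbind(1, 300), locus_length = 300)
  out <- apply_qc_filters(variant_table(aln), aln)
  expect_equal(nrow(out$variants), 3L)     # pos 10 (lead edge) and 260 (tail) go
  expect_equal(out$variants$pos, c(60L, 100L, 150L))
})

test_that("quality filtering and uncovered flagging work and singletons survive", {
  m <- rbind(c("G", "A"), c("A", "A"), c("A", "C"), c("A", "C"))
  aln <- toy_alignment(m, positions = c(100, 400),
                       amplicons = cbind(1, 200), locus_length = 500)
  vt <- variant_table(aln, quality = c("100" = 99, "400" = 80))
  out <- apply_qc_filters(vt, aln)
  expect_equal(out$variants$pos, 100L)     # pos 400 under-quality
  expect_equal(out$report$removed_low_quality, 1L)
  expect_true(out$variants$flag_singleton[1])

  vt2 <- variant_table(aln)
  out2 <- apply_qc_filters(vt2, aln)       # no quality scores: both retained
  expect_true(out2$variants$flag_uncovered[out2$variants$pos == 400])
})

test_that("polarization keeps counts, annotates ancestry, flags mismatches", {
  m <- rbind(c("A", "A"), c("A", "A"), c("G", "G"), c("G", "G"))
  aln <- toy_alignment(m, positions = c(1, 2))
  vt <- variant_table(aln)
  og <- c("A", "C")
  pol <- polarize_sites(vt, og)
  expect_equal(pol$anc[1], "A")
  expect_equal(pol$der[1], "G")
  expect_equal(pol$d_total[1], 2L)
  expect_true(is.na(pol$anc[2]))           # outgroup C matches neither allele
  expect_equal(nrow(pol), nrow(vt))        # annotation only
})

test_that("a ten-site toy polarizes 8 sites and leaves 2 unpolarized", {
  set.seed(1)
  m <- matrix("A", 6, 10)
  for (j in 1:10) m[sample(6, 2), j] <- "G"
  rownames(m) <- sprintf("s%d.%d", rep(1:3, each = 2), rep(1:2, 3))
  pops <- setNames(rep("p", 6), rownames(m))
  aln <- haplotype_alignment(m, 1:10, pops)
  og <- c(rep("A", 5), rep("G", 3), "C", "T")   # 2 mismatching outgroup bases
  pol <- polarize_sites(variant_table(aln), og)
  expect_equal(sum(!is.na(pol$anc)), 8L)
  expect_equal(sum(is.na(pol$anc)), 2L)
  # derived counts with ancestral G are the A-carriers (4 of 6)
  expect_true(all(pol$d_total[pol$anc == "G"] == 4L, na.rm = TRUE))
})

test_that("segregating sites and fixed differences are counted exclusively", {
  m <- rbind(c("A", "C", "G", "T", "A"),
             c("A", "C", "G", "T", "G"),
             c("A", "G", "G", "T", "G"),
             c("A", "G", "T", "T", "G"))
  aln <- toy_alignment(m)
  og_same <- c("A", "C", "G", "T", "A")
  # identical consensus: sites 2,3,5 polymorphic; no fixed difference
  d0 <- count_segregating_and_fixed(toy_alignment(matrix("A", 4, 3)),
                                    c("A", "A", "A"))
  expect_equal(c(d0$S, d0$FD), c(0L, 0L))
  # outgroup differs at monomorphic sites 1 and 4, and at polymorphic site 2
  d1 <- count_segregating_and_fixed(aln, c("G", "T", "G", "C", "A"))
  expect_equal(d1$S, 3L)
  expect_equal(d1$FD, 2L)                  # polymorphic sites never count as FD
})

test_that("segregating/fixed membership is mutually exclusive on random data", {
  set.seed(42)
  for (rep in 1:20) {
    m <- matrix(sample(c("A", "G"), 4 * 8, TRUE, prob = c(0.8, 0.2)), 4, 8)
    aln <- toy_alignment(m)
    og <- sample(c("A", "C"), 8, TRUE)
    d <- count_segregating_and_fixed(aln, og)
    seg <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
    fix <- sum(vapply(seq_len(8), function(j)
      length(unique(m[, j])) == 1 && og[j] != m[1, j] &&
        og[j] %in% c("A", "C", "G", "T"), logical(1)))
    expect_equal(d$S, seg)
    expect_equal(d$FD, fix)
    expect_equal(d$S + d$FD, seg + fix)    # no double counting possible
  }
})

test_that("SNPs per fixed difference reproduce printed ratios exactly", {
  expect_equal(round(snp_fixed_ratio(22, 10), 1), 2.2)
  expect_equal(round(snp_fixed_ratio(287, 352), 2), 0.82)
  expect_equal(round(snp_fixed_ratio(45, 7), 1), 6.4)
  expect_equal(snp_fixed_ratio(0, 5), 0)
  expect_error(snp_fixed_ratio(10, 0), "FD = 0")
  # the exact internal value is retained: ratio * FD == S
  expect_identical(snp_fixed_ratio(22, 10) * 10, 22)
  expect_equal(snp_fixed_ratio(287, 352) * 352, 287)
})

test_that("pairwise r2 covers perfect LD, independence and a hand case", {
  co <- cbind(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0))
  expect_equal(pairwise_r2(co, cbind(1, 2))$r2, 1)
  orth <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(pairwise_r2(orth, cbind(1, 2))$r2, 0)
  # hand computation: x = 4/2 split, y = 2/4 split, overlap 2 -> r2 = 0.25
  hand <- cbind(c(1, 1, 1, 1, 0, 0), c(1, 1, 0, 0, 0, 0))
  expect_equal(pairwise_r2(hand, cbind(1, 2))$r2, 0.25)
  mono <- cbind(c(1, 1, 1, 1), c(1, 0, 1, 0))
  expect_true(is.na(pairwise_r2(mono, cbind(1, 2))$r2))
})
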
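# shared fixture builders; everything is generated in code at test time

# tiny alignment: 4 haplotypes (2 diploids, 2 populations), explicit columns
toy_alignment <- function(cols, positions = seq_len(ncol(cols)),
                          region = "noncoding", amplicons = NULL,
                          locus_length = NULL) {
  rownames(cols) <- c("s1.1", "s1.2", "s2.1", "s2.2")[seq_len(nrow(cols))]
  pops <- setNames(rep(c("popA", "popB"), each = 2)[seq_len(nrow(cols))],
                   rownames(cols))
  haplotype_alignment(cols, positions, pops, region = region,
                      amplicons = amplicons, locus_length = locus_length)
}

# alignment from a 0/1 matrix: 0 -> A, 1 -> G, one population
binary_alignment <- function(m, population = "pop") {
  alle <- ifelse(m == 1L, "G", "A")
  rownames(alle) <- sprintf("h%02d.%d", rep(seq_len(nrow(m) / 2), each = 2),
                            rep(1:2, nrow(m) / 2))[seq_len(nrow(m))]
  if (nrow(m) %% 2 == 1) rownames(alle)[nrow(m)] <- "hx.1"
  pops <- setNames(rep(population, nrow(m)), rownames(alle))
  haplotype_alignment(alle, seq_len(ncol(m)), pops)
}

write_toy_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}

write_toy_vcf <- function(path = tempfile(fileext = ".vcf"),
                          gts = c("0|0", "0|1", "1|1"),
                          samples = c("s1", "s2", "s3"),
                          pos = 5L, ref = "A", alt = "G") {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste(c("chr1", pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
          collapse = "\t"))
  writeLines(lines, path)
  path
}

toy_popmap <- function(samples, pops) {
  data.frame(sample = samples, population = pops)
}

# a hand-made genealogy: three leaves with branch lengths 1, 1, 2 to a
# common root (leaves 1,2 at time 1, leaf 3 at time 0, root at time 2)
three_leaf_genealogy <- function() {
  edges <- cbind(child = 1:3, parent = 4L, left = 0, right = 1)
  structure(list(node_time = c(1, 1, 0, 2), edges = edges, n = 3L,
                 sample_deme = rep(1L, 3), tmrca = 2,
                 total_length = 4, n_recomb = 0L),
            class = "genealogy")
}

# small-n single-population neutral simulation returning folded counts
sim_folded_counts <- function(n, S, model = constant_model()) {
  cfg <- sim_config(n = n, L = 1000, rho_per_bp = 0, S_condition = S)
  g <- simulate_genealogy(cfg, model)
  sim_fold_freqs(place_mutations(g, S = S))
}
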
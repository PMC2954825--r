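#' Specification of a synthetic locus fixture
#'
#' The defaults restate the study design being emulated: 30 diploids from
#' each of 6 populations (360 phased haplotypes) over an 8,794-bp locus of
#' which 2,883 bp are protein coding, with a chimpanzee-like outgroup at
#' 6 Myr divergence. In `"balancing"` mode two allelic classes are
#' maintained structurally — modelled as two demes of relative size 0.5
#' with no exchange that merge into the ancestral population at the clade
#' split time — which reproduces the genetic signatures of long-term
#' balancing selection (two deep haplogroups near frequency 0.5 and an
#' excess of intermediate-frequency variants) without simulating selection
#' coefficients. The default split age corresponds to ~1.4 Myr (generation
#' time 25 y, reference N 7310, i.e. ~3.83 units of 2N generations).
#'
#' @param mode `"neutral"` (three-population out-of-Africa null) or
#'   `"balancing"`.
#' @param n_diploids diploids per population.
#' @param populations population labels; mapped onto the demographic demes
#'   via `deme_of`.
#' @param deme_of named map population -> deme (`AF`/`EU`/`AS`).
#' @param L locus length (bp).
#' @param coding_span 1-based inclusive (start, end) of the coding block.
#' @param S total segregating sites to condition on (locus default 79:
#'   22 coding + 57 non-coding).
#' @param T_b clade split age, units of 2N generations (balancing mode).
#' @param clade_freq target frequency of clade A.
#' @param divergence_time_years outgroup divergence calibration.
#' @param N_ref,gen_years reference size and generation time.
#' @param outgroup_scale stem length for fixed differences; `NULL` uses
#'   `2 * divergence_time_years / gen_years / (2 N_ref)` (the full
#'   two-lineage divergence branch).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(mode = c("balancing", "neutral"),
                         n_diploids = 30,
                         populations = c("Yoruba", "Luhya", "Palestinian",
                                         "Gujarati", "Han", "Toscani"),
                         deme_of = c(Yoruba = "AF", Luhya = "AF",
                                     Palestinian = "EU", Gujarati = "EU",
                                     Han = "AS", Toscani = "EU"),
                         L = 8794, coding_span = c(2956, 5838),
                         S = 79, T_b = NULL, clade_freq = 0.5,
                         divergence_time_years = 6e6,
                         N_ref = 7310, gen_years = 25,
                         outgroup_scale = NULL) {
  mode <- match.arg(mode)
  if (clade_freq <= 0 || clade_freq >= 1) stop("clade frequency must be in (0,1)")
  if (L <= 0) stop("locus length must be positive")
  unit_gens <- 2 * N_ref
  if (is.null(T_b)) T_b <- 1.4e6 / gen_years / unit_gens
  if (is.null(outgroup_scale))
    outgroup_scale <- 2 * divergence_time_years / gen_years / unit_gens
  structure(list(mode = mode, n_diploids = n_diploids,
                 populations = populations, deme_of = deme_of,
                 L = L, coding_span = coding_span, S = S, T_b = T_b,
                 clade_freq = clade_freq,
                 divergence_time_years = divergence_time_years,
                 N_ref = N_ref, gen_years = gen_years,
                 outgroup_scale = outgroup_scale),
            class = "fixture_spec")
}

# two allelic classes as isolated demes merging at T_b
balancing_model <- function(spec) {
  demographic_model(
    c("cladeA", "cladeB"), sizes0 = c(0.5, 0.5),
    events = list(
      list(time = spec$T_b, kind = "join", from = "cladeB", to = "cladeA"),
      list(time = spec$T_b, kind = "size", deme = "cladeA", size = 1)),
    N_ref = spec$N_ref, gen_years = spec$gen_years)
}

#' Generate a synthetic locus fixture
#'
#' Simulates haplotypes under the spec's mode, converts the 0/1 matrix to
#' nucleotides on a deterministic background sequence, attaches populations
#' and an outgroup sequence carrying the fixed differences, and (optionally)
#' writes haplotype FASTA, outgroup FASTA, popmap TSV and a truth JSON to
#' `dir`. All output is a pure function of `(spec, seed)`.
#'
#' @param spec a [fixture_spec()].
#' @param seed integer seed.
#' @param dir optional output directory for the file bundle.
#' @return list with `aln` (a [haplotype_alignment()]), `outgroup`
#'   (character vector), `popmap` (data.frame), and `truth` (clade labels,
#'   diagnostic sites, split/TMRCA ages, FD, seed).
#' @export
gen_locus_fixture <- function(spec, seed, dir = NULL) {
  set.seed(seed)
  n_pop <- length(spec$populations)
  n_hap <- 2L * spec$n_diploids * n_pop
  if (spec$mode == "balancing") {
    n_a <- round(spec$clade_freq * n_hap)
    if (n_a < 1 || n_a > n_hap - 1)
      stop("infeasible clade frequency for this sample size")
    model <- balancing_model(spec)
    cfg <- sim_config(n = c(cladeA = n_a, cladeB = n_hap - n_a), L = spec$L,
                      S_condition = spec$S)
    clade <- rep(c("A", "B"), c(n_a, n_hap - n_a))
  } else {
    model <- ooa_model(N_A = spec$N_ref, gen_years = spec$gen_years)
    demes <- spec$deme_of[spec$populations]
    n_by_deme <- vapply(c("AF", "EU", "AS"), function(d)
      as.integer(2 * spec$n_diploids * sum(demes == d)), integer(1))
    cfg <- sim_config(n = n_by_deme, L = spec$L, S_condition = spec$S)
    clade <- rep(NA_character_, n_hap)
  }
  g <- simulate_genealogy(cfg, model)
  rep_ <- place_mutations(g, S = spec$S)
  rep_ <- add_outgroup_divergence(rep_, spec$outgroup_scale)

  # haplotype ids and populations; in balancing mode each population takes
  # equal shares of both clades so clade frequency is uniform across groups
  ids <- pops <- character(n_hap)
  n_per_pop <- 2L * spec$n_diploids
  if (spec$mode == "balancing") {
    # sim rows: clade A block then clade B block; deal equal shares of each
    # clade to every population
    idx_a <- which(clade == "A"); idx_b <- which(clade == "B")
    per_a <- split_counts(length(idx_a), n_pop)
    per_b <- split_counts(length(idx_b), n_pop)
    ord <- integer(0); ca <- cb <- 0L
    for (p in seq_len(n_pop)) {
      ord <- c(ord, idx_a[ca + seq_len(per_a[p])], idx_b[cb + seq_len(per_b[p])])
      ca <- ca + per_a[p]; cb <- cb + per_b[p]
    }
  } else {
    # sim rows come in deme blocks (AF, EU, AS); hand each population the
    # next block of its deme, following the population order of the spec
    demes <- spec$deme_of[spec$populations]
    block_start <- c(AF = 0L,
                     EU = n_per_pop * sum(demes == "AF"),
                     AS = n_per_pop * sum(demes %in% c("AF", "EU")))
    cursor <- c(AF = 0L, EU = 0L, AS = 0L)
    ord <- integer(0)
    for (p in seq_len(n_pop)) {
      d <- demes[p]
      ord <- c(ord, block_start[d] + cursor[d] + seq_len(n_per_pop))
      cursor[d] <- cursor[d] + n_per_pop
    }
  }
  mat <- rep_$mat[ord, , drop = FALSE]
  clade <- clade[ord]
  i <- 1L
  for (p in spec$populations) for (s in seq_len(spec$n_diploids)) for (ph in 1:2) {
    ids[i] <- sprintf("%s%02d.%d", substr(p, 1, 3), s, ph)
    pops[i] <- p
    i <- i + 1L
  }

  # map continuous positions to integer locus coordinates and to nucleotides
  S <- ncol(mat)
  all_pos <- sort(sample.int(spec$L, S + rep_$fd))
  snp_pos <- sort(sample(all_pos, S))
  fd_pos <- setdiff(all_pos, snp_pos)
  background <- sample(c("A", "C", "G", "T"), spec$L, replace = TRUE)
  region <- rep("noncoding", spec$L)
  region[spec$coding_span[1]:spec$coding_span[2]] <- "coding"
  alle <- matrix(background[snp_pos], n_hap, S, byrow = TRUE)
  derived_base <- vapply(snp_pos, function(p)
    sample(setdiff(c("A", "C", "G", "T"), background[p]), 1), character(1))
  for (j in seq_len(S)) alle[mat[, j] == 1L, j] <- derived_base[j]
  rownames(alle) <- ids
  aln <- haplotype_alignment(alle, snp_pos, stats::setNames(pops, ids),
                             region = region[snp_pos],
                             locus_length = spec$L)
  outgroup <- background
  for (p in fd_pos)
    outgroup[p] <- sample(setdiff(c("A", "C", "G", "T"), background[p]), 1)

  mu_unit <- if (g$total_length > 0) spec$S / g$total_length else NA_real_
  years_per_unit <- 2 * spec$N_ref * spec$gen_years
  diag_sites <- if (spec$mode == "balancing") {
    part <- list(group = stats::setNames(clade, ids))
    diagnostic_snps(aln, part)
  } else NULL
  truth <- list(mode = spec$mode, seed = seed,
                clade = if (spec$mode == "balancing")
                  stats::setNames(clade, ids) else NULL,
                diagnostic_sites = diag_sites$diagnostic,
                T_b_units = if (spec$mode == "balancing") spec$T_b else NULL,
                T_b_years = if (spec$mode == "balancing")
                  spec$T_b * years_per_unit else NULL,
                tmrca_units = g$tmrca,
                tmrca_years = g$tmrca * years_per_unit,
                FD = rep_$fd, S = S,
                mu_locus_per_year = mu_unit / years_per_unit,
                ancestral = background[snp_pos])
  popmap <- data.frame(sample = unique(sub("\\.[12]$", "", ids)),
                       population = pops[seq(1, n_hap, by = 2)])
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    # full-length resequencing-style records: background with each
    # haplotype's variant alleles substituted
    full <- matrix(background, n_hap, spec$L, byrow = TRUE)
    full[, snp_pos] <- alle
    rownames(full) <- ids
    full_aln <- haplotype_alignment(full, seq_len(spec$L),
                                    stats::setNames(pops, ids),
                                    region = region, locus_length = spec$L)
    write_haplotype_fasta(full_aln, file.path(dir, "haplotypes.fa"))
    writeLines(c(">outgroup", paste0(outgroup, collapse = "")),
               file.path(dir, "outgroup.fa"))
    utils::write.table(popmap, file.path(dir, "popmap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(aln = aln, outgroup = outgroup, popmap = popmap, truth = truth)
}

split_counts <- function(total, k) {
  base <- total %/% k
  extra <- total - base * k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

#' Generate a panel of neutral control-region fixtures
#'
#' Independent neutral loci sharing the sample layout of `spec`, emulating
#' a resequenced control panel (default 47 regions with ~6 segregating
#' sites each, i.e. a pooled panel of ~280 SNPs). Each region gets its own
#' logged seed derived from `seed`.
#'
#' @param count number of control regions (default 47).
#' @param spec a [fixture_spec()]; its mode is forced to `"neutral"`.
#' @param seed master seed.
#' @param S_per_region segregating sites per control region.
#' @param L_per_region control-region length in bp.
#' @return list of fixtures (as from [gen_locus_fixture()]), with the
#'   per-region seeds in `attr(, "seeds")`.
#' @export
gen_control_panel <- function(count = 47, spec, seed, S_per_region = 6,
                              L_per_region = 2000) {
  cspec <- spec
  cspec$mode <- "neutral"
  cspec$S <- S_per_region
  cspec$L <- L_per_region
  cspec$coding_span <- c(1, L_per_region)  # controls scored as one class
  seeds <- seed + seq_len(count)
  out <- lapply(seeds, function(s) gen_locus_fixture(cspec, s))
  attr(out, "seeds") <- seeds
  out
}

#' Generate a synthetic allele-specific qPCR plate
#'
#' Standards are serial mixes of the two homozygous templates at the given
#' allele-B fractions; unknowns carry the true cDNA B:A ratio; a
#' heterozygous genomic-DNA control carries equal template (ratio 1).
#' Channel Ct values follow the exact template model
#' `Ct = base_ct - log2(amount)` plus Gaussian noise `ct_sd` per well, so
#' the true standard curve has slope 1 and intercept 0 on the
#' `log2(ratio) ~ delta Ct` scale.
#'
#' @param true_ratio true B:A cDNA ratio of the unknown samples.
#' @param ct_sd per-well Ct noise standard deviation (cycles; default 0.1).
#' @param fractions allele-B fractions of the standards.
#' @param n_replicates wells per point (default triplicates).
#' @param n_unknowns unknown cDNA samples.
#' @param base_ct nominal Ct of one template unit.
#' @param seed integer seed.
#' @return data.frame of wells (`sample`, `role`, `fraction`, `ct_a`,
#'   `ct_b`, `replicate`, `treatment`) with the truth in
#'   `attr(, "truth")`.
#' @export
gen_qpcr_fixture <- function(true_ratio = 0.3, ct_sd = 0.1,
                             fractions = seq(0.1, 0.9, by = 0.1),
                             n_replicates = 3, n_unknowns = 1,
                             base_ct = 24, seed = 1) {
  if (true_ratio <= 0) stop("true ratio must be positive")
  set.seed(seed)
  well <- function(sample, role, fraction, amount_a, amount_b, treatment) {
    data.frame(sample = sample, role = role, fraction = fraction,
               ct_a = base_ct - log2(amount_a) +
                 stats::rnorm(n_replicates, 0, ct_sd),
               ct_b = base_ct - log2(amount_b) +
                 stats::rnorm(n_replicates, 0, ct_sd),
               replicate = seq_len(n_replicates), treatment = treatment)
  }
  out <- list()
  for (f in fractions)
    out[[length(out) + 1L]] <- well(sprintf("std_%0.2f", f), "standard", f,
                                    1 - f, f, "untreated")
  for (u in seq_len(n_unknowns))
    out[[length(out) + 1L]] <- well(sprintf("unknown_%d", u), "unknown", NA,
                                    1 / (1 + true_ratio),
                                    true_ratio / (1 + true_ratio), "untreated")
  out[[length(out) + 1L]] <- well("gdna_het", "gDNA-control", NA, 0.5, 0.5,
                                  "untreated")
  res <- do.call(rbind, out)
  attr(res, "truth") <- list(true_ratio = true_ratio, slope = 1, intercept = 0,
                             ct_sd = ct_sd, seed = seed)
  res
}

#' Generate a synthetic flow-cytometry MFI table
#'
#' Log-normal MFIs for two experiments x three genotypes. The standardized
#' (HLA/CD19) mean of BB homozygotes is reduced by `genotype_effect`
#' (heterozygotes by half of it); experiment 2 is shifted by
#' `experiment_effect`; optional outliers are injected by tripling the
#' standardized value. Defaults: 20% genotype effect, 30% experiment
#' shift, 6 samples per genotype per experiment, biological CV about 15%.
#'
#' @param genotype_effect fractional reduction of the BB standardized mean.
#' @param experiment_effect fractional shift of experiment 2.
#' @param n_per_cell samples per experiment x genotype cell.
#' @param outlier_rate probability a sample is an injected outlier.
#' @param sdlog log-scale biological noise.
#' @param seed integer seed.
#' @return data.frame (`sample`, `genotype`, `experiment`, `hla_mfi`,
#'   `cd19_mfi`) with truth in `attr(, "truth")`.
#' @export
gen_mfi_fixture <- function(genotype_effect = 0.2, experiment_effect = 0.3,
                            n_per_cell = 6, outlier_rate = 0,
                            sdlog = 0.15, seed = 1) {
  if (outlier_rate < 0 || outlier_rate >= 1) stop("outlier rate must be in [0,1)")
  set.seed(seed)
  rows <- list()
  geno_mult <- c(AA = 1, AB = 1 - genotype_effect / 2, BB = 1 - genotype_effect)
  i <- 0L
  for (e in 1:2) for (g in names(geno_mult)) for (s in seq_len(n_per_cell)) {
    i <- i + 1L
    cd19 <- stats::rlnorm(1, log(2000), sdlog)
    std <- stats::rlnorm(1, log(1.0 * geno_mult[g] *
                                  (1 + experiment_effect * (e - 1))), sdlog)
    if (stats::runif(1) < outlier_rate) std <- std * 3
    rows[[i]] <- data.frame(sample = sprintf("s%03d", i), genotype = g,
                            experiment = e, hla_mfi = std * cd19,
                            cd19_mfi = cd19)
  }
  res <- do.call(rbind, rows)
  attr(res, "truth") <- list(genotype_effect = genotype_effect,
                             experiment_effect = experiment_effect,
                             outlier_rate = outlier_rate, sdlog = sdlog,
                             seed = seed)
  res
}

#' Toy five-exon gene model with an allele-dependent donor
#'
#' Mirrors the splice biology under study: the SNP sits at intronic
#' position +3 of the canonical donor of intron 3, turning the 9-mer
#' ATGGTAAGG (allele A) into ATGGTGAGG (allele B). Under the built-in toy
#' PWM these score 9.07 and 8.10; with the gene's threshold of 8.6 the B
#' allele deactivates the canonical site, so the cryptic donor 56 nt into
#' intron 3 is used, extending exon 3 by 56 nt. The extension carries two
#' in-frame TAG stop codons whose position leaves the stop 197 nt upstream
#' of the final exon junction: a premature termination codon that meets the
#' 50-nt NMD rule. Allele A yields a 120-aa full-length protein; allele B a
#' truncated 62-aa protein flagged for NMD.
#'
#' @return a [gene_model()] with `min_score = 8.6`.
#' @export
gen_gene_model_fixture <- function() {
  L <- 909
  seq <- rep("C", L)
  exons <- rbind(c(1, 30), c(131, 220), c(321, 389), c(510, 659), c(760, 909))
  cds_start <- 10
  # CDS filler: ATG start then GCT codons, per exon (each exon holds whole
  # codons so the frame restarts cleanly at every exon start)
  fill_codons <- function(from, to) {
    idx <- from:to
    rep(c("G", "C", "T"), length.out = length(idx))
  }
  seq[10:12] <- c("A", "T", "G")
  seq[13:30] <- fill_codons(13, 30)
  seq[1:9] <- "C"
  seq[131:220] <- fill_codons(131, 220)
  seq[321:389] <- fill_codons(321, 389)
  seq[510:659] <- fill_codons(510, 659)
  seq[760:909] <- fill_codons(760, 909)
  seq[790:792] <- c("T", "A", "A")          # canonical stop, final exon
  # donor signals: last 3 exonic bases ATG + intronic GTAAGG
  for (e in c(30, 220, 659)) {
    seq[(e - 2):e] <- c("A", "T", "G")
    seq[(e + 1):(e + 6)] <- c("G", "T", "A", "A", "G", "G")
  }
  seq[387:389] <- c("A", "T", "G")          # canonical donor of intron 3
  seq[390:395] <- c("G", "T", "A", "A", "G", "G")   # SNP at 392 (A/G)
  # 56-nt exon-3 extension: in-frame TAGs at extension codons 3 and 5
  seq[396:398] <- c("T", "A", "G")
  seq[399:401] <- c("G", "C", "T")
  seq[402:404] <- c("T", "A", "G")
  seq[405:442] <- "C"
  seq[443:445] <- c("A", "T", "G")          # cryptic donor at intron pos 56
  seq[446:451] <- c("G", "T", "A", "C", "G", "G")
  gene_model(paste0(seq, collapse = ""), exons, cds_start,
             cryptic_donors = list(integer(0), integer(0), 445L, integer(0)),
             snp = list(pos = 392L, A = "A", B = "G"),
             min_score = 8.6)
}
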
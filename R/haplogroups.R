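#' Partition haplotypes into deep haplogroups
#'
#' Agglomerative clustering (complete linkage, resistant to chaining through
#' recombinant haplotypes) on the pairwise Hamming distance between
#' haplotypes, cut into `k` groups. With `k = 2` this recovers the two deep
#' clades expected under long-term balancing selection. Group labels are
#' assigned deterministically: the group containing the first haplotype (in
#' input order) is `"A"`.
#'
#' @param x a [haplotype_alignment()] or a 0/1 matrix (rows = haplotypes).
#' @param k number of groups (default 2).
#' @param populations optional named population vector (taken from the
#'   alignment when available) for per-population frequencies.
#' @return object of class `haplogroup_partition`: `group` (named character
#'   vector), `frequencies` (pooled), `by_population` (matrix), `support`
#'   (ratio of mean between-group to mean within-group distance) and
#'   `low_support` flag (`support < 2`, star-like data without deep
#'   structure).
#' @export
partition_haplogroups <- function(x, k = 2, populations = NULL) {
  if (inherits(x, "hap_aln")) {
    if (is.null(populations)) populations <- x$populations
    m <- as_binary_matrix(x)
    rownames(m) <- rownames(x$alleles)
  } else m <- as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 haplotypes")
  d <- stats::dist(m, method = "manhattan")
  if (all(d == 0)) stop("all haplotypes identical: no structure to partition")
  hc <- stats::hclust(d, method = "complete")
  grp <- stats::cutree(hc, k = k)
  labels <- LETTERS[seq_len(k)]
  # relabel so the first haplotype's group is A, next new group B, ...
  seen <- unique(grp)
  grp <- labels[match(grp, seen)]
  names(grp) <- rownames(m)
  dm <- as.matrix(d)
  same <- outer(grp, grp, "==")
  diag(same) <- NA
  within <- mean(dm[which(same)], na.rm = TRUE)
  between <- mean(dm[which(!same)], na.rm = TRUE)
  support <- if (is.nan(within) || within == 0) Inf else between / within
  freqs <- prop.table(table(factor(grp, levels = labels)))
  by_pop <- NULL
  if (!is.null(populations)) {
    pops <- populations[names(grp)]
    by_pop <- prop.table(table(factor(grp, levels = labels), pops), margin = 2)
  }
  structure(list(group = grp, frequencies = c(freqs),
                 by_population = by_pop, support = support,
                 low_support = support < 2, k = k, linkage = "complete"),
            class = "haplogroup_partition")
}

#' @export
print.haplogroup_partition <- function(x, ...) {
  cat(sprintf("Haplogroup partition (k = %d, complete linkage)%s\n", x$k,
              if (x$low_support) "  [low support]" else ""))
  print(round(x$frequencies, 3))
  invisible(x)
}

#' Diagnostic SNPs between two haplogroups
#'
#' A site is *diagnostic* when one allele is carried by every haplotype of
#' group A and the other by every haplotype of group B; sites where at most
#' `f` haplotypes cross over are reported separately as *nearly diagnostic*.
#'
#' @param x alignment or 0/1 matrix used for the partition.
#' @param partition a [partition_haplogroups()] result with two groups.
#' @param f mismatch tolerance for nearly diagnostic sites (default 1).
#' @return list with integer vectors `diagnostic` and `nearly_diagnostic`
#'   (column indices, or locus positions when an alignment is given).
#' @export
diagnostic_snps <- function(x, partition, f = 1) {
  pos <- NULL
  if (inherits(x, "hap_aln")) {
    pos <- x$positions
    m <- as_binary_matrix(x)
    rownames(m) <- rownames(x$alleles)
  } else m <- as.matrix(x)
  if (length(unique(partition$group)) != 2L) stop("two groups required")
  ga <- partition$group[rownames(m)] == "A"
  if (is.null(rownames(m))) ga <- partition$group == "A"
  diag_idx <- integer(0); near_idx <- integer(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    ok <- !is.na(col)
    # mismatches under the best allele->group orientation
    mis1 <- sum(col[ok & ga] != 0L) + sum(col[ok & !ga] != 1L)
    mis2 <- sum(col[ok & ga] != 1L) + sum(col[ok & !ga] != 0L)
    mis <- min(mis1, mis2)
    if (mis == 0L) diag_idx <- c(diag_idx, j)
    else if (mis <= f) near_idx <- c(near_idx, j)
  }
  if (!is.null(pos)) {
    diag_idx <- pos[diag_idx]; near_idx <- pos[near_idx]
  }
  list(diagnostic = diag_idx, nearly_diagnostic = near_idx)
}

#' Per-population haplogroup frequencies
#'
#' @param partition a [partition_haplogroups()] result.
#' @param popmap optional data.frame (`sample`, `population`) or named
#'   vector; defaults to the populations stored in the partition.
#' @return list with `pooled` (named numeric) and `by_population` (matrix;
#'   populations without haplotypes are reported as `NA`, not 0/0).
#' @export
haplogroup_frequencies <- function(partition, popmap = NULL) {
  pooled <- partition$frequencies
  by_pop <- partition$by_population
  if (!is.null(popmap)) {
    pops <- if (is.data.frame(popmap))
      stats::setNames(as.character(popmap$population), popmap$sample)
    else popmap
    samp <- sub("\\.[12]$", "", names(partition$group))
    pl <- pops[samp]
    all_pops <- sort(unique(as.character(pops)))
    tab <- table(factor(partition$group), factor(pl, levels = all_pops))
    by_pop <- prop.table(tab, margin = 2)   # empty populations give NaN
    by_pop[, colSums(tab) == 0] <- NA
  }
  list(pooled = pooled, by_population = by_pop)
}

#' Rho-statistic TMRCA with outgroup calibration
#'
#' The rho statistic is the mean mutational distance from the sampled
#' haplotypes to the root, here fixed at the outgroup-inferred ancestral
#' allele at every polarized site (a deterministic substitute for a network
#' root). Its standard deviation uses the branch decomposition
#' `sigma^2 = sum_s c_s^2 / n^2`, where `c_s` is the derived-allele count at
#' site `s` (each segregating site is one mutation on a branch with `c_s`
#' sampled descendants). The per-year locus mutation rate is calibrated from
#' the fixed differences accumulated over the two lineages separating the
#' ingroup from the outgroup: `mu = FD / (2 * divergence_time_years)`; the
#' age is `rho / mu`.
#'
#' @param x 0/1 matrix of derived-allele indicators at polarized sites (0 =
#'   ancestral), or a polarized [variant_table()] from which per-site derived
#'   counts are taken.
#' @param calibration list with `divergence_time_years` (default 6e6) and
#'   `FD` (> 0).
#' @param n number of chromosomes (required for a variant-table input).
#' @return object of class `tmrca_estimate` with `rho`, `sigma`,
#'   `mu_locus_per_year`, `age_years`, `sigma_years`, `calibration`.
#' @export
rho_tmrca <- function(x, calibration, n = NULL) {
  if (is.null(calibration$divergence_time_years))
    calibration$divergence_time_years <- 6e6
  fd <- calibration$FD
  if (is.null(fd) || fd <= 0) stop("cannot calibrate: FD must be positive")
  if (inherits(x, "variant_table")) {
    pol <- !is.na(x$anc)
    if (!any(pol)) stop("ancestral state known for no site")
    counts <- x$d_total[pol]
    if (is.null(n)) n <- max(x$m_total)
  } else {
    m <- as.matrix(x)
    n <- nrow(m)
    counts <- colSums(m, na.rm = TRUE)
  }
  rho <- sum(counts) / n
  sigma <- sqrt(sum(counts^2)) / n
  mu <- fd / (2 * calibration$divergence_time_years)
  structure(list(rho = rho, sigma = sigma, mu_locus_per_year = mu,
                 age_years = rho / mu, sigma_years = sigma / mu,
                 calibration = calibration, n = n),
            class = "tmrca_estimate")
}

#' @export
print.tmrca_estimate <- function(x, ...) {
  cat(sprintf("rho = %.3f (sd %.3f); mu = %.3g /locus/year\n",
              x$rho, x$sigma, x$mu_locus_per_year))
  cat(sprintf("TMRCA = %.3g years (sd %.3g)\n", x$age_years, x$sigma_years))
  invisible(x)
}
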
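#' Subset an alignment to one population
#'
#' @param aln a [haplotype_alignment()].
#' @param population population label.
#' @return a [haplotype_alignment()] with only that population's haplotypes.
#' @export
subset_alignment <- function(aln, population) {
  keep <- aln$populations == population
  if (!any(keep)) stop("population '", population, "' absent from alignment")
  haplotype_alignment(aln$alleles[keep, , drop = FALSE], aln$positions,
                      aln$populations[keep], region = aln$region,
                      amplicons = aln$amplicons, locus_length = aln$locus_length)
}

#' Balancing-selection scan of a candidate locus against controls
#'
#' Runs the full per-population pipeline: variant tabulation, outgroup
#' polarization, hypergeometric projection of folded site frequencies,
#' Tajima's D, the MWUhigh rank test against the pooled control-region
#' frequencies, and the HKA polymorphism/divergence test on the coding
#' region — with significance assessed against coalescent simulations under
#' the demographic null, conditioned on the observed number of informative
#' sites. Produces a per-population results table mirroring the classic
#' neutrality-test summary (S, TajD, p(TajD), p(MWU), p(HKA)).
#'
#' @param test a [haplotype_alignment()] for the candidate locus.
#' @param outgroup aligned outgroup sequence for the test locus.
#' @param controls list of control fixtures, each a list with elements
#'   `aln` and `outgroup` (e.g. from [gen_control_panel()]).
#' @param model demographic null, default [ooa_model()].
#' @param deme_of named map population -> deme of the model.
#' @param n_project projection sample size in chromosomes (default 15).
#' @param n_sims coalescent replicates per null distribution (default
#'   10,000, the conventional choice; reduce for quick runs).
#' @param seed integer seed for all simulation randomness.
#' @param alpha significance level used only for the printed summary.
#' @param bonferroni apply a Bonferroni correction across populations in
#'   the printed significance flags (reported unadjusted by default).
#' @param hka_region region class used for the HKA counts (default
#'   `"coding"`).
#' @param test_divergence,control_divergence optional lists with `S` and
#'   `FD` overriding the divergence counting — required when the
#'   alignments carry variant columns only (fixed differences are then not
#'   derivable from the matrix).
#' @return data.frame of class `scan_result` with one row per population
#'   and columns `population`, `n`, `S`, `TajD`, `p_TajD`, `U_MWU`,
#'   `p_MWU`, `X2_HKA`, `p_HKA`, `p_HKA_analytic`; the run manifest
#'   (seed, model, sizes, package version) is in `attr(, "manifest")`.
#' @export
run_scan <- function(test, outgroup, controls, model = ooa_model(),
                     deme_of = c(Yoruba = "AF", Luhya = "AF",
                                 Palestinian = "EU", Gujarati = "EU",
                                 Han = "AS", Toscani = "EU"),
                     n_project = 15, n_sims = 10000, seed = 1,
                     alpha = 0.05, bonferroni = FALSE, hka_region = "coding",
                     test_divergence = NULL, control_divergence = NULL) {
  set.seed(seed)
  vt <- polarize_sites(variant_table(test), outgroup)
  pops <- sort(unique(test$populations))
  # per-population projection target never exceeds the sampled chromosomes
  n_pop <- vapply(pops, function(p) sum(test$populations == p), integer(1))
  n_proj <- stats::setNames(pmin(n_project, n_pop), pops)

  # pooled control folded frequencies per population, and pooled S/FD
  control_freqs <- stats::setNames(vector("list", length(pops)), pops)
  ctrl_S <- 0L; ctrl_FD <- 0L
  for (ctl in controls) {
    cvt <- polarize_sites(variant_table(ctl$aln), ctl$outgroup)
    if (is.null(control_divergence)) {
      div <- count_segregating_and_fixed(ctl$aln, ctl$outgroup, region = "all")
      ctrl_S <- ctrl_S + div$S; ctrl_FD <- ctrl_FD + div$FD
    }
    for (p in pops) {
      seg <- segregating_in(cvt, p)
      if (!any(seg)) next
      sp <- project_spectrum(cvt[seg, , drop = FALSE], n_proj[p], p)
      control_freqs[[p]] <- c(control_freqs[[p]], sp$site_freqs)
    }
  }
  if (!is.null(control_divergence)) {
    ctrl_S <- control_divergence$S
    ctrl_FD <- control_divergence$FD
  }

  rows <- list()
  for (p in pops) {
    sub <- subset_alignment(test, p)
    n_p <- nrow(sub$alleles)
    th <- theta_estimates(sub)
    S_p <- th$S
    tajd <- if (S_p > 0) tajimas_d(S_p, th$theta_pi, n_p) else NA_real_

    seg <- segregating_in(vt, p)
    sp <- project_spectrum(vt[seg, , drop = FALSE], n_proj[p], p)
    mwu <- mwu_high(sp$site_freqs, control_freqs[[p]])

    div <- if (is.null(test_divergence))
      count_segregating_and_fixed(sub, outgroup, region = hka_region)
    else test_divergence
    hka <- tryCatch(
      hka_test(list(S = div$S, FD = div$FD, n = n_p),
               list(S = ctrl_S, FD = ctrl_FD, n = n_p)),
      error = function(e) NULL)

    # null distributions conditioned on the observed informative sites
    deme <- deme_of[p]
    nvec <- stats::setNames(rep(0L, length(model$labels)), model$labels)
    nvec[deme] <- n_p
    cfg <- sim_config(n = nvec, L = test$locus_length,
                      S_condition = S_p, n_reps = n_sims)
    tajd_draws <- null_distribution(list(TajD = sim_tajimas_d), cfg, model,
                                    n_reps = n_sims)
    p_tajd <- if (!is.na(tajd)) empirical_p(tajd, tajd_draws[, 1], "upper")
              else NA_real_
    p_hka <- if (!is.null(hka))
      hka_sim_p(hka, n_sims, n_test = n_p, n_ctrl = n_p) else NA_real_

    rows[[p]] <- data.frame(
      population = p, n = n_p, S = S_p, TajD = tajd, p_TajD = p_tajd,
      U_MWU = mwu$U, p_MWU = mwu$p,
      X2_HKA = if (is.null(hka)) NA_real_ else hka$X2,
      p_HKA = p_hka,
      p_HKA_analytic = if (is.null(hka)) NA_real_ else hka$p_analytic)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "manifest") <- list(
    seed = seed, n_sims = n_sims, n_project = n_project,
    n_controls = length(controls), control_S = ctrl_S, control_FD = ctrl_FD,
    model_labels = model$labels, alpha = alpha, bonferroni = bonferroni,
    package_version = as.character(utils::packageVersion("balsel")))
  class(res) <- c("scan_result", class(res))
  res
}

segregating_in <- function(vt, population) {
  m <- vt[[paste0("m_", population)]]
  mn <- vt[[paste0("minor_", population)]]
  !is.na(m) & mn > 0 & mn < m
}

# parametric coalescent bootstrap of the HKA statistic under the fitted
# neutral parameters: S* from fixed-theta mutation placement on a simulated
# genealogy, FD* Poisson with an exponential ancestral-coalescence component
hka_sim_p <- function(hka, n_sims, n_test, n_ctrl) {
  u <- hka$T_hat + 1
  draws <- numeric(n_sims)
  cfg_t <- sim_config(n = n_test, L = 1000, rho_per_bp = 0, theta = hka$theta[1])
  cfg_c <- sim_config(n = n_ctrl, L = 1000, rho_per_bp = 0, theta = hka$theta[2])
  m1 <- constant_model()
  for (r in seq_len(n_sims)) {
    g1 <- simulate_genealogy(cfg_t, m1)
    g2 <- simulate_genealogy(cfg_c, m1)
    S1 <- stats::rpois(1, hka$theta[1] / 2 * g1$total_length)
    S2 <- stats::rpois(1, hka$theta[2] / 2 * g2$total_length)
    D1 <- stats::rpois(1, hka$theta[1] * (u - 1 + stats::rexp(1)))
    D2 <- stats::rpois(1, hka$theta[2] * (u - 1 + stats::rexp(1)))
    draws[r] <- tryCatch(
      hka_test(list(S = S1, FD = D1, n = n_test),
               list(S = S2, FD = D2, n = n_ctrl))$X2,
      error = function(e) NA_real_)
  }
  empirical_p(hka$X2, draws, "upper")
}

#' @export
print.scan_result <- function(x, ...) {
  man <- attr(x, "manifest")
  cat(sprintf("Balancing-selection scan (%d control regions, %d simulations, seed %d)\n",
              man$n_controls, man$n_sims, man$seed))
  df <- as.data.frame(x)
  df$TajD <- round(df$TajD, 2)
  for (cn in grep("^p_", names(df), value = TRUE)) df[[cn]] <- signif(df[[cn]], 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export a scan result as TSV and a JSON manifest
#'
#' @param res a `scan_result`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_scan_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(res), file.path(dir, "scan_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(attr(res, "manifest"), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
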
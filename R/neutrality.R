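#' Watterson and pairwise estimates of the scaled mutation rate
#'
#' `theta_w = S / a1(n)` with `a1 = sum(1/i, i = 1..n-1)`; `theta_pi` is the
#' mean number of pairwise differences over all haplotype pairs, computed
#' with pairwise handling of missing data when an alignment or 0/1 matrix is
#' supplied.
#'
#' @param x a [haplotype_alignment()], a 0/1 haplotype matrix (`NA` =
#'   missing), or `NULL` if `S`, `n` and `theta_pi` are given directly.
#' @param S,n,theta_pi used when `x` is `NULL`.
#' @return list of class `theta_estimates` with `theta_w`, `theta_pi`, `S`, `n`.
#' @export
theta_estimates <- function(x = NULL, S = NULL, n = NULL, theta_pi = NULL) {
  if (!is.null(x)) {
    m <- as_binary_matrix(x)
    n <- nrow(m)
    seg <- apply(m, 2, function(col) {
      v <- col[!is.na(col)]; length(unique(v)) >= 2L
    })
    S <- sum(seg)
    theta_pi <- mean_pairwise_diff(m)
  }
  if (n < 2L) stop("need at least 2 haplotypes")
  a1 <- sum(1 / seq_len(n - 1L))
  structure(list(theta_w = S / a1, theta_pi = theta_pi, S = S, n = n),
            class = "theta_estimates")
}

as_binary_matrix <- function(x) {
  if (inherits(x, "hap_aln")) {
    m <- matrix(NA_integer_, nrow(x$alleles), ncol(x$alleles))
    for (j in seq_len(ncol(m))) {
      col <- x$alleles[, j]
      called <- !(col %in% MISSING_CODES)
      tab <- sort(table(col[called]), decreasing = TRUE)
      m[called, j] <- as.integer(col[called] != names(tab)[1])
    }
    m
  } else {
    x <- as.matrix(x)
    storage.mode(x) <- "integer"
    x
  }
}

mean_pairwise_diff <- function(m) {
  n <- nrow(m)
  if (!anyNA(m)) {
    # complete data: per-site allele counts give the pairwise sum directly
    d <- colSums(m)
    return(sum(2 * d * (n - d)) / (n * (n - 1)))
  }
  tot <- 0; npairs <- 0L
  for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
    ok <- !is.na(m[i, ]) & !is.na(m[k, ])
    tot <- tot + sum(m[i, ok] != m[k, ok])
    npairs <- npairs + 1L
  }
  tot / npairs
}

#' Tajima's D
#'
#' Normalized difference between the pairwise and Watterson estimators of the
#' scaled mutation rate, using the 1989 variance constants computed from the
#' sample size. Significantly positive values indicate genealogies with long
#' internal branches (an excess of intermediate-frequency variants), the
#' signature of long-term balancing selection.
#'
#' @param S number of segregating sites (> 0).
#' @param theta_pi mean pairwise differences.
#' @param n number of chromosomes.
#' @return the D statistic (scalar). `S = 0` is an error; report a null
#'   result upstream instead.
#' @export
tajimas_d <- function(S, theta_pi, n) {
  if (S <= 0) stop("Tajima's D undefined for S = 0")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (theta_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' One-sided Mann-Whitney test for an intermediate-frequency excess (MWUhigh)
#'
#' Compares the per-site folded allele frequencies of a test region with
#' those of neutral control regions, asking whether the test distribution is
#' shifted towards *higher* folded frequencies. Ties receive midranks. For
#' combined sample sizes up to `exact_max` the p-value is computed by exact
#' enumeration of all assignments of the pooled values; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param test_freqs per-site folded frequencies (or expected folded minor
#'   counts) of the test region; non-empty.
#' @param control_freqs pooled per-site folded frequencies of the control
#'   regions; non-empty.
#' @param exact_max largest combined size for the exact-enumeration path.
#' @return list of class `mwu_result` with `U`, `p` (one-sided, upper),
#'   `method` (`"exact"` or `"normal"`), `n_test`, `n_control`.
#' @export
mwu_high <- function(test_freqs, control_freqs, exact_max = 12L) {
  n1 <- length(test_freqs); n2 <- length(control_freqs)
  if (n1 == 0L || n2 == 0L) stop("empty frequency list")
  pooled <- c(test_freqs, control_freqs)
  r <- rank(pooled)                       # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  if (N <= exact_max) {
    combs <- utils::combn(N, n1)
    Us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(Us >= U - 1e-9)
    method <- "exact"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    mu <- n1 * n2 / 2
    z <- (U - mu - 0.5) / sqrt(sigma2)    # continuity-corrected
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  structure(list(U = U, p = p, method = method, n_test = n1, n_control = n2),
            class = "mwu_result")
}

#' Two-locus HKA polymorphism/divergence test
#'
#' Classic goodness-of-fit comparison of within-species polymorphism (`S`)
#' and divergence to an outgroup (`FD`) between a test locus and a pooled
#' neutral control locus. Per-locus mutation parameters and a shared
#' divergence time are fitted by the method of moments; the statistic is
#'
#' `X^2 = sum over loci of (S - E[S])^2/Var(S) + (FD - E[FD])^2/Var(FD)`
#'
#' with `E[S] = theta a1(n)`, `Var(S) = theta a1 + theta^2 a2`,
#' `E[FD] = theta (T + 1)`, `Var(FD) = theta (T + 1) + theta^2` (time in
#' units of 2N generations; the `+1` absorbs coalescence in the common
#' ancestor). An excess of polymorphism relative to divergence at the test
#' locus inflates `X^2`. The analytic reference distribution is chi-squared
#' with 1 degree of freedom; a simulation-based p-value from
#' [null_distribution()]/[empirical_p()] is preferred.
#'
#' @param test list or `divergence_summary` with `S`, `FD`, and `n`.
#' @param control same for the pooled control regions.
#' @return list of class `hka_result` with `X2`, `p_analytic`, fitted
#'   `theta` (length 2), `T_hat`, and per-locus expected values.
#' @export
hka_test <- function(test, control) {
  S <- c(test$S, control$S); D <- c(test$FD, control$FD)
  n <- c(test$n, control$n)
  if (any(S + D <= 0)) stop("each locus needs S + FD > 0")
  if (sum(S) == 0 || sum(D) == 0) stop("degenerate totals: all-zero S or FD")
  a1 <- vapply(n, function(k) sum(1 / seq_len(k - 1L)), numeric(1))
  a2 <- vapply(n, function(k) sum(1 / seq_len(k - 1L)^2), numeric(1))
  # Solve sum_i theta_i(u) a1_i = S_total for u = T + 1,
  # where theta_i(u) = (S_i + D_i) / (a1_i + u).
  gap <- function(u) sum((S + D) / (a1 + u) * a1) - sum(S)
  # gap is decreasing in u; bracket then root-find
  lo <- 1e-9; hi <- 10
  while (gap(hi) > 0 && hi < 1e9) hi <- hi * 10
  u <- if (gap(lo) < 0) lo else stats::uniroot(gap, c(lo, hi), tol = 1e-12)$root
  theta <- (S + D) / (a1 + u)
  ES <- theta * a1
  ED <- theta * u
  VS <- theta * a1 + theta^2 * a2
  VD <- theta * u + theta^2
  X2 <- sum((S - ES)^2 / VS + (D - ED)^2 / VD)
  structure(list(X2 = X2, p_analytic = stats::pchisq(X2, df = 1, lower.tail = FALSE),
                 theta = theta, T_hat = u - 1, E_S = ES, E_FD = ED),
            class = "hka_result")
}

#' Empirical p-value from simulated null draws
#'
#' Uses the add-one estimator `p = (1 + #extreme) / (1 + N)` so that a p-value
#' of exactly zero is never reported (a paper-style print of "0" corresponds
#' to `p < 1/N`).
#'
#' @param observed observed statistic value.
#' @param null_draws numeric vector of simulated null statistics.
#' @param tail `"upper"`, `"lower"`, or `"two"` (twice the smaller tail,
#'   capped at 1).
#' @return p-value in (0, 1].
#' @export
empirical_p <- function(observed, null_draws, tail = c("upper", "lower", "two")) {
  tail <- match.arg(tail)
  null_draws <- null_draws[!is.na(null_draws)]
  if (!length(null_draws)) stop("empty null draws")
  N <- length(null_draws)
  up <- (1 + sum(null_draws >= observed)) / (1 + N)
  lo <- (1 + sum(null_draws <= observed)) / (1 + N)
  switch(tail, upper = up, lower = lo, two = min(1, 2 * min(up, lo)))
}

#' Bundle a statistic with its simulation-based significance
#'
#' @param statistic name (`"TajD"`, `"MWUhigh"`, `"HKA"`, ...).
#' @param value observed value.
#' @param null_draws simulated null draws (optional).
#' @param tail passed to [empirical_p()].
#' @param p_analytic optional analytic p-value (secondary diagnostic).
#' @param population,region,inputs provenance fields.
#' @return list of class `neutrality_result`.
#' @export
neutrality_result <- function(statistic, value, null_draws = NULL,
                              tail = "upper", p_analytic = NA_real_,
                              population = NA_character_,
                              region = NA_character_, inputs = list()) {
  p_sim <- if (!is.null(null_draws)) empirical_p(value, null_draws, tail)
           else NA_real_
  structure(list(statistic = statistic, value = value, p_sim = p_sim,
                 p_analytic = p_analytic,
                 n_sims = if (is.null(null_draws)) 0L else length(null_draws),
                 population = population, region = region, inputs = inputs),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf("%s = %.4g", x$statistic, x$value))
  if (!is.na(x$p_sim))
    cat(sprintf(", p_sim = %s (%d simulations)",
                format_p(x$p_sim, x$n_sims), x$n_sims))
  if (!is.na(x$p_analytic)) cat(sprintf(", p_analytic = %.4g", x$p_analytic))
  cat("\n")
  invisible(x)
}

format_p <- function(p, n_sims) {
  if (n_sims > 0 && p <= 1 / n_sims) sprintf("< %.2g", 1 / n_sims)
  else sprintf("%.4g", p)
}
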
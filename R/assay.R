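#' Fit an allele-discrimination standard curve
#'
#' Standards are serial mixes of two homozygous genomic DNAs with known
#' allele-B fraction. The model is standard allelic-discrimination
#' practice: `log2(B:A ratio)` is linear in `delta Ct = Ct_A - Ct_B`.
#' The fit is refused when R-squared falls below `min_r2`.
#'
#' @param standards data.frame of standard wells with columns `fraction`
#'   (allele-B template fraction in (0, 1)), `ct_a`, `ct_b`. Replicate
#'   wells are used individually.
#' @param min_r2 minimum acceptable R-squared (default 0.9).
#' @return object of class `ase_curve` with `slope`, `intercept`, `r2`,
#'   `n_points`.
#' @export
fit_standard_curve <- function(standards, min_r2 = 0.9) {
  fr <- standards$fraction
  if (length(unique(fr)) < 3L)
    stop("need standards at >= 3 distinct mix fractions")
  if (any(fr <= 0 | fr >= 1)) stop("mix fractions must be in (0, 1)")
  y <- log2(fr / (1 - fr))
  x <- standards$ct_a - standards$ct_b
  fit <- stats::lm(y ~ x)
  # a noiseless synthetic plate fits exactly; the perfect-fit warning from
  # summary.lm is expected there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (r2 < min_r2)
    stop(sprintf("standard curve rejected: R^2 = %.3f < %.2f", r2, min_r2))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, n_points = length(x)),
            class = "ase_curve")
}

#' Allelic expression ratio of a sample
#'
#' Maps each replicate's `delta Ct` through the standard curve:
#' `ratio = 2^(slope * dCt + intercept)` (B:A). Missing replicates are
#' dropped with a flag.
#'
#' @param sample data.frame of replicate wells with `ct_a`, `ct_b`
#'   (possibly containing `NA`).
#' @param curve a fitted [fit_standard_curve()].
#' @return list with `ratio` (mean over replicates), `sem`, `ratios`
#'   (per replicate), `n_replicates`, `incomplete` flag.
#' @export
allelic_ratio <- function(sample, curve) {
  dct <- sample$ct_a - sample$ct_b
  ok <- !is.na(dct)
  if (!any(ok)) stop("no complete replicate")
  r <- 2^(curve$slope * dct[ok] + curve$intercept)
  list(ratio = mean(r),
       sem = if (sum(ok) > 1) stats::sd(r) / sqrt(sum(ok)) else NA_real_,
       ratios = r, n_replicates = sum(ok), incomplete = any(!ok))
}

#' Contrast allelic ratios with and without NMD inhibition
#'
#' For a heterozygous cell line, decay of the B-haplotype mRNA shows as a
#' B:A ratio below 1 in untreated cells that is restored towards 1 when
#' NMD is blocked. The call is `"NMD-consistent"` when the untreated ratio
#' is significantly below 1 (one-sample t against 1 on the replicate
#' ratios) and the blocked ratio is not; `"no NMD signal"` otherwise.
#'
#' @param untreated,blocked [allelic_ratio()] results for the paired
#'   conditions of one cell line.
#' @param alpha significance level for the one-sample tests.
#' @return list with the two ratios, their confidence intervals, `p_untreated`,
#'   `p_blocked`, and `call`.
#' @export
nmd_effect <- function(untreated, blocked, alpha = 0.05) {
  if (is.null(untreated) || is.null(blocked))
    stop("both treatment arms are required (paired design)")
  tt <- function(x) {
    if (length(x$ratios) < 2) return(list(p = NA_real_, ci = c(NA, NA)))
    t <- stats::t.test(log2(x$ratios), mu = 0)
    list(p = t$p.value, ci = 2^t$conf.int)
  }
  tu <- tt(untreated); tb <- tt(blocked)
  reduced <- !is.na(tu$p) && tu$p < alpha && untreated$ratio < 1
  restored <- is.na(tb$p) || tb$p >= alpha || abs(log2(blocked$ratio)) < 0.25
  call <- if (reduced && restored) "NMD-consistent" else "no NMD signal"
  list(ratio_untreated = untreated$ratio, ci_untreated = tu$ci,
       p_untreated = tu$p,
       ratio_blocked = blocked$ratio, ci_blocked = tb$ci, p_blocked = tb$p,
       call = call)
}

#' Interquartile-range outlier filter within groups
#'
#' Within each group, values outside `[Q1 - k IQR, Q3 + k IQR]` are
#' removed; quartiles use linear interpolation (`stats::quantile` type 7),
#' which matters for which points are fenced. Groups smaller than
#' `min_group` pass through untouched and are flagged. The filter is
#' idempotent on its own output only when re-derived fences retain all
#' remaining points; the returned mask refers to the input vector.
#'
#' @param values numeric vector.
#' @param groups grouping factor (e.g. experiment x genotype), recycled.
#' @param k fence multiplier (default 1.5).
#' @param min_group smallest group size with defined quartiles (default 4).
#' @return logical mask of retained values, with attribute `small_groups`
#'   listing pass-through groups.
#' @export
iqr_filter <- function(values, groups = rep(1, length(values)), k = 1.5,
                       min_group = 4) {
  groups <- rep_len(as.character(groups), length(values))
  keep <- rep(TRUE, length(values))
  small <- character(0)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    v <- values[idx]
    if (length(v) < min_group) { small <- c(small, g); next }
    q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, type = 7)
    iqr <- q[2] - q[1]
    keep[idx] <- v >= q[1] - k * iqr & v <= q[2] + k * iqr
  }
  attr(keep, "small_groups") <- small
  keep
}

#' Genotype-effect inference on standardized MFI data
#'
#' Reproduces the analysis design for surface-marker flow cytometry:
#' per-experiment Welch t-tests comparing the two homozygote genotypes, and
#' a two-factor additive ANOVA (experiment entered first, then genotype, no
#' interaction) on the pooled homozygote data, so the genotype F-test is
#' adjusted for differences among experiments. Boxplot-ready summaries
#' (quartiles, mean, outliers beyond the 1.5 IQR fences) are returned per
#' experiment x genotype cell.
#'
#' @param records data.frame with columns `sample`, `genotype`
#'   (`"AA"`/`"AB"`/`"BB"`), `experiment`, `hla_mfi`, `cd19_mfi`.
#' @param measure `"standardized"` (HLA/CD19, default), `"HLA"`, or
#'   `"CD19"`.
#' @param genotypes the two genotypes contrasted (default AA vs BB).
#' @return list with `anova` (data.frame: factor, df, F, p), `t_tests`
#'   (per experiment: estimate difference, p), `boxstats`, `measure`.
#' @export
mfi_inference <- function(records, measure = c("standardized", "HLA", "CD19"),
                          genotypes = c("AA", "BB")) {
  measure <- match.arg(measure)
  y <- switch(measure,
              standardized = records$hla_mfi / records$cd19_mfi,
              HLA = records$hla_mfi,
              CD19 = records$cd19_mfi)
  dat <- data.frame(y = y, genotype = records$genotype,
                    experiment = factor(records$experiment))
  dat <- dat[dat$genotype %in% genotypes, ]
  dat$genotype <- factor(dat$genotype, levels = genotypes)
  tab <- table(dat$experiment, dat$genotype)
  if (any(tab == 0))
    stop("each experiment must contain both genotypes: ",
         paste(rownames(tab)[rowSums(tab == 0) > 0], collapse = ", "))
  fit <- stats::aov(y ~ experiment + genotype, data = dat)
  an <- summary(fit)[[1]]
  anova_df <- data.frame(factor = trimws(rownames(an)),
                         df = an[, "Df"], F = an[, "F value"],
                         p = an[, "Pr(>F)"])
  tts <- lapply(levels(dat$experiment), function(e) {
    sub <- dat[dat$experiment == e, ]
    t <- stats::t.test(y ~ genotype, data = sub)   # Welch
    data.frame(experiment = e,
               mean_1 = t$estimate[1], mean_2 = t$estimate[2],
               p = t$p.value, row.names = NULL)
  })
  box <- by(dat$y, list(dat$experiment, dat$genotype), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
    fence <- c(q[1] - 1.5 * (q[3] - q[1]), q[3] + 1.5 * (q[3] - q[1]))
    list(q1 = q[[1]], median = q[[2]], q3 = q[[3]], mean = mean(v),
         outliers = v[v < fence[1] | v > fence[2]])
  })
  list(anova = anova_df, t_tests = do.call(rbind, tts), boxstats = box,
       measure = measure)
}

#' Hardy-Weinberg genotype proportions
#'
#' @param p frequency of the first allele.
#' @return named vector `c(AA = p^2, AB = 2 p (1-p), BB = (1-p)^2)`.
#' @export
hwe_genotype_freqs <- function(p) {
  stopifnot(p >= 0, p <= 1)
  c(AA = p^2, AB = 2 * p * (1 - p), BB = (1 - p)^2)
}
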
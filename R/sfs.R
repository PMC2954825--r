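#' Hypergeometric projection weights for one site
#'
#' Downsamples a site with `d` derived copies among `m` called chromosomes to
#' a target sample size `n` without replacement. The weight on derived count
#' `j` in the projected sample is the hypergeometric probability
#' `C(d, j) C(m - d, n - j) / C(m, n)`.
#'
#' @param d derived (or minor) allele count at the site, `0 <= d <= m`.
#' @param m called chromosomes at the site.
#' @param n projection target, `n <= m`.
#' @return numeric vector of length `n + 1` over `j = 0..n`, summing to 1.
#' @export
projection_weights <- function(d, m, n) {
  if (n > m) stop("projection target n exceeds called chromosomes m")
  if (d < 0 || d > m) stop("require 0 <= d <= m")
  j <- 0:n
  w <- exp(lchoose(d, j) + lchoose(m - d, n - j) - lchoose(m, n))
  w[j > d | (n - j) > (m - d)] <- 0
  w / sum(w)
}

#' Project a variant table onto a site-frequency spectrum
#'
#' Builds the expected unfolded and folded site-frequency spectra at a common
#' sample size `n` by hypergeometric projection of every usable site
#' (expectation over the projection distribution, not a sampled outcome).
#' Polarized sites contribute to the unfolded spectrum over derived counts
#' `1..n-1`; the probability mass projected to `j = 0` or `j = n`
#' (monomorphic after projection) is accumulated in `discarded_mass`.
#' Unpolarized sites are excluded from the unfolded spectrum but still
#' contribute to the folded spectrum through their minor-allele counts.
#'
#' @param variants a [variant_table()] (polarized or not).
#' @param n projection target sample size (chromosomes). Sites with fewer
#'   than `n` called chromosomes are dropped and counted in `dropped_sites`.
#' @param population population label, or `"total"` for the pooled sample.
#' @return object of class `sfs_spectrum`: list with `n`, `unfolded`
#'   (length `n - 1`, derived counts `1..n-1`), `folded` (length
#'   `floor(n/2)`), `site_freqs` (per-site expected folded minor count, for
#'   rank tests), `discarded_mass`, `dropped_sites`, `n_sites`.
#' @export
project_spectrum <- function(variants, n, population = "total") {
  pops <- attr(variants, "populations")
  if (!(population %in% c(pops, "total")))
    stop("population '", population, "' absent from variant table")
  mcol <- paste0("m_", population)
  dcol <- paste0("d_", population)
  mincol <- paste0("minor_", population)
  unfolded <- numeric(max(n - 1L, 0L))
  folded <- numeric(floor(n / 2))
  discarded <- 0
  site_freqs <- numeric(0)
  dropped <- 0L
  js <- 0:n
  fold_of <- pmin(js, n - js)        # folded class of projected count j
  for (i in seq_len(nrow(variants))) {
    m <- variants[[mcol]][i]
    if (is.na(m) || m < n || m == 0L) { dropped <- dropped + 1L; next }
    polarized <- !is.na(variants$anc[i])
    if (polarized) {
      w <- projection_weights(variants[[dcol]][i], m, n)
      unfolded <- unfolded + w[2:n]
      discarded <- discarded + w[1] + w[n + 1L]
    } else {
      w <- projection_weights(variants[[mincol]][i], m, n)
    }
    # expected folded minor count for this site (rank-test statistic)
    fexp <- sum(w * fold_of)
    site_freqs <- c(site_freqs, fexp)
    wf <- numeric(floor(n / 2))
    for (j in js[w > 0]) if (fold_of[j + 1L] >= 1L)
      wf[fold_of[j + 1L]] <- wf[fold_of[j + 1L]] + w[j + 1L]
    folded <- folded + wf
    if (!polarized) discarded <- discarded + w[1] + w[n + 1L]
  }
  structure(list(n = as.integer(n), unfolded = unfolded, folded = folded,
                 site_freqs = site_freqs, discarded_mass = discarded,
                 dropped_sites = dropped,
                 n_sites = nrow(variants) - dropped,
                 population = population),
            class = "sfs_spectrum")
}

#' Fold an unfolded spectrum
#'
#' `folded[k] = unfolded[k] + unfolded[n - k]` for `k < n/2`, and
#' `folded[n/2] = unfolded[n/2]` when `n` is even (midpoint not doubled).
#'
#' @param spectrum an `sfs_spectrum` or a numeric unfolded vector over
#'   derived counts `1..n-1`.
#' @param n sample size (required when a bare vector is given).
#' @return numeric folded vector over minor counts `1..floor(n/2)`.
#' @export
fold_spectrum <- function(spectrum, n = NULL) {
  if (inherits(spectrum, "sfs_spectrum")) {
    u <- spectrum$unfolded; n <- spectrum$n
  } else {
    u <- spectrum
    if (is.null(n)) n <- length(u) + 1L
  }
  half <- floor(n / 2)
  f <- numeric(half)
  for (k in seq_len(half)) {
    f[k] <- u[k] + if (n - k != k) u[n - k] else 0
  }
  f
}

#' @export
print.sfs_spectrum <- function(x, ...) {
  cat(sprintf("Projected SFS (n = %d, %s): %d sites (%d dropped), discarded mass %.3f\n",
              x$n, x$population, x$n_sites, x$dropped_sites, x$discarded_mass))
  cat("folded:", paste(sprintf("%.2f", x$folded), collapse = " "), "\n")
  invisible(x)
}

#' Export a spectrum as a long-format table
#'
#' @param spectrum an `sfs_spectrum`.
#' @param path optional TSV path; when given the table is written there.
#' @return data.frame with columns `kind` (unfolded/folded), `j`, `count`.
#' @export
spectrum_table <- function(spectrum, path = NULL) {
  df <- rbind(
    data.frame(kind = "unfolded", j = seq_along(spectrum$unfolded),
               count = spectrum$unfolded),
    data.frame(kind = "folded", j = seq_along(spectrum$folded),
               count = spectrum$folded))
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
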
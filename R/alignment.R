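#' Phased haplotype alignment
#'
#' Container for a rectangular matrix of phased haplotypes over a locus.
#' Rows are haplotypes (two per diploid sample, ids `"SAMPLE.1"`/`"SAMPLE.2"`),
#' columns are aligned locus positions (1-based, strictly increasing). Each
#' haplotype carries a population label; positions carry a region class
#' (`"coding"`/`"noncoding"`); optional amplicon spans support edge filtering.
#'
#' @param alleles character matrix of nucleotide codes (`A`,`C`,`G`,`T`; `N` or
#'   `-` for missing), rows named by haplotype id.
#' @param positions integer vector of 1-based locus coordinates, one per
#'   column, strictly increasing.
#' @param populations named character vector mapping haplotype id to
#'   population label.
#' @param region character vector per position, `"coding"` or `"noncoding"`.
#'   A single value is recycled.
#' @param amplicons optional two-column matrix or data.frame of 1-based
#'   inclusive `(start, end)` amplicon spans within the locus.
#' @param locus_length total locus length in bp (defaults to `max(positions)`).
#'
#' @return An object of class `hap_aln`.
#' @export
haplotype_alignment <- function(alleles, positions = seq_len(ncol(alleles)),
                                populations, region = "noncoding",
                                amplicons = NULL, locus_length = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "character"
  alleles[] <- toupper(alleles)
  if (is.null(rownames(alleles)))
    stop("haplotype ids required as rownames of the allele matrix")
  positions <- as.integer(positions)
  if (length(positions) != ncol(alleles))
    stop("one position per alignment column required")
  if (ncol(alleles) > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  ids <- rownames(alleles)
  missing_pop <- setdiff(ids, names(populations))
  if (length(missing_pop))
    stop("haplotypes missing from population map: ",
         paste(missing_pop, collapse = ", "))
  region <- rep_len(as.character(region), ncol(alleles))
  if (!all(region %in% c("coding", "noncoding")))
    stop("region classes must be 'coding' or 'noncoding'")
  if (is.null(locus_length)) locus_length <- max(positions, 1L)
  if (!is.null(amplicons)) {
    amplicons <- as.matrix(amplicons)[, 1:2, drop = FALSE]
    colnames(amplicons) <- c("start", "end")
    storage.mode(amplicons) <- "integer"
    if (any(amplicons[, 1] < 1L) || any(amplicons[, 2] > locus_length) ||
        any(amplicons[, 1] > amplicons[, 2]))
      stop("amplicon spans must lie within the locus")
  }
  structure(
    list(alleles = alleles, positions = positions,
         populations = populations[ids], region = region,
         amplicons = amplicons, locus_length = as.integer(locus_length)),
    class = "hap_aln")
}

#' @export
print.hap_aln <- function(x, ...) {
  cat(sprintf("Phased haplotype alignment: %d haplotypes x %d positions\n",
              nrow(x$alleles), ncol(x$alleles)))
  cat(sprintf("  populations: %s\n",
              paste(sprintf("%s (%d)", names(table(x$populations)),
                            table(x$populations)), collapse = ", ")))
  cat(sprintf("  locus length %d bp, %d coding positions, %d amplicons\n",
              x$locus_length, sum(x$region == "coding"),
              if (is.null(x$amplicons)) 0L else nrow(x$amplicons)))
  invisible(x)
}

MISSING_CODES <- c("N", "-", ".")

#' Read phased haplotypes from FASTA or VCF
#'
#' Multi-record FASTA input must contain equal-length records, one per phased
#' haplotype; ids of the form `"SAMPLE.1"`/`"SAMPLE.2"` are mapped to the
#' sample column of the population map. Phased VCF input (GT separated by
#' `"|"`) yields two haplotypes per diploid, with columns at the variant
#' positions only; in strict mode only the first ALT allele is honoured and
#' any further alleles raise an error.
#'
#' @param path FASTA (`.fa`, `.fasta`) or VCF (`.vcf`) file.
#' @param popmap data.frame with columns `sample` and `population`, or the
#'   path of a TSV with those columns.
#' @param region,amplicons,locus_length passed to [haplotype_alignment()].
#' @param strict logical; VCF strict mode (first ALT only, extra ALTs error).
#' @return A [haplotype_alignment()] object.
#' @export
read_haplotypes <- function(path, popmap, region = "noncoding",
                            amplicons = NULL, locus_length = NULL,
                            strict = FALSE) {
  popmap <- read_popmap(popmap)
  pops <- stats::setNames(as.character(popmap$population),
                          as.character(popmap$sample))
  if (grepl("\\.vcf($|\\.)", path, ignore.case = TRUE)) {
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)$GT
    if (any(grepl("/", gt, fixed = TRUE)))
      stop("unphased genotype encountered (GT with '/')")
    ref <- as.character(VariantAnnotation::ref(vcf))
    altl <- VariantAnnotation::alt(vcf)
    n_alt <- lengths(altl)
    if (strict && any(n_alt > 1L))
      stop("strict mode: multiallelic VCF record encountered")
    alt1 <- vapply(seq_along(altl),
                   function(i) as.character(altl[[i]][1]), character(1))
    pos <- as.integer(BiocGenerics::start(SummarizedExperiment::rowRanges(vcf)))
    samples <- colnames(gt)
    alle <- matrix(NA_character_, nrow = 2L * length(samples), nrow(gt))
    ids <- character(2L * length(samples))
    for (j in seq_along(samples)) {
      parts <- strsplit(gt[, j], "|", fixed = TRUE)
      if (any(lengths(parts) != 2L))
        stop("diploid phased genotypes required")
      codes <- do.call(rbind, parts)
      for (ph in 1:2) {
        row <- 2L * (j - 1L) + ph
        ids[row] <- paste0(samples[j], ".", ph)
        a <- codes[, ph]
        out <- rep("N", length(a))
        out[a == "0"] <- ref[a == "0"]
        out[a == "1"] <- alt1[a == "1"]
        if (!strict && any(a > "1"))
          out[a > "1"] <- "N"  # further ALTs unmodelled in lenient mode
        alle[row, ] <- out
      }
    }
    rownames(alle) <- ids
    samp_of <- sub("\\.[12]$", "", ids)
    pops_h <- stats::setNames(pops[samp_of], ids)
    if (anyNA(pops_h)) stop("sample missing from popmap: ",
                            paste(unique(samp_of[is.na(pops_h)]), collapse = ", "))
    ord <- order(pos)
    return(haplotype_alignment(alle[, ord, drop = FALSE], pos[ord], pops_h,
                               region = region, amplicons = amplicons,
                               locus_length = locus_length))
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(unique(Biostrings::width(seqs))) != 1L)
    stop("ragged alignment: FASTA records have unequal lengths")
  alle <- as.matrix(seqs)
  ids <- names(seqs)
  rownames(alle) <- ids
  samp_of <- sub("\\.[12]$", "", ids)
  pops_h <- stats::setNames(pops[samp_of], ids)
  if (anyNA(pops_h))
    stop("sample missing from popmap: ",
         paste(unique(samp_of[is.na(pops_h)]), collapse = ", "))
  haplotype_alignment(alle, seq_len(ncol(alle)), pops_h, region = region,
                      amplicons = amplicons, locus_length = locus_length)
}

read_popmap <- function(popmap) {
  if (is.character(popmap) && length(popmap) == 1L)
    popmap <- utils::read.delim(popmap, stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(popmap)))
    stop("popmap needs 'sample' and 'population' columns")
  popmap
}

#' Write a haplotype alignment (plus optional outgroup) as FASTA
#'
#' @param aln a [haplotype_alignment()].
#' @param path output FASTA path.
#' @export
write_haplotype_fasta <- function(aln, path) {
  seqs <- apply(aln$alleles, 1, paste0, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Tabulate segregating sites of an alignment
#'
#' Scans alignment columns for polymorphism within the ingroup. Missing codes
#' (`N`, `-`, `.`) are excluded from per-site called-chromosome counts. Sites
#' with more than two alleles are kept with the two most frequent alleles as
#' major/minor and flagged `triallelic`.
#'
#' @param aln a [haplotype_alignment()].
#' @param quality optional named numeric vector of per-position variant
#'   quality scores (names = positions).
#' @return A data.frame of class `variant_table`: one row per segregating
#'   site with position, major/minor alleles, per-population minor-allele and
#'   called-chromosome counts (`minor_<pop>`, `m_<pop>`), totals, region
#'   class, ancestral state (`NA` until [polarize_sites()]), and QC flags.
#' @export
variant_table <- function(aln, quality = NULL) {
  stopifnot(inherits(aln, "hap_aln"))
  pops <- sort(unique(aln$populations))
  rows <- list()
  for (j in seq_len(ncol(aln$alleles))) {
    col <- aln$alleles[, j]
    called <- !(col %in% MISSING_CODES)
    tab <- sort(table(col[called]), decreasing = TRUE)
    tab <- tab[names(tab) %in% c("A", "C", "G", "T")]
    if (length(tab) < 2L) next
    major <- names(tab)[1]; minor <- names(tab)[2]
    rec <- list(pos = aln$positions[j],
                major = major, minor = minor,
                anc = NA_character_, der = NA_character_,
                class = aln$region[j],
                n_alleles = length(tab),
                quality = if (!is.null(quality))
                  unname(quality[as.character(aln$positions[j])]) else NA_real_)
    keep <- called & col %in% c(major, minor)
    for (p in pops) {
      in_p <- aln$populations == p
      rec[[paste0("m_", p)]] <- sum(keep & in_p)
      rec[[paste0("minor_", p)]] <- sum(keep & in_p & col == minor)
      rec[[paste0("d_", p)]] <- NA_integer_
    }
    rec$m_total <- sum(keep)
    rec$minor_total <- sum(keep & col == minor)
    rec$d_total <- NA_integer_
    rows[[length(rows) + 1L]] <- rec
  }
  vt <- if (length(rows)) do.call(rbind.data.frame, rows) else
    empty_variant_table(pops)
  vt$flag_singleton <- !is.na(vt$minor_total) & vt$minor_total == 1L
  vt$flag_triallelic <- vt$n_alleles > 2L
  vt$flag_edge <- FALSE
  vt$flag_lowq <- FALSE
  vt$flag_uncovered <- FALSE
  class(vt) <- c("variant_table", "data.frame")
  attr(vt, "populations") <- pops
  vt
}

empty_variant_table <- function(pops) {
  vt <- data.frame(pos = integer(0), major = character(0), minor = character(0),
                   anc = character(0), der = character(0), class = character(0),
                   n_alleles = integer(0), quality = numeric(0))
  for (p in pops)
    for (pre in c("m_", "minor_", "d_"))
      vt[[paste0(pre, p)]] <- integer(0)
  vt$m_total <- integer(0); vt$minor_total <- integer(0); vt$d_total <- integer(0)
  vt
}

#' Amplicon-edge and quality filtering of variants
#'
#' Variants whose position falls within `edge_bp` of either end of any
#' containing amplicon (1-based offsets `1..edge_bp` from each end, boundary
#' inclusive) are removed, as are variants with a supplied quality score below
#' `min_quality`. Singletons and triallelic sites are *flagged* for review,
#' never removed, unless `strict = TRUE` drops triallelic sites. Variants not
#' covered by any amplicon are flagged `uncovered` and retained. Filtering is
#' idempotent.
#'
#' @param variants a [variant_table()].
#' @param aln the alignment providing amplicon spans.
#' @param rules list with `edge_bp` (default 50) and `min_quality`
#'   (default 99; applied only to variants with a quality score).
#' @param strict drop triallelic sites as well.
#' @return list with elements `variants` (filtered table) and `report`
#'   (counts removed/flagged per rule).
#' @export
apply_qc_filters <- function(variants, aln,
                             rules = list(edge_bp = 50, min_quality = 99),
                             strict = FALSE) {
  edge_bp <- if (is.null(rules$edge_bp)) 50L else as.integer(rules$edge_bp)
  minq <- if (is.null(rules$min_quality)) 99 else rules$min_quality
  amp <- aln$amplicons
  n0 <- nrow(variants)
  in_edge <- rep(FALSE, n0)
  covered <- rep(is.null(amp), n0)
  if (!is.null(amp) && n0) {
    for (k in seq_len(nrow(amp))) {
      a <- amp[k, 1]; b <- amp[k, 2]
      inside <- variants$pos >= a & variants$pos <= b
      covered <- covered | inside
      off_l <- variants$pos - a + 1L       # 1-based offset from amplicon start
      off_r <- b - variants$pos + 1L       # 1-based offset from amplicon end
      in_edge <- in_edge | (inside & (off_l <= edge_bp | off_r <= edge_bp))
    }
  }
  lowq <- !is.na(variants$quality) & variants$quality < minq
  drop <- in_edge | lowq
  if (strict) drop <- drop | variants$flag_triallelic
  out <- variants[!drop, , drop = FALSE]
  out$flag_edge <- FALSE
  out$flag_lowq <- FALSE
  out$flag_uncovered <- !covered[!drop]
  report <- list(input = n0,
                 removed_edge = sum(in_edge),
                 removed_low_quality = sum(lowq & !in_edge),
                 removed_triallelic = if (strict)
                   sum(variants$flag_triallelic & !in_edge & !lowq) else 0L,
                 flagged_singleton = sum(out$flag_singleton),
                 flagged_triallelic = sum(out$flag_triallelic),
                 flagged_uncovered = sum(out$flag_uncovered),
                 retained = nrow(out))
  list(variants = out, report = report)
}

#' Polarize segregating sites against an aligned outgroup
#'
#' The ancestral allele is the outgroup base when it matches one of the two
#' segregating alleles; otherwise (mismatch, gap, or missing) the site stays
#' unpolarized (`anc = NA`). Derived counts per population are filled for
#' polarized sites. Counts of segregating sites are never changed, only
#' annotated.
#'
#' @param variants a [variant_table()].
#' @param outgroup single aligned outgroup sequence: character string, vector
#'   of bases (length = locus length), or `DNAStringSet`/`DNAString`.
#' @return the variant table with `anc`, `der` and `d_*` columns filled.
#' @export
polarize_sites <- function(variants, outgroup) {
  og <- outgroup_vector(outgroup)
  pops <- attr(variants, "populations")
  for (i in seq_len(nrow(variants))) {
    base <- if (variants$pos[i] <= length(og)) og[variants$pos[i]] else "N"
    if (base %in% c(variants$major[i], variants$minor[i])) {
      anc <- base
      der <- if (anc == variants$major[i]) variants$minor[i] else variants$major[i]
      variants$anc[i] <- anc
      variants$der[i] <- der
      der_is_minor <- der == variants$minor[i]
      for (p in c(pops, "total")) {
        m <- variants[[paste0("m_", p)]][i]
        mn <- variants[[paste0("minor_", p)]][i]
        variants[[paste0("d_", p)]][i] <- if (der_is_minor) mn else m - mn
      }
    } else {
      variants$anc[i] <- NA_character_
      variants$der[i] <- NA_character_
    }
  }
  variants
}

outgroup_vector <- function(outgroup) {
  if (inherits(outgroup, "DNAStringSet")) outgroup <- outgroup[[1]]
  if (inherits(outgroup, "DNAString")) outgroup <- as.character(outgroup)
  if (is.character(outgroup) && length(outgroup) == 1L)
    outgroup <- strsplit(outgroup, "")[[1]]
  toupper(outgroup)
}

#' Count segregating sites and fixed differences
#'
#' A site is *segregating* (counted in `S`) if at least two nucleotides occur
#' within the ingroup; it is a *fixed difference* (counted in `FD`) if it is
#' monomorphic within the ingroup and the ingroup base differs from a called
#' outgroup base. By definition a site is never both.
#'
#' @param aln a [haplotype_alignment()] (full-sequence alignment).
#' @param outgroup aligned outgroup sequence (see [polarize_sites()]).
#' @param region `"all"`, `"coding"` or `"noncoding"`.
#' @return list of class `divergence_summary` with `S`, `FD`, `region`, `n`.
#' @export
count_segregating_and_fixed <- function(aln, outgroup, region = "all") {
  og <- outgroup_vector(outgroup)
  keep <- if (region == "all") rep(TRUE, ncol(aln$alleles)) else
    aln$region == region
  S <- 0L; FD <- 0L
  for (j in which(keep)) {
    col <- aln$alleles[, j]
    bases <- unique(col[!(col %in% MISSING_CODES)])
    bases <- bases[bases %in% c("A", "C", "G", "T")]
    if (length(bases) >= 2L) { S <- S + 1L; next }
    if (length(bases) == 1L) {
      ob <- if (aln$positions[j] <= length(og)) og[aln$positions[j]] else "N"
      if (ob %in% c("A", "C", "G", "T") && ob != bases) FD <- FD + 1L
    }
  }
  structure(list(S = S, FD = FD, region = region, n = nrow(aln$alleles)),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf("S = %d segregating sites, FD = %d fixed differences (%s region)\n",
              x$S, x$FD, x$region))
  invisible(x)
}

#' SNPs per fixed difference
#'
#' @param S segregating-site count (or a `divergence_summary`).
#' @param FD fixed-difference count; must be positive.
#' @return exact ratio `S/FD` (display at reduced precision is left to the
#'   caller; the exact value is returned so that `ratio * FD == S`).
#' @export
snp_fixed_ratio <- function(S, FD) {
  if (inherits(S, "divergence_summary")) { FD <- S$FD; S <- S$S }
  if (FD <= 0) stop("undefined ratio: no fixed differences (FD = 0)")
  S / FD
}

#' Pairwise linkage disequilibrium (r-squared)
#'
#' Squared correlation of allelic indicator variables at pairs of biallelic
#' sites; haplotypes missing at either site are dropped pairwise.
#'
#' @param aln a [haplotype_alignment()] or a 0/1 haplotype matrix.
#' @param pairs two-column matrix of positions (for an alignment) or column
#'   indices (for a matrix).
#' @return data.frame with `site1`, `site2`, `r2` (`NA` with a message
#'   attribute when a site is monomorphic among jointly called haplotypes).
#' @export
pairwise_r2 <- function(aln, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  get_ind <- function(k) {
    if (inherits(aln, "hap_aln")) {
      j <- match(k, aln$positions)
      if (is.na(j)) stop("position ", k, " not in alignment")
      col <- aln$alleles[, j]
      called <- !(col %in% MISSING_CODES)
      tab <- sort(table(col[called]), decreasing = TRUE)
      ind <- ifelse(called, as.integer(col == names(tab)[1]), NA_integer_)
    } else {
      ind <- as.integer(aln[, k])
    }
    ind
  }
  res <- data.frame(site1 = pairs[, 1], site2 = pairs[, 2], r2 = NA_real_)
  for (i in seq_len(nrow(pairs))) {
    x <- get_ind(pairs[i, 1]); y <- get_ind(pairs[i, 2])
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) next  # monomorphic
    res$r2[i] <- stats::cor(x, y)^2
  }
  res
}
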
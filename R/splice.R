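#' Donor splice-site scoring models
#'
#' A donor (5') splice-site model scores the 9-mer spanning positions -3..+6
#' of the exon/intron boundary (last 3 exonic bases + first 6 intronic
#' bases) on a log2-odds scale.
#'
#' `pwm_donor_model()` builds a position-weight-matrix model: the score is
#' `sum(log2(pwm[base, pos] / background[base]))`, so a PWM equal to the
#' background scores 0 for every 9-mer.
#'
#' `maxent_donor_model()` loads the published table-driven maximum-entropy
#' 5' model: the score is
#' `log2(cons1[s4] * cons2[s5] / (bgd[s4] * bgd[s5]) * table[i(seq)])`, where
#' `i(seq)` indexes the 16384-entry table by the 7-mer at positions
#' 1,2,3,6,7,8,9 (base-4, A=0 < C < G < T, first position most significant)
#' and `cons1`/`cons2` are the consensus frequencies of the near-invariant
#' GT dinucleotide. The table file (one numeric value per line, 16384 lines,
#' the `me2x5` asset distributed with the original scorer) must be supplied
#' by the user; it is not shipped with the package.
#'
#' @param pwm 4 x 9 matrix of base probabilities, rows named A,C,G,T.
#' @param background length-4 base composition (default uniform).
#' @return object of class `donor_model`.
#' @export
pwm_donor_model <- function(pwm, background = rep(0.25, 4)) {
  stopifnot(nrow(pwm) == 4, ncol(pwm) == 9)
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  names(background) <- rownames(pwm)
  structure(list(kind = "pwm", pwm = pwm, background = background),
            class = "donor_model")
}

#' @param path path of an `me2x5`-format table file (16384 lines).
#' @param bgd,cons1,cons2 background and GT-consensus base frequencies used
#'   by the published scoring pipeline; override only to reproduce variant
#'   scorer builds.
#' @rdname pwm_donor_model
#' @export
maxent_donor_model <- function(path,
                               bgd = c(A = 0.27, C = 0.23, G = 0.23, T = 0.27),
                               cons1 = c(A = 0.004, C = 0.0032, G = 0.9896, T = 0.0032),
                               cons2 = c(A = 0.0034, C = 0.0039, G = 0.0042, T = 0.9884)) {
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) != 4^7)
    stop("expected ", 4^7, " table values, got ", length(vals))
  structure(list(kind = "maxent-table", table = vals, bgd = bgd,
                 cons1 = cons1, cons2 = cons2),
            class = "donor_model")
}

#' Built-in toy donor PWM
#'
#' A position-weight matrix assembled from canonical human donor-site base
#' frequencies (near-invariant GT at +1/+2, A-rich exonic tail). It ranks
#' strong donors above weak ones and lets the splicing machinery run
#' offline; it is not the published maximum-entropy scorer and its absolute
#' scores are not comparable to published values.
#'
#' @return a `donor_model` of kind `"pwm"`.
#' @export
toy_donor_pwm <- function() {
  pwm <- matrix(c(
    # -3    -2    -1    +1     +2     +3    +4    +5    +6
    0.33, 0.60, 0.08, 0.001, 0.004, 0.55, 0.71, 0.06, 0.16,
    0.37, 0.13, 0.04, 0.001, 0.004, 0.05, 0.08, 0.06, 0.20,
    0.18, 0.14, 0.81, 0.997, 0.004, 0.28, 0.12, 0.81, 0.19,
    0.12, 0.13, 0.07, 0.001, 0.988, 0.12, 0.09, 0.07, 0.45),
    nrow = 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm_donor_model(sweep(pwm, 2, colSums(pwm), "/"))
}

#' Score a donor 9-mer
#'
#' @param seq9 character string of length 9 over A,C,G,T (3 exonic + 6
#'   intronic bases).
#' @param model a `donor_model`.
#' @return log2-odds score (scalar).
#' @export
score_donor <- function(seq9, model) {
  seq9 <- toupper(seq9)
  b <- strsplit(seq9, "")[[1]]
  if (length(b) != 9L || !all(b %in% c("A", "C", "G", "T")))
    stop("donor site must be a 9-mer over ACGT")
  if (model$kind == "pwm") {
    s <- 0
    for (i in 1:9)
      s <- s + log2(model$pwm[b[i], i] / model$background[b[i]])
    return(unname(s))
  }
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  rest <- b[c(1, 2, 3, 6, 7, 8, 9)]
  idx <- sum(code[rest] * 4L^(6:0)) + 1L
  cons <- model$cons1[b[4]] * model$cons2[b[5]] /
    (model$bgd[b[4]] * model$bgd[b[5]])
  unname(log2(cons * model$table[idx]))
}

#' Choose a donor among scored candidates
#'
#' The highest-scoring candidate with score `>= min_score` is used; exact
#' ties go to the most upstream candidate. When no candidate reaches the
#' threshold, the nearest candidate downstream of the canonical one is
#' activated (cryptic-site usage); if there is none, donor choice fails.
#'
#' @param candidates data.frame with columns `pos` (genomic coordinate of
#'   the last exonic base) and `score`; the first row is the canonical
#'   donor.
#' @param min_score activation threshold.
#' @return the chosen row of `candidates` (with a `cryptic` flag).
#' @export
select_donor <- function(candidates, min_score) {
  if (!nrow(candidates)) stop("empty donor candidate list")
  ok <- candidates$score >= min_score
  if (any(ok)) {
    sub <- candidates[ok, , drop = FALSE]
    best <- sub[order(-sub$score, sub$pos), , drop = FALSE][1, ]
  } else {
    canonical_pos <- candidates$pos[1]
    down <- candidates[candidates$pos > canonical_pos, , drop = FALSE]
    if (!nrow(down)) stop("no donor above threshold and no downstream cryptic site")
    best <- down[order(down$pos), , drop = FALSE][1, ]
  }
  best$cryptic <- best$pos != candidates$pos[1]
  best
}

#' Gene model for allele-aware splicing
#'
#' @param seq genomic sequence (character string).
#' @param exons k x 2 matrix of 1-based inclusive exon (start, end)
#'   coordinates, ordered and non-overlapping.
#' @param cds_start genomic coordinate of the first CDS base (within an
#'   exon).
#' @param cryptic_donors list (length k-1, one per intron) of integer
#'   vectors of alternative exon-end coordinates (possibly empty). The
#'   canonical donor of intron i is the annotated end of exon i.
#' @param snp list with `pos` (genomic coordinate) and single-base alleles
#'   `A` and `B`.
#' @param min_score default donor activation threshold for this gene.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(seq, exons, cds_start, cryptic_donors = NULL,
                       snp = NULL, min_score = 0) {
  exons <- as.matrix(exons)
  stopifnot(ncol(exons) == 2, all(exons[, 1] <= exons[, 2]))
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("exons must be ordered and non-overlapping")
  in_exon <- any(cds_start >= exons[, 1] & cds_start <= exons[, 2])
  if (!in_exon) stop("CDS start must lie within an exon")
  if (is.null(cryptic_donors)) cryptic_donors <- rep(list(integer(0)), nrow(exons) - 1L)
  structure(list(seq = toupper(seq), exons = exons, cds_start = cds_start,
                 cryptic_donors = cryptic_donors, snp = snp,
                 min_score = min_score),
            class = "gene_model")
}

donor_9mer <- function(seq_chars, exon_end) {
  paste0(seq_chars[(exon_end - 2):(exon_end + 6)], collapse = "")
}

#' Splice a gene for one allele and translate the transcript
#'
#' Applies the allele base at the gene's SNP position, scores the canonical
#' and cryptic donor candidates of every intron, selects a donor per intron
#' with [select_donor()], concatenates the resulting exon intervals into the
#' mature mRNA, and translates from the CDS start to the first in-frame stop
#' codon. A stop codon upstream of the final exon is a premature
#' termination codon (PTC); [classify_nmd()] is applied with the default
#' 50-nt rule.
#'
#' @param gene a [gene_model()].
#' @param allele `"A"` or `"B"`.
#' @param model a `donor_model` (default [toy_donor_pwm()]).
#' @param min_score donor threshold (default the gene's).
#' @return object of class `transcript_fate`: `mrna`, `junctions` (1-based
#'   mRNA offsets of the last base of each non-terminal exon), `protein`,
#'   `protein_length` (aa), `stop_offset` (1-based mRNA offset of the first
#'   stop-codon base; `NA` if non-stop), `ptc`, `nmd`, `donors` (per-intron
#'   choice), `nonstop`.
#' @export
splice_and_translate <- function(gene, allele = c("A", "B"),
                                 model = toy_donor_pwm(),
                                 min_score = gene$min_score) {
  allele <- match.arg(allele)
  chars <- strsplit(gene$seq, "")[[1]]
  if (!is.null(gene$snp)) chars[gene$snp$pos] <- gene$snp[[allele]]
  k <- nrow(gene$exons)
  ends <- gene$exons[, 2]
  donors <- list()
  for (i in seq_len(max(k - 1L, 0L))) {
    cand_pos <- c(gene$exons[i, 2], gene$cryptic_donors[[i]])
    cand <- data.frame(pos = cand_pos,
                       score = vapply(cand_pos, function(p)
                         score_donor(donor_9mer(chars, p), model), numeric(1)))
    choice <- select_donor(cand, min_score)
    ends[i] <- choice$pos
    donors[[i]] <- choice
  }
  pieces <- lapply(seq_len(k), function(i)
    chars[gene$exons[i, 1]:ends[i]])
  mrna <- unlist(pieces)
  lens <- lengths(pieces)
  junctions <- cumsum(lens)[-k]
  # map CDS start into mRNA coordinates
  cds_mrna <- genomic_to_mrna(gene$cds_start, gene$exons[, 1], ends, lens)
  if (is.na(cds_mrna)) stop("CDS start spliced out of the mature mRNA")
  if (paste0(mrna[cds_mrna:(cds_mrna + 2)], collapse = "") != "ATG")
    stop("no start codon at the CDS start")
  cds <- mrna[cds_mrna:length(mrna)]
  ncod <- length(cds) %/% 3
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste0(cds[seq_len(3 * ncod)], collapse = "")),
    no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  nonstop <- stop_at < 0
  if (nonstop) {
    protein <- aa
    stop_offset <- NA_integer_
  } else {
    protein <- substr(aa, 1, stop_at - 1)
    stop_offset <- cds_mrna + 3L * (stop_at - 1L)   # first base of stop codon
  }
  fate <- structure(list(mrna = paste0(mrna, collapse = ""),
                         junctions = junctions,
                         protein = protein, protein_length = nchar(protein),
                         stop_offset = stop_offset,
                         ptc = NA, nmd = NA, nonstop = nonstop,
                         donors = donors, allele = allele),
                    class = "transcript_fate")
  fate$ptc <- !nonstop && length(junctions) > 0 &&
    (stop_offset + 2L) <= junctions[length(junctions)]
  fate$nmd <- classify_nmd(fate)
  fate
}

genomic_to_mrna <- function(gpos, starts, ends, lens) {
  off <- 0L
  for (i in seq_along(starts)) {
    if (gpos >= starts[i] && gpos <= ends[i])
      return(off + gpos - starts[i] + 1L)
    off <- off + lens[i]
  }
  NA_integer_
}

#' Classify a transcript for nonsense-mediated decay
#'
#' The established rule: a transcript is an NMD substrate when its stop
#' codon lies at least `rule_nt` nucleotides upstream of the final
#' exon-exon junction. The distance is measured from the last base of the
#' stop codon to the junction, so a stop exactly `rule_nt - 1` nt upstream
#' is spared. A stop in the final exon is never a PTC.
#'
#' @param fate a `transcript_fate`.
#' @param rule_nt boundary (default 50; cited requirements span 50-55).
#' @return logical NMD flag.
#' @export
classify_nmd <- function(fate, rule_nt = 50) {
  if (!isTRUE(fate$ptc)) return(FALSE)
  last_junction <- fate$junctions[length(fate$junctions)]
  stop_end <- fate$stop_offset + 2L
  (last_junction - stop_end) >= rule_nt
}

#' @export
print.transcript_fate <- function(x, ...) {
  cat(sprintf("Transcript (allele %s): %d nt mRNA, %d aa protein%s\n",
              x$allele, nchar(x$mrna), x$protein_length,
              if (x$nonstop) " [non-stop]" else ""))
  cat(sprintf("  PTC: %s, NMD: %s\n", x$ptc, x$nmd))
  invisible(x)
}

#' Translate a transcript sequence from its first start codon
#'
#' Utility for full-transcript inputs (e.g. downloaded mRNA records): finds
#' the first ATG, translates to the first stop, and reports the protein
#' length.
#'
#' @param x transcript sequence (character, `DNAString`, or FASTA path).
#' @return list with `protein_length`, `protein`, `cds_start`.
#' @export
translate_transcript <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- as.character(Biostrings::readDNAStringSet(x)[[1]])
  if (inherits(x, "DNAString")) x <- as.character(x)
  x <- toupper(x)
  start <- as.integer(regexpr("ATG", x, fixed = TRUE))
  if (start < 0) stop("no start codon in transcript")
  # scan successive ATGs and keep the longest open reading frame
  best <- NULL
  while (start > 0) {
    cds <- substr(x, start, nchar(x))
    ncod <- nchar(cds) %/% 3
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(cds, 1, 3 * ncod)), no.init.codon = TRUE))
    stop_at <- as.integer(regexpr("*", aa, fixed = TRUE))
    len <- if (stop_at < 0) nchar(aa) else stop_at - 1L
    if (is.null(best) || len > best$protein_length)
      best <- list(protein_length = len,
                   protein = substr(aa, 1, len), cds_start = start)
    nxt <- as.integer(regexpr("ATG", substr(x, start + 1, nchar(x)),
                              fixed = TRUE))
    start <- if (nxt < 0) -1L else start + nxt
  }
  best
}
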
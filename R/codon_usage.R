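# Per-gene codon-usage statistics: codon counts, RSCU, GC/GC3s, Wright's
# effective number of codons and its neutral expectation, and parity-rule-2
# third-position asymmetries.

#' Count sense codons in a sequence
#'
#' Codons containing `-` or `N`, and stop codons, are excluded from the
#' counts and tallied separately.
#'
#' @param seq in-frame nucleotide string (or a single element of
#'   `codon_alignment$seqs`)
#' @param code_id NCBI genetic code id
#' @return list with `counts` (named integer vector over the sense codons),
#'   `n_codons_typed`, `n_codons_excluded`
#' @export
count_codons <- function(seq, code_id = 1L) {
  tabs <- codon_tables(code_id)
  seq <- chartr("U", "T", toupper(seq))
  cods <- split_codons(seq)
  keep <- is_typed_codon(cods) & !(cods %in% tabs$stop_codons)
  counts <- table(factor(cods[keep], levels = tabs$sense_codons))
  counts <- stats::setNames(as.integer(counts), tabs$sense_codons)
  list(counts = counts,
       n_codons_typed = sum(counts),
       n_codons_excluded = length(cods) - sum(counts))
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c in a family of size k is `count_c * k / sum(family
#' counts)`. Families with zero observed usage are `NA` (not 0). The
#' single-codon families Met (ATG) and Trp (TGG) are reported as 1 when
#' observed (and are excluded from interclade screens).
#'
#' @param counts result of [count_codons()], or a named count vector over
#'   the sense codons
#' @param code_id NCBI genetic code id
#' @return named numeric vector over the sense codons
#' @export
rscu <- function(counts, code_id = 1L) {
  if (is.list(counts)) counts <- counts$counts
  tabs <- codon_tables(code_id)
  out <- stats::setNames(rep(NA_real_, length(tabs$sense_codons)),
                         tabs$sense_codons)
  for (fam in tabs$families) {
    tot <- sum(counts[fam])
    if (tot > 0)
      out[fam] <- counts[fam] * length(fam) / tot
  }
  out
}

#' Wright's effective number of codons (Nc)
#'
#' Per amino-acid family with n >= 2 observed codons the codon homozygosity
#' is F = (n * sum(p^2) - 1) / (n - 1). F is averaged within degeneracy
#' classes (standard code: nine 2-fold, one 3-fold, five 4-fold families and
#' the three 6-fold families Leu/Ser/Arg), and
#' Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, clamped to `[20, 61]`. A missing
#' 3-fold mean is imputed as (F2 + F4)/2 (Wright 1990); any other missing or
#' non-positive class mean makes Nc `NA`.
#'
#' @inheritParams rscu
#' @return Nc in `[20, 61]`, or `NA` when undefined
#' @export
effective_number_of_codons <- function(counts, code_id = 1L) {
  if (is.list(counts)) counts <- counts$counts
  tabs <- codon_tables(code_id)
  fam_F <- function(fam) {
    n <- sum(counts[fam])
    if (n < 2) return(NA_real_)
    p <- counts[fam] / n
    (n * sum(p^2) - 1) / (n - 1)
  }
  Fs <- vapply(tabs$families, fam_F, numeric(1))
  deg <- tabs$degeneracy[names(Fs)]
  class_mean <- function(k) {
    v <- Fs[deg == k]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }
  f2 <- class_mean(2L); f3 <- class_mean(3L)
  f4 <- class_mean(4L); f6 <- class_mean(6L)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  fbar <- c(f2, f3, f4, f6)
  if (anyNA(fbar) || any(fbar <= 0)) return(NA_real_)
  nc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(max(nc, 20), 61)
}

#' Expected Nc under neutral evolution at a given GC3s
#'
#' Wright's neutral curve `Nc = 2 + s + 29 / (s^2 + (1 - s)^2)` where `s` is
#' the synonymous third-position G+C fraction.
#'
#' @param gc3s numeric in `[0, 1]` (vectorised)
#' @return expected Nc
#' @export
wright_expected_nc <- function(gc3s) {
  if (any(gc3s < 0 | gc3s > 1, na.rm = TRUE))
    stop("gc3s must be in [0, 1]")
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' GC content and synonymous third-position GC content
#'
#' `gc` is the G+C fraction over all typed bases; `gc3s` is the G+C fraction
#' at third positions of typed sense codons whose amino acid has a
#' synonymous alternative (ATG and TGG excluded).
#'
#' @param seq in-frame nucleotide string
#' @param code_id NCBI genetic code id
#' @return list with `gc` and `gc3s` (either may be `NA`)
#' @export
gc_contents <- function(seq, code_id = 1L) {
  tabs <- codon_tables(code_id)
  seq <- chartr("U", "T", toupper(seq))
  bases <- strsplit(seq, "")[[1]]
  typed <- bases %in% NUCS
  gc <- if (any(typed)) mean(bases[typed] %in% c("G", "C")) else NA_real_
  cods <- split_codons(seq)
  syn <- cods[is_typed_codon(cods) & cods %in% tabs$syn3_codons]
  gc3s <- if (length(syn)) mean(substr(syn, 3, 3) %in% c("G", "C"))
          else NA_real_
  list(gc = gc, gc3s = gc3s)
}

#' Parity-rule-2 third-position asymmetries
#'
#' Computed over third positions of fourfold-degenerate codon boxes only
#' (Sueoka's convention), which removes amino-acid-level selection from the
#' asymmetry: `pr2_at = A3 / (A3 + T3)` and `pr2_gc = G3 / (G3 + C3)`, with
#' equilibrium 0.5 under unbiased synonymous-site evolution. `NA` when the
#' denominator is zero.
#'
#' @inheritParams gc_contents
#' @return list with `pr2_at` and `pr2_gc`
#' @export
pr2_bias <- function(seq, code_id = 1L) {
  tabs <- codon_tables(code_id)
  seq <- chartr("U", "T", toupper(seq))
  cods <- split_codons(seq)
  ff <- cods[is_typed_codon(cods) & cods %in% tabs$fourfold_codons]
  third <- substr(ff, 3, 3)
  cnt <- function(b) sum(third == b)
  at <- cnt("A") + cnt("T"); gcn <- cnt("G") + cnt("C")
  list(pr2_at = if (at > 0) cnt("A") / at else NA_real_,
       pr2_gc = if (gcn > 0) cnt("G") / gcn else NA_real_)
}

#' Per-gene codon usage profiles for an alignment
#'
#' One row per gene with `gc`, `gc3s`, `nc`, `pr2_at`, `pr2_gc`, codon
#' counts summary, and one `rscu_<codon>` column per sense codon.
#'
#' @param aln a [codon_alignment()]
#' @return data.frame, one row per gene
#' @export
codon_usage_profiles <- function(aln) {
  tabs <- codon_tables(aln$code_id)
  rows <- lapply(seq_along(aln$seqs), function(i) {
    s <- aln$seqs[[i]]
    cc <- count_codons(s, aln$code_id)
    g <- gc_contents(s, aln$code_id)
    p <- pr2_bias(s, aln$code_id)
    r <- rscu(cc, aln$code_id)
    out <- data.frame(gene_id = names(aln$seqs)[i],
                      n_codons_typed = cc$n_codons_typed,
                      n_codons_excluded = cc$n_codons_excluded,
                      gc = g$gc, gc3s = g$gc3s,
                      nc = effective_number_of_codons(cc, aln$code_id),
                      pr2_at = p$pr2_at, pr2_gc = p$pr2_gc,
                      stringsAsFactors = FALSE)
    rmat <- as.data.frame(as.list(r))
    names(rmat) <- paste0("rscu_", names(r))
    cbind(out, rmat)
  })
  prof <- do.call(rbind, rows)
  merge(aln$meta, prof, by = "gene_id", sort = FALSE)
}
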
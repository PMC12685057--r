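# Nei-Gojobori (1986) counting estimator of dN/dS: synonymous/nonsynonymous
# site counting, pathway-averaged difference counting, and Jukes-Cantor
# corrected pairwise rates.

# all single-nucleotide neighbours of a codon
codon_neighbours <- function(codon) {
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(NUCS, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      out <- c(out, mut)
    }
  }
  out
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each position, the synonymous site fraction is the number of the 3
#' possible single-nucleotide changes that are synonymous, divided by 3;
#' changes to stop codons are excluded from the numerator but kept in the
#' denominator. `s + n = 3` for every sense codon.
#'
#' @param codon a sense codon
#' @param code_id NCBI genetic code id
#' @return list with `s` and `n`
#' @export
ng86_site_counts <- function(codon, code_id = 1L) {
  tabs <- codon_tables(code_id)
  codon <- chartr("U", "T", toupper(codon))
  if (!codon %in% tabs$sense_codons)
    stop("not a sense codon: ", codon)
  aa <- tabs$aa_of[[codon]]
  nb <- codon_neighbours(codon)
  syn <- sum(tabs$aa_of[nb] == aa & tabs$aa_of[nb] != "*")
  s <- syn / 3
  list(s = s, n = 3 - s)
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' Codons differing at d positions are connected by d! single-change
#' pathways. Each step is synonymous if it preserves the amino acid. By
#' default pathways passing through a stop codon are excluded and `sd`/`nd`
#' are averaged over the remaining pathways; when none remains the pair is
#' flagged `no_path` (and excluded by [ng86_pair()]). With
#' `exclude_stop_paths = FALSE` all pathways are averaged with equal weight
#' and steps into or out of a stop codon count as nonsynonymous.
#'
#' @param codon_a,codon_b sense codons
#' @param code_id NCBI genetic code id
#' @param exclude_stop_paths drop pathways whose intermediates include stops
#' @return list with `sd`, `nd`, `no_path`
#' @export
ng86_pathway_diffs <- function(codon_a, codon_b, code_id = 1L,
                               exclude_stop_paths = TRUE) {
  tabs <- codon_tables(code_id)
  a <- chartr("U", "T", toupper(codon_a))
  b <- chartr("U", "T", toupper(codon_b))
  if (!a %in% tabs$sense_codons || !b %in% tabs$sense_codons)
    stop("both codons must be sense codons")
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  d <- length(pos)
  if (d == 0) return(list(sd = 0, nd = 0, no_path = FALSE))

  orderings <- perms(pos)
  sd_tot <- 0; nd_tot <- 0; n_paths <- 0L
  for (k in seq_len(nrow(orderings))) {
    cur <- a
    sd <- 0; nd <- 0; ok <- TRUE
    for (p in orderings[k, ]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      aa_cur <- tabs$aa_of[[cur]]; aa_nxt <- tabs$aa_of[[nxt]]
      if (exclude_stop_paths && aa_nxt == "*" && nxt != b) {
        ok <- FALSE
        break
      }
      if (aa_cur == aa_nxt && aa_cur != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) {
      sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd
      n_paths <- n_paths + 1L
    }
  }
  if (n_paths == 0L) return(list(sd = NA_real_, nd = NA_real_,
                                 no_path = TRUE))
  list(sd = sd_tot / n_paths, nd = nd_tot / n_paths, no_path = FALSE)
}

# all permutations of a small vector (d <= 3 here)
perms <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# memoised NG86 lookup tables over the sense codons
ng86_tables <- function(code_id = 1L, exclude_stop_paths = TRUE) {
  key <- paste0("ng86_", code_id, "_", exclude_stop_paths)
  if (!is.null(.cladon_cache[[key]])) return(.cladon_cache[[key]])
  tabs <- codon_tables(code_id)
  sc <- tabs$sense_codons
  s_sites <- vapply(sc, function(cd) ng86_site_counts(cd, code_id)$s,
                    numeric(1))
  m <- length(sc)
  SD <- matrix(0, m, m, dimnames = list(sc, sc))
  ND <- SD
  NOPATH <- matrix(FALSE, m, m, dimnames = list(sc, sc))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i) next
      pd <- ng86_pathway_diffs(sc[i], sc[j], code_id, exclude_stop_paths)
      if (pd$no_path) {
        NOPATH[i, j] <- NOPATH[j, i] <- TRUE
      } else {
        SD[i, j] <- SD[j, i] <- pd$sd
        ND[i, j] <- ND[j, i] <- pd$nd
      }
    }
  }
  res <- list(s_sites = s_sites, SD = SD, ND = ND, NOPATH = NOPATH)
  .cladon_cache[[key]] <- res
  res
}

#' Jukes-Cantor distance from a proportion of differences
#'
#' `d = -(3/4) log(1 - (4/3) p)`; `NA` (saturated) when `p >= 3/4`.
#'
#' @param p proportion of differing sites (vectorised)
#' @return corrected distance
#' @export
jc_correction <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise NG86 dN/dS between two aligned sequences
#'
#' Codons with a gap, N, or stop in either sequence are excluded pairwise.
#' Synonymous/nonsynonymous sites are the mean of the two sequences' site
#' sums over the compared codons; differences are pathway-averaged per codon
#' pair and summed. `pS = Sd/S_sites`, `pN = Nd/N_sites`, each
#' Jukes-Cantor-corrected to `dS`/`dN`; `omega = dN/dS` (`NA` when `dS` is 0
#' or undefined).
#'
#' @param seq_a,seq_b aligned in-frame nucleotide strings of equal length
#' @param code_id NCBI genetic code id
#' @param exclude_stop_paths see [ng86_pathway_diffs()]
#' @return list with `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `dS`,
#'   `dN`, `omega`, `n_codons_compared`, `n_codons_no_path`
#' @export
ng86_pair <- function(seq_a, seq_b, code_id = 1L,
                      exclude_stop_paths = TRUE) {
  tabs <- codon_tables(code_id)
  nt <- ng86_tables(code_id, exclude_stop_paths)
  a <- split_codons(chartr("U", "T", toupper(seq_a)))
  b <- split_codons(chartr("U", "T", toupper(seq_b)))
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  keep <- a %in% tabs$sense_codons & b %in% tabs$sense_codons
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("no compared codons after pairwise deletion")
  idx <- cbind(match(a, tabs$sense_codons), match(b, tabs$sense_codons))
  nopath <- nt$NOPATH[idx]
  n_nopath <- sum(nopath)
  a <- a[!nopath]; b <- b[!nopath]; idx <- idx[!nopath, , drop = FALSE]
  if (!nrow(idx)) stop("no compared codons with a stop-free pathway")
  S_sites <- (sum(nt$s_sites[a]) + sum(nt$s_sites[b])) / 2
  N_sites <- 3 * nrow(idx) - S_sites
  Sd <- sum(nt$SD[idx]); Nd <- sum(nt$ND[idx])
  pS <- Sd / S_sites; pN <- Nd / N_sites
  dS <- jc_correction(pS); dN <- jc_correction(pN)
  omega <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  list(S_sites = S_sites, N_sites = N_sites, Sd = Sd, Nd = Nd,
       pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
       n_codons_compared = nrow(idx), n_codons_no_path = n_nopath)
}

#' NG86 dN/dS over sequence pairs of an alignment
#'
#' @param aln a [codon_alignment()]
#' @param pairs "all" for every pair, or "within_clade" to restrict to pairs
#'   sharing a `clade_label`
#' @param exclude_stop_paths see [ng86_pathway_diffs()]
#' @return data.frame with one row per pair
#' @export
ng86_pairs <- function(aln, pairs = c("all", "within_clade"),
                       exclude_stop_paths = TRUE) {
  pairs <- match.arg(pairs)
  ids <- names(aln$seqs)
  if (length(ids) < 2) stop("need at least 2 sequences")
  pr <- utils::combn(ids, 2)
  if (pairs == "within_clade") {
    cl <- stats::setNames(aln$meta$clade_label, aln$meta$gene_id)
    keep <- !is.na(cl[pr[1, ]]) & cl[pr[1, ]] == cl[pr[2, ]]
    pr <- pr[, keep, drop = FALSE]
    if (!ncol(pr)) stop("no within-clade pairs")
  }
  rows <- lapply(seq_len(ncol(pr)), function(k) {
    r <- ng86_pair(aln$seqs[[pr[1, k]]], aln$seqs[[pr[2, k]]],
                   aln$code_id, exclude_stop_paths)
    data.frame(gene_a = pr[1, k], gene_b = pr[2, k],
               as.data.frame(r), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
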
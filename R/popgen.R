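# Population-genetic summaries: segregating sites, nucleotide diversity,
# Watterson's theta and Tajima's D. Sites with any gap or N in any member of
# the group are excluded (complete deletion).

# character matrix of an alignment (rows = sequences)
seq_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  rownames(m) <- names(aln$seqs)
  m
}

#' Segregating sites and nucleotide diversity
#'
#' Complete deletion: alignment columns containing any gap or N are dropped
#' before counting. `pi_total` is the mean pairwise difference count over all
#' `choose(n, 2)` sequence pairs; `pi_site = pi_total / L`;
#' `theta_w = S / a1` with `a1 = sum(1/i), i = 1..n-1` (per locus).
#'
#' @param aln a [codon_alignment()] (or subset) with n >= 2 sequences
#' @param group_id optional label carried into the result
#' @return list with `group_id`, `n`, `L` (compared sites), `S`, `pi_total`,
#'   `pi_site`, `theta_w`, `tajima_d` (filled by [tajimas_d()], `NA` when
#'   n < 4 or S = 0)
#' @export
segregating_sites_and_pi <- function(aln, group_id = NA_character_) {
  n <- n_seqs(aln)
  if (n < 2) stop("need at least 2 sequences")
  m <- seq_matrix(aln)
  keep <- apply(m, 2, function(col) all(col %in% NUCS))
  m <- m[, keep, drop = FALSE]
  L <- ncol(m)
  if (L == 0) stop("no compared sites remain after complete deletion")
  states <- apply(m, 2, function(col) length(unique(col)))
  S <- sum(states > 1)
  pairs <- utils::combn(n, 2)
  diffs <- apply(pairs, 2, function(ij) sum(m[ij[1], ] != m[ij[2], ]))
  pi_total <- mean(diffs)
  a1 <- sum(1 / seq_len(n - 1))
  d <- tajimas_d(n, S, pi_total)
  list(group_id = group_id, n = n, L = L, S = S,
       pi_total = pi_total, pi_site = pi_total / L,
       theta_w = S / a1, tajima_d = d)
}

#' Tajima's D
#'
#' Tajima (1989): with `a1 = sum 1/i`, `a2 = sum 1/i^2` (i = 1..n-1),
#' `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2+a2)`,
#' `D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S-1))`. Requires n >= 4 and
#' S >= 1; otherwise `NA` (the variance constants are unstable for n of 2
#' or 3, and D is undefined without polymorphism).
#'
#' @param n number of sequences
#' @param S number of segregating sites
#' @param pi_total mean pairwise difference count
#' @return Tajima's D, or `NA`
#' @export
tajimas_d <- function(n, S, pi_total) {
  if (n < 4 || S < 1) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Per-group population-genetic summaries
#'
#' Splits an alignment by clade, taxonomic order, or their combination and
#' computes [segregating_sites_and_pi()] per group. Groups with fewer than 2
#' sequences are skipped with a warning; groups with n < 4 carry `NA`
#' Tajima's D.
#'
#' @param aln a [codon_alignment()] whose metadata carries `clade_label`
#'   and/or `order_label` (or pass `clade_map`)
#' @param grouping one of "clade", "order", "clade_x_order"
#' @param clade_map optional data.frame (gene_id, clade_label, order_label)
#'   overriding alignment metadata
#' @return data.frame, one row per group
#' @export
group_popgen <- function(aln, grouping = c("clade", "order", "clade_x_order"),
                         clade_map = NULL) {
  grouping <- match.arg(grouping)
  meta <- aln$meta
  if (!is.null(clade_map)) {
    idx <- match(meta$gene_id, clade_map$gene_id)
    for (col in intersect(c("clade_label", "order_label"), names(clade_map)))
      meta[[col]] <- clade_map[[col]][idx]
  }
  key <- switch(grouping,
    clade = meta$clade_label,
    order = meta$order_label,
    clade_x_order = paste(meta$clade_label, meta$order_label, sep = ":"))
  if (all(is.na(key))) stop("empty grouping: no labels available")
  groups <- split(meta$gene_id, key)
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    if (length(ids) < 2) {
      warning("group '", g, "' has < 2 sequences; skipped")
      return(NULL)
    }
    sub <- subset_alignment(aln, ids)
    as.data.frame(segregating_sites_and_pi(sub, group_id = g),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no group with >= 2 sequences")
  out
}
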
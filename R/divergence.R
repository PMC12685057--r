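# Clade divergence relative to a slowly evolving reference gene set, plus
# tree clade utilities (monophyly, clade extraction).

#' Pairwise Jukes-Cantor distance between two aligned sequences
#'
#' Sites with a gap or N in either sequence are excluded pairwise. With
#' `sites = "ff3"` the comparison is restricted to third positions of codons
#' that are fourfold-degenerate in both sequences, approximating synonymous
#' site divergence.
#'
#' @param seq_a,seq_b aligned nucleotide strings of equal length
#' @param sites "all" (every typed site) or "ff3" (fourfold third positions)
#' @param code_id NCBI genetic code id (used for `sites = "ff3"`)
#' @return JC distance (`NA` when saturated, p >= 3/4)
#' @export
pairwise_jc_distance <- function(seq_a, seq_b, sites = c("all", "ff3"),
                                 code_id = 1L) {
  sites <- match.arg(sites)
  a <- strsplit(chartr("U", "T", toupper(seq_a)), "")[[1]]
  b <- strsplit(chartr("U", "T", toupper(seq_b)), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  if (sites == "all") {
    keep <- a %in% NUCS & b %in% NUCS
  } else {
    tabs <- codon_tables(code_id)
    ca <- split_codons(paste(a, collapse = ""))
    cb <- split_codons(paste(b, collapse = ""))
    ff <- ca %in% tabs$fourfold_codons & cb %in% tabs$fourfold_codons
    keep <- rep(FALSE, length(a))
    keep[which(ff) * 3L] <- TRUE
  }
  if (!any(keep)) stop("no compared sites")
  p <- mean(a[keep] != b[keep])
  jc_correction(p)
}

# mean over all within-alignment pairwise JC distances; NA pairs dropped
mean_pairwise_jc <- function(aln, ids = NULL, sites = "all") {
  seqs <- if (is.null(ids)) aln$seqs else aln$seqs[ids]
  if (length(seqs) < 2) return(list(mean = NA_real_, n_pairs = 0L,
                                    n_dropped = 0L))
  pr <- utils::combn(length(seqs), 2)
  d <- apply(pr, 2, function(ij)
    pairwise_jc_distance(seqs[[ij[1]]], seqs[[ij[2]]], sites = sites,
                         code_id = aln$code_id))
  list(mean = mean(d, na.rm = TRUE), n_pairs = length(d),
       n_dropped = sum(is.na(d)))
}

#' Clade divergence relative to a reference gene set
#'
#' Per clade: the mean over all within-clade pairwise Jukes-Cantor distances,
#' divided by the corresponding mean over reference-sequence pairs. The
#' reference mean is computed over reference sequences from the species
#' present in that clade; when fewer than two such sequences exist, all
#' reference pairs are used and the fallback is recorded. Mean-of-pairs
#' aggregation; saturated pairs are dropped with counts reported.
#'
#' @param clade_alignments named list of [codon_alignment()]s, one per clade
#' @param reference a [codon_alignment()] of slowly evolving reference genes
#'   (e.g. mitochondrial markers), with `species` metadata
#' @param sites "all" or "ff3" (see [pairwise_jc_distance()])
#' @return data.frame with `clade_label`, `n_genes`, `mean_pairwise_jc`,
#'   `reference_mean_jc`, `fold` (`NA` when the reference mean is 0),
#'   `reference_matched` (FALSE when the all-pairs fallback was used)
#' @export
clade_fold_divergence <- function(clade_alignments, reference,
                                  sites = "all") {
  if (n_seqs(reference) < 2) stop("reference needs >= 2 sequences")
  rows <- lapply(names(clade_alignments), function(cl) {
    aln <- clade_alignments[[cl]]
    if (n_seqs(aln) < 2) stop("clade '", cl, "' needs >= 2 genes")
    cl_jc <- mean_pairwise_jc(aln, sites = sites)
    cl_species <- unique(stats::na.omit(aln$meta$species))
    ref_ids <- reference$meta$gene_id[reference$meta$species %in% cl_species]
    matched <- length(ref_ids) >= 2
    if (!matched) ref_ids <- reference$meta$gene_id
    ref_jc <- mean_pairwise_jc(reference, ids = ref_ids, sites = sites)
    fold <- if (!is.na(ref_jc$mean) && ref_jc$mean > 0)
      cl_jc$mean / ref_jc$mean else NA_real_
    data.frame(clade_label = cl, n_genes = n_seqs(aln),
               mean_pairwise_jc = cl_jc$mean,
               reference_mean_jc = ref_jc$mean,
               fold = fold, reference_matched = matched,
               n_pairs_dropped = cl_jc$n_dropped,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Test whether a tip set is monophyletic
#'
#' Rooted tree: true iff some node's descendant tip set equals `tips`.
#' Unrooted tree: true iff the bipartition `{tips | rest}` is induced by
#' some edge, which makes the answer invariant to rerooting outside the
#' candidate clade.
#'
#' @param tree an [ape::phylo] tree
#' @param tips character vector, nonempty proper subset of the tree's tips
#' @return logical
#' @export
is_monophyletic <- function(tree, tips) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) stop("unknown tips: ", paste(unknown, collapse = ", "))
  if (!length(tips) || length(tips) >= length(tree$tip.label))
    stop("tips must be a nonempty proper subset of the tree's tips")
  tipset <- sort(match(tips, tree$tip.label))
  if (ape::is.rooted(tree)) {
    if (length(tipset) == 1) return(TRUE)
    node <- ape::getMRCA(tree, tips)
    desc <- descendant_tips(tree, node)
    return(identical(sort(desc), tipset))
  }
  # unrooted: check every edge's induced bipartition
  if (length(tipset) == 1 || length(tipset) == length(tree$tip.label) - 1)
    return(TRUE)
  parts <- ape::prop.part(tree)  # clades w.r.t. the stored (arbitrary) root
  ntip <- length(tree$tip.label)
  comp <- sort(setdiff(seq_len(ntip), tipset))
  for (p in parts) {
    sp <- sort(p)
    if (identical(sp, tipset) || identical(sp, comp)) return(TRUE)
  }
  FALSE
}

# tip indices descending from an internal node
descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  sort(unlist(lapply(kids, descendant_tips, tree = tree)))
}

#' Extract the clade spanned by a tip set
#'
#' Returns all tips descending from the most recent common ancestor of the
#' input tips. Unrooted trees must be rooted first, so an `outgroup` tip is
#' required for them.
#'
#' @param tree an [ape::phylo] tree
#' @param tips character vector of tip labels (nonempty)
#' @param outgroup outgroup tip label, required when `tree` is unrooted
#' @return character vector of tip labels of the spanned clade
#' @export
extract_clade <- function(tree, tips, outgroup = NULL) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) stop("unknown tips: ", paste(unknown, collapse = ", "))
  if (!length(tips)) stop("tips must be nonempty")
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup))
      stop("unrooted tree: an outgroup tip is required")
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  if (length(tips) == 1) return(tips)
  node <- ape::getMRCA(tree, tips)
  tree$tip.label[descendant_tips(tree, node)]
}
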
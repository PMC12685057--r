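# Codon tables derived from the standard genetic code. Only code_id = 1 is
# shipped with tests; other NCBI code ids are accepted and built the same way
# from Biostrings::getGeneticCode().

.cladon_cache <- new.env(parent = emptyenv())

NUCS <- c("A", "C", "G", "T")

#' Codon tables for a genetic code
#'
#' Internal lookup tables: sense codons, amino-acid families, degeneracy
#' classes and fourfold-degenerate codon boxes, memoised per code id.
#'
#' @param code_id NCBI genetic code id (1 = standard).
#' @return list with elements `codons`, `aa`, `sense_codons`, `stop_codons`,
#'   `families` (aa -> sense codons), `family_of` (codon -> aa),
#'   `degeneracy` (aa -> family size), `fourfold_codons` (codons in
#'   fourfold-degenerate boxes), `syn3_codons` (sense codons with a
#'   synonymous third position, i.e. excluding ATG/TGG-type singletons).
#' @keywords internal
codon_tables <- function(code_id = 1L) {
  key <- paste0("code_", code_id)
  if (!is.null(.cladon_cache[[key]])) return(.cladon_cache[[key]])
  gc_tab <- Biostrings::getGeneticCode(as.character(code_id))
  codons <- names(gc_tab)
  aa <- unname(gc_tab)
  sense <- codons[aa != "*"]
  stops <- codons[aa == "*"]
  aa_sense <- aa[aa != "*"]
  families <- split(sense, aa_sense)
  family_of <- stats::setNames(aa_sense, sense)
  degeneracy <- vapply(families, length, integer(1))

  # fourfold boxes: prefixes whose four codons are all sense and synonymous
  prefixes <- unique(substr(codons, 1, 2))
  ff <- character(0)
  for (pre in prefixes) {
    box <- paste0(pre, NUCS)
    if (all(box %in% sense) && length(unique(family_of[box])) == 1L)
      ff <- c(ff, box)
  }

  tabs <- list(
    codons = codons, aa = aa, aa_of = stats::setNames(aa, codons),
    sense_codons = sense, stop_codons = stops,
    families = families, family_of = family_of,
    degeneracy = degeneracy,
    fourfold_codons = ff,
    syn3_codons = sense[degeneracy[family_of[sense]] > 1L]
  )
  .cladon_cache[[key]] <- tabs
  tabs
}

#' Split a sequence into codons
#' @param seq uppercase nucleotide string, length divisible by 3
#' @return character vector of codons
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# codon is fully typed (no gap or ambiguity)
is_typed_codon <- function(codons) !grepl("[^ACGT]", codons)
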
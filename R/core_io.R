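#' Construct a codon alignment
#'
#' The shared container for in-frame coding-sequence alignments. Sequences are
#' case-normalised to uppercase and U is converted to T on ingest; the gap
#' character is `-` (`.` is rejected) and `N` is permitted. Codons containing
#' `-` or `N` are "untyped" and are excluded codon-wise by downstream
#' statistics. A fully typed stop codon at the final position is masked to
#' gaps with a warning; an internal in-frame stop is an error.
#'
#' @param seqs named character vector of aligned nucleotide sequences
#'   (names are gene ids, unique).
#' @param meta optional data.frame with columns `gene_id` and any of
#'   `species`, `order_label`, `clade_label`; matched to `seqs` by `gene_id`.
#' @param code_id NCBI genetic code id (default 1, the standard code).
#' @param check_stops logical; set `FALSE` for generic nucleotide loci
#'   (e.g. coalescent simulations) where the no-internal-stop invariant does
#'   not apply.
#' @return object of class `codon_alignment` with elements `seqs`, `meta`,
#'   `length` (alignment columns) and `code_id`.
#' @export
codon_alignment <- function(seqs, meta = NULL, code_id = 1L,
                            check_stops = TRUE) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named by gene_id")
  ids <- names(seqs)
  if (anyDuplicated(ids))
    stop("duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("invalid characters (alphabet is A,C,G,T,N,-) in: ",
         paste(ids[bad], collapse = ", "))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("sequences differ in aligned length")
  L <- lens[1]
  if (L %% 3L != 0L)
    stop("frame error: alignment length ", L, " not divisible by 3 (",
         ids[1], ", ...)")

  tabs <- codon_tables(code_id)
  if (check_stops && L > 0L) {
    n_codons <- L %/% 3L
    for (i in seq_along(seqs)) {
      cods <- split_codons(seqs[[i]])
      typed <- is_typed_codon(cods)
      is_stop <- typed & cods %in% tabs$stop_codons
      if (any(is_stop[-n_codons]))
        stop("frame error: internal stop codon in '", ids[i],
             "' at codon ", which(is_stop[-n_codons])[1])
      if (is_stop[n_codons]) {
        warning("terminal stop codon in '", ids[i], "' masked to gaps")
        cods[n_codons] <- "---"
        seqs[[i]] <- paste(cods, collapse = "")
      }
    }
  }

  m <- data.frame(gene_id = ids, species = NA_character_,
                  order_label = NA_character_, clade_label = NA_character_,
                  stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (!"gene_id" %in% names(meta)) stop("meta must have a gene_id column")
    unknown <- setdiff(meta$gene_id, ids)
    if (length(unknown))
      stop("meta refers to unknown gene ids: ",
           paste(unknown, collapse = ", "))
    idx <- match(meta$gene_id, m$gene_id)
    for (col in intersect(c("species", "order_label", "clade_label"),
                          names(meta))) {
      keep <- !is.na(meta[[col]])
      m[[col]][idx[keep]] <- as.character(meta[[col]][keep])
    }
  }

  structure(list(seqs = seqs, meta = m, length = unname(L),
                 code_id = as.integer(code_id)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$seqs), "sequences x", x$length,
      "sites (", x$length %/% 3L, "codons ), genetic code", x$code_id, "\n")
  invisible(x)
}

#' Number of sequences in a codon alignment
#' @param x a `codon_alignment`
#' @export
n_seqs <- function(x) length(x$seqs)

#' Subset a codon alignment by gene id
#' @param aln a `codon_alignment`
#' @param ids gene ids to keep (order preserved as given)
#' @return a `codon_alignment`
#' @export
subset_alignment <- function(aln, ids) {
  missing <- setdiff(ids, names(aln$seqs))
  if (length(missing))
    stop("unknown gene ids: ", paste(missing, collapse = ", "))
  codon_alignment(aln$seqs[ids],
                  meta = aln$meta[match(ids, aln$meta$gene_id), ],
                  code_id = aln$code_id, check_stops = FALSE)
}

#' Read an in-frame codon alignment from FASTA
#'
#' FASTA headers may carry metadata as `id key=value ...` with keys
#' `species`, `order` and `clade`; a sidecar TSV (columns `gene_id`,
#' `species`, `order_label`/`order`, `clade_label`/`clade`) overrides header
#' metadata.
#'
#' @param path FASTA file of aligned, in-frame coding sequences.
#' @param code_id NCBI genetic code id (default 1).
#' @param meta_path optional sidecar metadata TSV.
#' @return a [codon_alignment()].
#' @export
read_codon_alignment <- function(path, code_id = 1L, meta_path = NULL) {
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  seqs <- as.character(ss)
  ids <- sub("\\s.*$", "", headers)
  names(seqs) <- ids

  # header key=value metadata
  meta <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  keymap <- c(species = "species", order = "order_label",
              clade = "clade_label")
  for (key in names(keymap)) {
    pat <- paste0(".*\\b", key, "=([^[:space:]]+).*")
    hit <- grepl(pat, headers)
    vals <- rep(NA_character_, length(headers))
    vals[hit] <- sub(pat, "\\1", headers[hit])
    meta[[keymap[[key]]]] <- vals
  }

  if (!is.null(meta_path)) {
    side <- read_clade_map(meta_path)
    # a sidecar may cover several FASTAs (gene family + reference); rows
    # for ids absent from this alignment are ignored
    side <- side[side$gene_id %in% meta$gene_id, , drop = FALSE]
    idx <- match(side$gene_id, meta$gene_id)
    for (col in c("species", "order_label", "clade_label")) {
      if (col %in% names(side)) {
        keep <- !is.na(side[[col]])
        meta[[col]][idx[keep]] <- side[[col]][keep]
      }
    }
  }
  codon_alignment(seqs, meta = meta, code_id = code_id)
}

#' Write a codon alignment to FASTA
#'
#' Metadata fields present in the alignment are emitted as `key=value` pairs
#' on the header line, so a write/read round trip preserves them.
#'
#' @param aln a `codon_alignment`
#' @param path output FASTA path
#' @export
write_codon_alignment <- function(aln, path) {
  hdr <- aln$meta$gene_id
  add <- function(hdr, val, key)
    ifelse(is.na(val), hdr, paste0(hdr, " ", key, "=", val))
  hdr <- add(hdr, aln$meta$species, "species")
  hdr <- add(hdr, aln$meta$order_label, "order")
  hdr <- add(hdr, aln$meta$clade_label, "clade")
  writeLines(paste0(">", hdr, "\n", aln$seqs), path)
  invisible(path)
}

#' Read gene metadata / clade map from TSV
#'
#' Accepts `order`/`clade` or `order_label`/`clade_label` column names.
#'
#' @param path TSV with a `gene_id` column
#' @return data.frame with `gene_id` and any of `species`, `order_label`,
#'   `clade_label`
#' @export
read_clade_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (!"gene_id" %in% names(tab)) stop("metadata TSV needs a gene_id column")
  if ("order" %in% names(tab) && !"order_label" %in% names(tab))
    names(tab)[names(tab) == "order"] <- "order_label"
  if ("clade" %in% names(tab) && !"clade_label" %in% names(tab))
    names(tab)[names(tab) == "clade"] <- "clade_label"
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id in metadata TSV")
  tab
}

#' Read a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]: duplicate tip labels
#' and malformed Newick are errors; absent branch lengths stay absent
#' (`NULL`/`NA`), never coerced to zero.
#'
#' @param path file containing one Newick tree, or a Newick string via
#'   `text`.
#' @param text optional Newick string (overrides `path`).
#' @return an [ape::phylo] tree
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    suppressWarnings(
      if (!is.null(text)) ape::read.tree(text = text)
      else ape::read.tree(path)),
    error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick parse error in ",
         if (!is.null(text)) "text input" else path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0, na.rm = TRUE))
    stop("negative branch lengths")
  tr
}

#' Write a Newick tree
#' @param tree an [ape::phylo] tree
#' @param path output path
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a keyed table as TSV
#'
#' All rows must share one key set; missing values are written as `NA`.
#' There is no quoting dialect, so embedded tabs or newlines in values are
#' an error. Optional `comments` are emitted as `# `-prefixed lines before
#' the header.
#'
#' @param rows data.frame, or list of named lists/vectors sharing a key set
#' @param path output path
#' @param comments optional character vector of header comment lines
#' @export
write_table <- function(rows, path, comments = NULL) {
  if (!is.data.frame(rows)) {
    if (length(rows) == 0L)
      stop("empty row list without key information; pass a data.frame")
    keys <- names(rows[[1]])
    same <- vapply(rows, function(r) identical(sort(names(r)), sort(keys)),
                   logical(1))
    if (!all(same)) stop("heterogeneous keys across rows")
    rows <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(as.list(r[keys]), stringsAsFactors = FALSE)))
  }
  chars <- vapply(rows, function(col)
    any(grepl("[\t\n]", as.character(col[!is.na(col)]))), logical(1))
  if (any(chars))
    stop("values contain tab/newline (no quoting dialect): column ",
         paste(names(rows)[chars], collapse = ", "))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
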
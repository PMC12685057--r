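# Synthetic data with the statistical structure the analysis assumes:
# Kingman-coalescent nucleotide loci for pi / Tajima's D, MG94-style codon
# evolution on trees (omega, kappa, third-position compositional bias), and
# full clade-structured gene-family scenarios with a slowly evolving
# mitochondrial-like reference.

#' Simulation parameter bundle
#'
#' @param seed integer RNG seed (recorded in every output)
#' @param n sample size (coalescent simulations)
#' @param L_codons gene length in codons
#' @param theta per-locus scaled mutation rate (coalescent)
#' @param omega nonsynonymous/synonymous rate ratio
#' @param kappa transition/transversion rate ratio
#' @param gc_bias target G+C at mutation level: `pi_G = pi_C = gc_bias/2`,
#'   `pi_A = pi_T = (1 - gc_bias)/2`
#' @param clade_rate_scales named numeric, clade label -> branch-length
#'   multiplier
#' @param reference_rate_scale branch-length multiplier of the reference
#'   gene set
#' @return list of class `sim_params`
#' @export
sim_params <- function(seed = 1L, n = 10L, L_codons = 300L, theta = 5,
                       omega = 1, kappa = 1, gc_bias = 0.5,
                       clade_rate_scales = NULL,
                       reference_rate_scale = 1) {
  stopifnot(n >= 2, L_codons >= 1, theta > 0, omega >= 0, kappa > 0,
            gc_bias > 0, gc_bias < 1, reference_rate_scale > 0)
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 L_codons = as.integer(L_codons), theta = theta,
                 omega = omega, kappa = kappa, gc_bias = gc_bias,
                 clade_rate_scales = clade_rate_scales,
                 reference_rate_scale = reference_rate_scale),
            class = "sim_params")
}

#' Simulate a neutral coalescent alignment (finite sites)
#'
#' A Kingman genealogy (exponential coalescence times at rate
#' `choose(k, 2)` in scaled units) with Poisson(`theta * tree_length / 2`)
#' mutations placed uniformly on branches and assigned to uniformly chosen
#' sites; each mutation replaces the base by one of the other three,
#' uniformly (finite-sites JC kernel). Loci are generic DNA, so the
#' returned alignment is built without the coding-frame stop check.
#'
#' @param params a [sim_params()] (`n`, `L_codons`, `theta` used)
#' @param seed optional seed; when `NULL` the current RNG state is used
#'   (pass a seed for byte-identical output)
#' @return list with `alignment` (a [codon_alignment()], L = 3 * L_codons),
#'   `tree` (the genealogy as [ape::phylo]), `n_mutations`
#' @export
simulate_coalescent_alignment <- function(params, seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n
  L <- 3L * params$L_codons
  nnode <- 2L * n - 1L
  parent <- integer(nnode)
  time <- numeric(nnode)
  active <- seq_len(n)
  nxt <- n + 1L
  t <- 0
  while (length(active) > 1) {
    k <- length(active)
    t <- t + stats::rexp(1, k * (k - 1) / 2)
    pair <- sample(active, 2)
    parent[pair] <- nxt
    time[nxt] <- t
    active <- c(setdiff(active, pair), nxt)
    nxt <- nxt + 1L
  }
  root <- nnode
  blen <- numeric(nnode)
  nz <- parent > 0L
  blen[nz] <- time[parent[nz]] - time[nz]

  # mutations: Poisson(theta/2 * branch length) per branch
  n_mut <- stats::rpois(nnode, params$theta / 2 * blen)
  seqs <- vector("list", nnode)
  seqs[[root]] <- sample(NUCS, L, replace = TRUE)
  # children before parents in construction order, so walk from root down
  for (v in rev(seq_len(nnode - 1L))) {
    s <- seqs[[parent[v]]]
    if (n_mut[v] > 0) {
      for (m in seq_len(n_mut[v])) {
        site <- sample.int(L, 1)
        s[site] <- sample(setdiff(NUCS, s[site]), 1)
      }
    }
    seqs[[v]] <- s
  }
  tips <- vapply(seqs[seq_len(n)], paste, character(1), collapse = "")
  names(tips) <- paste0("seq", seq_len(n))
  aln <- codon_alignment(tips, check_stops = FALSE)

  # genealogy as an ape phylo (tips 1..n, root n+1)
  remap <- c(seq_len(n), rev(seq.int(n + 1L, nnode)))
  edge <- cbind(remap[parent[-root]], remap[seq_len(nnode - 1L)])
  tree <- structure(list(edge = edge, edge.length = blen[-root],
                         tip.label = names(tips), Nnode = n - 1L),
                    class = "phylo")
  list(alignment = aln, tree = tree, n_mutations = sum(n_mut))
}

# MG94-flavoured codon rate machinery: rate(i -> j) over the sense codons is
# 0 unless i and j differ at one position, else
# pi_target_nucleotide * kappa^[transition] * omega^[nonsynonymous]
# (* codon preference weight of the target, when given). Reversible with
# stationary codon frequencies proportional to the product of target
# nucleotide frequencies (times the preference weight), renormalised over
# the sense codons; scaled to 1 expected substitution per codon site per
# unit branch length.
mg94_machine <- function(omega, kappa, gc_bias, codon_pref = NULL,
                         code_id = 1L) {
  tabs <- codon_tables(code_id)
  sc <- tabs$sense_codons
  m <- length(sc)
  pi_nt <- stats::setNames(
    c((1 - gc_bias) / 2, gc_bias / 2, gc_bias / 2, (1 - gc_bias) / 2),
    NUCS)
  w <- stats::setNames(rep(1, m), sc)
  if (!is.null(codon_pref)) {
    bad <- setdiff(names(codon_pref), sc)
    if (length(bad)) stop("codon_pref for non-sense codons: ",
                          paste(bad, collapse = ", "))
    w[names(codon_pref)] <- codon_pref
  }
  ts_pair <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  Q <- matrix(0, m, m, dimnames = list(sc, sc))
  chars <- do.call(rbind, strsplit(sc, ""))
  for (i in seq_len(m)) {
    diffs <- chars != matrix(chars[i, ], m, 3, byrow = TRUE)
    nd <- rowSums(diffs)
    js <- which(nd == 1L)
    for (j in js) {
      pos <- which(diffs[j, ])
      rate <- pi_nt[[chars[j, pos]]] * w[j]
      if (ts_pair(chars[i, pos], chars[j, pos])) rate <- rate * kappa
      if (tabs$aa_of[[sc[i]]] != tabs$aa_of[[sc[j]]]) rate <- rate * omega
      Q[i, j] <- rate
    }
  }
  pi_cod <- apply(chars, 1, function(cc) prod(pi_nt[cc])) * w
  pi_cod <- pi_cod / sum(pi_cod)
  mu <- sum(pi_cod * rowSums(Q))
  Q <- Q / mu
  R <- rowSums(Q)
  targets <- lapply(seq_len(m), function(i) which(Q[i, ] > 0))
  probs <- lapply(seq_len(m), function(i) Q[i, targets[[i]]] / R[i])
  list(codons = sc, Q = Q, pi = pi_cod, R = R, targets = targets,
       probs = probs)
}

# evolve codon-state indices along one branch of length t (exponential
# waiting times, jump chain)
evolve_branch <- function(states, t, mach) {
  for (s in seq_along(states)) {
    cur <- states[s]
    tleft <- t
    repeat {
      if (mach$R[cur] <= 0) break  # absorbing (e.g. ATG/TGG at omega = 0)
      wt <- stats::rexp(1, mach$R[cur])
      if (wt >= tleft) break
      tleft <- tleft - wt
      tg <- mach$targets[[cur]]
      cur <- if (length(tg) == 1) tg
             else tg[sample.int(length(tg), 1, prob = mach$probs[[cur]])]
    }
    states[s] <- cur
  }
  states
}

#' Simulate codon-sequence evolution on a tree
#'
#' Continuous-time Markov simulation on the 61 sense codons under an
#' MG94-flavoured model (target-nucleotide parameterisation): substitutions
#' between codons differing at one position occur at rate
#' `pi_target * kappa^[transition] * omega^[nonsynonymous]`, scaled to one
#' expected substitution per codon site per unit branch length. No simulated
#' sequence can contain a stop codon (stops are not states of the chain).
#'
#' @param tree rooted [ape::phylo] with branch lengths (expected
#'   substitutions per codon site)
#' @param params a [sim_params()] (`L_codons`, `omega`, `kappa`, `gc_bias`)
#' @param root "stationary" (root drawn from the stationary codon
#'   distribution) or an explicit in-frame nucleotide string without stops
#' @param codon_pref optional named numeric of codon preference weights
#'   (engineered codon-usage bias)
#' @param seed optional seed; `NULL` uses the current RNG state
#' @return a [codon_alignment()] over the tree's tips
#' @export
simulate_codon_evolution <- function(tree, params, root = "stationary",
                                     codon_pref = NULL,
                                     seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  if (!ape::is.rooted(tree)) stop("a rooted tree is required")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("all branch lengths must be present")
  mach <- mg94_machine(params$omega, params$kappa, params$gc_bias,
                       codon_pref)
  L <- params$L_codons
  if (identical(root, "stationary")) {
    root_states <- sample.int(length(mach$codons), L, replace = TRUE,
                              prob = mach$pi)
  } else {
    cods <- split_codons(chartr("U", "T", toupper(root)))
    root_states <- match(cods, mach$codons)
    if (anyNA(root_states))
      stop("root sequence contains a stop or untyped codon")
    L <- length(root_states)
  }
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1L]] <- root_states
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    states[[ch]] <- evolve_branch(states[[p]], tree$edge.length[e], mach)
  }
  tips <- vapply(seq_len(ntip), function(i)
    paste(mach$codons[states[[i]]], collapse = ""), character(1))
  names(tips) <- tree$tip.label
  codon_alignment(tips, check_stops = FALSE)
}

#' Simulate independent stationary genes after a fixed divergence
#'
#' Convenience for per-gene codon-usage statistics: each gene is drawn from
#' the stationary codon distribution and evolved along a single branch of
#' length `t`.
#'
#' @param n_genes number of independent genes
#' @param params a [sim_params()]
#' @param t branch length per gene
#' @param codon_pref optional codon preference weights
#' @param seed optional seed
#' @return a [codon_alignment()] with `n_genes` records (`gene1`, ...)
#' @export
simulate_stationary_genes <- function(n_genes, params, t = 0.3,
                                      codon_pref = NULL,
                                      seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  mach <- mg94_machine(params$omega, params$kappa, params$gc_bias,
                       codon_pref)
  seqs <- vapply(seq_len(n_genes), function(g) {
    st <- sample.int(length(mach$codons), params$L_codons, replace = TRUE,
                     prob = mach$pi)
    st <- evolve_branch(st, t, mach)
    paste(mach$codons[st], collapse = "")
  }, character(1))
  names(seqs) <- paste0("gene", seq_len(n_genes))
  codon_alignment(seqs, check_stops = FALSE)
}

# balanced ultrametric Newick for a label set, root-to-tip depth h
balanced_newick <- function(labels, h) {
  if (length(labels) == 1) return(labels)
  k <- ceiling(length(labels) / 2)
  left <- labels[seq_len(k)]; right <- labels[-seq_len(k)]
  el <- function(sub) if (length(sub) == 1) h else h / 2
  paste0("(", balanced_newick(left, h / 2), ":", el(left), ",",
         balanced_newick(right, h / 2), ":", el(right), ")")
}

#' Default scenario configuration
#'
#' A nine-species, two-order gene family patterned on a clade-structured
#' terpene-cyclase family: conserved diterpene-synthase-like subclades
#' (low rate scale, low omega) and faster sesquiterpene-synthase-like clades,
#' with a slowly evolving mitochondrial-like reference on the same species
#' tree.
#'
#' @param seed RNG seed
#' @param tree_depth species-tree root-to-tip depth in expected
#'   substitutions per codon site at rate scale 1
#' @return config list for [generate_gene_family_scenario()]
#' @export
default_scenario_config <- function(seed = 1L, tree_depth = 0.05) {
  list(
    seed = as.integer(seed),
    orders = list(
      Malacalcyonacea = paste0("mala_sp", 1:5),
      Scleralcyonacea = paste0("scler_sp", 1:4)),
    tree_depth = tree_depth,
    L_codons = 300L,
    kappa = 2,
    gc_bias = 0.5,
    clade_specs = data.frame(
      clade_label = c("1-I", "1-II", "1-III", "1-IV", "1-V", "2", "3", "4"),
      rate_scale  = c(1.0,   0.5,    3.5,     0.5,    3.0,   3.5, 2.0, 3.5),
      omega       = c(0.1,   0.1,    0.3,     0.1,    0.3,   0.3, 0.3, 0.3),
      gc_bias     = c(0.5,   0.5,    0.5,     0.5,    0.5,   0.5, 0.5, 0.5),
      stringsAsFactors = FALSE),
    codon_pref = list(),
    reference_rate_scale = 1,
    reference_omega = 0.05,
    reference_L_codons = 300L
  )
}

#' Generate a clade-structured gene-family scenario
#'
#' Builds a balanced two-order species tree, simulates one gene per species
#' per clade under per-clade rate scales (branch-length multipliers), omega,
#' compositional bias and optional engineered codon preferences, and a
#' reference gene set on the same tree at `reference_rate_scale`. The same
#' seed yields a byte-identical bundle.
#'
#' @param config list as from [default_scenario_config()]
#' @return list of class `scenario_bundle`: `clade_alignments` (named list
#'   of [codon_alignment()]s), `reference` ([codon_alignment()]), `tree`
#'   (species tree, [ape::phylo]), `clade_map` (data.frame), `truth`
#'   (the config)
#' @export
generate_gene_family_scenario <- function(config = default_scenario_config()) {
  req <- c("seed", "orders", "tree_depth", "L_codons", "kappa", "gc_bias",
           "clade_specs", "reference_rate_scale", "reference_omega",
           "reference_L_codons")
  miss <- setdiff(req, names(config))
  if (length(miss))
    stop("invalid config, missing fields: ", paste(miss, collapse = ", "))
  if (length(config$orders) < 2 ||
      any(lengths(config$orders) < 2))
    stop("need >= 2 orders with >= 2 species each")
  if (nrow(config$clade_specs) < 2) stop("need >= 2 clades")
  set.seed(config$seed)

  D <- config$tree_depth
  subs <- vapply(config$orders, function(sp) balanced_newick(sp, D / 2),
                 character(1))
  nwk <- paste0("(", paste0(subs, ":", D / 2, collapse = ","), ");")
  tree <- read_newick(text = nwk)
  species <- unlist(config$orders, use.names = FALSE)
  order_of <- stats::setNames(
    rep(names(config$orders), lengths(config$orders)), species)

  clade_alns <- list()
  maps <- list()
  for (i in seq_len(nrow(config$clade_specs))) {
    spec <- config$clade_specs[i, ]
    cl <- spec$clade_label
    tr <- tree
    tr$edge.length <- tr$edge.length * spec$rate_scale
    pars <- sim_params(seed = config$seed, L_codons = config$L_codons,
                       omega = spec$omega, kappa = config$kappa,
                       gc_bias = spec$gc_bias)
    pref <- config$codon_pref[[cl]]
    aln <- simulate_codon_evolution(tr, pars, codon_pref = pref,
                                    seed = NULL)
    ids <- paste0("TC_", gsub("-", "", cl), "_", names(aln$seqs))
    map <- data.frame(gene_id = ids, species = names(aln$seqs),
                      order_label = unname(order_of[names(aln$seqs)]),
                      clade_label = cl, stringsAsFactors = FALSE)
    names(aln$seqs) <- ids
    clade_alns[[cl]] <- codon_alignment(aln$seqs, meta = map,
                                        check_stops = FALSE)
    maps[[cl]] <- map
  }

  ref_tree <- tree
  ref_tree$edge.length <- ref_tree$edge.length * config$reference_rate_scale
  ref_pars <- sim_params(seed = config$seed,
                         L_codons = config$reference_L_codons,
                         omega = config$reference_omega,
                         kappa = config$kappa, gc_bias = config$gc_bias)
  ref <- simulate_codon_evolution(ref_tree, ref_pars, seed = NULL)
  ref_ids <- paste0("mito_", names(ref$seqs))
  ref_map <- data.frame(gene_id = ref_ids, species = names(ref$seqs),
                        order_label = unname(order_of[names(ref$seqs)]),
                        clade_label = "reference",
                        stringsAsFactors = FALSE)
  names(ref$seqs) <- ref_ids
  reference <- codon_alignment(ref$seqs, meta = ref_map, check_stops = FALSE)

  structure(list(clade_alignments = clade_alns, reference = reference,
                 tree = tree, clade_map = do.call(rbind, c(maps,
                   make.row.names = FALSE)),
                 truth = config),
            class = "scenario_bundle")
}

#' Merge the clade alignments of a scenario into one alignment
#' @param bundle a `scenario_bundle`
#' @return a [codon_alignment()] of all gene-family members
#' @export
combine_clades <- function(bundle) {
  seqs <- unlist(lapply(bundle$clade_alignments, function(a) a$seqs))
  names(seqs) <- unlist(lapply(bundle$clade_alignments,
                               function(a) names(a$seqs)),
                        use.names = FALSE)
  codon_alignment(seqs, meta = bundle$clade_map, check_stops = FALSE)
}

#' Write a scenario bundle as a runnable file set
#'
#' Emits one FASTA per clade, a combined gene-family FASTA, the reference
#' FASTA, the species tree (Newick) and the metadata TSV; every file is
#' consumable by the analysis functions unchanged.
#'
#' @param bundle a `scenario_bundle`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(bundle$clade_alignments))
    write_codon_alignment(bundle$clade_alignments[[cl]],
                          file.path(dir, paste0("clade_",
                                    gsub("[^A-Za-z0-9]", "", cl),
                                    ".fasta")))
  write_codon_alignment(combine_clades(bundle),
                        file.path(dir, "gene_family.fasta"))
  write_codon_alignment(bundle$reference, file.path(dir, "reference.fasta"))
  write_newick(bundle$tree, file.path(dir, "species_tree.nwk"))
  meta <- rbind(bundle$clade_map, bundle$reference$meta)
  write_table(meta, file.path(dir, "meta.tsv"),
              comments = paste0("seed: ", bundle$truth$seed))
  invisible(dir)
}
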
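# Marginal ancestral sequence reconstruction on a fixed tree by Felsenstein
# pruning under a time-reversible substitution model. Branch lengths are
# taken as given; gaps are missing data (all-ones partial likelihoods).

#' Construct a reversible substitution model
#'
#' The rate matrix is rescaled so the expected number of substitutions per
#' site per unit branch length is 1, and eigendecomposed (via symmetrisation,
#' valid for reversible models) for fast transition probabilities.
#'
#' @param rate_matrix square rate matrix (rows sum to 0, off-diagonals >= 0)
#' @param stationary_freqs stationary distribution (must satisfy detailed
#'   balance with `rate_matrix`)
#' @param alphabet ordered state labels
#' @param name model name
#' @return object of class `subst_model`
#' @export
substitution_model <- function(rate_matrix, stationary_freqs, alphabet,
                               name = "custom") {
  k <- length(alphabet)
  stopifnot(nrow(rate_matrix) == k, ncol(rate_matrix) == k,
            length(stationary_freqs) == k)
  pi <- stationary_freqs / sum(stationary_freqs)
  Q <- rate_matrix
  if (max(abs(rowSums(Q))) > 1e-8) stop("rate matrix rows must sum to 0")
  if (any(Q - diag(diag(Q)) < -1e-12)) stop("negative off-diagonal rates")
  db <- pi * Q - t(pi * Q)
  if (max(abs(db)) > 1e-8) stop("detailed balance violated")
  # scale to 1 expected substitution per unit branch length
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  # symmetrise: B = D^{1/2} Q D^{-1/2} is symmetric for reversible Q
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(alphabet = alphabet, Q = Q, pi = pi, name = name,
                 evec = diag(1 / sp) %*% eig$vectors,
                 inv_evec = t(eig$vectors) %*% diag(sp),
                 eval = eig$values),
            class = "subst_model")
}

#' Jukes-Cantor nucleotide model
#' @return a `subst_model` over A, C, G, T with equal rates and frequencies
#' @export
jc_model <- function() {
  Q <- matrix(1 / 3, 4, 4); diag(Q) <- -1
  substitution_model(Q, rep(0.25, 4), c("A", "C", "G", "T"), name = "JC")
}

#' Poisson amino-acid model
#' @return a `subst_model` over the 20 amino acids with equal exchange rates
#'   and equal frequencies
#' @export
poisson_model <- function() {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  Q <- matrix(1 / 19, 20, 20); diag(Q) <- -1
  substitution_model(Q, rep(0.05, 20), aa, name = "Poisson")
}

#' Transition probability matrix P(t) = exp(Q t)
#'
#' Computed from the cached spectral decomposition of the (reversible) rate
#' matrix. Rows sum to 1; `t = 0` gives the identity.
#'
#' @param model a `subst_model`
#' @param t branch length, >= 0
#' @return stochastic matrix with dimnames from the model alphabet
#' @export
transition_probability <- function(model, t) {
  if (t < 0) stop("branch length must be >= 0")
  P <- model$evec %*% (exp(model$eval * t) * model$inv_evec)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(model$alphabet, model$alphabet)
  P
}

# alignment (codon_alignment or character matrix) -> character site matrix
as_site_matrix <- function(alignment) {
  if (inherits(alignment, "codon_alignment")) seq_matrix(alignment)
  else if (is.matrix(alignment)) alignment
  else do.call(rbind, strsplit(toupper(unlist(alignment)), ""))
}

# tip partial-likelihood matrix (k states x n sites); unknown symbols
# (gaps, N, ...) are missing data: all-ones columns
tip_partials <- function(states, alphabet) {
  k <- length(alphabet)
  L <- matrix(1, k, length(states))
  hit <- match(states, alphabet)
  obs <- which(!is.na(hit))
  L[, obs] <- 0
  L[cbind(hit[obs], obs)] <- 1
  L
}

# validated rooted tree + per-node branch-length/transition set-up
prepare_tree <- function(tree, model) {
  # a basal multifurcation is treated as the root: for reversible models the
  # likelihood is invariant to root placement (pulley principle)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("all branch lengths must be present")
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode); blen <- rep(NA_real_, nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length
  children <- lapply(seq_len(nnode), function(v)
    tree$edge[tree$edge[, 1] == v, 2])
  # post-order: reverse preorder of edges
  post <- rev(unique(c(ntip + 1L, tree$edge[, 2])))
  list(ntip = ntip, nnode = nnode, root = ntip + 1L, parent = parent,
       blen = blen, children = children, postorder = post)
}

# pruning pass: list of partial-likelihood matrices per node, plus per-site
# scaling (log) to avoid underflow
pruning_pass <- function(tp, tipL, Pmat) {
  part <- vector("list", tp$nnode)
  logscale <- 0
  for (v in tp$postorder) {
    if (v <= tp$ntip) {
      part[[v]] <- tipL[[v]]
    } else {
      L <- 1
      for (w in tp$children[[v]])
        L <- L * (Pmat[[w]] %*% part[[w]])
      mx <- apply(L, 2, max)
      mx[mx == 0] <- 1
      logscale <- logscale + sum(log(mx))
      part[[v]] <- sweep(L, 2, mx, "/")
    }
  }
  list(part = part, logscale = logscale)
}

#' Log-likelihood of one site pattern under a model on a rooted tree
#'
#' Felsenstein pruning; the root partial is combined with the model's
#' stationary frequencies. Symbols outside the model alphabet (gaps, N) are
#' missing data.
#'
#' @param tree rooted [ape::phylo] with branch lengths
#' @param model a `subst_model`
#' @param site_pattern named character vector, tip label -> symbol
#' @return log-likelihood
#' @export
site_log_likelihood <- function(tree, model, site_pattern) {
  missing <- setdiff(tree$tip.label, names(site_pattern))
  if (length(missing))
    stop("pattern missing tips: ", paste(missing, collapse = ", "))
  tp <- prepare_tree(tree, model)
  Pmat <- lapply(seq_len(tp$nnode), function(v)
    if (is.na(tp$blen[v])) NULL else transition_probability(model, tp$blen[v]))
  tipL <- vector("list", tp$ntip)
  for (i in seq_len(tp$ntip))
    tipL[[i]] <- tip_partials(site_pattern[[tree$tip.label[i]]],
                              model$alphabet)
  pp <- pruning_pass(tp, tipL, Pmat)
  log(sum(model$pi * pp$part[[tp$root]][, 1])) + pp$logscale
}

#' Marginal ancestral sequence reconstruction
#'
#' Per internal node and site, the marginal posterior over ancestral states
#' given the tips, tree, and model, computed by combining in-subtree partial
#' likelihoods (pruning) with out-subtree likelihoods from a preorder pass —
#' equivalent to rerooting at each node, which is exact for reversible
#' models. MAP sequences break ties by alphabet order.
#'
#' @param tree rooted [ape::phylo] with branch lengths; tip labels must match
#'   sequence ids
#' @param alignment a [codon_alignment()] (nucleotide states) or character
#'   matrix (rows = tips) of symbols in the model alphabet
#' @param model a `subst_model`
#' @return list with `posteriors` (list per internal node id of k x sites
#'   matrices), `map_sequences` (named character vector per internal node),
#'   `node_ids` (internal node numbers, root first),
#'   `total_log_likelihood`
#' @export
marginal_asr <- function(tree, alignment, model) {
  m <- as_site_matrix(alignment)
  missing <- setdiff(tree$tip.label, rownames(m))
  extra <- setdiff(rownames(m), tree$tip.label)
  if (length(missing) || length(extra))
    stop("tip/sequence mismatch; missing: [",
         paste(missing, collapse = ", "), "], unmatched: [",
         paste(extra, collapse = ", "), "]")
  m <- m[tree$tip.label, , drop = FALSE]
  nsite <- ncol(m)
  tp <- prepare_tree(tree, model)
  Pmat <- lapply(seq_len(tp$nnode), function(v)
    if (is.na(tp$blen[v])) NULL else transition_probability(model, tp$blen[v]))
  tipL <- lapply(seq_len(tp$ntip), function(i)
    tip_partials(m[i, ], model$alphabet))

  pp <- pruning_pass(tp, tipL, Pmat)
  part <- pp$part

  # preorder outside pass: G[[v]][x, site] is the likelihood of everything
  # outside v's subtree given state x at v (root prior included)
  k <- length(model$alphabet)
  G <- vector("list", tp$nnode)
  G[[tp$root]] <- matrix(model$pi, k, nsite)
  preorder <- rev(tp$postorder)
  for (v in preorder) {
    if (v <= tp$ntip) next
    kids <- tp$children[[v]]
    msgs <- lapply(kids, function(w) Pmat[[w]] %*% part[[w]])
    for (j in seq_along(kids)) {
      w <- kids[j]
      if (w <= tp$ntip) next  # posteriors only needed at internal nodes
      sib <- G[[v]]
      for (jj in seq_along(kids)) if (jj != j) sib <- sib * msgs[[jj]]
      gw <- t(Pmat[[w]]) %*% sib
      mx <- apply(gw, 2, max); mx[mx == 0] <- 1
      G[[w]] <- sweep(gw, 2, mx, "/")
    }
  }

  internal <- (tp$ntip + 1L):tp$nnode
  node_names <- if (!is.null(tree$node.label) &&
                    all(nzchar(tree$node.label)))
    tree$node.label else paste0("node", internal)
  posteriors <- vector("list", length(internal))
  maps <- character(length(internal))
  for (j in seq_along(internal)) {
    v <- internal[j]
    post <- G[[v]] * part[[v]]
    post <- sweep(post, 2, colSums(post), "/")
    rownames(post) <- model$alphabet
    posteriors[[j]] <- post
    maps[j] <- paste(model$alphabet[apply(post, 2, which.max)],
                     collapse = "")
  }
  names(posteriors) <- node_names
  names(maps) <- node_names
  total_ll <- sum(log(colSums(model$pi * part[[tp$root]]))) + pp$logscale
  list(posteriors = posteriors, map_sequences = maps,
       node_ids = internal, total_log_likelihood = total_ll)
}
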
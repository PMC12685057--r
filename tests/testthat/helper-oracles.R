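# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the package's own code paths.

GC1 <- Biostrings::GENETIC_CODE
SENSE <- names(GC1)[GC1 != "*"]

oracle_translate <- function(codon) unname(GC1[codon])

# Tajima's D written directly from the variance decomposition, structured
# differently from the package implementation
oracle_tajima <- function(n, S, pi_total) {
  if (n < 4 || S < 1) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  e1 <- (b1 - 1 / a1) / a1
  e2 <- (b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)) / (a1 * a1 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# exact two-sided Mann-Whitney p by complete enumeration of labelings
oracle_mw_enum <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * length(y) / 2
  sel <- utils::combn(length(pooled), nx)
  Us <- apply(sel, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# NG86 pathway classification by independent enumeration: all orderings of
# the differing positions, excluding pathways through stop codons
oracle_ng86_path <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0, npath = 1))
  ords <- if (length(pos) == 1) matrix(pos) else {
    pm <- expand.grid(rep(list(pos), length(pos)))
    pm <- pm[apply(pm, 1, function(r) length(unique(r)) == length(pos)), ,
             drop = FALSE]
    as.matrix(pm)
  }
  sd <- 0; nd <- 0; npath <- 0
  for (k in seq_len(nrow(ords))) {
    cur <- a; s <- 0; n <- 0; ok <- TRUE
    for (p in ords[k, ]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (oracle_translate(nxt) == "*") { ok <- FALSE; break }
      if (oracle_translate(cur) == oracle_translate(nxt)) s <- s + 1
      else n <- n + 1
      cur <- nxt
    }
    if (ok) { sd <- sd + s; nd <- nd + n; npath <- npath + 1 }
  }
  if (npath == 0) return(c(sd = NA, nd = NA, npath = 0))
  c(sd = sd / npath, nd = nd / npath, npath = npath)
}

# NG86 synonymous site count of a codon by mutant enumeration
oracle_ng86_sites <- function(codon) {
  s <- 0
  for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                   substr(codon, p, p))) {
    mut <- codon
    substr(mut, p, p) <- b
    if (oracle_translate(mut) != "*" &&
        oracle_translate(mut) == oracle_translate(codon)) s <- s + 1
  }
  s / 3
}

# JC transition probability, closed form
oracle_jc_p <- function(t) {
  same <- 0.25 + 0.75 * exp(-4 * t / 3)
  diff <- 0.25 - 0.25 * exp(-4 * t / 3)
  P <- matrix(diff, 4, 4,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(P) <- same
  P
}

# marginal ancestral posteriors by brute-force enumeration over all joint
# internal-state assignments (JC model, closed-form P); returns a list of
# 4 x 1 posteriors per internal node id
oracle_asr_brute <- function(tree, pattern) {
  nucs <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1):nnode
  Pm <- lapply(seq_len(nrow(tree$edge)), function(e)
    oracle_jc_p(tree$edge.length[e]))
  grids <- expand.grid(rep(list(nucs), length(internal)),
                       stringsAsFactors = FALSE)
  post <- matrix(0, 4, length(internal),
                 dimnames = list(nucs, as.character(internal)))
  for (g in seq_len(nrow(grids))) {
    assign_state <- character(nnode)
    assign_state[internal] <- unlist(grids[g, ])
    assign_state[seq_len(ntip)] <- pattern[tree$tip.label]
    pr <- 0.25  # root prior
    for (e in seq_len(nrow(tree$edge))) {
      from <- assign_state[tree$edge[e, 1]]
      to <- assign_state[tree$edge[e, 2]]
      pr <- pr * Pm[[e]][from, to]
    }
    for (j in seq_along(internal))
      post[assign_state[internal[j]], j] <- post[assign_state[internal[j]], j] + pr
  }
  sweep(post, 2, colSums(post), "/")
}

# descendant tip set of the MRCA of `tips`, by exhaustive node enumeration
oracle_mrca_tips <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  desc <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  want <- match(tips, tree$tip.label)
  best <- NULL
  for (v in seq_len(nnode)) {
    d <- desc(v)
    if (all(want %in% d) && (is.null(best) || length(d) < length(best)))
      best <- d
  }
  sort(tree$tip.label[best])
}

# tiny FASTA writer for fixtures
write_fasta_lines <- function(headers, seqs, path) {
  writeLines(paste0(">", headers, "\n", seqs), path)
  path
}
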
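test_that("transition probabilities match closed forms and limits", {
  m <- jc_model()
  expect_equal(transition_probability(m, 0), diag(4), ignore_attr = TRUE)
  P <- transition_probability(m, 0.1)
  expect_equal(P[1, 1], 0.25 + 0.75 * exp(-0.4 / 3))
  expect_equal(round(P[1, 1], 4), 0.9064)
  expect_equal(unname(transition_probability(m, 1e6)),
               matrix(0.25, 4, 4), tolerance = 1e-9)
  expect_equal(unname(rowSums(transition_probability(m, 0.37))), rep(1, 4))
  expect_error(transition_probability(m, -0.1), ">= 0")
  # full agreement with the closed form across t
  for (t in c(0.01, 0.3, 2)) {
    expect_equal(unname(transition_probability(m, t)),
                 unname(oracle_jc_p(t)), tolerance = 1e-12)
  }
  # rate matrix validation
  expect_error(substitution_model(matrix(1, 2, 2), c(0.5, 0.5), c("x", "y")),
               "sum to 0")
})

test_that("site log-likelihood matches brute-force enumeration on a star tree", {
  m <- jc_model()
  tr <- read_newick(text = "(a:0.1,b:0.2,c:0.15);")
  pat <- c(a = "A", b = "A", c = "C")
  ll <- site_log_likelihood(tr, m, pat)
  brute <- sum(vapply(c("A", "C", "G", "T"), function(x)
    0.25 * oracle_jc_p(0.1)[x, "A"] * oracle_jc_p(0.2)[x, "A"] *
      oracle_jc_p(0.15)[x, "C"], numeric(1)))
  expect_equal(ll, log(brute), tolerance = 1e-12)

  # invariant to child ordering
  tr2 <- read_newick(text = "(c:0.15,a:0.1,b:0.2);")
  expect_equal(site_log_likelihood(tr2, m, pat), ll)

  # gap tips are missing data
  ll_gap <- site_log_likelihood(tr, m, c(a = "A", b = "-", c = "A"))
  two <- sum(vapply(c("A", "C", "G", "T"), function(x)
    0.25 * oracle_jc_p(0.1)[x, "A"] * oracle_jc_p(0.15)[x, "A"],
    numeric(1)))
  expect_equal(ll_gap, log(two), tolerance = 1e-12)
})

test_that("total log-likelihood is invariant to root placement (pulley)", {
  m <- jc_model()
  set.seed(5)
  tr <- ape::rtree(6)
  pat <- stats::setNames(sample(c("A", "C", "G", "T"), 6, TRUE),
                         tr$tip.label)
  ll0 <- site_log_likelihood(tr, m, pat)
  un <- ape::unroot(tr)
  for (tip in un$tip.label) {
    rr <- ape::root(un, outgroup = tip, resolve.root = TRUE)
    expect_equal(site_log_likelihood(rr, m, pat), ll0, tolerance = 1e-9)
  }
})

test_that("marginal posteriors match brute-force joint enumeration", {
  m <- jc_model()
  # frozen 3-tip example: tips A, A, C at t = 0.1 from the root
  tr <- read_newick(text = "(a:0.1,b:0.1,c:0.1);")
  aln <- matrix(c("A", "A", "C"), 3, 1,
                dimnames = list(c("a", "b", "c"), NULL))
  rec <- marginal_asr(tr, aln, m)
  expect_equal(unname(rec$posteriors[[1]]["A", 1]), 0.9645,
               tolerance = 1e-4)
  expect_equal(sum(rec$posteriors[[1]][, 1]), 1, tolerance = 1e-9)

  # random rooted topologies up to 5 tips vs enumeration oracle
  set.seed(6)
  for (ntip in 3:5) {
    for (rep in 1:5) {
      tr <- ape::rtree(ntip)
      pat <- stats::setNames(sample(c("A", "C", "G", "T"), ntip, TRUE),
                             tr$tip.label)
      aln <- matrix(pat[tr$tip.label], ntip, 1,
                    dimnames = list(tr$tip.label, NULL))
      rec <- marginal_asr(tr, aln, m)
      brute <- oracle_asr_brute(tr, pat)
      for (j in seq_along(rec$node_ids)) {
        expect_equal(unname(rec$posteriors[[j]][, 1]),
                     unname(brute[, as.character(rec$node_ids[j])]),
                     tolerance = 1e-10)
      }
      expect_equal(rec$total_log_likelihood,
                   site_log_likelihood(tr, m, pat), tolerance = 1e-9)
    }
  }
})

test_that("degenerate and mismatch cases behave as specified", {
  m <- jc_model()
  tr <- read_newick(text = "(a:0,b:0,c:0);")
  aln <- matrix("A", 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  rec <- marginal_asr(tr, aln, m)
  expect_equal(unname(rec$posteriors[[1]]["A", ]), c(1, 1))
  expect_equal(rec$map_sequences[[1]], "AA")

  expect_error(marginal_asr(tr, aln[1:2, , drop = FALSE], m),
               "tip/sequence mismatch")
  tr_nb <- read_newick(text = "(a,b,c);")
  expect_error(marginal_asr(tr_nb, aln, m), "branch lengths")
})

test_that("ancestral states are recovered at short branch lengths", {
  # simulate nucleotide evolution via the codon machinery at near-zero
  # divergence and check the root MAP sequence matches the true root
  set.seed(7)
  tr <- read_newick(
    text = "((a:0.01,b:0.01):0.01,(c:0.01,d:0.01):0.01);")
  p <- sim_params(seed = NULL, L_codons = 120, omega = 1, kappa = 1,
                  gc_bias = 0.5)
  root_aln <- simulate_stationary_genes(1, p, t = 0, seed = NULL)
  root_seq <- unname(root_aln$seqs[[1]])
  aln <- simulate_codon_evolution(tr, p, root = root_seq, seed = NULL)
  rec <- marginal_asr(tr, aln, jc_model())
  root_map <- rec$map_sequences[[1]]
  agree <- mean(strsplit(root_map, "")[[1]] == strsplit(root_seq, "")[[1]])
  expect_gte(agree, 0.99)
})
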
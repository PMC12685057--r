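test_that("coalescent simulation is deterministic and hits Watterson scale", {
  p <- sim_params(seed = 31, n = 8, L_codons = 200, theta = 4)
  s1 <- simulate_coalescent_alignment(p)
  s2 <- simulate_coalescent_alignment(p)
  expect_identical(s1$alignment$seqs, s2$alignment$seqs)
  expect_equal(ape::Ntip(s1$tree), 8)
  expect_equal(s1$alignment$length, 600)

  # light Monte-Carlo check of E[S] = theta * a1 (full-scale version is an
  # acceptance property)
  set.seed(32)
  pp <- sim_params(seed = NULL, n = 10, L_codons = 500, theta = 5)
  S <- replicate(300, {
    sim <- simulate_coalescent_alignment(pp, seed = NULL)
    segregating_sites_and_pi(sim$alignment)$S
  })
  expect_equal(mean(S), 5 * sum(1 / (1:9)), tolerance = 0.08)
})

test_that("codon evolution respects its structural invariants", {
  tabs <- cladon:::codon_tables(1)
  tr <- read_newick(text = "((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1);")
  p <- sim_params(seed = 33, L_codons = 150, omega = 0.5, kappa = 2,
                  gc_bias = 0.6)
  aln <- simulate_codon_evolution(tr, p)
  # no in-frame stops, ever
  for (s in aln$seqs)
    expect_false(any(cladon:::split_codons(s) %in% tabs$stop_codons))

  # zero branch lengths: all tips equal the root
  tr0 <- read_newick(text = "((a:0,b:0):0,(c:0,d:0):0);")
  root <- strrep("ATGAAATTTGGC", 5)
  aln0 <- simulate_codon_evolution(tr0, p, root = root)
  expect_true(all(aln0$seqs == root))

  # omega = 0: every tip translates to the root protein
  p0 <- sim_params(seed = 34, L_codons = 50, omega = 0, kappa = 1,
                   gc_bias = 0.5)
  aln_syn <- simulate_codon_evolution(tr, p0, root = root)
  tr_prot <- function(s) paste(tabs$aa_of[cladon:::split_codons(s)],
                               collapse = "")
  expect_true(all(vapply(aln_syn$seqs, tr_prot, character(1)) ==
                    tr_prot(root)))
  expect_false(all(aln_syn$seqs == root))  # but synonymous changes happened

  expect_error(simulate_codon_evolution(tr, p0, root = "ATGTAA"),
               "stop")
})

test_that("stationary composition tracks the gc_bias dial", {
  # long gene at stationarity: GC3s within 0.03 of the mutation-level target
  for (g in c(0.5, 0.8)) {
    p <- sim_params(seed = 35, L_codons = 2000, omega = 1, kappa = 1,
                    gc_bias = g)
    aln <- simulate_stationary_genes(1, p, t = 0)
    gc3 <- gc_contents(aln$seqs[[1]])$gc3s
    expect_lt(abs(gc3 - g), 0.03)
  }

  # Nc decreases as composition departs from 0.5, tracking Wright's curve
  ncs <- vapply(c(0.5, 0.7, 0.9), function(g) {
    p <- sim_params(seed = 36, L_codons = 2000, omega = 1, kappa = 1,
                    gc_bias = g)
    aln <- simulate_stationary_genes(1, p, t = 0)
    effective_number_of_codons(count_codons(aln$seqs[[1]]))
  }, numeric(1))
  expect_true(all(diff(ncs) < 0))
  for (i in seq_along(ncs)) {
    g <- c(0.5, 0.7, 0.9)[i]
    p <- sim_params(seed = 36, L_codons = 2000, omega = 1, kappa = 1,
                    gc_bias = g)
    aln <- simulate_stationary_genes(1, p, t = 0)
    gc3 <- gc_contents(aln$seqs[[1]])$gc3s
    expect_lt(abs(ncs[i] - wright_expected_nc(gc3)), 3)
  }
})

test_that("gene-family scenarios are reproducible, structured, and writable", {
  cfg <- default_scenario_config(seed = 37)
  b1 <- generate_gene_family_scenario(cfg)
  b2 <- generate_gene_family_scenario(cfg)
  expect_identical(lapply(b1$clade_alignments, `[[`, "seqs"),
                   lapply(b2$clade_alignments, `[[`, "seqs"))
  expect_identical(b1$reference$seqs, b2$reference$seqs)

  expect_equal(length(b1$clade_alignments), nrow(cfg$clade_specs))
  expect_equal(nrow(b1$clade_map), 8 * 9)  # 8 clades x 9 species
  expect_equal(ape::Ntip(b1$tree), 9)
  expect_setequal(unique(b1$clade_map$order_label),
                  c("Malacalcyonacea", "Scleralcyonacea"))

  d <- tempfile()
  write_scenario(b1, d)
  expect_true(all(file.exists(file.path(d, c(
    "gene_family.fasta", "reference.fasta", "species_tree.nwk",
    "meta.tsv")))))
  back <- read_codon_alignment(file.path(d, "gene_family.fasta"),
                               meta_path = file.path(d, "meta.tsv"))
  expect_equal(n_seqs(back), 72)
  expect_false(any(is.na(back$meta$clade_label)))

  bad <- cfg; bad$clade_specs <- NULL
  expect_error(generate_gene_family_scenario(bad), "missing fields")
})

test_that("PR2 means sit at 0.5 under symmetric mutation (light check)", {
  p <- sim_params(seed = 38, L_codons = 300, omega = 1, kappa = 1,
                  gc_bias = 0.5)
  aln <- simulate_stationary_genes(40, p, t = 0.3)
  pr2 <- vapply(aln$seqs, function(s) unlist(pr2_bias(s)), numeric(2))
  expect_lt(abs(mean(pr2[1, ]) - 0.5), 0.04)
  expect_lt(abs(mean(pr2[2, ]) - 0.5), 0.04)
})
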
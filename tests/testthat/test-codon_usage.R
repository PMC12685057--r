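sense <- cladon:::codon_tables(1)$sense_codons
families <- cladon:::codon_tables(1)$families

make_counts <- function(named) {
  cnt <- stats::setNames(rep(0L, 61), sense)
  cnt[names(named)] <- named
  list(counts = cnt)
}

test_that("codon counting excludes untyped and stop codons and normalises case", {
  cc <- count_codons("ATGAAATTT")
  expect_equal(unname(cc$counts[c("ATG", "AAA", "TTT")]), c(1L, 1L, 1L))
  expect_equal(cc$n_codons_typed, 3L)
  expect_equal(cc$n_codons_excluded, 0L)

  cc2 <- count_codons("ATGA-ATTT")
  expect_equal(unname(cc2$counts["ATG"]), 1L)
  expect_equal(cc2$n_codons_typed, 2L)
  expect_equal(cc2$n_codons_excluded, 1L)

  expect_equal(count_codons("atgaaattt")$counts, cc$counts)
  expect_equal(count_codons("ATGTAAAAA")$n_codons_excluded, 1L)
})

test_that("RSCU matches hand arithmetic and sums to family size", {
  r <- rscu(make_counts(c(TTT = 3L, TTC = 1L)))
  expect_equal(unname(r["TTT"]), 1.5)
  expect_equal(unname(r["TTC"]), 0.5)
  expect_true(is.na(r["GGG"]))  # zero-usage family is missing, not 0

  # uniform usage in every family -> all RSCU 1
  uni <- stats::setNames(rep(5L, 61), sense)
  expect_equal(unname(rscu(list(counts = uni))), rep(1, 61))

  # property: family sums equal family size for random counts
  set.seed(1)
  for (rep in 1:20) {
    cnt <- stats::setNames(rpois(61, 4), sense)
    r <- rscu(list(counts = cnt))
    for (fam in families) {
      if (sum(cnt[fam]) > 0)
        expect_equal(sum(r[fam]), length(fam))
    }
  }
})

test_that("Nc hits its boundary cases and stays in [20, 61]", {
  uni <- stats::setNames(rep(1000L, 61), sense)
  expect_equal(effective_number_of_codons(list(counts = uni)), 61)

  one <- stats::setNames(rep(0L, 61), sense)
  one[vapply(families, `[`, character(1), 1)] <- 1000L
  expect_equal(effective_number_of_codons(list(counts = one)), 20)

  # all 2-fold families with n <= 1 -> missing
  sparse <- stats::setNames(rep(0L, 61), sense)
  deg <- cladon:::codon_tables(1)$degeneracy
  fam2 <- families[deg[names(families)] == 2]
  for (f in families) sparse[f[1]] <- 5L
  for (f in fam2) sparse[f] <- 0L
  expect_true(is.na(effective_number_of_codons(list(counts = sparse))))

  set.seed(2)
  for (rep in 1:25) {
    cnt <- stats::setNames(rpois(61, 8), sense)
    nc <- effective_number_of_codons(list(counts = cnt))
    if (!is.na(nc)) expect_true(nc >= 20 && nc <= 61)
  }
})

test_that("Wright's neutral curve evaluates in closed form", {
  expect_equal(wright_expected_nc(0.5), 60.5)
  expect_equal(wright_expected_nc(0), 31)
  expect_equal(wright_expected_nc(1), 32)
  expect_error(wright_expected_nc(1.2), "in \\[0, 1\\]")
})

test_that("GC and GC3s follow the synonymous-third-position rules", {
  g <- gc_contents("GGGCCC")
  expect_equal(g$gc, 1)
  expect_equal(g$gc3s, 1)
  expect_equal(gc_contents("AAAGGG")$gc3s, 0.5)
  g3 <- gc_contents("ATG")
  expect_true(is.na(g3$gc3s))  # no synonymous third position
  expect_equal(g3$gc, 1 / 3)
})

test_that("PR2 asymmetries use fourfold boxes and are order-invariant", {
  # GGA x10 + GGT x10: A3 = 10, T3 = 10
  expect_equal(pr2_bias(strrep("GGA", 10))$pr2_at, 1)
  s <- paste0(strrep("GGA", 10), strrep("GGT", 10))
  expect_equal(pr2_bias(s)$pr2_at, 0.5)
  s2 <- paste0(strrep("GGA", 3), "GGT")
  expect_equal(pr2_bias(s2)$pr2_at, 0.75)
  # no fourfold codons -> missing (ATG, AAA are not in fourfold boxes)
  p <- pr2_bias("ATGAAA")
  expect_true(is.na(p$pr2_at) && is.na(p$pr2_gc))
  # permutation invariance
  set.seed(3)
  cods <- sample(sense, 60, replace = TRUE)
  a <- pr2_bias(paste(cods, collapse = ""))
  b <- pr2_bias(paste(sample(cods), collapse = ""))
  expect_equal(a, b)
})

test_that("per-gene profiles table carries metadata and all RSCU columns", {
  aln <- codon_alignment(
    c(g1 = "ATGAAATTTGGA", g2 = "ATGAAGTTCGGC"),
    meta = data.frame(gene_id = c("g1", "g2"), clade_label = c("a", "b")))
  prof <- codon_usage_profiles(aln)
  expect_equal(nrow(prof), 2)
  expect_equal(sum(grepl("^rscu_", names(prof))), 61)
  expect_equal(prof$clade_label, c("a", "b"))
  expect_equal(prof$n_codons_typed, c(4L, 4L))
})
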
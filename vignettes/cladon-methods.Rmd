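---
title: "Methods: comparative molecular evolution of clade-structured gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative molecular evolution of clade-structured gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladon)
```

## Scope and motivation

`cladon` implements the comparative molecular-evolution workflow used to
contrast clades of a gene family — the motivating case is the octocoral
terpene cyclases (TCs), a family partitioned into conserved
diterpene-synthase subclades and faster, functionally diverse
sesquiterpene-synthase clades across the two octocoral orders
Malacalcyonacea and Scleralcyonacea. The same questions recur in any
clade-structured family: do clades differ in divergence rate relative to a
conserved reference such as mitochondrial markers, in nucleotide diversity
and allele-frequency spectra, in selective constraint (dN/dS), and in
synonymous codon usage?

Inputs are in-frame coding-sequence alignments (FASTA), trees with branch
lengths (Newick), and gene-to-clade / gene-to-order tables (TSV). All
outputs are plain TSV. A synthetic codon-evolution generator reproduces the
statistical structure the analysis assumes, so every stage is testable
without external data.

## Codon-usage statistics

Per gene, on codons free of gaps/`N` (untyped codons are excluded
codon-wise; stop codons are excluded everywhere):

* **RSCU**: for codon $c$ in a synonymous family of size $k$,
  $\mathrm{RSCU}_c = k\,x_c / \sum_{c'} x_{c'}$. Families with zero usage
  are reported missing rather than zero; the single-codon families ATG and
  TGG are fixed at 1 and excluded from screens.
* **Nc** (Wright's effective number of codons): per family with $n \ge 2$
  observed codons, homozygosity $F = (n\sum p_j^2 - 1)/(n-1)$; $F$ is
  averaged within degeneracy classes (nine 2-fold, one 3-fold, five 4-fold,
  three 6-fold with Leu/Ser/Arg taken as single 6-fold families) and
  $N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$, clamped to
  $[20, 61]$. A missing 3-fold mean is imputed as $(\bar F_2+\bar F_4)/2$,
  following Wright (1990); any other missing or non-positive class mean
  yields a missing Nc — missingness signals insufficient data, never 0.
* The **neutral expectation** plotted against GC3s is
  $N_c = 2 + s + 29/(s^2 + (1-s)^2)$.
* **GC3s** is the G+C fraction at third positions of typed sense codons
  with a synonymous alternative. The field sometimes reports GC3 over all
  third positions; we compute and document GC3s, which differs only through
  ATG/TGG.
* **PR2 asymmetries**: $A_3/(A_3+T_3)$ and $G_3/(G_3+C_3)$ restricted to
  the eight fourfold-degenerate codon boxes (Sueoka's convention). The
  restriction removes amino-acid-level selection from the asymmetry, so 0.5
  is the expectation under unbiased synonymous-site evolution; computing it
  over all third positions would confound composition of the encoded
  protein with mutational asymmetry.

## Population-genetic and selection statistics

$S$, $\pi$ and Watterson's $\theta_W = S/a_1$ use complete deletion (sites
with any gap/`N` in the group are dropped), the usual convention for these
statistics. Tajima's D follows the 1989 variance constants and is reported
missing when $S = 0$ or $n < 4$ — for $n \in \{2,3\}$ the constants are
unstable and a 0 would be misleading.

Pairwise dN/dS uses the Nei–Gojobori (1986) counting estimator: per-codon
synonymous site fractions count, at each position, the fraction of the
three single-nucleotide changes that are synonymous (mutations to stops
excluded from the numerator, kept in the denominator); differences between
codon pairs are averaged over all single-step pathways whose intermediates
are sense codons, and pairs with no stop-free pathway are excluded and
counted (the equal-weighting variant that traverses stops is available via
`exclude_stop_paths = FALSE`). $p_S$ and $p_N$ are Jukes–Cantor corrected;
$\omega = d_N/d_S$ is missing when $d_S = 0$ or a proportion saturates at
$p \ge 3/4$. Codon pairs with gaps are deleted pairwise — unlike the
complete deletion used for $\pi$ — matching the most common convention for
each statistic. No ML codon models are provided; NG86 is a deliberate,
documented choice.

## Clade divergence relative to a reference

For each clade, the mean over all within-clade pairwise Jukes–Cantor
distances is divided by the same quantity over reference sequences
restricted to the species present in that clade (falling back, with a flag,
to all reference pairs). JC on all sites is the minimal correction
consistent with "nucleotide divergence"; `sites = "ff3"` computes the same
ratio on fourfold-degenerate third positions as a synonymous-site
approximation. Aggregation is mean-of-pairs, with saturated pairs dropped
and counted. Under the generator, the fold estimate tracks the simulated
clade-to-reference branch-scale ratio (the multi-seed recovery is exercised
in the test suite).

## Marginal ancestral reconstruction

Ancestral sequences (e.g. the subclade ancestors of a gene-family tree) are
reconstructed by Felsenstein pruning under a reversible model (JC for
nucleotides, Poisson for amino acids, arbitrary reversible matrices
accepted), with the rate matrix scaled to one expected substitution per
unit branch length and exponentiated via spectral decomposition. Marginal
(per-node) posteriors are computed by combining in-subtree partial
likelihoods with an out-subtree preorder pass — equivalent to rerooting at
each node, exact for reversible models. Marginal rather than joint
reconstruction is used because resurrection studies consume per-node MAP
sequences and because it is directly testable against brute-force
enumeration. Gaps are missing data (all-ones partials); MAP ties break by
alphabet order, deterministically; branch lengths are taken as given, never
optimised. Basal multifurcations are accepted as root placements (pulley
principle). Per-site posteriors sum to 1 within 1e-9.

## Group comparisons and the RSCU screen

The sources of the motivating analyses rarely name their tests; we adopt
distribution-free defaults — Mann–Whitney for two groups, Kruskal–Wallis
for more — because per-clade samples are small and non-normal, with a
permutation test on the mean (`permutation_mean_test`) as a sensitivity
check. Exact Mann–Whitney p-values are used for $n_x + n_y \le 12$ without
ties (by the exact Wilcoxon distribution; with ties, by complete
enumeration of labelings), otherwise a normal approximation with tie and
continuity corrections. Kruskal–Wallis on fully tied data returns
$H = 0, p = 1$ by convention. FDR control is Benjamini–Hochberg exactly.

The interclade RSCU screen tests each of the 59 codons with a synonymous
alternative by Kruskal–Wallis across clades on per-gene RSCU, adjusts
across codons by BH, and additionally requires the range of clade-mean
RSCU (means, not medians) to exceed `range_min` (default 0.7, with
`alpha = 0.05`). A codon needs at least two clades with two usable genes.

**Known limitation.** The screen treats genes as exchangeable within
clades. When genes within a clade share recent ancestry (as they do in the
tree-structured scenario generator and in real gene families), within-clade
RSCU values are correlated and the effective sample size is smaller than
the gene count, inflating significance across *all* codons. The screen's
FDR guarantee therefore applies to exchangeable genes; phylogenetically
corrected comparisons (PGLS-style) are out of scope and flagged as the
principled remedy.

For order-level contrasts of $\pi$ and Tajima's D, both groupings — genes
pooled per order, or clade-within-order groups compared across orders —
are exposed (`order_popgen_grouping`), since either is defensible; the
pipeline defaults to clade-within-order groups, which avoids conflating
between-clade divergence with within-order diversity.

## The synthetic-data generator

Two generative models back the tests:

* **Kingman coalescent** (`simulate_coalescent_alignment`): exponential
  coalescence times at rate $\binom{k}{2}$, Poisson
  $(\theta\,L_{tree}/2)$ mutations placed uniformly on branches and sites,
  finite-sites JC change kernel. Finite sites keep outputs valid DNA and
  let $\pi$ saturate realistically; the cost is a small downward bias in
  $S$ and $\pi$ from repeat hits, so the closed-form expectations
  $E[S] = \theta a_1$ and $E[\pi] = \theta$ hold in the low per-site
  $\theta$ regime. The validation suite uses $n = 10$, $\theta = 5$ on a
  3 kb locus (per-site $\theta \approx 0.0017$, the scale of a
  mitochondrial marker such as *mutS*), where the mean of Tajima's D over
  2000 replicates sits within $\pm 0.1$ of 0; at 0.9 kb the repeat-hit
  bias is already visible. These loci are generic DNA, so the generator
  bypasses the coding-frame stop check of the alignment container.
* **MG94-flavoured codon model** (`simulate_codon_evolution`): CTMC on the
  61 sense codons; single-position changes occur at rate
  $\pi_{nt}(\text{target})\,\kappa^{[ts]}\,\omega^{[nonsyn]}$, scaled to 1
  expected substitution per codon site per unit branch length. The
  target-*nucleotide* parameterisation (MG94-style rather than GY94) makes
  `gc_bias` interpretable at mutation level: $\pi_G = \pi_C =$
  `gc_bias`$/2$. Optional per-codon preference weights multiply target
  rates and stationary frequencies (the construction preserves detailed
  balance), providing engineered codon-usage bias for screen validation.
  Stops are not states of the chain, so simulated coding sequences can
  never contain one.

The default gene-family scenario emulates the motivating study's scale:
nine species in two orders (5 + 4) on a balanced ultrametric species tree
(root-to-tip 0.05 substitutions/codon site at scale 1), eight clades — five
conserved "subclade"-like groups at rate scales 0.5–1 with $\omega = 0.1$
and three fast clades at scales 2–3.5 with $\omega = 0.3$ — of 300-codon
genes (one per species), $\kappa = 2$, and a mitochondrial-like reference
at rate scale 1 with $\omega = 0.05$ on the same tree. All randomness flows
from one seed, recorded in every output; identical seeds give
byte-identical bundles.

What the generator does **not** emulate: gene duplication/loss within
clades, recombination, indel evolution, selection on codon usage beyond the
preference weights, demographic change, and among-site rate variation.
Passing tests therefore validate the estimators and their composition, not
the full complexity of real gene families.

## Numerical choices

* Nc is clamped to $[20, 61]$ and never reported above 61; with
  1000 observations per codon the unclamped value is $\approx 61.04$.
* Jukes–Cantor corrections return missing at $p \ge 3/4$ (saturation),
  with reasons carried as counts where aggregated.
* Transition probabilities are computed from a cached symmetrised
  eigendecomposition; negative round-off entries are truncated at 0 and
  rows renormalised.
* Pruning rescales partial likelihoods per site to avoid underflow.
* MAP ties break by alphabet order; `which.max` semantics make this
  deterministic.
* Exact Mann–Whitney enumeration is capped at $\binom{n}{n_x} \le 2\times
  10^5$ labelings; beyond that, exact mode with ties is refused rather
  than silently approximated.

## Problem sizes in the validation suite

The test suite validates at sizes chosen to put Monte-Carlo error well
inside the asserted bands: 200 genes × 300 codons for the PR2 equilibrium
(mean within $0.5 \pm 0.02$); 200 replicates per $\omega$ for NG86 recovery
(median within $[0.85, 1.15]$ at $\omega = 1$; below 0.5 at
$\omega = 0.2$); 2000 coalescent replicates for $E[S]$ (within 3% of
$\theta a_1$) and mean Tajima's D; 20 seeds for the 3× fold-divergence
recovery (median within $[2.5, 3.5]$); 10 seeds of 48 null genes for the
screen's false-positive control. Oracle-equivalence checks are exhaustive
where feasible: all $61 \times 61$ codon pairs for NG86 pathway counts and
all 123 rooted topologies with 3–5 tips for ASR posteriors (tolerance
1e-10).
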
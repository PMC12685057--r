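# Distribution-free group comparisons: Mann-Whitney U, Kruskal-Wallis,
# permutation tests, Benjamini-Hochberg FDR, and the RSCU interclade screen.

#' Mann-Whitney U test (two-sided)
#'
#' `mode = "exact"` uses the exact null distribution (via the Wilcoxon
#' distribution when there are no ties, by complete enumeration of labelings
#' otherwise); `mode = "normal"` uses the normal approximation with tie and
#' continuity corrections. `mode = "auto"` picks exact when
#' `n_x + n_y <= 12` and there are no ties.
#'
#' @param x,y numeric samples (nonempty)
#' @param mode "auto", "exact" or "normal"
#' @return list with `statistic` (U of `x`), `p_value`, `method`, `n_x`,
#'   `n_y`
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (mode == "auto") mode <- if (!ties && N <= 12) "exact" else "normal"

  if (mode == "exact") {
    if (!ties) {
      p <- if (U > nx * ny / 2)
        stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
      else stats::pwilcox(U, nx, ny)
      p <- min(2 * p, 1)
      method <- "mann_whitney_exact"
    } else {
      if (choose(N, nx) > 2e5)
        stop("exact mode with ties infeasible at this sample size")
      sel <- utils::combn(N, nx)
      mu <- nx * ny / 2
      Us <- apply(sel, 2, function(ix)
        sum(r[ix]) - nx * (nx + 1) / 2)
      p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
      method <- "mann_whitney_exact_enumeration"
    }
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(pooled)
    sigma2 <- nx * ny / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)),
               1)
    }
    method <- "mann_whitney_normal"
  }
  list(statistic = U, p_value = p, method = method, n_x = nx, n_y = ny)
}

#' Kruskal-Wallis rank-sum test
#'
#' H with tie correction; p from the chi-square approximation with k-1
#' degrees of freedom. When all pooled values are identical the convention
#' `H = 0, p = 1` is returned.
#'
#' @param groups list of >= 2 nonempty numeric vectors
#' @return list with `statistic` (H), `df`, `p_value`, `method`
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(!vapply(groups, length, integer(1))))
    stop("all groups must be nonempty")
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                method = "kruskal_wallis"))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(pooled, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, method = "kruskal_wallis")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, monotone and clamped at 1, order-preserving
#' relative to the input. `NA`s propagate.
#'
#' @param p_values numeric vector in `[0, 1]`
#' @return adjusted p-values (q-values)
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Permutation test for a difference in group means
#'
#' Two-sided p from `n_perm` random relabelings (plus the observed one, to
#' keep p > 0). A sensitivity-check companion to the rank tests; uses the
#' session RNG, so seed before calling for reproducibility.
#'
#' @param x,y numeric samples
#' @param n_perm number of permutations
#' @return list with `statistic` (mean(x) - mean(y)), `p_value`, `method`
#' @export
permutation_mean_test <- function(x, y, n_perm = 1000) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  obs <- mean(x) - mean(y)
  pooled <- c(x, y); nx <- length(x)
  perm <- replicate(n_perm, {
    ix <- sample.int(length(pooled), nx)
    mean(pooled[ix]) - mean(pooled[-ix])
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(statistic = obs, p_value = p, method = "permutation_mean")
}

#' RSCU interclade screen
#'
#' For each of the 59 testable codons (single-codon families ATG/TGG
#' excluded): Kruskal-Wallis across clades on per-gene RSCU (genes with
#' missing RSCU dropped; a codon needs >= 2 clades with >= 2 usable genes,
#' otherwise its p is `NA`), Benjamini-Hochberg adjustment across codons,
#' and the range (max - min) of clade-mean RSCU. A codon passes when
#' `q_value < alpha` and `rscu_range > range_min`.
#'
#' @param profiles data.frame from [codon_usage_profiles()] (needs
#'   `clade_label` and `rscu_*` columns)
#' @param clade_map optional data.frame (gene_id, clade_label) overriding
#'   the profile clade labels
#' @param alpha FDR threshold (default 0.05)
#' @param range_min clade-mean RSCU range threshold (default 0.7)
#' @param code_id NCBI genetic code id
#' @return data.frame with `codon`, `amino_acid`, `p_value`, `q_value`,
#'   `rscu_range`, `passes`
#' @export
rscu_interclade_screen <- function(profiles, clade_map = NULL, alpha = 0.05,
                                   range_min = 0.7, code_id = 1L) {
  tabs <- codon_tables(code_id)
  clades <- profiles$clade_label
  if (!is.null(clade_map))
    clades <- clade_map$clade_label[match(profiles$gene_id,
                                          clade_map$gene_id)]
  if (length(unique(stats::na.omit(clades))) < 2)
    stop("need >= 2 clades")
  testable <- tabs$sense_codons[
    tabs$degeneracy[tabs$aa_of[tabs$sense_codons]] > 1L]
  rows <- lapply(testable, function(cod) {
    v <- profiles[[paste0("rscu_", cod)]]
    ok <- !is.na(v) & !is.na(clades)
    grp <- split(v[ok], clades[ok])
    means <- vapply(grp, mean, numeric(1))
    usable <- grp[lengths(grp) >= 2]
    pv <- if (length(usable) >= 2) kruskal_wallis(usable)$p_value
          else NA_real_
    data.frame(codon = cod, amino_acid = unname(tabs$aa_of[cod]),
               p_value = pv,
               rscu_range = if (length(means)) max(means) - min(means)
                            else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out$passes <- !is.na(out$q_value) & out$q_value < alpha &
    !is.na(out$rscu_range) & out$rscu_range > range_min
  out[, c("codon", "amino_acid", "p_value", "q_value", "rscu_range",
          "passes")]
}

#' Compare a per-gene (or per-group) metric between two taxonomic orders
#'
#' Two-sided Mann-Whitney test of the metric between the two orders (or a
#' permutation test on the mean as a sensitivity check). Missing metric
#' values are dropped, with counts reported.
#'
#' @param tab data.frame with an `order_label` column and the metric column
#' @param metric column name, e.g. "pr2_at", "pr2_gc", "pi_site",
#'   "tajima_d", "nc", "gc3s"
#' @param method "mann_whitney" or "permutation"
#' @param n_perm permutations when `method = "permutation"`
#' @return list with `metric`, `orders`, `n` (per order, after dropping NA),
#'   `n_dropped`, `statistic`, `p_value`, `method`
#' @export
compare_orders <- function(tab, metric, method = c("mann_whitney",
                                                   "permutation"),
                           n_perm = 1000) {
  method <- match.arg(method)
  if (!metric %in% names(tab)) stop("unknown metric column: ", metric)
  orders <- sort(unique(stats::na.omit(tab$order_label)))
  if (length(orders) != 2)
    stop("exactly 2 orders required, found: ",
         paste(orders, collapse = ", "))
  v <- tab[[metric]]
  keep <- !is.na(v) & !is.na(tab$order_label)
  x <- v[keep & tab$order_label == orders[1]]
  y <- v[keep & tab$order_label == orders[2]]
  if (!length(x) || !length(y)) stop("an order has no usable values")
  res <- if (method == "mann_whitney") mann_whitney_u(x, y)
         else permutation_mean_test(x, y, n_perm)
  list(metric = metric, orders = orders, n = c(length(x), length(y)),
       n_dropped = sum(!keep), statistic = res$statistic,
       p_value = res$p_value, method = res$method)
}
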
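check_subset <- function(x, universe, label) {
  extra <- setdiff(x, universe)
  if (length(extra))
    stop(sprintf("%s contains id(s) outside the universe: %s", label,
                 paste(utils::head(extra, 10), collapse = ", ")))
}

#' Set-overlap test (hypergeometric)
#'
#' Tests whether two unit-id sets drawn from a common universe overlap more
#' (or less) than expected by chance under the hypergeometric null with
#' parameters (universe size, |A|, |B|). Both one-sided p-values are exact
#' tail sums: `p_enrichment = P(X >= |A n B|)`,
#' `p_depletion = P(X <= |A n B|)`. The p-values are symmetric in A and B;
#' the reported overlap fraction `|A n B| / |A|` is not.
#'
#' @param a,b Character (or atomic) vectors of unit ids; subsets of
#'   `universe`.
#' @param universe The id universe (typically all units surviving the
#'   low-signal filter).
#' @param method `"hypergeometric"` (exact, default) or `"permutation"`
#'   (resampling A within the universe, for stratified extensions).
#' @param n_perm,seed Permutation settings.
#' @return An `overlap_result` list: sizes, overlap, fraction, p-values,
#'   method tag.
#' @export
overlap_test <- function(a, b, universe,
                         method = c("hypergeometric", "permutation"),
                         n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  check_subset(a, universe, "A")
  check_subset(b, universe, "B")
  q <- length(intersect(a, b))
  N <- length(universe); mA <- length(a); mB <- length(b)
  if (method == "hypergeometric") {
    p_enr <- stats::phyper(q - 1, mB, N - mB, mA, lower.tail = FALSE)
    p_dep <- stats::phyper(q, mB, N - mB, mA, lower.tail = TRUE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    qs <- vapply(seq_len(n_perm), function(i)
      length(intersect(sample(universe, mA), b)), numeric(1))
    p_enr <- (1 + sum(qs >= q)) / (n_perm + 1)
    p_dep <- (1 + sum(qs <= q)) / (n_perm + 1)
  }
  structure(list(universe_size = N, size_a = mA, size_b = mB, overlap = q,
                 fraction = if (mA > 0) q / mA else NA_real_,
                 p_enrichment = min(p_enr, 1), p_depletion = min(p_dep, 1),
                 method = method),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> |A|=%d |B|=%d |AnB|=%d of %d (fraction %.3f)\n",
              x$size_a, x$size_b, x$overlap, x$universe_size, x$fraction))
  cat(sprintf("  p(enrichment) = %.3g, p(depletion) = %.3g [%s]\n",
              x$p_enrichment, x$p_depletion, x$method))
  invisible(x)
}

#' Exact two-proportion comparison (Fisher)
#'
#' Compares k1/n1 against k2/n2 with Fisher's exact test on the 2x2 table:
#' the two-sided p-value sums the probabilities of all tables (with the
#' observed margins) no more probable than the observed one. The odds ratio
#' is the sample odds ratio, with the Haldane 0.5 correction applied to all
#' cells when any cell is zero.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return List with `p_value`, `odds_ratio`, `haldane` flag, and the table.
#' @export
compare_proportions <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2)
    stop("need 0 <= k <= n and n > 0 in both groups")
  K <- k1 + k2
  support <- max(0, K - n2):min(K, n1)
  probs <- stats::dhyper(support, n1, n2, K)
  p_obs <- stats::dhyper(k1, n1, n2, K)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  cells <- c(k1, n1 - k1, k2, n2 - k2)
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(p_value = p, odds_ratio = or, haldane = haldane,
       table = matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE,
                      dimnames = list(c("group1", "group2"),
                                      c("yes", "no"))))
}

#' Venn counts of two sets in a universe
#' @inheritParams overlap_test
#' @return Named integer vector `(only_a, only_b, both, neither)` summing to
#'   the universe size.
#' @export
venn_counts <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  check_subset(a, universe, "A")
  check_subset(b, universe, "B")
  both <- length(intersect(a, b))
  c(only_a = length(a) - both, only_b = length(b) - both, both = both,
    neither = length(universe) - length(union(a, b)))
}
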
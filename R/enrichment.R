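#' Hypergeometric upper-tail overlap test for two gene sets
#'
#' With `k` shared genes between a query of size `n` and a reference of size
#' `K` drawn from a universe of `N` genes, computes the enrichment tail
#' `P(X >= k)` of the hypergeometric distribution. Terms are accumulated in
#' log space (log-sum-exp over `lchoose` terms) so extreme overlaps (printed
#' p-values of 1e-50 and below) do not underflow.
#'
#' @param query,reference [gene_set()]s (or character vectors of symbols).
#' @param universe_size number of genes in the universe; must be at least
#'   `|query U reference|`. The study universe is never printed with such
#'   overlaps, so this is a required, explicit choice (20000-60000 covers
#'   annotated human genes through all transcripts).
#' @return `list(k, n, K, N, p_upper)` of class `overlap_result`.
#' @export
hypergeometric_overlap <- function(query, reference, universe_size) {
  q <- toupper(as.character(query)); r <- toupper(as.character(reference))
  q <- unique(q); r <- unique(r)
  k <- length(intersect(q, r)); n <- length(q); K <- length(r)
  N <- universe_size
  if (N < length(union(q, r)))
    stop_("universe_size %d smaller than |query U reference| = %d", N, length(union(q, r)))
  p <- hyper_upper_tail(k, n, K, N)
  structure(list(k = k, n = n, K = K, N = N, p_upper = p),
            class = "overlap_result")
}

# P(X >= k) for X ~ Hypergeometric(N, K, n), log-space accumulation
hyper_upper_tail <- function(k, n, K, N) {
  if (k <= 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- k:hi
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lt)
  exp(m + log(sum(exp(lt - m))))
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap: k = %d of query n = %d vs reference K = %d (universe N = %d)\n",
              x$k, x$n, x$K, x$N))
  cat(sprintf("P(X >= k) = %.4e\n", x$p_upper))
  invisible(x)
}

#' Chi-square test with Yates continuity correction on a 2x2 table
#'
#' `chi2 = sum((|O - E| - 0.5)^2 / E)` with the correction clipped at zero
#' whenever `|O - E| < 0.5`; p from the chi-square distribution with 1 df.
#'
#' @param table 2x2 matrix of non-negative integer counts with no zero
#'   marginal.
#' @return `list(statistic, df = 1, p_two_tailed)`.
#' @export
yates_chi2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop_("need a 2x2 table")
  if (any(tab < 0) || any(tab != floor(tab))) stop_("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop_("zero marginal in table")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  adj <- pmax(abs(tab - E) - 0.5, 0)
  chi <- sum(adj^2 / E)
  list(statistic = chi, df = 1L,
       p_two_tailed = pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Cross-tabulate fold-change directions of two contrasts
#'
#' Classifies each gene as up (`logfc > 0`) vs not-up in each contrast and
#' returns the 2x2 table, ready for [yates_chi2()].
#'
#' @param logfc_a,logfc_b named numeric vectors of log fold changes.
#' @param genes [gene_set()] of genes to tabulate; every gene must appear in
#'   both maps.
#' @return 2x2 integer matrix with dimnames `a`/`b` in `up`, `not_up`.
#' @export
direction_contingency <- function(logfc_a, logfc_b, genes) {
  g <- as.character(genes)
  miss <- setdiff(g, intersect(names(logfc_a), names(logfc_b)))
  if (length(miss))
    stop_("gene(s) missing from a fold-change map: %s", paste(miss, collapse = ", "))
  up_a <- factor(logfc_a[g] > 0, levels = c(TRUE, FALSE), labels = c("up", "not_up"))
  up_b <- factor(logfc_b[g] > 0, levels = c(TRUE, FALSE), labels = c("up", "not_up"))
  tab <- table(a = up_a, b = up_b)
  matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
}
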
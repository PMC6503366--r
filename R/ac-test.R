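#' Audic-Claverie point probability p(y|x)
#'
#' Probability of observing `y` reads for a gene in the second library given
#' `x` reads in the first, under the Audic-Claverie model for two libraries
#' of depths `N1` and `N2`:
#' \deqn{p(y|x) = (N_2/N_1)^y \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}}
#' Evaluated in log-space via `lgamma`, so it is overflow-free for counts of
#' any realistic magnitude. Over `y`, this is the negative-binomial
#' distribution with size `x + 1` and success probability `N1 / (N1 + N2)`,
#' which is what makes the normalization \eqn{\sum_y p(y|x) = 1} exact.
#'
#' @param y nonnegative count(s) in the second library.
#' @param x nonnegative count(s) in the first library.
#' @param N1,N2 positive library totals for the first and second library.
#' @return `p(y|x)` in (0, 1), vectorized over `x` and `y`.
#' @examples
#' ac_point_prob(0, 0, 1e6, 1e6)  # 0.5
#' @export
ac_point_prob <- function(y, x, N1, N2) {
  check_ac_input(x, y, N1, N2)
  r <- N2 / N1
  lp <- y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
  exp(lp)
}

check_ac_input <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts x and y must be nonnegative")
  if (any(x != floor(x)) || any(y != floor(y)))
    stop("counts x and y must be integers (raw read counts)")
  if (N1 <= 0 || N2 <= 0) stop("library totals must be positive")
  invisible(NULL)
}

#' Audic-Claverie two-sided p-value
#'
#' For a gene with `x` reads in library 1 (total `N1`) and `y` reads in
#' library 2 (total `N2`), computes the cumulative sum
#' \eqn{S = \sum_{i=0}^{y} p(i|x)} and returns `2*S` when `S <= 0.5` and
#' `2*(1-S)` otherwise, clamped into (0, 1]. The point probabilities are
#' accumulated from `i = 0` upward in log-space; sums use R's
#' extended-precision accumulator. On the `2*(1-S)` branch the complement is
#' never formed by subtraction: the upper tail \eqn{\sum_{i>y} p(i|x)} is
#' summed directly (in geometric-decay chunks until relative convergence),
#' so small p-values keep full relative precision on either branch.
#'
#' The cost per gene is O(y); the function is vectorized over genes.
#'
#' @param x,y nonnegative integer counts (library 1, library 2).
#' @param N1,N2 positive library totals.
#' @return p-value(s) in (0, 1].
#' @examples
#' ac_pvalue(5, 0, 1e6, 1e6)  # 0.03125
#' @export
ac_pvalue <- function(x, y, N1, N2) {
  check_ac_input(x, y, N1, N2)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  r <- N2 / N1
  lr <- log(r)
  l1r <- log1p(r)
  log_point <- function(xg, i) {
    i * lr + lgamma(xg + i + 1) - lgamma(xg + 1) - lgamma(i + 1) -
      (xg + i + 1) * l1r
  }
  p <- vapply(seq_len(n), function(g) {
    S <- sum(exp(log_point(x[g], 0:y[g])))
    if (S <= 0.5) return(2 * S)
    # upper tail, summed directly in chunks; terms decay at least
    # geometrically once i exceeds the mode, so convergence is fast
    tail_sum <- 0
    from <- y[g] + 1
    repeat {
      chunk <- sum(exp(log_point(x[g], from:(from + 63L))))
      tail_sum <- tail_sum + chunk
      if (chunk < 1e-17 * tail_sum || chunk == 0) break
      from <- from + 64L
    }
    2 * tail_sum
  }, numeric(1L))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment with an explicit test count
#'
#' Step-up FDR adjustment over a (possibly partial) list of p-values with the
#' total number of tests `m_total` supplied explicitly, as needed when only
#' the smallest p-values of a larger family are at hand (e.g. the printed
#' rows of a pathway table out of all tested pathways). Delegates to
#' [stats::p.adjust()] with `n = m_total`; values are returned in input
#' order, capped at 1.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @param m_total total number of tests; must be at least `length(pvalues)`.
#' @return adjusted p-values (FDR / Q values) in input order.
#' @export
bh_adjust <- function(pvalues, m_total = length(pvalues)) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  if (m_total < length(pvalues))
    stop("m_total must be at least the number of p-values")
  stats::p.adjust(pvalues, method = "BH", n = m_total)
}

#' Call differentially expressed genes
#'
#' Threshold rule of the two-library analysis: a gene is `up` when its FDR is
#' at or below `fdr_threshold` and its log2 ratio (pregnant/nonpregnant) is
#' at or above `lfc_threshold`; `down` symmetrically; otherwise
#' `not_significant`.
#'
#' @param log2_ratio per-gene log2 ratios.
#' @param fdr per-gene BH-adjusted p-values.
#' @param fdr_threshold FDR cutoff (default 0.001).
#' @param lfc_threshold absolute log2-ratio cutoff (default 1).
#' @return character vector in `{"up", "down", "not_significant"}`.
#' @export
call_degs <- function(log2_ratio, fdr, fdr_threshold = 0.001,
                      lfc_threshold = 1.0) {
  if (length(log2_ratio) != length(fdr))
    stop("log2_ratio and fdr must have equal length")
  out <- rep("not_significant", length(fdr))
  sig <- !is.na(fdr) & fdr <= fdr_threshold
  out[sig & log2_ratio >= lfc_threshold] <- "up"
  out[sig & log2_ratio <= -lfc_threshold] <- "down"
  out
}

#' Detect library-specific genes
#'
#' A gene is specifically expressed in one library when it has at least
#' `min_count` reads there and exactly zero reads in the other. Library A is
#' the nonpregnant library and B the pregnant one.
#'
#' @param count_a,count_b nonnegative counts in libraries A and B.
#' @param min_count minimum count to call a gene "expressed" (default 1).
#' @return character vector in `{"none", "pregnant_only",
#'   "nonpregnant_only"}`.
#' @export
detect_specific <- function(count_a, count_b, min_count = 1L) {
  if (min_count < 1) stop("min_count must be a positive integer")
  if (any(count_a < 0) || any(count_b < 0)) stop("counts must be nonnegative")
  out <- rep("none", max(length(count_a), length(count_b)))
  out[count_a == 0 & count_b >= min_count] <- "pregnant_only"
  out[count_b == 0 & count_a >= min_count] <- "nonpregnant_only"
  out
}

#' Two-library differential-expression test
#'
#' Runs the full per-gene analysis on a count table: RPKM and log2 ratio,
#' Audic-Claverie p-value (x = nonpregnant count, y = pregnant count,
#' N1/N2 = the library totals), BH FDR over all tested genes, DEG calls at
#' the given thresholds, and the library-specificity flag.
#'
#' Genes with zero counts in both libraries carry no information for the test
#' and are excluded; their number is attached as attribute `n_untested`.
#'
#' @param counts a [count_table()].
#' @param fdr_threshold,lfc_threshold DEG thresholds (defaults 0.001 and 1).
#' @param min_count minimum count for the specificity call.
#' @param zero_floor passed to [rpkm_table()].
#' @return data.frame with columns `(gene_id, count_np, count_p, rpkm_np,
#'   rpkm_p, log2_ratio, p_value, fdr, call, specific)`, sorted by `fdr`,
#'   then decreasing `|log2_ratio|`, then `gene_id`.
#' @export
de_test <- function(counts, fdr_threshold = 0.001, lfc_threshold = 1.0,
                    min_count = 1L, zero_floor = NULL) {
  stopifnot(inherits(counts, "count_table"))
  totals <- lib_totals(counts)
  expr <- rpkm_table(counts, zero_floor = zero_floor)
  tested <- counts$count_a > 0 | counts$count_b > 0
  p <- rep(NA_real_, nrow(counts))
  p[tested] <- ac_pvalue(counts$count_a[tested], counts$count_b[tested],
                         totals[["lib_total_a"]], totals[["lib_total_b"]])
  fdr <- rep(NA_real_, nrow(counts))
  fdr[tested] <- bh_adjust(p[tested], m_total = sum(tested))
  out <- data.frame(gene_id = counts$gene_id,
                    count_np = counts$count_a,
                    count_p = counts$count_b,
                    rpkm_np = expr$rpkm_a,
                    rpkm_p = expr$rpkm_b,
                    log2_ratio = expr$log2_ratio,
                    p_value = p,
                    fdr = fdr,
                    call = call_degs(expr$log2_ratio, fdr,
                                     fdr_threshold, lfc_threshold),
                    specific = detect_specific(counts$count_a, counts$count_b,
                                               min_count),
                    stringsAsFactors = FALSE)
  out <- out[tested, , drop = FALSE]
  ord <- order(out$fdr, -abs(out$log2_ratio), out$gene_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_untested") <- sum(!tested)
  out
}

#' Write differential-expression results to TSV
#'
#' @param results output of [de_test()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_de_results <- function(results, path) {
  out <- results
  for (col in c("rpkm_np", "rpkm_p", "log2_ratio"))
    out[[col]] <- signif(out[[col]], 6L)
  for (col in c("p_value", "fdr"))
    out[[col]] <- formatC(out[[col]], format = "e", digits = 3L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
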
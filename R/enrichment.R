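#' Construct an annotation set
#'
#' Flat gene-to-term mapping used by the over-representation test. The
#' background universe is the set of genes carrying at least one annotation;
#' no ontology-graph propagation is performed (terms are taken as annotated).
#'
#' @param gene_id,term_id parallel character vectors; one row per
#'   gene-term link (duplicates are collapsed).
#' @param term_label optional named character vector mapping term ids to
#'   human-readable labels.
#' @param category optional named character vector mapping term ids to a
#'   category (e.g. GO-BP/CC/MF or KEGG).
#' @return an `annotation_set`: list with elements `mapping` (data.frame of
#'   unique gene/term pairs), `universe` (character), `term_sizes` (named
#'   integer), `term_label`, `category`.
#' @export
annotation_set <- function(gene_id, term_id, term_label = NULL,
                           category = NULL) {
  if (length(gene_id) != length(term_id))
    stop("gene_id and term_id must have equal length")
  mapping <- unique(data.frame(gene_id = as.character(gene_id),
                               term_id = as.character(term_id),
                               stringsAsFactors = FALSE))
  if (nrow(mapping) == 0L) stop("annotation set is empty")
  sizes <- table(mapping$term_id)
  out <- list(mapping = mapping,
              universe = unique(mapping$gene_id),
              term_sizes = stats::setNames(as.integer(sizes), names(sizes)),
              term_label = term_label,
              category = category)
  class(out) <- "annotation_set"
  out
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes, %d terms, %d links\n",
              length(x$universe), length(x$term_sizes), nrow(x$mapping)))
  invisible(x)
}

#' Read gene-to-term annotations
#'
#' Accepts either a two-column TSV `(gene_id, term_id)` (header optional) or
#' a GMT file (one term per line: term id, description, then member genes).
#'
#' @param path file path.
#' @param format `"tsv"` or `"gmt"`.
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad) > 0L)
      stop("GMT line ", bad[1L], " has fewer than 3 fields")
    term <- vapply(parts, `[[`, character(1L), 1L)
    label <- vapply(parts, `[[`, character(1L), 2L)
    genes <- lapply(parts, function(p) p[-(1:2)])
    return(annotation_set(unlist(genes),
                          rep(term, lengths(genes)),
                          term_label = stats::setNames(label, term)))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "", fileEncoding = "UTF-8")
  if (ncol(tab) < 2L) stop("annotation TSV needs two columns (gene_id, term_id)")
  if (identical(tolower(tab[1L, 1L]), "gene_id")) tab <- tab[-1L, , drop = FALSE]
  annotation_set(tab[[1L]], tab[[2L]])
}

#' Upper-tail hypergeometric p-value
#'
#' Probability that at least `m` of `n` drawn genes fall in a term of size
#' `M` within a universe of `N` annotated genes:
#' \deqn{p = P(X \ge m) = 1 - \sum_{i=0}^{m-1}
#'   \binom{M}{i}\binom{N-M}{n-i} / \binom{N}{n}}
#' The upper tail is summed directly in log-space (via `lchoose`), term by
#' term from `i = m` to `min(n, M)`; because the quantity itself is the sum
#' of positive terms, no `1 - CDF` cancellation can occur, which preserves
#' full relative precision for extreme p-values (down to ~1e-300).
#'
#' @param m observed overlap (draws in the term).
#' @param M term size in the universe.
#' @param n number of draws (e.g. annotated DEGs).
#' @param N universe size (genes with any annotation).
#' @return `P(X >= m)` in (0, 1]; `m = 0` gives exactly 1. Vectorized.
#' @examples
#' hypergeom_upper_p(4, 4, 5, 10)  # 6/252
#' @export
hypergeom_upper_p <- function(m, M, n, N) {
  k <- max(length(m), length(M), length(n), length(N))
  m <- rep_len(m, k); M <- rep_len(M, k)
  n <- rep_len(n, k); N <- rep_len(N, k)
  if (any(c(m, M, n, N) < 0)) stop("all counts must be nonnegative")
  if (any(M > N) || any(n > N)) stop("M and n must not exceed N")
  if (any(m > pmin(n, M))) stop("m must not exceed min(n, M)")
  vapply(seq_len(k), function(j) {
    if (m[j] == 0L) return(1)
    i <- m[j]:min(n[j], M[j])
    lt <- lchoose(M[j], i) + lchoose(N[j] - M[j], n[j] - i) -
      lchoose(N[j], n[j])
    min(sum(exp(lt)), 1)
  }, numeric(1L))
}

#' Over-representation analysis of a gene set
#'
#' For every term with at least one annotated gene in `deg_genes`, tests
#' whether the overlap exceeds what a hypergeometric draw from the annotated
#' universe would give. `N` is the universe size, `n` the number of
#' `deg_genes` present in the universe (genes without any annotation are
#' dropped, with a message); terms with zero overlap are not tested and do
#' not count toward the Bonferroni factor.
#'
#' @param deg_genes character vector of genes of interest (e.g. DEGs).
#' @param annotations an [annotation_set()].
#' @param correction `"bonferroni"` (GO-style) or `"bh"` (KEGG-style Q
#'   values).
#' @param alpha significance threshold on the corrected p (default 0.05).
#' @param m_total for `"bh"`: total number of tests in the family, when it
#'   exceeds the number of terms actually listed (e.g. all pathways with an
#'   annotated DEG). Defaults to the number of tested terms.
#' @return data.frame with one row per tested term: `(term_id, label, N, n,
#'   M, m, p_raw, p_corrected, significant)`, sorted by `p_raw` then
#'   `term_id`.
#' @export
enrich <- function(deg_genes, annotations, correction = c("bonferroni", "bh"),
                   alpha = 0.05, m_total = NULL) {
  correction <- match.arg(correction)
  stopifnot(inherits(annotations, "annotation_set"))
  deg_genes <- unique(as.character(deg_genes))
  N <- length(annotations$universe)
  if (N == 0L) stop("annotation universe is empty")
  in_universe <- deg_genes %in% annotations$universe
  if (any(!in_universe))
    message(sum(!in_universe), " gene(s) of interest lack annotations and were dropped")
  deg <- deg_genes[in_universe]
  n <- length(deg)
  hits <- annotations$mapping[annotations$mapping$gene_id %in% deg, ]
  m_by_term <- table(hits$term_id)
  terms <- names(m_by_term)
  if (length(terms) == 0L) {
    return(data.frame(term_id = character(), label = character(),
                      N = integer(), n = integer(), M = integer(),
                      m = integer(), p_raw = numeric(),
                      p_corrected = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  m <- as.integer(m_by_term)
  M <- annotations$term_sizes[terms]
  p_raw <- hypergeom_upper_p(m, M, n, N)
  n_tested <- length(terms)
  p_corr <- switch(correction,
    bonferroni = pmin(1, p_raw * n_tested),
    bh = bh_adjust(p_raw, m_total = if (is.null(m_total)) n_tested
                                    else m_total))
  label <- if (!is.null(annotations$term_label))
    unname(annotations$term_label[terms]) else terms
  out <- data.frame(term_id = terms, label = label,
                    N = N, n = n, M = as.integer(M), m = m,
                    p_raw = p_raw, p_corrected = p_corr,
                    significant = p_corr <= alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' KEGG-style Q values
#'
#' BH adjustment of pathway p-values with the family size set to the total
#' number of pathways carrying at least one annotated DEG, which may exceed
#' the number of pathways listed (only the most significant rows of a
#' pathway table are usually printed).
#'
#' @param p_raw raw hypergeometric p-values.
#' @param total_pathways total number of pathways in the family.
#' @return Q values in input order.
#' @export
kegg_qvalues <- function(p_raw, total_pathways) {
  bh_adjust(p_raw, m_total = total_pathways)
}
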
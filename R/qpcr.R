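#' Construct a qPCR Ct panel
#'
#' Replicate-level threshold-cycle (Ct) measurements for target genes and a
#' designated reference gene (default GAPDH) in the two conditions. Each
#' (condition, gene) must carry at least two replicates and the reference
#' must be measured in both conditions; replicate indices pair target and
#' reference measurements from the same run.
#'
#' @param condition character vector in `{"pregnant", "nonpregnant"}`.
#' @param gene_id character vector of gene ids.
#' @param replicate integer replicate index within (condition, gene).
#' @param ct numeric Ct values (cycles).
#' @param reference_gene id of the reference gene (default `"GAPDH"`).
#' @return a `qpcr_panel`: data.frame with columns `condition`, `gene_id`,
#'   `replicate`, `ct` and attribute `reference_gene`.
#' @export
qpcr_panel <- function(condition, gene_id, replicate, ct,
                       reference_gene = "GAPDH") {
  n <- length(ct)
  if (length(condition) != n || length(gene_id) != n || length(replicate) != n)
    stop("condition, gene_id, replicate and ct must have equal length")
  if (!all(condition %in% c("pregnant", "nonpregnant")))
    stop("condition must be 'pregnant' or 'nonpregnant'")
  out <- data.frame(condition = condition, gene_id = as.character(gene_id),
                    replicate = as.integer(replicate), ct = as.numeric(ct),
                    stringsAsFactors = FALSE)
  reps <- stats::aggregate(replicate ~ condition + gene_id, out, length)
  if (any(reps$replicate < 2L))
    stop("every (condition, gene) needs at least 2 replicates")
  ref_conditions <- unique(out$condition[out$gene_id == reference_gene])
  if (!all(c("pregnant", "nonpregnant") %in% ref_conditions))
    stop("reference gene '", reference_gene,
         "' must be measured in both conditions")
  attr(out, "reference_gene") <- reference_gene
  class(out) <- c("qpcr_panel", "data.frame")
  out
}

#' Read a qPCR panel from TSV
#'
#' Expects columns `(condition, gene_id, replicate, ct)` with a header.
#'
#' @param path file path.
#' @param reference_gene reference gene id (default `"GAPDH"`).
#' @return a [qpcr_panel()].
#' @export
read_qpcr_table <- function(path, reference_gene = "GAPDH") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           fileEncoding = "UTF-8")
  required <- c("condition", "gene_id", "replicate", "ct")
  if (!all(required %in% names(tab)))
    stop("qPCR table must have columns: ", paste(required, collapse = ", "))
  qpcr_panel(tab$condition, tab$gene_id, tab$replicate, tab$ct,
             reference_gene = reference_gene)
}

#' Relative expression by the 2^-ddCt method
#'
#' For one target gene: per condition, replicate-level dCt values are the
#' target Ct minus the reference Ct of the same replicate index; the
#' condition dCt is their mean, ddCt = dCt(pregnant) - dCt(nonpregnant),
#' and the relative expression ratio (pregnant over nonpregnant) is
#' 2^-ddCt. A two-sample t-test (Student's by default, Welch optional)
#' compares the replicate dCt values between conditions.
#'
#' Because the reference Ct is subtracted within each condition, adding any
#' constant to all Ct values of one condition leaves the ratio unchanged.
#'
#' @param panel a [qpcr_panel()].
#' @param gene target gene id (must differ from the reference gene).
#' @param var_equal use the equal-variance Student's t-test (default TRUE).
#' @return list with `ratio`, `log2_ratio`, `ddct`, `p_value`,
#'   `significant` (p < 0.05), and `replicate_ratios` (pregnant-replicate
#'   ratios against the mean nonpregnant dCt).
#' @export
ddct_ratio <- function(panel, gene, var_equal = TRUE) {
  stopifnot(inherits(panel, "qpcr_panel"))
  ref <- attr(panel, "reference_gene")
  if (identical(gene, ref)) stop("target gene must differ from the reference")
  if (!gene %in% panel$gene_id) stop("gene '", gene, "' not in panel")
  dct <- function(cond) {
    tgt <- panel[panel$condition == cond & panel$gene_id == gene, ]
    rf <- panel[panel$condition == cond & panel$gene_id == ref, ]
    if (nrow(tgt) < 2L) stop("fewer than 2 replicates for ", gene, " in ", cond)
    i <- match(tgt$replicate, rf$replicate)
    if (anyNA(i)) stop("replicate indices of ", gene,
                       " and the reference do not pair in ", cond)
    tgt$ct - rf$ct[i]
  }
  dct_p <- dct("pregnant")
  dct_np <- dct("nonpregnant")
  ddct <- mean(dct_p) - mean(dct_np)
  # degenerate noise-free panels have zero within-group variance; the t
  # statistic is then +/-Inf (p = 0) for any mean difference, 1 for none
  if (stats::var(dct_p) == 0 && stats::var(dct_np) == 0) {
    p_value <- if (ddct == 0) 1 else 0
  } else {
    p_value <- stats::t.test(dct_p, dct_np, var.equal = var_equal)$p.value
  }
  list(ratio = 2^(-ddct),
       log2_ratio = -ddct,
       ddct = ddct,
       p_value = p_value,
       significant = p_value < 0.05,
       replicate_ratios = 2^(-(dct_p - mean(dct_np))))
}

#' 2^-ddCt summary for every target gene in a panel
#'
#' @param panel a [qpcr_panel()].
#' @param var_equal use the equal-variance Student's t-test (default TRUE).
#' @return data.frame `(gene_id, ratio, log2_ratio, p_value, significant)`,
#'   one row per non-reference gene, in panel order.
#' @export
ddct_table <- function(panel, var_equal = TRUE) {
  stopifnot(inherits(panel, "qpcr_panel"))
  genes <- setdiff(unique(panel$gene_id), attr(panel, "reference_gene"))
  rows <- lapply(genes, function(g) {
    r <- ddct_ratio(panel, g, var_equal = var_equal)
    data.frame(gene_id = g, ratio = r$ratio, log2_ratio = r$log2_ratio,
               p_value = r$p_value, significant = r$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
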
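#' Read a pipeline configuration
#'
#' YAML document with any of the keys below (all optional; missing keys take
#' the defaults shown by [default_pipeline_config()]):
#'
#' * `counts`, `annotations`, `qpcr`: input file paths. When `counts` is
#'   absent, the `simulate` block is used to generate data instead.
#' * `simulate`: named arguments for [simulation_config()].
#' * `fdr_threshold`, `lfc_threshold`, `min_count`: DEG-calling thresholds.
#' * `enrichment_correction` (`"bonferroni"` or `"bh"`), `enrichment_alpha`.
#' * `seed`: integer seed (overrides `simulate$seed`).
#'
#' @param path YAML file path.
#' @return a pipeline-config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_pipeline_config(), cfg)
}

#' Default pipeline configuration
#'
#' @return list of default thresholds and options (see
#'   [read_pipeline_config()]).
#' @export
default_pipeline_config <- function() {
  list(counts = NULL, annotations = NULL, qpcr = NULL,
       simulate = list(),
       fdr_threshold = 0.001, lfc_threshold = 1.0, min_count = 1L,
       enrichment_correction = "bh", enrichment_alpha = 0.05,
       seed = 1L)
}

#' Run the two-library analysis pipeline
#'
#' Executes simulate (or load) -> RPKM -> Audic-Claverie test -> DEG calls
#' -> optional enrichment -> optional qPCR, writing one TSV per stage plus a
#' key/value summary to `out_dir`. The same config and seed always produce
#' byte-identical outputs.
#'
#' Files written: `counts.tsv`, `truth.tsv` (simulated runs only),
#' `expression.tsv`, `de_results.tsv`, `enrichment.tsv` (when annotations
#' are available), `qpcr_results.tsv` (when a panel is available), and
#' `summary.tsv`.
#'
#' @param config a config list as returned by [read_pipeline_config()] /
#'   [default_pipeline_config()], or a path to a YAML config.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage progress messages.
#' @return the summary as a named list, invisibly; also written to
#'   `summary.tsv`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  truth <- NULL
  if (is.null(config$counts)) {
    sim_args <- config$simulate
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    sim_cfg <- do.call(simulation_config, sim_args)
    sim <- generate_counts(sim_cfg)
    counts <- sim$counts
    truth <- sim$truth
    write_count_table(counts, file.path(out_dir, "counts.tsv"))
    write_ground_truth(truth, file.path(out_dir, "truth.tsv"))
    say("simulate: %d genes, library totals %.0f / %.0f",
        nrow(counts), sum(counts$count_a), sum(counts$count_b))
  } else {
    counts <- read_count_table(config$counts)
    say("load: %d genes read from %s", nrow(counts), config$counts)
  }

  expr <- rpkm_table(counts)
  write_expression(expr, file.path(out_dir, "expression.tsv"))

  de <- de_test(counts,
                fdr_threshold = config$fdr_threshold,
                lfc_threshold = config$lfc_threshold,
                min_count = config$min_count)
  write_de_results(de, file.path(out_dir, "de_results.tsv"))
  say("detest: %d genes tested, %d untested (zero in both libraries)",
      nrow(de), attr(de, "n_untested"))

  summary <- list(
    genes_total = nrow(counts),
    genes_tested = nrow(de),
    genes_untested = attr(de, "n_untested"),
    deg_total = sum(de$call != "not_significant"),
    deg_up = sum(de$call == "up"),
    deg_down = sum(de$call == "down"),
    specific_pregnant = sum(de$specific == "pregnant_only"),
    specific_nonpregnant = sum(de$specific == "nonpregnant_only")
  )
  say("degs: %d (%d up, %d down); specific: %d pregnant-only, %d nonpregnant-only",
      summary$deg_total, summary$deg_up, summary$deg_down,
      summary$specific_pregnant, summary$specific_nonpregnant)

  if (!is.null(config$annotations)) {
    ann <- if (inherits(config$annotations, "annotation_set"))
      config$annotations else read_annotations(config$annotations)
    deg_genes <- de$gene_id[de$call != "not_significant"]
    enr <- enrich(deg_genes, ann,
                  correction = config$enrichment_correction,
                  alpha = config$enrichment_alpha)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    summary$terms_tested <- nrow(enr)
    summary$terms_significant <- sum(enr$significant)
    say("enrich: %d terms tested, %d significant at corrected p <= %g",
        nrow(enr), sum(enr$significant), config$enrichment_alpha)
  }

  if (!is.null(config$qpcr)) {
    panel <- if (inherits(config$qpcr, "qpcr_panel")) config$qpcr
             else read_qpcr_table(config$qpcr)
    qp <- ddct_table(panel)
    utils::write.table(qp, file.path(out_dir, "qpcr_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    summary$qpcr_genes = nrow(qp)
    say("qpcr: %d target genes quantified", nrow(qp))
  }

  utils::write.table(
    data.frame(key = names(summary),
               value = unlist(summary, use.names = FALSE)),
    file.path(out_dir, "summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(summary)
}

#' Format a pathway-enrichment report from printed inputs
#'
#' Rebuilds a publication-style pathway table — overlap percentages, raw
#' hypergeometric p and BH Q value — from the raw ingredients `(label, m,
#' M, pathway_id)` plus the universe sizes `N` (all annotated genes), `n`
#' (annotated DEGs) and the total number of tested pathways. This lets a
#' printed table be recomputed and diffed directly.
#'
#' Input may be a data.frame or a TSV path with header columns
#' `(pathway, m, M, pathway_id)`; the TSV may carry `#N=`, `#n=` and
#' `#total_pathways=` metadata lines which serve as defaults for the
#' corresponding arguments.
#'
#' @param x data.frame or TSV path.
#' @param N,n universe size and DEG-draw size (required if not in metadata).
#' @param total_pathways BH family size (defaults to `nrow(x)` if absent).
#' @param path optional output TSV path.
#' @return data.frame `(pathway, m, m_pct_of_n, M, M_pct_of_N, p_value,
#'   q_value, pathway_id)`, sorted by `p_value` then `pathway_id`;
#'   percentages rounded to 2 decimals, p and Q formatted to 3 significant
#'   digits in the written file.
#' @export
report_table3 <- function(x, N = NULL, n = NULL, total_pathways = NULL,
                          path = NULL) {
  if (is.character(x)) {
    lines <- readLines(x, encoding = "UTF-8")
    for (kv in sub("^#\\s*", "", grep("^#", lines, value = TRUE))) {
      if (grepl("^N=", kv) && is.null(N)) N <- as.integer(sub("^N=", "", kv))
      if (grepl("^n=", kv) && is.null(n)) n <- as.integer(sub("^n=", "", kv))
      if (grepl("^total_pathways=", kv) && is.null(total_pathways))
        total_pathways <- as.integer(sub("^total_pathways=", "", kv))
    }
    x <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           quote = "")
  }
  required <- c("pathway", "m", "M", "pathway_id")
  if (!all(required %in% names(x)))
    stop("pathway table needs columns: ", paste(required, collapse = ", "))
  if (is.null(N) || is.null(n))
    stop("universe size N and DEG count n are required")
  if (is.null(total_pathways)) total_pathways <- nrow(x)
  p <- hypergeom_upper_p(x$m, x$M, n, N)
  q <- kegg_qvalues(p, total_pathways)
  out <- data.frame(pathway = x$pathway,
                    m = x$m, m_pct_of_n = round(100 * x$m / n, 2L),
                    M = x$M, M_pct_of_N = round(100 * x$M / N, 2L),
                    p_value = p, q_value = q,
                    pathway_id = x$pathway_id,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    fmt <- out
    fmt$p_value <- formatC(fmt$p_value, format = "e", digits = 2L)
    fmt$q_value <- formatC(fmt$q_value, format = "e", digits = 2L)
    utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  out
}
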
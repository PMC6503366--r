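#' Simulation configuration for two-library count data
#'
#' Defines the generative model used throughout the package's calibration
#' studies. The defaults mirror the ovary study design this package targets:
#' ~20,651 expressed genes, two pooled libraries of ~13.5-13.7 million
#' mapped reads (library A nonpregnant, library B pregnant), ~8.3% of genes
#' truly differential with ~60% of those up in the pregnant library, and
#' 7.1% / 9.7% of genes expressed in only one library.
#'
#' Counts are Negative Binomial with mean from a log-normal abundance
#' profile and a single dispersion knob; `dispersion = 0` reduces to
#' Poisson. Gene lengths are uniform on `gene_length_range` (RPKM
#' correctness is tested independently of the length distribution).
#'
#' @param n_genes number of genes.
#' @param lib_size_a,lib_size_b expected total reads per library
#'   (nonpregnant, pregnant).
#' @param frac_de fraction of genes with true differential expression.
#' @param lfc_mean,lfc_sd mean and sd of the true |log2 fold change| of DE
#'   genes (draws are truncated at 0).
#' @param prop_up fraction of DE genes up-regulated in the pregnant library.
#' @param dispersion NB dispersion (1/size); 0 gives Poisson sampling.
#' @param frac_specific_a,frac_specific_b fractions of genes expressed only
#'   in library A (nonpregnant) / only in library B (pregnant).
#' @param gene_length_range integer range (bp) for uniform gene lengths.
#' @param abundance_sdlog sd of the log-normal relative-abundance profile
#'   (heavier right tail for larger values).
#' @param seed integer seed; all draws of [generate_counts()] flow from it.
#' @return a validated `simulation_config` (list).
#' @export
simulation_config <- function(n_genes = 20651L,
                              lib_size_a = 13549560,
                              lib_size_b = 13676394,
                              frac_de = 0.083,
                              lfc_mean = 2, lfc_sd = 0.5,
                              prop_up = 0.6,
                              dispersion = 0.1,
                              frac_specific_a = 0.071,
                              frac_specific_b = 0.097,
                              gene_length_range = c(200L, 10000L),
                              abundance_sdlog = 1.2,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              lib_size_a = lib_size_a, lib_size_b = lib_size_b,
              frac_de = frac_de, lfc_mean = lfc_mean, lfc_sd = lfc_sd,
              prop_up = prop_up, dispersion = dispersion,
              frac_specific_a = frac_specific_a,
              frac_specific_b = frac_specific_b,
              gene_length_range = as.integer(gene_length_range),
              abundance_sdlog = abundance_sdlog,
              seed = as.integer(seed))
  fracs <- c(cfg$frac_de, cfg$frac_specific_a, cfg$frac_specific_b)
  if (cfg$n_genes < 1L) stop("n_genes must be positive")
  if (cfg$lib_size_a <= 0 || cfg$lib_size_b <= 0)
    stop("library sizes must be positive")
  if (any(fracs < 0) || any(fracs > 1) || sum(fracs) > 1)
    stop("fractions must lie in [0,1] and sum to at most 1")
  if (cfg$prop_up < 0 || cfg$prop_up > 1) stop("prop_up must lie in [0,1]")
  if (cfg$dispersion < 0) stop("dispersion must be nonnegative")
  if (length(cfg$gene_length_range) != 2L ||
      cfg$gene_length_range[1L] < 1L ||
      diff(cfg$gene_length_range) < 0)
    stop("gene_length_range must be an increasing pair of positive integers")
  class(cfg) <- "simulation_config"
  cfg
}

# uniform integer draw on [lo, hi]; safe when lo == hi (sample() would
# otherwise treat a scalar as 1:n)
sample_int_range <- function(range, n) {
  range[1L] + sample.int(range[2L] - range[1L] + 1L, n, replace = TRUE) - 1L
}

# NB (or Poisson) draw with mean mu; dispersion = 1/size
r_counts <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

# zero-truncated draw via inverse CDF: u ~ U(P(X=0), 1), then quantile
r_counts_positive <- function(n, mu, dispersion) {
  if (n == 0L) return(integer(0))
  if (dispersion <= 0) {
    p0 <- stats::dpois(0, mu)
    stats::qpois(stats::runif(n, p0, 1), mu)
  } else {
    size <- 1 / dispersion
    p0 <- stats::dnbinom(0, mu = mu, size = size)
    stats::qnbinom(stats::runif(n, p0, 1), mu = mu, size = size)
  }
}

#' Generate a two-library count table with known ground truth
#'
#' Draws per-gene relative abundances from a log-normal profile, assigns
#' gene labels (`null`, `up`, `down`, `specific_a`, `specific_b`) according
#' to the configured fractions, scales expected counts so each library's
#' expected total equals its configured size, and samples NB (or Poisson)
#' counts. Genes labelled `specific_a` are guaranteed at least one read in
#' library A and exactly zero in library B (zero-truncated sampling), and
#' symmetrically for `specific_b`.
#'
#' The same `config` (including its seed) always reproduces the identical
#' table and truth.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (a [count_table()]) and `truth` (data.frame
#'   `gene_id`, `label`, `true_mean_a`, `true_mean_b`, `true_lfc`; `true_lfc`
#'   is `NA` for library-specific genes).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("gene%05d", seq_len(n))
  length_bp <- sample_int_range(config$gene_length_range, n)

  n_de <- round(n * config$frac_de)
  n_sa <- round(n * config$frac_specific_a)
  n_sb <- round(n * config$frac_specific_b)
  label <- rep("null", n)
  idx <- sample.int(n, n_de + n_sa + n_sb)
  de_idx <- idx[seq_len(n_de)]
  label[idx[n_de + seq_len(n_sa)]] <- "specific_a"
  label[idx[n_de + n_sa + seq_len(n_sb)]] <- "specific_b"
  lfc <- rep(0, n)
  if (n_de > 0L) {
    magnitude <- abs(stats::rnorm(n_de, config$lfc_mean, config$lfc_sd))
    sign_up <- stats::runif(n_de) < config$prop_up
    lfc[de_idx] <- ifelse(sign_up, magnitude, -magnitude)
    label[de_idx] <- ifelse(sign_up, "up", "down")
  }

  w <- stats::rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
  w_a <- w * (label != "specific_b")
  w_b <- w * 2^lfc * (label != "specific_a")
  mu_a <- config$lib_size_a * w_a / sum(w_a)
  mu_b <- config$lib_size_b * w_b / sum(w_b)

  count_a <- r_counts(n, mu_a, config$dispersion)
  count_b <- r_counts(n, mu_b, config$dispersion)
  is_sa <- label == "specific_a"
  is_sb <- label == "specific_b"
  count_a[is_sa] <- r_counts_positive(sum(is_sa), mu_a[is_sa], config$dispersion)
  count_a[is_sb] <- 0
  count_b[is_sb] <- r_counts_positive(sum(is_sb), mu_b[is_sb], config$dispersion)
  count_b[is_sa] <- 0

  truth <- data.frame(gene_id = gene_id, label = label,
                      true_mean_a = mu_a, true_mean_b = mu_b,
                      true_lfc = ifelse(is_sa | is_sb, NA_real_, lfc),
                      stringsAsFactors = FALSE)
  list(counts = count_table(gene_id, length_bp, count_a, count_b),
       truth = truth)
}

#' Write simulation ground truth to TSV
#'
#' Columns `(gene_id, label, true_lfc)`.
#'
#' @param truth the `truth` element of [generate_counts()] output.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth[, c("gene_id", "label", "true_lfc")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Generate synthetic gene-to-term annotations
#'
#' Builds an annotation set over the simulated genes in which
#' `enriched_terms` terms draw a fraction `enrichment_strength` of their
#' members from the true-DE genes (labels `up`/`down` in `truth`) and the
#' remainder uniformly from the other genes; all other terms are uniform
#' draws from all genes. With `enrichment_strength = 1` a planted term
#' consists solely of true DEGs.
#'
#' @param truth ground-truth data.frame from [generate_counts()].
#' @param n_terms total number of terms.
#' @param enriched_terms number of planted (DE-enriched) terms; these get
#'   term ids `ENR0001, ...`, the rest `TERM0001, ...`.
#' @param enrichment_strength fraction in `[0, 1]` of each planted term's
#'   members drawn from true-DE genes.
#' @param seed integer seed.
#' @param term_size_range integer range of term sizes.
#' @return an [annotation_set()].
#' @export
generate_annotations <- function(truth, n_terms, enriched_terms = 0L,
                                 enrichment_strength = 0,
                                 seed = 1L,
                                 term_size_range = c(10L, 100L)) {
  if (enriched_terms > n_terms || enriched_terms < 0L)
    stop("need 0 <= enriched_terms <= n_terms")
  if (enrichment_strength < 0 || enrichment_strength > 1)
    stop("enrichment_strength must lie in [0, 1]")
  set.seed(seed)
  genes <- truth$gene_id
  de_genes <- genes[truth$label %in% c("up", "down")]
  other_genes <- setdiff(genes, de_genes)
  sizes <- sample_int_range(term_size_range, n_terms)
  term_ids <- c(sprintf("ENR%04d", seq_len(enriched_terms)),
                sprintf("TERM%04d", seq_len(n_terms - enriched_terms)))
  members <- lapply(seq_len(n_terms), function(t) {
    s <- min(sizes[t], length(genes))
    if (t <= enriched_terms) {
      n_de <- min(round(s * enrichment_strength), length(de_genes))
      c(sample(de_genes, n_de),
        sample(other_genes, s - n_de))
    } else {
      sample(genes, s)
    }
  })
  annotation_set(unlist(members), rep(term_ids, lengths(members)))
}

#' Generate a synthetic qPCR Ct panel
#'
#' Constructs replicate Ct measurements for target genes and a reference
#' gene in two conditions such that the expected 2^-ddCt of each target
#' equals its requested true ratio (pregnant over nonpregnant); Gaussian
#' noise with sd `ct_noise_sd` is added independently to every measured Ct.
#'
#' @param true_ratios positive numeric vector of true expression ratios, one
#'   per target gene; names are used as gene ids (default `q1, q2, ...`).
#' @param ct_noise_sd nonnegative per-measurement Ct noise (cycles).
#' @param replicates number of replicates per (condition, gene); >= 2.
#' @param seed integer seed.
#' @param reference_gene reference gene id (default `"GAPDH"`).
#' @param base_ct baseline target Ct in the nonpregnant condition (cycles).
#' @param reference_ct reference-gene Ct in both conditions (cycles).
#' @return a [qpcr_panel()].
#' @export
generate_qpcr_panel <- function(true_ratios, ct_noise_sd = 0.2,
                                replicates = 3L, seed = 1L,
                                reference_gene = "GAPDH",
                                base_ct = 26, reference_ct = 18) {
  if (any(true_ratios <= 0)) stop("true ratios must be positive")
  if (ct_noise_sd < 0) stop("ct_noise_sd must be nonnegative")
  if (replicates < 2L) stop("at least 2 replicates are required")
  set.seed(seed)
  genes <- names(true_ratios)
  if (is.null(genes)) genes <- sprintf("q%d", seq_along(true_ratios))
  all_genes <- c(genes, reference_gene)
  grid <- expand.grid(condition = c("nonpregnant", "pregnant"),
                      gene_id = all_genes,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  base <- stats::setNames(c(rep(base_ct, length(genes)), reference_ct), all_genes)
  # pregnant target Ct lowered by log2(ratio): dCt_p - dCt_np = -log2(ratio)
  shift <- stats::setNames(c(-log2(true_ratios), 0), all_genes)
  mu <- base[grid$gene_id] +
    ifelse(grid$condition == "pregnant", shift[grid$gene_id], 0)
  ct <- mu + if (ct_noise_sd > 0) stats::rnorm(nrow(grid), 0, ct_noise_sd) else 0
  qpcr_panel(grid$condition, grid$gene_id, grid$replicate, as.numeric(ct),
             reference_gene = reference_gene)
}
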
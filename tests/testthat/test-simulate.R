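test_that("all three generators are deterministic under a fixed seed", {
  cfg <- simulation_config(n_genes = 500L, lib_size_a = 1e5, lib_size_b = 1.2e5,
                           seed = 77L)
  s1 <- generate_counts(cfg)
  s2 <- generate_counts(cfg)
  expect_identical(s1, s2)

  a1 <- generate_annotations(s1$truth, n_terms = 20, enriched_terms = 2,
                             enrichment_strength = 0.8, seed = 5L)
  a2 <- generate_annotations(s1$truth, n_terms = 20, enriched_terms = 2,
                             enrichment_strength = 0.8, seed = 5L)
  expect_identical(a1, a2)

  q1 <- generate_qpcr_panel(c(g1 = 2, g2 = 0.5), ct_noise_sd = 0.2, seed = 9L)
  q2 <- generate_qpcr_panel(c(g1 = 2, g2 = 0.5), ct_noise_sd = 0.2, seed = 9L)
  expect_identical(q1, q2)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(frac_de = 0.6, frac_specific_a = 0.3,
                                 frac_specific_b = 0.2), "sum to at most 1")
  expect_error(simulation_config(lib_size_a = 0), "positive")
  expect_error(simulation_config(dispersion = -1), "nonnegative")
  expect_error(simulation_config(frac_de = -0.1), "\\[0,1\\]")
  expect_error(generate_annotations(data.frame(gene_id = "g", label = "null"),
                                    n_terms = 3, enriched_terms = 5),
               "enriched_terms")
  expect_error(generate_annotations(data.frame(gene_id = "g", label = "null"),
                                    n_terms = 3, enrichment_strength = 1.5),
               "enrichment_strength")
  expect_error(generate_qpcr_panel(c(g1 = -2)), "positive")
  expect_error(generate_qpcr_panel(c(g1 = 2), replicates = 1L), "replicates")
})

test_that("specificity labels match the zero-count pattern exactly", {
  cfg <- simulation_config(n_genes = 1000L, lib_size_a = 1e6, lib_size_b = 1e6,
                           frac_de = 0, frac_specific_a = 0.1,
                           frac_specific_b = 0.05, seed = 13L)
  sim <- generate_counts(cfg)
  sa <- sim$truth$label == "specific_a"
  sb <- sim$truth$label == "specific_b"
  expect_equal(sum(sa), 100L)
  expect_equal(sum(sb), 50L)
  expect_true(all(sim$counts$count_a[sa] >= 1))
  expect_true(all(sim$counts$count_b[sa] == 0))
  expect_true(all(sim$counts$count_b[sb] >= 1))
  expect_true(all(sim$counts$count_a[sb] == 0))
  expect_true(all(is.na(sim$truth$true_lfc[sa | sb])))
})

test_that("null Poisson simulations are symmetric and library totals track config", {
  cfg <- simulation_config(n_genes = 2000L, lib_size_a = 1e6, lib_size_b = 1e6,
                           frac_de = 0, dispersion = 0,
                           frac_specific_a = 0, frac_specific_b = 0,
                           seed = 4L)
  sim <- generate_counts(cfg)
  expect_equal(sum(sim$counts$count_a), 1e6, tolerance = 0.01)
  expect_equal(sum(sim$counts$count_b), 1e6, tolerance = 0.01)
  expr <- rpkm_table(sim$counts)
  expect_equal(mean(expr$log2_ratio), 0, tolerance = 0.02)
  # unequal depths scale the totals proportionally
  cfg2 <- simulation_config(n_genes = 2000L, lib_size_a = 5e5, lib_size_b = 2e6,
                            frac_de = 0, dispersion = 0,
                            frac_specific_a = 0, frac_specific_b = 0, seed = 4L)
  sim2 <- generate_counts(cfg2)
  expect_equal(sum(sim2$counts$count_b) / sum(sim2$counts$count_a), 4,
               tolerance = 0.05)
})

test_that("true fold changes drive the observed ratios of DE genes", {
  cfg <- simulation_config(n_genes = 2000L, lib_size_a = 2e6, lib_size_b = 2e6,
                           frac_de = 0.1, lfc_mean = 2, lfc_sd = 0,
                           prop_up = 0.6, dispersion = 0,
                           frac_specific_a = 0, frac_specific_b = 0,
                           seed = 21L)
  sim <- generate_counts(cfg)
  expect_equal(sum(sim$truth$label %in% c("up", "down")), 200L)
  up <- sim$truth$label == "up"
  down <- sim$truth$label == "down"
  expect_equal(sim$truth$true_lfc[up], rep(2, sum(up)))
  expect_equal(sim$truth$true_lfc[down], rep(-2, sum(down)))
  expr <- rpkm_table(sim$counts)
  # observed ratios of DE genes center near the truth (small composition
  # shift from per-library normalization is expected)
  expect_equal(mean(expr$log2_ratio[up]), 2, tolerance = 0.3)
  expect_equal(mean(expr$log2_ratio[down]), -2, tolerance = 0.3)
})

test_that("a fully planted term is recovered as the top enrichment hit", {
  cfg <- simulation_config(n_genes = 2000L, lib_size_a = 1e6, lib_size_b = 1e6,
                           frac_de = 0.1, lfc_mean = 2, lfc_sd = 0,
                           dispersion = 0, frac_specific_a = 0,
                           frac_specific_b = 0, seed = 31L)
  sim <- generate_counts(cfg)
  ann <- generate_annotations(sim$truth, n_terms = 50, enriched_terms = 1,
                              enrichment_strength = 1, seed = 31L,
                              term_size_range = c(50L, 50L))
  expect_equal(unname(ann$term_sizes["ENR0001"]), 50L)
  de <- de_test(sim$counts)
  res <- enrich(de$gene_id[de$call != "not_significant"], ann)
  expect_equal(res$term_id[1L], "ENR0001")
})

test_that("qPCR panels encode the requested true ratios", {
  # noise-free: recovered ratio is exact
  p1 <- generate_qpcr_panel(c(g1 = 1, g2 = 4), ct_noise_sd = 0, seed = 2L)
  expect_equal(ddct_ratio(p1, "g1")$ratio, 1)
  r2 <- ddct_ratio(p1, "g2")
  expect_equal(r2$ddct, -2)
  expect_equal(r2$ratio, 4)
  # Monte Carlo: mean recovered ratio within 5% of truth at sd 0.1
  ratios <- vapply(1:50, function(s) {
    p <- generate_qpcr_panel(c(g = 4), ct_noise_sd = 0.1, replicates = 3L,
                             seed = s)
    ddct_ratio(p, "g")$ratio
  }, numeric(1))
  expect_equal(mean(ratios), 4, tolerance = 0.05)
})

test_that("ground truth writes the documented TSV columns", {
  cfg <- simulation_config(n_genes = 50L, lib_size_a = 1e4, lib_size_b = 1e4,
                           seed = 1L)
  sim <- generate_counts(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(sim$truth, path)
  back <- read.delim(path)
  expect_named(back, c("gene_id", "label", "true_lfc"))
  expect_equal(nrow(back), 50L)
})
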
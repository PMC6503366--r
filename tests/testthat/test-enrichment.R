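test_that("hypergeometric upper tail matches exact small cases", {
  expect_equal(hypergeom_upper_p(0, 4, 5, 10), 1)
  expect_equal(hypergeom_upper_p(4, 4, 5, 10), 6 / 252, tolerance = 1e-14)
  expect_error(hypergeom_upper_p(5, 4, 5, 10), "min\\(n, M\\)")
  expect_error(hypergeom_upper_p(1, 11, 5, 10), "exceed N")
})

test_that("hypergeometric tail agrees with exact enumeration on an N <= 60 grid", {
  for (N in c(10L, 25L, 40L, 60L)) {
    for (M in unique(pmin(N, c(2L, 5L, N %/% 3L, N %/% 2L)))) {
      for (n in unique(pmin(N, c(3L, N %/% 4L, N %/% 2L)))) {
        for (m in 0:min(n, M)) {
          expect_equal(hypergeom_upper_p(m, M, n, N),
                       hyper_upper_enum(m, M, n, N),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("hypergeometric tail is monotone in m and complements the lower tail", {
  N <- 500L; M <- 60L; n <- 80L
  p <- hypergeom_upper_p(0:min(n, M), M, n, N)
  expect_true(all(diff(p) < 0))
  # P(X >= m) + P(X <= m - 1) = 1, with phyper as the independent oracle
  for (m in c(1L, 5L, 20L, 45L)) {
    expect_equal(hypergeom_upper_p(m, M, n, N) +
                   phyper(m - 1, M, N - M, n),
                 1, tolerance = 1e-12)
  }
})

test_that("extreme tails keep full relative precision", {
  # smaller-tail-direct summation: compare against phyper's log tail
  p <- hypergeom_upper_p(51, 235, 1413, 22885)
  log_oracle <- phyper(50, 235, 22885 - 235, 1413, lower.tail = FALSE,
                       log.p = TRUE)
  expect_equal(log(p), log_oracle, tolerance = 1e-10)
})

test_that("enrich computes (N, n, M, m) from the annotation set", {
  ann <- annotation_set(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6", "g1", "g2"),
    term_id = c("T1", "T1", "T1", "T2", "T2", "T2", "T3", "T3"))
  res <- enrich(c("g1", "g2"), ann, correction = "bonferroni")
  expect_equal(unique(res$N), 6L)
  expect_equal(unique(res$n), 2L)
  t3 <- res[res$term_id == "T3", ]
  expect_equal(t3$m, 2L)
  expect_equal(t3$M, 2L)
  expect_equal(t3$p_raw, hyper_upper_enum(2, 2, 2, 6), tolerance = 1e-12)
  # Bonferroni multiplies by the number of tested terms (T2 has m = 0)
  expect_equal(nrow(res), 2L)
  expect_equal(t3$p_corrected, min(1, t3$p_raw * 2))
  # rows sorted by raw p
  expect_true(!is.unsorted(res$p_raw))
})

test_that("genes outside the universe are dropped with a message", {
  ann <- annotation_set(c("g1", "g2", "g3"), c("T1", "T1", "T2"))
  expect_message(res <- enrich(c("g1", "gX"), ann), "dropped")
  expect_equal(unique(res$n), 1L)
})

test_that("Bonferroni with a single tested term leaves p unchanged", {
  ann <- annotation_set(c("g1", "g2", "g3", "g4"), rep("T1", 4))
  res <- enrich(c("g1", "g2"), ann, correction = "bonferroni")
  expect_equal(res$p_corrected, res$p_raw)
})

test_that("KEGG Q values follow BH with the full pathway family size", {
  rows <- table3_rows()
  q <- kegg_qvalues(rows$p_printed, 242)
  # rank 5 is determined directly by its own raw value
  expect_equal(q[5], rows$p_printed[5] * 242 / 5, tolerance = 1e-12)
  expect_equal(kegg_qvalues(rep(1, 4), 10), rep(1, 4))
})

test_that("null annotations give conservative, near-uniform p-values", {
  set.seed(201)
  truth <- data.frame(gene_id = sprintf("g%04d", 1:2000),
                      label = "null", true_lfc = 0,
                      stringsAsFactors = FALSE)
  pvals <- unlist(lapply(1:5, function(s) {
    ann <- generate_annotations(truth, n_terms = 60, seed = s)
    deg <- sample(truth$gene_id, 200)  # an arbitrary, label-free gene set
    enrich(deg, ann, correction = "bh")$p_raw
  }))
  # stochastically >= uniform: the empirical CDF never sits far above the
  # uniform CDF (discrete tests are conservative)
  for (t in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(pvals <= t), t + 3 * sqrt(t * (1 - t) / length(pvals)))
  }
})

test_that("annotation I/O supports two-column TSV and GMT", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tterm_id", "g1\tT1", "g2\tT1", "g3\tT2"), tsv)
  ann <- read_annotations(tsv)
  expect_equal(length(ann$universe), 3L)
  expect_equal(unname(ann$term_sizes["T1"]), 2L)

  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tfirst term\tg1\tg2", "T2\tsecond term\tg3"), gmt)
  ann2 <- read_annotations(gmt, format = "gmt")
  expect_equal(ann2$term_sizes, c(T1 = 2L, T2 = 1L))
  expect_equal(unname(ann2$term_label["T2"]), "second term")
})
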
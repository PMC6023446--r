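test_that("fisher p matches enumeration on the worked corner cases", {
  expect_equal(fisher_exact_p(5, 5, 5, 5), 1.0)
  # margins (4,4)/(4,4): enumeration over the 5 candidate tables
  expect_equal(fisher_exact_p(3, 1, 1, 3), oracle_fisher_p(3, 1, 1, 3))
  expect_equal(fisher_exact_p(3, 1, 1, 3), 0.4857143, tolerance = 1e-6)
  # extreme corner: both one-sided tails are single tables
  expect_equal(fisher_exact_p(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(fisher_exact_p(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_p(-1, 1, 1, 1), "non-negative")
})

test_that("fisher p agrees with stats::fisher.test on random tables", {
  withr::local_seed(31)
  for (i in 1:200) {
    cells <- rmultinom(1, sample(4:40, 1), prob = runif(4))[, 1]
    p_pkg <- fisher_exact_p(cells[1], cells[2], cells[3], cells[4])
    p_ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, min(1, p_ref), tolerance = 1e-10)
  }
})

test_that("fisher p is invariant under simultaneous row and column swaps", {
  withr::local_seed(32)
  for (i in 1:50) {
    x <- sample(0:12, 4, replace = TRUE)
    if (sum(x) == 0) next
    p <- fisher_exact_p(x[1], x[2], x[3], x[4])
    expect_equal(fisher_exact_p(x[4], x[3], x[2], x[1]), p)  # both swapped
    expect_equal(fisher_exact_p(x[3], x[4], x[1], x[2]), p)  # rows swapped
    expect_equal(fisher_exact_p(x[2], x[1], x[4], x[3]), p)  # cols swapped
  }
})

test_that("corrections match hand-computed values and preserve order", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)  # m = 1
  expect_equal(adjust_pvalues(rep(0.01, 5), "bonferroni"), rep(0.05, 5))
  # BH step-up by hand: adj_i = min_{j>=i} (m/j) p_(j), m = 4:
  # (4*.01/1, 4*.02/2, 4*.03/3, 4*.04/4) -> (.04,.04,.04,.04)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "fdr"),
               rep(0.04, 4))
  p <- c(0.2, 0.001, 0.8, 0.05)
  expect_equal(adjust_pvalues(p, "none"), p)
  expect_equal(adjust_pvalues(numeric(0), "fdr"), numeric(0))
  # BH is rank-monotone: same order up to ties
  withr::local_seed(33)
  p <- runif(50)
  adj <- adjust_pvalues(p, "fdr")
  expect_true(all(diff(adj[order(p)]) > -1e-12))
  expect_error(adjust_pvalues(c(0.5, 0), "fdr"), "\\(0, 1\\]")
})

test_that("contingency tables count presence/absence per class", {
  calls <- matrix(c(rep("A/A", 3), rep("A/G", 2), rep("A/G", 5)), nrow = 1)
  gt <- genotype_table(calls, "P1", paste0("S", 1:10))
  cl <- tibble::tibble(sample_id = paste0("S", 1:10),
                       class = factor(rep(c("RESP", "NoRESP"), each = 5),
                                      levels = c("RESP", "NoRESP")))
  tab <- build_contingency(gt, cl, "P1", "A/A")
  expect_equal(unlist(tab), c(a = 3L, b = 2L, c = 0L, d = 5L))
  expect_error(build_contingency(gt, cl, "P1", "G/G"), "not observed")

  # one NoCall in class A: margins sum to 9
  calls[1, 1] <- "NoCall"
  gt <- genotype_table(calls, "P1", paste0("S", 1:10))
  tab <- build_contingency(gt, cl, "P1", "A/A")
  expect_equal(sum(unlist(tab)), 9)
})

test_that("contingency margins reconcile with the distribution matrix per class", {
  withr::local_seed(34)
  calls <- random_call_matrix(20, 16, nocall_rate = 0.1)
  gt <- genotype_table(calls)
  cl <- balanced_classes(colnames(calls))
  counts <- dmetscreen:::genotype_class_counts(gt, cl)
  dist <- genotype_distribution(gt)
  per_probe <- dplyr::summarise(
    dplyr::group_by(counts, probe_id),
    total = a[1] + b[1] + c[1] + d[1], .groups = "drop"
  )
  called <- 16 - dist$NoCall
  expect_equal(per_probe$total,
               called[match(per_probe$probe_id, dist$probe_id)])
  # a + c equals the distribution count of that genotype
  for (i in sample(nrow(counts), 10)) {
    g <- counts$genotype[i]
    expect_equal(counts$a[i] + counts$c[i],
                 dist[[g]][dist$probe_id == counts$probe_id[i]])
  }
})

test_that("the screen ranks a perfectly separating genotype first", {
  withr::local_seed(35)
  calls <- random_call_matrix(30, 20)
  calls[7, ] <- rep(c("C/C", "T/T"), each = 10)  # planted separator
  gt <- genotype_table(calls)
  cl <- tibble::tibble(sample_id = colnames(calls),
                       class = factor(rep(c("RESP", "NoRESP"), each = 10),
                                      levels = c("RESP", "NoRESP")))
  scr <- fisher_screen(gt, cl, corrector = "bonferroni", alpha = 0.05)
  expect_equal(scr$probe_id[1], "P007")
  expect_equal(attr(scr, "family"), "probe x genotype")
  # sorted by adjusted then raw p
  expect_true(all(diff(scr$p_adjusted) > -1e-15))
  # correction applied over the whole (probe x genotype) family
  expect_equal(scr$p_adjusted, pmin(1, scr$p_value * nrow(scr)))
})

test_that("a single probe with a single category gives p_adjusted = p = 1", {
  gt <- genotype_table(matrix(rep("A/A", 8), 1), "P1", paste0("S", 1:8))
  cl <- balanced_classes(paste0("S", 1:8))
  scr <- fisher_screen(gt, cl, corrector = "bonferroni")
  expect_equal(nrow(scr), 1)
  expect_equal(scr$p_value, 1)
  expect_equal(scr$p_adjusted, scr$p_value)  # m = 1
})

test_that("tidy and glance summarise a screen", {
  wx <- worked_example_fixture()
  scr <- fisher_screen(wx$genotype, wx$classes)
  expect_s3_class(tidy(scr), "tbl_df")
  expect_false(inherits(tidy(scr), "dmet_fisher_screen"))
  g <- glance(scr)
  expect_equal(g$n_tests, nrow(scr))
  expect_equal(g$class_a, "RESP")
})
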
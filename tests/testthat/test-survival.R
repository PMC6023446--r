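test_that("KM estimates match hand product-limit computations", {
  # all censored: no event rows, S = 1 everywhere
  km0 <- km_estimate(c(3, 5, 7, 9, 11), rep(0, 5))
  expect_equal(nrow(km0), 0)
  expect_equal(attr(km0, "n_events"), 0)

  km1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km1$n_at_risk, c(3L, 2L, 1L))

  # middle subject censored: risk set at t=3 is 1
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$time, c(1, 3))
  expect_equal(km2$survival, c(2 / 3, 0))

  expect_error(km_estimate(numeric(0), numeric(0)), "at least one")
  expect_error(km_estimate(c(1, -1), c(1, 1)), "finite and >= 0")
})

test_that("KM with no censoring equals the empirical survival function", {
  withr::local_seed(51)
  for (i in 1:10) {
    t <- round(rexp(40, 0.2), 1)
    km <- km_estimate(t, rep(1, 40))
    for (j in seq_len(nrow(km))) {
      expect_equal(km$survival[j], mean(t > km$time[j]))
    }
  }
})

test_that("KM agrees with survival::survfit under censoring", {
  withr::local_seed(52)
  for (i in 1:10) {
    t <- round(rexp(60, 0.15), 1)
    e <- rbinom(60, 1, 0.7)
    if (sum(e) == 0) next
    km <- km_estimate(t, e)
    sf <- survival::survfit(survival::Surv(t, e) ~ 1)
    at_events <- sf$n.event > 0
    expect_equal(km$time, sf$time[at_events])
    expect_equal(km$survival, sf$surv[at_events], tolerance = 1e-12)
    expect_equal(km$n_at_risk, sf$n.risk[at_events])
  }
})

test_that("median follows the S(t) <= 0.5 convention", {
  drop_to <- function(s_values, times) {
    # minimal synthetic curve object
    structure(tibble::tibble(time = times, n_at_risk = rev(seq_along(times)),
                             n_event = 1L, survival = s_values),
              class = c("dmet_km", class(tibble::tibble())),
              group_label = "g", n_subjects = length(times),
              n_events = length(times))
  }
  expect_equal(median_survival(drop_to(c(0.8, 0.4), c(5, 10))), 10)
  expect_true(is.na(median_survival(drop_to(c(0.9, 0.7), c(5, 10)))))
  expect_equal(median_survival(drop_to(c(0.5, 0.2), c(8, 12))), 8)
})

test_that("log-rank matches the survival package and is symmetric", {
  withr::local_seed(53)
  for (i in 1:15) {
    t1 <- round(rexp(25, 0.2), 1); e1 <- rbinom(25, 1, 0.8)
    t2 <- round(rexp(25, 0.35), 1); e2 <- rbinom(25, 1, 0.8)
    if (sum(e1) + sum(e2) == 0) next
    lr <- logrank_test(t1, e1, t2, e2)
    ref <- oracle_logrank(t1, e1, t2, e2)
    expect_equal(lr$chi_square, ref$chisq, tolerance = 1e-10)
    expect_equal(c(lr$o1, lr$o2), unname(ref$obs))
    expect_equal(c(lr$e1, lr$e2), unname(ref$exp), tolerance = 1e-10)
    # conservation: O1 + O2 = E1 + E2 = total events
    expect_equal(lr$o1 + lr$o2, sum(e1) + sum(e2))
    expect_equal(lr$e1 + lr$e2, sum(e1) + sum(e2), tolerance = 1e-10)
    # symmetry: swapped groups
    sw <- logrank_test(t2, e2, t1, e1)
    expect_equal(sw$chi_square, lr$chi_square, tolerance = 1e-10)
    expect_equal(sw$p_value, lr$p_value, tolerance = 1e-10)
    expect_equal(sw$hazard_ratio, 1 / lr$hazard_ratio, tolerance = 1e-10)
  }
})

test_that("log-rank corner cases behave", {
  # identical groups: chi-square 0, p 1
  lr <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)
  # fully separated small groups, verified against the survival package
  lr2 <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  ref <- oracle_logrank(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(lr2$chi_square, ref$chisq, tolerance = 1e-10)
  # no events at all: not applicable
  lr3 <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_false(lr3$applicable)
  expect_error(logrank_test(numeric(0), numeric(0), 1, 1), "non-empty")
})

test_that("stratify_by_probe splits carriers vs other called samples", {
  calls <- matrix(c(rep("A/A", 6), rep("A/G", 3), "NoCall"), nrow = 1)
  gt <- genotype_table(calls, "P1", paste0("S", 1:10))
  gr <- stratify_by_probe(gt, "P1", "A/A")
  expect_length(gr$group_1, 6)
  expect_length(gr$group_2, 3)  # NoCall sample in neither group
  expect_error(stratify_by_probe(gt, "P1", "G/G"), "not observed")
})

test_that("the survival screen ranks a planted hazard effect first", {
  withr::local_seed(54)
  n <- 120
  calls <- random_call_matrix(15, n)
  carrier <- calls[8, ] == "A/A" | calls[8, ] == "A/G"
  gt <- genotype_table(calls)
  h <- ifelse(carrier, 0.5, 0.1)
  sv <- tibble::tibble(sample_id = colnames(calls),
                       os_time = rexp(n, h), os_event = 1,
                       pfs_time = NA_real_, pfs_event = NA_real_)
  scr <- survival_screen(gt, sv, "OS")
  expect_equal(scr$probe_id[1], "P008")
  expect_true(all(diff(scr$p_value) > -1e-15))
  expect_true(all(scr$n1 > 0 & scr$n2 > 0))
  # ranking is on raw p; p_bh is informational
  expect_true(all(scr$p_bh >= scr$p_value - 1e-12))
})

test_that("a monomorphic probe contributes no comparison and 2-category probes one", {
  calls <- rbind(P1 = rep(c("A/A", "A/G"), each = 4), P2 = rep("C/C", 8))
  colnames(calls) <- paste0("S", 1:8)
  gt <- genotype_table(calls)
  sv <- tibble::tibble(sample_id = paste0("S", 1:8),
                       os_time = c(1, 2, 3, 4, 5, 6, 7, 8), os_event = 1,
                       pfs_time = NA_real_, pfs_event = NA_real_)
  scr <- survival_screen(gt, sv, "OS")
  expect_equal(nrow(scr), 1)
  expect_equal(scr$probe_id, "P1")
  expect_error(survival_screen(gt, sv[1, ], "OS"), "fewer than 2")
})

test_that("worked-example medians and hazard direction are hand-verifiable", {
  wx <- worked_example_fixture()
  scr <- survival_screen(wx$genotype, wx$survival, "OS")
  row <- scr[scr$probe_id == "AM_008", ]
  # carriers of C/T (S01-S06): events at 10,12,14,16,20, censored 18
  # S = 5/6, 4/6, 3/6 at t = 14 -> median 14
  expect_equal(row$median_1, 14)
  # T/T group: events 2..7, S hits 0.5 at the 3rd event time (t = 4)
  expect_equal(row$median_2, 4)
  expect_lt(row$hazard_ratio, 1)  # carriers die slower
  curves <- km_by_genotype(wx$genotype, wx$survival, "AM_008", "C/T", "OS")
  expect_setequal(unique(curves$group), c("C/T", "other"))
  expect_equal(curves$survival[curves$time == 0], c(1, 1))
})
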
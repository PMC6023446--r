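test_that("fisher_filter keeps exactly the probes with min category p <= threshold", {
  withr::local_seed(41)
  calls <- random_call_matrix(40, 20)
  calls[5, ] <- rep(c("C/C", "T/T"), each = 10)  # perfectly separating probe
  gt <- genotype_table(calls)
  cl <- tibble::tibble(sample_id = colnames(calls),
                       class = factor(rep(c("RESP", "NoRESP"), each = 10),
                                      levels = c("RESP", "NoRESP")))
  expect_equal(probe_ids(fisher_filter(gt, cl, threshold = 1)), probe_ids(gt))
  pruned <- fisher_filter(gt, cl, threshold = 0.05)
  expect_true("P005" %in% probe_ids(pruned))
  # brute-force per-row oracle over every observed category
  oracle_keep <- vapply(rownames(calls), function(pr) {
    row <- calls[pr, ]
    cls <- as.character(cl$class)
    ps <- vapply(unique(row), function(g) {
      a <- sum(row == g & cls == "RESP"); b <- sum(row != g & cls == "RESP")
      c_ <- sum(row == g & cls == "NoRESP"); d <- sum(row != g & cls == "NoRESP")
      stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    }, numeric(1))
    min(ps) <= 0.05
  }, logical(1))
  expect_equal(probe_ids(pruned), rownames(calls)[oracle_keep])
  expect_error(fisher_filter(gt, cl, threshold = 0), "\\(0, 1\\]")
  expect_error(fisher_filter(gt, cl, threshold = 1.2), "\\(0, 1\\]")
})

test_that("transactions carry one item per called probe plus the class item", {
  calls <- rbind(P1 = c("A/A", "A/A"), P2 = c("NoCall", "A/G"),
                 P3 = c("C/C", "NoCall"), P4 = c("T/T", "T/T"),
                 P5 = c("NoCall", "NoCall"))
  colnames(calls) <- c("S1", "S2")
  gt <- genotype_table(calls)
  cl <- tibble::tibble(sample_id = "S1",
                       class = factor("RESP", levels = c("RESP", "NoRESP")))
  cl2 <- tibble::tibble(sample_id = c("S1", "S2"),
                        class = factor(c("RESP", "NoRESP"),
                                       levels = c("RESP", "NoRESP")))
  tx <- build_transactions(gt, cl2)
  expect_equal(nrow(tx), 2)  # one per assigned sample
  expect_setequal(tx$items[[1]], c("P1=A/A", "P3=C/C", "P4=T/T", "RESP"))
  expect_setequal(tx$items[[2]], c("P1=A/A", "P2=A/G", "P4=T/T", "NoRESP"))
  # conservation: genotype items = non-NoCall cells among assigned samples
  n_geno_items <- sum(lengths(tx$items)) - nrow(tx)
  expect_equal(n_geno_items, sum(calls != "NoCall"))
})

test_that("fp_growth reproduces the hand-enumerated toy example", {
  out <- fp_growth(list(c("A", "B"), c("A", "B"), c("A", "C")),
                   min_support = 2 / 3)
  keys <- itemsets_as_keys(out)
  expect_setequal(paste(keys$key, keys$count),
                  c("A 3", "B 2", "A;B 2"))
  expect_equal(out$support[vapply(out$items, identical, logical(1), "A")], 1)
  # min_support 1 keeps only itemsets present in every transaction
  out1 <- fp_growth(list(c("A", "B"), c("A", "B"), c("A", "C")), 1)
  expect_equal(itemsets_as_keys(out1)$key, "A")
  expect_equal(nrow(fp_growth(list(), 0.5)), 0)
})

test_that("fp_growth equals brute-force enumeration on random transaction sets", {
  withr::local_seed(42)
  items <- LETTERS[1:10]
  for (rep in 1:30) {
    n_tx <- sample(10:40, 1)
    tx <- lapply(seq_len(n_tx), function(i) {
      items[runif(10) < runif(1, 0.2, 0.7)]
    })
    tx <- Filter(length, tx)
    if (length(tx) == 0) next
    ms <- sample(c(0.1, 0.2, 0.3, 0.5), 1)
    got <- itemsets_as_keys(fp_growth(tx, ms))
    want <- oracle_frequent_itemsets(tx, ms)
    got <- got[order(got$key), ]
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want[order(want$key), ]
      expect_equal(got$key, want$key)
      expect_equal(got$count, want$count)
    }
  }
})

test_that("fp_growth output is anti-monotone and order-invariant", {
  withr::local_seed(43)
  tx <- lapply(1:25, function(i) LETTERS[1:8][runif(8) < 0.5])
  tx <- Filter(length, tx)
  out <- fp_growth(tx, 0.2)
  keys <- itemsets_as_keys(out)$key
  # every subset of a frequent itemset is frequent
  for (s in out$items) {
    if (length(s) < 2) next
    for (drop in seq_along(s)) {
      expect_true(paste(sort(s[-drop]), collapse = ";") %in% keys)
    }
  }
  # invariance under transaction permutation
  out_perm <- fp_growth(tx[sample(length(tx))], 0.2)
  expect_equal(itemsets_as_keys(out_perm), itemsets_as_keys(out))
})

test_that("FP-tree header chains conserve scan-counted supports", {
  withr::local_seed(44)
  tx <- lapply(1:30, function(i) unique(sample(LETTERS[1:6], sample(1:5, 1))))
  sup1 <- table(unlist(lapply(tx, unique)))
  item_names <- names(sort(sup1, decreasing = TRUE))
  rank_of <- stats::setNames(seq_along(item_names), item_names)
  coded <- lapply(tx, function(t) sort(unname(rank_of[t])))
  tree <- dmetscreen:::fp_tree_build(coded, rep(1, length(tx)),
                                     length(item_names))
  for (it in seq_along(item_names)) {
    expect_equal(dmetscreen:::fp_tree_item_support(tree, it),
                 unname(sup1[item_names[it]]))
  }
  # every root-to-node path lists items in the fixed mining order
  for (node in 2:tree$n_nodes) {
    path <- dmetscreen:::fp_tree_path(tree, node)
    expect_true(all(diff(path) > 0))
  }
})

test_that("rules are generated only from itemsets with exactly one class item", {
  sets <- tibble::tibble(
    items = list("g1", c("g1", "RESP"), c("g1", "g2"), "RESP",
                 c("RESP", "NoRESP")),
    count = c(5L, 4L, 3L, 6L, 0L),
    support = c(0.5, 0.4, 0.3, 0.6, 0)
  )
  rules <- generate_rules(sets, min_confidence = 0.5,
                          class_items = c("RESP", "NoRESP"))
  expect_equal(nrow(rules), 1)
  expect_equal(rules$antecedent[[1]], "g1")
  expect_equal(rules$consequent, "RESP")
  expect_equal(rules$confidence, 0.8)  # 0.4 / 0.5
  expect_equal(rules$support, 0.4)
  # raising the bar drops it
  expect_equal(nrow(generate_rules(sets, 0.85, c("RESP", "NoRESP"))), 0)
})

test_that("split_and_rank partitions rules and breaks ties deterministically", {
  rules <- tibble::tibble(
    antecedent = list("b", "a", "c"),
    consequent = c("RESP", "NoRESP", "RESP"),
    support = c(0.3, 0.4, 0.3),
    confidence = c(0.9, 0.8, 0.9),
    antecedent_support = c(1, 1, 1) / 3
  )
  by_class <- split_and_rank_rules(rules)
  expect_equal(vapply(by_class, nrow, integer(1)),
               c(RESP = 2L, NoRESP = 1L))
  # equal confidence and support: antecedent lexicographic
  expect_equal(unlist(by_class$RESP$antecedent), c("b", "c"))
  # concatenation is a permutation of the input
  all_back <- dplyr::bind_rows(by_class)
  expect_setequal(unlist(all_back$antecedent), unlist(rules$antecedent))
})

test_that("mine_rules recovers the worked example's hand-computed rules", {
  wx <- worked_example_fixture()
  res <- mine_rules(wx$genotype, wx$classes, fisher_threshold = 1,
                    min_support = 0.25, min_confidence = 0.8)
  df <- tidy(res)
  # S01-S05 carry AM_002=A/G and AM_003=T/T and are all RESP:
  # support 5/12, confidence 1
  joint <- df[df$antecedent == "AM_002=A/G;AM_003=T/T", ]
  expect_equal(nrow(joint), 1)
  expect_equal(joint$consequent, "RESP")
  expect_equal(joint$support, 5 / 12)
  expect_equal(joint$confidence, 1)
  # AM_003=T/T alone: 6 carriers, 5 RESP -> confidence 5/6
  single <- df[df$antecedent == "AM_003=T/T", ]
  expect_equal(single$confidence, 5 / 6)
  # AM_002=A/G alone: 8 carriers, 6 RESP -> 0.75 < 0.8, no rule
  expect_equal(nrow(df[df$antecedent == "AM_002=A/G", ]), 0)
  # every ranked list is confidence-sorted
  for (cl in names(attr(res, "by_class"))) {
    conf <- attr(res, "by_class")[[cl]]$confidence
    expect_true(all(diff(conf) < 1e-12))
  }
})
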
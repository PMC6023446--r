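#' Prune probes by per-row minimum Fisher p-value
#'
#' Rule mining works on a search space reduced by a per-probe Fisher filter:
#' a probe is retained exactly when the minimum raw two-sided Fisher p-value
#' across its observed genotype categories is at or below `threshold`. The
#' filter uses raw (uncorrected) p-values and is computed independently of the
#' corrected association screen, so the mining stage can use a different
#' cut-off than the statistical stage.
#'
#' @inheritParams fisher_screen
#' @param threshold Retention threshold on the per-probe minimum raw p, in
#'   `(0, 1]`. A threshold of 1 retains every probe.
#' @return The pruned genotype table (probe order preserved), with attribute
#'   `"fisher_filter"`: a tibble of per-probe minimum p-values and retention
#'   flags.
#' @export
fisher_filter <- function(table, classes, threshold = 0.05, workers = 1) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0 || threshold > 1) {
    abort("fisher_filter threshold must lie in (0, 1]")
  }
  counts <- genotype_class_counts(table, classes)
  probes <- probe_ids(table)
  min_p <- rep(Inf, length(probes))
  if (nrow(counts) > 0) {
    chunks <- chunk_indices(nrow(counts), workers)
    p <- unlist(parallel_map(chunks, function(ix) {
      fisher_exact_p(counts$a[ix], counts$b[ix], counts$c[ix], counts$d[ix])
    }, workers = workers), use.names = FALSE)
    agg <- tapply(p, factor(counts$probe_id, levels = probes), min)
    min_p[!is.na(agg)] <- agg[!is.na(agg)]
  }
  retained <- min_p <= threshold
  out <- table[table$probe_id %in% probes[retained], , drop = FALSE]
  attr(out, "fisher_filter") <- tibble(probe_id = probes, min_p = min_p,
                                       retained = retained)
  out
}

#' Convert a genotype table into class-labelled transactions
#'
#' Each class-assigned sample becomes one transaction whose items are a
#' `"probe=genotype"` token per called probe plus the sample's class label
#' (NoCall probes contribute no item). These transactions are the input to
#' [fp_growth()].
#'
#' @inheritParams fisher_screen
#' @return Tibble (`sample_id`, `class`, `items`) with `items` a list-column
#'   of character item vectors, one row per class-assigned sample.
#' @export
build_transactions <- function(table, classes) {
  check_two_classes(classes)
  called <- table %>%
    semi_join(classes, by = "sample_id") %>%
    filter(!is.na(.data$call)) %>%
    mutate(item = paste0(.data$probe_id, "=", .data$call))
  items_by_sample <- split(called$item,
                           factor(called$sample_id, levels = classes$sample_id))
  tibble(
    sample_id = classes$sample_id,
    class = classes$class,
    items = purrr::map2(items_by_sample, as.character(classes$class),
                        function(g, cl) c(unname(g), cl))
  )
}

#' FP-Growth frequent-itemset mining
#'
#' Mines all itemsets whose support (fraction of transactions containing the
#' itemset) is at least `min_support`, using the FP-Growth algorithm: a
#' support scan drops infrequent items, the remaining items are totally
#' ordered by support descending (ties lexicographic), transactions are
#' compressed into an FP-tree, and conditional pattern bases are mined
#' recursively with a single-path shortcut. No candidate generation takes
#' place; reported supports are exact.
#'
#' @param transactions Either a transaction tibble from
#'   [build_transactions()] or a plain list of character item vectors.
#' @param min_support Minimum support as a proportion in `(0, 1]`, measured
#'   against all transactions.
#' @return Tibble (`items` list-column of sorted character vectors, `count`,
#'   `support`), ordered by support descending then itemset. Empty input
#'   yields an empty tibble.
#' @examples
#' fp_growth(list(c("A", "B"), c("A", "B"), c("A", "C")), min_support = 2 / 3)
#' @export
fp_growth <- function(transactions, min_support) {
  if (!is.numeric(min_support) || length(min_support) != 1 ||
      is.na(min_support) || min_support <= 0 || min_support > 1) {
    abort("min_support must lie in (0, 1]")
  }
  tx <- as_item_list(transactions)
  n <- length(tx)
  empty <- tibble(items = list(), count = integer(), support = numeric())
  if (n == 0) return(empty)
  tx <- lapply(tx, unique)
  min_count <- min_support * n - 1e-9
  sup1 <- sort(table(unlist(tx, use.names = FALSE)), decreasing = TRUE)
  frequent <- sup1[sup1 >= min_count]
  if (length(frequent) == 0) return(empty)
  # fixed mining order: support descending, ties lexicographic
  ord <- order(-as.numeric(frequent), names(frequent), method = "radix")
  item_names <- names(frequent)[ord]
  rank_of <- setNames(seq_along(item_names), item_names)
  coded <- lapply(tx, function(items) {
    ids <- unname(rank_of[items[items %in% item_names]])
    sort(ids)
  })
  tree <- fp_tree_build(coded, rep(1, n), length(item_names))
  acc <- itemset_accumulator()
  fp_mine(tree, seq_along(item_names), min_count, integer(0), acc)
  found <- acc$collect()
  counts <- as.integer(round(found$counts))
  sets <- lapply(found$sets, function(ids) {
    sort(item_names[ids], method = "radix")
  })
  key <- vapply(sets, paste, character(1), collapse = "\x1f")
  out <- tibble(items = sets, count = counts, support = counts / n)
  out[order(-out$count, key, method = "radix"), ]
}

as_item_list <- function(transactions) {
  if (is.data.frame(transactions)) {
    if (!"items" %in% names(transactions)) {
      abort("transaction tibble must have an 'items' list-column")
    }
    transactions <- transactions$items
  }
  if (!is.list(transactions)) abort("transactions must be a list of item vectors")
  lapply(transactions, as.character)
}

#' Generate class-association rules from frequent itemsets
#'
#' Every frequent itemset containing exactly one class item and at least one
#' genotype item yields one candidate rule: antecedent = the genotype items,
#' consequent = the class item, confidence = support(itemset) /
#' support(antecedent), both taken from the exact mined supports. Rules below
#' `min_confidence` are dropped. Class items never appear in an antecedent.
#'
#' @param itemsets Frequent itemsets from [fp_growth()].
#' @param min_confidence Minimum confidence in `(0, 1]`.
#' @param class_items Character vector of the class-item labels.
#' @return Tibble (`antecedent` list-column, `consequent`, `support`,
#'   `confidence`, `antecedent_support`).
#' @export
generate_rules <- function(itemsets, min_confidence, class_items) {
  if (!is.numeric(min_confidence) || length(min_confidence) != 1 ||
      is.na(min_confidence) || min_confidence <= 0 || min_confidence > 1) {
    abort("min_confidence must lie in (0, 1]")
  }
  empty <- tibble(antecedent = list(), consequent = character(),
                  support = numeric(), confidence = numeric(),
                  antecedent_support = numeric())
  if (nrow(itemsets) == 0) return(empty)
  key <- vapply(itemsets$items, paste, character(1), collapse = "\x1f")
  support_of <- setNames(itemsets$support, key)
  rows <- purrr::map(seq_len(nrow(itemsets)), function(i) {
    items <- itemsets$items[[i]]
    is_class <- items %in% class_items
    if (sum(is_class) != 1 || all(is_class)) return(NULL)
    ante <- items[!is_class]
    ante_sup <- support_of[[paste(ante, collapse = "\x1f")]]
    # antecedent is a subset of a frequent itemset, hence itself frequent
    conf <- itemsets$support[i] / ante_sup
    if (conf < min_confidence - 1e-12) return(NULL)
    tibble(antecedent = list(ante), consequent = items[is_class],
           support = itemsets$support[i], confidence = conf,
           antecedent_support = ante_sup)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

#' Partition rules by class and rank within class
#'
#' Splits a rule set by consequent class and sorts each list by confidence
#' descending, ties by support descending, then by antecedent
#' lexicographically, mirroring the two per-class result views of a
#' class-association mining run.
#'
#' @param rules Rule tibble from [generate_rules()].
#' @param class_labels Optional label vector fixing which (possibly empty)
#'   per-class lists to return; defaults to the consequents present.
#' @return Named list of rule tibbles, one per class label.
#' @export
split_and_rank_rules <- function(rules, class_labels = NULL) {
  if (is.null(class_labels)) class_labels <- unique(rules$consequent)
  rank_rules <- function(df) {
    if (nrow(df) == 0) return(df)
    ante_key <- vapply(df$antecedent, paste, character(1), collapse = ";")
    df[order(-df$confidence, -df$support, ante_key, method = "radix"), ]
  }
  setNames(lapply(class_labels, function(cl) {
    rank_rules(rules[rules$consequent == cl, , drop = FALSE])
  }), class_labels)
}

#' Mine class-association rules from a genotype table
#'
#' Full rule-mining stage: Fisher-filter row pruning ([fisher_filter()]),
#' transaction building ([build_transactions()]), FP-Growth frequent-itemset
#' mining ([fp_growth()]) and class-constrained rule generation
#' ([generate_rules()]). Minimum support is measured against all transactions,
#' not per class.
#'
#' @inheritParams fisher_screen
#' @param fisher_threshold Fisher-filter retention threshold (raw per-probe
#'   minimum p), default 0.05.
#' @param min_support Minimum itemset support, default 0.2.
#' @param min_confidence Minimum rule confidence, default 0.8.
#' @return A tibble of class `dmet_rules`: all retained rules, ranked by
#'   confidence then support, with mining parameters and per-class splits in
#'   attributes (`attr(x, "by_class")`).
#' @export
mine_rules <- function(table, classes, fisher_threshold = 0.05,
                       min_support = 0.2, min_confidence = 0.8, workers = 1) {
  check_two_classes(classes)
  labels <- levels(classes$class)
  pruned <- fisher_filter(table, classes, fisher_threshold, workers = workers)
  tx <- build_transactions(pruned, classes)
  sets <- fp_growth(tx, min_support)
  rules <- generate_rules(sets, min_confidence, class_items = labels)
  by_class <- split_and_rank_rules(rules, class_labels = labels)
  ranked <- bind_rows(by_class)
  if (nrow(ranked) == 0) ranked <- rules
  structure(ranked,
            class = c("dmet_rules", class(ranked)),
            by_class = by_class,
            params = list(fisher_threshold = fisher_threshold,
                          min_support = min_support,
                          min_confidence = min_confidence,
                          support_basis = "all transactions",
                          n_transactions = nrow(tx),
                          n_probes_after_filter = length(probe_ids(pruned))),
            class_labels = labels)
}

#' @method tidy dmet_rules
#' @export
tidy.dmet_rules <- function(x, ...) {
  out <- as_tibble(unclass_result(x))
  attr(out, "by_class") <- NULL
  out$antecedent <- vapply(out$antecedent, paste, character(1), collapse = ";")
  out
}

#' @method glance dmet_rules
#' @export
glance.dmet_rules <- function(x, ...) {
  p <- attr(x, "params")
  tibble(n_rules = nrow(x),
         n_transactions = p$n_transactions,
         n_probes_after_filter = p$n_probes_after_filter,
         fisher_threshold = p$fisher_threshold,
         min_support = p$min_support,
         min_confidence = p$min_confidence)
}

#' @method autoplot dmet_rules
#' @export
autoplot.dmet_rules <- function(object, top = 25, ...) {
  df <- head(tidy(object), top)
  df$label <- paste0(df$antecedent, " => ", df$consequent)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$support, y = .data$confidence,
                                   colour = .data$consequent)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = "Class-association rules",
                  x = "support", y = "confidence") +
    ggplot2::theme_minimal()
}
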
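#' Two-sided Fisher exact p-value for 2x2 tables
#'
#' Computes the exact two-sided p-value of independence for the table
#' `[[a, b], [c, d]]` by summing, over all tables with the same margins, the
#' hypergeometric point probabilities that do not exceed the observed table's
#' point probability. Probability ties are resolved with a relative tolerance
#' of `1e-7`, matching common statistical practice for the point-probability
#' definition of the two-sided test.
#'
#' In the association screen the rows are genotype present/absent and the
#' columns the two phenotype classes, i.e. `a` = class-A samples carrying the
#' genotype, `b` = class-A samples not carrying it, `c`/`d` likewise for
#' class B.
#'
#' @param a,b,c,d Non-negative integer cell counts (vectorized, recycled to a
#'   common length).
#' @param tie_tol Relative tolerance for point-probability ties.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @examples
#' fisher_exact_p(5, 5, 5, 5)   # most probable table: p = 1
#' fisher_exact_p(10, 0, 0, 10) # extreme corner table
#' @export
fisher_exact_p <- function(a, b, c, d, tie_tol = 1e-7) {
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  cells <- cbind(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("contingency cells must be non-negative integers")
  }
  vapply(seq_len(len), function(i) {
    fisher_p_one(a[i], b[i], c[i], d[i], tie_tol)
  }, numeric(1))
}

fisher_p_one <- function(a, b, c, d, tie_tol) {
  if (a + b + c + d == 0) abort("all-zero contingency table")
  m <- a + b   # first row margin
  n2 <- c + d  # second row margin
  k <- a + c   # first column margin
  x <- max(0, k - n2):min(k, m)
  px <- dhyper(x, m, n2, k)
  p_obs <- px[x == a]
  min(1, sum(px[px <= p_obs * (1 + tie_tol)]))
}

# Cross-product odds ratio with the 0-cell convention: a*d / (b*c),
# yielding Inf when only the denominator is zero and NaN when both are.
odds_ratio_2x2 <- function(a, b, c, d) {
  (as.numeric(a) * as.numeric(d)) / (as.numeric(b) * as.numeric(c))
}

#' Build the 2x2 presence/absence contingency table for one genotype
#'
#' Counts, at one probe, how many class-A and class-B samples carry the given
#' genotype category versus any other called genotype. NoCall samples and
#' samples without a class assignment are excluded.
#'
#' @param table Long genotype tibble.
#' @param classes Class assignment tibble from [read_class_file()] (or any
#'   tibble with `sample_id` and a two-level factor `class`).
#' @param probe Probe identifier.
#' @param genotype Canonical genotype category; must be observed at the probe
#'   among class-assigned, called samples.
#' @return One-row tibble `a`, `b`, `c`, `d` (see [fisher_exact_p()] for the
#'   cell semantics).
#' @export
build_contingency <- function(table, classes, probe, genotype) {
  counts <- genotype_class_counts(table[table$probe_id == probe, , drop = FALSE],
                                  classes)
  row <- counts[counts$genotype == genotype, c("a", "b", "c", "d")]
  if (nrow(row) != 1) {
    abort(sprintf("genotype '%s' is not observed at probe '%s' among class-assigned samples",
                  genotype, probe))
  }
  row
}

# All (probe, genotype) presence/absence tables at once: one row per observed
# category, probes in table order, genotypes in C-locale sort order.
genotype_class_counts <- function(table, classes) {
  check_two_classes(classes)
  lv <- levels(classes$class)
  cl <- setNames(as.character(classes$class), classes$sample_id)[table$sample_id]
  keep <- !is.na(cl) & !is.na(table$call)
  probes <- probe_ids(table)
  cats <- sort(unique(table$call[keep]), method = "radix")
  empty <- tibble(probe_id = character(), genotype = character(),
                  a = integer(), b = integer(), c = integer(), d = integer())
  if (!any(keep) || length(cats) == 0) return(empty)
  tab <- table(factor(table$probe_id[keep], levels = probes),
               factor(table$call[keep], levels = cats),
               factor(cl[keep], levels = lv))
  cnt_a <- matrix(tab[, , 1], nrow = length(probes))
  cnt_b <- matrix(tab[, , 2], nrow = length(probes))
  tot_a <- rowSums(cnt_a)
  tot_b <- rowSums(cnt_b)
  present <- which(cnt_a + cnt_b > 0, arr.ind = TRUE)
  present <- present[order(present[, 1], present[, 2]), , drop = FALSE]
  if (nrow(present) == 0) return(empty)
  i <- present[, 1]; j <- present[, 2]
  tibble(
    probe_id = probes[i],
    genotype = cats[j],
    a = as.integer(cnt_a[present]),
    b = as.integer(tot_a[i] - cnt_a[present]),
    c = as.integer(cnt_b[present]),
    d = as.integer(tot_b[i] - cnt_b[present])
  )
}

#' Multiple-testing correction
#'
#' Adjusts a family of p-values with the Bonferroni (family-wise) or
#' Benjamini-Hochberg false-discovery-rate step-up correction, delegating to
#' [stats::p.adjust()]. Output order matches input order; `"none"` is the
#' identity.
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @param method One of `"none"`, `"bonferroni"`, `"fdr"` (Benjamini-Hochberg;
#'   `"fdr_bh"` and `"bh"` are accepted aliases).
#' @return Adjusted p-values, capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("none", "bonferroni", "fdr", "fdr_bh", "bh")) {
  method <- match.arg(tolower(method[1]), c("none", "bonferroni", "fdr", "fdr_bh", "bh"))
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  switch(method,
         none = p,
         bonferroni = p.adjust(p, method = "bonferroni"),
         p.adjust(p, method = "BH"))
}

#' Exhaustive per-probe Fisher association screen
#'
#' For every probe and every genotype category observed among class-assigned,
#' called samples, tests the association between carrying that genotype and
#' the two phenotype classes with the two-sided Fisher exact test, then
#' corrects the whole (probe x genotype) family of tests at once. NoCall
#' samples are excluded per probe, not listwise.
#'
#' @inheritParams build_contingency
#' @param corrector `"bonferroni"` (default), `"fdr"` (Benjamini-Hochberg) or
#'   `"none"`.
#' @param alpha Significance level applied to the adjusted p-values.
#' @param workers Worker processes for the per-probe tests (see
#'   [parallel_map()]); results are identical for any worker count.
#' @return A tibble of class `dmet_fisher_screen`, one row per (probe,
#'   genotype) pair with the contingency cells `a`-`d`, `odds_ratio`,
#'   `p_value`, `p_adjusted` and `significant`, sorted by adjusted p
#'   ascending with ties broken by raw p, probe then genotype. Attributes
#'   record the corrector, alpha, family size and the correction family
#'   (`"probe x genotype"`).
#' @export
fisher_screen <- function(table, classes,
                          corrector = c("bonferroni", "fdr", "none"),
                          alpha = 0.05, workers = 1) {
  corrector <- match.arg(corrector)
  counts <- genotype_class_counts(table, classes)
  if (nrow(counts) == 0) {
    res <- counts %>% mutate(odds_ratio = numeric(0), p_value = numeric(0),
                             p_adjusted = numeric(0), significant = logical(0))
  } else {
    chunks <- chunk_indices(nrow(counts), workers)
    p <- unlist(parallel_map(chunks, function(ix) {
      fisher_exact_p(counts$a[ix], counts$b[ix], counts$c[ix], counts$d[ix])
    }, workers = workers), use.names = FALSE)
    res <- counts %>%
      mutate(
        odds_ratio = odds_ratio_2x2(.data$a, .data$b, .data$c, .data$d),
        p_value = p,
        p_adjusted = adjust_pvalues(p, corrector),
        significant = .data$p_adjusted <= alpha
      ) %>%
      arrange(.data$p_adjusted, .data$p_value, .data$probe_id, .data$genotype)
  }
  structure(res,
            class = c("dmet_fisher_screen", class(res)),
            corrector = corrector, alpha = alpha,
            n_tests = nrow(res), family = "probe x genotype",
            class_labels = levels(classes$class))
}

#' @method tidy dmet_fisher_screen
#' @export
tidy.dmet_fisher_screen <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @method glance dmet_fisher_screen
#' @export
glance.dmet_fisher_screen <- function(x, ...) {
  tibble(
    n_tests = attr(x, "n_tests"),
    n_significant = sum(x$significant),
    corrector = attr(x, "corrector"),
    alpha = attr(x, "alpha"),
    class_a = attr(x, "class_labels")[1],
    class_b = attr(x, "class_labels")[2]
  )
}

#' @method autoplot dmet_fisher_screen
#' @export
autoplot.dmet_fisher_screen <- function(object, top = 30, ...) {
  df <- head(tidy(object), top) %>%
    mutate(label = paste0(.data$probe_id, " [", .data$genotype, "]"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, -.data$p_adjusted),
                                   y = -log10(.data$p_adjusted),
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10]~adjusted~p),
                  title = "Fisher association screen") +
    ggplot2::theme_minimal()
}

unclass_result <- function(x) {
  cls <- class(x)
  class(x) <- cls[!startsWith(cls, "dmet_")]
  for (at in c("corrector", "alpha", "n_tests", "family", "class_labels",
               "endpoint", "params")) attr(x, at) <- NULL
  x
}

chunk_indices <- function(n, workers) {
  workers <- max(1L, resolve_workers(workers))
  k <- min(workers, n)
  if (n == 0) return(list())
  if (k <= 1) return(list(seq_len(n)))
  unname(split(seq_len(n), cut(seq_len(n), breaks = k, labels = FALSE)))
}
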
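# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Fisher oracle enumerates hypergeometric
# point probabilities via lchoose(), the itemset oracle enumerates every
# subset with bitmasks, and survival oracles go through the survival package.

# Two-sided Fisher p by full enumeration over all tables with the observed
# margins, point-probability criterion with relative tie tolerance 1e-7.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  tot <- m + n2
  xs <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n2, k - xs) - lchoose(tot, k)
  p <- exp(logp)
  p_obs <- p[xs == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Brute-force frequent-itemset enumeration over <= 20 distinct items.
# Returns a tibble (key = ";"-joined sorted items, count) for all itemsets
# with count/n >= min_support.
oracle_frequent_itemsets <- function(tx, min_support) {
  items <- sort(unique(unlist(tx)))
  stopifnot(length(items) <= 20)
  n <- length(tx)
  bits <- vapply(tx, function(t) {
    sum(bitwShiftL(1L, match(unique(t), items) - 1L))
  }, integer(1))
  rows <- list()
  for (mask in seq_len(2^length(items) - 1L)) {
    cnt <- sum(bitwAnd(bits, mask) == mask)
    if (cnt / n >= min_support - 1e-9) {
      sel <- items[bitwAnd(mask, bitwShiftL(1L, seq_along(items) - 1L)) != 0L]
      rows[[length(rows) + 1L]] <- data.frame(
        key = paste(sel, collapse = ";"), count = cnt,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Canonical key form of an fp_growth() result, for comparison with the oracle.
itemsets_as_keys <- function(sets) {
  data.frame(
    key = vapply(sets$items, function(s) paste(sort(s), collapse = ";"),
                 character(1)),
    count = sets$count, stringsAsFactors = FALSE
  )
}

# Random genotype-call matrix with no class effect (null), biallelic probes.
random_call_matrix <- function(n_probes, n_samples, nocall_rate = 0,
                               maf = NULL) {
  calls <- matrix(NA_character_, n_probes, n_samples)
  for (i in seq_len(n_probes)) {
    q <- if (is.null(maf)) runif(1, 0.1, 0.5) else maf
    g <- sample(c("A/A", "A/G", "G/G"), n_samples, replace = TRUE,
                prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    calls[i, ] <- g
  }
  if (nocall_rate > 0) calls[runif(length(calls)) < nocall_rate] <- "NoCall"
  rownames(calls) <- sprintf("P%03d", seq_len(n_probes))
  colnames(calls) <- sprintf("S%03d", seq_len(n_samples))
  calls
}

random_classes <- function(sample_ids, labels = c("RESP", "NoRESP")) {
  tibble::tibble(
    sample_id = sample_ids,
    class = factor(sample(labels, length(sample_ids), replace = TRUE),
                   levels = labels)
  )
}

balanced_classes <- function(sample_ids, labels = c("RESP", "NoRESP")) {
  tibble::tibble(
    sample_id = sample_ids,
    class = factor(rep(labels, length.out = length(sample_ids)),
                   levels = labels)
  )
}

# Log-rank oracle via the survival package (chi-square with 1 df).
oracle_logrank <- function(t1, e1, t2, e2) {
  sd <- survival::survdiff(
    survival::Surv(c(t1, t2), c(e1, e2)) ~ rep(1:2, c(length(t1), length(t2)))
  )
  list(chisq = sd$chisq, obs = sd$obs, exp = sd$exp)
}
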
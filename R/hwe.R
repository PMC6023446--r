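#' Hardy-Weinberg equilibrium test per probe
#'
#' For every biallelic probe, tests the observed genotype counts (homozygous
#' major, heterozygous, homozygous minor, NoCall excluded) against the
#' Hardy-Weinberg proportions `n * (p^2, 2pq, q^2)` with allele frequencies
#' estimated from the same data, using a 1-degree-of-freedom chi-square
#' goodness-of-fit statistic. Probes that are monomorphic or carry more than
#' two allele symbols are flagged not-applicable rather than tested.
#'
#' @param table Long genotype tibble.
#' @return Tibble, one row per probe in table order: major/minor allele and
#'   their counts, genotype counts, `chi_square`, `p_value`, `applicable` and
#'   a `note` explaining non-applicable probes. The major allele is the more
#'   frequent one (ties broken lexicographically).
#' @examples
#' gt <- genotype_table(matrix(rep(c("A/A", "A/G", "G/G"), c(25, 50, 25)),
#'                             nrow = 1), "P1")
#' hwe_test(gt) # exact HW proportions: chi_square = 0, p = 1
#' @export
hwe_test <- function(table) {
  probes <- probe_ids(table)
  calls_by_probe <- split(table$call, factor(table$probe_id, levels = probes))
  purrr::map2(probes, calls_by_probe, hwe_one) %>% bind_rows()
}

hwe_one <- function(probe, calls) {
  na_row <- function(note) {
    tibble(probe_id = probe, allele_major = NA_character_,
           allele_minor = NA_character_, n_allele_major = NA_integer_,
           n_allele_minor = NA_integer_, n_hom_major = NA_integer_,
           n_het = NA_integer_, n_hom_minor = NA_integer_,
           chi_square = NA_real_, p_value = NA_real_,
           applicable = FALSE, note = note)
  }
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0) return(na_row("no called samples"))
  alleles <- call_alleles(calls)
  counts <- sort(table(alleles), decreasing = TRUE)
  if (length(counts) == 1) return(na_row("monomorphic"))
  if (length(counts) > 2) {
    return(na_row(sprintf("%d alleles observed", length(counts))))
  }
  # tie on allele counts: lexicographically smaller allele is "major"
  nm <- names(counts)
  if (counts[1] == counts[2]) nm <- sort(nm, method = "radix")
  maj <- nm[1]; mnr <- nm[2]
  hom_major <- paste(sort(c(maj, maj), method = "radix"), collapse = "/")
  hom_minor <- paste(sort(c(mnr, mnr), method = "radix"), collapse = "/")
  het <- paste(sort(c(maj, mnr), method = "radix"), collapse = "/")
  obs <- c(sum(calls == hom_major), sum(calls == het), sum(calls == hom_minor))
  n <- length(calls)
  p <- (2 * obs[1] + obs[2]) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi <- sum((obs - expected)^2 / expected)
  tibble(
    probe_id = probe,
    allele_major = maj, allele_minor = mnr,
    n_allele_major = as.integer(2 * obs[1] + obs[2]),
    n_allele_minor = as.integer(2 * obs[3] + obs[2]),
    n_hom_major = obs[1], n_het = obs[2], n_hom_minor = obs[3],
    chi_square = chi,
    p_value = pchisq(chi, df = 1, lower.tail = FALSE),
    applicable = TRUE, note = NA_character_
  )
}
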
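#' Drop low-information probes from a genotype table
#'
#' Probes that cannot contribute to any downstream screen are removed before
#' analysis: probes whose missing-call (NoCall) fraction exceeds
#' `max_nocall_fraction`, and, when `drop_monomorphic` is set, probes showing
#' fewer than two distinct genotypes among their called samples. A probe
#' failing both tests is recorded once, with the excess-NoCall reason taking
#' precedence. Filtering is idempotent and preserves probe order; an empty
#' result is legal and flagged in the report.
#'
#' @param table Long genotype tibble.
#' @param max_nocall_fraction Maximum tolerated NoCall fraction per probe, in
#'   `[0, 1]`. Default 0.1.
#' @param drop_monomorphic Drop probes with a single observed genotype.
#'   Default `TRUE`.
#' @return The filtered table, with attribute `"preprocess_report"` (see
#'   [preprocess_report()]): one row per input probe with its NoCall fraction
#'   and, for removed probes, the removal reason (`"excess-NoCall"` or
#'   `"monomorphic"`).
#' @export
filter_uninformative <- function(table, max_nocall_fraction = 0.1,
                                 drop_monomorphic = TRUE) {
  if (!is.numeric(max_nocall_fraction) || length(max_nocall_fraction) != 1 ||
      is.na(max_nocall_fraction) || max_nocall_fraction < 0 ||
      max_nocall_fraction > 1) {
    abort("max_nocall_fraction must be a single value in [0, 1]")
  }
  per_probe <- table %>%
    group_by(.data$probe_id) %>%
    summarise(
      nocall_fraction = mean(is.na(.data$call)),
      n_genotypes = dplyr::n_distinct(.data$call[!is.na(.data$call)]),
      .groups = "drop"
    )
  # restore input probe order (group_by sorts)
  per_probe <- per_probe[match(probe_ids(table), per_probe$probe_id), ]
  reason <- dplyr::case_when(
    per_probe$nocall_fraction > max_nocall_fraction ~ "excess-NoCall",
    drop_monomorphic & per_probe$n_genotypes < 2 ~ "monomorphic",
    TRUE ~ NA_character_
  )
  report <- tibble(
    probe_id = per_probe$probe_id,
    nocall_fraction = per_probe$nocall_fraction,
    removed = !is.na(reason),
    reason = reason
  )
  kept <- report$probe_id[!report$removed]
  out <- table[table$probe_id %in% kept, , drop = FALSE]
  if (length(kept) == 0) {
    warn("all probes were removed by preprocessing; the filtered table is empty")
  }
  attr(out, "preprocess_report") <- report
  out
}

#' Preprocessing report of a filtered genotype table
#'
#' @param table A table returned by [filter_uninformative()].
#' @return Tibble (`probe_id`, `nocall_fraction`, `removed`, `reason`), one
#'   row per probe of the unfiltered table.
#' @export
preprocess_report <- function(table) {
  rep <- attr(table, "preprocess_report")
  if (is.null(rep)) abort("no preprocess report attached; run filter_uninformative() first")
  rep
}

#' Per-probe genotype distribution
#'
#' Counts, for every probe, how many samples carry each observed genotype
#' category, with NoCall as its own category. This is the matrix behind the
#' SNP-distribution heat-map view of a genotype dataset; every row sums to
#' the number of samples.
#'
#' @param table Long genotype tibble (non-empty).
#' @return A wide tibble: `probe_id`, one integer column per observed genotype
#'   category (sorted), and a final `NoCall` column.
#' @seealso [plot_genotype_heatmap()]
#' @export
genotype_distribution <- function(table) {
  if (nrow(table) == 0) abort("genotype table is empty")
  probes <- probe_ids(table)
  cat <- ifelse(is.na(table$call), NOCALL_TOKEN, table$call)
  cats <- c(sort(unique(cat[cat != NOCALL_TOKEN]), method = "radix"), NOCALL_TOKEN)
  counts <- table(factor(table$probe_id, levels = probes),
                  factor(cat, levels = cats))
  out <- as_tibble(as.data.frame.matrix(counts), rownames = "probe_id")
  class(out) <- c("dmet_distribution", class(out))
  out
}

#' Heat-map of the per-probe genotype distribution
#'
#' @param dist A distribution tibble from [genotype_distribution()].
#' @param max_probes Show at most this many probes (first rows), keeping the
#'   plot readable for large arrays.
#' @return A ggplot object: probes on the y axis, genotype categories on the
#'   x axis, fill = fraction of samples.
#' @export
plot_genotype_heatmap <- function(dist, max_probes = 50) {
  dist <- head(dist, max_probes)
  long <- tidyr::pivot_longer(as_tibble(dist), -"probe_id",
                              names_to = "genotype", values_to = "n") %>%
    group_by(.data$probe_id) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$genotype,
                                     y = factor(.data$probe_id,
                                                levels = rev(unique(.data$probe_id))),
                                     fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "genotype category", y = NULL, fill = "fraction") +
    ggplot2::theme_minimal()
}
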
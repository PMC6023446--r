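#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function from right-censored times with the
#' product-limit estimator: at each distinct observed event time `t_i` with
#' `d_i` events among `n_i` subjects at risk, `S` is multiplied by
#' `1 - d_i / n_i`. Censored subjects leave the risk set just after their
#' time, so events and censorings tied at the same time count the censored
#' subjects as still at risk (events before censorings).
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators, 1 = event observed, 0 = censored.
#' @param group_label Label attached to the curve.
#' @return A tibble of class `dmet_km`, one row per distinct event time:
#'   `time`, `n_at_risk`, `n_event`, `survival`. Attributes carry
#'   `group_label`, `n_subjects`, `n_events`. Before the first event time
#'   the curve equals 1; with no events it is 1 everywhere (zero rows).
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))        # S = 2/3, 1/3, 0
#' km_estimate(c(1, 2, 3), c(1, 0, 1))        # S = 2/3, 2/3 * 0 at t = 3
#' @export
km_estimate <- function(time, event, group_label = "all") {
  if (length(time) == 0) abort("at least one subject is required")
  if (length(event) != length(time)) abort("time and event lengths differ")
  if (any(is.na(time)) || any(!is.finite(time)) || any(time < 0)) {
    abort("times must be finite and >= 0")
  }
  if (any(is.na(event)) || any(!(event %in% c(0, 1)))) {
    abort("event indicators must be 0 or 1")
  }
  ord <- order(time)
  time_s <- time[ord]; event_s <- event[ord]
  etimes <- sort(unique(time_s[event_s == 1]))
  first <- match(etimes, time_s)          # index of first subject with T >= t
  n_at_risk <- length(time) - first + 1
  n_event <- tabulate(match(time_s, etimes)[event_s == 1],
                      nbins = length(etimes))
  surv <- cumprod(1 - n_event / n_at_risk)
  out <- tibble(time = etimes, n_at_risk = as.integer(n_at_risk),
                n_event = as.integer(n_event), survival = surv)
  structure(out, class = c("dmet_km", class(out)),
            group_label = group_label,
            n_subjects = length(time), n_events = sum(event))
}

#' Median survival time of a Kaplan-Meier curve
#'
#' The smallest event time at which the estimated survival drops to 0.5 or
#' below; undefined (`NA`) when the curve never reaches 0.5.
#'
#' @param curve A curve from [km_estimate()].
#' @return A duration, or `NA_real_` when the median is not reached.
#' @export
median_survival <- function(curve) {
  hit <- which(curve$survival <= 0.5 + 1e-12)
  if (length(hit) == 0) NA_real_ else curve$time[hit[1]]
}

#' @method tidy dmet_km
#' @export
tidy.dmet_km <- function(x, ...) as_tibble(unclass_km(x))

#' @method glance dmet_km
#' @export
glance.dmet_km <- function(x, ...) {
  tibble(group_label = attr(x, "group_label"),
         n_subjects = attr(x, "n_subjects"),
         n_events = attr(x, "n_events"),
         median = median_survival(x))
}

#' @method autoplot dmet_km
#' @export
autoplot.dmet_km <- function(object, ...) {
  df <- km_step_coords(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = paste("Kaplan-Meier:", attr(object, "group_label")),
                  x = "time", y = "S(t)") +
    ggplot2::theme_minimal()
}

unclass_km <- function(x) {
  cls <- class(x)
  class(x) <- cls[!startsWith(cls, "dmet_")]
  for (at in c("group_label", "n_subjects", "n_events")) attr(x, at) <- NULL
  x
}

# Step-function coordinates including the (0, 1) origin, for plotting and
# for the per-curve CSV files.
km_step_coords <- function(curve) {
  bind_rows(
    tibble(time = 0, survival = 1,
           n_at_risk = attr(curve, "n_subjects") %||% NA_integer_),
    tibble(time = curve$time, survival = curve$survival,
           n_at_risk = curve$n_at_risk)
  )
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank comparison. At each distinct pooled event time
#' `j` with `d_j` events among `n_j` at risk (`n_1j` in group 1), the expected
#' group-1 events are `E_1j = n_1j d_j / n_j` and the variance term is
#' `V_j = d_j (n_1j / n_j) (1 - n_1j / n_j) (n_j - d_j) / (n_j - 1)` (skipped
#' when `n_j = 1`). The statistic `(O_1 - E_1)^2 / sum(V_j)` is referred to a
#' 1-df chi-square distribution. The hazard ratio is the model-free
#' observed-over-expected form `(O_1 / E_1) / (O_2 / E_2)`.
#'
#' @param time_1,event_1 Times and event indicators of group 1.
#' @param time_2,event_2 Times and event indicators of group 2.
#' @return One-row tibble: `chi_square`, `p_value`, `o1`, `e1`, `o2`, `e2`,
#'   `variance`, `hazard_ratio`, `applicable`. When neither group has an
#'   event the test is flagged not applicable (`chi_square`/`p_value` `NA`).
#' @export
logrank_test <- function(time_1, event_1, time_2, event_2) {
  r <- logrank_core(time_1, event_1, time_2, event_2)
  tibble(chi_square = r[["chi_square"]], p_value = r[["p_value"]],
         o1 = r[["o1"]], e1 = r[["e1"]], o2 = r[["o2"]], e2 = r[["e2"]],
         variance = r[["variance"]], hazard_ratio = r[["hazard_ratio"]],
         applicable = r[["applicable"]] == 1)
}

# Plain-vector implementation behind logrank_test(); kept free of data-frame
# overhead because the screen calls it once per (probe, genotype) pair.
logrank_core <- function(time_1, event_1, time_2, event_2) {
  if (length(time_1) == 0 || length(time_2) == 0) {
    abort("both groups must be non-empty")
  }
  time <- c(time_1, time_2)
  event <- c(event_1, event_2)
  g1 <- rep(c(TRUE, FALSE), c(length(time_1), length(time_2)))
  if (any(is.na(time)) || any(time < 0) || !all(event %in% c(0, 1))) {
    abort("invalid survival data")
  }
  total_events <- sum(event)
  if (total_events == 0) {
    return(c(chi_square = NA_real_, p_value = NA_real_, o1 = 0, e1 = 0,
             o2 = 0, e2 = 0, variance = 0, hazard_ratio = NA_real_,
             applicable = 0))
  }
  ord <- order(time)
  time_s <- time[ord]; event_s <- event[ord]; g1_s <- g1[ord]
  n <- length(time_s); n1 <- sum(g1_s)
  etimes <- sort(unique(time_s[event_s == 1]))
  first <- match(etimes, time_s)   # subjects before this index have T < t
  nj <- n - first + 1
  cum1 <- cumsum(g1_s)
  n1j <- n1 - ifelse(first == 1, 0, cum1[pmax(first - 1, 1)])
  idx <- match(time_s, etimes)
  dj <- tabulate(idx[event_s == 1], nbins = length(etimes))
  d1j <- tabulate(idx[event_s == 1 & g1_s], nbins = length(etimes))
  o1 <- sum(d1j)
  e1 <- sum(n1j * dj / nj)
  vterm <- dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  v <- sum(vterm[nj > 1])
  o2 <- total_events - o1
  e2 <- total_events - e1
  chi <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- if (v > 0) pchisq(chi, df = 1, lower.tail = FALSE) else 1
  hr <- (o1 / e1) / (o2 / e2)
  c(chi_square = chi, p_value = p, o1 = o1, e1 = e1, o2 = o2, e2 = e2,
    variance = v, hazard_ratio = hr, applicable = 1)
}

# Median survival straight from vectors (no curve object), same convention
# as median_survival().
km_median_vec <- function(time, event) {
  ord <- order(time)
  time_s <- time[ord]; event_s <- event[ord]
  etimes <- sort(unique(time_s[event_s == 1]))
  if (length(etimes) == 0) return(NA_real_)
  first <- match(etimes, time_s)
  nj <- length(time_s) - first + 1
  dj <- tabulate(match(time_s, etimes)[event_s == 1], nbins = length(etimes))
  s <- cumprod(1 - dj / nj)
  hit <- which(s <= 0.5 + 1e-12)
  if (length(hit) == 0) NA_real_ else etimes[hit[1]]
}

#' Split samples by genotype at one probe
#'
#' Group 1 contains the called samples carrying `genotype` at `probe`;
#' group 2 contains the samples with any other called genotype. NoCall
#' samples belong to neither group.
#'
#' @param table Long genotype tibble.
#' @param probe Probe identifier.
#' @param genotype Canonical genotype category; must be observed at the probe.
#' @return List with character vectors `group_1` and `group_2` of sample ids.
#' @export
stratify_by_probe <- function(table, probe, genotype) {
  row <- table[table$probe_id == probe & !is.na(table$call), , drop = FALSE]
  if (!genotype %in% row$call) {
    abort(sprintf("genotype '%s' is not observed at probe '%s'", genotype, probe))
  }
  list(group_1 = row$sample_id[row$call == genotype],
       group_2 = row$sample_id[row$call != genotype])
}

#' Per-probe survival screen ranked by log-rank significance
#'
#' For every probe and every observed genotype category, compares the
#' survival of the carriers of that genotype (group 1) against all other
#' called samples (group 2) with the log-rank test, for one endpoint (OS or
#' PFS). Comparisons where either group is empty or no event is observed are
#' skipped. Results are ranked by raw log-rank p-value (ascending; ties by
#' chi-square descending, then probe); a Benjamini-Hochberg adjusted column
#' `p_bh` is added for convenience, but the ranking uses the raw p-values.
#'
#' @param table Long genotype tibble.
#' @param surv Survival annotation tibble (see [read_survival_file()]).
#' @param endpoint `"OS"` or `"PFS"`.
#' @return A tibble of class `dmet_survival_screen`: `probe_id`, `genotype`,
#'   `n1`, `n2`, `o1`, `e1`, `o2`, `e2`, `chi_square`, `p_value`, `p_bh`,
#'   `hazard_ratio`, `median_1`, `median_2`.
#' @export
survival_screen <- function(table, surv, endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  tcol <- if (endpoint == "OS") "os_time" else "pfs_time"
  ecol <- if (endpoint == "OS") "os_event" else "pfs_event"
  ann <- surv[!is.na(surv[[tcol]]) & !is.na(surv[[ecol]]), , drop = FALSE]
  validate_survival(ann)
  if (nrow(ann) < 2) {
    abort(sprintf("fewer than 2 samples carry %s annotations", endpoint))
  }
  tmap <- setNames(ann[[tcol]], ann$sample_id)
  emap <- setNames(ann[[ecol]], ann$sample_id)
  sub <- table %>%
    filter(!is.na(.data$call), .data$sample_id %in% ann$sample_id)
  probes <- intersect(probe_ids(table), unique(sub$probe_id))
  blocks <- split(sub[c("sample_id", "call")],
                  factor(sub$probe_id, levels = probes))
  acc_probe <- character(0); acc_geno <- character(0)
  acc_n1 <- integer(0); acc_n2 <- integer(0)
  acc_stats <- list(); acc_m1 <- numeric(0); acc_m2 <- numeric(0)
  for (pr in probes) {
    block <- blocks[[pr]]
    cats <- sort(unique(block$call), method = "radix")
    if (length(cats) < 2) next
    # with exactly two categories the two category-vs-rest splits are the
    # same comparison; keep only the first
    if (length(cats) == 2) cats <- cats[1]
    bt <- unname(tmap[block$sample_id])
    be <- unname(emap[block$sample_id])
    for (g in cats) {
      in1 <- block$call == g
      t1 <- bt[in1]; e1v <- be[in1]
      t2 <- bt[!in1]; e2v <- be[!in1]
      if (sum(e1v) + sum(e2v) < 1) next
      k <- length(acc_probe) + 1L
      acc_probe[k] <- pr; acc_geno[k] <- g
      acc_n1[k] <- length(t1); acc_n2[k] <- length(t2)
      acc_stats[[k]] <- logrank_core(t1, e1v, t2, e2v)
      acc_m1[k] <- km_median_vec(t1, e1v)
      acc_m2[k] <- km_median_vec(t2, e2v)
    }
  }
  if (length(acc_probe) > 0) {
    st <- do.call(rbind, acc_stats)
    res <- tibble(probe_id = acc_probe, genotype = acc_geno,
                  n1 = acc_n1, n2 = acc_n2,
                  o1 = st[, "o1"], e1 = st[, "e1"],
                  o2 = st[, "o2"], e2 = st[, "e2"],
                  chi_square = st[, "chi_square"], p_value = st[, "p_value"],
                  hazard_ratio = st[, "hazard_ratio"],
                  median_1 = acc_m1, median_2 = acc_m2)
  } else {
    res <- tibble()
  }
  if (nrow(res) == 0) {
    res <- tibble(probe_id = character(), genotype = character(),
                  n1 = integer(), n2 = integer(),
                  o1 = numeric(), e1 = numeric(), o2 = numeric(), e2 = numeric(),
                  chi_square = numeric(), p_value = numeric(), p_bh = numeric(),
                  hazard_ratio = numeric(), median_1 = numeric(),
                  median_2 = numeric())
  } else {
    res <- res %>%
      arrange(.data$p_value, desc(.data$chi_square), .data$probe_id,
              .data$genotype) %>%
      mutate(p_bh = adjust_pvalues(.data$p_value, "fdr")) %>%
      select("probe_id", "genotype", "n1", "n2", "o1", "e1", "o2", "e2",
             "chi_square", "p_value", "p_bh", "hazard_ratio",
             "median_1", "median_2")
  }
  structure(res, class = c("dmet_survival_screen", class(res)),
            endpoint = endpoint)
}

#' @method tidy dmet_survival_screen
#' @export
tidy.dmet_survival_screen <- function(x, ...) as_tibble(unclass_result(x))

#' @method glance dmet_survival_screen
#' @export
glance.dmet_survival_screen <- function(x, ...) {
  tibble(endpoint = attr(x, "endpoint"),
         n_comparisons = nrow(x),
         min_p = if (nrow(x)) min(x$p_value) else NA_real_,
         top_probe = if (nrow(x)) x$probe_id[1] else NA_character_)
}

#' @method autoplot dmet_survival_screen
#' @export
autoplot.dmet_survival_screen <- function(object, top = 30, ...) {
  df <- head(tidy(object), top)
  df$label <- paste0(df$probe_id, " [", df$genotype, "]")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, -.data$p_value),
                                   y = -log10(.data$p_value))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10]~p),
                  title = paste(attr(object, "endpoint"),
                                "log-rank screen")) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curve pair for one probe and genotype
#'
#' @inheritParams survival_screen
#' @param probe,genotype The comparison to plot/export: carriers of
#'   `genotype` at `probe` versus all other called samples.
#' @return Tibble of step-function coordinates for both groups: `group`,
#'   `time`, `survival`, `n_at_risk` (including the `t = 0, S = 1` origin).
#' @export
km_by_genotype <- function(table, surv, probe, genotype,
                           endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  tcol <- if (endpoint == "OS") "os_time" else "pfs_time"
  ecol <- if (endpoint == "OS") "os_event" else "pfs_event"
  ann <- surv[!is.na(surv[[tcol]]) & !is.na(surv[[ecol]]), , drop = FALSE]
  groups <- stratify_by_probe(table, probe, genotype)
  take <- function(ids, label) {
    ids <- intersect(ids, ann$sample_id)
    if (length(ids) == 0) return(NULL)
    idx <- match(ids, ann$sample_id)
    crv <- km_estimate(ann[[tcol]][idx], ann[[ecol]][idx], label)
    df <- km_step_coords(crv)
    df$group <- label
    df[, c("group", "time", "survival", "n_at_risk")]
  }
  bind_rows(take(groups$group_1, genotype),
            take(groups$group_2, "other"))
}
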
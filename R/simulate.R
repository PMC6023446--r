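#' Specification of a synthetic DMET-like dataset
#'
#' Collects every knob of the synthetic-data generator: cohort and array
#' size, the two-class split, the background minor-allele-frequency (MAF)
#' distribution, the missing-call rate, exponential survival parameters and
#' the lists of planted effects. Defaults describe a typical pharmacogenomic
#' screening cohort: 100 samples, 200 probes, an even responder split,
#' background MAF uniform on \[0.1, 0.5\] (DMET probes target ascertained
#' polymorphic variants), 2% NoCalls, baseline hazard 0.1 per time unit and
#' 30% censoring.
#'
#' @param n_samples,n_probes Cohort and array dimensions.
#' @param class_split Proportion of samples in the first class.
#' @param class_labels Length-2 label vector, first label = class A.
#' @param maf_range Background MAF drawn uniformly from this interval.
#' @param nocall_rate Per-cell probability of a NoCall.
#' @param planted_association List of [planted_association()] effects: the
#'   planted genotype is drawn with a different frequency in each class.
#' @param planted_rule List of [planted_rule()] effects: samples carrying the
#'   full antecedent are assigned the target class with the stated
#'   probability.
#' @param planted_survival List of [planted_survival()] effects: carriers of
#'   the planted genotype have their hazard multiplied by the stated ratio.
#' @param baseline_hazard Exponential event hazard for non-carriers.
#' @param censoring_rate Expected censored fraction at the baseline hazard,
#'   achieved with independent uniform censoring (0 disables censoring).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A validated list of class `dmet_sim_spec`.
#' @export
simulation_spec <- function(n_samples = 100, n_probes = 200,
                            class_split = 0.5,
                            class_labels = c("RESP", "NoRESP"),
                            maf_range = c(0.1, 0.5),
                            nocall_rate = 0.02,
                            planted_association = list(),
                            planted_rule = list(),
                            planted_survival = list(),
                            baseline_hazard = 0.1,
                            censoring_rate = 0.3,
                            seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               n_probes = as.integer(n_probes),
               class_split = class_split, class_labels = class_labels,
               maf_range = maf_range, nocall_rate = nocall_rate,
               planted_association = planted_association,
               planted_rule = planted_rule,
               planted_survival = planted_survival,
               baseline_hazard = baseline_hazard,
               censoring_rate = censoring_rate, seed = as.integer(seed))
  props <- c(spec$class_split, spec$nocall_rate, spec$censoring_rate,
             spec$maf_range)
  if (any(props < 0 | props > 1)) abort("all proportions must lie in [0, 1]")
  if (length(class_labels) != 2 || anyDuplicated(class_labels)) {
    abort("class_labels must be two distinct labels")
  }
  planted_probes <- c(
    vapply(planted_association, `[[`, numeric(1), "probe"),
    unlist(lapply(planted_rule, function(r) r$antecedent_probes)),
    vapply(planted_survival, `[[`, numeric(1), "probe")
  )
  if (length(planted_probes) > 0) {
    if (anyDuplicated(planted_probes)) abort("planted probe indices must be distinct")
    if (any(planted_probes < 1 | planted_probes > spec$n_probes)) {
      abort("planted probe indices must lie in 1..n_probes")
    }
  }
  structure(spec, class = "dmet_sim_spec")
}

#' Planted effects for the synthetic generator
#'
#' `planted_association()` plants a genotype whose frequency differs between
#' the classes; `planted_rule()` plants a multi-probe antecedent that
#' predicts the target class with the stated conditional probability (each
#' antecedent probe carries its genotype with frequency `antecedent_freq`);
#' `planted_survival()` multiplies the event hazard of carriers by
#' `hazard_ratio`.
#'
#' @param probe 1-based probe index.
#' @param freq_a,freq_b Frequency of `genotype` in class A / class B.
#' @param genotype Planted genotype category.
#' @return A list describing the effect, for use in [simulation_spec()].
#' @export
planted_association <- function(probe, freq_a, freq_b, genotype = "A/A") {
  list(probe = probe, freq_a = freq_a, freq_b = freq_b,
       genotype = canonicalize_call(genotype)[1])
}

#' @rdname planted_association
#' @param antecedent_probes Integer vector of probe indices forming the
#'   antecedent.
#' @param target_class Class label the rule predicts.
#' @param confidence Probability of the target class given full antecedent
#'   carriage.
#' @param antecedent_freq Carriage frequency of each antecedent genotype.
#' @export
planted_rule <- function(antecedent_probes, target_class, confidence,
                         genotype = "A/A", antecedent_freq = 0.7) {
  list(antecedent_probes = antecedent_probes, target_class = target_class,
       confidence = confidence, genotype = canonicalize_call(genotype)[1],
       antecedent_freq = antecedent_freq)
}

#' @rdname planted_association
#' @param hazard_ratio Hazard multiplier for carriers of `genotype`.
#' @param carrier_freq Carriage frequency of the planted genotype.
#' @export
planted_survival <- function(probe, hazard_ratio, genotype = "A/A",
                             carrier_freq = 0.5) {
  list(probe = probe, hazard_ratio = hazard_ratio,
       genotype = canonicalize_call(genotype)[1], carrier_freq = carrier_freq)
}

# The two genotype categories that accompany a planted category: for a
# planted homozygote A/A over alleles {A, G} these are A/G and G/G.
companion_genotypes <- function(genotype) {
  al <- strsplit(genotype, "/", fixed = TRUE)[[1]]
  other <- if (al[1] == "A") "G" else "A"
  if (al[1] == al[2]) {
    c(paste(sort(c(al[1], other), method = "radix"), collapse = "/"),
      paste(other, other, sep = "/"))
  } else {
    c(paste(al[1], al[1], sep = "/"), paste(al[2], al[2], sep = "/"))
  }
}

draw_planted_column <- function(n, genotype, freq) {
  others <- companion_genotypes(genotype)
  sample(c(genotype, others), n, replace = TRUE,
         prob = c(freq, (1 - freq) / 2, (1 - freq) / 2))
}

#' Generate a synthetic DMET-like dataset with planted effects
#'
#' Produces a genotype table, a two-class assignment and a survival
#' annotation whose ground truth is known. Background probes draw a random
#' biallelic pair and sample genotypes under Hardy-Weinberg proportions from
#' a MAF drawn uniformly on the spec's interval. Planted association probes
#' are drawn per class at the stated genotype frequencies; planted rules
#' re-assign the class of full-antecedent carriers to the target class with
#' the stated probability; planted survival effects multiply the
#' exponential event hazard of carriers. Censoring is independent uniform on
#' `(0, b)` with `b` solved so the expected censored fraction at the baseline
#' hazard equals the spec's rate. NoCalls are sprinkled uniformly at the
#' spec's rate. The whole draw is reproducible from the spec seed.
#'
#' @param spec A [simulation_spec()].
#' @return List with elements `genotype` (long tibble), `classes`,
#'   `survival`, and `truth` (tibbles listing every planted effect).
#' @export
simulate_dataset <- function(spec) {
  if (!inherits(spec, "dmet_sim_spec")) spec <- do.call(simulation_spec, spec)
  withr::with_seed(spec$seed, simulate_dataset_impl(spec))
}

simulate_dataset_impl <- function(spec) {
  n <- spec$n_samples
  n_probes <- spec$n_probes
  samples <- sprintf("S%04d", seq_len(n))
  probes <- sprintf("AM_%05d", seq_len(n_probes))
  labels <- spec$class_labels

  # 1. class assignment from the split
  cls <- ifelse(runif(n) < spec$class_split, labels[1], labels[2])

  calls <- matrix(NA_character_, nrow = n_probes, ncol = n)

  # 2. planted rule antecedent probes, then class re-assignment
  for (rule in spec$planted_rule) {
    carrier <- rep(TRUE, n)
    for (pr in rule$antecedent_probes) {
      calls[pr, ] <- draw_planted_column(n, rule$genotype, rule$antecedent_freq)
      carrier <- carrier & calls[pr, ] == rule$genotype
    }
    other <- setdiff(labels, rule$target_class)
    hit <- carrier & (runif(n) < rule$confidence)
    cls[carrier] <- ifelse(hit[carrier], rule$target_class, other)
  }
  if (length(unique(cls)) < 2) {
    # guarantee two non-empty classes even in tiny draws
    cls[1] <- setdiff(labels, cls[1])[1]
  }

  # 3. planted association probes, drawn per final class
  for (eff in spec$planted_association) {
    is_a <- cls == labels[1]
    col <- character(n)
    col[is_a] <- draw_planted_column(sum(is_a), eff$genotype, eff$freq_a)
    col[!is_a] <- draw_planted_column(sum(!is_a), eff$genotype, eff$freq_b)
    calls[eff$probe, ] <- col
  }

  # 4. planted survival probes
  for (eff in spec$planted_survival) {
    calls[eff$probe, ] <- draw_planted_column(n, eff$genotype, eff$carrier_freq)
  }

  # 5. background probes under Hardy-Weinberg proportions
  base_pairs <- list(c("A", "C"), c("A", "G"), c("A", "T"),
                     c("C", "G"), c("C", "T"), c("G", "T"))
  background <- which(apply(calls, 1, function(r) all(is.na(r))))
  for (pr in background) {
    q <- runif(1, spec$maf_range[1], spec$maf_range[2])
    al <- base_pairs[[sample.int(6, 1)]]
    geno <- c(paste(al[1], al[1], sep = "/"),
              paste(al[1], al[2], sep = "/"),
              paste(al[2], al[2], sep = "/"))
    calls[pr, ] <- sample(geno, n, replace = TRUE,
                          prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  }

  # 6. survival: exponential with planted hazard multipliers, uniform censoring
  hazard <- rep(spec$baseline_hazard, n)
  for (eff in spec$planted_survival) {
    carrier <- calls[eff$probe, ] == eff$genotype
    hazard[carrier] <- hazard[carrier] * eff$hazard_ratio
  }
  death <- rexp(n, rate = hazard)
  progression <- rexp(n, rate = hazard)
  pfs_raw <- pmin(death, progression)
  if (spec$censoring_rate > 0) {
    b <- censor_bound(spec$baseline_hazard, spec$censoring_rate)
    cens <- runif(n, 0, b)
  } else {
    cens <- rep(Inf, n)
  }
  surv <- tibble(
    sample_id = samples,
    os_time = pmin(death, cens),
    os_event = as.numeric(death <= cens),
    pfs_time = pmin(pfs_raw, cens),
    pfs_event = as.numeric(pfs_raw <= cens)
  )

  # 7. sprinkle NoCalls
  if (spec$nocall_rate > 0) {
    drop <- runif(length(calls)) < spec$nocall_rate
    calls[drop] <- NA_character_
  }

  truth <- list(
    associations = bind_rows(lapply(spec$planted_association, function(e) {
      tibble(probe_id = probes[e$probe], genotype = e$genotype,
             freq_a = e$freq_a, freq_b = e$freq_b)
    })),
    rules = bind_rows(lapply(spec$planted_rule, function(e) {
      tibble(antecedent = paste(paste0(probes[e$antecedent_probes], "=",
                                       e$genotype), collapse = ";"),
             target_class = e$target_class, confidence = e$confidence)
    })),
    survival = bind_rows(lapply(spec$planted_survival, function(e) {
      tibble(probe_id = probes[e$probe], genotype = e$genotype,
             hazard_ratio = e$hazard_ratio)
    }))
  )

  list(
    genotype = genotype_table(calls, probes, samples),
    classes = tibble(sample_id = samples,
                     class = factor(cls, levels = labels)),
    survival = surv,
    truth = truth
  )
}

# Upper bound b of Uniform(0, b) censoring such that P(C < T) equals `rate`
# for T ~ Exp(hazard): P(censored) = E[exp(-h C)] = (1 - exp(-h b)) / (h b),
# which decreases from 1 (b -> 0) to 0 (b -> Inf).
censor_bound <- function(hazard, rate) {
  f <- function(b) (1 - exp(-hazard * b)) / (hazard * b) - rate
  uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Write a simulated dataset to a directory of CSV files
#'
#' @param sim Output of [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written (`genotype.csv`, `classes.csv`,
#'   `survival.csv`, `truth.json`).
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("genotype.csv", "classes.csv",
                                "survival.csv", "truth.json"))
  write_genotype_table(sim$genotype, paths[1])
  readr::write_csv(sim$classes, paths[2])
  readr::write_csv(sim$survival, paths[3])
  jsonlite::write_json(sim$truth, paths[4], dataframe = "rows", pretty = TRUE)
  invisible(paths)
}

#' Hand-checkable worked-example dataset
#'
#' A deterministic 8-probe by 12-sample bundle whose screening results can be
#' verified by hand; it exercises every pipeline stage. Samples S01-S06 are
#' `RESP`, S07-S12 `NoRESP`.
#'
#' * `AM_001` separates the classes perfectly (`A/A` in all responders,
#'   `G/G` otherwise): its presence/absence table is (6, 0, 0, 6).
#' * `AM_002` (`A/G` in 8 samples) and `AM_003` (`T/T` in 6) jointly predict
#'   `RESP`: all five S01-S05 carriers of both are responders.
#' * `AM_004` is monomorphic (`A/C` everywhere) and `AM_005` has 3/12
#'   NoCalls, so preprocessing removes both at its defaults.
#' * `AM_006` sits exactly at Hardy-Weinberg proportions (3, 6, 3);
#'   `AM_007` maximally violates them (6, 0, 6).
#' * `AM_008` carriers of `C/T` (S01-S06) survive markedly longer than the
#'   `T/T` group in the attached OS/PFS annotation.
#'
#' @return List with `genotype`, `classes`, `survival` tibbles.
#' @export
worked_example_fixture <- function() {
  samples <- sprintf("S%02d", 1:12)
  calls <- rbind(
    AM_001 = c(rep("A/A", 6), rep("G/G", 6)),
    AM_002 = c(rep("A/G", 8), rep("G/G", 4)),
    AM_003 = c(rep("T/T", 5), "C/T", "C/T", "C/T", "T/T", "C/T", "C/T", "C/T"),
    AM_004 = rep("A/C", 12),
    AM_005 = c(rep("T/T", 6), rep("C/C", 3), rep("NoCall", 3)),
    AM_006 = c(rep("C/C", 3), rep("C/G", 6), rep("G/G", 3)),
    AM_007 = c(rep("C/C", 6), rep("T/T", 6)),
    AM_008 = c(rep("C/T", 6), rep("T/T", 6))
  )
  colnames(calls) <- samples
  surv <- tibble(
    sample_id = samples,
    os_time = c(10, 12, 14, 16, 18, 20, 2, 3, 4, 5, 6, 7),
    os_event = c(1, 1, 1, 1, 0, 1, 1, 1, 1, 1, 1, 1),
    pfs_time = c(8, 10, 12, 14, 16, 18, 1, 2, 3, 4, 5, 6),
    pfs_event = c(1, 1, 1, 1, 0, 1, 1, 1, 1, 1, 1, 1)
  )
  list(
    genotype = genotype_table(calls, rownames(calls), samples),
    classes = tibble(sample_id = samples,
                     class = factor(rep(c("RESP", "NoRESP"), each = 6),
                                    levels = c("RESP", "NoRESP"))),
    survival = surv
  )
}
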
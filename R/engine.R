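#' Deterministic parallel map
#'
#' Applies `.f` to every element of `.x`, optionally on a bounded pool of
#' forked workers, and returns the results in input order. Results are
#' identical to sequential execution for any worker count; a failure in one
#' item propagates as an error naming that item.
#'
#' @param .x List (or vector) of independent work items.
#' @param .f Function (or purrr-style lambda) applied to each item.
#' @param workers Number of worker processes; `1` runs sequentially in the
#'   current process, `0` auto-detects the available cores.
#' @param ... Further arguments passed to `.f`.
#' @return List of results, same length and order as `.x`.
#' @export
parallel_map <- function(.x, .f, workers = 1L, ...) {
  .f <- rlang::as_function(.f)
  workers <- resolve_workers(workers)
  nm <- names(.x) %||% as.character(seq_along(.x))
  run_one <- function(i) {
    tryCatch(list(ok = TRUE, value = .f(.x[[i]], ...)),
             error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
  }
  idx <- seq_along(.x)
  res <- if (workers <= 1L || length(.x) < 2L) {
    lapply(idx, run_one)
  } else {
    parallel::mclapply(idx, run_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  }
  for (i in idx) {
    r <- res[[i]]
    if (!is.list(r) || !isTRUE(r$ok)) {
      msg <- if (is.list(r)) r$msg else as.character(r)
      abort(sprintf("parallel_map failed on item '%s': %s", nm[i], msg))
    }
  }
  lapply(res, `[[`, "value")
}

resolve_workers <- function(workers) {
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 0) abort("workers must be a non-negative integer")
  if (workers == 0L) workers <- parallel::detectCores()
  min(workers, parallel::detectCores())
}

#' Pipeline configuration
#'
#' Bundles every input and tuning parameter of [run_pipeline()]. Genotype,
#' class and survival inputs may be given as file paths or as already-loaded
#' tibbles; the survival input is optional (the survival stage is then
#' skipped and the skip recorded in the manifest).
#'
#' @param genotype Genotype table: path or long tibble.
#' @param classes Class assignment: path or tibble.
#' @param survival Optional survival annotation: path or tibble.
#' @param max_nocall_fraction,drop_monomorphic Preprocessing thresholds (see
#'   [filter_uninformative()]).
#' @param corrector,alpha Association-screen correction and significance
#'   level (see [fisher_screen()]).
#' @param fisher_filter,min_support,min_confidence Rule-mining parameters
#'   (see [mine_rules()]).
#' @param endpoints Survival endpoints to screen, subset of `c("OS", "PFS")`.
#' @param workers Worker count for per-probe stages and the two analysis
#'   branches; `0` auto-detects. Outputs are identical for any value.
#' @param seed Integer seed echoed into the manifest (the analyses themselves
#'   are deterministic; only synthetic-data generation consumes randomness).
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes the full results bundle there.
#' @param delim,transpose Genotype file dialect (see
#'   [read_genotype_table()]).
#' @return A validated list of class `dmet_config`.
#' @export
pipeline_config <- function(genotype, classes, survival = NULL,
                            max_nocall_fraction = 0.1,
                            drop_monomorphic = TRUE,
                            corrector = c("bonferroni", "fdr", "none"),
                            alpha = 0.05,
                            fisher_filter = 0.05, min_support = 0.2,
                            min_confidence = 0.8,
                            endpoints = c("OS", "PFS"),
                            workers = 1L, seed = NULL, out_dir = NULL,
                            delim = ",", transpose = FALSE) {
  corrector <- match.arg(corrector)
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  stopifnot(alpha > 0, alpha <= 1,
            max_nocall_fraction >= 0, max_nocall_fraction <= 1,
            fisher_filter > 0, fisher_filter <= 1,
            min_support > 0, min_support <= 1,
            min_confidence > 0, min_confidence <= 1)
  resolve_workers(workers)  # validates
  structure(list(genotype = genotype, classes = classes, survival = survival,
                 max_nocall_fraction = max_nocall_fraction,
                 drop_monomorphic = drop_monomorphic,
                 corrector = corrector, alpha = alpha,
                 fisher_filter = fisher_filter, min_support = min_support,
                 min_confidence = min_confidence, endpoints = endpoints,
                 workers = as.integer(workers), seed = seed,
                 out_dir = out_dir, delim = delim, transpose = transpose),
            class = "dmet_config")
}

#' Run the full screening pipeline
#'
#' Executes the stage graph load/parse -> preprocess -> \{survival screens\}
#' in parallel with \{Fisher screen + HWE -> rule mining\}. The survival
#' branch and the statistical branch are independent: a failure in one is
#' recorded in the manifest while the other still completes. All results are
#' bit-identical for the same configuration regardless of the worker count.
#'
#' @param config A [pipeline_config()] (or arguments for one).
#' @return An object of class `dmet_pipeline`: a list with the filtered
#'   `table`, `distribution`, `fisher`, `hwe`, `rules`, per-endpoint
#'   `survival` screens, the per-stage `stages` status tibble and the echoed
#'   `config`. When `config$out_dir` is set the results bundle is written
#'   there (see [write_results_bundle()]).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "dmet_config")) config <- do.call(pipeline_config, config)
  stages <- list()
  note_stage <- function(name, status, message = NA_character_, secs = NA_real_) {
    stages[[name]] <<- tibble(stage = name, status = status,
                              message = message, seconds = secs)
  }
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    tryCatch({
      value <- force(expr)
      note_stage(name, "completed", secs = proc.time()[["elapsed"]] - t0)
      value
    }, error = function(e) {
      note_stage(name, "failed", conditionMessage(e),
                 proc.time()[["elapsed"]] - t0)
      NULL
    })
  }

  # ---- load ----
  loaded <- run_stage("load", {
    gt <- if (is.character(config$genotype)) {
      read_genotype_table(config$genotype, delim = config$delim,
                          transpose = config$transpose)
    } else config$genotype
    cl <- if (is.character(config$classes)) {
      read_class_file(config$classes, table = gt)
    } else config$classes
    sv <- if (is.null(config$survival)) NULL
          else if (is.character(config$survival)) {
            read_survival_file(config$survival, table = gt)
          } else config$survival
    check_two_classes(cl)
    list(gt = gt, cl = cl, sv = sv)
  })
  if (is.null(loaded)) {
    return(finish_pipeline(NULL, stages, config))
  }

  # ---- preprocess ----
  prep <- run_stage("preprocess", {
    filtered <- filter_uninformative(loaded$gt,
                                     max_nocall_fraction = config$max_nocall_fraction,
                                     drop_monomorphic = config$drop_monomorphic)
    list(table = filtered, report = preprocess_report(filtered),
         distribution = genotype_distribution(loaded$gt))
  })
  if (is.null(prep)) {
    return(finish_pipeline(NULL, stages, config))
  }

  # ---- two independent branches ----
  stat_branch <- function() {
    out <- list()
    out$fisher <- run_stage("fisher", {
      fisher_screen(prep$table, loaded$cl, corrector = config$corrector,
                    alpha = config$alpha, workers = 1L)
    })
    out$hwe <- run_stage("hwe", hwe_test(prep$table))
    out$rules <- run_stage("rules", {
      mine_rules(prep$table, loaded$cl,
                 fisher_threshold = config$fisher_filter,
                 min_support = config$min_support,
                 min_confidence = config$min_confidence, workers = 1L)
    })
    list(out = out, stages = stages[c("fisher", "hwe", "rules")])
  }
  surv_branch <- function() {
    out <- list()
    for (ep in c("OS", "PFS")) {
      nm <- paste0("survival_", ep)
      if (is.null(loaded$sv)) {
        note_stage(nm, "skipped", "no survival annotation supplied")
      } else if (!ep %in% config$endpoints) {
        note_stage(nm, "skipped", "endpoint not requested")
      } else {
        out[[ep]] <- run_stage(nm, survival_screen(prep$table, loaded$sv, ep))
      }
    }
    list(out = out, stages = stages[c("survival_OS", "survival_PFS")])
  }

  workers <- resolve_workers(config$workers)
  if (workers > 1L) {
    branches <- parallel_map(list(stat = stat_branch, surv = surv_branch),
                             function(f) f(), workers = 2L)
  } else {
    branches <- list(stat = stat_branch(), surv = surv_branch())
  }
  # merge stage notes taken inside forked branches
  for (br in branches) for (nm in names(br$stages)) stages[[nm]] <- br$stages[[nm]]

  result <- list(
    table = prep$table,
    preprocess = prep$report,
    distribution = prep$distribution,
    fisher = branches$stat$out$fisher,
    hwe = branches$stat$out$hwe,
    rules = branches$stat$out$rules,
    survival = branches$surv$out
  )
  finish_pipeline(result, stages, config)
}

finish_pipeline <- function(result, stages, config) {
  out <- c(result, list(
    stages = bind_rows(stages),
    config = config,
    version = as.character(packageVersion("dmetscreen"))
  ))
  class(out) <- "dmet_pipeline"
  if (!is.null(config$out_dir)) write_results_bundle(out, config$out_dir)
  out
}

#' @method print dmet_pipeline
#' @export
print.dmet_pipeline <- function(x, ...) {
  cat("<dmet_pipeline>\n")
  st <- x$stages
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  %-12s %s%s\n", st$stage[i], st$status[i],
                ifelse(is.na(st$message[i]), "",
                       paste0(" (", st$message[i], ")"))))
  }
  if (!is.null(x$fisher)) {
    cat(sprintf("  fisher: %d tests, %d significant\n",
                nrow(x$fisher), sum(x$fisher$significant)))
  }
  if (!is.null(x$rules)) cat(sprintf("  rules: %d\n", nrow(x$rules)))
  for (ep in names(x$survival)) {
    cat(sprintf("  survival %s: %d comparisons\n", ep, nrow(x$survival[[ep]])))
  }
  invisible(x)
}

#' @method glance dmet_pipeline
#' @export
glance.dmet_pipeline <- function(x, ...) {
  tibble(
    n_probes_retained = length(probe_ids(x$table)),
    n_fisher_tests = if (is.null(x$fisher)) NA_integer_ else nrow(x$fisher),
    n_significant = if (is.null(x$fisher)) NA_integer_ else sum(x$fisher$significant),
    n_rules = if (is.null(x$rules)) NA_integer_ else nrow(x$rules),
    n_survival_os = if (is.null(x$survival$OS)) NA_integer_ else nrow(x$survival$OS),
    n_survival_pfs = if (is.null(x$survival$PFS)) NA_integer_ else nrow(x$survival$PFS)
  )
}

#' Write the full results bundle of a pipeline run
#'
#' Writes deterministic CSV outputs for every completed stage plus a JSON run
#' manifest: `fisher_results.csv`, `hwe_results.csv`, one `rules_<class>.csv`
#' per class (header-only when no rule survives), `survival_OS.csv` /
#' `survival_PFS.csv`, one `km_curve_<probe>_<group>.csv` per significant
#' survival comparison, `heatmap_matrix.csv`, `preprocess_report.csv` and
#' `run_manifest.json`. Identical inputs and configuration produce
#' byte-identical CSV files; the manifest additionally records wall times and
#' is informational.
#'
#' @param result A `dmet_pipeline` object.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_results_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path, progress = FALSE)
    files[[name]] <<- nrow(df)
  }
  if (!is.null(result$preprocess)) emit(result$preprocess, "preprocess_report.csv")
  if (!is.null(result$distribution)) {
    emit(as_tibble(unclass_result(result$distribution)), "heatmap_matrix.csv")
  }
  if (!is.null(result$fisher)) emit(tidy(result$fisher), "fisher_results.csv")
  if (!is.null(result$hwe)) emit(result$hwe, "hwe_results.csv")
  if (!is.null(result$rules)) {
    by_class <- attr(result$rules, "by_class")
    for (cl in names(by_class)) {
      df <- by_class[[cl]]
      df$antecedent <- vapply(df$antecedent, paste, character(1), collapse = ";")
      emit(as_tibble(df)[, c("antecedent", "consequent", "support",
                             "confidence", "antecedent_support")],
           sprintf("rules_%s.csv", sanitize_token(cl)))
    }
  }
  alpha <- result$config$alpha %||% 0.05
  for (ep in names(result$survival)) {
    scr <- result$survival[[ep]]
    emit(tidy(scr), sprintf("survival_%s.csv", ep))
    sig <- scr[scr$p_value <= alpha, , drop = FALSE]
    sv <- if (is.character(result$config$survival)) {
      read_survival_file(result$config$survival, table = result$table)
    } else result$config$survival
    for (i in seq_len(nrow(sig))) {
      curves <- km_by_genotype(result$table, sv, sig$probe_id[i],
                               sig$genotype[i], endpoint = ep)
      for (grp in unique(curves$group)) {
        nm <- sprintf("km_curve_%s_%s.csv", sig$probe_id[i],
                      sanitize_token(paste(ep, sig$genotype[i], grp, sep = "_")))
        emit(curves[curves$group == grp, c("time", "survival", "n_at_risk")], nm)
      }
    }
  }
  manifest <- list(
    package = "dmetscreen",
    version = result$version,
    config = manifest_config(result$config),
    correction_family = "probe x genotype",
    stages = result$stages,
    files = tibble(file = names(files), rows = unlist(unname(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

manifest_config <- function(config) {
  cfg <- unclass(config)
  for (nm in c("genotype", "classes", "survival")) {
    cfg[[nm]] <- if (is.character(cfg[[nm]])) cfg[[nm]]
                 else if (is.null(cfg[[nm]])) NULL else "<in-memory>"
  }
  cfg
}

sanitize_token <- function(x) gsub("[^A-Za-z0-9_.-]", "-", x)
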
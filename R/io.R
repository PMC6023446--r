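#' Build a genotype table from a character matrix of calls
#'
#' Constructs the long-format genotype table used throughout the package from
#' a probes-by-samples character matrix. Cells are canonicalized with
#' [canonicalize_call()]; `"NoCall"` and unparseable cells become `NA`.
#'
#' @param calls Character matrix, rows = probes, columns = samples.
#' @param probe_ids,sample_ids Identifiers; default to `rownames`/`colnames`.
#' @return A tibble with columns `probe_id`, `sample_id`, `call` (canonical
#'   call or `NA`), ordered probe-major. Probe and sample order follow the
#'   input.
#' @export
genotype_table <- function(calls, probe_ids = rownames(calls),
                           sample_ids = colnames(calls)) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (is.null(probe_ids)) probe_ids <- paste0("P", seq_len(nrow(calls)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(calls)))
  check_unique_ids(probe_ids, "probe")
  check_unique_ids(sample_ids, "sample")
  stopifnot(length(probe_ids) == nrow(calls),
            length(sample_ids) == ncol(calls))
  canon <- canonicalize_call(as.vector(t(calls)))
  tibble(
    probe_id = rep(as.character(probe_ids), each = length(sample_ids)),
    sample_id = rep(as.character(sample_ids), times = length(probe_ids)),
    call = as.character(canon)
  )
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate %s identifier(s): %s", what,
                  paste(dup, collapse = ", ")))
  }
  invisible(ids)
}

probe_ids <- function(table) unique(table$probe_id)
sample_ids <- function(table) unique(table$sample_id)

#' Read a DMET-style genotype-call table
#'
#' Reads a delimited text export of a genotype-call table: one row per probe,
#' one column per sample, first column holding probe identifiers and the
#' header row holding sample identifiers (use `transpose = TRUE` for the
#' samples-as-rows layout). Cells are diploid calls such as `"A/A"` or
#' `"G/A"`, or the missing token `"NoCall"`. All calls are canonicalized so
#' heterozygote allele order is irrelevant; cells that cannot be parsed as a
#' call are mapped to missing and recorded in the parse report (see
#' [parse_report()]) rather than aborting the read.
#'
#' @param path Path to the file.
#' @param delim Field delimiter, default `","` (`"\t"` for TSV exports).
#' @param transpose If `TRUE`, the file stores samples as rows and probes as
#'   columns.
#' @return A long tibble (`probe_id`, `sample_id`, `call`), probe-major, with
#'   attribute `"parse_report"`: a tibble of cells that were neither valid
#'   calls nor a recognised missing token.
#' @details Ragged rows (a row whose field count differs from the header) and
#'   duplicated probe or sample identifiers are hard errors naming the
#'   offending line or identifier. Numeric parsing is locale-independent.
#' @export
read_genotype_table <- function(path, delim = ",", transpose = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  header <- trimws(header)
  body <- readr::read_delim(
    path, delim = delim, col_names = FALSE, skip = 1L,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
  probs <- readr::problems(body)
  if (nrow(probs) > 0) {
    bad <- probs[grepl("columns", probs$expected), , drop = FALSE]
    if (nrow(bad) > 0) {
      abort(sprintf(
        "ragged row in %s: line %d has %s where %s were expected",
        path, bad$row[1] + 1L, bad$actual[1], bad$expected[1]
      ))
    }
  }
  if (nrow(body) == 0) abort(sprintf("no data rows in %s", path))
  if (ncol(body) != length(header)) {
    abort(sprintf("header of %s has %d fields but data rows have %d",
                  path, length(header), ncol(body)))
  }
  row_ids <- as.character(body[[1]])
  col_ids <- header[-1]
  cells <- as.matrix(body[, -1, drop = FALSE])
  dimnames(cells) <- NULL
  if (transpose) {
    cells <- t(cells)
    tmp <- row_ids; row_ids <- col_ids; col_ids <- tmp
  }
  check_unique_ids(row_ids, "probe")
  check_unique_ids(col_ids, "sample")
  canon <- canonicalize_call(as.vector(t(cells)))
  unparseable <- attr(canon, "unparseable")
  out <- tibble(
    probe_id = rep(row_ids, each = length(col_ids)),
    sample_id = rep(col_ids, times = length(row_ids)),
    call = as.character(canon)
  )
  report <- out[unparseable, c("probe_id", "sample_id")]
  report$raw <- as.vector(t(cells))[unparseable]
  if (nrow(report) > 0) {
    warn(sprintf("%d cell(s) could not be parsed as genotype calls; treated as NoCall (see parse_report())",
                 nrow(report)))
  }
  attr(out, "parse_report") <- as_tibble(report)
  out
}

#' Parse report of a genotype table read
#'
#' @param table A table returned by [read_genotype_table()].
#' @return Tibble of unparseable cells (`probe_id`, `sample_id`, `raw`), or an
#'   empty tibble when every cell parsed.
#' @export
parse_report <- function(table) {
  attr(table, "parse_report") %||%
    tibble(probe_id = character(), sample_id = character(), raw = character())
}

#' Write a genotype table to delimited text
#'
#' Inverse of [read_genotype_table()]: probes as rows, samples as columns,
#' missing calls written as `"NoCall"`. Reading the file back yields a table
#' equal to the input (calls are already canonical).
#'
#' @param table Long genotype tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path, delim = ",") {
  wide <- table %>%
    mutate(call = ifelse(is.na(.data$call), NOCALL_TOKEN, .data$call)) %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "call")
  readr::write_delim(wide, path, delim = delim)
  invisible(path)
}

#' Read a two-class phenotype assignment file
#'
#' Reads a two-column delimited file (`sample_id`, class label) assigning each
#' sample to one of exactly two phenotype classes (for example responders
#' `RESP` versus non-responders `NoRESP`). The first class level is "class A"
#' in every downstream contingency table.
#'
#' @param path Path to the file (header row required).
#' @param table Optional genotype table defining the sample universe. Samples
#'   in the class file but absent from the table are dropped with a warning;
#'   an error is raised if a class becomes empty after the intersection.
#' @param levels Optional length-2 character vector fixing the class order;
#'   defaults to order of first appearance in the file, except that the pair
#'   `RESP`/`NoRESP` always orders `RESP` first.
#' @return Tibble (`sample_id`, `class`) with `class` a two-level factor.
#' @export
read_class_file <- function(path, table = NULL, levels = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(path, delim = ",",
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2) abort("class file must have two columns: sample_id, class")
  cls <- tibble(sample_id = as.character(raw[[1]]),
                class = as.character(raw[[2]]))
  check_unique_ids(cls$sample_id, "sample")
  observed <- unique(cls$class)
  if (length(observed) > 2) {
    abort(sprintf("class file defines %d labels (%s); exactly two are required",
                  length(observed), paste(observed, collapse = ", ")))
  }
  if (is.null(levels)) {
    levels <- if (setequal(observed, c("RESP", "NoRESP"))) {
      c("RESP", "NoRESP")
    } else {
      observed
    }
  }
  if (!all(cls$class %in% levels)) {
    abort(sprintf("class label(s) outside the declared levels: %s",
                  paste(setdiff(cls$class, levels), collapse = ", ")))
  }
  cls$class <- factor(cls$class, levels = levels)
  if (!is.null(table)) cls <- intersect_with_table(cls, table, "class")
  check_two_classes(cls)
  cls
}

intersect_with_table <- function(df, table, what) {
  universe <- sample_ids(table)
  extra <- setdiff(df$sample_id, universe)
  if (length(extra) > 0) {
    warn(sprintf("%d sample(s) in the %s file are absent from the genotype table and were dropped: %s",
                 length(extra), what, paste(head(extra, 10), collapse = ", ")))
    df <- df[df$sample_id %in% universe, , drop = FALSE]
  }
  df
}

check_two_classes <- function(classes) {
  sizes <- table(classes$class)
  if (length(sizes) != 2 || any(sizes == 0)) {
    abort(sprintf("both phenotype classes must be non-empty (sizes: %s)",
                  paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
  }
  invisible(classes)
}

#' Read a per-sample survival annotation file
#'
#' Reads a delimited file with columns `sample_id`, `os_time`, `os_event` and
#' optionally `pfs_time`, `pfs_event`, where times are non-negative follow-up
#' durations and events are `1` (event observed) or `0` (censored). Overall
#' survival (OS) and progression-free survival (PFS) are screened
#' independently downstream; samples lacking a row are simply excluded from
#' the survival stage.
#'
#' @inheritParams read_class_file
#' @return Tibble (`sample_id`, `os_time`, `os_event`, `pfs_time`,
#'   `pfs_event`); PFS columns are `NA` when absent from the file. Rows with
#'   `pfs_time > os_time` are accepted with a warning.
#' @export
read_survival_file <- function(path, table = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(path, delim = ",", trim_ws = TRUE, progress = FALSE,
                           show_col_types = FALSE,
                           col_types = readr::cols(
                             sample_id = readr::col_character(),
                             .default = readr::col_double()
                           ))
  need <- c("sample_id", "os_time", "os_event")
  if (!all(need %in% names(raw))) {
    abort(sprintf("survival file must contain columns %s",
                  paste(need, collapse = ", ")))
  }
  surv <- tibble(
    sample_id = raw$sample_id,
    os_time = raw$os_time,
    os_event = raw$os_event,
    pfs_time = if ("pfs_time" %in% names(raw)) raw$pfs_time else NA_real_,
    pfs_event = if ("pfs_event" %in% names(raw)) raw$pfs_event else NA_real_
  )
  check_unique_ids(surv$sample_id, "sample")
  validate_survival(surv)
  if (!is.null(table)) surv <- intersect_with_table(surv, table, "survival")
  surv
}

validate_survival <- function(surv) {
  times <- c(surv$os_time, surv$pfs_time)
  if (any(!is.na(times) & (!is.finite(times) | times < 0))) {
    abort("survival times must be finite and >= 0")
  }
  events <- c(surv$os_event, surv$pfs_event)
  if (any(!is.na(events) & !(events %in% c(0, 1)))) {
    abort("event indicators must be 0 (censored) or 1 (event)")
  }
  viol <- !is.na(surv$pfs_time) & !is.na(surv$os_time) &
    surv$pfs_time > surv$os_time
  if (any(viol)) {
    warn(sprintf("%d sample(s) have pfs_time > os_time: %s",
                 sum(viol), paste(head(surv$sample_id[viol], 10), collapse = ", ")))
  }
  invisible(surv)
}
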
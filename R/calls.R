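#' Canonicalize diploid genotype-call strings
#'
#' DMET-style genotype tables store a diploid call per probe/sample cell as
#' two allele symbols separated by `/` (for example `"A/G"`), or the literal
#' `"NoCall"` when the array could not call the genotype. Heterozygous calls
#' may be written in either allele order; `canonicalize_call()` maps each call
#' to a canonical form in which the two alleles are sorted under a fixed
#' (C-locale lexicographic) total order, so that `"G/A"` and `"A/G"` compare
#' equal. Missing calls and strings that are not parseable as calls become
#' `NA`.
#'
#' An allele symbol is a single IUPAC base code (`A`, `C`, `G`, `T` or an
#' ambiguity code), the deletion token `"-"`, or a multi-base insertion string
#' such as `"TA"`. Half-calls with one empty side (e.g. `"A/"`) are treated as
#' unparseable, i.e. missing.
#'
#' @param x Character vector of raw call strings.
#' @return A character vector the same length as `x`: canonical `"a1/a2"`
#'   strings with `a1 <= a2`, or `NA` for `"NoCall"` / unparseable cells. The
#'   logical attribute `"unparseable"` marks cells that were neither valid
#'   calls nor a recognised missing token.
#' @examples
#' canonicalize_call(c("G/A", "A/A", "NoCall", "T/-", "??"))
#' @export
canonicalize_call <- function(x) {
  x <- as.character(x)
  trimmed <- trimws(x)
  missing_token <- is.na(trimmed) | tolower(trimmed) %in%
    c("nocall", "no call", "no_call", "na", "---", "")
  allele_re <- "([ACGTRYSWKMBDHVN]+|-)"
  call_re <- paste0("^", allele_re, "/", allele_re, "$")
  valid <- !missing_token & grepl(call_re, toupper(trimmed))
  out <- rep(NA_character_, length(x))
  if (any(valid)) {
    up <- toupper(trimmed[valid])
    a1 <- sub("/.*$", "", up)
    a2 <- sub("^.*/", "", up)
    # C-locale allele order, vectorized via ranks in a radix-sorted level set
    lv <- sort(unique(c(a1, a2)), method = "radix")
    swap <- match(a1, lv) > match(a2, lv)
    out[valid] <- ifelse(swap, paste(a2, a1, sep = "/"),
                         paste(a1, a2, sep = "/"))
  }
  attr(out, "unparseable") <- !missing_token & !valid
  out
}

# Alleles of a vector of canonical calls, as a character vector (2 per call).
# NA calls contribute nothing.
call_alleles <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L) return(character(0))
  unlist(strsplit(calls, "/", fixed = TRUE), use.names = FALSE)
}

# Token used for missing calls when writing tables to disk.
NOCALL_TOKEN <- "NoCall"
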
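#' Write results as a tab-separated table
#'
#' One data row per retained term with columns `go_id`, `category`,
#' `background_genes`, `genes` (comma+space separated, sorted), `score`
#' (4 decimal places, round-half-even) and `term_name`.  Deterministic:
#' identical inputs produce identical bytes.
#'
#' @param terms A `goleaf` object or its `tidy()` tibble (already
#'   ranked).
#' @param path Output file path, or `""` for standard output.
#' @return Invisibly, the number of data rows written.
#' @export
write_results <- function(terms, path) {
  if (inherits(terms, "goleaf")) terms <- tidy(terms)
  con <- if (identical(path, "")) stdout() else {
    ok <- tryCatch(file(path, open = "wt"), error = function(e) NULL)
    if (is.null(ok)) {
      abort(paste0("Cannot open output path: ", path),
            class = "goleaf_io_error")
    }
    ok
  }
  if (!identical(path, "")) on.exit(close(con))
  header <- c("go_id", "category", "background_genes", "genes", "score",
              "term_name")
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(terms) > 0) {
    rows <- vapply(seq_len(nrow(terms)), function(i) {
      paste(
        terms$term_id[i],
        terms$category[i],
        terms$background_genes[i],
        paste(sort(terms$shared_genes[[i]]), collapse = ", "),
        format_score(terms$score[i]),
        terms$term_name[i],
        sep = "\t"
      )
    }, character(1))
    writeLines(rows, con)
  }
  invisible(nrow(terms))
}

# 4 decimal places; sprintf on doubles applies IEEE round-half-even.
format_score <- function(x) sprintf("%.4f", x)

#' Read back a results table written by [write_results()]
#'
#' @param path Path to a TSV produced by [write_results()].
#' @return Tibble with the written columns; `genes` is split back into
#'   a `shared_genes` list-column and `score` parsed numeric.
#' @export
read_results <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         colClasses = "character")
  tibble::tibble(
    term_id = d$go_id,
    category = d$category,
    background_genes = as.integer(d$background_genes),
    shared_genes = strsplit(d$genes, ", ", fixed = TRUE),
    n_shared = lengths(strsplit(d$genes, ", ", fixed = TRUE)),
    score = as.numeric(d$score),
    term_name = d$term_name
  )
}
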
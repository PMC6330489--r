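#' Read a GAF 2.x gene-association file
#'
#' Parses the tab-separated GAF 2.1/2.2 format (17 columns, `!` comment
#' lines).  Records whose qualifier contains `NOT` are dropped — a NOT
#' annotation states that the gene does *not* have the function, so it
#' must never feed shared-term detection.  Records are then restricted to
#' the requested evidence codes.
#'
#' @param path Path to a GAF file.
#' @param evidence_filter Character vector of evidence codes to keep, or
#'   `"ALL"` (default) to keep every code.  See [go_evidence_codes].
#' @return A tibble with one row per retained annotation: `gene_id`
#'   (column 2, the database object id), `gene_symbol` (column 3),
#'   `qualifier`, `term_id` (column 5), `evidence_code` (column 7) and
#'   `taxon` (column 13).
#' @examples
#' fx <- simulate_go_fixture(seed = 1, dir = tempfile("fx"))
#' ann <- read_gaf(fx$paths$gaf)
#' dplyr::count(ann, evidence_code)
#' @export
read_gaf <- function(path, evidence_filter = "ALL") {
  if (!file.exists(path)) {
    abort(paste0("GAF file not found: ", path), class = "goleaf_io_error")
  }
  check_evidence_filter(evidence_filter)
  lines <- readLines(path, warn = FALSE)
  data_at <- which(!startsWith(lines, "!") & nzchar(trimws(lines)))
  if (length(data_at) == 0) {
    return(empty_annotation_tbl())
  }
  # sentinel keeps trailing empty columns countable
  fields <- strsplit(paste0(lines[data_at], "\tEOL"), "\t", fixed = TRUE)
  nfield <- lengths(fields) - 1L
  bad <- which(nfield != 17)
  if (length(bad) > 0) {
    abort(paste0("GAF line ", data_at[bad[1]], " has ", nfield[bad[1]],
                 " columns; expected 17"),
          class = "goleaf_parse_error")
  }
  m <- do.call(rbind, fields)
  rec <- tibble::tibble(
    gene_id = m[, 2],
    gene_symbol = m[, 3],
    qualifier = m[, 4],
    term_id = m[, 5],
    evidence_code = m[, 7],
    taxon = m[, 13]
  )

  unknown <- setdiff(unique(rec$evidence_code), go_evidence_codes)
  if (length(unknown) > 0) {
    warn(paste0("Evidence code(s) outside the GO vocabulary kept as-is: ",
                paste(unknown, collapse = ", ")))
  }

  has_not <- vapply(
    strsplit(rec$qualifier, "|", fixed = TRUE),
    function(q) "NOT" %in% q, logical(1)
  )
  rec <- rec[!has_not, , drop = FALSE]

  if (!identical(evidence_filter, "ALL")) {
    rec <- rec[rec$evidence_code %in% evidence_filter, , drop = FALSE]
  }
  rec
}

empty_annotation_tbl <- function() {
  tibble::tibble(gene_id = character(0), gene_symbol = character(0),
                 qualifier = character(0), term_id = character(0),
                 evidence_code = character(0), taxon = character(0))
}

check_evidence_filter <- function(evidence_filter) {
  if (identical(evidence_filter, "ALL")) return(invisible(TRUE))
  bad <- setdiff(evidence_filter, go_evidence_codes)
  if (length(bad) > 0) {
    abort(paste0("Unknown evidence code(s): ", paste(bad, collapse = ", ")),
          class = "goleaf_input_error")
  }
  invisible(TRUE)
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and `#` comment lines are
#' skipped; surrounding whitespace is trimmed.
#'
#' @param path Path to a UTF-8 text file.
#' @return Character vector of raw identifiers (possibly with
#'   duplicates; deduplication happens at matching time).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Gene list not found: ", path), class = "goleaf_io_error")
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    abort(paste0("Gene list is empty after stripping blanks/comments: ",
                 path),
          class = "goleaf_input_error")
  }
  lines
}
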
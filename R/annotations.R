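#' Build a bidirectional gene/term annotation index
#'
#' Turns GAF records into gene-to-terms and term-to-genes maps, resolving
#' alternate ids against the ontology and quarantining records whose term
#' cannot be resolved (unknown or obsolete).  With `propagate = TRUE`
#' (the default) every annotation is extended to all ancestors of its
#' term — the true-path rule: a gene annotated to a term is implicitly
#' annotated to every ancestor of that term.  Background counts
#' \eqn{g(t)} are taken from this index over the whole filtered
#' annotation file, independent of any input gene list.
#'
#' Genes are keyed by the database object id (GAF column 2); symbols are
#' kept as a matching convenience because symbols collide across
#' sources.
#'
#' @param records Annotation tibble from [read_gaf()].
#' @param ontology A `go_ontology` from [read_obo()].
#' @param propagate Propagate annotations to ancestor terms (default
#'   `TRUE`, matching the ancestor-inclusive gene maps of the classic
#'   Bioconductor GO builds).  Switchable for sensitivity analysis.
#' @return A `go_annotation_index`: list with `gene_to_terms` and
#'   `term_to_genes` (named lists of sorted character vectors, exact
#'   transposes of each other), `symbol_to_gene` (named vector, upper-
#'   cased symbol -> gene id), `propagated`, `background_size` (distinct
#'   genes) and `quarantined` (count of dropped records).
#' @examples
#' fx <- simulate_go_fixture(seed = 1, dir = tempfile("fx"))
#' ont <- read_obo(fx$paths$obo)
#' idx <- build_annotation_index(read_gaf(fx$paths$gaf), ont)
#' idx
#' @export
build_annotation_index <- function(records, ontology, propagate = TRUE) {
  stopifnot(inherits(ontology, "go_ontology"))

  resolved <- rep(NA_character_, nrow(records))
  primary <- ontology$terms$term_id
  known <- match(records$term_id, primary)
  resolved[!is.na(known)] <- records$term_id[!is.na(known)]
  alt_hit <- is.na(resolved) & records$term_id %in% names(ontology$alt_index)
  resolved[alt_hit] <- unname(ontology$alt_index[records$term_id[alt_hit]])

  quarantined <- sum(is.na(resolved))
  if (quarantined > 0) {
    warn(paste0(quarantined, " annotation record(s) quarantined: term id ",
                "unknown or obsolete in the ontology"))
  }
  rec <- records[!is.na(resolved), , drop = FALSE]
  rec$term_id <- resolved[!is.na(resolved)]

  pairs <- unique(data.frame(gene = rec$gene_id, term = rec$term_id,
                             stringsAsFactors = FALSE))

  if (propagate && nrow(pairs) > 0) {
    anc <- ancestor_sets(ontology, unique(pairs$term))
    ext <- lapply(seq_len(nrow(pairs)), function(i) {
      up <- anc[[pairs$term[i]]]
      if (length(up) == 0) return(NULL)
      data.frame(gene = pairs$gene[i], term = up, stringsAsFactors = FALSE)
    })
    pairs <- unique(rbind(pairs, do.call(rbind, ext)))
  }

  term_to_genes <- lapply(split(pairs$gene, pairs$term),
                          function(g) sort(unique(g)))
  gene_to_terms <- lapply(split(pairs$term, pairs$gene),
                          function(t) sort(unique(t)))

  sym <- unique(data.frame(symbol = toupper(rec$gene_symbol),
                           gene = rec$gene_id, stringsAsFactors = FALSE))
  symbol_to_gene <- stats::setNames(sym$gene, sym$symbol)

  structure(
    list(
      gene_to_terms = gene_to_terms,
      term_to_genes = term_to_genes,
      symbol_to_gene = symbol_to_gene,
      propagated = propagate,
      background_size = length(unique(rec$gene_id)),
      quarantined = quarantined
    ),
    class = "go_annotation_index"
  )
}

#' Match raw gene identifiers against the annotation index
#'
#' Each raw entry is matched case-insensitively, first against gene
#' symbols, then against database object ids.  Duplicates collapse to
#' one gene; unmatched entries are returned verbatim so they can be
#' reported, never silently dropped.
#'
#' @param index A `go_annotation_index`.
#' @param raw_list Character vector of gene symbols or ids.
#' @return List with `matched` (character vector of gene ids) and
#'   `unmatched` (raw entries with no match, original spelling).
#' @export
map_genes <- function(index, raw_list) {
  stopifnot(inherits(index, "go_annotation_index"))
  raw_list <- trimws(raw_list)
  raw_list <- raw_list[nzchar(raw_list)]
  if (length(raw_list) == 0) {
    abort("Gene list is empty", class = "goleaf_input_error")
  }
  raw_list <- unique(raw_list)
  up <- toupper(raw_list)
  gene_ids_up <- stats::setNames(names(index$gene_to_terms),
                                 toupper(names(index$gene_to_terms)))
  hit_sym <- index$symbol_to_gene[up]
  hit_id <- gene_ids_up[up]
  gene <- ifelse(!is.na(hit_sym), hit_sym, hit_id)
  list(
    matched = sort(unique(unname(gene[!is.na(gene)]))),
    unmatched = raw_list[is.na(gene)]
  )
}

#' Background annotation count of a term
#'
#' The number of distinct genes in the annotation source annotated to
#' the term (after any propagation) — the \eqn{g(t)} of the specificity
#' score.  A term with no annotations has count 0.
#'
#' @param index A `go_annotation_index`.
#' @param term_id A term id (primary or alternate if `ontology` given).
#' @param ontology Optional `go_ontology` used to resolve alternate ids;
#'   without it `term_id` must be primary.
#' @return Integer count.
#' @export
background_count <- function(index, term_id, ontology = NULL) {
  stopifnot(inherits(index, "go_annotation_index"))
  id <- if (is.null(ontology)) term_id else resolve_term(ontology, term_id)
  g <- index$term_to_genes[[id]]
  if (is.null(g)) 0L else length(g)
}

#' @export
print.go_annotation_index <- function(x, ...) {
  cat("<go_annotation_index> ", x$background_size, " genes, ",
      length(x$term_to_genes), " annotated terms (propagated: ",
      x$propagated, ", quarantined: ", x$quarantined, ")\n", sep = "")
  invisible(x)
}
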
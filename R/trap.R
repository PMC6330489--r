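#' Terms shared by enough genes of one input list
#'
#' A term qualifies when at least `threshold` of the input genes are
#' annotated to it (after whatever propagation the index was built
#' with).  The minimum threshold is 2: a shared term must be shared by
#' at least two input genes.
#'
#' @param index A `go_annotation_index`.
#' @param genes Character vector of gene ids (already mapped, see
#'   [map_genes()]).
#' @param threshold Integer >= 2.
#' @return Named list: term id -> character vector of the input genes
#'   annotated to it (sorted).
#' @export
shared_terms_within <- function(index, genes, threshold = 2) {
  check_threshold(threshold)
  genes <- unique(genes)
  if (length(genes) < threshold) {
    abort(paste0("Only ", length(genes), " mapped gene(s); no term can be ",
                 "shared by ", threshold),
          class = "goleaf_input_error")
  }
  hits <- lapply(index$term_to_genes, function(tg) sort(intersect(tg, genes)))
  hits[lengths(hits) >= threshold]
}

#' Terms shared across two input lists
#'
#' A term qualifies when its input-gene support (union of both lists)
#' has at least `threshold` genes *and* contains at least one gene from
#' each list.  A gene present in both lists is counted once and
#' satisfies both sides; a warning reports the overlap.
#'
#' @param index A `go_annotation_index`.
#' @param list_a,list_b Character vectors of mapped gene ids.
#' @param threshold Integer >= 2.
#' @return Named list: term id -> sorted character vector of supporting
#'   genes drawn from either list.
#' @export
shared_terms_between <- function(index, list_a, list_b, threshold = 2) {
  check_threshold(threshold)
  list_a <- unique(list_a)
  list_b <- unique(list_b)
  both <- intersect(list_a, list_b)
  if (length(both) > 0) {
    warn(paste0("Gene(s) present in both lists (counted once, satisfy ",
                "both sides): ", paste(both, collapse = ", ")))
  }
  pool <- union(list_a, list_b)
  hits <- lapply(index$term_to_genes, function(tg) sort(intersect(tg, pool)))
  keep <- vapply(hits, function(h) {
    length(h) >= threshold &&
      length(intersect(h, list_a)) > 0 &&
      length(intersect(h, list_b)) > 0
  }, logical(1))
  hits[keep]
}

#' Prune shared terms to the most specific ones
#'
#' Removes every shared term that has a shared strict descendant, so
#' that only the leaves of the subgraph induced by the shared set
#' remain — the last shared terms at the end of each branch.  The test
#' is against descendants within the shared set, not against children
#' in the full ontology: a term that is a non-leaf of the full ontology
#' survives as long as none of its refinements is itself shared.
#'
#' @param ontology A `go_ontology`.
#' @param shared Named list from [shared_terms_within()] or
#'   [shared_terms_between()].
#' @return The surviving subset of `shared`, gene sets untouched.
#' @export
prune_shared_parents <- function(ontology, shared) {
  if (length(shared) == 0) return(shared)
  ids <- names(shared)
  anc <- ancestor_sets(ontology, ids)
  # t has a shared strict descendant iff t is an ancestor of some shared term
  is_parent <- ids %in% unique(unlist(anc, use.names = FALSE))
  shared[!is_parent]
}

#' Specificity score of a term from its background count
#'
#' \eqn{score(t) = -\log_2(p(t))} with \eqn{p(t) = 2/g(t)}, i.e.
#' \eqn{\log_2 g(t) - 1}.  The constant 2 is the minimum number of
#' background genes a shared term can have, so the score is 0 at
#' \eqn{g = 2} and strictly increasing in \eqn{g}: the fewer background
#' genes annotated to a term, the lower its score and the more specific
#' the term.
#'
#' @param g Integer vector of background gene counts, all >= 2.
#' @return Numeric vector of scores (log2 units).
#' @examples
#' go_term_score(c(2, 27, 66))
#' @export
go_term_score <- function(g) {
  if (any(g < 2)) {
    abort("Background count below 2: p(t) = 2/g(t) would exceed 1",
          class = "goleaf_domain_error")
  }
  log2(g) - 1
}

check_threshold <- function(threshold) {
  if (length(threshold) != 1 || is.na(threshold) || threshold < 2 ||
      threshold != as.integer(threshold)) {
    abort("threshold must be an integer >= 2 (a shared term needs at least two input genes)",
          class = "goleaf_input_error")
  }
}

#' Find, prune, score and rank the most specific shared GO terms
#'
#' The full pipeline: detect the terms shared by at least `threshold`
#' input genes ("within" one list, or "between" two lists with at least
#' one gene from each), remove every shared term that has a shared
#' strict descendant, score the surviving leaves by
#' \eqn{-\log_2(2/g(t))} from the background annotation counts, and
#' rank ascending (lowest score = most specific), ties broken by term
#' id.
#'
#' @param ontology A `go_ontology` from [read_obo()].
#' @param index A `go_annotation_index` built against the same ontology.
#' @param genes Character vector of raw gene symbols or ids (first
#'   list).
#' @param genes2 Second list, required for `mode = "between"`.
#' @param mode `"within"` (associations inside one list) or
#'   `"between"` (terms shared across two lists).
#' @param threshold Minimum number of input genes sharing a term
#'   (integer >= 2).
#' @param namespace Restrict output to one GO namespace: `"BP"`,
#'   `"MF"`, `"CC"` or `"all"` (default).
#' @return A `goleaf` object.  `tidy()` returns the ranked result
#'   tibble (`term_id`, `category`, `background_genes`, `shared_genes`
#'   list-column, `n_shared`, `score`, `term_name`); `glance()` returns
#'   the one-row run report (genes mapped/unmatched, terms shared
#'   pre-pruning, terms retained, quarantined annotations).
#' @examples
#' fx <- simulate_go_fixture(seed = 1, dir = tempfile("fx"))
#' ont <- read_obo(fx$paths$obo)
#' idx <- build_annotation_index(read_gaf(fx$paths$gaf), ont)
#' res <- goleaf(ont, idx, genes = readLines(fx$paths$list_a))
#' tidy(res)
#' @export
goleaf <- function(ontology, index, genes, genes2 = NULL,
                   mode = c("within", "between"), threshold = 2,
                   namespace = c("all", "BP", "MF", "CC")) {
  mode <- match.arg(mode)
  namespace <- match.arg(namespace)
  check_threshold(threshold)
  stopifnot(inherits(ontology, "go_ontology"),
            inherits(index, "go_annotation_index"))

  map_a <- map_genes(index, genes)
  if (mode == "between") {
    if (is.null(genes2)) {
      abort("between mode needs a second gene list",
            class = "goleaf_input_error")
    }
    map_b <- map_genes(index, genes2)
    shared <- shared_terms_between(index, map_a$matched, map_b$matched,
                                   threshold)
  } else {
    if (!is.null(genes2)) {
      warn("genes2 ignored in within mode")
    }
    map_b <- NULL
    shared <- shared_terms_within(index, map_a$matched, threshold)
  }

  kept <- prune_shared_parents(ontology, shared)

  results <- trapped_tibble(ontology, index, kept)
  if (namespace != "all") {
    results <- results[results$category %in% namespace, , drop = FALSE]
  }

  report <- list(
    mode = mode,
    threshold = as.integer(threshold),
    propagated = index$propagated,
    n_genes_mapped = length(map_a$matched) +
      if (is.null(map_b)) 0L else length(map_b$matched),
    unmatched = c(map_a$unmatched, if (!is.null(map_b)) map_b$unmatched),
    n_terms_shared = length(shared),
    n_terms_retained = nrow(results),
    quarantined = index$quarantined
  )

  structure(list(results = results, report = report),
            class = "goleaf")
}

# Assemble the ranked output tibble from surviving term -> gene sets.
trapped_tibble <- function(ontology, index, kept) {
  if (length(kept) == 0) {
    return(tibble::tibble(
      term_id = character(0), category = character(0),
      background_genes = integer(0), shared_genes = list(),
      n_shared = integer(0), score = numeric(0), term_name = character(0)
    ))
  }
  ids <- names(kept)
  info <- ontology$terms[match(ids, ontology$terms$term_id), ]
  bg <- vapply(ids, function(t) background_count(index, t), integer(1))
  out <- tibble::tibble(
    term_id = ids,
    category = unname(go_namespace_abbrev[info$namespace]),
    background_genes = unname(bg),
    shared_genes = lapply(kept, identity),
    n_shared = lengths(kept),
    score = go_term_score(unname(bg)),
    term_name = info$name
  )
  out[order(out$score, out$term_id), , drop = FALSE]
}

#' @export
print.goleaf <- function(x, ...) {
  r <- x$report
  cat("<goleaf> mode=", r$mode, " threshold=", r$threshold,
      " | shared terms: ", r$n_terms_shared,
      " -> most specific: ", r$n_terms_retained, "\n", sep = "")
  if (length(r$unmatched) > 0) {
    cat("  unmatched input genes:", paste(r$unmatched, collapse = ", "),
        "\n")
  }
  print(tidy(x), ...)
  invisible(x)
}

#' @describeIn goleaf Ranked result table, one row per retained term.
#' @param x A `goleaf` object.
#' @param ... Unused.
#' @method tidy goleaf
#' @export
tidy.goleaf <- function(x, ...) {
  x$results
}

#' @describeIn goleaf One-row run summary.
#' @method glance goleaf
#' @export
glance.goleaf <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    mode = r$mode,
    threshold = r$threshold,
    propagated = r$propagated,
    n_genes_mapped = r$n_genes_mapped,
    n_unmatched = length(r$unmatched),
    n_terms_shared = r$n_terms_shared,
    n_terms_retained = r$n_terms_retained,
    quarantined = r$quarantined
  )
}

#' Plot the specificity scores of a result
#'
#' Horizontal bar chart of the retained terms ordered by score (most
#' specific at the top), coloured by GO category.
#'
#' @param object A `goleaf` object.
#' @param top_n Show at most this many terms (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot goleaf
#' @export
autoplot.goleaf <- function(object, top_n = 20, ...) {
  d <- utils::head(tidy(object), top_n)
  if (nrow(d) == 0) {
    abort("Nothing to plot: no terms retained",
          class = "goleaf_input_error")
  }
  d$label <- paste0(d$term_id, " ", substr(d$term_name, 1, 40))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$label, -.data$score),
    fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = expression(score(t) == -log[2](2 / g(t))),
      y = NULL, fill = "GO category",
      title = "Most specific shared GO terms"
    ) +
    ggplot2::theme_minimal()
}
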
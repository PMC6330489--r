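#' Parse an OBO ontology file into a term graph
#'
#' Reads an OBO 1.2/1.4 flat file (the go-basic style distribution of the
#' Gene Ontology) and builds a directed acyclic term graph.  Only `[Term]`
#' stanzas are interpreted; `[Typedef]` and other stanzas are skipped.
#' `is_a:` lines and `relationship:` lines whose relation is in
#' `relations` become child-to-parent edges.  Obsolete terms are excluded
#' from the graph but kept in a side index so that annotations pointing at
#' them can be reported rather than silently lost.  `alt_id:` lines
#' populate an alternate-identifier index resolving to the primary id.
#'
#' Cross-namespace edges (possible through some `part_of` links) are kept;
#' closure queries never special-case the namespace.  `intersection_of`
#' and `disjoint_from` lines are ignored: they are not part of the
#' parent-child semantics the shared-term method relies on.
#'
#' @param path Path to an OBO file.
#' @param relations Character vector of relationship types to use as
#'   parent edges, a subset of `is_a`, `part_of`, `regulates`,
#'   `positively_regulates`, `negatively_regulates`.  The default
#'   `c("is_a", "part_of")` matches the parent maps of classic
#'   Bioconductor GO releases; the regulates family can be opted in.
#' @return A `go_ontology` object: a list with `terms` (tibble with one
#'   row per non-obsolete term: `term_id`, `name`, `namespace`),
#'   `parents` (named list of tibbles `relation`/`parent` per term),
#'   `graph` (an igraph with child -> parent edges restricted to
#'   `relations`), `alt_index`, `obsolete` (ids of obsolete terms) and
#'   `relations` in use.
#' @examples
#' fx <- simulate_go_fixture(seed = 1, dir = tempfile("fx"))
#' ont <- read_obo(fx$paths$obo)
#' ont
#' @export
read_obo <- function(path, relations = c("is_a", "part_of")) {
  if (!file.exists(path)) {
    abort(paste0("OBO file not found: ", path), class = "goleaf_io_error")
  }
  bad <- setdiff(relations, go_known_relations)
  if (length(bad) > 0) {
    abort(paste0("Unknown relation type(s): ", paste(bad, collapse = ", ")),
          class = "goleaf_input_error")
  }
  lines <- readLines(path, warn = FALSE)

  stanzas <- parse_obo_stanzas(lines)

  ids <- character(0)
  names_ <- character(0)
  namespaces <- character(0)
  parent_tbl <- list()   # per term: tibble(relation, parent)
  alt_from <- character(0)
  alt_to <- character(0)
  obsolete <- character(0)

  for (st in stanzas) {
    fld <- st$fields
    id <- fld$id
    if (is.null(id)) {
      abort(paste0("OBO [Term] stanza starting at line ", st$line,
                   " has no id: line"),
            class = "goleaf_parse_error")
    }
    if (!grepl("^GO:\\d{7}$", id)) {
      abort(paste0("Malformed term id '", id, "' near line ", st$line),
            class = "goleaf_parse_error")
    }
    if (isTRUE(fld$is_obsolete)) {
      # indexed, but carries no parents and is not part of the graph
      obsolete <- c(obsolete, id)
      next
    }
    ids <- c(ids, id)
    names_ <- c(names_, fld$name %||% NA_character_)
    namespaces <- c(namespaces, fld$namespace %||% NA_character_)
    pl <- fld$parents
    keep <- pl$relation %in% relations
    parent_tbl[[id]] <- pl[keep, , drop = FALSE]
    if (length(fld$alt_ids) > 0) {
      alt_from <- c(alt_from, fld$alt_ids)
      alt_to <- c(alt_to, rep(id, length(fld$alt_ids)))
    }
  }

  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(paste0("Duplicate term id in OBO file: ", dup),
          class = "goleaf_parse_error")
  }

  # every retained parent must exist as a non-obsolete term
  all_parents <- unique(unlist(lapply(parent_tbl, function(x) x$parent),
                               use.names = FALSE))
  missing <- setdiff(all_parents, ids)
  if (length(missing) > 0) {
    abort(paste0("Parent term(s) not defined in file: ",
                 paste(utils::head(missing, 5), collapse = ", ")),
          class = "goleaf_parse_error")
  }

  edges <- do.call(rbind, lapply(ids, function(id) {
    p <- parent_tbl[[id]]
    if (nrow(p) == 0) return(NULL)
    data.frame(child = id, parent = p$parent, relation = p$relation,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(child = character(0), parent = character(0),
                        relation = character(0))
  }

  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")],
    directed = TRUE,
    vertices = data.frame(name = ids)
  )
  igraph::E(g)$relation <- edges$relation

  if (!igraph::is_dag(g)) {
    cyc <- find_directed_cycle(parent_tbl, ids)
    abort(paste0("Ontology graph has a directed cycle under relations {",
                 paste(relations, collapse = ", "), "}: ",
                 paste(cyc, collapse = " -> ")),
          class = "goleaf_cycle_error")
  }

  alt_index <- stats::setNames(alt_to, alt_from)

  structure(
    list(
      terms = tibble::tibble(term_id = ids, name = names_,
                             namespace = namespaces),
      parents = parent_tbl,
      graph = g,
      alt_index = alt_index,
      obsolete = obsolete,
      relations = relations
    ),
    class = "go_ontology"
  )
}

# Split OBO lines into [Term] stanzas and parse the tag lines of each.
parse_obo_stanzas <- function(lines) {
  is_header <- grepl("^\\[[^]]+\\]\\s*$", lines)
  header_at <- which(is_header)
  stanzas <- list()
  for (k in seq_along(header_at)) {
    start <- header_at[k]
    if (trimws(lines[start]) != "[Term]") next
    end <- if (k < length(header_at)) header_at[k + 1] - 1 else length(lines)
    body <- lines[(start + 1):end]
    body_lines <- (start + 1):end
    fld <- list(parents = data.frame(relation = character(0),
                                     parent = character(0),
                                     stringsAsFactors = FALSE),
                alt_ids = character(0), is_obsolete = FALSE)
    for (j in seq_along(body)) {
      ln <- body[j]
      if (grepl("^\\s*$", ln) || grepl("^!", ln)) next
      ln <- sub("\\s!.*$", "", ln)  # trailing comments
      m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
      if (length(m) == 0) {
        abort(paste0("Malformed OBO line ", body_lines[j], ": '", ln, "'"),
              class = "goleaf_parse_error")
      }
      tag <- m[2]
      val <- trimws(m[3])
      if (tag == "id") fld$id <- val
      else if (tag == "name") fld$name <- val
      else if (tag == "namespace") fld$namespace <- val
      else if (tag == "alt_id") fld$alt_ids <- c(fld$alt_ids, val)
      else if (tag == "is_obsolete") fld$is_obsolete <- identical(val, "true")
      else if (tag == "is_a") {
        target <- trimws(strsplit(val, "!", fixed = TRUE)[[1]][1])
        fld$parents <- rbind(fld$parents,
                             data.frame(relation = "is_a", parent = target,
                                        stringsAsFactors = FALSE))
      } else if (tag == "relationship") {
        parts <- strsplit(val, "\\s+")[[1]]
        if (length(parts) < 2) {
          abort(paste0("Malformed relationship line ", body_lines[j],
                       ": '", ln, "'"),
                class = "goleaf_parse_error")
        }
        fld$parents <- rbind(fld$parents,
                             data.frame(relation = parts[1],
                                        parent = parts[2],
                                        stringsAsFactors = FALSE))
      }
      # other tags (def, synonym, xref, intersection_of, ...) ignored
    }
    stanzas[[length(stanzas) + 1]] <- list(line = start, fields = fld)
  }
  stanzas
}

# DFS cycle finder used only to produce a readable error message.
find_directed_cycle <- function(parent_tbl, ids) {
  color <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 open, 2 done
  stack <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    color[v] <<- 1L
    stack <<- c(stack, v)
    for (p in parent_tbl[[v]]$parent) {
      if (color[p] == 1L) {
        i <- match(p, stack)
        found <<- c(stack[i:length(stack)], p)
        return()
      }
      if (color[p] == 0L) visit(p)
      if (!is.null(found)) return()
    }
    color[v] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (v in ids) {
    if (color[v] == 0L) visit(v)
    if (!is.null(found)) break
  }
  found %||% character(0)
}

#' Resolve a term identifier to its primary id
#'
#' Accepts a primary id or an alternate id and returns the primary id.
#' Obsolete and unknown identifiers raise classed errors
#' (`goleaf_obsolete_error`, `goleaf_lookup_error`).
#'
#' @param ontology A `go_ontology` from [read_obo()].
#' @param term_id A GO accession string.
#' @return The primary term id.
#' @export
resolve_term <- function(ontology, term_id) {
  stopifnot(inherits(ontology, "go_ontology"), length(term_id) == 1)
  if (term_id %in% ontology$terms$term_id) return(term_id)
  if (term_id %in% names(ontology$alt_index)) {
    return(unname(ontology$alt_index[[term_id]]))
  }
  if (term_id %in% ontology$obsolete) {
    abort(paste0("Term is obsolete: ", term_id),
          class = "goleaf_obsolete_error", term_id = term_id)
  }
  abort(paste0("Unknown term id: ", term_id),
        class = "goleaf_lookup_error", term_id = term_id)
}

#' Ancestor and descendant closures of a term
#'
#' Transitive closure over the relations the ontology was built with,
#' excluding the query term itself.  Ancestors of a namespace root are the
#' empty set.  Going down the graph terms get more specific, so
#' descendants are the more specific refinements of a term.
#'
#' @param ontology A `go_ontology`.
#' @param term_id A primary or alternate term id.
#' @return Character vector of term ids (possibly empty).
#' @export
go_ancestors <- function(ontology, term_id) {
  id <- resolve_term(ontology, term_id)
  out <- igraph::subcomponent(ontology$graph, id, mode = "out")
  setdiff(names(out), id)
}

#' @rdname go_ancestors
#' @export
go_descendants <- function(ontology, term_id) {
  id <- resolve_term(ontology, term_id)
  out <- igraph::subcomponent(ontology$graph, id, mode = "in")
  setdiff(names(out), id)
}

# Ancestor sets for many terms at once (named list), used by propagation
# and pruning; one reverse BFS per term through igraph.
ancestor_sets <- function(ontology, term_ids) {
  stats::setNames(lapply(term_ids, function(t) go_ancestors(ontology, t)),
                  term_ids)
}

#' @export
print.go_ontology <- function(x, ...) {
  cat("<go_ontology> ", nrow(x$terms), " terms, ",
      igraph::ecount(x$graph), " edges (",
      paste(x$relations, collapse = ", "), "), ",
      length(x$obsolete), " obsolete, ",
      length(x$alt_index), " alt ids\n", sep = "")
  ns <- table(x$terms$namespace)
  cat("  namespaces:",
      paste(names(ns), ns, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
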
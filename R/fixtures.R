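#' Generate a synthetic ontology + annotation fixture with planted truth
#'
#' Writes a small but structurally realistic test world: a three-
#' namespace OBO file whose term graph is acyclic by construction
#' (edges only run from later to earlier terms in a random topological
#' order), with multi-parent terms, at least one alternate id and one
#' obsolete term; a GAF 2.2 annotation file with mixed evidence codes
#' and one planted NOT-qualified record; and two gene lists.  A shared
#' leaf is planted: one gene from each list is annotated directly to
#' the same childless term, so a most-specific shared term is
#' guaranteed to exist at threshold 2 in both modes.
#'
#' Everything is driven by `seed`; the same seed reproduces identical
#' files byte for byte.  The returned manifest records the full ground
#' truth (terms, edges, annotations, lists) so that the independent
#' brute-force reference [goleaf_oracle()] can recompute expected
#' outputs without touching the parsers or the pipeline.
#'
#' The generator aims for structural realism only (multi-parent terms,
#' depth >= 4, cross-list shared paths), not for GO's real term-size
#' distribution.
#'
#' @param seed Integer seed.
#' @param dir Directory to write files into (created if needed).
#' @param n_terms Terms per namespace (>= 3).
#' @param n_genes Number of genes (>= 2).
#' @param p_multi_parent Probability that a non-root term gets a second
#'   parent.
#' @param evidence_mix Named numeric vector of evidence-code weights
#'   for sampling annotation evidence.
#' @param mean_direct Mean number of direct annotations per gene
#'   (Poisson, floored at 1).
#' @param overlap_genes Number of genes planted in both lists
#'   (default 0; used to exercise the duplicate-gene warning).
#' @return The fixture manifest: a list with `seed`, `terms`, `edges`,
#'   `alt` (alt_id/primary), `annotations` (direct, pre-filter),
#'   `list_a`, `list_b` (symbols), `planted_leaf` and `paths` (obo,
#'   gaf, list_a, list_b, edges, annotations).
#' @examples
#' fx <- simulate_go_fixture(seed = 42, dir = tempfile("fx"))
#' fx$planted_leaf
#' @export
simulate_go_fixture <- function(seed, dir,
                                n_terms = 12, n_genes = 20,
                                p_multi_parent = 0.3,
                                evidence_mix = c(IDA = 4, IMP = 2,
                                                 TAS = 1, IEA = 3),
                                mean_direct = 2,
                                overlap_genes = 0) {
  if (n_terms < 3) {
    abort("n_terms must be >= 3 per namespace", class = "goleaf_input_error")
  }
  if (n_genes < 2) {
    abort("n_genes must be >= 2", class = "goleaf_input_error")
  }
  if (overlap_genes > n_genes) {
    abort("overlap_genes cannot exceed n_genes",
          class = "goleaf_input_error")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  namespaces <- names(go_namespace_abbrev)
  n_total <- n_terms * length(namespaces)
  term_ids <- sprintf("GO:%07d", seq_len(n_total))
  terms <- tibble::tibble(
    term_id = term_ids,
    name = paste0("synthetic term ", seq_len(n_total)),
    namespace = rep(namespaces, each = n_terms),
    obsolete = FALSE
  )

  # edges run strictly from later to earlier ids: acyclic by construction
  edges <- list()
  for (ns_i in seq_along(namespaces)) {
    base <- (ns_i - 1) * n_terms
    for (i in 2:n_terms) {
      child <- term_ids[base + i]
      # bias toward recent terms so chains get deep (depth >= 4 at n = 12)
      recent <- seq(max(1, i - 3), i - 1)
      pick <- if (stats::runif(1) < 0.7) pick1(recent) else
        pick1(seq_len(i - 1))
      edges[[length(edges) + 1]] <-
        data.frame(child = child, parent = term_ids[base + pick],
                   relation = "is_a", stringsAsFactors = FALSE)
      if (stats::runif(1) < p_multi_parent) {
        # second parent: usually same namespace, sometimes a cross-
        # namespace part_of into an earlier namespace
        cross <- ns_i > 1 && stats::runif(1) < 0.15
        pool <- if (cross) seq_len(base) else base + seq_len(i - 1)
        p2 <- term_ids[pick1(pool)]
        rel <- sample(c("part_of", "regulates"), 1, prob = c(0.85, 0.15))
        if (p2 != term_ids[base + pick]) {
          edges[[length(edges) + 1]] <-
            data.frame(child = child, parent = p2, relation = rel,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- unique(do.call(rbind, edges))

  # alternate id for one random non-root term; one obsolete extra term
  alt_target <- pick1(terms$term_id[-seq(1, n_total, by = n_terms)])
  alt <- tibble::tibble(alt_id = "GO:8000001", primary = alt_target)
  obsolete_id <- sprintf("GO:%07d", n_total + 1)
  terms <- rbind(terms,
                 tibble::tibble(term_id = obsolete_id,
                                name = "synthetic obsolete term",
                                namespace = namespaces[1], obsolete = TRUE))

  genes <- tibble::tibble(
    gene_id = sprintf("SYN:%04d", seq_len(n_genes)),
    symbol = sprintf("SGN%d", seq_len(n_genes))
  )

  # a childless term in the first namespace to plant as shared leaf
  has_child <- unique(edges$parent)
  leaves_ns1 <- setdiff(term_ids[seq_len(n_terms)], has_child)
  planted_leaf <- if (length(leaves_ns1) > 0)
    leaves_ns1[length(leaves_ns1)] else term_ids[n_terms]

  codes <- names(evidence_mix)
  live_terms <- terms$term_id[!terms$obsolete]
  ann <- list()
  for (i in seq_len(n_genes)) {
    k <- max(1, stats::rpois(1, mean_direct))
    tt <- sample(live_terms, min(k, length(live_terms)))
    ann[[i]] <- data.frame(
      gene_id = genes$gene_id[i], gene_symbol = genes$symbol[i],
      qualifier = "involved_in", term_id = tt,
      evidence_code = sample(codes, length(tt), replace = TRUE,
                             prob = evidence_mix),
      stringsAsFactors = FALSE
    )
  }
  ann <- do.call(rbind, ann)

  # planted shared leaf: first gene and last gene annotated directly
  plant <- data.frame(
    gene_id = genes$gene_id[c(1, n_genes)],
    gene_symbol = genes$symbol[c(1, n_genes)],
    qualifier = "involved_in", term_id = planted_leaf,
    evidence_code = "IDA", stringsAsFactors = FALSE
  )
  # planted NOT annotation (must be dropped by the reader)
  not_row <- data.frame(
    gene_id = genes$gene_id[1], gene_symbol = genes$symbol[1],
    qualifier = "NOT|involved_in",
    term_id = pick1(live_terms), evidence_code = "IDA",
    stringsAsFactors = FALSE
  )
  ann <- unique(rbind(ann, plant, not_row))

  half <- ceiling(n_genes / 2)
  list_a_sym <- genes$symbol[seq_len(half)]
  list_b_sym <- genes$symbol[(half + 1):n_genes]
  if (overlap_genes > 0) {
    list_b_sym <- unique(c(genes$symbol[seq_len(overlap_genes)],
                           list_b_sym))
  }

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    obo = file.path(dir, "fixture.obo"),
    gaf = file.path(dir, "fixture.gaf"),
    list_a = file.path(dir, "list_a.txt"),
    list_b = file.path(dir, "list_b.txt"),
    edges = file.path(dir, "manifest_edges.tsv"),
    annotations = file.path(dir, "manifest_annotations.tsv")
  )
  write_fixture_obo(paths$obo, terms, edges, alt)
  write_fixture_gaf(paths$gaf, ann)
  writeLines(c("# synthetic gene list A", list_a_sym), paths$list_a)
  writeLines(c("# synthetic gene list B", list_b_sym), paths$list_b)
  utils::write.table(edges, paths$edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(seed = seed, terms = terms, edges = tibble::as_tibble(edges),
       alt = alt, annotations = tibble::as_tibble(ann),
       list_a = list_a_sym, list_b = list_b_sym,
       planted_leaf = planted_leaf, paths = paths)
}

# sample one element of a vector regardless of its length
pick1 <- function(v) v[sample.int(length(v), 1)]

write_fixture_obo <- function(path, terms, edges, alt) {
  out <- c("format-version: 1.2",
           "ontology: synthetic-go-fixture", "")
  for (i in seq_len(nrow(terms))) {
    id <- terms$term_id[i]
    st <- c("[Term]",
            paste0("id: ", id),
            paste0("name: ", terms$name[i]),
            paste0("namespace: ", terms$namespace[i]))
    if (id %in% alt$primary) {
      st <- c(st, paste0("alt_id: ", alt$alt_id[alt$primary == id]))
    }
    if (terms$obsolete[i]) {
      st <- c(st, "is_obsolete: true")
    } else {
      e <- edges[edges$child == id, , drop = FALSE]
      for (j in seq_len(nrow(e))) {
        st <- c(st, if (e$relation[j] == "is_a")
          paste0("is_a: ", e$parent[j], " ! parent")
          else paste0("relationship: ", e$relation[j], " ", e$parent[j],
                      " ! parent"))
      }
    }
    out <- c(out, st, "")
  }
  writeLines(out, path)
}

write_fixture_gaf <- function(path, ann) {
  rows <- vapply(seq_len(nrow(ann)), function(i) {
    paste(c("SYNDB", ann$gene_id[i], ann$gene_symbol[i],
            ann$qualifier[i], ann$term_id[i], "SYNDB:REF:0001",
            ann$evidence_code[i], "", "P", "synthetic gene product", "",
            "protein", "taxon:9606", "20260101", "SYNDB", "", ""),
          collapse = "\t")
  }, character(1))
  writeLines(c("!gaf-version: 2.2", rows), path)
}

#' Brute-force reference pipeline over a fixture manifest
#'
#' An independent implementation of the whole method that works
#' directly from the fixture manifest (edge list and annotation table),
#' sharing no code with the parsers, the igraph-backed closure or the
#' pipeline: ancestor sets come from iterated single-step parent
#' expansion to a fixpoint, the mode condition and pruning are applied
#' by exhaustive scans, and scores are recomputed from first
#' principles.  Used as the oracle that the real pipeline must agree
#' with on every seeded fixture.
#'
#' @param manifest A manifest from [simulate_go_fixture()].
#' @param mode `"within"` or `"between"`.
#' @param threshold Integer >= 2.
#' @param evidence_filter Character vector of codes or `"ALL"`.
#' @param relations Relations used as parent edges.
#' @param propagate Apply the true-path rule before counting.
#' @param genes,genes2 Input symbol lists; default the manifest's
#'   `list_a` (and `list_b` for between mode).
#' @return Tibble `term_id`, `category`, `background_genes`,
#'   `shared_genes` (list-column, sorted), `n_shared`, `score`,
#'   sorted ascending by score then term id.
#' @export
goleaf_oracle <- function(manifest, mode = c("within", "between"),
                          threshold = 2, evidence_filter = "ALL",
                          relations = c("is_a", "part_of"),
                          propagate = TRUE,
                          genes = NULL, genes2 = NULL) {
  mode <- match.arg(mode)
  ann <- as.data.frame(manifest$annotations)

  # NOT-qualified rows never count
  keep <- !vapply(strsplit(ann$qualifier, "|", fixed = TRUE),
                  function(q) "NOT" %in% q, logical(1))
  ann <- ann[keep, , drop = FALSE]
  if (!identical(evidence_filter, "ALL")) {
    ann <- ann[ann$evidence_code %in% evidence_filter, , drop = FALSE]
  }
  # resolve alt ids; drop annotations to obsolete/unknown terms
  hit <- match(ann$term_id, manifest$alt$alt_id)
  ann$term_id[!is.na(hit)] <- manifest$alt$primary[hit[!is.na(hit)]]
  live <- manifest$terms$term_id[!manifest$terms$obsolete]
  ann <- ann[ann$term_id %in% live, , drop = FALSE]

  ed <- as.data.frame(manifest$edges)
  ed <- ed[ed$relation %in% relations, , drop = FALSE]

  # ancestors by iterated single-step parent expansion to fixpoint
  step_up <- function(ts) unique(ed$parent[ed$child %in% ts])
  anc_of <- function(t) {
    seen <- character(0)
    frontier <- step_up(t)
    while (length(frontier) > 0) {
      seen <- union(seen, frontier)
      frontier <- setdiff(step_up(frontier), seen)
    }
    seen
  }
  anc <- lapply(stats::setNames(live, live), anc_of)

  pairs <- unique(ann[, c("gene_id", "term_id")])
  if (propagate) {
    extra <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      up <- anc[[pairs$term_id[i]]]
      if (length(up) == 0) return(NULL)
      data.frame(gene_id = pairs$gene_id[i], term_id = up,
                 stringsAsFactors = FALSE)
    }))
    pairs <- unique(rbind(pairs, extra))
  }
  t2g <- lapply(split(pairs$gene_id, pairs$term_id),
                function(g) sort(unique(g)))

  sym2id <- stats::setNames(manifest$annotations$gene_id,
                            toupper(manifest$annotations$gene_symbol))
  to_ids <- function(sym) sort(unique(unname(sym2id[toupper(sym)])))
  a_ids <- to_ids(genes %||% manifest$list_a)
  if (mode == "between") {
    b_ids <- to_ids(genes2 %||% manifest$list_b)
    pool <- union(a_ids, b_ids)
  } else {
    pool <- a_ids
  }

  # exhaustive scan: every annotated term, intersect, apply condition
  shared <- list()
  for (t in names(t2g)) {
    h <- intersect(t2g[[t]], pool)
    ok <- if (mode == "within") length(h) >= threshold else
      length(h) >= threshold && any(h %in% a_ids) && any(h %in% b_ids)
    if (ok) shared[[t]] <- sort(h)
  }

  # prune: t goes iff t is an ancestor of another shared term
  ids <- names(shared)
  keep <- vapply(ids, function(t) {
    !any(vapply(setdiff(ids, t), function(s) t %in% anc[[s]], logical(1)))
  }, logical(1))
  kept <- shared[keep]

  ids <- names(kept)
  if (length(ids) == 0) {
    return(tibble::tibble(term_id = character(0), category = character(0),
                          background_genes = integer(0),
                          shared_genes = list(), n_shared = integer(0),
                          score = numeric(0)))
  }
  bg <- vapply(ids, function(t) length(t2g[[t]]), integer(1))
  ns <- manifest$terms$namespace[match(ids, manifest$terms$term_id)]
  out <- tibble::tibble(
    term_id = ids,
    category = unname(go_namespace_abbrev[ns]),
    background_genes = unname(bg),
    shared_genes = lapply(kept, identity),
    n_shared = lengths(kept),
    score = -log2(2 / unname(bg))
  )
  out[order(out$score, out$term_id), , drop = FALSE]
}
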
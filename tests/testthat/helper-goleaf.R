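# Builders for small hand-written OBO/GAF fixtures, plus brute-force
# reference helpers used as independent oracles in the unit tests.

# terms: list of lists with id, name, ns, is_a (chr), rel (named chr:
# relation -> parent), alt (chr), obsolete (lgl)
write_test_obo <- function(terms, path = tempfile(fileext = ".obo")) {
  out <- c("format-version: 1.2", "")
  for (t in terms) {
    st <- c("[Term]", paste0("id: ", t$id),
            paste0("name: ", t$name %||% tolower(t$id)),
            paste0("namespace: ", t$ns %||% "biological_process"))
    for (a in t$alt %||% character(0)) st <- c(st, paste0("alt_id: ", a))
    if (isTRUE(t$obsolete)) st <- c(st, "is_obsolete: true")
    for (p in t$is_a %||% character(0)) st <- c(st, paste0("is_a: ", p))
    rel <- t$rel %||% character(0)
    for (i in seq_along(rel)) {
      st <- c(st, paste0("relationship: ", names(rel)[i], " ", rel[i]))
    }
    out <- c(out, st, "")
  }
  writeLines(out, path)
  path
}

# ann: data.frame with gene_id, gene_symbol, qualifier, term_id,
# evidence_code
write_test_gaf <- function(ann, path = tempfile(fileext = ".gaf")) {
  rows <- vapply(seq_len(nrow(ann)), function(i) {
    paste(c("TESTDB", ann$gene_id[i], ann$gene_symbol[i],
            ann$qualifier[i], ann$term_id[i], "REF:1",
            ann$evidence_code[i], "", "P", "", "", "protein",
            "taxon:9606", "20260101", "TESTDB", "", ""),
          collapse = "\t")
  }, character(1))
  writeLines(c("!gaf-version: 2.2", rows), path)
  path
}

ann_row <- function(gene, term, evidence = "IDA",
                    qualifier = "involved_in", symbol = gene) {
  data.frame(gene_id = gene, gene_symbol = symbol, qualifier = qualifier,
             term_id = term, evidence_code = evidence,
             stringsAsFactors = FALSE)
}

# Chain ontology GO:0000001 <- GO:0000002 <- GO:0000003 (A <- B <- C)
chain_obo <- function(path = tempfile(fileext = ".obo")) {
  write_test_obo(list(
    list(id = "GO:0000001", name = "chain root"),
    list(id = "GO:0000002", name = "chain mid", is_a = "GO:0000001"),
    list(id = "GO:0000003", name = "chain leaf", is_a = "GO:0000002")
  ), path)
}

# Worked two-gene scenario: genes g1, g2 both annotated to a child term;
# by propagation they also share its parent and the root; a third gene
# keeps the parent's background strictly larger than the child's.
fig2_world <- function() {
  obo <- write_test_obo(list(
    list(id = "GO:0000001", name = "root"),
    list(id = "GO:0000002", name = "parent", is_a = "GO:0000001"),
    list(id = "GO:0000003", name = "child", is_a = "GO:0000002")
  ))
  ann <- rbind(
    ann_row("G1", "GO:0000003", symbol = "GENEA"),
    ann_row("G2", "GO:0000003", symbol = "GENEB"),
    ann_row("G3", "GO:0000002", symbol = "GENEC")
  )
  gaf <- write_test_gaf(ann)
  ont <- read_obo(obo)
  idx <- build_annotation_index(read_gaf(gaf), ont)
  list(ont = ont, idx = idx, obo = obo, gaf = gaf)
}

# Brute-force ancestor closure by iterated single-step expansion over an
# edge data.frame (child, parent, relation) — independent of igraph.
bf_ancestors <- function(edges, id, relations = c("is_a", "part_of")) {
  ed <- edges[edges$relation %in% relations, , drop = FALSE]
  seen <- character(0)
  frontier <- unique(ed$parent[ed$child == id])
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(ed$parent[ed$child %in% frontier]), seen)
  }
  seen
}

bf_descendants <- function(edges, id, relations = c("is_a", "part_of")) {
  ed <- edges[edges$relation %in% relations, , drop = FALSE]
  seen <- character(0)
  frontier <- unique(ed$child[ed$parent == id])
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(ed$child[ed$parent %in% frontier]), seen)
  }
  seen
}

`%||%` <- rlang::`%||%`
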
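test_that("within mode keeps exactly the terms shared by enough input genes", {
  w <- fig2_world()
  shared <- shared_terms_within(w$idx, c("G1", "G2"), threshold = 2)
  # child + its propagated ancestors are shared by both genes
  expect_setequal(names(shared),
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
  expect_equal(shared[["GO:0000003"]], c("G1", "G2"))

  # threshold 3 when every term carries only two input genes -> empty:
  # two disjoint rooted branches, two genes each
  obo2 <- write_test_obo(list(
    list(id = "GO:0000010", name = "root x"),
    list(id = "GO:0000011", name = "leaf x", is_a = "GO:0000010"),
    list(id = "GO:0000020", name = "root y", ns = "molecular_function"),
    list(id = "GO:0000021", name = "leaf y", is_a = "GO:0000020")
  ))
  ont2 <- read_obo(obo2)
  idx2 <- build_annotation_index(read_gaf(write_test_gaf(rbind(
    ann_row("G1", "GO:0000011"), ann_row("G2", "GO:0000011"),
    ann_row("G3", "GO:0000021"), ann_row("G4", "GO:0000021")
  ))), ont2)
  expect_length(
    shared_terms_within(idx2, c("G1", "G2", "G3", "G4"), 3), 0)
  expect_error(shared_terms_within(w$idx, "G1", 2),
               class = "goleaf_input_error")
  expect_error(shared_terms_within(w$idx, c("G1", "G2"), 1),
               class = "goleaf_input_error")
})

test_that("between mode demands support from each list", {
  w <- fig2_world()
  # G1 from list A and G2 from list B both reach the child term
  shared <- shared_terms_between(w$idx, "G1", "G2", threshold = 2)
  expect_true("GO:0000003" %in% names(shared))
  expect_equal(shared[["GO:0000003"]], c("G1", "G2"))
  # two genes from one list only -> excluded even though |shared| >= 2
  one_sided <- shared_terms_between(w$idx, c("G1", "G2"), "G3", 2)
  expect_false("GO:0000003" %in% names(one_sided))
  # parent is shared by G3 (list B) and G1,G2 (list A)
  expect_true("GO:0000002" %in% names(one_sided))
  # a gene in both lists warns and is counted once
  expect_warning(
    both <- shared_terms_between(w$idx, c("G1", "G2"), c("G2", "G3"), 2),
    "both lists"
  )
  expect_equal(both[["GO:0000003"]], c("G1", "G2"))
})

test_that("pruning keeps only terms without a shared strict descendant", {
  w <- fig2_world()
  # parent/child pair -> the parent goes
  shared <- list("GO:0000002" = c("G1", "G2"),
                 "GO:0000003" = c("G1", "G2"))
  kept <- prune_shared_parents(w$ont, shared)
  expect_equal(names(kept), "GO:0000003")
  expect_equal(kept[["GO:0000003"]], c("G1", "G2"))

  # an antichain is a fixpoint
  obo <- write_test_obo(list(
    list(id = "GO:0000001", name = "r"),
    list(id = "GO:0000002", name = "u", is_a = "GO:0000001"),
    list(id = "GO:0000003", name = "v", is_a = "GO:0000001")
  ))
  ont <- read_obo(obo)
  anti <- list("GO:0000002" = "G1", "GO:0000003" = "G2")
  expect_equal(prune_shared_parents(ont, anti), anti)
  expect_length(prune_shared_parents(ont, list()), 0)
})

test_that("pruning equals the brute-force descendant scan on random shared sets", {
  fx <- simulate_go_fixture(seed = 31, dir = withr::local_tempdir(),
                            n_terms = 14)
  ont <- read_obo(fx$paths$obo)
  ed <- as.data.frame(fx$edges)
  ids <- ont$terms$term_id
  set.seed(99)
  for (trial in 1:10) {
    pick <- sample(ids, sample(3:25, 1))
    shared <- setNames(as.list(paste0("G", seq_along(pick))), pick)
    kept <- prune_shared_parents(ont, shared)
    want <- pick[vapply(pick, function(t) {
      length(intersect(bf_descendants(ed, t), pick)) == 0
    }, logical(1))]
    expect_setequal(names(kept), want)
  }
})

test_that("specificity score is log2(g) - 1 with domain guard", {
  expect_equal(go_term_score(2), 0)
  expect_error(go_term_score(1), class = "goleaf_domain_error")
  g <- 2:100
  s <- go_term_score(g)
  expect_true(all(diff(s) > 0))        # strictly increasing in g
  expect_equal(s, -log(2 / g, base = 2))
})

test_that("results rank ascending by score with term-id tie-break", {
  # two leaves with equal background (ties) plus a bigger mid term
  obo <- write_test_obo(list(
    list(id = "GO:0000001", name = "r"),
    list(id = "GO:0000005", name = "leaf b", is_a = "GO:0000001"),
    list(id = "GO:0000002", name = "leaf a", is_a = "GO:0000001")
  ))
  ont <- read_obo(obo)
  gaf <- write_test_gaf(rbind(
    ann_row("G1", "GO:0000002"), ann_row("G2", "GO:0000002"),
    ann_row("G1", "GO:0000005"), ann_row("G2", "GO:0000005"),
    ann_row("G3", "GO:0000001")
  ))
  idx <- build_annotation_index(read_gaf(gaf), ont)
  res <- tidy(goleaf(ont, idx, genes = c("G1", "G2")))
  expect_equal(res$term_id, c("GO:0000002", "GO:0000005"))
  expect_equal(res$score, c(0, 0))
})

test_that("the full run composes the stages and matches the oracle in both modes", {
  fx <- simulate_go_fixture(seed = 41, dir = withr::local_tempdir())
  ont <- read_obo(fx$paths$obo)
  idx <- build_annotation_index(read_gaf(fx$paths$gaf), ont)
  a <- read_gene_list(fx$paths$list_a)
  b <- read_gene_list(fx$paths$list_b)
  for (th in 2:4) {
    got_w <- tidy(goleaf(ont, idx, genes = a, threshold = th))
    want_w <- goleaf_oracle(fx, "within", threshold = th)
    expect_equal(as.data.frame(got_w[names(want_w)]),
                 as.data.frame(want_w), ignore_attr = TRUE)
    got_b <- tidy(goleaf(ont, idx, genes = a, genes2 = b,
                         mode = "between", threshold = th))
    want_b <- goleaf_oracle(fx, "between", threshold = th)
    expect_equal(as.data.frame(got_b[names(want_b)]),
                 as.data.frame(want_b), ignore_attr = TRUE)
  }
})

test_that("when only the apex is shared it is retained with its score", {
  # two genes on disjoint branches share nothing but the root
  obo <- write_test_obo(list(
    list(id = "GO:0000001", name = "apex"),
    list(id = "GO:0000002", name = "left", is_a = "GO:0000001"),
    list(id = "GO:0000003", name = "right", is_a = "GO:0000001")
  ))
  ont <- read_obo(obo)
  gaf <- write_test_gaf(rbind(ann_row("G1", "GO:0000002"),
                              ann_row("G2", "GO:0000003")))
  idx <- build_annotation_index(read_gaf(gaf), ont)
  res <- tidy(goleaf(ont, idx, genes = c("G1", "G2"), threshold = 2))
  expect_equal(res$term_id, "GO:0000001")
  expect_equal(res$score, log2(2) - 1)
})

test_that("raising the threshold never adds a shared term", {
  fx <- simulate_go_fixture(seed = 47, dir = withr::local_tempdir())
  ont <- read_obo(fx$paths$obo)
  idx <- build_annotation_index(read_gaf(fx$paths$gaf), ont)
  genes <- map_genes(idx, fx$list_a)$matched
  prev <- shared_terms_within(idx, genes, 2)
  for (th in 3:6) {
    cur <- shared_terms_within(idx, genes, th)
    expect_true(all(names(cur) %in% names(prev)))
    prev <- cur
  }
})

test_that("namespace filtering and the run report behave consistently", {
  fx <- simulate_go_fixture(seed = 53, dir = withr::local_tempdir())
  ont <- read_obo(fx$paths$obo)
  idx <- build_annotation_index(read_gaf(fx$paths$gaf), ont)
  res <- goleaf(ont, idx, genes = fx$list_a, namespace = "BP")
  expect_true(all(tidy(res)$category == "BP"))
  g <- glance(goleaf(ont, idx, genes = fx$list_a))
  expect_true(g$n_terms_retained <= g$n_terms_shared)
  expect_equal(g$n_unmatched, 0)
})
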
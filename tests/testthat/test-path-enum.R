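triangle_net <- function() {
  layered_network(ppi = data.frame(
    protein_a = c("S", "S", "A"), protein_b = c("M", "A", "M"),
    confidence = 0.9))
}

test_that("triangle enumerates the direct and one-intermediate path only", {
  paths <- enumerate_cross_paths(triangle_net(), "S", "M", "S")
  expect_setequal(paths$nodes, c("S|M", "S|A|M"))
  expect_setequal(paths$type_label, c("S-M", "S-P-M"))
})

test_that("the three-intermediate bound is sharp", {
  mk_chain <- function(nodes) {
    layered_network(ppi = data.frame(
      protein_a = nodes[-length(nodes)], protein_b = nodes[-1],
      confidence = 0.9))
  }
  ok <- enumerate_cross_paths(mk_chain(c("S", "a", "b", "c", "M")), "S", "M", "S")
  expect_identical(ok$type_label, "S-P-P-P-M")
  none <- enumerate_cross_paths(mk_chain(c("S", "a", "b", "c", "d", "M")),
                                "S", "M", "S")
  expect_identical(nrow(none), 0L)
})

test_that("regulatory modules prepend the TF/miR edge and label types", {
  net <- layered_network(
    ppi = data.frame(protein_a = "G1", protein_b = "M1", confidence = 0.9),
    tf = data.frame(source = "TF1", target = "G1"),
    mir = data.frame(source = "miR1", target = "G1"))
  tf_paths <- enumerate_cross_paths(net, "TF1", "M1", "TF")
  expect_identical(tf_paths$nodes, "TF1|G1|M1")
  expect_identical(tf_paths$type_label, "TF-TG/P-M")
  mir_paths <- enumerate_cross_paths(net, "miR1", c("G1", "M1"), "miR")
  expect_setequal(mir_paths$nodes, c("miR1|G1", "miR1|G1|M1"))
  expect_setequal(mir_paths$type_label, c("miR-TG/M", "miR-TG/P-M"))
})

test_that("enumeration equals the brute-force DFS oracle on random networks", {
  for (seed in 1:25) {
    net <- random_layered_net(seed)
    ids <- net$nodes$id[net$nodes$kind == "protein"]
    set.seed(seed + 500)
    sources <- sample(ids, 4)
    dests <- sample(setdiff(ids, sources), 5)
    for (module in c("S", "TF", "miR")) {
      src <- switch(module, S = sources, TF = unique(net$tf$source),
                    miR = unique(net$mir$source))
      got <- enumerate_cross_paths(net, src, dests, module)
      expect_identical(sort(got$nodes), enum_oracle(net, src, dests, module),
                       info = paste("seed", seed, "module", module))
      # every emitted path satisfies its type label's length
      relabeled <- path_type_label(module,
                                   lengths(strsplit(got$nodes, "|", fixed = TRUE)))
      expect_identical(got$type_label, relabeled)
    }
  }
})

test_that("source-set members can be excluded as intermediates", {
  net <- layered_network(ppi = data.frame(
    protein_a = c("S1", "S2", "S1"), protein_b = c("S2", "M", "M"),
    confidence = 0.9))
  with_s2 <- enumerate_cross_paths(net, c("S1", "S2"), "M", "S")
  expect_true("S1|S2|M" %in% with_s2$nodes)
  without <- enumerate_cross_paths(net, c("S1", "S2"), "M", "S",
                                   exclude_sources_as_intermediates = TRUE)
  expect_false("S1|S2|M" %in% without$nodes)
  expect_true("S1|M" %in% without$nodes)
})

test_that("context filter keeps deregulated terminals and tolerant interiors", {
  paths <- enumerate_cross_paths(triangle_net(), "S", "M", "S")
  keep <- context_filter_paths(paths, regulation_calls(
    c("S", "A", "M"), c("UP", "NEUTRAL", "DOWN")))
  expect_setequal(keep$nodes, c("S|M", "S|A|M"))
  drop_src <- context_filter_paths(paths, regulation_calls(
    c("S", "A", "M"), c("NEUTRAL", "NEUTRAL", "UP")))
  expect_identical(nrow(drop_src), 0L)
  drop_mid <- context_filter_paths(paths, regulation_calls(
    c("S", "A", "M"), c("UP", "ABSENT", "UP")))
  expect_identical(drop_mid$nodes, "S|M")
  expect_error(context_filter_paths(paths, regulation_calls("S", "UP")),
               "without regulation status")
})

test_that("regulatory target must itself be deregulated", {
  net <- layered_network(
    ppi = data.frame(protein_a = "G1", protein_b = "M1", confidence = 0.9),
    tf = data.frame(source = "TF1", target = "G1"))
  paths <- enumerate_cross_paths(net, "TF1", "M1", "TF")
  keep <- context_filter_paths(paths, regulation_calls(
    c("TF1", "G1", "M1"), c("UP", "NEUTRAL", "UP")))
  expect_identical(nrow(keep), 0L)
  keep2 <- context_filter_paths(paths, regulation_calls(
    c("TF1", "G1", "M1"), c("UP", "DOWN", "UP")))
  expect_identical(nrow(keep2), 1L)
})

test_that("context filter is idempotent and returns a subset", {
  for (seed in 41:45) {
    net <- random_layered_net(seed)
    ids <- net$nodes$id[net$nodes$kind == "protein"]
    set.seed(seed)
    paths <- enumerate_cross_paths(net, sample(ids, 4),
                                   sample(ids, 6), "S")
    calls <- random_calls(net$nodes$id, seed)
    once <- context_filter_paths(paths, calls)
    expect_true(all(once$nodes %in% paths$nodes))
    twice <- context_filter_paths(once, calls)
    expect_identical(twice$nodes, once$nodes)
  }
})

test_that("pathway connection counts multiply terminal memberships", {
  annot <- pathway_annotation(list(
    sigA = list(name = "sigA", class = "signaling", category = "st",
                members = "S"),
    sigB = list(name = "sigB", class = "signaling", category = "st",
                members = c("S", "X")),
    met1 = list(name = "met1", class = "metabolic",
                category = "nucleotide metabolism", members = "M")))
  paths <- enumerate_cross_paths(triangle_net(), "S", "M", "S")
  tab <- pathway_connection_counts(paths[1, ], annot)
  expect_identical(nrow(tab), 2L)  # 2 source pathways x 1 category
  expect_true(all(tab$n_paths == 1L))
  # totals invariant: sum equals paths x |src pathways| x |dest categories|
  tab_all <- pathway_connection_counts(paths, annot)
  expect_identical(sum(tab_all$n_paths), nrow(paths) * 2L)
  empty <- pathway_connection_counts(paths[0, ], annot)
  expect_identical(nrow(empty), 0L)
  # unannotated terminals land in "unassigned"
  net2 <- layered_network(ppi = data.frame(protein_a = "Q", protein_b = "M",
                                           confidence = 0.9))
  p2 <- enumerate_cross_paths(net2, "Q", "M", "S")
  t2 <- pathway_connection_counts(p2, annot)
  expect_identical(t2$source_pathway, "unassigned")
})
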
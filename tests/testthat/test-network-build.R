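test_that("confidence filtering keeps the inclusive boundary", {
  net <- layered_network(ppi = data.frame(
    protein_a = c("A", "A"), protein_b = c("B", "C"),
    confidence = c(0.70, 0.69)))
  kept <- build_hppin(net, 0.7)
  expect_identical(nrow(kept$ppi), 1L)
  expect_setequal(c(kept$ppi$protein_a, kept$ppi$protein_b), c("A", "B"))
  # cutoff 0 is the identity on edges
  all0 <- build_hppin(net, 0)
  expect_identical(nrow(all0$ppi), 2L)
})

test_that("confidence filtering equals a linear-scan oracle on random networks", {
  for (seed in 1:5) {
    net <- random_layered_net(seed)
    kept <- build_hppin(net, 0.5)
    manual <- net$ppi[net$ppi$confidence >= 0.5, , drop = FALSE]
    expect_setequal(paste(kept$ppi$protein_a, kept$ppi$protein_b),
                    paste(manual$protein_a, manual$protein_b))
  }
})

test_that("context network applies the two-level expansion rule", {
  chain <- layered_network(ppi = data.frame(
    protein_a = c("A", "B", "C"), protein_b = c("B", "C", "D"),
    confidence = 0.9))
  calls <- regulation_calls(c("A", "B", "C", "D"),
                            c("UP", "NEUTRAL", "NEUTRAL", "NEUTRAL"))
  ctx <- build_context_network(chain, calls, "ppin")
  edges <- paste(ctx$network$ppi$protein_a, ctx$network$ppi$protein_b)
  expect_setequal(edges, c("A B", "B C"))
  expect_setequal(ctx$edge_level, c("level1", "level2"))
  # level-1 edges always carry a deregulated endpoint
  lvl1 <- ctx$network$ppi[ctx$edge_level == "level1", ]
  expect_true(all(ctx$status[lvl1$protein_a] %in% c("UP", "DOWN") |
                  ctx$status[lvl1$protein_b] %in% c("UP", "DOWN")))
})

test_that("TF context requires both TF and target deregulated", {
  net <- layered_network(
    ppi = data.frame(protein_a = "G1", protein_b = "M1", confidence = 0.9),
    tf = data.frame(source = c("TF1", "TF2"), target = c("G1", "M1")))
  calls <- regulation_calls(c("TF1", "TF2", "G1", "M1"),
                            c("UP", "UP", "NEUTRAL", "DOWN"))
  ctx <- build_context_network(net, calls, "tf")
  expect_identical(nrow(ctx$network$tf), 1L)   # TF1->G1 excluded (G1 neutral)
  expect_identical(ctx$network$tf$target, "M1")
})

test_that("all-ABSENT calls give an empty context network", {
  net <- random_layered_net(3)
  calls <- regulation_calls(net$nodes$id, rep("ABSENT", nrow(net$nodes)))
  ctx <- build_context_network(net, calls, "ppin")
  expect_identical(nrow(ctx$network$ppi), 0L)
  expect_false(any(ctx$status %in% c("UP", "DOWN", "NEUTRAL") &
                   names(ctx$status) %in% ctx$network$nodes$id))
})

test_that("context construction is idempotent and never keeps ABSENT nodes", {
  for (seed in 4:8) {
    net <- random_layered_net(seed)
    calls <- random_calls(net$nodes$id, seed + 100)
    ctx <- build_context_network(net, calls, "ppin")
    st <- calls$status[match(ctx$network$nodes$id, calls$entity_id)]
    in_ppi <- ctx$network$nodes$id %in%
      c(ctx$network$ppi$protein_a, ctx$network$ppi$protein_b)
    expect_true(all(st[in_ppi] %in% c("UP", "DOWN", "NEUTRAL")))
    again <- build_context_network(ctx$network, calls, "ppin")
    expect_setequal(paste(again$network$ppi$protein_a, again$network$ppi$protein_b),
                    paste(ctx$network$ppi$protein_a, ctx$network$ppi$protein_b))
  }
})

test_that("degree distribution is the exact empirical P(k) = n_k / N", {
  tri <- igraph::make_ring(3)
  dd <- degree_distribution_table(tri)
  expect_identical(dd$k, 2L)
  expect_identical(dd$p_k, 1)
  path3 <- igraph::make_graph(~ a - b, b - c)
  dd3 <- degree_distribution_table(path3)
  expect_equal(dd3$p_k[dd3$k == 1], 2 / 3)
  expect_equal(dd3$p_k[dd3$k == 2], 1 / 3)
  for (seed in 1:3) {
    g <- igraph::sample_gnp(30, 0.1)
    if (igraph::vcount(g) > 0)
      expect_equal(sum(degree_distribution_table(g)$p_k), 1)
  }
  expect_error(degree_distribution_table(igraph::make_empty_graph(0)), "empty")
})

test_that("random ensembles preserve counts and are seed-deterministic", {
  g <- igraph::sample_pa(100, m = 2, directed = FALSE)
  cmp <- random_ensemble_compare(g, n_random = 10, seed = 5)
  for (r in cmp$random) {
    expect_identical(r$n, igraph::vcount(g))
    expect_identical(r$m, igraph::ecount(g))
  }
  cmp2 <- random_ensemble_compare(g, n_random = 10, seed = 5)
  expect_identical(cmp, cmp2)
  expect_error(random_ensemble_compare(igraph::make_full_graph(4), 1),
               NA)  # m at maximum is fine
})

test_that("preferential-attachment input shows a heavier tail than G(n,m)", {
  set.seed(99)
  g <- igraph::sample_pa(1000, m = 2, directed = FALSE)
  cmp <- random_ensemble_compare(g, n_random = 10, seed = 21)
  rand_r2 <- vapply(cmp$random, function(r) r$diagnostic[["r_squared"]],
                    numeric(1))
  expect_gt(cmp$observed$diagnostic[["r_squared"]], mean(rand_r2, na.rm = TRUE))
})
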
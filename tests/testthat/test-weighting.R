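test_that("normalization equalizes library sizes and averages tumor samples", {
  set.seed(3)
  vals <- matrix(rexp(40, 0.01), 10, 4,
                 dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:4)))
  expr <- expression_matrix(vals, c("tumor", "tumor", "normal", "normal"))
  xbar <- normalize_expression(expr)
  # two-line oracle
  scaled <- sweep(vals, 2, colSums(vals), "/") * mean(colSums(vals))
  expect_equal(xbar, rowMeans(scaled[, 1:2]), tolerance = 1e-12)
  expect_equal(unname(colSums(scaled)), rep(mean(colSums(vals)), 4))
  # identical tumor samples reproduce either one
  v2 <- cbind(vals[, c(1, 1)], vals[, 3:4])
  colnames(v2) <- colnames(vals)
  e2 <- expression_matrix(v2, c("tumor", "tumor", "normal", "normal"))
  s1 <- v2[, 1] / sum(v2[, 1]) * mean(colSums(v2))
  expect_equal(normalize_expression(e2), s1, tolerance = 1e-12)
  # all-zero sample rejected
  v3 <- vals; v3[, 2] <- 0
  expect_error(normalize_expression(
    expression_matrix(v3, c("tumor", "tumor", "normal", "normal"))), "all-zero")
})

star_graph <- function() {
  layered_network(ppi = data.frame(
    protein_a = "hub", protein_b = c("j", "k", "l"), confidence = 0.9))
}

test_that("mass-action transitions follow neighbor abundance", {
  net <- layered_network(ppi = data.frame(
    protein_a = c("i", "i"), protein_b = c("j", "k"), confidence = 0.9))
  tm <- transition_probabilities(net, c(i = 1, j = 2, k = 6))
  e <- tm$edges
  expect_equal(e$p[e$from == "i" & e$to == "j"], 0.25)
  expect_equal(e$p[e$from == "i" & e$to == "k"], 0.75)
  # equal abundances give the uniform distribution
  tmu <- transition_probabilities(star_graph(),
                                  c(hub = 5, j = 3, k = 3, l = 3))
  pj <- tmu$edges$p[tmu$edges$from == "hub"]
  expect_equal(pj, rep(1 / 3, 3))
  # zero neighborhood falls back to uniform
  tm0 <- transition_probabilities(net, c(i = 1, j = 0, k = 0))
  expect_equal(sort(tm0$edges$p[tm0$edges$from == "i"]), c(0.5, 0.5))
  expect_error(transition_probabilities(net, c(i = 1, j = -2, k = 1)),
               "negative")
})

test_that("transition rows are stochastic on random networks", {
  for (seed in 11:15) {
    net <- random_layered_net(seed)
    g <- ppi_graph(net)
    xb <- setNames(rexp(igraph::vcount(g), 0.01), igraph::V(g)$name)
    tm <- transition_probabilities(g, xb)
    sums <- tapply(tm$edges$p, tm$edges$from, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("local entropy attains its analytic values and bounds", {
  g4 <- layered_network(ppi = data.frame(
    protein_a = "c", protein_b = c("a", "b", "d", "e"), confidence = 0.9))
  tm <- transition_probabilities(g4, c(c = 1, a = 2, b = 2, d = 2, e = 2))
  s <- local_entropy(tm)
  expect_equal(unname(s["c"]), log(4), tolerance = 1e-9)
  expect_equal(unname(s["a"]), 0)  # degree 1
  tm2 <- transition_probabilities(
    layered_network(ppi = data.frame(protein_a = c("i", "i"),
                                     protein_b = c("j", "k"),
                                     confidence = 0.9)),
    c(i = 1, j = 6, k = 2))
  expect_equal(unname(local_entropy(tm2)["i"]),
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-9)
  expect_equal(round(unname(local_entropy(tm2)["i"]), 4), 0.5623)
  # 0 <= S_i <= ln(k_i) with equality under uniform abundance
  for (seed in 21:23) {
    net <- random_layered_net(seed)
    g <- ppi_graph(net)
    xb <- setNames(rexp(igraph::vcount(g), 0.01), igraph::V(g)$name)
    s <- local_entropy(transition_probabilities(g, xb))
    k <- igraph::degree(g)[names(s)]
    expect_true(all(s >= -1e-12 & s <= log(pmax(k, 1)) + 1e-9))
    su <- local_entropy(transition_probabilities(
      g, setNames(rep(2, length(xb)), names(xb))))
    expect_equal(unname(su[k >= 1]), unname(log(k[k >= 1])), tolerance = 1e-9)
  }
})

test_that("node weight is the any-of-seven indicator", {
  calls <- regulation_calls(c("a", "b", "c"), c("UP", "NEUTRAL", "NEUTRAL"))
  topo <- data.frame(node = "c", hub = TRUE, central = FALSE,
                     gnpn = FALSE, lnpn = FALSE)
  class(topo) <- c("topology_classification", "data.frame")
  nw <- node_weight_vector(c("a", "b", "c"), calls, topology = topo)
  expect_identical(nw$w, c(1, 0, 1))   # dEXP only; nothing; hub only
  frac <- node_weight_vector(c("a", "b", "c"), calls, topology = topo,
                             mode = "fraction")
  expect_equal(frac$w, c(1 / 7, 0, 1 / 7))
  ann <- data.frame(node_id = "b", rle = TRUE, sc = FALSE)
  nw2 <- node_weight_vector("b", calls, annotations = ann)
  expect_identical(nw2$w, 1)
})

test_that("effect-on-node matches fixtures and the nested-loop oracle", {
  w1 <- c(hub = 1, j = 1, k = 1, l = 1)
  expect_equal(unname(effect_on_node(star_graph(), w1, "hub")), 12)
  pathg <- layered_network(ppi = data.frame(
    protein_a = c("a", "b"), protein_b = c("b", "c"), confidence = 0.9))
  expect_equal(unname(effect_on_node(pathg, c(a = 1, b = 1, c = 1), "b")), 6)
  expect_equal(unname(effect_on_node(star_graph(),
                                     c(hub = 0, j = 0, k = 0, l = 0), "hub")), 0)
  for (seed in 61:70) {
    net <- random_layered_net(seed, n_nodes = 20, n_edges = 40)
    g <- ppi_graph(net)
    ids <- igraph::V(g)$name
    w <- setNames(rbinom(length(ids), 1, 0.5), ids)
    effs <- effect_on_node(g, w)
    for (nd in sample(ids, 5))
      expect_equal(unname(effs[nd]), effs_oracle(net$ppi, as.list(w), nd))
  }
})

test_that("min-max emission ingredients handle constant vectors", {
  net <- star_graph()
  vals <- matrix(rep(c(4, 4, 8, 8), each = 4), 4, 4,
                 dimnames = list(c("hub", "j", "k", "l"), sprintf("s%d", 1:4)))
  expr <- expression_matrix(vals, c("tumor", "tumor", "normal", "normal"))
  calls <- regulation_calls(c("hub", "j", "k", "l"), rep("NEUTRAL", 4))
  topo <- data.frame(node = c("hub", "j", "k", "l"), hub = FALSE,
                     central = FALSE, gnpn = FALSE, lnpn = FALSE)
  class(topo) <- c("topology_classification", "data.frame")
  wt <- compute_weighting(net, expr, calls, topology = topo)
  expect_true(all(wt$records$eff_norm >= 0 & wt$records$eff_norm <= 1))
  # all weights are 0 (no property true) so effs is constant 0 -> all map to 1
  expect_equal(wt$records$eff_norm, rep(1, 4))
})
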
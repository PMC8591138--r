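# hand-built weighting object over the chain S - P - M with uniform
# abundance: p(S->P) = 1, p(P->M) = p(P->S) = 0.5, emissions settable
chain_weighting <- function(eff = c(S = 1, P = 1, M = 1),
                            ent = c(S = 1, P = 1, M = 1)) {
  net <- layered_network(ppi = data.frame(
    protein_a = c("S", "P"), protein_b = c("P", "M"), confidence = 0.9))
  tm <- transition_probabilities(net, c(S = 2, P = 2, M = 2))
  records <- data.frame(node = c("S", "P", "M"),
                        eff_norm = unname(eff[c("S", "P", "M")]),
                        entropy_norm = unname(ent[c("S", "P", "M")]),
                        stringsAsFactors = FALSE)
  list(tm = tm, records = records)
}

chain_paths <- function() {
  net <- layered_network(ppi = data.frame(
    protein_a = c("S", "P"), protein_b = c("P", "M"), confidence = 0.9))
  enumerate_cross_paths(net, "S", "M", "S")
}

test_that("path score is the log chain product of transitions and emissions", {
  paths <- chain_paths()  # single path S|P|M
  expect_identical(paths$nodes, "S|P|M")
  sc <- score_paths(paths, chain_weighting(), beta = 0.5)
  expect_equal(sc$log_score, log(1) + log(0.5), tolerance = 1e-12)
  expect_equal(sc$prob_score, 0.5, tolerance = 1e-12)
  # all-ones emissions and transitions give score 0 / probability 1
  direct <- layered_network(ppi = data.frame(protein_a = "S", protein_b = "M",
                                             confidence = 0.9))
  p1 <- enumerate_cross_paths(direct, "S", "M", "S")
  tm1 <- transition_probabilities(direct, c(S = 3, M = 3))
  sc1 <- score_paths(p1, list(tm = tm1, records = data.frame(
    node = c("S", "M"), eff_norm = 1, entropy_norm = 1)), beta = 0.5)
  expect_equal(sc1$log_score, 0)
  expect_equal(sc1$prob_score, 1)
})

test_that("lowering an intermediate's effect-on-node lowers the score", {
  paths <- chain_paths()
  hi <- score_paths(paths, chain_weighting(eff = c(S = 1, P = 0.9, M = 1)), 0.5)
  lo <- score_paths(paths, chain_weighting(eff = c(S = 1, P = 0.3, M = 1)), 0.5)
  expect_lt(lo$log_score, hi$log_score)
})

test_that("regulatory first edges carry probability one", {
  net <- layered_network(
    ppi = data.frame(protein_a = "G", protein_b = "M", confidence = 0.9),
    tf = data.frame(source = "TF1", target = "G"))
  paths <- enumerate_cross_paths(net, "TF1", "M", "TF")
  tm <- transition_probabilities(ppi_graph(net), c(G = 2, M = 2))
  sc <- score_paths(paths, list(tm = tm, records = data.frame(
    node = c("G", "M"), eff_norm = 1, entropy_norm = 1)), beta = 0.5)
  # TF1 has no record (emission 1) and its edge is not a PPI transition:
  # only p(G->M) = 1 remains
  expect_equal(sc$log_score, 0)
  # a missing PPI edge is an error
  bad <- paths
  bad$nodes <- "TF1|G|X"
  expect_error(score_paths(bad, list(tm = tm, records = data.frame(
    node = c("G", "M"), eff_norm = 1, entropy_norm = 1))), "absent")
})

test_that("stratified z-scores standardize within strata with degenerate rules", {
  zs <- stratified_zscore(c(1, 2, 3), rep("a", 3))
  expect_equal(zs$z, c(-1, 0, 1))
  expect_false(any(zs$passthrough))
  zc <- stratified_zscore(c(5, 5, 5, 5), rep("b", 4))
  expect_equal(zc$z, rep(0, 4))
  z1 <- stratified_zscore(c(2, 9), c("s", "s"))
  expect_equal(z1$z, c(0, 0))
  expect_true(all(z1$passthrough))
  mix <- stratified_zscore(c(1, 2, 3, 7), c("a", "a", "a", "solo"))
  expect_equal(mix$z, c(-1, 0, 1, 0))
  expect_identical(mix$passthrough, c(FALSE, FALSE, FALSE, TRUE))
})

# scored_paths fixture with controllable per-path scores
mk_scored <- function(df) {
  df$module <- df$module %||% "S"
  df$type_label <- path_type_label("S", lengths(strsplit(df$nodes, "|",
                                                         fixed = TRUE)))
  df$source <- vapply(strsplit(df$nodes, "|", fixed = TRUE), `[`, "", 1)
  df$destination <- vapply(strsplit(df$nodes, "|", fixed = TRUE),
                           function(x) x[length(x)], "")
  df$n_intermediates <- pmax(lengths(strsplit(df$nodes, "|", fixed = TRUE)) - 2L, 0L)
  df$prob_score <- exp(df$log_score)
  class(df) <- c("scored_paths", "cross_paths", "data.frame")
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Model 1 aggregates path probabilities per pair", {
  sc <- mk_scored(data.frame(
    nodes = c("S1|A|M1", "S1|B|M1", "S2|C|M2"),
    log_score = log(c(0.5, 0.25, 0.1)), stringsAsFactors = FALSE))
  pairs <- model1_select_pairs(sc)
  p1 <- pairs[pairs$source == "S1", ]
  expect_equal(exp(p1$log_score), 0.75, tolerance = 1e-12)
  expect_identical(p1$n_paths, 2L)
  # both pairs share one stratum of size 2 -> pass-through selection
  expect_true(all(pairs$passthrough))
  expect_true(all(pairs$selected))
})

test_that("adding a path never lowers a pair score", {
  two <- mk_scored(data.frame(nodes = c("S1|A|M1", "S1|B|M1"),
                              log_score = log(c(0.5, 0.25))))
  one <- mk_scored(data.frame(nodes = "S1|A|M1", log_score = log(0.5)))
  expect_gte(model1_select_pairs(two)$log_score,
             model1_select_pairs(one)$log_score)
})

test_that("pair stratum comes from its shortest member path", {
  sc <- mk_scored(data.frame(
    nodes = c("S1|M1", "S1|A|B|M1", "S2|X|M2", "S3|Y|M3", "S4|Z|M4"),
    log_score = log(c(0.5, 0.2, 0.3, 0.4, 0.35))))
  pairs <- model1_select_pairs(sc)
  expect_identical(pairs$stratum[pairs$source == "S1"], "S-M")
  expect_identical(pairs$stratum[pairs$source == "S2"], "S-P-M")
})

test_that("Model 2 keeps paths within the 80% band of each selected pair", {
  sc <- mk_scored(data.frame(
    nodes = c("S1|A|M1", "S1|B|M1", "S1|C|M1",
              "S2|D|M2", "S3|E|M3", "S4|F|M4"),
    log_score = log(c(0.5, 0.42, 0.2, 0.3, 0.31, 0.32))))
  pairs <- model1_select_pairs(sc)
  pairs$selected <- TRUE
  sel <- model2_select_paths(pairs, sc, frac = 0.8)
  s1 <- sel[sel$source == "S1", ]
  expect_setequal(s1$nodes, c("S1|A|M1", "S1|B|M1"))  # 0.2 < 0.8 * 0.5
  # single-path pairs always keep their path
  expect_true("S2|D|M2" %in% sel$nodes)
  # frac = 1 keeps only the argmax (ties included)
  sel1 <- model2_select_paths(pairs, sc, frac = 1)
  expect_identical(sel1$nodes[sel1$source == "S1"], "S1|A|M1")
  # selection is a subset of the selected pairs' paths
  expect_true(all(paste(sel$source, sel$destination) %in%
                  paste(pairs$source, pairs$destination)))
})

test_that("Model 2 selection is invariant to within-pair monotone rescaling", {
  sc <- mk_scored(data.frame(
    nodes = c("S1|A|M1", "S1|B|M1", "S1|C|M1"),
    log_score = log(c(0.5, 0.42, 0.2))))
  pairs <- model1_select_pairs(sc); pairs$selected <- TRUE
  base <- model2_select_paths(pairs, sc, 0.8)$nodes
  sc2 <- sc; sc2$log_score <- sc$log_score + 3; sc2$prob_score <- exp(sc2$log_score)
  pairs2 <- model1_select_pairs(sc2); pairs2$selected <- TRUE
  expect_identical(model2_select_paths(pairs2, sc2, 0.8)$nodes, base)
})
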
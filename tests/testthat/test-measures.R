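test_that("gs_sim satisfies the correlation identities", {
  pv <- c(s1 = 0.001, s2 = 0.2, s3 = 0.9, s4 = 1.0)
  pa <- as_semantic_profile(pv, "c", "A")
  expect_equal(gs_sim(pa, pa)$value, 1.0, tolerance = 1e-15)

  # two points determine a perfect anti-correlation under any transform
  p2a <- as_semantic_profile(c(x = 1e-300, y = 1.0), "c", "A")
  p2b <- as_semantic_profile(c(x = 1.0, y = 1e-300), "c", "B")
  for (tr in c("exp", "identity", "neglog10"))
    expect_equal(gs_sim(p2a, p2b, transform = tr)$value, -1.0,
                 tolerance = 1e-12)

  # agreement with an independent PCC on exp-transformed entries
  pb <- as_semantic_profile(c(s1 = 0.005, s2 = 0.3, s3 = 0.8, s4 = 0.95),
                            "c", "B")
  expect_equal(gs_sim(pa, pb, transform = "exp")$value,
               cor(exp(pa$pvalues), exp(pb$pvalues)), tolerance = 1e-12)
})

test_that("gs_sim agrees with cor() to 1e-12 and stays in [-1,1] on random profiles", {
  withr::with_seed(7, {
    for (i in 1:50) {
      n <- sample(10:100, 1)
      nm <- paste0("s", seq_len(n))
      pa <- as_semantic_profile(setNames(runif(n), nm), "c", "A")
      pb <- as_semantic_profile(setNames(runif(n), nm), "c", "B")
      tr <- sample(c("exp", "identity", "neglog10"), 1)
      v <- gs_sim(pa, pb, transform = tr)$value
      expect_equal(v, cor(transform_profile(pa, tr),
                          transform_profile(pb, tr)), tolerance = 1e-12)
      expect_lte(abs(v), 1)
      # symmetry
      expect_equal(v, gs_sim(pb, pa, transform = tr)$value,
                   tolerance = 1e-15)
    }
  })
})

test_that("gs_sim flags zero-variance profiles and mismatched collections", {
  flat <- as_semantic_profile(c(a = 1, b = 1, c = 1), "c", "A")
  var_ <- as_semantic_profile(c(a = 0.1, b = 0.5, c = 1), "c", "B")
  sc <- gs_sim(flat, var_)
  expect_equal(sc$value, 0)
  expect_true("zero_variance" %in% sc$flags)
  other <- as_semantic_profile(c(a = 0.1, b = 0.5, c = 1), "other", "B")
  expect_error(gs_sim(flat, other), "same collection")
})

test_that("jaccard and overlap coefficient match their definitions", {
  expect_equal(jaccard_index(c("G1", "G2", "G3"), c("G2", "G3", "G4")), 0.5)
  expect_equal(overlap_coefficient(c("G1", "G2", "G3"), c("G2", "G3", "G4")),
               2 / 3)
  expect_equal(jaccard_index(c("A", "B"), c("C", "D")), 0)
  expect_equal(overlap_coefficient(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard_index(c("A", "B"), c("A", "B")), 1)
  expect_equal(overlap_coefficient(c("A", "B"), c("A", "B", "C")), 1)
  expect_error(jaccard_index(character(0), character(0)), "empty")
})

test_that("jaccard <= oc always, equality iff equal sizes or empty intersection", {
  withr::with_seed(11, {
    pool <- sprintf("g%02d", 1:30)
    for (i in 1:100) {
      a <- sample(pool, sample(1:15, 1))
      b <- sample(pool, sample(1:15, 1))
      ji <- jaccard_index(a, b); oc <- overlap_coefficient(a, b)
      expect_lte(ji, oc + 1e-15)
      if (abs(ji - oc) < 1e-15)
        expect_true(length(a) == length(b) ||
                      length(intersect(a, b)) == 0L)
      # symmetry
      expect_equal(ji, jaccard_index(b, a))
      expect_equal(oc, overlap_coefficient(b, a))
    }
  })
})

test_that("sab reproduces the worked path-graph examples", {
  g <- igraph::graph_from_edgelist(
    cbind(c("A", "B", "C"), c("B", "C", "D")), directed = FALSE)
  s <- sab(c("A", "B"), c("C", "D"), g)
  expect_equal(s$d_aa, 1); expect_equal(s$d_bb, 1)
  expect_equal(s$d_ab, 1.5)
  expect_equal(s$s_ab, 0.5)
  # identical sets: shared genes at distance 0, overlapping modules
  s2 <- sab(c("A", "B"), c("A", "B"), g)
  expect_equal(s2$d_ab, 0)
  expect_equal(s2$s_ab, -1)
  # singleton convention: within-distance 0
  s3 <- sab("A", "D", g)
  expect_equal(s3$d_aa, 0); expect_equal(s3$d_bb, 0)
  expect_equal(s3$s_ab, 3)
  expect_error(sab(c("ZZ"), c("A"), g), "unmapped")
})

test_that("sab equals the brute-force BFS oracle on random small graphs", {
  withr::with_seed(23, {
    for (rep in 1:200) {
      n <- sample(4:12, 1)
      nodes <- sprintf("N%02d", seq_len(n))
      # random graph: each possible edge present w.p. 0.35
      all_pairs <- t(combn(nodes, 2))
      keep <- runif(nrow(all_pairs)) < 0.35
      if (!any(keep)) next
      edges <- all_pairs[keep, , drop = FALSE]
      g <- igraph::graph_from_edgelist(edges, directed = FALSE)
      present <- igraph::V(g)$name
      a <- sample(present, sample(seq_len(min(3, length(present))), 1))
      b <- sample(present, sample(seq_len(min(3, length(present))), 1))
      want <- sab_oracle(a, b, present, edges)
      if (is.na(want$d_ab)) next  # oracle says no finite cross distance
      got <- sab(a, b, g)
      expect_equal(got$d_ab, want$d_ab)
      expect_equal(got$d_aa, want$d_aa)
      expect_equal(got$d_bb, want$d_bb)
      expect_equal(got$s_ab, want$s_ab)
      # symmetry
      expect_equal(sab(b, a, g)$s_ab, got$s_ab)
    }
  })
})

test_that("sab drops and counts genes absent from the network or unreachable", {
  # path A-B-C-D plus a separate component E-F
  g <- igraph::graph_from_edgelist(
    cbind(c("A", "B", "C", "E"), c("B", "C", "D", "F")), directed = FALSE)
  s <- sab(c("A", "GHOST"), c("C", "D"), g)
  expect_equal(s$n_dropped_a, 1)   # GHOST absent from the network
  expect_true(is.finite(s$s_ab))
  # E is in the network but unreachable from every counterpart
  s2 <- sab(c("A", "E"), c("C", "D"), g)
  expect_equal(s2$n_dropped_a, 1)
  expect_equal(s2$d_ab, mean(c(2, 2, 3)))  # A->C, C->A, D->A
  expect_true(is.finite(s2$s_ab))
})

test_that("score_pair and score_all produce deterministic long-format output", {
  coll <- tiny_collection()
  da <- disease_gene_set("dZ", coll$sets$S1$genes)
  db <- disease_gene_set("dA", coll$sets$S2$genes)
  out <- score_pair(da, db, collection = coll,
                    measures = c("gs_sim", "jaccard", "oc"))
  expect_identical(out$measure, c("gs_sim", "jaccard", "oc"))
  all_out <- score_all(list(da, db), collection = coll,
                       measures = c("jaccard", "gs_sim"))
  # lexicographic pair order
  expect_identical(all_out$disease_a[1], "dA")
  expect_identical(all_out$disease_b[1], "dZ")
  expect_equal(nrow(all_out), 2L)
})
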
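test_that("make_collection is seeded, sized and contained in the universe", {
  spec <- synthetic_spec(seed = 2L)
  c1 <- make_collection(spec)
  c2 <- make_collection(spec)
  expect_length(c1$sets, 50L)
  sizes <- lengths(lapply(c1$sets, `[[`, "genes"))
  expect_true(all(sizes >= 20 & sizes <= 60))
  expect_true(all(unlist(lapply(c1$sets, `[[`, "genes")) %in% c1$universe))
  # bit-reproducible
  expect_identical(lapply(c1$sets, `[[`, "genes"),
                   lapply(c2$sets, `[[`, "genes"))
  expect_error(make_collection(
    synthetic_spec(universe_size = 2000L, set_size_range = c(3000L, 4000L))),
    "set_size_range")
})

test_that("disjoint-genes pair design yields exactly zero overlap", {
  spec <- synthetic_spec(pair_design = "shared_drivers_disjoint_genes",
                         disease_size_range = c(30L, 50L), seed = 3L)
  coll <- make_collection(spec)
  for (s in 1:10) {
    pr <- make_disease_pair(spec, coll, seed = 50L + s)
    expect_equal(jaccard_index(pr$a, pr$b), 0)
    expect_equal(overlap_coefficient(pr$a, pr$b), 0)
    expect_identical(pr$truth$drivers_a, pr$truth$drivers_b)
  }
})

test_that("overlapping design plants shared genes; independent design uses other drivers", {
  spec_o <- synthetic_spec(pair_design = "shared_drivers_overlapping_genes",
                           disease_size_range = c(30L, 50L), seed = 3L)
  coll <- make_collection(spec_o)
  pr <- make_disease_pair(spec_o, coll, seed = 7L)
  expect_gte(length(intersect(pr$a$genes, pr$b$genes)), 1L)

  spec_i <- synthetic_spec(pair_design = "independent",
                           disease_size_range = c(30L, 50L), seed = 3L)
  pri <- make_disease_pair(spec_i, coll, seed = 7L)
  expect_length(intersect(pri$truth$drivers_a, pri$truth$drivers_b), 0L)
})

test_that("shared-driver pairs score higher profile similarity than independent pairs", {
  spec_s <- synthetic_spec(pair_design = "shared_drivers_disjoint_genes",
                           disease_size_range = c(30L, 50L), seed = 13L)
  spec_i <- synthetic_spec(pair_design = "independent",
                           disease_size_range = c(30L, 50L), seed = 13L)
  coll <- make_collection(spec_s)
  sim_of <- function(spec, s) {
    pr <- make_disease_pair(spec, coll, seed = 600L + s)
    gs_sim(semantic_profile(pr$a, coll),
           semantic_profile(pr$b, coll))$value
  }
  shared <- vapply(1:20, function(s) sim_of(spec_s, s), numeric(1))
  indep <- vapply(1:20, function(s) sim_of(spec_i, s), numeric(1))
  expect_gt(mean(shared), mean(indep))
})

test_that("make_cohort plants the requested relative risk and marginals", {
  # closed-form check: p_a=0.1, p_b=0.12, r=3 -> q=0.1, P(B|A)=0.3
  spec <- synthetic_spec(n_samples = 50000L, seed = 4L)
  pl <- data.frame(disease_a = "A", disease_b = "B", target_rr = 3,
                   prevalence_a = 0.1, prevalence_b = 0.12)
  co <- make_cohort(spec, pl)
  r <- relative_risk(co, "A", "B")
  expect_lt(abs(r$rr - 3), 0.35)
  expect_lt(abs(mean(co[, "B"]) - 0.12), 0.01)
  # r = 1: independence
  pl1 <- data.frame(disease_a = "X", disease_b = "Y", target_rr = 1)
  r1 <- relative_risk(make_cohort(spec, pl1), "X", "Y")
  expect_true(r1$ci_low <= 1 && 1 <= r1$ci_high)
  # infeasible RR is rejected
  # q = 0.5 / (0.05*10 + 0.95) = 0.345, so P(B|A) = 3.4 > 1
  bad <- data.frame(disease_a = "U", disease_b = "V", target_rr = 10,
                    prevalence_a = 0.05, prevalence_b = 0.5)
  expect_error(make_cohort(spec, bad), "infeasible RR")
})

test_that("planted-RR estimation is consistent as the cohort grows", {
  errs <- vapply(c(1e3, 1e4, 5e4), function(n) {
    spec <- synthetic_spec(n_samples = as.integer(n), seed = 10L)
    pl <- data.frame(disease_a = "A", disease_b = "B", target_rr = 5)
    median(vapply(1:5, function(s)
      abs(relative_risk(make_cohort(spec, pl, seed = s), "A", "B")$rr - 5),
      numeric(1)))
  }, numeric(1))
  expect_lt(errs[3], errs[1])
})

test_that("the benchmark has no gene overlap anywhere and is reproducible", {
  b1 <- make_benchmark(n_pairs = 10L, n_comorbid = 4L)
  b2 <- make_benchmark(n_pairs = 10L, n_comorbid = 4L)
  for (i in seq_along(b1$pairs)) {
    expect_length(intersect(b1$pairs[[i]]$a$genes,
                            b1$pairs[[i]]$b$genes), 0L)
    expect_identical(b1$pairs[[i]]$a$genes, b2$pairs[[i]]$a$genes)
  }
  expect_identical(b1$labels, b2$labels)
  sc <- score_benchmark(b1, measures = c("jaccard", "oc"))
  expect_true(all(sc$jaccard == 0))
  expect_true(all(sc$oc == 0))
})
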
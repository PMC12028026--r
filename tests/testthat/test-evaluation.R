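test_that("relative risk matches the worked 2x2 examples", {
  # 100 A-positive, 30 with B; 200 A-negative, 20 with B -> RR = 3
  r <- rr_from_counts(30, 70, 20, 180)
  expect_equal(r$rr, 3.0)
  expect_true(r$ci_low <= r$rr && r$rr <= r$ci_high)
  expect_equal(r$p, chisq_oracle(30, 70, 20, 180), tolerance = 1e-12)
  # identical rates -> RR = 1
  expect_equal(rr_from_counts(10, 90, 20, 180)$rr, 1.0)
})

test_that("relative risk matches a direct-formula oracle on exhaustive small tables", {
  for (n11 in c(0, 1, 3, 12, 50)) for (n10 in c(1, 7, 50))
    for (n01 in c(0, 2, 9, 50)) for (n00 in c(1, 11, 50)) {
      r <- rr_from_counts(n11, n10, n01, n00)
      if (n11 > 0 && n01 > 0) {
        expect_equal(r$rr, (n11 / (n11 + n10)) / (n01 / (n01 + n00)),
                     tolerance = 1e-12)
        se <- sqrt(1 / n11 - 1 / (n11 + n10) + 1 / n01 - 1 / (n01 + n00))
        expect_equal(r$ci_low, exp(log(r$rr) - qnorm(0.975) * se),
                     tolerance = 1e-12)
      } else {
        expect_true("continuity_corrected" %in% r$flags)
        expect_true(is.finite(r$rr))
      }
    }
  expect_error(rr_from_counts(0, 0, 5, 5), "non-empty")
})

test_that("relative_risk on a cohort builds the right 2x2 table", {
  m <- matrix(0L, 10, 2, dimnames = list(NULL, c("A", "B")))
  m[1:4, "A"] <- 1L
  m[c(1, 2, 5), "B"] <- 1L
  co <- cohort_table(m)
  r <- relative_risk(co, "A", "B")
  expect_equal(c(r$n11, r$n10, r$n01, r$n00), c(2, 2, 1, 5))
  expect_equal(r$rr, (2 / 4) / (1 / 6))
  expect_error(relative_risk(co, "A", "Z"), "not in cohort")
})

test_that("bonferroni_threshold is alpha / m", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 3828), 3), 1.31e-5)
  expect_equal(signif(bonferroni_threshold(0.05, 7658), 3), 6.53e-6)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("label_pairs applies the significance gate and all RR thresholds", {
  mk <- function(rr, p) {
    r <- rr_from_counts(10, 10, 10, 10)
    r$rr <- rr; r$p <- p
    r$disease_a <- "X"; r$disease_b <- "Y"
    r
  }
  results <- c(list(mk(12, 1e-9), mk(3, 1e-9), mk(12, 0.01)),
               replicate(97, mk(1, 0.5), simplify = FALSE))
  lab <- label_pairs(results, alpha = 0.05)  # M = 100 -> threshold 5e-4
  l1 <- lab[1:3, ]  # rr=12, p=1e-9: all three thresholds
  expect_identical(l1$label, c(1L, 1L, 1L))
  l2 <- lab[4:6, ]  # rr=3: only threshold 1
  expect_identical(l2$label, c(1L, 0L, 0L))
  l3 <- lab[7:9, ]  # p=0.01 fails the gate everywhere
  expect_identical(l3$label, c(0L, 0L, 0L))
})

test_that("rank_auc matches its closed forms and the brute-force oracle", {
  expect_equal(rank_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_equal(rank_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1.0)
  expect_equal(rank_auc(c(1, 2, 3, 3, 4), c(0, 0, 1, 0, 1))$auc,
               auc_oracle(c(1, 2, 3, 3, 4), c(0, 0, 1, 0, 1)))
  withr::with_seed(17, {
    for (i in 1:30) {
      n <- sample(5:40, 1)
      s <- sample(1:10, n, replace = TRUE)  # plenty of ties
      l <- rbinom(n, 1, 0.4)
      if (length(unique(l)) < 2) next
      expect_equal(rank_auc(s, l)$auc, auc_oracle(s, l), tolerance = 1e-12)
      # complement identity
      expect_equal(rank_auc(s, l)$auc + rank_auc(-s, l)$auc, 1,
                   tolerance = 1e-12)
    }
  })
  expect_error(rank_auc(1:5, rep(1, 5)), "one positive and one negative")
})

test_that("rank_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(19, {
    s <- rnorm(60)
    l <- rbinom(60, 1, 0.5)
    expect_equal(rank_auc(s, l)$auc,
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  })
})

test_that("single-measure logistic model reproduces the raw AUC exactly", {
  withr::with_seed(5, {
    s <- rnorm(100)
    l <- rbinom(100, 1, plogis(s))
    if (length(unique(l)) < 2) l[1:2] <- c(0L, 1L)
    lr <- lr_combine(data.frame(m1 = s), l, model_specs = list("m1"))
    expect_equal(lr$best_auc, rank_auc(s, l)$auc, tolerance = 1e-12)
  })
})

test_that("best-subset search never loses to a searched subset and null AUC is near 0.5", {
  withr::with_seed(6, {
    sm <- data.frame(m1 = rnorm(200), m2 = rnorm(200), m3 = rnorm(200))
    l <- rbinom(200, 1, plogis(sm$m1 + 0.5 * sm$m2))
    lr <- lr_combine(sm, l, model_specs = list("m1", "m2",
                                               c("m1", "m2"),
                                               c("m1", "m2", "m3")))
    expect_equal(lr$best_auc, max(lr$results$auc))
    expect_gte(lr$best_auc,
               max(lr$results$auc[lr$results$model %in% c("m1", "m2")]))
    # labels independent of scores -> AUC near 0.5
    l0 <- rbinom(200, 1, 0.5)
    lr0 <- lr_combine(sm, l0, model_specs = list("m1"))
    expect_lt(abs(lr0$best_auc - 0.5), 0.1)
  })
})

test_that("perfect separation is flagged but still scored", {
  sm <- data.frame(m1 = c(rep(0, 20), rep(10, 20)))
  l <- rep(c(0, 1), each = 20)
  lr <- lr_combine(sm, l, model_specs = list("m1"))
  expect_equal(lr$best_auc, 1.0)
  expect_true(any(grepl("perfect_separation", lr$results$flags)))
})

test_that("evaluate_scores ties the whole pipeline together", {
  spec <- synthetic_spec(n_samples = 5000L, target_rr = 8, seed = 31L)
  labels <- data.frame(disease_a = c("P1A", "P2A", "P3A", "P4A"),
                       disease_b = c("P1B", "P2B", "P3B", "P4B"),
                       target_rr = c(8, 8, 1, 1))
  cohort <- make_cohort(spec, labels)
  scores <- data.frame(
    disease_a = rep(labels$disease_a, 2),
    disease_b = rep(labels$disease_b, 2),
    measure = rep(c("gs_sim", "jaccard"), each = 4),
    value = c(0.9, 0.8, 0.1, 0.2, 0, 0, 0, 0))
  rep_ <- evaluate_scores(scores, cohort, thresholds = c(1, 5))
  expect_equal(rep_$n_pairs, 4L)
  auc1 <- rep_$auc[rep_$auc$rr_threshold == 1 & rep_$auc$measure == "gs_sim", ]
  expect_equal(auc1$auc, 1.0)   # planted scores rank the planted comorbidity
  aucj <- rep_$auc[rep_$auc$rr_threshold == 1 & rep_$auc$measure == "jaccard", ]
  expect_equal(aucj$auc, 0.5)   # all-zero scores are pure ties
})
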
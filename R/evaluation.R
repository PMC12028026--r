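## Evaluation framework: relative-risk gold standards from cohort
## diagnosis matrices, Bonferroni-gated comorbidity labels at RR
## thresholds 1/5/10, rank-based AUC, and logistic-regression combination
## of scores.

#' Relative risk of disease B given disease A in a cohort
#'
#' Builds the 2x2 table (exposed = A-positive, outcome = B-positive) and
#' estimates `RR = P(B | A = 1) / P(B | A = 0)` with a Wald 95% confidence
#' interval `exp(log RR +/- 1.96 * sqrt(1/n11 - 1/n1. + 1/n01 - 1/n0.))`
#' and a Pearson chi-square p-value without continuity correction. When an
#' outcome count is zero in either arm the estimate is recomputed with a
#' 0.5 continuity correction added to every cell and flagged.
#'
#' @param cohort A [cohort_table()].
#' @param disease_a,disease_b Disease codes (columns of the cohort).
#' @return An object of class `RRResult`: counts `n11`, `n10`, `n01`,
#'   `n00` (A+B+, A+B-, A-B+, A-B-), `rr`, `ci_low`, `ci_high`, `p`,
#'   `flags`, disease ids.
#' @export
relative_risk <- function(cohort, disease_a, disease_b) {
  stopifnot(inherits(cohort, "CohortTable"))
  for (d in c(disease_a, disease_b))
    if (!d %in% colnames(cohort)) stop("disease not in cohort: ", d)
  a <- cohort[, disease_a] == 1L
  b <- cohort[, disease_b] == 1L
  res <- rr_from_counts(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
  res$disease_a <- disease_a
  res$disease_b <- disease_b
  res
}

#' @rdname relative_risk
#' @param n11,n10,n01,n00 2x2 cell counts: exposed with / without outcome,
#'   unexposed with / without outcome.
#' @export
rr_from_counts <- function(n11, n10, n01, n00) {
  if (n11 + n10 == 0L || n01 + n00 == 0L)
    stop("exposed and unexposed groups must both be non-empty")
  flags <- character(0)
  x11 <- n11; x10 <- n10; x01 <- n01; x00 <- n00
  if (n11 == 0L || n01 == 0L) {
    # zero outcome count in an arm: 0.5 added to all cells for estimation
    x11 <- n11 + 0.5; x10 <- n10 + 0.5; x01 <- n01 + 0.5; x00 <- n00 + 0.5
    flags <- "continuity_corrected"
  }
  r1 <- x11 / (x11 + x10)
  r0 <- x01 / (x01 + x00)
  rr <- r1 / r0
  se <- sqrt(1 / x11 - 1 / (x11 + x10) + 1 / x01 - 1 / (x01 + x00))
  z <- qnorm(0.975)
  ci <- exp(log(rr) + c(-1, 1) * z * se)
  tab <- matrix(c(n11, n10, n01, n00), nrow = 2, byrow = TRUE)
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
  else suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 rr = rr, ci_low = ci[1], ci_high = ci[2], p = p,
                 flags = flags, disease_a = NA_character_,
                 disease_b = NA_character_),
            class = "RRResult")
}

#' @export
print.RRResult <- function(x, ...) {
  cat("RR(", x$disease_a, " -> ", x$disease_b, ") = ",
      format(x$rr, digits = 4), "  95% CI [",
      format(x$ci_low, digits = 4), ", ", format(x$ci_high, digits = 4),
      "], p = ", format(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' Family-wise threshold `alpha / m` over `m` simultaneous tests; used
#' both to gate the relative-risk gold standard and to label significant
#' core gene sets.
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Comorbidity labels from relative-risk results
#'
#' A pair is labelled comorbid at a given RR threshold iff its chi-square
#' p-value passes the Bonferroni threshold `alpha / M` over the `M` tested
#' pairs AND its RR exceeds the threshold. Thresholds 1, 5 and 10 give
#' progressively stricter gold standards.
#'
#' @param rr_results List of `RRResult`s (one per tested pair).
#' @param alpha Family-wise error rate (default 0.05).
#' @param thresholds Numeric RR thresholds (default `c(1, 5, 10)`).
#' @return Data frame with columns `disease_a`, `disease_b`, `rr`, `p`,
#'   `rr_threshold`, `label` (0/1).
#' @export
label_pairs <- function(rr_results, alpha = 0.05, thresholds = c(1, 5, 10)) {
  if (length(rr_results) == 0L) stop("no RR results to label")
  M <- length(rr_results)
  thr_p <- bonferroni_threshold(alpha, M)
  rows <- lapply(rr_results, function(r) {
    data.frame(disease_a = r$disease_a, disease_b = r$disease_b,
               rr = r$rr, p = r$p, rr_threshold = thresholds,
               label = as.integer(r$p <= thr_p & r$rr > thresholds),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney probability that
#' a random positive outscores a random negative, with ties counting one
#' half. Equivalent to the trapezoidal area over all score thresholds.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels 0/1 (or logical) class labels, same length.
#' @return An object of class `ROCResult`: `auc`, `n_pos`, `n_neg`.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  ok <- is.finite(scores)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("need at least one positive and one negative label")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat("AUC = ", format(x$auc, digits = 4), " (", x$n_pos, " positives, ",
      x$n_neg, " negatives)\n", sep = "")
  invisible(x)
}

#' Logistic-regression combination of comorbidity scores
#'
#' Fits an unregularised maximum-likelihood logistic model for every
#' requested subset of measures (missing scores are set to zero first) and
#' reports the in-sample AUC of the fitted probabilities; the subset with
#' the highest AUC wins. A single-measure model reproduces that measure's
#' raw AUC exactly, because the logistic transform is monotone. Perfect
#' separation is flagged but the AUC of the separating direction is still
#' reported.
#'
#' @param score_matrix Data frame or matrix, one row per pair, one column
#'   per measure.
#' @param labels 0/1 labels, one per row.
#' @param model_specs List of character vectors naming the measure subsets
#'   to search; default: every single measure plus the full set.
#' @return An object of class `LRCombineResult`: `best_measures`,
#'   `best_auc`, `results` (data frame model / auc / flags), `fits`.
#' @export
lr_combine <- function(score_matrix, labels, model_specs = NULL) {
  sm <- as.data.frame(score_matrix)
  labels <- as.integer(as.logical(labels))
  if (nrow(sm) != length(labels)) stop("score rows and labels differ in length")
  sm[is.na(sm)] <- 0
  if (is.null(model_specs)) {
    model_specs <- c(as.list(names(sm)),
                     if (ncol(sm) > 1L) list(names(sm)))
  }
  res <- lapply(model_specs, function(vars) {
    if (!all(vars %in% names(sm))) stop("unknown measure(s): ",
                                        paste(setdiff(vars, names(sm)),
                                              collapse = ", "))
    dat <- cbind(sm[, vars, drop = FALSE], .y = labels)
    flags <- character(0)
    fit <- withCallingHandlers(
      glm(.y ~ ., data = dat, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          flags <<- "perfect_separation"
        invokeRestart("muffleWarning")
      })
    # a separating direction drives the deviance to zero
    if (fit$deviance < 1e-6) flags <- union(flags, "perfect_separation")
    auc <- rank_auc(fit$fitted.values, labels)$auc
    list(vars = vars, auc = auc, flags = flags, fit = fit)
  })
  aucs <- vapply(res, `[[`, numeric(1), "auc")
  best <- which.max(aucs)
  tab <- data.frame(model = vapply(res, function(r)
    paste(r$vars, collapse = "+"), character(1)),
    auc = aucs,
    flags = vapply(res, function(r) paste(r$flags, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE)
  structure(list(best_measures = res[[best]]$vars, best_auc = aucs[best],
                 results = tab, fits = lapply(res, `[[`, "fit")),
            class = "LRCombineResult")
}

#' @export
print.LRCombineResult <- function(x, ...) {
  cat("Logistic combination: best model '",
      paste(x$best_measures, collapse = "+"), "' with in-sample AUC ",
      format(x$best_auc, digits = 4), "\n", sep = "")
  print(x$results, row.names = FALSE)
  invisible(x)
}
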
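## Core gene-set extraction: a two-component mixture of Gaussian linear
## regressions (fit by EM) splits the paired p-value vectors of a comorbid
## disease pair into a high-similarity "core" component and the rest.

#' Fit a two-component mixture of linear regressions by EM
#'
#' Models the paired transformed p-values (x_i, y_i) of a disease pair as
#' draws from one of two Gaussian regression lines
#' `y ~ N(b0_k + b1_k * x, sigma2_k)` with mixing weights `pi_k`. The
#' E-step computes posterior component memberships (responsibilities); the
#' M-step refits each line by responsibility-weighted least squares and
#' updates the weighted residual variance and the mixing weights.
#' Responsibilities are initialised from a symmetric Dirichlet, the EM is
#' restarted `n_restarts` times from different seeded initialisations, and
#' the fit with the best log-likelihood is kept. The log-likelihood is
#' non-decreasing within every run (EM guarantee); a variance floor of
#' `1e-10` prevents component collapse onto single points.
#'
#' If all points are collinear to machine precision there is nothing for a
#' second component to explain: the fit falls back to a single line holding
#' every point in component 1, flagged `degenerate_single_line`.
#'
#' @param x,y Numeric vectors of equal length (>= 10): the two transformed
#'   p-value vectors of the pair.
#' @param n_components Fixed at 2.
#' @param seed Integer seed for the restarts.
#' @param n_restarts Number of random restarts (default 5).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Convergence tolerance on the log-likelihood change
#'   (default 1e-6).
#' @return An object of class `MMRFit`: `coefficients` (2 x 2 matrix of
#'   intercept/slope per component), `sigma2`, `weights` (mixing
#'   proportions), `responsibilities` (n x 2), `assignments` (hard labels
#'   by max posterior), `loglik`, `loglik_trace`, `converged`, `flags`,
#'   `seed`, `n_restarts`.
#' @export
mmr_fit <- function(x, y, n_components = 2L, seed = 1L, n_restarts = 5L,
                    max_iter = 500L, tol = 1e-6) {
  if (n_components != 2L)
    stop("the mixture is fixed at two components")
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 10L) stop("need at least 10 points to fit the mixture")

  # single-line degeneracy: one OLS line already explains everything
  X <- cbind(1, x)
  ols <- lm.wfit(X, y, w = rep(1, n))
  scale_y <- max(abs(y), 1)
  if (max(abs(ols$residuals)) < 1e-10 * scale_y) {
    resp <- cbind(rep(1, n), rep(0, n))
    return(structure(list(
      coefficients = rbind(c(ols$coefficients[1], ols$coefficients[2]),
                           c(NA_real_, NA_real_)),
      sigma2 = c(.VAR_FLOOR, NA_real_),
      weights = c(1, 0), responsibilities = resp,
      assignments = rep(1L, n), loglik = NA_real_,
      loglik_trace = numeric(0), converged = FALSE,
      flags = "degenerate_single_line",
      seed = seed, n_restarts = n_restarts), class = "MMRFit"))
  }

  best <- NULL
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    fit <- .mmr_em_once(x, y, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$seed <- seed
  best$n_restarts <- n_restarts
  class(best) <- "MMRFit"
  best
}

.VAR_FLOOR <- 1e-10

.mmr_em_once <- function(x, y, max_iter, tol) {
  n <- length(x)
  X <- cbind(1, x)
  # random responsibilities ~ symmetric Dirichlet(1,1): uniform split
  u <- runif(n)
  resp <- cbind(u, 1 - u)
  beta <- matrix(NA_real_, 2, 2)
  sigma2 <- c(NA_real_, NA_real_)
  pi_k <- c(0.5, 0.5)
  trace <- numeric(0)
  ll <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # M-step: weighted least squares per component
    for (k in 1:2) {
      w <- pmax(resp[, k], 1e-12)
      wf <- lm.wfit(X, y, w = w)
      beta[k, ] <- wf$coefficients
      res <- y - X %*% beta[k, ]
      sigma2[k] <- max(sum(w * res^2) / sum(w), .VAR_FLOOR)
      pi_k[k] <- mean(resp[, k])
    }
    pi_k <- pmax(pi_k, 1e-12)
    pi_k <- pi_k / sum(pi_k)
    # E-step: log joint densities, stabilised softmax
    logd <- vapply(1:2, function(k)
      log(pi_k[k]) + dnorm(y, X %*% beta[k, ], sqrt(sigma2[k]), log = TRUE),
      numeric(n))
    m <- pmax(logd[, 1], logd[, 2])
    lse <- m + log(exp(logd[, 1] - m) + exp(logd[, 2] - m))
    resp <- exp(logd - lse)
    ll_new <- sum(lse)
    trace <- c(trace, ll_new)
    if (is.finite(ll) && abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(coefficients = beta, sigma2 = sigma2, weights = pi_k,
       responsibilities = resp,
       assignments = max.col(resp, ties.method = "first"),
       loglik = ll, loglik_trace = trace, converged = converged,
       flags = character(0))
}

#' @export
print.MMRFit <- function(x, ...) {
  cat("Two-component mixture of regressions",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  for (k in 1:2)
    cat(sprintf("  component %d: y = %.4g + %.4g x, sigma2 = %.3g, pi = %.3f\n",
                k, x$coefficients[k, 1], x$coefficients[k, 2],
                x$sigma2[k], x$weights[k]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  invisible(x)
}

#' Extract the core gene sets of a comorbid pair
#'
#' Given a fitted two-component mixture on the paired transformed p-values
#' of two diseases, computes the profile-correlation score within each
#' hard-assigned component and declares the component with the larger
#' score the "core" gene sets — the functional sets whose paired p-values
#' move together and thus drive the pair's comorbidity signal. Each core
#' member is additionally labelled significant when either disease's raw
#' p-value passes the Bonferroni threshold `alpha / n` over the `n`
#' functional sets.
#'
#' @param fit An `MMRFit` from [mmr_fit()].
#' @param profile_a,profile_b The two `SemanticProfile`s the fit was built
#'   from (same collection, same order as `fit`'s observations).
#' @param alpha Family-wise significance level for the Bonferroni labels
#'   (default 0.05).
#' @param transform Transform under which the within-component scores are
#'   computed (should match the scale passed to [mmr_fit()]).
#' @return An object of class `CoreSubsetResult`: `core_set_names`,
#'   `rest_set_names`, `core_gs_sim`, `rest_gs_sim`, `core_component`,
#'   `significance_labels` (named logical over core members),
#'   `bonferroni_threshold`, `flags`, and a per-set `table` data frame
#'   (set_name, p_a, p_b, component, in_core, significant_bonferroni).
#' @export
extract_core <- function(fit, profile_a, profile_b, alpha = 0.05,
                         transform = c("exp", "identity", "neglog10")) {
  transform <- match.arg(transform)
  stopifnot(inherits(fit, "MMRFit"),
            inherits(profile_a, "SemanticProfile"),
            inherits(profile_b, "SemanticProfile"))
  n <- length(profile_a$pvalues)
  if (length(fit$assignments) != n)
    stop("fit and profiles disagree on the number of gene sets")
  set_names <- names(profile_a$pvalues)
  x <- transform_profile(profile_a, transform)
  y <- transform_profile(profile_b, transform)
  flags <- fit$flags

  if ("degenerate_single_line" %in% fit$flags) {
    core_idx <- seq_len(n)
    rest_idx <- integer(0)
    core_component <- 1L
    core_sim <- .pcc(x, y)
    rest_sim <- list(value = NA_real_, flags = "empty_component")
    flags <- c(flags, "rest_empty")
  } else {
    idx <- split(seq_len(n), factor(fit$assignments, levels = 1:2))
    sims <- lapply(idx, function(i) {
      if (length(i) < 2L) list(value = -Inf, flags = "too_few_members")
      else .pcc(x[i], y[i])
    })
    sizes <- lengths(idx)
    if (any(sizes < 3L)) {
      # a component this small cannot anchor a correlation: the other is core
      core_component <- which.max(sizes)
      flags <- c(flags, "small_component")
    } else {
      core_component <- which.max(vapply(sims, `[[`, numeric(1), "value"))
    }
    core_idx <- idx[[core_component]]
    rest_idx <- idx[[3L - core_component]]
    core_sim <- sims[[core_component]]
    rest_sim <- sims[[3L - core_component]]
  }

  thr <- bonferroni_threshold(alpha, n)
  sig <- (profile_a$pvalues <= thr) | (profile_b$pvalues <= thr)
  tab <- data.frame(set_name = set_names,
                    p_a = unname(profile_a$pvalues),
                    p_b = unname(profile_b$pvalues),
                    component = fit$assignments,
                    in_core = seq_len(n) %in% core_idx,
                    significant_bonferroni = unname(sig),
                    stringsAsFactors = FALSE)
  structure(list(core_set_names = set_names[core_idx],
                 rest_set_names = set_names[rest_idx],
                 core_gs_sim = core_sim$value,
                 rest_gs_sim = rest_sim$value,
                 core_component = core_component,
                 significance_labels = setNames(sig[core_idx],
                                                set_names[core_idx]),
                 bonferroni_threshold = thr,
                 transform = transform,
                 flags = unique(c(flags, core_sim$flags, rest_sim$flags)),
                 table = tab),
            class = "CoreSubsetResult")
}

#' @export
print.CoreSubsetResult <- function(x, ...) {
  cat("Core subset: ", length(x$core_set_names), " of ",
      nrow(x$table), " gene sets (component ", x$core_component, ")\n",
      "  core GS.sim = ", format(x$core_gs_sim, digits = 4),
      ", rest GS.sim = ", format(x$rest_gs_sim, digits = 4), "\n",
      "  Bonferroni threshold = ", format(x$bonferroni_threshold, digits = 3),
      "; ", sum(x$significance_labels), " core member(s) significant\n",
      sep = "")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  invisible(x)
}
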
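# Independent oracles and fixture builders shared across the suite.
# Each oracle recomputes a quantity by the most direct route available
# (enumeration, textbook formula, hand BFS) without touching the package
# code path it checks.

# Exhaustive hypergeometric upper tail P(X >= k): direct summation of
# C(K, x) C(N-K, n-x) / C(N, n).
hyper_tail_oracle <- function(N, K, n, k) {
  xs <- seq(k, min(K, n))
  if (length(xs) == 0L || k <= 0L) return(1)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Hand-rolled BFS shortest-path distances from one node over an adjacency
# list (list of integer neighbour vectors). Inf where unreachable.
bfs_dist <- function(adj, start) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[start] <- 0
  frontier <- start
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (v in frontier) for (w in adj[[v]]) if (is.infinite(d[w])) {
      d[w] <- d[v] + 1
      nxt <- c(nxt, w)
    }
    frontier <- unique(nxt)
  }
  d
}

# Brute-force separation score on a node-named edge matrix, applying the
# stated convention (nearest counterpart, shared genes at 0, singleton
# within-distance 0, unreachable dropped) from first principles.
sab_oracle <- function(genes_a, genes_b, nodes, edges) {
  adj <- lapply(seq_along(nodes), function(i) integer(0))
  for (r in seq_len(nrow(edges))) {
    i <- match(edges[r, 1], nodes); j <- match(edges[r, 2], nodes)
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  D <- t(vapply(seq_along(nodes), function(i) bfs_dist(adj, i),
                numeric(length(nodes))))
  ia <- match(intersect(genes_a, nodes), nodes)
  ib <- match(intersect(genes_b, nodes), nodes)
  nearest <- function(from, to, excl_self = FALSE) {
    vapply(from, function(i) {
      t2 <- if (excl_self) setdiff(to, i) else to
      if (length(t2) == 0L) 0 else min(D[i, t2])
    }, numeric(1))
  }
  fin_mean <- function(v, empty = 0)
    if (any(is.finite(v))) mean(v[is.finite(v)]) else empty
  cross <- c(nearest(ia, ib), nearest(ib, ia))
  d_ab <- fin_mean(cross, NA_real_)
  d_aa <- fin_mean(nearest(ia, ia, TRUE))
  d_bb <- fin_mean(nearest(ib, ib, TRUE))
  list(d_ab = d_ab, d_aa = d_aa, d_bb = d_bb,
       s_ab = d_ab - (d_aa + d_bb) / 2)
}

# O(pos x neg) AUC by enumerating every positive-negative pair,
# half-credit for ties.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Textbook Pearson chi-square on a 2x2 table, no continuity correction.
chisq_oracle <- function(n11, n10, n01, n00) {
  O <- matrix(c(n11, n10, n01, n00), 2, 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stats::pchisq(sum((O - E)^2 / E), df = 1, lower.tail = FALSE)
}

# --- fixture builders ------------------------------------------------------

# Tiny deterministic collection: n_sets sets over a synthetic universe.
tiny_collection <- function(n_sets = 4L, universe_size = 40L, seed = 42L) {
  withr::with_seed(seed, {
    u <- sprintf("U%03d", seq_len(universe_size))
    sets <- lapply(seq_len(n_sets), function(i)
      gene_set(paste0("S", i), sample(u, 8)))
    gene_set_collection(sets, universe = u, collection_id = "tiny")
  })
}

write_tmp_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Two-line mixture benchmark: slopes 1.0 and -0.5 (intercept 2), sd 0.05.
two_line_data <- function(n = 200L, sigma = 0.05, seed = 1L) {
  withr::with_seed(seed, {
    x <- runif(n, 0, 2)
    lab <- rep(1:2, length.out = n)
    y <- ifelse(lab == 1, 1.0 * x, -0.5 * x + 2) + rnorm(n, 0, sigma)
    list(x = x, y = y, labels = lab)
  })
}

# A disease whose genes come from a handful of planted functional sets.
planted_disease <- function(collection, n_drivers = 5L, n_genes = 60L,
                            seed = 1L, id = "planted") {
  withr::with_seed(seed, {
    drivers <- sample(names(collection$sets), n_drivers)
    pool <- unique(unlist(lapply(collection$sets[drivers], `[[`, "genes")))
    disease_gene_set(id, sample(pool, min(n_genes, length(pool))))
  })
}

# Paired p-value profiles with a planted correlated cluster: the first
# n_core sets share (nearly) identical log10 p-values across the two
# diseases, the rest are independent.
planted_profiles <- function(n_core = 120L, n_rest = 80L, seed = 1L,
                             noise = 0.05) {
  withr::with_seed(seed, {
    n <- n_core + n_rest
    la <- c(runif(n_core, -12, -1), runif(n_rest, -12, -1))
    lb <- c(la[seq_len(n_core)] + rnorm(n_core, 0, noise),
            runif(n_rest, -12, -1))
    nm <- sprintf("GS%04d", seq_len(n))
    list(a = as_semantic_profile(setNames(10^la, nm), "planted", "A"),
         b = as_semantic_profile(setNames(pmin(10^lb, 1), nm), "planted", "B"),
         core = seq_len(n_core))
  })
}
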
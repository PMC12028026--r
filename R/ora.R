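## Over-representation analysis: one-sided Fisher (hypergeometric tail)
## p-values of a disease gene list against every set of a functional
## collection, giving the disease's semantic profiling vector.

.TRANSFORMS <- c("exp", "identity", "neglog10")

#' One-sided Fisher over-representation p-value
#'
#' Upper hypergeometric tail `P(X >= k)` for the 2x2 table
#' (in-list / not-in-list) x (in-set / not-in-set), i.e. the one-sided
#' Fisher exact test for over-representation. Computed in log space so the
#' result is never an exact zero (floor `1e-320`). Depletion is never
#' rewarded: `k = 0` gives p = 1.
#'
#' @param list_genes Character vector: the query gene list (already
#'   restricted to the universe).
#' @param functional_set Character vector: the functional gene set.
#' @param universe Character vector: the background population.
#' @return p-value in `(0, 1]`, with attribute `degenerate = TRUE` when the
#'   list or set is empty (p = 1 in that case).
#' @export
fisher_ora_p <- function(list_genes, functional_set, universe) {
  N <- length(universe)
  if (N == 0L) stop("empty universe")
  n <- length(list_genes)
  K <- length(functional_set)
  if (n == 0L || K == 0L)
    return(structure(1.0, degenerate = TRUE))
  k <- length(intersect(list_genes, functional_set))
  if (k == 0L) return(1.0)
  # P(X >= k) = 1 - P(X <= k-1); log-space tail keeps tiny p-values exact
  logp <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  max(exp(logp), .P_FLOOR)
}

#' Semantic profile of a disease gene list
#'
#' One raw over-representation p-value per functional gene set, in
#' collection order. This ordered vector is the disease's semantic
#' profiling vector; two profiles built on the same collection are
#' index-aligned and comparable.
#'
#' @param disease A [disease_gene_set()].
#' @param collection A [gene_set_collection()].
#' @return An object of class `SemanticProfile`: list with `collection_id`,
#'   `disease_id`, `pvalues` (named numeric, collection order),
#'   `n_genes_tested`, `degenerate` (logical vector per set).
#' @export
semantic_profile <- function(disease, collection) {
  stopifnot(inherits(disease, "DiseaseGeneSet"),
            inherits(collection, "GeneSetCollection"))
  disease <- filter_to_universe(disease, collection$universe)
  res <- lapply(collection$sets, function(s)
    fisher_ora_p(disease$genes, s$genes, collection$universe))
  p <- vapply(res, as.numeric, numeric(1))
  degen <- vapply(res, function(r) isTRUE(attr(r, "degenerate")), logical(1))
  structure(list(collection_id = collection$collection_id,
                 disease_id = disease$disease_id,
                 pvalues = p,
                 n_genes_tested = length(disease$genes),
                 degenerate = degen),
            class = "SemanticProfile")
}

#' Build a semantic profile from precomputed p-values
#'
#' Wraps an existing vector of over-representation p-values (e.g. imported
#' from another tool) in a `SemanticProfile` so it can be scored with
#' [gs_sim()] or decomposed with [mmr_fit()]/[extract_core()]. The names
#' and order of the vector define the profile index.
#'
#' @param pvalues Named numeric vector of raw p-values in `(0, 1]`.
#' @param collection_id Identifier of the collection the p-values were
#'   computed on; profiles are only comparable within one collection.
#' @param disease_id Disease identifier.
#' @return A `SemanticProfile`.
#' @export
as_semantic_profile <- function(pvalues, collection_id, disease_id) {
  pvalues <- setNames(as.numeric(pvalues), names(pvalues))
  if (anyNA(pvalues) || any(pvalues <= 0) || any(pvalues > 1))
    stop("pvalues must lie in (0, 1]")
  if (is.null(names(pvalues)))
    names(pvalues) <- paste0("set", seq_along(pvalues))
  structure(list(collection_id = collection_id, disease_id = disease_id,
                 pvalues = pvalues, n_genes_tested = NA_integer_,
                 degenerate = rep(FALSE, length(pvalues))),
            class = "SemanticProfile")
}

#' @export
print.SemanticProfile <- function(x, ...) {
  cat("SemanticProfile: disease '", x$disease_id, "' vs collection '",
      x$collection_id, "' (", length(x$pvalues), " sets, ",
      x$n_genes_tested, " genes tested)\n", sep = "")
  cat("  min p = ", format(min(x$pvalues), digits = 3),
      ", median p = ", format(stats::median(x$pvalues), digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Transform a profile's p-value vector
#'
#' The similarity score is a correlation of transformed p-value vectors.
#' Three conventions are supported and the choice is always recorded
#' downstream: `exp` (elementwise `exp(p)`, the default), `identity`
#' (raw p), and `neglog10` (`-log10(p)` with p floored at `1e-320`;
#' recommended when p-values span many orders of magnitude). All three are
#' strictly monotone, so profile rank order is transform-invariant.
#'
#' @param profile A `SemanticProfile`, or a bare numeric p-value vector.
#' @param mode One of `"exp"`, `"identity"`, `"neglog10"`.
#' @return Named numeric vector of transformed values, same length/order.
#' @export
transform_profile <- function(profile, mode = c("exp", "identity", "neglog10")) {
  mode <- match.arg(mode)
  p <- if (inherits(profile, "SemanticProfile")) profile$pvalues else profile
  if (!is.numeric(p)) stop("profile must be a SemanticProfile or numeric")
  switch(mode,
         exp = exp(p),
         identity = p,
         neglog10 = -log10(pmax(p, .P_FLOOR)))
}
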
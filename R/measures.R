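## Comorbidity measures for a disease pair: the profile-correlation score
## GS.sim, the overlap-based Jaccard index and overlap coefficient, and the
## network-separation score Sab on a PPI graph.

.comorbidity_score <- function(a, b, measure, value, flags = character(0)) {
  structure(list(disease_a = a, disease_b = b, measure = measure,
                 value = value, flags = flags),
            class = "ComorbidityScore")
}

#' @export
print.ComorbidityScore <- function(x, ...) {
  cat(x$measure, "(", x$disease_a, ", ", x$disease_b, ") = ",
      format(x$value, digits = 4), sep = "")
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ","), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Gene-set-based similarity score (GS.sim)
#'
#' Pearson correlation of the two transformed semantic profiling vectors:
#' \deqn{GS.sim = \frac{\sum_i (P_{A,i}-\bar P_A)(P_{B,i}-\bar P_B)}
#'   {\sqrt{\sum_i (P_{A,i}-\bar P_A)^2}\sqrt{\sum_i (P_{B,i}-\bar P_B)^2}}}
#' where the sum runs over the `n` functional gene sets of the shared
#' collection. Higher positive values indicate greater comorbidity. If
#' either transformed vector has zero variance the score is defined as 0
#' and flagged `zero_variance` (a constant profile carries no similarity
#' evidence, and the pipeline must still rank the pair).
#'
#' @param profile_a,profile_b `SemanticProfile` objects built on the same
#'   collection (same id, length and set order).
#' @param transform Transform applied to both p-value vectors before the
#'   correlation; see [transform_profile()].
#' @return A `ComorbidityScore` (measure `"gs_sim"`); `$value` in
#'   `[-1, 1]`, attribute-free direct-summation computation.
#' @export
gs_sim <- function(profile_a, profile_b,
                   transform = c("exp", "identity", "neglog10")) {
  transform <- match.arg(transform)
  stopifnot(inherits(profile_a, "SemanticProfile"),
            inherits(profile_b, "SemanticProfile"))
  if (!identical(profile_a$collection_id, profile_b$collection_id) ||
      length(profile_a$pvalues) != length(profile_b$pvalues) ||
      !identical(names(profile_a$pvalues), names(profile_b$pvalues)))
    stop("profiles were not built on the same collection")
  x <- transform_profile(profile_a, transform)
  y <- transform_profile(profile_b, transform)
  res <- .pcc(x, y)
  sc <- .comorbidity_score(profile_a$disease_id, profile_b$disease_id,
                           "gs_sim", res$value, res$flags)
  sc$transform <- transform
  sc
}

# Direct-summation Pearson correlation; zero-variance convention 0 + flag.
.pcc <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx * dx)
  syy <- sum(dy * dy)
  if (sxx == 0 || syy == 0)
    return(list(value = 0, flags = "zero_variance"))
  r <- sum(dx * dy) / (sqrt(sxx) * sqrt(syy))
  list(value = min(1, max(-1, r)), flags = character(0))
}

#' Overlap-based similarity of two gene sets
#'
#' `jaccard_index` is `|A intersect B| / |A union B|`; `overlap_coefficient`
#' is `|A intersect B| / min(|A|, |B|)`. Both are 0 whenever the sets share
#' no genes, which is what makes them blind to comorbid pairs with disjoint
#' gene lists.
#'
#' @param a,b Character vectors of gene symbols, or `DiseaseGeneSet`s.
#' @return Numeric score in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- .as_gene_vector(a); b <- .as_gene_vector(b)
  if (length(a) == 0L && length(b) == 0L) stop("both gene sets are empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' @rdname jaccard_index
#' @export
overlap_coefficient <- function(a, b) {
  a <- .as_gene_vector(a); b <- .as_gene_vector(b)
  if (length(a) == 0L || length(b) == 0L) stop("both gene sets must be non-empty")
  length(intersect(a, b)) / min(length(a), length(b))
}

.as_gene_vector <- function(x) {
  if (inherits(x, "DiseaseGeneSet")) x$genes
  else if (inherits(x, "GeneSet")) x$genes
  else .normalize_genes(x)
}

#' Network separation of two disease modules (Sab)
#'
#' Separation of disease gene sets A and B on a protein-protein interaction
#' network:
#' \deqn{S_{AB} = d_{AB} - \frac{d_{AA} + d_{BB}}{2}}
#' `d_AB` is the mean, over every mapped gene of both sets, of the
#' shortest-path (hop) distance to the nearest mapped gene of the other
#' set; a gene carried by both diseases contributes distance 0. `d_AA` and
#' `d_BB` are the mean distance from each mapped gene of a set to its
#' nearest other gene of the same set; a singleton set has within-distance
#' 0 by convention. Genes absent from the network, or unreachable from
#' every counterpart, are dropped from the relevant mean and counted
#' (`n_dropped_a`, `n_dropped_b`) rather than contributing infinity, so
#' the score stays finite on a fragmented network. Negative values mean
#' the two disease modules overlap topologically.
#'
#' @param a,b Gene sets (character vectors or `DiseaseGeneSet`s).
#' @param net An undirected `igraph` PPI network, e.g. from
#'   [read_edge_list()].
#' @return An object of class `SabResult`: list with `d_ab`, `d_aa`,
#'   `d_bb`, `s_ab`, `n_dropped_a`, `n_dropped_b`, `disease_a`, `disease_b`.
#' @export
sab <- function(a, b, net) {
  id_a <- if (inherits(a, "DiseaseGeneSet")) a$disease_id else "A"
  id_b <- if (inherits(b, "DiseaseGeneSet")) b$disease_id else "B"
  ga <- .as_gene_vector(a)
  gb <- .as_gene_vector(b)
  nodes <- igraph::V(net)$name
  ma <- intersect(ga, nodes)
  mb <- intersect(gb, nodes)
  if (length(ma) == 0L || length(mb) == 0L)
    stop("unmapped disease: no genes of '",
         if (length(ma) == 0L) id_a else id_b, "' are in the network")
  dropped_a <- length(ga) - length(ma)
  dropped_b <- length(gb) - length(mb)

  D <- igraph::distances(net, v = union(ma, mb), to = union(ma, mb))

  # nearest-counterpart distance for each gene of `from` into `to`;
  # distance 0 when the gene itself belongs to `to`; Inf (unreachable)
  # entries are dropped and counted
  nearest <- function(from, to, exclude_self = FALSE) {
    vapply(from, function(g) {
      targets <- if (exclude_self) setdiff(to, g) else to
      if (length(targets) == 0L) return(0)   # singleton-set convention
      min(D[g, targets])
    }, numeric(1))
  }

  cross <- c(nearest(ma, mb), nearest(mb, ma))
  within_a <- nearest(ma, ma, exclude_self = TRUE)
  within_b <- nearest(mb, mb, exclude_self = TRUE)

  # a gene counts as dropped once: absent from the graph, or with no
  # finite distance to any counterpart
  n_unreach <- c(a = sum(is.infinite(cross[seq_along(ma)])),
                 b = sum(is.infinite(cross[length(ma) + seq_along(mb)])))
  d_ab <- mean(cross[is.finite(cross)])
  d_aa <- if (any(is.finite(within_a))) mean(within_a[is.finite(within_a)]) else 0
  d_bb <- if (any(is.finite(within_b))) mean(within_b[is.finite(within_b)]) else 0
  if (is.nan(d_ab))
    stop("unmapped disease: no finite cross-set distance between '",
         id_a, "' and '", id_b, "'")
  structure(list(d_ab = d_ab, d_aa = d_aa, d_bb = d_bb,
                 s_ab = d_ab - (d_aa + d_bb) / 2,
                 n_dropped_a = dropped_a + unname(n_unreach["a"]),
                 n_dropped_b = dropped_b + unname(n_unreach["b"]),
                 disease_a = id_a, disease_b = id_b),
            class = "SabResult")
}

#' @export
print.SabResult <- function(x, ...) {
  cat("Sab(", x$disease_a, ", ", x$disease_b, ") = ",
      format(x$s_ab, digits = 4),
      "  (d_ab=", format(x$d_ab, digits = 4),
      ", d_aa=", format(x$d_aa, digits = 4),
      ", d_bb=", format(x$d_bb, digits = 4),
      "; dropped ", x$n_dropped_a, "+", x$n_dropped_b, ")\n", sep = "")
  invisible(x)
}

#' Score a disease pair with selected measures
#'
#' Convenience wrapper computing any subset of the four measures for one
#' pair, returning a long-format data frame.
#'
#' @param disease_a,disease_b `DiseaseGeneSet`s.
#' @param collection `GeneSetCollection` (needed for `gs_sim`).
#' @param net `igraph` PPI network (needed for `sab`).
#' @param measures Character subset of
#'   `c("gs_sim", "jaccard", "oc", "sab")`.
#' @param transform Transform for `gs_sim`.
#' @return Data frame with columns `disease_a`, `disease_b`, `measure`,
#'   `value`, `flags`.
#' @export
score_pair <- function(disease_a, disease_b, collection = NULL, net = NULL,
                       measures = c("gs_sim", "jaccard", "oc", "sab"),
                       transform = "exp") {
  measures <- match.arg(measures, several.ok = TRUE)
  rows <- lapply(measures, function(m) {
    val <- NA_real_; flags <- character(0)
    if (m == "gs_sim") {
      if (is.null(collection)) stop("gs_sim requires a collection")
      sc <- gs_sim(semantic_profile(disease_a, collection),
                   semantic_profile(disease_b, collection),
                   transform = transform)
      val <- sc$value; flags <- sc$flags
    } else if (m == "jaccard") {
      val <- jaccard_index(disease_a, disease_b)
    } else if (m == "oc") {
      val <- overlap_coefficient(disease_a, disease_b)
    } else if (m == "sab") {
      if (is.null(net)) stop("sab requires a PPI network")
      val <- tryCatch(sab(disease_a, disease_b, net)$s_ab,
                      error = function(e) { flags <<- "unmapped"; NA_real_ })
    }
    data.frame(disease_a = disease_a$disease_id,
               disease_b = disease_b$disease_id,
               measure = m, value = val,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score all unordered pairs of a disease table
#'
#' Enumerates every unordered pair of the supplied diseases in
#' lexicographic id order (deterministic output order) and applies
#' [score_pair()].
#'
#' @param diseases Named list of `DiseaseGeneSet`s.
#' @inheritParams score_pair
#' @return Long-format data frame, one row per pair x measure.
#' @export
score_all <- function(diseases, collection = NULL, net = NULL,
                      measures = c("gs_sim", "jaccard", "oc"),
                      transform = "exp") {
  ids <- sort(vapply(diseases, `[[`, character(1), "disease_id"))
  diseases <- diseases[order(vapply(diseases, `[[`, character(1),
                                    "disease_id"))]
  if (length(ids) < 2L) stop("need at least two diseases")
  # profiles are reused across pairs
  profiles <- NULL
  if ("gs_sim" %in% measures) {
    if (is.null(collection)) stop("gs_sim requires a collection")
    profiles <- lapply(diseases, semantic_profile, collection = collection)
  }
  rows <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq(i + 1L, length(ids))) {
      for (m in measures) {
        val <- NA_real_; flags <- character(0)
        if (m == "gs_sim") {
          sc <- gs_sim(profiles[[i]], profiles[[j]], transform = transform)
          val <- sc$value; flags <- sc$flags
        } else if (m == "jaccard") {
          val <- jaccard_index(diseases[[i]], diseases[[j]])
        } else if (m == "oc") {
          val <- overlap_coefficient(diseases[[i]], diseases[[j]])
        } else if (m == "sab") {
          val <- tryCatch(sab(diseases[[i]], diseases[[j]], net)$s_ab,
                          error = function(e) NA_real_)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(disease_a = ids[i], disease_b = ids[j], measure = m,
                     value = val, flags = paste(flags, collapse = ";"),
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
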
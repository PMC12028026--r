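## Synthetic fixtures: gene universes, functional collections, disease
## pairs with planted pathway coherence (with or without shared genes),
## and patient cohorts with planted relative risks. These emulate the
## statistical shape of curated disease-gene resources and
## claims-database diagnosis matrices; they make no attempt to mimic GO's
## DAG structure or gene-set nesting.

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic-data specification
#'
#' Parameters of the synthetic universe, functional collection, disease
#' pairs and cohort. Defaults give a 2000-gene universe with 50 functional
#' sets of 20-60 genes, diseases built from 5 driver sets with 10%
#' background genes, and a 50,000-sample cohort with 10% baseline
#' prevalences.
#'
#' @param universe_size Number of genes in the universe.
#' @param n_functional_sets Number of functional gene sets.
#' @param set_size_range Length-2 integer range of set sizes.
#' @param n_driver_sets Functional sets driving each synthetic disease.
#' @param background_fraction Fraction of disease genes drawn outside the
#'   driver sets, in `[0, 1)`.
#' @param disease_size_range Length-2 range of disease gene-set sizes.
#' @param pair_design One of `"shared_drivers_overlapping_genes"`,
#'   `"shared_drivers_disjoint_genes"`, `"independent"`.
#' @param overlap_fraction Under the overlapping design, fraction of the
#'   second disease's driver genes copied from the first.
#' @param n_samples Cohort size.
#' @param prevalence_a,prevalence_b Baseline disease prevalences.
#' @param target_rr Planted relative risk for comorbid pairs (>= 1).
#' @param seed Integer seed.
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(universe_size = 2000L, n_functional_sets = 50L,
                           set_size_range = c(20L, 60L),
                           n_driver_sets = 5L,
                           background_fraction = 0.1,
                           disease_size_range = c(30L, 300L),
                           pair_design = c("shared_drivers_disjoint_genes",
                                           "shared_drivers_overlapping_genes",
                                           "independent"),
                           overlap_fraction = 0.5,
                           n_samples = 50000L,
                           prevalence_a = 0.1, prevalence_b = 0.1,
                           target_rr = 5, seed = 1L) {
  pair_design <- match.arg(pair_design)
  stopifnot(universe_size > 0, n_functional_sets > 0,
            length(set_size_range) == 2L, all(set_size_range > 0),
            background_fraction >= 0, background_fraction < 1,
            target_rr >= 1,
            prevalence_a > 0, prevalence_a < 1,
            prevalence_b > 0, prevalence_b < 1)
  if (set_size_range[2] > universe_size)
    stop("set_size_range exceeds the universe size")
  structure(list(universe_size = as.integer(universe_size),
                 n_functional_sets = as.integer(n_functional_sets),
                 set_size_range = as.integer(set_size_range),
                 n_driver_sets = as.integer(n_driver_sets),
                 background_fraction = background_fraction,
                 disease_size_range = as.integer(disease_size_range),
                 pair_design = pair_design,
                 overlap_fraction = overlap_fraction,
                 n_samples = as.integer(n_samples),
                 prevalence_a = prevalence_a, prevalence_b = prevalence_b,
                 target_rr = target_rr, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic functional gene-set collection
#'
#' Universe genes are `G00001, ...`; each functional set samples its
#' members without replacement from the universe, with sizes uniform in
#' `set_size_range`. Bit-reproducible under `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A `GeneSetCollection`.
#' @export
make_collection <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  .with_seed(spec$seed, {
    universe <- sprintf("G%05d", seq_len(spec$universe_size))
    sizes <- sample(seq(spec$set_size_range[1], spec$set_size_range[2]),
                    spec$n_functional_sets, replace = TRUE)
    sets <- lapply(seq_len(spec$n_functional_sets), function(i)
      gene_set(sprintf("FS%04d", i), sample(universe, sizes[i]),
               description = "synthetic"))
    gene_set_collection(sets, universe = universe,
                        collection_id = "synthetic_collection")
  })
}

#' Generate a synthetic disease pair
#'
#' Each disease draws `1 - background_fraction` of its genes from the
#' union of its driver functional sets and the rest from outside them.
#' Under `shared_drivers_disjoint_genes` both diseases use the same
#' drivers but the sampled genes are partitioned so the two gene lists
#' share no gene at all (the comorbid-without-overlap scenario); under
#' `shared_drivers_overlapping_genes` a planted fraction of driver genes
#' is copied between the lists; under `independent` the drivers are
#' sampled disjointly.
#'
#' @param spec A [synthetic_spec()].
#' @param collection Collection from [make_collection()].
#' @param ids Length-2 character vector of disease ids.
#' @param seed Seed for this pair (default `spec$seed`).
#' @return List with `a`, `b` (`DiseaseGeneSet`s) and `truth`
#'   (design, driver set names per disease).
#' @export
make_disease_pair <- function(spec, collection, ids = c("DA", "DB"),
                              seed = spec$seed) {
  stopifnot(inherits(spec, "SyntheticSpec"),
            inherits(collection, "GeneSetCollection"))
  .with_seed(seed, {
    set_names <- names(collection$sets)
    universe <- collection$universe
    drivers_a <- sample(set_names, spec$n_driver_sets)
    drivers_b <- switch(spec$pair_design,
      shared_drivers_disjoint_genes = drivers_a,
      shared_drivers_overlapping_genes = drivers_a,
      independent = sample(setdiff(set_names, drivers_a),
                           spec$n_driver_sets))
    pool_a <- unique(unlist(lapply(collection$sets[drivers_a], `[[`, "genes")))
    pool_b <- unique(unlist(lapply(collection$sets[drivers_b], `[[`, "genes")))
    sizes <- sample(seq(spec$disease_size_range[1],
                        spec$disease_size_range[2]), 2, replace = TRUE)

    draw <- function(size, pool, background_pool) {
      n_drv <- round((1 - spec$background_fraction) * size)
      n_bg <- size - n_drv
      if (n_drv > length(pool))
        stop("driver sets too small to supply ", n_drv, " genes")
      if (n_bg > length(background_pool))
        stop("background pool too small")
      c(sample(pool, n_drv), sample(background_pool, n_bg))
    }

    genes_a <- draw(sizes[1], pool_a, setdiff(universe, pool_a))
    if (spec$pair_design == "shared_drivers_disjoint_genes") {
      genes_b <- draw(sizes[2], setdiff(pool_b, genes_a),
                      setdiff(universe, union(pool_b, genes_a)))
    } else if (spec$pair_design == "shared_drivers_overlapping_genes") {
      n_drv_b <- round((1 - spec$background_fraction) * sizes[2])
      n_shared <- min(round(spec$overlap_fraction * n_drv_b),
                      sum(genes_a %in% pool_b))
      shared <- sample(genes_a[genes_a %in% pool_b], n_shared)
      fresh <- draw(sizes[2] - n_shared, setdiff(pool_b, shared),
                    setdiff(universe, pool_b))
      genes_b <- c(shared, fresh)
    } else {
      genes_b <- draw(sizes[2], pool_b, setdiff(universe, pool_b))
    }
    list(a = disease_gene_set(ids[1], genes_a),
         b = disease_gene_set(ids[2], genes_b),
         truth = list(design = spec$pair_design,
                      drivers_a = drivers_a, drivers_b = drivers_b))
  })
}

#' Generate a cohort with planted relative risks
#'
#' For every pair, disease A is drawn Bernoulli at its baseline
#' prevalence `p_a`; disease B is drawn with
#' `P(B | A = 1) = r q` and `P(B | A = 0) = q` where
#' `q = p_b / (p_a r + 1 - p_a)`, which plants relative risk `r` while
#' preserving B's marginal prevalence `p_b`. `r = 1` gives independent
#' diseases.
#'
#' @param spec A [synthetic_spec()]; supplies `n_samples` and default
#'   prevalences.
#' @param pair_labels Data frame with columns `disease_a`, `disease_b`,
#'   `target_rr` and optionally `prevalence_a`, `prevalence_b`.
#' @param seed Seed (default `spec$seed`).
#' @return A `CohortTable` with two columns per pair.
#' @export
make_cohort <- function(spec, pair_labels, seed = spec$seed) {
  stopifnot(inherits(spec, "SyntheticSpec"), is.data.frame(pair_labels))
  .with_seed(seed, {
    n <- spec$n_samples
    cols <- list()
    for (i in seq_len(nrow(pair_labels))) {
      pl <- pair_labels[i, ]
      p_a <- if ("prevalence_a" %in% names(pl)) pl$prevalence_a else spec$prevalence_a
      p_b <- if ("prevalence_b" %in% names(pl)) pl$prevalence_b else spec$prevalence_b
      r <- pl$target_rr
      if (r < 1) stop("target_rr must be >= 1")
      q <- p_b / (p_a * r + 1 - p_a)
      if (r * q > 1)
        stop("infeasible RR: P(B|A) = ", r * q, " > 1 for pair ",
             pl$disease_a, "/", pl$disease_b)
      a <- rbinom(n, 1L, p_a)
      b <- rbinom(n, 1L, ifelse(a == 1L, r * q, q))
      cols[[pl$disease_a]] <- a
      cols[[pl$disease_b]] <- b
    }
    m <- do.call(cbind, cols)
    colnames(m) <- names(cols)
    rownames(m) <- sprintf("S%06d", seq_len(n))
    cohort_table(m)
  })
}

#' Generate the comorbidity benchmark
#'
#' A seeded benchmark of disease pairs in which no pair shares a single
#' gene: comorbid pairs follow the `shared_drivers_disjoint_genes` design
#' (same driver pathways, disjoint gene lists), non-comorbid pairs use
#' independent drivers with gene disjointness enforced the same way.
#' Overlap-based similarity is therefore identically zero on every pair,
#' while profile similarity still separates the classes.
#'
#' @param spec A [synthetic_spec()]; `disease_size_range` is the size
#'   range of each benchmark disease.
#' @param n_pairs Total number of disease pairs (default 60).
#' @param n_comorbid Number of comorbid pairs (default 20).
#' @return List with `collection`, `pairs` (list of
#'   [make_disease_pair()] results), `labels` (data frame `disease_a`,
#'   `disease_b`, `comorbid`), `spec`.
#' @export
make_benchmark <- function(spec = NULL, n_pairs = 60L, n_comorbid = 20L) {
  if (is.null(spec))
    spec <- synthetic_spec(disease_size_range = c(30L, 50L))
  stopifnot(inherits(spec, "SyntheticSpec"), n_comorbid <= n_pairs)
  collection <- make_collection(spec)
  spec_pos <- spec; spec_pos$pair_design <- "shared_drivers_disjoint_genes"
  spec_neg <- spec; spec_neg$pair_design <- "independent"
  comorbid <- rep(c(TRUE, FALSE), c(n_comorbid, n_pairs - n_comorbid))
  pairs <- vector("list", n_pairs)
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    ids <- sprintf("D%03d%s", i, c("A", "B"))
    s <- if (comorbid[i]) spec_pos else spec_neg
    pr <- make_disease_pair(s, collection, ids = ids,
                            seed = spec$seed + 1000L + i)
    if (!comorbid[i]) {
      # enforce gene disjointness for negatives too, so overlap-based
      # measures are zero on the whole benchmark
      clash <- pr$b$genes %in% pr$a$genes
      if (any(clash)) {
        avail <- setdiff(collection$universe,
                         union(pr$a$genes, pr$b$genes))
        pr$b$genes <- c(pr$b$genes[!clash],
                        .with_seed(spec$seed + 2000L + i,
                                   sample(avail, sum(clash))))
      }
    }
    pairs[[i]] <- pr
    rows[[i]] <- data.frame(disease_a = ids[1], disease_b = ids[2],
                            comorbid = comorbid[i],
                            design = pr$truth$design,
                            stringsAsFactors = FALSE)
  }
  list(collection = collection, pairs = pairs,
       labels = do.call(rbind, rows), spec = spec)
}

#' Score a benchmark with the comorbidity measures
#'
#' Runs the requested measures on every benchmark pair (each pair is
#' scored between its own two diseases) and returns one wide row per
#' pair, ready for [rank_auc()] / [lr_combine()] against the benchmark
#' labels.
#'
#' @param benchmark Result of [make_benchmark()].
#' @param measures Subset of `c("gs_sim", "jaccard", "oc")`.
#' @param transform Transform for `gs_sim`.
#' @return Data frame: `disease_a`, `disease_b`, `comorbid`, one column
#'   per measure.
#' @export
score_benchmark <- function(benchmark, measures = c("gs_sim", "jaccard", "oc"),
                            transform = "exp") {
  rows <- lapply(seq_along(benchmark$pairs), function(i) {
    pr <- benchmark$pairs[[i]]
    out <- benchmark$labels[i, c("disease_a", "disease_b", "comorbid")]
    if ("gs_sim" %in% measures) {
      sc <- gs_sim(semantic_profile(pr$a, benchmark$collection),
                   semantic_profile(pr$b, benchmark$collection),
                   transform = transform)
      out$gs_sim <- sc$value
    }
    if ("jaccard" %in% measures) out$jaccard <- jaccard_index(pr$a, pr$b)
    if ("oc" %in% measures) out$oc <- overlap_coefficient(pr$a, pr$b)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
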
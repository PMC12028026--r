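## Split-versus-null simulation: split one disease gene set into two
## pseudo-diseases at prefixed ratios and compare the resulting GS.sim
## scores against identically-sized splits of random universe genes.

#' Simulation configuration
#'
#' @param ratios Split fractions in `(0, 0.5]`; each ratio `r` splits an
#'   `m`-gene set into parts of size `round(r * m)` and the remainder.
#'   Default covers the 3:7 to equal-split range.
#' @param reps_per_ratio Replicates per ratio (real and null each).
#' @param seed Integer seed driving all randomness of the run.
#' @param transform Transform used for the GS.sim scores.
#' @return An object of class `SimulationConfig`.
#' @export
simulation_config <- function(ratios = c(0.3, 0.35, 0.4, 0.45, 0.5),
                              reps_per_ratio = 200L, seed = 1L,
                              transform = c("exp", "identity", "neglog10")) {
  transform <- match.arg(transform)
  ratios <- as.numeric(ratios)
  if (any(ratios <= 0 | ratios > 0.5))
    stop("ratios must lie in (0, 0.5]")
  if (reps_per_ratio < 0) stop("reps_per_ratio must be >= 0")
  structure(list(ratios = ratios, reps_per_ratio = as.integer(reps_per_ratio),
                 seed = as.integer(seed), transform = transform),
            class = "SimulationConfig")
}

#' Split a gene set into two pseudo-diseases
#'
#' Uniform random partition into disjoint parts of size `round(ratio * m)`
#' and `m - round(ratio * m)`. Randomness comes from R's global RNG; seed
#' with `set.seed()` for reproducibility.
#'
#' @param genes Character vector (or `DiseaseGeneSet`) with at least 2
#'   genes.
#' @param ratio Fraction in `(0, 0.5]` for the first part.
#' @return List of two character vectors, `part1` and `part2`.
#' @export
split_genes <- function(genes, ratio) {
  genes <- .as_gene_vector(genes)
  m <- length(genes)
  if (m < 2L) stop("need at least 2 genes to split")
  if (ratio <= 0 || ratio > 0.5) stop("ratio must lie in (0, 0.5]")
  n1 <- round(ratio * m)
  if (n1 < 1L || m - n1 < 1L) stop("split sizes must both be >= 1")
  pick <- sample.int(m, n1)
  list(part1 = genes[pick], part2 = genes[-pick])
}

#' Null split: random universe genes of matched size
#'
#' Samples `m` genes uniformly without replacement from the universe, then
#' splits them exactly like [split_genes()]. This is the null counterpart
#' of a real disease split: same sizes, no shared biology.
#'
#' @param universe Character vector of background genes.
#' @param m Number of genes to sample (size of the disease set emulated).
#' @param ratio Split fraction in `(0, 0.5]`.
#' @return List of two character vectors, `part1` and `part2`.
#' @export
null_split <- function(universe, m, ratio) {
  if (m > length(universe))
    stop("cannot sample ", m, " genes from a universe of ", length(universe))
  split_genes(sample(universe, m), ratio)
}

#' Run the split-versus-null simulation
#'
#' For each ratio and replicate, the disease's genes are split into two
#' pseudo-diseases and scored with GS.sim; a matched null replicate does
#' the same with randomly sampled universe genes of the same total size.
#' Real and null replicates of the same index are paired, and a two-sided
#' paired t-test over all matched replicates summarises the separation.
#' Degenerate scores (e.g. a constant profile) are kept and flagged.
#'
#' @param disease A `DiseaseGeneSet`.
#' @param collection A `GeneSetCollection` (its universe is used for the
#'   null sampling unless `universe` is given).
#' @param config A [simulation_config()].
#' @param universe Optional explicit null-sampling universe.
#' @return An object of class `SimulationResult`: `replicates` (data frame
#'   ratio, rep, real_score, null_score, flags), `summary` (per-ratio mean
#'   real/null scores), `t_statistic`, `p_value`, `config`.
#' @export
run_simulation <- function(disease, collection, config = simulation_config(),
                           universe = NULL) {
  stopifnot(inherits(disease, "DiseaseGeneSet"),
            inherits(collection, "GeneSetCollection"),
            inherits(config, "SimulationConfig"))
  if (is.null(universe)) universe <- collection$universe
  disease <- filter_to_universe(disease, collection$universe)
  m <- length(disease$genes)
  if (config$reps_per_ratio == 0L)
    stop("reps_per_ratio is 0: nothing to summarise")

  set.seed(config$seed)
  score_split <- function(parts) {
    flags <- character(0)
    val <- tryCatch({
      pa <- suppressWarnings(semantic_profile(
        disease_gene_set("part1", parts$part1), collection))
      pb <- suppressWarnings(semantic_profile(
        disease_gene_set("part2", parts$part2), collection))
      sc <- gs_sim(pa, pb, transform = config$transform)
      flags <<- sc$flags
      sc$value
    }, error = function(e) {
      flags <<- "degenerate"
      NA_real_
    })
    list(value = val, flags = flags)
  }

  rows <- list()
  for (ratio in config$ratios) {
    for (rep in seq_len(config$reps_per_ratio)) {
      real <- score_split(split_genes(disease$genes, ratio))
      null <- score_split(null_split(universe, m, ratio))
      rows[[length(rows) + 1L]] <- data.frame(
        ratio = ratio, rep = rep,
        real_score = real$value, null_score = null$value,
        flags = paste(unique(c(real$flags, null$flags)), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, rows)

  ok <- is.finite(reps$real_score) & is.finite(reps$null_score)
  tt <- t.test(reps$real_score[ok], reps$null_score[ok], paired = TRUE)
  summ <- do.call(rbind, lapply(split(reps, reps$ratio), function(d)
    data.frame(ratio = d$ratio[1],
               mean_real = mean(d$real_score, na.rm = TRUE),
               mean_null = mean(d$null_score, na.rm = TRUE))))
  rownames(summ) <- NULL
  structure(list(replicates = reps, summary = summ,
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value, config = config,
                 disease_id = disease$disease_id),
            class = "SimulationResult")
}

#' @export
print.SimulationResult <- function(x, ...) {
  cat("Split-vs-null simulation for '", x$disease_id, "' (",
      nrow(x$replicates), " paired replicates)\n", sep = "")
  print(x$summary, row.names = FALSE)
  cat("paired t = ", format(x$t_statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}
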
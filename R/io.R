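## Domain types and file I/O: gene sets (GMT), disease gene lists, PPI edge
## lists, cohort diagnosis matrices and flat mapping tables.
##
## Gene identity is case-insensitive: every symbol is uppercased at ingest,
## so "Tp53" and "TP53" collapse to one gene everywhere downstream.

.normalize_genes <- function(genes) {
  genes <- toupper(trimws(as.character(genes)))
  unique(genes[nzchar(genes)])
}

#' Construct a gene set
#'
#' A named set of gene symbols. Symbols are uppercased and deduplicated;
#' an empty set or empty name is an error.
#'
#' @param name Set identifier (non-empty string).
#' @param genes Character vector of gene symbols.
#' @param description Optional free-text description (GMT field 2).
#' @return An object of class `GeneSet` with elements `name`, `genes`,
#'   `description`.
#' @export
gene_set <- function(name, genes, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene set name must be a non-empty string")
  genes <- .normalize_genes(genes)
  if (length(genes) == 0L)
    stop("gene set '", name, "' has no genes")
  structure(list(name = name, genes = genes, description = description),
            class = "GeneSet")
}

#' Construct a gene-set collection
#'
#' An ordered collection of functional gene sets over a gene universe.
#' The order of the sets defines the index of the semantic profile vector,
#' so it is preserved by all I/O and never re-sorted.
#'
#' @param sets List of [gene_set()] objects (or named list of character
#'   vectors, which are promoted).
#' @param universe Character vector of background gene symbols. Default:
#'   the union of all member genes.
#' @param collection_id Identifier recorded in profiles built from this
#'   collection.
#' @return An object of class `GeneSetCollection` with elements `sets`
#'   (named list, file order), `universe`, `collection_id`.
#' @export
gene_set_collection <- function(sets, universe = NULL,
                                collection_id = "collection") {
  if (length(sets) == 0L) stop("collection has no gene sets")
  if (!all(vapply(sets, inherits, logical(1), "GeneSet"))) {
    nms <- names(sets)
    if (is.null(nms) || any(!nzchar(nms)))
      stop("sets must be GeneSet objects or a fully named list")
    sets <- lapply(seq_along(sets), function(i) gene_set(nms[i], sets[[i]]))
  }
  nms <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate gene set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  member_union <- .normalize_genes(unlist(lapply(sets, `[[`, "genes")))
  if (is.null(universe)) {
    universe <- member_union
  } else {
    universe <- .normalize_genes(universe)
    missing <- setdiff(member_union, universe)
    if (length(missing) > 0L)
      stop(length(missing), " member gene(s) not in the supplied universe, ",
           "e.g. ", paste(head(missing, 3L), collapse = ", "))
  }
  structure(list(sets = sets, universe = universe,
                 collection_id = collection_id),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  sizes <- lengths(lapply(x$sets, `[[`, "genes"))
  cat("GeneSetCollection '", x$collection_id, "': ", length(x$sets),
      " sets (sizes ", min(sizes), "-", max(sizes), "), universe of ",
      length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Construct a disease gene set
#'
#' @param disease_id Disease identifier.
#' @param genes Character vector of gene symbols (uppercased, deduplicated).
#' @return An object of class `DiseaseGeneSet`.
#' @export
disease_gene_set <- function(disease_id, genes) {
  genes <- .normalize_genes(genes)
  if (length(genes) == 0L)
    stop("disease '", disease_id, "' has no genes")
  structure(list(disease_id = as.character(disease_id), genes = genes),
            class = "DiseaseGeneSet")
}

#' Read a GMT gene-set file
#'
#' Tab-separated MSigDB dialect: set name, description, then one gene per
#' field. Within-line duplicate genes collapse (set semantics); duplicate
#' set names are an error. The file order of the sets is kept, because it
#' defines the profile vector index.
#'
#' @param path Path to the GMT file.
#' @param universe Optional character vector overriding the default
#'   universe (union of all member genes).
#' @param collection_id Collection identifier; default: file name.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL, collection_id = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, " in ", path,
           ": expected >= 3 tab-separated fields, got ", length(fields))
    sets[[i]] <- gene_set(fields[1], fields[-(1:2)], description = fields[2])
  }
  if (is.null(collection_id)) collection_id <- basename(path)
  gene_set_collection(sets, universe = universe, collection_id = collection_id)
}

#' Write a collection to GMT
#'
#' @param collection A `GeneSetCollection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(collection$sets, function(s) {
    desc <- if (nzchar(s$description)) s$description else "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a disease gene list
#'
#' Plain text, one gene symbol per line; blank lines and lines starting
#' with `#` are ignored; symbols are uppercased and deduplicated.
#'
#' @param path Path to the list file.
#' @param disease_id Disease identifier; default: file name without
#'   extension.
#' @return A [disease_gene_set()].
#' @export
read_gene_list <- function(path, disease_id = NULL) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no genes in ", path)
  if (is.null(disease_id))
    disease_id <- sub("\\.[^.]*$", "", basename(path))
  disease_gene_set(disease_id, lines)
}

#' @rdname read_gene_list
#' @param disease A `DiseaseGeneSet`.
#' @export
write_gene_list <- function(disease, path) {
  stopifnot(inherits(disease, "DiseaseGeneSet"))
  writeLines(disease$genes, path)
  invisible(path)
}

#' Read a protein-protein interaction network
#'
#' Two whitespace/tab-separated gene symbols per line. The result is an
#' undirected simple [igraph][igraph::graph_from_data_frame] graph:
#' self-loops and duplicate edges are dropped, with counts reported via
#' `message()` and stored in the graph attributes `n_self_loops` /
#' `n_duplicate_edges`.
#'
#' @param path Path to the edge list.
#' @return An undirected simple `igraph` graph (possibly empty).
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  parts <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L)
    stop("malformed edge list line ", bad[1], " in ", path,
         ": expected two columns")
  ends <- t(vapply(parts, function(p) toupper(p[1:2]), character(2)))
  g <- igraph::graph_from_data_frame(as.data.frame(ends), directed = FALSE)
  n_loops <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (n_loops + n_multi > 0L)
    message("read_edge_list: dropped ", n_loops, " self-loop(s) and ",
            n_multi, " duplicate edge(s)")
  g$n_self_loops <- n_loops
  g$n_duplicate_edges <- n_multi
  g
}

#' @rdname read_edge_list
#' @param net An `igraph` graph.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  invisible(path)
}

#' Construct a cohort diagnosis table
#'
#' A binary sample-by-disease indicator matrix (1 = diagnosed).
#'
#' @param matrix Numeric/integer matrix with entries 0/1; rows are samples,
#'   columns are diseases, both named.
#' @return An object of class `CohortTable` (a 0/1 integer matrix with
#'   dimnames).
#' @export
cohort_table <- function(matrix) {
  m <- as.matrix(matrix)
  if (is.null(rownames(m)))
    rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("cohort requires unique disease codes as column names")
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad) > 0L) {
    i <- ((bad[1] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(m)) + 1L
    stop("non-binary cohort cell at sample '", rownames(m)[i],
         "', disease '", colnames(m)[j], "': ", m[bad[1]])
  }
  storage.mode(m) <- "integer"
  structure(m, class = c("CohortTable", "matrix", "array"))
}

#' Read a cohort diagnosis matrix
#'
#' TSV with a header row of disease codes and the sample id in the first
#' column; every cell must be 0 or 1.
#'
#' @param path Path to the TSV file.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("cohort file needs a sample column and >= 1 disease")
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicate disease code in cohort header: ",
         paste(unique(colnames(df)[-1][duplicated(colnames(df)[-1])]),
               collapse = ", "))
  samples <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "numeric")
  if (anyNA(m)) {
    idx <- which(is.na(m))[1]
    stop("non-binary cohort cell at row ", ((idx - 1L) %% nrow(m)) + 1L,
         ", column '", colnames(m)[((idx - 1L) %/% nrow(m)) + 1L], "'")
  }
  rownames(m) <- samples
  cohort_table(m)
}

#' @rdname read_cohort
#' @param cohort A `CohortTable`.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(sample = rownames(cohort),
                   unclass(cohort), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat two-column mapping table
#'
#' Keeps only one-to-one rows: any source or target id that appears more
#' than once is dropped entirely.
#'
#' @param path TSV with two columns (source id, target id); a header is
#'   detected and skipped if the first line repeats no ids.
#' @return Data frame with columns `from`, `to`, one-to-one.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  df <- read.delim(path, header = FALSE, sep = "\t",
                   colClasses = "character")
  if (ncol(df) < 2L) stop("mapping table needs two columns: ", path)
  df <- df[, 1:2]
  names(df) <- c("from", "to")
  keep <- !(df$from %in% df$from[duplicated(df$from)]) &
    !(df$to %in% df$to[duplicated(df$to)])
  df[keep, , drop = FALSE]
}

#' Filter disease genes to a universe
#'
#' Genes absent from the universe cannot enter a Fisher table and are
#' dropped with a warning.
#'
#' @param disease A `DiseaseGeneSet`.
#' @param universe Character vector of background genes.
#' @return The filtered `DiseaseGeneSet`; errors if nothing remains.
#' @export
filter_to_universe <- function(disease, universe) {
  stopifnot(inherits(disease, "DiseaseGeneSet"))
  keep <- disease$genes %in% universe
  if (!all(keep))
    warning("disease '", disease$disease_id, "': dropped ",
            sum(!keep), "/", length(keep), " gene(s) absent from universe",
            call. = FALSE)
  if (!any(keep))
    stop("disease '", disease$disease_id,
         "' has no genes in the universe (no testable genes)")
  disease$genes <- disease$genes[keep]
  disease
}
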
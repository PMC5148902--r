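#' Construct a multi-group expression dataset
#'
#' Bundles a genes x samples numeric matrix (expression on a log-like scale,
#' assumed fully preprocessed) with a group label per sample. This is the
#' input container for all analysis functions.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers, column names sample identifiers; both must be
#'   unique and non-missing.
#' @param groups Group labels: either a character vector named by sample id,
#'   or an unnamed vector aligned with the matrix columns. Every sample must
#'   receive exactly one label.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (the matrix) and `groups` (character vector named by sample id,
#'   in matrix column order).
#' @examples
#' x <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expression_dataset(x, c("A", "A", "B", "B"))
#' group_sizes(ds)
#' @export
expression_dataset <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || anyDuplicated(gid) || any(is.na(gid)) || any(gid == ""))
    stop("row names of 'values' must be unique, non-missing gene ids")
  if (is.null(sid) || anyDuplicated(sid) || any(is.na(sid)) || any(sid == ""))
    stop("column names of 'values' must be unique, non-missing sample ids")
  if (any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values; ",
         "complete matrices are required (no imputation is performed)")
  groups <- as.character(if (is.factor(groups)) as.character(groups) else groups)
  if (!is.null(names(groups)) && !all(names(groups) == "")) {
    miss <- setdiff(sid, names(groups))
    if (length(miss))
      stop("samples missing from the group map: ", paste(miss, collapse = ", "))
    groups <- groups[sid]
  } else {
    if (length(groups) != length(sid))
      stop("'groups' must have one label per sample")
    names(groups) <- sid
  }
  if (any(is.na(groups)))
    stop("every sample must have exactly one group label")
  structure(list(values = values, groups = groups),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  gs <- table(x$groups)
  cat(sprintf("expression_dataset: %d genes x %d samples, %d groups\n",
              nrow(x$values), ncol(x$values), length(gs)))
  cat("  group sizes: ",
      paste(sprintf("%s=%d", names(gs), as.integer(gs)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Group sizes of an expression dataset
#'
#' @param dataset An [expression_dataset()].
#' @return Named integer vector of samples per group.
#' @export
group_sizes <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  tab <- table(dataset$groups)
  stats::setNames(as.integer(tab), names(tab))
}

# column indices of one group's samples
group_index <- function(dataset, group) {
  idx <- which(dataset$groups == group)
  if (!length(idx)) stop("group not present in dataset: ", group)
  idx
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors of gene ids. Names must be
#'   unique; duplicate genes within a set are collapsed; empty sets rejected.
#' @param descriptions Optional character vector of set descriptions, same
#'   length/order as `sets` (defaults to "").
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("'sets' must be a named list of gene id vectors")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(vapply(sets, length, 1L) == 0L))
    stop("gene sets must be non-empty")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets))
    stop("'descriptions' must match 'sets' in length")
  descriptions <- stats::setNames(as.character(descriptions), names(sets))
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- vapply(x$sets, length, 1L)
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d, median %.0f)\n",
              length(sz), if (length(sz)) min(sz) else 0L,
              if (length(sz)) max(sz) else 0L,
              if (length(sz)) stats::median(sz) else 0))
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(x$sets[i], x$descriptions[i])
}

#' Read gene sets in GMT format
#'
#' Standard Broad/MSigDB dialect: one set per line, tab-separated fields
#' `name`, `description`, then one or more gene ids. Duplicate genes within a
#' line are collapsed; duplicate set names and malformed lines are errors.
#'
#' @param path Path to a GMT file. Blank lines are ignored.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep))
    return(structure(list(sets = stats::setNames(list(), character(0)),
                          descriptions = stats::setNames(character(0),
                                                         character(0))),
                     class = "gene_set_collection"))
  sets <- list(); desc <- character(0)
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(f)))
    nm <- f[1]
    if (nm %in% names(sets))
      stop(sprintf("duplicate gene set name at line %d: %s", i, nm))
    sets[[nm]] <- unique(f[-(1:2)])
    desc[nm] <- f[2]
  }
  gene_set_collection(sets, unname(desc[names(sets)]))
}

#' Write gene sets in GMT format
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# delimiter auto-detection: tab is canonical, comma accepted
detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (!length(header)) stop("empty file: ", path)
  nt <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  nc <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (nt >= nc) "\t" else ","
}

#' Read an expression matrix and group map
#'
#' The matrix file is delimited text (tab canonical, comma accepted,
#' auto-detected from the header) with a header row of sample ids and gene
#' ids in the first column. The group map is a two-column file
#' (sample id, group label), no header required; a `sample<TAB>group` header
#' is tolerated. Samples are kept in matrix column order; every matrix sample
#' must appear in the group map (extra map rows are ignored).
#'
#' @param matrix_path Path to the expression matrix.
#' @param groups_path Path to the two-column group map.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, groups_path) {
  delim <- detect_delim(matrix_path)
  raw <- utils::read.table(matrix_path, sep = delim, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  gene_ids <- raw[[1]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in matrix: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  sample_ids <- colnames(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s' (cell \"%s\")",
                 gene_ids[bad[1, 1]], sample_ids[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]))
  dimnames(num) <- list(gene_ids, sample_ids)

  gdelim <- detect_delim(groups_path)
  gmap <- utils::read.table(groups_path, sep = gdelim, header = FALSE,
                            check.names = FALSE, colClasses = "character",
                            quote = "\"", comment.char = "")
  if (ncol(gmap) < 2L) stop("group map must have two columns (sample, group)")
  if (tolower(gmap[1, 1]) == "sample" && tolower(gmap[1, 2]) == "group")
    gmap <- gmap[-1, , drop = FALSE]
  labels <- stats::setNames(gmap[[2]], gmap[[1]])
  missing <- setdiff(sample_ids, names(labels))
  if (length(missing))
    stop("samples in matrix missing from group map: ",
         paste(missing, collapse = ", "))
  expression_dataset(num, labels[sample_ids])
}

#' Write a ranked gene set analysis result table
#'
#' Writes a TSV with columns `set_name`, `set_size`, `gsz_score`,
#' `ev_location`, `ev_scale`, `p_value`, `fdr`, sorted by ascending p-value;
#' ties broken by descending score, then set name.
#'
#' @param results An `mgszm` fit (see [mgszm()]) or its `as.data.frame()`.
#' @param path Output path.
#' @return Invisibly, the sorted data frame that was written.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "mgszm")) results <- as.data.frame(results)
  stopifnot(is.data.frame(results), nrow(results) > 0)
  need <- c("set_name", "set_size", "gsz_score", "ev_location", "ev_scale",
            "p_value", "fdr")
  if (!all(need %in% names(results)))
    stop("results must contain columns: ", paste(need, collapse = ", "))
  ord <- order(results$p_value, -results$gsz_score, results$set_name)
  out <- results[ord, need, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return Data frame with the result columns.
#' @export
read_results <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
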
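#' Construct a gene list
#'
#' A labeled, ordered collection of unique gene symbols. Duplicates are
#' removed (first occurrence wins) with a warning; an empty result is an
#' error, since the downstream proximity statistics are undefined on empty
#' lists. Matching against graph vertices is case-sensitive and does no alias
#' resolution.
#'
#' @param ids character vector of gene symbols.
#' @param label list label, e.g. `"L1"`.
#' @return An object of class `gene_list` with elements `ids` and `label`.
#' @examples
#' gene_list(c("TP53", "MDM2"), label = "L1")
#' @export
gene_list <- function(ids, label = "list") {
  ids <- as.character(ids)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("gene ids must be non-empty strings")
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("dropping duplicate ids in '", label, "': ",
            paste(dup, collapse = ", "))
    ids <- ids[!duplicated(ids)]
  }
  if (length(ids) == 0) stop("gene list '", label, "' is empty")
  structure(list(ids = ids, label = as.character(label)[1]),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("gene_list '%s': %d ids\n  %s%s\n", x$label, length(x$ids),
              paste(utils::head(x$ids, 8), collapse = ", "),
              if (length(x$ids) > 8) ", ..." else ""))
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$ids)

# coerce a bare character vector for convenience at API boundaries
as_gene_list <- function(x, label = "list") {
  if (inherits(x, "gene_list")) return(x)
  gene_list(x, label = label)
}

#' Check that a gene list is contained in a graph
#'
#' @param g a [pathway_graph()].
#' @param list a [gene_list()] or character vector.
#' @return A list with `ok` (logical: all ids present) and `missing`
#'   (character vector of absent ids).
#' @examples
#' toy <- toy_fig1()
#' validate_membership(toy$graph, toy$L1)$ok
#' @export
validate_membership <- function(g, list) {
  stopifnot(inherits(g, "pathway_graph"))
  list <- as_gene_list(list)
  missing <- setdiff(list$ids, vertex_names(g))
  list(ok = length(missing) == 0, missing = missing)
}

#' Restrict a gene list to the vertices of a graph
#'
#' Filters the list to ids present in the graph, preserving input order.
#' An empty intersection is an error: proximity statistics on an empty list
#' are undefined.
#'
#' @param list a [gene_list()] or character vector.
#' @param g a [pathway_graph()].
#' @return A [gene_list()] with the same label.
#' @export
intersect_with_graph <- function(list, g) {
  stopifnot(inherits(g, "pathway_graph"))
  list <- as_gene_list(list)
  keep <- list$ids[list$ids %in% vertex_names(g)]
  if (length(keep) == 0) {
    stop("gene list '", list$label,
         "' shares no genes with the graph; statistics undefined")
  }
  gene_list(keep, label = list$label)
}

#' Read gene lists from a two-column CSV
#'
#' Expects a header with columns `ID` and `List`; rows are grouped by `List`
#' into one [gene_list()] per label, in order of first appearance. Duplicate
#' ids within a list are dropped with a warning.
#'
#' @param path CSV file path.
#' @return Named list of [gene_list()] objects.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(ID = c("A", "B", "A"), List = c("L1", "L1", "L2")),
#'           f, row.names = FALSE)
#' read_gene_lists_csv(f)
#' @export
read_gene_lists_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, colClasses = "character")
  if (!all(c("ID", "List") %in% names(df))) {
    stop("gene-list CSV must have header columns 'ID' and 'List'")
  }
  labels <- unique(df$List)
  out <- lapply(labels, function(lb) {
    gene_list(df$ID[df$List == lb], label = lb)
  })
  stats::setNames(out, labels)
}

#' Read gene sets from a GMT file
#'
#' Standard MSigDB dialect: one set per line, tab-separated fields
#' `name`, `description`, then member symbols.
#'
#' @param path GMT file path.
#' @return Named list of [gene_list()] objects (labels = set names).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("malformed GMT line (need name, description, >=1 member): ",
           substr(ln, 1, 40))
    }
    gene_list(f[-(1:2)], label = f[1])
  })
  stats::setNames(out, vapply(out, function(x) x$label, character(1)))
}

#' Write gene lists to the two-column CSV dialect
#'
#' @param lists a list of [gene_list()] objects.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_gene_lists_csv <- function(lists, path) {
  if (inherits(lists, "gene_list")) lists <- list(lists)
  df <- do.call(rbind, lapply(lists, function(l) {
    data.frame(ID = l$ids, List = l$label)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
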
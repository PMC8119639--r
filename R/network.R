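#' Load a gene-interaction edge list
#'
#' Reads a two-column whitespace-delimited file of gene pairs (a STRING
#' export surrogate) into an undirected simple graph. Symbols are
#' uppercased; duplicate edges collapse; self-loops are dropped with a
#' warning. `#` comments and blank lines are ignored.
#'
#' @param path Path to the edge-list file.
#' @return An undirected [igraph::igraph] with gene-symbol vertex names.
#' @export
load_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  pairs <- matrix(NA_character_, nrow = length(keep), ncol = 2)
  for (i in seq_along(keep)) {
    tokens <- strsplit(trimws(lines[keep[i]]), "[ \t]+")[[1]]
    if (length(tokens) != 2) {
      stop("edge-list format error at line ", keep[i],
           ": expected 2 columns, found ", length(tokens))
    }
    pairs[i, ] <- toupper(tokens)
  }
  loops <- pairs[, 1] == pairs[, 2]
  if (any(loops)) {
    warning("dropping ", sum(loops), " self-loop(s): ",
            paste(unique(pairs[loops, 1]), collapse = ", "))
    pairs <- pairs[!loops, , drop = FALSE]
  }
  if (!nrow(pairs)) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Graph proximity of a gene to a seed set
#'
#' Breadth-first shortest-path distance from a candidate gene to the
#' nearest member of a seed set of known disease genes. A gene that is
#' itself a seed has distance 0; a gene absent from the graph, or with no
#' path to any seed, is unreachable (`Inf`).
#'
#' @param gene Gene symbol.
#' @param seeds Non-empty character vector of seed gene symbols.
#' @param graph Graph from [load_edge_list()].
#' @return List with `distance` (non-negative integer, or `Inf` when
#'   unreachable) and `nearest_seed` (symbol, or NA; ties broken
#'   alphabetically).
#' @export
proximity <- function(gene, seeds, graph) {
  if (!length(seeds)) stop("seeds must be non-empty")
  gene <- toupper(gene)
  seeds <- sort(unique(toupper(seeds)))
  if (gene %in% seeds) {
    return(list(distance = 0L, nearest_seed = gene))
  }
  vnames <- igraph::V(graph)$name
  if (is.null(vnames) || !gene %in% vnames) {
    return(list(distance = Inf, nearest_seed = NA_character_))
  }
  seeds_in <- intersect(seeds, vnames)
  if (!length(seeds_in)) {
    return(list(distance = Inf, nearest_seed = NA_character_))
  }
  d <- igraph::distances(graph, v = gene, to = seeds_in)[1, ]
  if (all(is.infinite(d))) {
    return(list(distance = Inf, nearest_seed = NA_character_))
  }
  best <- min(d)
  list(distance = as.integer(best),
       nearest_seed = sort(names(d)[d == best])[1])
}

#' Read a seed-gene list (one symbol per line, `#` comments allowed)
#'
#' @param path Path to the list.
#' @return Character vector of uppercased symbols.
#' @export
read_seed_genes <- function(path) read_panel(path)
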
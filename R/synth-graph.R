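#' Generate a synthetic relatedness pair graph
#'
#' Fixture for the relatedness permutation test: a simple undirected graph
#' on `n_individuals` nodes with a prescribed number of edges per kinship
#' degree (1 = parent-offspring/sibling, 2, 3).
#'
#' @param n_individuals number of nodes.
#' @param degree_pair_counts named or positional integer vector of edge
#'   counts for degrees 1, 2, 3 (recycled/zero-padded to length 3).
#' @param seed integer seed.
#' @return data.frame with columns i, j (1-based node indices, i < j) and
#'   degree; zero rows for an empty graph.
#' @export
generate_relatedness_graph <- function(n_individuals, degree_pair_counts,
                                       seed = 1L) {
  counts <- rep_len(c(degree_pair_counts, 0L, 0L)[1:3], 3)
  total <- sum(counts)
  n_pairs <- choose(n_individuals, 2)
  if (total > n_pairs)
    stop("requested ", total, " pairs but only ", n_pairs, " exist")
  set.seed(seed)
  if (total == 0)
    return(data.frame(i = integer(0), j = integer(0), degree = integer(0)))
  pick <- sample.int(n_pairs, total)  # pairs enumerated in column order
  # invert the (i, j), i < j enumeration: pair index -> node pair
  j <- ceiling((1 + sqrt(1 + 8 * pick)) / 2)
  i <- pick - (j - 1) * (j - 2) / 2
  data.frame(i = as.integer(i), j = as.integer(j),
             degree = rep(1:3, counts))
}

#' Read and write pair graphs
#'
#' @param graph data.frame i/j/degree from [generate_relatedness_graph()].
#' @param path file path.
#' @export
write_pair_graph <- function(graph, path) {
  utils::write.table(graph, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_graph
#' @export
read_pair_graph <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE)
}
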
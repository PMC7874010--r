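#' Read a protein-protein interaction edge list
#'
#' Reads a STRING-export-style TSV with two node columns and a combined
#' confidence score. Columns named `node1`/`node2`/`combined_score` are used
#' if present, otherwise the first two columns are taken as nodes and the
#' third as the score. Scores on the 0-1000 scale are detected automatically
#' (any value > 1) and divided by 1000; `scale` overrides the detection.
#' Self-loops are dropped with a warning and symmetric duplicate edges are
#' collapsed (keeping the maximum score).
#'
#' @param path TSV file path.
#' @param score_cutoff minimum combined score (on the 0-1 scale) kept.
#' @param scale `"auto"`, `"unit"` (scores already in \[0,1\]) or
#'   `"thousand"` (0-1000 scale).
#' @return an undirected `igraph` graph with a `weight` edge attribute.
#' @export
read_interaction_edges <- function(path, score_cutoff = 0,
                                   scale = c("auto", "unit", "thousand")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- names(df)
  n1 <- if ("node1" %in% cols) "node1" else cols[1]
  n2 <- if ("node2" %in% cols) "node2" else cols[2]
  sc <- if ("combined_score" %in% cols) "combined_score" else cols[3]
  if (length(cols) < 3L) stop("edge file needs two node columns and a score column")
  edges <- data.frame(from = as.character(df[[n1]]),
                      to = as.character(df[[n2]]),
                      weight = as.numeric(df[[sc]]),
                      stringsAsFactors = FALSE)
  if (any(!is.finite(edges$weight))) stop("malformed score values in edge file")
  if (scale == "auto") scale <- if (any(edges$weight > 1)) "thousand" else "unit"
  if (scale == "thousand") edges$weight <- edges$weight / 1000
  if (any(edges$weight < 0) || any(edges$weight > 1)) {
    stop("combined scores outside [0, 1] after scaling; check the score scale")
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sum(loops), " self-loop edge(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  edges <- edges[edges$weight >= score_cutoff, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(weight = "max"))
}

#' Candidate genes connected in the interaction network
#'
#' Restricts the graph to the supplied genes and keeps those with at least
#' one edge inside that induced subgraph. Genes absent from the graph count
#' as unconnected.
#'
#' @param graph an `igraph` graph (e.g. from [read_interaction_edges()]).
#' @param genes character vector of candidate genes.
#' @return character subset of `genes` with induced degree >= 1, in the input
#'   order.
#' @export
connected_candidates <- function(graph, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("empty gene set")
  present <- intersect(genes, igraph::V(graph)$name)
  if (length(present) == 0L) return(character(0))
  sub <- igraph::induced_subgraph(graph, present)
  deg <- igraph::degree(sub)
  keep <- names(deg)[deg >= 1]
  genes[genes %in% keep]
}

#' Maximal clique centrality (MCC) node scores
#'
#' For every node v, `MCC(v) = sum over maximal cliques C containing v of
#' (|C| - 1)!`. Maximal cliques are enumerated exactly (Bron-Kerbosch with
#' pivoting, via `igraph::max_cliques`); isolated nodes, which belong to no
#' clique of size >= 2, score 0 by convention.
#'
#' @param graph an `igraph` graph.
#' @param max_nodes guard against exponential enumeration on huge graphs.
#' @return data.frame with columns `node`, `mcc`, sorted by decreasing score
#'   with ties broken by node name.
#' @export
mcc_scores <- function(graph, max_nodes = 5000L) {
  nv <- igraph::vcount(graph)
  if (nv == 0L) stop("empty graph")
  if (nv > max_nodes) {
    stop("graph exceeds the ", max_nodes,
         "-node guard for exact clique enumeration")
  }
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(nv))
  score <- stats::setNames(rep(0, nv), nodes)
  cliques <- igraph::max_cliques(graph, min = 2)
  for (cl in cliques) {
    contrib <- factorial(length(cl) - 1)
    score[nodes[as.integer(cl)]] <- score[nodes[as.integer(cl)]] + contrib
  }
  out <- data.frame(node = nodes, mcc = unname(score), stringsAsFactors = FALSE)
  out <- out[order(-out$mcc, out$node, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top central nodes by MCC, with predictor overlap
#'
#' Returns the k highest-scoring nodes (ties broken by node name) and, when a
#' predictor set is supplied, the overlap between the central nodes and the
#' predictors.
#'
#' @param scores data.frame from [mcc_scores()].
#' @param k number of central nodes to keep.
#' @param predictors optional character vector to intersect with.
#' @return list with `nodes` (character vector of length k), `overlap`
#'   (predictors that are central; NULL when `predictors` is missing) and
#'   `n_overlap`.
#' @export
top_central <- function(scores, k, predictors = NULL) {
  if (!all(c("node", "mcc") %in% names(scores))) {
    stop("scores must have columns node and mcc")
  }
  k <- as.integer(k)
  if (k < 1L || k > nrow(scores)) stop("k must be between 1 and the node count")
  ord <- order(-scores$mcc, scores$node, method = "radix")
  nodes <- scores$node[ord][seq_len(k)]
  overlap <- if (is.null(predictors)) NULL else intersect(predictors, nodes)
  list(nodes = nodes, overlap = overlap,
       n_overlap = if (is.null(overlap)) NA_integer_ else length(overlap))
}
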
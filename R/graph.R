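# Heterogeneous document graph over mention, entity and sentence nodes.
#
# Connection rules:
#   MM : two mentions in the same sentence
#   SS : every pair of sentence nodes (the sentence subgraph is a clique,
#        modelling global information)
#   MS : each mention and its containing sentence
#   ME : each mention and its entity concept
#   ES : each entity and every sentence containing one of its mentions
# plus self-loops on all nodes (the per-node convolution includes the a_ii
# term).  The adjacency is binary and symmetric.

#' Build the document adjacency matrix
#'
#' Nodes are ordered mentions (N), then entities (R), then sentences (T),
#' matching [build_nodes()].
#'
#' @param document an aligned `cid_document`.
#' @return a `cid_graph`: `A` ((N+R+T) x (N+R+T) binary symmetric matrix
#'   with unit diagonal), `edges` (data frame `i`, `j`, `type` with i < j)
#'   and the node row maps.
#' @export
build_adjacency <- function(document) {
  N <- nrow(document$mentions)
  R <- nrow(document$concepts)
  T_ <- length(document$sentences)
  if (N > 0L && any(is.na(document$mentions$sentence_index))) {
    stop("mention without sentence assignment")
  }
  n <- N + R + T_
  A <- diag(1, n)
  ei <- integer(0); ej <- integer(0); et <- character(0)
  add <- function(i, j, type) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    ei <<- c(ei, lo); ej <<- c(ej, hi); et <<- c(et, rep(type, length(lo)))
  }

  srow <- function(s) N + R + s
  erow <- stats::setNames(N + seq_len(R), document$concepts$concept_id)

  # MM: same-sentence mention pairs (regardless of concept or type)
  if (N > 1L) {
    for (s in unique(document$mentions$sentence_index)) {
      ms <- which(document$mentions$sentence_index == s)
      if (length(ms) > 1L) {
        cmb <- utils::combn(ms, 2L)
        add(cmb[1, ], cmb[2, ], "MM")
      }
    }
  }
  # SS: sentence clique
  if (T_ > 1L) {
    cmb <- utils::combn(seq_len(T_), 2L)
    add(srow(cmb[1, ]), srow(cmb[2, ]), "SS")
  }
  # MS: mention -- containing sentence
  if (N > 0L) add(seq_len(N), srow(document$mentions$sentence_index), "MS")
  # ME: mention -- its entity
  if (N > 0L) add(seq_len(N), unname(erow[document$mentions$concept_id]), "ME")
  # ES: entity -- sentences where its mentions appear
  for (k in seq_len(R)) {
    ss <- unique(document$mentions$sentence_index[
      document$concepts$mention_idx[[k]]])
    add(rep(N + k, length(ss)), srow(ss), "ES")
  }

  edges <- unique(data.frame(i = ei, j = ej, type = et,
                             stringsAsFactors = FALSE))
  A[cbind(edges$i, edges$j)] <- 1
  A[cbind(edges$j, edges$i)] <- 1

  structure(list(A = A, edges = edges, n = n,
                 n_mention = N, n_entity = R, n_sentence = T_,
                 mention_row = seq_len(N), entity_row = erow,
                 sentence_row = N + R + seq_len(T_)),
            class = "cid_graph")
}

#' Replace the document graph by a fully connected one (ablation)
#'
#' @param graph a `cid_graph`.
#' @return the same graph with an all-ones adjacency; node maps preserved.
#' @export
make_fully_connected <- function(graph) {
  graph$A <- matrix(1, graph$n, graph$n)
  cmb <- if (graph$n > 1L) utils::combn(seq_len(graph$n), 2L) else
    matrix(integer(0), 2, 0)
  graph$edges <- data.frame(i = cmb[1, ], j = cmb[2, ],
                            type = rep("FULL", ncol(cmb)),
                            stringsAsFactors = FALSE)
  graph
}

#' Normalize an adjacency matrix
#'
#' @param A binary symmetric adjacency with self-loops.
#' @param mode `"none"` (the convolution as written, default), `"sym"` for
#'   D^(-1/2) A D^(-1/2), or `"row"` for D^(-1) A.
#' @return the (possibly) normalized real matrix.
#' @export
normalize_adjacency <- function(A, mode = c("none", "sym", "row")) {
  mode <- match.arg(mode)
  if (mode == "none") return(A)
  deg <- rowSums(A)
  if (any(deg <= 0)) stop("zero-degree node; self-loops are required")
  if (mode == "row") return(A / deg)
  Dm <- 1 / sqrt(deg)
  A * outer(Dm, Dm)
}

#' Export the edge list as TSV (for debugging/visualization)
#'
#' @param graph a `cid_graph`.
#' @param path output file path.
#' @export
export_edges <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
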
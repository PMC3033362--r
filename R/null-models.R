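#' Specification of a random-network null ensemble
#'
#' @param kind one of \code{"er"}, \code{"degree_preserving"},
#'   \code{"degree_triangle_preserving"},
#'   \code{"directed_degree_reciprocity_preserving"},
#'   \code{"degree_sequence_permutation"}.
#' @param n_samples number of ensemble samples.
#' @param swaps_per_edge attempted rewiring moves per edge used as burn-in
#'   (default 100).
#' @param seed integer seed for the ensemble.
#' @return a \code{null_ensemble_spec} list.
#' @export
null_ensemble_spec <- function(kind = c("degree_preserving", "er",
                                        "degree_triangle_preserving",
                                        "directed_degree_reciprocity_preserving",
                                        "degree_sequence_permutation"),
                               n_samples = 1000, swaps_per_edge = 100,
                               seed = 1L) {
  kind <- match.arg(kind)
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (swaps_per_edge < 0) stop("swaps_per_edge must be >= 0")
  structure(list(kind = kind, n_samples = as.integer(n_samples),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 seed = as.integer(seed)),
            class = "null_ensemble_spec")
}

#' Sample an Erdos-Renyi random network
#'
#' Every (ordered or unordered) pair of distinct nodes is connected
#' independently with probability p; the diagonal is zero.
#'
#' @param n number of nodes.
#' @param p connection probability in [0, 1].
#' @param directed logical.
#' @param seed optional integer seed (NULL uses the current RNG stream).
#' @return a binary \code{adjacency_network}.
#' @export
sample_er <- function(n, p, directed = FALSE, seed = NULL) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (n < 0) stop("n must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0, n, n)
  if (n >= 2) {
    if (directed) {
      A[] <- rbinom(n * n, 1, p)
      diag(A) <- 0
    } else {
      up <- upper.tri(A)
      A[up] <- rbinom(sum(up), 1, p)
      A <- A + t(A)
    }
  }
  adjacency_network(A, sprintf("V%03d", seq_len(n)), directed = directed)
}

net_edge_list <- function(net) {
  # 0-based edge endpoints for the C++ samplers
  A <- net$weights > 0
  if (net$directed) {
    mut <- which(A & t(A) & upper.tri(A), arr.ind = TRUE)
    asym <- which(A & !t(A), arr.ind = TRUE)
    list(asym = asym - 1L, mutual = mut - 1L)
  } else {
    e <- which(A & upper.tri(A), arr.ind = TRUE)
    e - 1L
  }
}

edges_to_network <- function(edges, net, directed, mutual = NULL) {
  n <- n_nodes(net)
  A <- matrix(0, n, n)
  if (nrow(edges)) {
    e <- edges + 1L
    A[e] <- 1
    if (!directed) A[e[, c(2, 1), drop = FALSE]] <- 1
  }
  if (!is.null(mutual) && nrow(mutual)) {
    m <- mutual + 1L
    A[m] <- 1
    A[m[, c(2, 1), drop = FALSE]] <- 1
  }
  adjacency_network(A, net$names, directed = directed)
}

#' Rewire a binary network within a constrained null ensemble
#'
#' Degree-preserving rewiring performs repeated double-edge swaps, so the
#' degree sequence of the output equals the input exactly.
#' \code{degree_triangle_preserving} additionally rejects any swap that
#' changes the global triangle count.
#' \code{directed_degree_reciprocity_preserving} swaps unidirectional arcs
#' and bidirectional pairs within disjoint pools, preserving every node's
#' in-degree, out-degree, and counts of unidirectional and bidirectional
#' connections. No self-loops or parallel edges are ever created.
#'
#' @param net a binary \code{adjacency_network} (weights in \{0, 1\};
#'   binarize weighted networks first).
#' @param kind the ensemble kind (see \code{\link{null_ensemble_spec}}).
#' @param swaps_per_edge attempted swaps per edge.
#' @return a rewired binary \code{adjacency_network}.
#' @export
rewire_network <- function(net, kind = "degree_preserving",
                           swaps_per_edge = 100) {
  if (!is_binary(net))
    stop("rewiring requires a binary network; binarize the weights first")
  if (kind == "er") {
    n <- n_nodes(net)
    m <- if (net$directed) sum(net$weights) else sum(net$weights) / 2
    npairs <- if (net$directed) n * (n - 1) else n * (n - 1) / 2
    out <- sample_er(n, if (npairs > 0) m / npairs else 0, net$directed)
    out$names <- net$names
    dimnames(out$weights) <- list(net$names, net$names)
    return(out)
  }
  if (kind == "degree_sequence_permutation")
    stop("degree_sequence_permutation applies to degree sequences ",
         "(see degree_correlation_table), not to network rewiring")
  if (kind %in% c("degree_preserving", "degree_triangle_preserving")) {
    if (net$directed)
      stop(kind, " rewiring expects an undirected network")
    e <- net_edge_list(net)
    nswaps <- as.integer(swaps_per_edge * max(1, nrow(e)))
    out <- cpp_rewire_undirected(e, n_nodes(net), nswaps,
                                 kind == "degree_triangle_preserving")
    return(edges_to_network(out, net, directed = FALSE))
  }
  if (kind == "directed_degree_reciprocity_preserving") {
    if (!net$directed) stop("reciprocity-preserving rewiring needs a directed network")
    e <- net_edge_list(net)
    sw_a <- as.integer(swaps_per_edge * max(1, nrow(e$asym)))
    sw_m <- as.integer(swaps_per_edge * max(1, nrow(e$mutual)))
    out <- cpp_rewire_directed(e$asym, e$mutual, n_nodes(net), sw_a, sw_m)
    return(edges_to_network(out$asym, net, directed = TRUE,
                            mutual = out$mutual))
  }
  stop("unknown null-ensemble kind: ", kind)
}

#' Stream samples from a null ensemble
#'
#' Calls \code{fun} on each of \code{spec$n_samples} independently rewired
#' copies of \code{net} (each rewired afresh from the original), collecting
#' the results in a list. Memory stays bounded by one network at a time.
#'
#' @param net binary \code{adjacency_network}.
#' @param spec a \code{\link{null_ensemble_spec}}.
#' @param fun function applied to each sample.
#' @return list of \code{fun} results, length \code{n_samples}.
#' @export
null_ensemble_apply <- function(net, spec, fun = identity) {
  stopifnot(inherits(spec, "null_ensemble_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  lapply(seq_len(spec$n_samples), function(i)
    fun(rewire_network(net, spec$kind, spec$swaps_per_edge)))
}
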
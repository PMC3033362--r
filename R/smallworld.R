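#' Geodesic distances and characteristic path length
#'
#' Breadth-first geodesics on the binarized network. The characteristic
#' path length L is the mean geodesic distance over all ordered pairs of
#' distinct neurons in the requested component; it diverges on a
#' disconnected component, which is reported as an error naming an
#' unreachable pair.
#'
#' @param net an \code{adjacency_network} (binarized internally).
#' @param component optional vector of neuron names restricting the
#'   analysis; defaults to all neurons.
#' @return list with \code{distances} (matrix, ordered pairs, rows =
#'   source), \code{L}, and \code{histogram} (table of distances).
#' @export
path_stats <- function(net, component = NULL) {
  if (!is.null(component)) {
    net <- adjacency_network(net$weights[component, component, drop = FALSE],
                             component, net$directed, net$quantitation)
  }
  g <- as_igraph(binarize(net))
  d <- igraph::distances(g, mode = if (net$directed) "out" else "all")
  off <- d[row(d) != col(d)]
  if (any(!is.finite(off))) {
    ij <- which(!is.finite(d) & row(d) != col(d), arr.ind = TRUE)[1, ]
    stop(sprintf("component is not %sconnected: no path %s -> %s (L diverges)",
                 if (net$directed) "strongly " else "", net$names[ij[1]],
                 net$names[ij[2]]))
  }
  list(distances = d, L = mean(off),
       histogram = table(factor(off, levels = 0:max(off))))
}

#' Clustering coefficients
#'
#' Undirected mode: C_i = 2 E_i / (n_i (n_i - 1)) where E_i is the number
#' of edges among the n_i neighbours of i. Out mode (directed networks):
#' the neighbourhood is the set of out-neighbours, capturing signal flow,
#' and E_i counts directed edges among them over n_i (n_i - 1) ordered
#' slots. Nodes with fewer than two neighbours have C_i = 0.
#'
#' @param net an \code{adjacency_network} (binarized internally).
#' @param mode \code{"undirected"} or \code{"out"}.
#' @return list with per-node \code{C_i} (named) and mean \code{C}.
#' @export
clustering <- function(net, mode = c("undirected", "out")) {
  mode <- match.arg(mode)
  A <- (net$weights > 0) * 1
  if (mode == "undirected") {
    if (net$directed) A <- ((A + t(A)) > 0) * 1
    nbrs <- function(i) which(A[i, ] > 0)
    denom <- function(k) k * (k - 1) / 2
  } else {
    if (!net$directed) stop("out-clustering requires a directed network")
    nbrs <- function(i) which(A[i, ] > 0)
    denom <- function(k) k * (k - 1)
  }
  n <- nrow(A)
  Ci <- vapply(seq_len(n), function(i) {
    nb <- nbrs(i)
    k <- length(nb)
    if (k < 2) return(0)
    sub <- A[nb, nb, drop = FALSE]
    e <- if (mode == "undirected") sum(sub) / 2 else sum(sub)
    e / denom(k)
  }, numeric(1))
  names(Ci) <- net$names
  list(C_i = Ci, C = mean(Ci))
}

#' Small-world-ness against a degree-matched null ensemble
#'
#' Computes the clustering coefficient C and characteristic path length L
#' on the giant component, and their ensemble means on degree-matched
#' rewired networks (each sample restricted to its own giant component).
#' S = (C / C_rand) / (L / L_rand); S substantially above 1 indicates high
#' clustering at no path-length cost.
#'
#' @param net binary \code{adjacency_network}.
#' @param null_spec a \code{\link{null_ensemble_spec}}; default 1000
#'   degree-preserving samples.
#' @return list with \code{L}, \code{C}, \code{L_rand}, \code{C_rand},
#'   their ensemble standard deviations, and \code{S}.
#' @export
small_world_ness <- function(net, null_spec = null_ensemble_spec()) {
  net <- binarize(net)
  gc <- giant_component(net)
  L <- path_stats(gc)$L
  C <- clustering(gc, if (net$directed) "out" else "undirected")$C
  stats <- null_ensemble_apply(net, null_spec, function(s) {
    sg <- giant_component(s)
    c(L = path_stats(sg)$L,
      C = clustering(sg, if (s$directed) "out" else "undirected")$C)
  })
  M <- do.call(rbind, stats)
  L_rand <- mean(M[, "L"]); C_rand <- mean(M[, "C"])
  S <- if (C_rand == 0) Inf else (C / C_rand) / (L / L_rand)
  list(L = L, C = C, L_rand = L_rand, C_rand = C_rand,
       L_rand_sd = sd(M[, "L"]), C_rand_sd = sd(M[, "C"]), S = S,
       n_samples = null_spec$n_samples)
}

#' Closeness centralities
#'
#' The normalized closeness of a neuron is the mean geodesic distance to
#' (mode \code{"out"}), from (mode \code{"in"}), or between (undirected)
#' the neurons it can reach; the centrality is its inverse. Unreachable
#' nodes are excluded from the mean; a neuron reaching nothing has
#' centrality 0.
#'
#' @param net an \code{adjacency_network} (binarized internally).
#' @param mode \code{"undirected"}, \code{"in"}, or \code{"out"}.
#' @return named numeric vector of centralities.
#' @export
closeness_centralities <- function(net, mode = c("undirected", "in", "out")) {
  mode <- match.arg(mode)
  g <- as_igraph(binarize(net))
  igmode <- switch(mode, undirected = "all", "in" = "in", out = "out")
  d <- igraph::distances(g, mode = if (mode == "out") "out" else
                           if (mode == "in") "in" else "all")
  n <- nrow(d)
  cent <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (!length(di)) return(0)
    1 / mean(di)
  }, numeric(1))
  names(cent) <- net$names
  cent
}
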
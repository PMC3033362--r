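#' Connected components of a network
#'
#' A weakly connected component is a maximal set of neurons mutually
#' reachable when connection directions may be violated; a strongly
#' connected component requires mutual reachability along directions.
#'
#' @param net an \code{adjacency_network}.
#' @param mode \code{"undirected"}, \code{"weak"}, or \code{"strong"}.
#' @return object of class \code{component_partition}: list with
#'   \code{mode}, \code{components} (list of name vectors, decreasing
#'   size), and \code{isolated} (members of size-1 components).
#' @export
connected_components <- function(net, mode = c("undirected", "weak",
                                                "strong")) {
  mode <- match.arg(mode)
  if (mode %in% c("weak", "strong") && !net$directed)
    stop("mode '", mode, "' requires a directed network")
  if (mode == "undirected" && net$directed)
    stop("mode 'undirected' requires an undirected network (use weak/strong)")
  g <- as_igraph(net)
  memb <- igraph::components(g, mode = if (mode == "strong") "strong"
                             else "weak")$membership
  comps <- split(net$names, memb)
  comps <- comps[order(-vapply(comps, length, 1L))]
  names(comps) <- NULL
  iso <- as.character(unlist(comps[vapply(comps, length, 1L) == 1]))
  structure(list(mode = mode, components = comps, isolated = iso),
            class = "component_partition")
}

#' @export
print.component_partition <- function(x, ...) {
  sizes <- vapply(x$components, length, 1L)
  cat(sprintf("component_partition (%s): %d components, giant = %d, %d isolated\n",
              x$mode, length(sizes), if (length(sizes)) max(sizes) else 0L,
              length(x$isolated)))
  invisible(x)
}

#' Extract the giant component of a network
#'
#' @param net an \code{adjacency_network}.
#' @param mode component mode; defaults to \code{"strong"} for directed and
#'   \code{"undirected"} otherwise.
#' @return the induced \code{adjacency_network} on the largest component.
#' @export
giant_component <- function(net, mode = NULL) {
  if (is.null(mode)) mode <- if (net$directed) "strong" else "undirected"
  part <- connected_components(net, mode)
  keep <- part$components[[1]]
  adjacency_network(net$weights[keep, keep, drop = FALSE], keep,
                    net$directed, net$quantitation)
}

# principal-branch Lambert W on [-1/e, 0) by Newton iteration
lambert_w0 <- function(x) {
  stopifnot(x >= -exp(-1) - 1e-12, x <= 0)
  w <- if (x > -0.25) x else -0.5
  for (i in 1:100) {
    ew <- exp(w)
    step <- (w * ew - x) / (ew * (1 + w))
    w <- w - step
    if (abs(step) < 1e-14) break
  }
  w
}

#' Giant-component statistics of an Erdos-Renyi network
#'
#' For mean degree c = p (n - 1) above 1 the giant-component size is
#' asymptotically normal. Its mean is n rho with rho the positive solution
#' of rho = 1 - exp(-c rho), expressible through the Lambert W function as
#' rho = 1 + W(-c e^(-c)) / c. The variance is computed as
#' n rho (1 - rho) / (1 - c (1 - rho))^2 and validated against Monte-Carlo
#' simulation rather than asserted as a closed-form citation.
#'
#' @param n number of nodes.
#' @param p connection probability.
#' @return list with \code{c}, \code{rho}, \code{mean_size},
#'   \code{variance}.
#' @export
er_giant_stats <- function(n, p) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  cc <- p * (n - 1)
  if (cc <= 1)
    return(list(c = cc, rho = 0, mean_size = 0, variance = 0))
  rho <- 1 + lambert_w0(-cc * exp(-cc)) / cc
  list(c = cc, rho = rho, mean_size = n * rho,
       variance = n * rho * (1 - rho) / (1 - cc * (1 - rho))^2)
}

#' Construct a degree distribution object
#'
#' @param probs probabilities of degrees 0, 1, 2, ... (sum to 1).
#' @return numeric vector of class \code{degree_distribution}.
#' @export
degree_distribution <- function(probs) {
  probs <- as.numeric(probs)
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-12) stop("probabilities must sum to 1")
  structure(probs, class = "degree_distribution")
}

#' Empirical degree distribution of a network
#'
#' @param net an \code{adjacency_network}; degrees are counted on the
#'   binarized network (undirected degree, or total degree of the
#'   symmetrized network when \code{net} is directed).
#' @return a \code{\link{degree_distribution}}.
#' @export
empirical_degree_distribution <- function(net) {
  A <- net$weights > 0
  if (net$directed) A <- A | t(A)
  deg <- rowSums(A)
  degree_distribution(tabulate(deg + 1, nbins = max(deg) + 1) / length(deg))
}

gf_g0 <- function(dist, x) sum(dist * x^(seq_along(dist) - 1))
gf_g0p <- function(dist, x) {
  k <- seq_along(dist) - 1
  sum(dist * k * x^pmax(k - 1, 0) * (k > 0))
}
gf_g1 <- function(dist, x) gf_g0p(dist, x) / gf_g0p(dist, 1)
gf_g1p <- function(dist, x) {
  k <- seq_along(dist) - 1
  sum(dist * k * pmax(k - 1, 0) * x^pmax(k - 2, 0) * (k > 1)) / gf_g0p(dist, 1)
}

#' Giant component of a random network with a given degree distribution
#'
#' Builds the generating functions G0(x) = sum p_k x^k and
#' G1(x) = G0'(x) / G0'(1). The extinction probability u is the smallest
#' non-negative solution of u = G1(u); the expected giant-component
#' fraction is S = 1 - G0(u); the mean size of the non-giant components is
#' 1 + z1 u^2 / ((1 - S)(1 - G1'(u))) with z1 the mean degree.
#'
#' @param dist a \code{\link{degree_distribution}}.
#' @return list with \code{u}, \code{giant_fraction},
#'   \code{mean_small_component}.
#' @export
gf_giant_component <- function(dist) {
  if (abs(sum(dist) - 1) > 1e-12) stop("degree distribution must sum to 1")
  z1 <- gf_g0p(dist, 1)
  if (z1 <= 0) stop("mean degree must be positive")
  # iterate u <- G1(u) from 0: converges to the smallest fixed point
  u <- 0
  for (i in 1:10000) {
    un <- gf_g1(dist, u)
    if (abs(un - u) < 1e-15) { u <- un; break }
    u <- un
  }
  S <- 1 - gf_g0(dist, u)
  msc <- if (S < 1) 1 + z1 * u^2 / ((1 - S) * (1 - gf_g1p(dist, u))) else NA_real_
  list(u = u, giant_fraction = S, mean_small_component = msc)
}

#' Expected path length of a random network with a given degree distribution
#'
#' With z1 the mean number of first neighbours and z2 the mean number of
#' second neighbours (z2 = sum k (k - 1) p_k), the expected geodesic
#' distance is ln(n / z1) / ln(z2 / z1) + 1.
#'
#' @param dist a \code{\link{degree_distribution}}.
#' @param n network size.
#' @return expected path length (numeric).
#' @export
gf_expected_path_length <- function(dist, n) {
  k <- seq_along(dist) - 1
  z1 <- sum(k * dist)
  z2 <- sum(k * (k - 1) * dist)
  if (z1 <= 0) stop("mean degree must be positive")
  if (z2 <= z1) stop("z2 <= z1: expected path length is undefined")
  log(n / z1) / log(z2 / z1) + 1
}
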
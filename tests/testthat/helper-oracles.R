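# helpers and independent oracles used across the suite

rand_net <- function(n, p, directed = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample_er(n, p, directed = directed)
}

net_from_edges <- function(edges, n = NULL, directed = FALSE,
                           names = NULL, weights = NULL) {
  # edges: 2-column matrix (or data.frame) of endpoints (names or indices)
  edges <- as.matrix(edges)
  if (is.null(names)) {
    if (is.character(edges)) names <- sort(unique(as.vector(edges)))
    else names <- paste0("V", seq_len(if (is.null(n)) max(edges) else n))
  }
  A <- matrix(0, length(names), length(names), dimnames = list(names, names))
  idx <- if (is.character(edges))
    cbind(match(edges[, 1], names), match(edges[, 2], names))
  else edges
  w <- if (is.null(weights)) rep(1, nrow(edges)) else weights
  A[idx] <- w
  if (!directed) A[idx[, c(2, 1), drop = FALSE]] <- w
  adjacency_network(A, names, directed = directed)
}

# O(n^3) Floyd-Warshall geodesics, independent of igraph's BFS
floyd_warshall <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# transitive-closure component oracle (undirected / strong)
components_oracle <- function(A, strong = FALSE) {
  n <- nrow(A)
  R <- (A > 0) | diag(TRUE, n)
  if (!strong) R <- R | t(R)
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  S <- R & t(R)  # mutual reachability
  memb <- integer(n)
  cur <- 0
  for (i in seq_len(n)) if (memb[i] == 0) {
    cur <- cur + 1
    memb[S[i, ]] <- cur
  }
  memb
}

# brute-force census: classify every subset with wirenet's pattern encoder
# but enumerate in R (independent of the C++ loops)
brute_census <- function(net, size, directed) {
  cls <- motif_classes(size, directed)
  cmap <- attr(cls, "classmap")
  A <- (net$weights > 0) * 1
  n <- nrow(A)
  counts <- setNames(numeric(nrow(cls)), cls$label)
  for (sub in asplit(combn(n, size), 2)) {
    code <- wirenet:::motif_encode(A[sub, sub, drop = FALSE], directed)
    counts[cmap[code + 1]] <- counts[cmap[code + 1]] + 1
  }
  counts
}

# independent stub-matching configuration-model sampler (whole-shuffle
# rejection), used to cross-check the rewiring ensemble
stub_match_sample <- function(deg, max_try = 50000) {
  n <- length(deg)
  stubs <- rep.int(seq_len(n), deg)
  for (t in seq_len(max_try)) {
    s <- sample(stubs)
    a <- s[seq(1, length(s), 2)]
    b <- s[seq(2, length(s), 2)]
    if (any(a == b)) next
    key <- pmin(a, b) * (n + 1) + pmax(a, b)
    if (anyDuplicated(key)) next
    A <- matrix(0, n, n)
    A[cbind(a, b)] <- 1
    A[cbind(b, a)] <- 1
    return(adjacency_network(A, paste0("V", seq_len(n)), directed = FALSE))
  }
  stop("stub matching failed")
}

expect_network_equal <- function(a, b) {
  expect_identical(a$names, b$names)
  expect_equal(a$weights, b$weights)
  expect_identical(a$directed, b$directed)
}

tmp_diagram_files <- function(diagram) {
  np <- tempfile(fileext = ".csv")
  sp <- tempfile(fileext = ".csv")
  write_wiring_diagram(diagram, np, sp)
  list(neurons = np, synapses = sp)
}
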
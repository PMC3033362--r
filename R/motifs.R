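.motif_cache <- new.env(parent = emptyenv())

# bit encoding of a labelled (di)graph on k nodes, matching src/census.cpp:
# vertex pairs (a < b) in lexicographic order; undirected one bit per pair,
# directed two bits (low = a->b, high = b->a).
motif_encode <- function(A, directed) {
  k <- nrow(A)
  code <- 0
  bit <- 0
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    if (directed) {
      if (A[a, b]) code <- code + 2^bit
      if (A[b, a]) code <- code + 2^(bit + 1)
      bit <- bit + 2
    } else {
      if (A[a, b]) code <- code + 2^bit
      bit <- bit + 1
    }
  }
  code
}

motif_decode <- function(code, k, directed) {
  A <- matrix(0, k, k)
  bit <- 0
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    if (directed) {
      if (bitwAnd(code, 2^bit) > 0) A[a, b] <- 1
      if (bitwAnd(code, 2^(bit + 1)) > 0) A[b, a] <- 1
      bit <- bit + 2
    } else {
      if (bitwAnd(code, 2^bit) > 0) A[a, b] <- A[b, a] <- 1
      bit <- bit + 1
    }
  }
  A
}

#' Isomorphism classes of k-node (sub)networks
#'
#' Enumerates all labelled graphs on \code{size} nodes (2^3 and 2^6
#' patterns for undirected triplets/quadruplets; 2^(2 pairs) for directed)
#' and groups them by isomorphism via explicit vertex permutations. There
#' are 4 undirected triplet classes, 11 undirected quadruplet classes, 3
#' directed doublet classes, and 16 directed triplet classes. Classes are
#' canonically ordered by edge count, then degree sequence, then pattern
#' code; this ordering defines the class index used throughout.
#'
#' @param size 2, 3, or 4 nodes.
#' @param directed logical.
#' @return data.frame with one row per class: \code{id}, \code{label},
#'   \code{edges}, \code{code} (canonical pattern); attribute
#'   \code{classmap} maps every pattern code (0-based) to a class id.
#' @export
motif_classes <- function(size, directed = FALSE) {
  key <- paste0(size, if (directed) "d" else "u")
  if (!is.null(.motif_cache[[key]])) return(.motif_cache[[key]])
  if (!((directed && size %in% 2:3) || (!directed && size %in% 2:4)))
    stop("supported: undirected size 2/3/4, directed size 2/3")
  nbits <- if (directed) size * (size - 1) else size * (size - 1) / 2
  perms <- permutations_of(size)
  ncodes <- 2^nbits
  canon <- integer(ncodes)
  for (code in 0:(ncodes - 1)) {
    A <- motif_decode(code, size, directed)
    canon[code + 1] <- min(vapply(perms, function(p)
      motif_encode(A[p, p, drop = FALSE], directed), numeric(1)))
  }
  ucanon <- sort(unique(canon))
  info <- lapply(ucanon, function(code) {
    A <- motif_decode(code, size, directed)
    edges <- if (directed) sum(A) else sum(A) / 2
    degseq <- if (directed)
      sort(rowSums(A) * (size + 1) + colSums(A), decreasing = TRUE)
    else sort(rowSums(A), decreasing = TRUE)
    list(code = code, edges = edges, degseq = degseq)
  })
  ord <- order(vapply(info, `[[`, 0, "edges"),
               vapply(info, function(x)
                 sum(x$degseq * (2 * size)^rev(seq_along(x$degseq) - 1)), 0),
               ucanon)
  info <- info[ord]
  edges <- vapply(info, `[[`, 0, "edges")
  lab <- if (directed && size == 2) c("null", "unidirectional", "bidirectional")
    else {
      l <- sprintf("%de", edges)
      stats::ave(l, l, FUN = function(v)
        if (length(v) > 1) paste0(v, "_", seq_along(v)) else v)
    }
  classes <- data.frame(id = seq_along(info), label = lab, edges = edges,
                        code = vapply(info, `[[`, 0, "code"))
  cmap <- integer(ncodes)
  cmap[] <- match(canon, classes$code)
  attr(classes, "classmap") <- cmap
  .motif_cache[[key]] <- classes
  classes
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_of(k - 1)
  out <- list()
  for (p in sub) for (pos in seq_len(k)) {
    out[[length(out) + 1]] <- append(p, k, after = pos - 1)
  }
  out
}

#' Census of induced subnetworks
#'
#' Counts the induced subgraph on every subset of \code{size} neurons and
#' classifies it by isomorphism class (including the empty class), so the
#' counts always sum to choose(n, size). All subsets are enumerated
#' directly in compiled code; for size 4 this is C(n, 4) checks, practical
#' to a few hundred neurons.
#'
#' @param net binary \code{adjacency_network} (binarized internally).
#' @param size 2, 3, or 4 (directed networks: 2 or 3; undirected: 3 or 4).
#' @return named numeric vector of class counts, with the class table as
#'   attribute \code{classes}.
#' @export
census <- function(net, size, directed = net$directed) {
  if (directed != net$directed)
    stop("census directedness must match the network")
  ok <- (directed && size %in% 2:3) || (!directed && size %in% 3:4)
  if (!ok) stop("unsupported census size for this directedness")
  cls <- motif_classes(size, directed)
  A <- (net$weights > 0) * 1L
  storage.mode(A) <- "integer"
  counts <- cpp_census(A, as.integer(size), directed,
                       attr(cls, "classmap"), nrow(cls))
  names(counts) <- cls$label
  attr(counts, "classes") <- cls
  counts
}

#' Null-ensemble census statistics
#'
#' Runs a full census on each of \code{spec$n_samples} networks rewired
#' from \code{net} (each sample rewired afresh), returning per-class
#' ensemble means, standard deviations, observed/null ratios, and the raw
#' per-sample count matrix needed by \code{\link{motif_significance}}.
#' The conventional pairings are degree-preserving nulls for undirected
#' triplets, degree+triangle-preserving for undirected quadruplets, and
#' reciprocity-preserving for directed doublets/triplets.
#'
#' @param net binary \code{adjacency_network}.
#' @param spec a \code{\link{null_ensemble_spec}}.
#' @param size subgraph size.
#' @param directed logical.
#' @return list with \code{observed}, \code{null_mean}, \code{null_sd},
#'   \code{ratio}, \code{samples} (n_samples x classes matrix).
#' @export
null_census_ensemble <- function(net, spec, size, directed = net$directed) {
  net <- binarize(net)
  observed <- census(net, size, directed)
  rows <- null_ensemble_apply(net, spec, function(s)
    as.numeric(census(s, size, directed)))
  samples <- do.call(rbind, rows)
  colnames(samples) <- names(observed)
  null_mean <- colMeans(samples)
  null_sd <- apply(samples, 2, sd)
  list(observed = as.numeric(observed), null_mean = null_mean,
       null_sd = null_sd,
       ratio = ifelse(null_mean > 0, as.numeric(observed) / null_mean, NA),
       samples = samples, classes = attr(observed, "classes"))
}

#' Motif significance with step-down min-P correction
#'
#' Raw one-sided (overrepresentation) p-values are
#' p_raw(c) = (1 + #\{samples with count >= observed\}) / (R + 1).
#' Multiplicity is corrected by the step-down min-P algorithm: each
#' ensemble sample is given plug-in p-values against the full ensemble,
#' and the adjusted p of the most extreme class is the fraction of samples
#' whose minimum plug-in p over the classes still in play is at most its
#' raw p, stepping down with enforced monotonicity. Set
#' \code{underrepresentation = TRUE} to test the opposite tail.
#'
#' @param observed per-class observed counts.
#' @param samples per-sample count matrix (R x classes, from
#'   \code{\link{null_census_ensemble}}).
#' @param underrepresentation test for depletion instead of enrichment.
#' @return data.frame with \code{class}, \code{observed}, \code{p_raw},
#'   \code{p_adjusted}.
#' @export
motif_significance <- function(observed, samples,
                               underrepresentation = FALSE) {
  observed <- as.numeric(observed)
  if (is.null(dim(samples)) || nrow(samples) < 1)
    stop("empty null ensemble")
  R <- nrow(samples)
  K <- ncol(samples)
  if (R < 100)
    warning("fewer than 100 ensemble samples: adjusted p-values unstable")
  if (underrepresentation) {
    samples <- -samples
    observed <- -observed
  }
  cnt_ge <- function(col, v) {
    s <- sort(col)
    length(col) - findInterval(v - 1e-9, s)
  }
  p_raw <- vapply(seq_len(K), function(c)
    (1 + cnt_ge(samples[, c], observed[c])) / (R + 1), numeric(1))
  # plug-in p-value of each sample's count against the full ensemble
  P <- vapply(seq_len(K), function(c) {
    s <- sort(samples[, c])
    (1 + (R - findInterval(samples[, c] - 1e-9, s))) / (R + 1)
  }, numeric(R))
  P <- matrix(P, nrow = R)
  ord <- order(p_raw)
  p_adj <- numeric(K)
  for (t in seq_len(K)) {
    in_play <- ord[t:K]
    minp <- apply(P[, in_play, drop = FALSE], 1, min)
    p_adj[ord[t]] <- (1 + sum(minp <= p_raw[ord[t]])) / (R + 1)
  }
  p_adj[ord] <- cummax(p_adj[ord])
  p_adj <- pmax(p_adj, p_raw)
  lbl <- colnames(samples)
  if (is.null(lbl)) lbl <- paste0("class", seq_len(K))
  data.frame(class = lbl,
             observed = if (underrepresentation) -observed else observed,
             p_raw = p_raw, p_adjusted = pmin(p_adj, 1),
             stringsAsFactors = FALSE)
}
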
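#' Joint state of every unordered neuron pair
#'
#' For each unordered pair the chemical state is \code{absent},
#' \code{unidirectional}, or \code{bidirectional}, and the gap state is
#' presence/absence of a gap junction. With \code{subset =
#' "gaba_presynaptic"} only pairs containing at least one GABAergic neuron
#' are kept, and the chemical state is classified from the connections of
#' the GABAergic member(s) acting presynaptically (an interpretation of
#' "pairs with a GABAergic presynaptic neuron"; a non-GABA-to-GABA-only
#' connection counts as absent).
#'
#' @param gap,chem \code{adjacency_network}s on a common index.
#' @param gaba named logical vector (or vector of GABAergic neuron names)
#'   used by the GABA subset.
#' @param subset \code{"all"} or \code{"gaba_presynaptic"}.
#' @return data.frame with columns \code{i}, \code{j}, \code{chem_state},
#'   \code{gap_present}.
#' @export
pair_states <- function(gap, chem, gaba = NULL,
                        subset = c("all", "gaba_presynaptic")) {
  subset <- match.arg(subset)
  if (!identical(gap$names, chem$names))
    stop("gap and chemical networks must share the same neuron index; ",
         "use align_networks()")
  n <- length(gap$names)
  iu <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  A <- chem$weights > 0
  fw <- A[iu]                       # i -> j (i < j)
  bw <- t(A)[iu]                    # j -> i
  gp <- (gap$weights > 0)[iu]
  if (subset == "gaba_presynaptic") {
    if (is.null(gaba)) stop("gaba flags required for the GABA subset")
    if (!is.logical(gaba)) gaba <- setNames(gap$names %in% gaba, gap$names)
    gl <- unname(gaba[gap$names])
    gi <- gl[iu[, 1]]
    gj <- gl[iu[, 2]]
    keep <- gi | gj
    # connections whose presynaptic end is the GABAergic member
    fw_g <- fw & gi
    bw_g <- bw & gj
    fw <- fw_g[keep]
    bw <- bw_g[keep]
    gp <- gp[keep]
    iu <- iu[keep, , drop = FALSE]
  }
  state <- ifelse(fw & bw, "bidirectional",
                  ifelse(fw | bw, "unidirectional", "absent"))
  data.frame(i = gap$names[iu[, 1]], j = gap$names[iu[, 2]],
             chem_state = state, gap_present = gp,
             stringsAsFactors = FALSE)
}

#' Likelihood ratios of chemical connection states given a gap junction
#'
#' For each state s in \{absent, unidirectional, bidirectional\} the
#' likelihood ratio is LR(s) = P(chem state = s | gap present) /
#' P(chem state = s | gap absent), with probabilities estimated as
#' empirical fractions over the selected pair universe. LR > 1 for
#' (bi)directional states means the two networks overlap more than
#' independent networks would. Confidence intervals come from a
#' neuron-resampling bootstrap: pair states sharing a neuron are not
#' independent (one hub shifts thousands of pairs at once), so resampling
#' pairs would understate the uncertainty; resampling neurons and taking
#' the induced pair multiset captures it. A zero denominator is reported
#' as an infinite ratio with a flag, not an error.
#'
#' @param gap,chem \code{adjacency_network}s on a common index.
#' @param subset \code{"all"} or \code{"gaba_presynaptic"}.
#' @param gaba GABAergic flags (see \code{\link{pair_states}}).
#' @param n_boot bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @return data.frame with one row per state: \code{LR}, \code{lo},
#'   \code{hi}, \code{undefined} flag, plus conditional fractions.
#' @export
likelihood_ratios <- function(gap, chem, subset = "all", gaba = NULL,
                              n_boot = 1000, conf = 0.95) {
  ps <- pair_states(gap, chem, gaba, subset)
  states <- c("absent", "unidirectional", "bidirectional")
  if (!any(ps$gap_present))
    stop("no pair with a gap junction: conditional probabilities undefined")
  if (all(ps$gap_present))
    stop("no pair without a gap junction: conditional probabilities undefined")
  # sparse representation: non-absent / gap pairs as index lists, so each
  # bootstrap replicate is O(edges) not O(pairs)
  nm_all <- unique(c(ps$i, ps$j))
  n <- length(nm_all)
  iu <- match(ps$i, nm_all)
  ju <- match(ps$j, nm_all)
  st <- match(ps$chem_state, states)
  gp <- ps$gap_present
  idx_uni <- which(st == 2)
  idx_bi <- which(st == 3)
  idx_gap <- which(gp)
  idx_uni_gap <- which(st == 2 & gp)
  idx_bi_gap <- which(st == 3 & gp)
  counts_for <- function(cnt) {
    # cnt: per-neuron multiplicity; weighted pair count of an index set is
    # sum over its pairs of cnt_i * cnt_j
    wsum <- function(idx) sum(cnt[iu[idx]] * cnt[ju[idx]])
    total <- (sum(cnt)^2 - sum(cnt^2)) / 2
    gap_w <- wsum(idx_gap)
    uni_w <- wsum(idx_uni)
    bi_w <- wsum(idx_bi)
    uni_gap <- wsum(idx_uni_gap)
    bi_gap <- wsum(idx_bi_gap)
    c1 <- c(gap_w - uni_gap - bi_gap, uni_gap, bi_gap)
    c0 <- c((total - gap_w) - (uni_w - uni_gap) - (bi_w - bi_gap),
            uni_w - uni_gap, bi_w - bi_gap)
    if (gap_w == 0 || total - gap_w == 0) return(NULL)
    p1 <- c1 / gap_w
    p0 <- c0 / (total - gap_w)
    list(p1 = p1, p0 = p0, lr = ifelse(p0 > 0, p1 / p0, Inf))
  }
  obs <- counts_for(rep(1L, n))
  if (is.null(obs)) stop("conditional probabilities undefined")
  boot <- matrix(NA_real_, n_boot, 3)
  for (b in seq_len(n_boot)) {
    f <- counts_for(tabulate(sample.int(n, n, replace = TRUE), n))
    if (!is.null(f)) boot[b, ] <- f$lr
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2, function(v)
    quantile(v[is.finite(v)], c(alpha, 1 - alpha), na.rm = TRUE,
             names = FALSE))
  data.frame(state = states, LR = obs$lr,
             lo = ci[1, ], hi = ci[2, ],
             undefined = !is.finite(obs$lr),
             p_given_gap = obs$p1, p_given_nogap = obs$p0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Degree-sequence correlations between the two networks
#'
#' Pearson correlations between the gap degree, chemical in-degree, and
#' chemical out-degree sequences, each compared to a permutation null
#' (one sequence randomly permuted \code{n_perm} times; the permuted
#' correlations have mean about 0 and sd about 1 / sqrt(n)).
#'
#' @param gap,chem \code{adjacency_network}s on a common index.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional seed.
#' @return data.frame with one row per pairing: \code{r}, \code{p_value}
#'   (two-sided permutation p), \code{perm_mean}, \code{perm_sd},
#'   \code{perm_q975}.
#' @export
degree_correlation_table <- function(gap, chem, n_perm = 1000,
                                     seed = NULL) {
  if (!identical(gap$names, chem$names))
    stop("gap and chemical networks must share the same neuron index; ",
         "use align_networks()")
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 1) stop("n_perm must be >= 1")
  gdeg <- rowSums(gap$weights > 0)
  indeg <- colSums(chem$weights > 0)
  outdeg <- rowSums(chem$weights > 0)
  pairs <- list(`gap/in` = list(gdeg, indeg),
                `gap/out` = list(gdeg, outdeg),
                `in/out` = list(indeg, outdeg))
  rows <- lapply(names(pairs), function(nm) {
    x <- pairs[[nm]][[1]]; y <- pairs[[nm]][[2]]
    if (sd(x) == 0 || sd(y) == 0)
      stop("correlation undefined: zero-variance degree sequence")
    r <- cor(x, y)
    rp <- vapply(seq_len(n_perm), function(i) cor(x, sample(y)), numeric(1))
    data.frame(pairing = nm, r = r,
               p_value = (1 + sum(abs(rp) >= abs(r))) / (n_perm + 1),
               perm_mean = mean(rp), perm_sd = sd(rp),
               perm_q975 = quantile(rp, 0.975, names = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
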
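#' Parameters for the synthetic connectome generator
#'
#' The defaults describe a nematode-scale nervous system: about 280 named
#' neurons in three categories with bilateral left/right pairs, a directed
#' chemical multigraph of roughly 2000 connections with heavy-tailed in- and
#' out-degrees, an undirected gap-junction multigraph of roughly 500
#' connections with a power-law degree tail, connection multiplicities with
#' a stretched-exponential body, a positive association between gap-junction
#' presence and chemical-connection presence, a GABAergic subset of the
#' motor/interneurons, and a sizeable fraction of polyadic chemical
#' contacts.
#'
#' @param n_neurons number of neurons.
#' @param frac_sensory,frac_inter,frac_motor category fractions (sum to 1).
#' @param gap_degree_exponent power-law exponent (> 1) of gap degrees.
#' @param chem_degree_exponent power-law exponent (> 1) of the chemical
#'   in/out propensity weights (Chung-Lu style expected degrees).
#' @param mean_chem_connections expected number of directed chemical
#'   connections.
#' @param mean_gap_connections target number of gap-junction connections
#'   (sets the minimum degree of the power-law degree draw).
#' @param multiplicity_shape,multiplicity_scale stretched-exponential
#'   multiplicity parameters beta and lambda: P(M >= m) =
#'   exp(-((m - 1)/lambda)^beta) for m >= 1.
#' @param overlap_odds multiplier on the odds of a chemical connection for
#'   neuron pairs joined by a gap junction (1 = independence).
#' @param gaba_fraction fraction of motor+interneurons flagged GABAergic.
#' @param polyadic_fraction probability that a chemical contact is polyadic.
#' @param bilateral use left/right paired names ("N001L"/"N001R").
#' @param seed integer seed; the generated diagram is a deterministic
#'   function of the full parameter set.
#' @return a \code{synth_params} list.
#' @export
synth_params <- function(n_neurons = 280,
                         frac_sensory = 0.3, frac_inter = 0.3,
                         frac_motor = 0.4,
                         gap_degree_exponent = 3.0,
                         chem_degree_exponent = 2.5,
                         mean_chem_connections = 2000,
                         mean_gap_connections = 500,
                         multiplicity_shape = 0.5,
                         multiplicity_scale = 2,
                         overlap_odds = 3,
                         gaba_fraction = 0.1,
                         polyadic_fraction = 0.4,
                         bilateral = TRUE,
                         seed = 1L) {
  p <- list(n_neurons = as.integer(n_neurons), frac_sensory = frac_sensory,
            frac_inter = frac_inter, frac_motor = frac_motor,
            gap_degree_exponent = gap_degree_exponent,
            chem_degree_exponent = chem_degree_exponent,
            mean_chem_connections = mean_chem_connections,
            mean_gap_connections = mean_gap_connections,
            multiplicity_shape = multiplicity_shape,
            multiplicity_scale = multiplicity_scale,
            overlap_odds = overlap_odds, gaba_fraction = gaba_fraction,
            polyadic_fraction = polyadic_fraction,
            bilateral = isTRUE(bilateral), seed = as.integer(seed))
  fr <- c(p$frac_sensory, p$frac_inter, p$frac_motor)
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-8)
    stop("category fractions must lie in [0,1] and sum to 1")
  if (p$gap_degree_exponent <= 1 || p$chem_degree_exponent <= 1)
    stop("degree exponents must exceed 1")
  if (p$multiplicity_shape <= 0 || p$multiplicity_scale <= 0)
    stop("multiplicity shape and scale must be positive")
  if (p$overlap_odds < 0) stop("overlap_odds must be >= 0")
  for (f in c("gaba_fraction", "polyadic_fraction"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0,1]")
  if (p$n_neurons < 0) stop("n_neurons must be non-negative")
  class(p) <- "synth_params"
  p
}

# draw from the discrete power law p(k) ~ k^-alpha on {kmin, ..., kmax}
rdiscrete_powerlaw <- function(n, alpha, kmin = 1L, kmax = 10000L) {
  ks <- kmin:kmax
  pk <- ks^(-alpha)
  sample(ks, n, replace = TRUE, prob = pk / sum(pk))
}

# stretched-exponential multiplicities: P(M >= m) = exp(-((m-1)/lambda)^beta)
rmultiplicity <- function(n, lambda, beta) {
  u <- runif(n)
  1L + as.integer(floor(lambda * (-log(u))^(1 / beta)))
}

# configuration-model pairing of a degree sequence into a simple graph.
# Conflicting pairings (self-loops, parallel edges) are resolved by
# rejection: the offending stubs are re-shuffled among themselves, up to
# `max_rounds` rounds.
pair_stubs_simple <- function(deg, max_rounds = 1000) {
  n <- length(deg)
  stubs <- rep.int(seq_len(n), deg)
  if (length(stubs) %% 2 == 1) {  # repair to even sum: one extra stub
    i <- sample.int(n, 1)
    deg[i] <- deg[i] + 1L
    stubs <- c(stubs, i)
  }
  stubs <- sample(stubs)
  m <- length(stubs) / 2
  e1 <- stubs[seq_len(m) * 2 - 1]
  e2 <- stubs[seq_len(m) * 2]
  for (round in seq_len(max_rounds)) {
    a <- pmin(e1, e2)
    b <- pmax(e1, e2)
    key <- a * (n + 1) + b
    bad <- which(e1 == e2 | key %in% unique(key[duplicated(key)]))
    if (!length(bad)) return(unname(cbind(a, b)))
    # reshuffle the offending stubs together with some innocent edges so the
    # re-pairing is not trapped inside the conflicted set
    good <- setdiff(seq_len(m), bad)
    extra <- good[sample.int(length(good), min(length(good), length(bad)))]
    idx <- c(bad, extra)
    pool <- sample(c(e1[idx], e2[idx]))
    k <- length(idx)
    e1[idx] <- pool[seq_len(k) * 2 - 1]
    e2[idx] <- pool[seq_len(k) * 2]
  }
  stop("configuration-model pairing failed after ", max_rounds,
       " rejection rounds; try a lighter-tailed degree sequence")
}

#' Generate a synthetic wiring diagram
#'
#' The gap-junction network is a configuration-model graph whose degrees are
#' drawn from a discrete power law; the chemical network draws each ordered
#' pair independently with Chung-Lu style heavy-tailed propensities, with
#' the odds multiplied by \code{overlap_odds} when the pair is joined by a
#' gap junction; multiplicities follow the discrete stretched-exponential
#' law; each chemical contact is flagged polyadic independently. The result
#' is a valid, self-consistent \code{wiring_diagram} and is a deterministic
#' function of the parameters (including the seed).
#'
#' @param params a \code{\link{synth_params}} object.
#' @return a \code{wiring_diagram}.
#' @export
generate_connectome <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  empty_rec <- data.frame(pre = character(), post = character(),
                          type = character(), contacts = numeric(),
                          polyadic = numeric(), stringsAsFactors = FALSE)
  if (p$n_neurons == 0) {
    return(wiring_diagram(
      data.frame(name = character(), category = character(),
                 gabaergic = logical(), side = character(),
                 class = character(), stringsAsFactors = FALSE), empty_rec))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(p$seed)

  n <- p$n_neurons
  if (p$bilateral) {
    npairs <- n %/% 2
    cls <- sprintf("N%03d", seq_len(npairs + n %% 2))
    name <- c(rbind(paste0(cls[seq_len(npairs)], "L"),
                    paste0(cls[seq_len(npairs)], "R")),
              if (n %% 2) paste0(cls[npairs + 1], "U"))
    side <- c(rep(c("L", "R"), npairs), if (n %% 2) "none")
    class_of <- c(rep(cls[seq_len(npairs)], each = 2),
                  if (n %% 2) cls[npairs + 1])
  } else {
    name <- sprintf("N%03dU", seq_len(n))
    side <- rep("none", n)
    class_of <- sprintf("N%03d", seq_len(n))
  }
  # categories assigned per class so bilateral pairs match
  ucls <- unique(class_of)
  ncat <- round(length(ucls) * c(p$frac_sensory, p$frac_inter, p$frac_motor))
  ncat[3] <- length(ucls) - ncat[1] - ncat[2]
  cat_by_class <- setNames(
    rep(NEURON_CATEGORIES, times = pmax(ncat, 0))[seq_along(ucls)], ucls)
  category <- unname(cat_by_class[class_of])
  gaba <- rep(FALSE, n)
  eligible <- which(category != "sensory")
  ngaba <- round(p$gaba_fraction * length(eligible))
  if (ngaba > 0) gaba[eligible[sample.int(length(eligible), ngaba)]] <- TRUE
  neurons <- data.frame(name = name, category = category, gabaergic = gaba,
                        side = side, class = class_of,
                        stringsAsFactors = FALSE)

  # --- gap-junction network: power-law degrees + configuration model
  target_mean_deg <- 2 * p$mean_gap_connections / n
  a <- p$gap_degree_exponent
  kmin <- if (a > 2) max(1L, round(target_mean_deg * (a - 2) / (a - 1))) else 1L
  deg <- rdiscrete_powerlaw(n, a, kmin = kmin, kmax = max(10L, n %/% 2))
  gap_edges <- pair_stubs_simple(deg)
  mg <- nrow(gap_edges)
  gap_mult <- rmultiplicity(mg, p$multiplicity_scale, p$multiplicity_shape)

  # --- chemical network: Chung-Lu propensities with gap-overlap odds boost.
  # The association knob also couples neuron-level propensities to the gap
  # degree (shared hubness, as in the real connectome where the same neurons
  # are hubs of both networks): a Gaussian-copula blend with weight
  # theta = 1 - 1/overlap_odds, which vanishes exactly at independence.
  theta <- max(0, 1 - 1 / max(p$overlap_odds, 1e-12))
  couple_to <- function(w, anchor, theta) {
    if (theta == 0) return(sample(w))
    z_anchor <- stats::qnorm((rank(anchor, ties.method = "random") - 0.5) /
                               length(anchor))
    score <- theta * z_anchor + sqrt(1 - theta^2) * stats::rnorm(length(w))
    sort(w)[rank(score, ties.method = "random")]
  }
  wout <- couple_to(rdiscrete_powerlaw(n, p$chem_degree_exponent), deg, theta)
  win <- couple_to(rdiscrete_powerlaw(n, p$chem_degree_exponent), deg, theta)
  S <- outer(wout, win) / (mean(wout) * mean(win))  # mean 1 propensity
  diag(S) <- 0
  gap_adj <- matrix(FALSE, n, n)
  gap_adj[gap_edges] <- TRUE
  gap_adj[gap_edges[, c(2, 1), drop = FALSE]] <- TRUE
  ov <- ifelse(gap_adj, p$overlap_odds, 1)
  expected_count <- function(c0) {
    o <- c0 * S * ov
    sum(o / (1 + o)) - p$mean_chem_connections
  }
  # base odds per unit propensity, calibrated to the target count
  upper <- 1
  while (expected_count(upper) < 0 && upper < 1e8) upper <- upper * 2
  c0 <- if (expected_count(1e-12) > 0) 1e-12 else
    uniroot(expected_count, c(1e-12, upper), tol = 1e-10)$root
  pmat <- {o <- c0 * S * ov; o / (1 + o)}
  draw <- matrix(runif(n * n) < pmat, n, n)
  diag(draw) <- FALSE
  chem_idx <- which(draw, arr.ind = TRUE)
  mc <- nrow(chem_idx)
  chem_mult <- rmultiplicity(mc, p$multiplicity_scale, p$multiplicity_shape)
  chem_poly <- rbinom(mc, chem_mult, p$polyadic_fraction)

  rec_gap <- if (mg) data.frame(  # paired records, both directions
    pre = c(name[gap_edges[, 1]], name[gap_edges[, 2]]),
    post = c(name[gap_edges[, 2]], name[gap_edges[, 1]]),
    type = "gap", contacts = rep(gap_mult, 2), polyadic = 0,
    stringsAsFactors = FALSE) else empty_rec
  rec_chem <- if (mc) data.frame(
    pre = name[chem_idx[, 1]], post = name[chem_idx[, 2]], type = "chem",
    contacts = chem_mult, polyadic = chem_poly, stringsAsFactors = FALSE)
    else empty_rec
  wiring_diagram(neurons, rbind(rec_chem, rec_gap))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' A pinned 12-neuron wiring diagram for documentation and brute-force tests
#'
#' Hand-written and fixed: contains a bidirectional chemical pair
#' (AIAL/AIBL), a gap-junction triangle (AVAL, AVAR, AVBL), a pair with
#' both a gap junction and a chemical connection (AVAL/AVBL), polyadic
#' contacts, and one GABAergic neuron (DD01). It passes
#' \code{\link{validate_consistency}} with an empty report.
#'
#' @return a \code{wiring_diagram}.
#' @export
worked_fixture <- function() {
  neurons <- data.frame(
    name = c("ASHL", "ASHR", "AWAL", "AWAR", "AIAL", "AIAR", "AIBL",
             "AVAL", "AVAR", "AVBL", "DD01", "VA01"),
    category = c("S", "S", "S", "S", "I", "I", "I", "I", "I", "I", "M", "M"),
    gabaergic = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0),
    side = c("L", "R", "L", "R", "L", "R", "L", "L", "R", "L",
             "none", "none"),
    class = c("ASH", "ASH", "AWA", "AWA", "AIA", "AIA", "AIB", "AVA",
              "AVA", "AVB", "DD", "VA"),
    stringsAsFactors = FALSE)
  chem <- data.frame(
    pre = c("ASHL", "ASHR", "AWAL", "AWAR", "AIAL", "AIBL", "AIBL",
            "AVAL", "AVAR", "AVBL", "DD01", "AVAL"),
    post = c("AVAL", "AVAR", "AIAL", "AIAR", "AIBL", "AIAL", "AVAL",
             "VA01", "VA01", "VA01", "VA01", "AVBL"),
    contacts = c(5, 4, 2, 2, 3, 2, 4, 6, 5, 3, 2, 2),
    polyadic = c(2, 1, 0, 1, 1, 0, 2, 3, 2, 1, 0, 1),
    stringsAsFactors = FALSE)
  chem$type <- "chem"
  gap_pairs <- data.frame(
    a = c("AVAL", "AVAR", "AVAL", "ASHL", "AIAL"),
    b = c("AVAR", "AVBL", "AVBL", "ASHR", "AIAR"),
    w = c(3, 2, 2, 1, 1), stringsAsFactors = FALSE)
  gap <- data.frame(pre = c(gap_pairs$a, gap_pairs$b),
                    post = c(gap_pairs$b, gap_pairs$a),
                    contacts = rep(gap_pairs$w, 2), polyadic = 0,
                    stringsAsFactors = FALSE)
  gap$type <- "gap"
  cols <- c("pre", "post", "type", "contacts", "polyadic")
  wiring_diagram(neurons, rbind(chem[, cols], gap[, cols]))
}
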
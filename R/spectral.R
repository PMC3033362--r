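#' Electrical parameters of the linear dynamics
#'
#' The gap-junction network behaves as a resistor network: membrane
#' potential obeys C_m dV/dt = -g L V (plus a leak term), so the natural
#' time unit is tau = C_m / g. Chemical synapses enter through the
#' linearized tonic-release coupling with per-contact conductance
#' \code{g_c}, assumed equal to the gap conductance by default. Printed
#' decay times are in units of tau unless constants are supplied in
#' physical units (pF, pS give tau in ms times 1000; with the defaults
#' tau = 1 pF / 100 pS = 10 ms).
#'
#' @param C_m membrane capacitance (pF).
#' @param g gap-junction conductance per contact (pS).
#' @param g_c chemical-synapse conductance per contact (pS), default g.
#' @param g_m membrane (leak) conductance (pS).
#' @param include_leak include the -g_m/g identity shift.
#' @return a \code{dynamics_params} list with derived \code{tau} (ms).
#' @export
dynamics_params <- function(C_m = 1, g = 100, g_c = g, g_m = 10,
                            include_leak = FALSE) {
  stopifnot(C_m > 0, g > 0, g_c > 0, g_m > 0)
  structure(list(C_m = C_m, g = g, g_c = g_c, g_m = g_m,
                 include_leak = isTRUE(include_leak),
                 tau = 1000 * C_m / g),   # pF / pS = 1000 ms
            class = "dynamics_params")
}

#' Graph Laplacian of a weighted undirected network
#'
#' L = D - A with D the diagonal matrix of weighted degrees. L is
#' symmetric positive semidefinite with smallest eigenvalue 0; the
#' multiplicity of 0 equals the number of connected components.
#'
#' @param net a symmetric \code{adjacency_network}.
#' @return the Laplacian matrix.
#' @export
graph_laplacian <- function(net) {
  A <- net$weights
  if (nrow(A) && max(abs(A - t(A))) > 0)
    stop("graph_laplacian requires a symmetric (undirected) network")
  diag(rowSums(A), nrow(A)) - A
}

#' Linear-dynamics matrix of the combined network
#'
#' In units of 1/tau the membrane-potential dynamics are dV/dt = M V with
#' \code{M[i, j] = m_gap(i, j) + s_j (g_c/g) m_chem(j -> i)} for i != j,
#' where s_j = -1 for GABAergic presynaptic neurons and +1 otherwise, and
#' \code{M[i, i] = -sum_j m_gap(i, j) - g_m/g} (the leak term only with
#' \code{include_leak}). With no chemical network this reduces to minus
#' the gap Laplacian (plus the optional leak shift). Chemical coupling is
#' purely off-diagonal: the linearized tonic-release current into the
#' postsynaptic neuron is proportional to the presynaptic voltage.
#'
#' @param gap undirected \code{adjacency_network}.
#' @param chem optional directed \code{adjacency_network} on the same
#'   index (NULL for gap-only dynamics).
#' @param signs named vector of +1/-1 per neuron (presynaptic sign);
#'   required when \code{chem} has connections.
#' @param params a \code{\link{dynamics_params}}.
#' @return square matrix over the common neuron index.
#' @export
dynamics_matrix <- function(gap, chem = NULL, signs = NULL,
                            params = dynamics_params()) {
  G <- gap$weights
  if (nrow(G) && max(abs(G - t(G))) > 0) stop("gap network must be symmetric")
  M <- G
  diag(M) <- -rowSums(G)
  if (!is.null(chem) && any(chem$weights > 0)) {
    if (!identical(gap$names, chem$names))
      stop("gap and chemical networks must share the same neuron index")
    pre <- chem$names[rowSums(chem$weights) > 0]
    if (is.null(signs) || !all(pre %in% names(signs)))
      stop("signs missing for presynaptic neuron(s): ",
           paste(setdiff(pre, names(signs)), collapse = ", "))
    s <- sign(signs[chem$names])
    # column j of t(W) scaled by s_j: current into i from presynaptic j
    M <- M + (params$g_c / params$g) * t(chem$weights * s)
  }
  if (params$include_leak)
    M <- M - diag(params$g_m / params$g, nrow(M))
  dimnames(M) <- list(gap$names, gap$names)
  M
}

#' Signs of presynaptic neurons from a wiring diagram
#'
#' GABAergic neurons are treated as sign-inverting (inhibitory, -1); all
#' others as excitatory (+1).
#'
#' @param diagram a \code{wiring_diagram}.
#' @return named vector of +1/-1.
#' @export
neuron_signs <- function(diagram) {
  setNames(ifelse(diagram$neurons$gabaergic, -1, 1), diagram$neurons$name)
}

#' Eigenmode analysis of a dynamics matrix
#'
#' Full eigendecomposition, modes L2-normalized with the sign/phase
#' convention that the largest-magnitude component is positive real.
#' Modes are ordered by decreasing real part of the eigenvalue (slowest
#' first). The decay time of mode k is tau / |Re lambda_k| (infinite for
#' Re lambda = 0). Sparseness is the L1 norm of the unit-L2 mode, between
#' 1 (a single neuron) and sqrt(n) (a flat mode): sparse slow modes are
#' the candidates for circuit-level interpretation.
#'
#' @param M square matrix (e.g. from \code{\link{dynamics_matrix}}).
#' @param params a \code{\link{dynamics_params}} (sets tau).
#' @return object of class \code{eigen_analysis}: list with
#'   \code{values}, \code{modes} (columns), \code{decay_times},
#'   \code{sparseness}, \code{residuals}.
#' @export
eigenmodes <- function(M, params = dynamics_params()) {
  eg <- eigen(M)
  ord <- order(-Re(eg$values))
  vals <- eg$values[ord]
  V <- eg$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(V))) {
    v <- V[, k]
    v <- v / sqrt(sum(Mod(v)^2))
    i <- which.max(Mod(v))
    ph <- v[i] / Mod(v[i])
    V[, k] <- v / ph
  }
  if (all(Im(vals) == 0)) {
    vals <- Re(vals)
    V <- Re(V)
  }
  res <- vapply(seq_along(vals), function(k)
    sqrt(sum(Mod(M %*% V[, k] - vals[k] * V[, k])^2)) /
      max(1e-300, Mod(vals[k]), max(Mod(M))), numeric(1))
  rownames(V) <- rownames(M)
  structure(list(values = vals, modes = V,
                 decay_times = ifelse(Re(vals) == 0, Inf,
                                      params$tau / abs(Re(vals))),
                 sparseness = colSums(Mod(V)),
                 residuals = res, tau = params$tau),
            class = "eigen_analysis")
}

#' @export
print.eigen_analysis <- function(x, ...) {
  cat(sprintf("eigen_analysis: %d modes, Re(lambda) in [%.4g, %.4g], max residual %.2g\n",
              length(x$values), min(Re(x$values)), max(Re(x$values)),
              max(x$residuals)))
  invisible(x)
}

#' Simulate the linear response to an initial excitation
#'
#' Solves dv/dt = (1/tau) M v, v(0) = v0, by eigendecomposition when the
#' eigenbasis is well conditioned and by RK4 time stepping otherwise; the
#' two paths agree to about 1e-6 relative on well-conditioned systems.
#'
#' @param M dynamics matrix.
#' @param v0 initial condition.
#' @param times non-negative, ascending times (same unit as tau).
#' @param params a \code{\link{dynamics_params}}.
#' @param method \code{"auto"}, \code{"eigen"}, or \code{"ode"}.
#' @return matrix with one column per time point.
#' @export
simulate_response <- function(M, v0, times, params = dynamics_params(),
                              method = c("auto", "eigen", "ode")) {
  method <- match.arg(method)
  if (any(diff(times) < 0) || any(times < 0))
    stop("times must be non-negative and ascending")
  tau <- params$tau
  n <- nrow(M)
  if (method == "auto") {
    eg <- eigen(M)
    kap <- tryCatch(kappa(eg$vectors, exact = FALSE), error = function(e) Inf)
    method <- if (is.finite(kap) && kap < 1e8) "eigen" else "ode"
  }
  if (method == "eigen") {
    eg <- eigen(M)
    c0 <- solve(eg$vectors, v0)
    out <- vapply(times, function(t)
      Re(eg$vectors %*% (exp(eg$values * t / tau) * c0)), numeric(n))
  } else {
    # fixed-step RK4 sized by the spectral radius
    out <- matrix(0, n, length(times))
    rad <- max(Mod(eigen(M, only.values = TRUE)$values), 1e-12)
    v <- as.numeric(v0)
    t_cur <- 0
    f <- function(v) as.numeric(M %*% v) / tau
    for (j in seq_along(times)) {
      dt_total <- times[j] - t_cur
      if (dt_total > 0) {
        nstep <- max(1L, ceiling(dt_total * rad / tau / 0.01))
        h <- dt_total / nstep
        for (s in seq_len(nstep)) {
          k1 <- f(v); k2 <- f(v + h / 2 * k1)
          k3 <- f(v + h / 2 * k2); k4 <- f(v + h * k3)
          v <- v + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        }
      }
      t_cur <- times[j]
      out[, j] <- v
    }
  }
  rownames(out) <- rownames(M)
  colnames(out) <- signif(times, 6)
  out
}

#' Signal-flow layout of a directed network
#'
#' Finds the vertical coordinate z minimizing
#' sum over contacts w_ij (z_j - z_i - 1)^2, i.e. pre- and postsynaptic
#' neurons should differ by one level; "frustration" (e.g. directed
#' cycles) makes the optimum nonzero. Stationarity gives the closed-form
#' linear system L_sym z = d_in - d_out, with L_sym the Laplacian of the
#' symmetrized weights, solved per weakly connected component under a
#' zero-mean gauge.
#'
#' @param chem directed \code{adjacency_network}.
#' @return named numeric vector z (postsynaptic neurons higher).
#' @export
signal_flow_layout <- function(chem) {
  W <- chem$weights
  Wsym <- W + t(W)
  L <- diag(rowSums(Wsym), nrow(W)) - Wsym
  b <- colSums(W) - rowSums(W)           # weighted in-strength minus out
  n <- nrow(W)
  z <- numeric(n)
  memb <- igraph::components(as_igraph(chem), mode = "weak")$membership
  for (comp in unique(memb)) {
    idx <- which(memb == comp)
    if (length(idx) == 1) { z[idx] <- 0; next }
    Lc <- L[idx, idx, drop = FALSE]
    bc <- b[idx]
    # gauge: fix the first node to 0, solve the rest, then centre
    zc <- c(0, solve(Lc[-1, -1, drop = FALSE], bc[-1]))
    z[idx] <- zc - mean(zc)
  }
  names(z) <- chem$names
  z
}

#' Affinity layout from the Laplacian eigenmodes
#'
#' Places neurons in the plane using the eigenvectors of the symmetrized
#' weighted graph Laplacian for the second- and third-smallest
#' eigenvalues, computed on the giant component: strongly (multiply)
#' connected neurons end up close together. Deterministic up to sign,
#' fixed by the largest-component-positive convention.
#'
#' @param combined weighted \code{adjacency_network} (symmetrized
#'   internally).
#' @param normalized use the degree-normalized Laplacian
#'   D^(-1/2) L D^(-1/2) instead of L.
#' @return data.frame with columns \code{name}, \code{x}, \code{y}
#'   (NA off the giant component), plus attribute \code{eigenvalues}.
#' @export
affinity_layout <- function(combined, normalized = FALSE) {
  A <- combined$weights
  S <- (A + t(A)) / 2
  und <- adjacency_network(S, combined$names, directed = FALSE)
  gc <- giant_component(und)
  if (length(gc$names) < 3)
    stop("giant component has fewer than 3 nodes; no planar layout")
  L <- graph_laplacian(gc)
  if (normalized) {
    dinv <- 1 / sqrt(pmax(rowSums(gc$weights), 1e-12))
    L <- L * outer(dinv, dinv)
  }
  eg <- eigen(L, symmetric = TRUE)
  k <- ncol(L)
  fix_sign <- function(v) if (v[which.max(abs(v))] < 0) -v else v
  x <- fix_sign(eg$vectors[, k - 1])
  y <- fix_sign(eg$vectors[, k - 2])
  out <- data.frame(name = combined$names, x = NA_real_, y = NA_real_,
                    stringsAsFactors = FALSE)
  out$x[match(gc$names, combined$names)] <- x
  out$y[match(gc$names, combined$names)] <- y
  attr(out, "eigenvalues") <- rev(eg$values)[2:3]
  out
}

#' Union bound on the chance of a circuit appearing in an eigenmode
#'
#' Bounds the probability that at least one of \code{n_circuits} known
#' k-neuron circuits is contained in some eigenmode support, if mode
#' supports were random subsets: P <= min(1, n_circuits *
#' sum_i C(m_i, k) / C(n, k)) over the mode support sizes m_i.
#'
#' @param n number of neurons.
#' @param mode_sizes support sizes of the eigenmodes.
#' @param k circuit size.
#' @param n_circuits number of candidate circuits.
#' @return the probability bound.
#' @export
circuit_probability_bound <- function(n, mode_sizes, k, n_circuits = 1) {
  if (k > n) stop("k must not exceed n")
  if (any(mode_sizes > n)) stop("mode sizes must not exceed n")
  tot <- sum(exp(lchoose(mode_sizes, k) - lchoose(n, k)))
  min(1, n_circuits * tot)
}

#' Epsilon-pseudospectrum on a complex-plane grid
#'
#' At each grid point z computes sigma_min(z I - M), the distance (in the
#' operator norm) to the nearest matrix with eigenvalue z. The
#' eps-pseudospectrum is the sublevel set sigma_min <= eps: the loci of
#' eigenvalues under all perturbations of norm <= eps. For a normal
#' matrix it is exactly the union of eps-disks around the eigenvalues;
#' non-normal matrices (like the chemical/combined dynamics) have larger
#' pseudospectra, signalling eigenvalue sensitivity to reconstruction
#' errors.
#'
#' @param M square matrix.
#' @param re_lim,im_lim real/imaginary axis limits c(lo, hi); default a
#'   margin around the spectrum.
#' @param n_grid grid points per axis (default 51; cost is one SVD per
#'   point).
#' @param eps_levels contour levels to report.
#' @return list with \code{re}, \code{im}, \code{sigma_min} (matrix
#'   [im, re]), \code{eps_levels}, \code{eigenvalues}.
#' @export
pseudospectrum <- function(M, re_lim = NULL, im_lim = NULL, n_grid = 51,
                           eps_levels = c(0.1, 0.5, 1)) {
  ev <- eigen(M, only.values = TRUE)$values
  pad <- 0.2 * max(1e-6, diff(range(Re(ev))), diff(range(Im(ev))))
  if (is.null(re_lim)) re_lim <- range(Re(ev)) + c(-pad, pad)
  if (is.null(im_lim)) im_lim <- range(Im(ev)) + c(-pad, pad)
  re <- seq(re_lim[1], re_lim[2], length.out = n_grid)
  im <- seq(im_lim[1], im_lim[2], length.out = n_grid)
  n <- nrow(M)
  I <- diag(n)
  sig <- matrix(0, length(im), length(re))
  for (a in seq_along(im))
    for (b in seq_along(re)) {
      z <- complex(real = re[b], imaginary = im[a])
      sig[a, b] <- min(svd(z * I - M, nu = 0, nv = 0)$d)
    }
  list(re = re, im = im, sigma_min = sig, eps_levels = eps_levels,
       eigenvalues = ev)
}
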
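test_that("Laplacian spectra of canonical graphs are exact", {
  edge <- net_from_edges(rbind(c(1, 2)), n = 2)
  expect_equal(sort(eigen(graph_laplacian(edge))$values), c(0, 2),
               tolerance = 1e-10)
  p3 <- net_from_edges(rbind(c(1, 2), c(2, 3)), n = 3)
  expect_equal(sort(eigen(graph_laplacian(p3))$values), c(0, 1, 3),
               tolerance = 1e-10)
  kn <- sample_er(6, 1)
  expect_equal(sort(eigen(graph_laplacian(kn))$values), c(0, rep(6, 5)),
               tolerance = 1e-10)
  dirnet <- net_from_edges(rbind(c(1, 2)), n = 2, directed = TRUE)
  expect_error(graph_laplacian(dirnet), "symmetric")
})

test_that("dynamics_matrix reduces to -L, signs GABA, shifts with leak", {
  d <- worked_fixture()
  gap <- build_network(d, "gap")
  M <- dynamics_matrix(gap)
  expect_equal(M, -graph_laplacian(gap))

  al <- align_networks(build_network(d, "gap", drop_isolated = FALSE),
                       build_network(d, "chemical", drop_isolated = FALSE))
  Mc <- dynamics_matrix(al$a, al$b, signs = neuron_signs(d))
  # DD01 is GABAergic with 2 contacts onto VA01: entry -2
  expect_equal(Mc["VA01", "DD01"], -2)
  # ASHL is excitatory with 5 contacts onto AVAL: entry +5 (no gap there)
  expect_equal(Mc["AVAL", "ASHL"], 5)
  expect_error(dynamics_matrix(al$a, al$b, signs = c(AVAL = 1)), "signs")

  pars <- dynamics_params(include_leak = TRUE, g_m = 10, g = 100)
  Ml <- dynamics_matrix(gap, params = pars)
  ev0 <- sort(eigen(M)$values)
  evl <- sort(eigen(Ml)$values)
  expect_equal(evl, ev0 - 0.1, tolerance = 1e-12)
})

test_that("eigenmodes: residuals, sparseness bounds, conjugate pairs", {
  set.seed(51)
  A <- matrix(rnorm(400), 20)
  M <- (A + t(A)) / 2
  eg <- eigenmodes(M)
  expect_lt(max(eg$residuals), 1e-8)
  expect_true(all(eg$sparseness >= 1 - 1e-12))
  expect_true(all(eg$sparseness <= sqrt(20) + 1e-12))
  expect_true(all(Im(eg$values) == 0))

  edge <- net_from_edges(rbind(c(1, 2)), n = 2)
  ee <- eigenmodes(-graph_laplacian(edge), dynamics_params(C_m = 1, g = 100))
  tau <- 1000 * 1 / 100
  expect_equal(sort(ee$decay_times), c(tau / 2, Inf))

  # sparseness extremes: unit vector 1, flat vector sqrt(n)
  D <- diag(c(-1, -2, -3, -4))
  expect_equal(sort(eigenmodes(D)$sparseness), rep(1, 4))
  J <- -graph_laplacian(sample_er(4, 1))  # flat zero mode on K4
  sp <- eigenmodes(J)
  expect_equal(sp$sparseness[which(abs(Re(sp$values)) < 1e-10)], 2,
               tolerance = 1e-8)

  # non-symmetric real matrix: complex eigenvalues in conjugate pairs
  set.seed(52)
  B <- matrix(rnorm(100), 10)
  vals <- eigenmodes(B)$values
  cx <- vals[Im(vals) > 1e-12]
  expect_true(all(vapply(cx, function(z)
    any(abs(vals - Conj(z)) < 1e-8), logical(1))))
})

test_that("simulate_response: eigen-evolution, conservation, rescaling", {
  d <- worked_fixture()
  gap <- giant_component(build_network(d, "gap"))
  M <- -graph_laplacian(gap)
  n <- nrow(M)
  pars <- dynamics_params()
  tau <- pars$tau

  # charge conservation on gap-only dynamics, to 1e-10
  v0 <- rnorm(n)
  traj <- simulate_response(M, v0, c(0, tau, 5 * tau, 50 * tau), pars)
  expect_lt(max(abs(colSums(traj) - sum(v0))), 1e-10)

  # v0 = eigenmode evolves as a pure exponential
  eg <- eigenmodes(M, pars)
  k <- 2
  u <- Re(eg$modes[, k])
  lam <- Re(eg$values[k])
  tr <- simulate_response(M, u, c(0, tau, 2 * tau), pars)
  expect_equal(tr[, 2], u * exp(lam * 1), tolerance = 1e-8,
               ignore_attr = TRUE)

  # long-time limit: projection on the flat zero mode
  tr_inf <- simulate_response(M, v0, 1e4 * tau, pars)
  expect_equal(as.numeric(tr_inf), rep(mean(v0), n), tolerance = 1e-6)

  # eigen and ode integration agree
  t_ode <- simulate_response(M, v0, c(0, tau, 5 * tau), pars, method = "ode")
  t_eig <- simulate_response(M, v0, c(0, tau, 5 * tau), pars, method = "eigen")
  expect_equal(t_ode, t_eig, tolerance = 1e-6)

  # doubling tau rescales time
  p2 <- dynamics_params(C_m = 2)
  expect_equal(simulate_response(M, v0, 2 * tau, p2),
               simulate_response(M, v0, tau, pars), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(simulate_response(M, v0, c(3, 1)), "ascending")
})

test_that("signal_flow_layout solves chains exactly and handles frustration", {
  chain <- net_from_edges(rbind(c("a", "b"), c("b", "c")),
                          names = c("a", "b", "c"), directed = TRUE)
  z <- signal_flow_layout(chain)
  expect_equal(unname(z), c(-1, 0, 1), tolerance = 1e-10)

  cyc <- net_from_edges(rbind(c(1, 2), c(2, 3), c(3, 1)), n = 3,
                        directed = TRUE)
  zc <- signal_flow_layout(cyc)
  expect_equal(unname(zc), c(0, 0, 0), tolerance = 1e-10)
  obj <- function(net, z) {
    W <- net$weights
    ij <- which(W > 0, arr.ind = TRUE)
    sum(W[ij] * (z[ij[, 2]] - z[ij[, 1]] - 1)^2)
  }
  expect_equal(obj(cyc, zc), 3)

  single <- adjacency_network(matrix(0, 1, 1), "X", directed = TRUE)
  expect_equal(unname(signal_flow_layout(single)), 0)

  # stationarity: gradient of the objective vanishes at the solution
  d <- worked_fixture()
  chem <- build_network(d, "chemical", drop_isolated = FALSE)
  zf <- signal_flow_layout(chem)
  W <- chem$weights
  Wsym <- W + t(W)
  grad <- (diag(rowSums(Wsym)) - Wsym) %*% zf - (colSums(W) - rowSums(W))
  expect_lt(max(abs(grad)), 1e-8)

  # unfrustrated DAG chain-of-levels reproduces topological depth
  dag <- net_from_edges(rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)), n = 4,
                        directed = TRUE)
  zd <- signal_flow_layout(dag)
  expect_equal(unname(zd - zd[1]), c(0, 1, 1, 2), tolerance = 1e-10)
})

test_that("affinity_layout separates cliques and orders paths", {
  # two K4 cliques joined by one edge: Fiedler sign splits them
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1
  A[5:8, 5:8] <- 1
  diag(A) <- 0
  A[4, 5] <- A[5, 4] <- 1
  net <- adjacency_network(A, paste0("V", 1:8), directed = FALSE)
  xy <- affinity_layout(net)
  expect_equal(length(unique(sign(xy$x[1:4]))), 1)
  expect_equal(length(unique(sign(xy$x[5:8]))), 1)
  expect_true(sign(xy$x[1]) != sign(xy$x[8]))

  path <- net_from_edges(cbind(1:7, 2:8), n = 8)
  xp <- affinity_layout(path)
  expect_true(all(diff(xp$x) > 0) || all(diff(xp$x) < 0))

  tiny <- net_from_edges(rbind(c(1, 2)), n = 2)
  expect_error(affinity_layout(tiny), "fewer than 3")

  # disconnected input: giant component laid out, the rest flagged NA
  disc <- net_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5)), n = 5)
  xd <- affinity_layout(disc)
  expect_true(all(is.na(xd$x[4:5])))
  expect_true(all(is.finite(xd$x[1:3])))
})

test_that("circuit_probability_bound is exact binomial arithmetic", {
  expect_equal(circuit_probability_bound(10, 3, 2, 1), 3 / 45)
  expect_equal(circuit_probability_bound(10, c(3, 4), 5, 1), 0)
  expect_equal(circuit_probability_bound(10, 8, 2, 1e9), 1)
  expect_error(circuit_probability_bound(5, 3, 7), "k must")
})

test_that("pseudospectrum: normal matrices give eps-disks, Jordan inflates", {
  M <- diag(c(0, -1))
  ps <- pseudospectrum(M, re_lim = c(-1.5, 0.5), im_lim = c(-1, 1),
                       n_grid = 41)
  # sigma_min at each grid point equals distance to the nearest eigenvalue
  for (a in c(5, 21, 35)) for (b in c(5, 21, 35)) {
    z <- complex(real = ps$re[b], imaginary = ps$im[a])
    expect_equal(ps$sigma_min[a, b], min(Mod(z - c(0, -1))),
                 tolerance = 1e-10)
  }

  J <- matrix(c(0, 0, 10, 0), 2, 2)  # non-normal amplification
  sj <- min(svd((0.3 + 0i) * diag(2) - J)$d)
  expect_lt(sj, 0.3)  # inside the 0.1-pseudospectrum far beyond the disk
  expect_lt(min(svd((0.9 + 0i) * diag(2) - J)$d), 0.1)
})
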
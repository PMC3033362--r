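test_that("connected_components matches hand-checked examples", {
  und <- net_from_edges(cbind("A", "B"), names = c("A", "B", "C"))
  p <- connected_components(und, "undirected")
  expect_equal(sort(p$components[[1]]), c("A", "B"))
  expect_equal(p$isolated, "C")

  dirnet <- net_from_edges(rbind(c("A", "B"), c("B", "C"), c("C", "A"),
                                 c("D", "A")),
                           names = c("A", "B", "C", "D"), directed = TRUE)
  ps <- connected_components(dirnet, "strong")
  expect_equal(sort(ps$components[[1]]), c("A", "B", "C"))
  expect_equal(ps$components[[2]], "D")
  pw <- connected_components(dirnet, "weak")
  expect_equal(length(pw$components), 1)

  empty <- adjacency_network(matrix(0, 5, 5), paste0("V", 1:5),
                             directed = FALSE)
  expect_equal(length(connected_components(empty, "undirected")$components),
               5)
  expect_error(connected_components(und, "strong"), "directed")
})

test_that("components agree with transitive-closure oracle on small graphs", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    directed <- i %% 2 == 0
    net <- sample_er(n, runif(1, 0.1, 0.6), directed = directed)
    part <- connected_components(net, if (directed) "strong" else "undirected")
    memb <- components_oracle(net$weights, strong = directed)
    sizes_oracle <- sort(as.integer(table(memb)), decreasing = TRUE)
    sizes_pkg <- sort(vapply(part$components, length, 1L), decreasing = TRUE)
    expect_equal(sizes_pkg, sizes_oracle)
  }
})

test_that("er_giant_stats reproduces the Lambert-function fixed point", {
  expect_equal(er_giant_stats(100, 0.005)$rho, 0)  # subcritical

  # oracle: direct fixed-point iteration of rho = 1 - exp(-c rho)
  fp <- function(cc) {
    r <- 0.5
    for (i in 1:200) r <- 1 - exp(-cc * r)
    r
  }
  for (cc in c(1.5, 2, 4)) {
    st <- er_giant_stats(2001, cc / 2000)
    expect_equal(st$rho, fp(cc), tolerance = 1e-10)
    expect_equal(st$mean_size, 2001 * st$rho)
    expect_gt(st$variance, 0)
  }
  expect_equal(er_giant_stats(2001, 2 / 2000)$rho, 0.7968121, tolerance = 1e-6)
  expect_error(er_giant_stats(100, -0.1), "p must")
})

test_that("generating-function giant component solves the stated examples", {
  # p1 = p3 = 1/2: G1(u) = 1/4 + 3/4 u^2, smallest fixed point u = 1/3
  d <- degree_distribution(c(0, 0.5, 0, 0.5))
  g <- gf_giant_component(d)
  expect_equal(g$u, 1 / 3, tolerance = 1e-10)
  expect_equal(g$giant_fraction, 22 / 27, tolerance = 1e-10)

  dimer <- degree_distribution(c(0, 1))
  g2 <- gf_giant_component(dimer)
  expect_equal(g2$u, 1)
  expect_equal(g2$giant_fraction, 0)

  expect_error(gf_giant_component(c(0.5, 0.4)), "sum to 1")
  expect_error(degree_distribution(c(-0.1, 1.1)), "non-negative")
})

test_that("gf_expected_path_length implements ln(n/z1)/ln(z2/z1) + 1", {
  d <- degree_distribution(c(0, 0.5, 0, 0.5))   # z1 = 2, z2 = 3
  expect_equal(gf_expected_path_length(d, 100), log(50) / log(1.5) + 1,
               tolerance = 1e-12)
  expect_error(gf_expected_path_length(degree_distribution(c(0, 0, 1)), 100),
               "undefined")   # z2 = z1 = 2
  # Poisson-like: z1 = 4, z2 = 16 gives the quoted 4.983
  pois <- dpois(0:30, 4)
  pois[17] <- pois[17] + (1 - sum(pois))  # absorb truncation mass high up
  d2 <- degree_distribution(pois / sum(pois))
  ell <- gf_expected_path_length(d2, 1000)
  expect_equal(ell, log(1000 / 4) / log(sum((0:30) * ((0:30) - 1) * d2) /
                                          sum((0:30) * d2)) + 1)
})

test_that("giant-fraction analytics match configuration-model simulation", {
  set.seed(17)
  # p1 = p3 = 1/2 at n = 2000, 60 reps (scaled-down simulation oracle)
  reps <- 60
  S_hat <- replicate(reps, {
    deg <- sample(c(1, 3), 2000, replace = TRUE)
    if (sum(deg) %% 2 == 1) deg[1] <- deg[1] + 1
    g <- igraph::sample_degseq(deg, method = "fast.heur.simple")
    max(igraph::components(g)$csize) / 2000
  })
  expect_lt(abs(mean(S_hat) - 22 / 27), 3 * sd(S_hat) / sqrt(reps))

  # mean small-component size against the same simulation (node-weighted)
  msc <- gf_giant_component(degree_distribution(c(0, .5, 0, .5)))$mean_small_component
  small_sizes <- unlist(replicate(30, {
    deg <- sample(c(1, 3), 2000, replace = TRUE)
    if (sum(deg) %% 2 == 1) deg[1] <- deg[1] + 1
    g <- igraph::sample_degseq(deg, method = "fast.heur.simple")
    cs <- igraph::components(g)$csize
    rep(cs[-which.max(cs)], cs[-which.max(cs)])  # node-weighted sizes
  }, simplify = FALSE))
  expect_equal(mean(small_sizes), msc, tolerance = 0.15)
})

test_that("er_giant_stats mean matches ER simulation within 3 sigma", {
  set.seed(23)
  for (cc in c(1.5, 2, 4)) {
    n <- 2000
    reps <- 120
    sizes <- replicate(reps,
      max(igraph::components(igraph::sample_gnp(n, cc / (n - 1)))$csize))
    st <- er_giant_stats(n, cc / (n - 1))
    expect_lt(abs(mean(sizes) - st$mean_size), 3 * sd(sizes) / sqrt(reps))
    # predicted ensemble variance is the right scale too
    expect_lt(abs(sd(sizes) - sqrt(st$variance)), 0.5 * sd(sizes))
  }
})
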
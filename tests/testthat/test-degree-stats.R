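test_that("degree_summary counts degrees, strengths, and terminals", {
  gap <- net_from_edges(cbind("A", "B"), names = c("A", "B", "C"),
                        weights = 3)
  ds <- degree_summary(gap)
  expect_equal(ds["A", "degree"], 1)
  expect_equal(ds["A", "strength"], 3)
  expect_equal(ds["C", "degree"], 0)
  expect_equal(attr(ds, "multiplicities"), 3)

  nm <- c("A", "B")
  W <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(nm, nm))  # A->B 2, B->A 1
  chem <- adjacency_network(W, nm, directed = TRUE)
  ds2 <- degree_summary(chem)
  expect_equal(ds2["A", "in_degree"], 1)
  expect_equal(ds2["A", "out_number"], 2)
  expect_equal(ds2["A", "in_number"], 1)
  expect_true(all(ds2$strength >= ds2$degree))
  expect_equal(sum(ds2$in_degree), sum(ds2$out_degree))

  empty <- adjacency_network(matrix(0, 2, 2), nm, directed = FALSE)
  expect_true(all(degree_summary(empty)[, c("degree", "strength")] == 0))

  # mean multiplicity = total contacts / total connections, exactly
  d <- worked_fixture()
  chemw <- build_network(d, "chemical", drop_isolated = FALSE)
  mult <- attr(degree_summary(chemw), "multiplicities")
  r <- d$records[d$records$type == "chem", ]
  expect_equal(mean(mult), sum(r$contacts) / nrow(r))
})

test_that("survival_function is the complement CDF with a step table", {
  sf <- survival_function(c(1, 1, 2))
  expect_equal(sf$F[sf$k == 1], 1)
  expect_equal(sf$F[sf$k == 2], 1 / 3)
  expect_equal(sf$F[sf$k == 3], 0)
  expect_equal(survival_function(rep(7, 5))$F, c(1, 0))
  expect_equal(survival_function(c(2, 5, 9), k = 0)$F, 1)
  set.seed(1)
  x <- rpois(200, 4)
  expect_true(all(diff(survival_function(x)$F) <= 0))
  expect_error(survival_function(numeric()), "non-empty")
})

test_that("power-law MLE equals a dense grid search (oracle equivalence)", {
  set.seed(31)
  for (i in 1:3) {
    x <- wirenet:::rtail_model(list(family = "power_law",
                                    params = list(alpha = runif(1, 1.8, 3.5)),
                                    xmin = 1), 400)
    a_hat <- wirenet:::pl_fit_alpha(x, 1)$alpha
    # oracle: direct zeta-based likelihood over a dense grid
    grid <- seq(1.05, 6, by = 1e-3)
    ll <- vapply(grid, function(a)
      -a * sum(log(x)) - length(x) * log(sum((1:50000)^(-a))), numeric(1))
    expect_lt(abs(a_hat - grid[which.max(ll)]), 1e-3 + 1e-3)
  }
})

test_that("fit_tail selects xmin by KS and rejects degenerate tails", {
  set.seed(4)
  x <- wirenet:::rtail_model(list(family = "power_law",
                                  params = list(alpha = 2.5), xmin = 1), 2000)
  f <- fit_tail(x, "power_law")
  expect_s3_class(f, "tail_fit")
  expect_gte(f$xmin, min(x))
  expect_gte(f$ks, 0)
  expect_equal(f$params$alpha, 2.5, tolerance = 0.15)

  expect_error(fit_tail(c(5, 5, 5, 5), "power_law"), "degenerate")

  y <- rgeom(2000, 0.35) + 1
  fe <- fit_tail(y, "exponential")
  expect_equal(1 - exp(-fe$params$rate), 0.35, tolerance = 0.05)
})

test_that("bootstrap gof p-value behaves at its extremes and calibrates", {
  set.seed(6)
  x <- wirenet:::rtail_model(list(family = "power_law",
                                  params = list(alpha = 2.5), xmin = 1), 600)
  f <- fit_tail(x, "power_law")
  expect_error(gof_pvalue(f, x, n_boot = 0), "n_boot")

  fz <- f
  fz$ks <- 0  # no replicate can be smaller
  expect_equal(gof_pvalue(fz, x, n_boot = 20, seed = 1)$gof_pvalue, 1)

  # well-specified data should usually pass the p > 0.1 plausibility bar
  ps <- vapply(1:5, function(s) {
    set.seed(400 + s)
    x <- wirenet:::rtail_model(list(family = "power_law",
                                    params = list(alpha = 2.3), xmin = 1), 500)
    gof_pvalue(fit_tail(x, "power_law"), x, n_boot = 60)$gof_pvalue
  }, numeric(1))
  expect_gte(sum(ps > 0.1), 4)
})

test_that("stretched-exponential fitting recovers and degenerates cleanly", {
  set.seed(9)
  m <- wirenet:::rmultiplicity(4000, 2, 0.5)
  f <- fit_stretched_exponential(m)
  expect_equal(f$params$lambda, 2, tolerance = 0.4)
  expect_equal(f$params$beta, 0.5, tolerance = 0.1)

  m1 <- wirenet:::rmultiplicity(4000, 1.5, 1)   # beta = 1: geometric-like
  f1 <- fit_stretched_exponential(m1)
  expect_equal(f1$params$beta, 1, tolerance = 0.1)

  expect_error(fit_stretched_exponential(c(1, 1, 1)), "degenerate")
  expect_error(fit_stretched_exponential(c(0, 1, 2)), ">= 1")
})

test_that("compare_fits prefers the generating family on a common support", {
  set.seed(13)
  x <- wirenet:::rtail_model(list(family = "power_law",
                                  params = list(alpha = 2.5), xmin = 1), 2000)
  fp <- fit_tail(x, "power_law")
  fe <- fit_tail(x, "exponential")
  cmp <- compare_fits(fp, fe, x)
  expect_equal(cmp$preferred, "power_law")
  expect_equal(cmp$fit_a$xmin, cmp$fit_b$xmin)

  y <- rgeom(2000, 0.4) + 1
  cmp2 <- compare_fits(fit_tail(y, "power_law"), fit_tail(y, "exponential"), y)
  expect_equal(cmp2$preferred, "exponential")

  cmp3 <- compare_fits(fp, fp, x)
  expect_equal(cmp3$delta_loglik, 0)
})

test_that("sequence_correlation covers both methods and degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(sequence_correlation(x, x)$r, 1)
  expect_equal(sequence_correlation(x, -x)$r, -1)
  expect_equal(sequence_correlation(x, c(1, 3, 2, 4), "spearman")$r, 0.8)
  expect_error(sequence_correlation(x, rep(1, 4)), "zero variance")
  expect_error(sequence_correlation(1:2, 1:2), "length")
})
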
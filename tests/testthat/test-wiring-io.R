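neuron_df <- function(names) {
  data.frame(name = names, category = "I", gabaergic = 0,
             side = "none", class = names, stringsAsFactors = FALSE)
}

rec <- function(pre, post, type = "chem", contacts = 1, polyadic = 0) {
  data.frame(pre = pre, post = post, type = type, contacts = contacts,
             polyadic = polyadic, stringsAsFactors = FALSE)
}

test_that("minimal diagrams load and referential integrity is enforced", {
  d <- wiring_diagram(neuron_df(c("A", "B", "C")),
                      rbind(rec("A", "B", contacts = 3),
                            rec("B", "C", contacts = 1)))
  expect_s3_class(d, "wiring_diagram")
  expect_equal(nrow(d$neurons), 3)
  expect_equal(nrow(d$records), 2)

  expect_error(wiring_diagram(neuron_df(c("A", "B")), rec("A", "XXX")),
               "XXX")
  expect_error(wiring_diagram(neuron_df(c("A", "B")), rec("A", "A")),
               "self-record")
  expect_error(wiring_diagram(neuron_df(c("A", "B")),
                              rec("A", "B", contacts = -2)), "positive")
  expect_error(wiring_diagram(neuron_df(c("A", "B")),
                              rec("A", "B", contacts = 1, polyadic = 2)),
               "polyadic")
  expect_error(wiring_diagram(neuron_df(c("A", "B"))[, -2],
                              rec("A", "B")), "missing column")
})

test_that("load/write round trip is the identity on a wiring diagram", {
  d <- generate_connectome(synth_params(n_neurons = 40,
                                        mean_chem_connections = 120,
                                        mean_gap_connections = 40, seed = 9))
  f <- tmp_diagram_files(d)
  d2 <- load_wiring_diagram(f$neurons, f$synapses)
  expect_identical(d$neurons, d2$neurons)
  expect_equal(d$records, d2$records)
  expect_error(load_wiring_diagram("/nonexistent.csv", f$synapses),
               "not found")
})

test_that("validate_consistency reports unpaired gaps and duplicates", {
  n <- neuron_df(c("A", "B", "C"))
  ok <- wiring_diagram(n, rbind(rec("A", "B", "gap", 2),
                                rec("B", "A", "gap", 2)))
  expect_equal(nrow(validate_consistency(ok)), 0)

  unp <- wiring_diagram(n, rec("A", "B", "gap", 2))
  v <- validate_consistency(unp)
  expect_equal(v$kind, "unpaired gap")

  dup <- wiring_diagram(n, rbind(rec("A", "B"), rec("A", "B", contacts = 2)))
  expect_equal(validate_consistency(dup)$kind, "duplicate")

  mism <- wiring_diagram(n, rbind(rec("A", "B", "gap", 2),
                                  rec("B", "A", "gap", 3)))
  expect_true("gap count mismatch" %in% validate_consistency(mism)$kind)
})

test_that("build_network applies directionality, merging and quantitation", {
  n <- neuron_df(c("A", "B", "C"))
  chem <- build_network(wiring_diagram(n, rec("A", "B", contacts = 3)),
                        "chemical", drop_isolated = FALSE)
  expect_equal(chem$weights["A", "B"], 3)
  expect_equal(chem$weights["B", "A"], 0)

  gap <- build_network(wiring_diagram(n, rbind(rec("A", "B", "gap", 2),
                                               rec("B", "A", "gap", 2))),
                       "gap")
  expect_equal(gap$weights["A", "B"], 2)  # merged, not 4
  expect_equal(max(abs(gap$weights - t(gap$weights))), 0)

  ps <- build_network(wiring_diagram(n, rec("A", "B", contacts = 2,
                                            polyadic = 2)),
                      "chemical", quantitation = "polyad_split",
                      drop_isolated = FALSE)
  expect_equal(ps$weights["A", "B"], 1.0)  # 2 x 1/2

  # refusal on inconsistent data
  expect_error(build_network(wiring_diagram(n, rec("A", "B", "gap", 1)),
                             "gap"), "validate_consistency")
})

test_that("chemical matrix totals equal record totals (full quantitation)", {
  d <- generate_connectome(synth_params(n_neurons = 60, seed = 2,
                                        mean_chem_connections = 200,
                                        mean_gap_connections = 60))
  chem <- build_network(d, "chemical", drop_isolated = FALSE)
  r <- d$records
  expect_equal(sum(chem$weights),
               sum(r$contacts[r$type == "chem"]))
  gap <- build_network(d, "gap", drop_isolated = FALSE)
  expect_equal(max(abs(gap$weights - t(gap$weights))), 0)
})

test_that("combine_networks implements binary OR and weighted sum", {
  nm <- c("A", "B", "C")
  gap <- net_from_edges(cbind("A", "B"), names = nm, weights = 2)
  chem0 <- adjacency_network(matrix(0, 3, 3, dimnames = list(nm, nm)),
                             nm, directed = TRUE)
  bin <- combine_networks(gap, chem0, "binary")
  expect_equal(bin$weights["A", "B"], 1)
  expect_equal(bin$weights["B", "A"], 1)

  chem <- net_from_edges(cbind("A", "B"), names = nm, directed = TRUE,
                         weights = 3)
  wtd <- combine_networks(gap, chem, "weighted")
  expect_equal(wtd$weights["A", "B"], 5)
  expect_equal(wtd$weights["B", "A"], 2)
  # entrywise identity: chem + symmetrized gap
  expect_equal(wtd$weights, chem$weights + gap$weights,
               ignore_attr = TRUE)

  gap0 <- adjacency_network(matrix(0, 3, 3, dimnames = list(nm, nm)),
                            nm, directed = FALSE)
  expect_equal(combine_networks(gap0, chem, "weighted")$weights,
               chem$weights)

  bad <- adjacency_network(matrix(0, 2, 2), c("A", "B"), directed = TRUE)
  expect_error(combine_networks(gap, bad, "binary"), "index")
})

test_that("export writes GraphML and TSV edge lists", {
  d <- worked_fixture()
  gap <- build_network(d, "gap")
  p1 <- tempfile(fileext = ".graphml")
  p2 <- tempfile(fileext = ".tsv")
  export_network(gap, p1, "graphml")
  export_network(gap, p2, "tsv")
  expect_true(file.exists(p1))
  tsv <- read.delim(p2)
  expect_equal(nrow(tsv), sum(gap$weights > 0) / 2)
  g <- igraph::read_graph(p1, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(tsv))
})
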
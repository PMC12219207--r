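test_that("per-edge contributions match their closed forms", {
  expect_equal(edge_contribution("M1", 2, 3), 5)
  expect_equal(edge_contribution("M2", 2, 3), 6)
  expect_equal(edge_contribution("GA", 2, 2), 1)
  expect_equal(edge_contribution("ABC", 3, 3), 2 / 3)
  expect_equal(edge_contribution("SO", 2, 2), 2 * sqrt(2))
  expect_equal(edge_contribution("H", 1, 3), 0.5)
  expect_equal(edge_contribution("SC", 2, 2), 0.5)
  expect_equal(edge_contribution("N", 2, 2), 2)
  expect_error(edge_contribution("XX", 1, 1), "valid ids")
  expect_warning(v <- edge_contribution("ABC", 1, 1), "limit value 0")
  expect_equal(v, 0)
})

test_that("the Diclofenac partition reproduces the published index vector", {
  iv <- compute_all(diclofenac_partition())
  printed <- c(M1 = 94, M2 = 107, H = 8.7, HM = 452, F = 238, ABC = 14.458,
               R = 9.075, SC = 9.302, GA = 19.302, SO = 68.363, N = 43.237)
  # printed precision is 3 decimals; SO is truncated in print (68.3636)
  expect_true(all(abs(round(iv, 3) - printed) <= 0.001 + 1e-12))
  expect_equal(compute_index(diclofenac_partition(), "M1"), 94)
  expect_equal(compute_index(diclofenac_partition(), "H"), 8.7)
})

test_that("cycle partitions follow the regular-graph closed forms", {
  for (n in c(3L, 6L, 11L)) {
    p <- as_edge_partition(data.frame(a = 2, b = 2, count = n))
    iv <- compute_all(p)
    expect_equal(iv, c(M1 = 4 * n, M2 = 4 * n, H = n / 2, HM = 16 * n,
                       F = 8 * n, ABC = n / sqrt(2), R = n / 2, SC = n / 2,
                       GA = n, SO = 2 * sqrt(2) * n, N = 2 * n))
  }
  expect_equal(compute_index(data.frame(a = 2, b = 2, count = 6), "SO"),
               12 * sqrt(2))
})

test_that("partition-based computation equals per-edge summation on random graphs", {
  for (g in pool_graphs(15)) {
    iv <- compute_all(edge_partition(g))
    expect_equal(iv, oracle_all_indices(g), tolerance = 1e-12)
  }
})

test_that("structural identities hold on random graphs", {
  for (g in pool_graphs(25)) {
    iv <- compute_all(edge_partition(g))
    expect_lte(abs(iv[["HM"]] - iv[["F"]] - 2 * iv[["M2"]]), 1e-9 * iv[["HM"]])
    expect_equal(iv[["M1"]], sum(degrees(g)^2))
    expect_lte(iv[["GA"]], nrow(g$edges) + 1e-12)
  }
  # GA attains |E| exactly iff all edges have equal endpoint degrees
  c6 <- as_edge_partition(data.frame(a = 2, b = 2, count = 6))
  expect_equal(compute_index(c6, "GA"), 6)
})

test_that("adding an edge strictly increases the monotone indices", {
  for (seed in 1:8) {
    g <- random_molecular_graph(10, extra_edge_prob = 0.1, seed = seed)
    deg <- degrees(g)
    key <- paste(g$edges[, 1], g$edges[, 2])
    cand <- NULL
    for (u in 0:(g$n_vertices - 2)) for (v in (u + 1):(g$n_vertices - 1))
      if (deg[u + 1] < 4 && deg[v + 1] < 4 && !paste(u, v) %in% key)
        cand <- c(cand, list(c(u, v)))
    if (is.null(cand)) next
    g2 <- molecular_graph(rbind(g$edges, cand[[1]]))
    iv1 <- compute_all(edge_partition(g))
    iv2 <- compute_all(edge_partition(g2))
    for (id in c("M1", "M2", "HM", "F", "SO", "N"))
      expect_gt(iv2[[id]], iv1[[id]])
  }
})

test_that("batch computation reproduces the fixture schema from partitions", {
  long <- data.frame(drug = "Diclofenac",
                     a = c(1, 2, 2, 3), b = c(3, 2, 3, 3),
                     count = c(4, 5, 8, 3))
  tab <- compute_index_table(long)
  expect_named(tab, c("drug", index_ids()))
  expect_equal(tab$M1, 94)

  dir <- withr::local_tempdir()
  write_edge_list(diclofenac_graph(), file.path(dir, "Diclofenac.txt"))
  tab2 <- compute_index_table(dir)
  expect_equal(tab2, tab)

  out <- withr::local_tempfile(fileext = ".csv")
  compute_index_table(long, file = out)
  expect_equal(utils::read.csv(out)$HM, 452)
})
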
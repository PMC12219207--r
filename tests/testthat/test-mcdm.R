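test_that("weight constructors normalise as specified", {
  expect_equal(equal_weights(7), rep(1 / 7, 7))
  expect_equal(equal_weights(1), 1)
  expect_equal(ratio_weights(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(ratio_weights(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_error(ratio_weights(c(0, 0)), "positive")
  expect_error(ratio_weights(c(-1, 2)), "nonnegative")
  ct <- correlation_table(load_index_table(), load_property_table())
  w <- ratio_weights(abs(ct["BP", ]))
  expect_length(w, 11L)
  expect_equal(sum(w), 1)
})

test_that("decision matrices are assembled with the documented missing policies", {
  D <- build_decision_matrix("properties", "predicted")
  expect_equal(dim(D), c(22L, 7L))
  expect_false(anyNA(D))
  subs <- attr(D, "substitutions")
  expect_equal(nrow(subs), 5L)
  # the published predicted table omits the same cells, so every
  # substitution falls back to the column mean
  expect_true(all(subs$source == "column mean"))
  pt <- load_property_table()
  expect_equal(D["Lifitegrast", "BP"], mean(pt$BP, na.rm = TRUE))

  Dm <- build_decision_matrix("properties", "mean")
  expect_equal(Dm["Lifitegrast", "BP"], mean(pt$BP, na.rm = TRUE))

  Dd <- build_decision_matrix("properties", "drop-criterion")
  expect_equal(colnames(Dd), c("MR", "MV"))

  Di <- build_decision_matrix("indices")
  expect_equal(dim(Di), c(22L, 11L))
  expect_equal(nrow(attr(Di, "substitutions")), 0L)
})

test_that("TOPSIS matches a hand-worked 3x2 example including tie-breaking", {
  m <- rbind(a = c(4, 1), b = c(3, 2), c = c(1, 3))
  res <- topsis(as_decision_matrix(m), w = c(0.6, 0.4))
  # frozen from the five-stage hand computation
  expect_equal(res$C, c(0.622791, 0.619173, 0.377209), tolerance = 1e-5)
  expect_equal(res$Dplus, c(0.213809, 0.158981, 0.353009), tolerance = 1e-5)
  expect_equal(res$rank, c(1L, 2L, 3L))
})

test_that("TOPSIS honours dominance and degeneracy rules", {
  D <- as_decision_matrix(rbind(a = 10, b = 5))
  res <- topsis(D, w = 1)
  expect_equal(res$C[match(c("a", "b"), res$alternative)], c(1, 0))
  expect_error(topsis(as_decision_matrix(rbind(a = c(2, 2), b = c(2, 2)))),
               "identical")
})

test_that("TOPSIS closeness is invariant to positive column rescaling", {
  for (seed in 1:5) {
    D <- synth_decision_matrix(6, 4, seed = seed)
    base <- topsis(D)
    scaled <- unclass(D)
    scaled[, 2] <- scaled[, 2] * 137.5
    res <- topsis(as_decision_matrix(scaled))
    expect_equal(res$C, base$C, tolerance = 1e-12)
    expect_equal(res$rank, base$rank)
  }
})

test_that("VIKOR matches a hand-worked 3x2 example with alphabetical ties", {
  m <- rbind(a = c(4, 1), b = c(3, 2), c = c(1, 3))
  res <- vikor(as_decision_matrix(m), w = c(0.5, 0.5), v = 0.5)
  expect_equal(res$S, c(0.5, 0.416667, 0.5), tolerance = 1e-6)
  expect_equal(res$R, c(0.5, 0.25, 0.5), tolerance = 1e-6)
  expect_equal(res$Q, c(1, 0, 1), tolerance = 1e-12)
  # a and c tie on Q; alphabetical order makes ranks deterministic
  expect_equal(res$rank, c(2L, 1L, 3L))
})

test_that("VIKOR extreme alternatives pin Q to 0 and 1 for every v", {
  for (v in c(0, 0.25, 0.5, 1)) {
    D <- synth_decision_matrix(7, 4, with_dominant = TRUE,
                               with_dominated = TRUE, seed = 9)
    res <- vikor(D, v = v)
    expect_equal(res$Q[res$alternative == "dominant"], 0)
    expect_equal(res$rank[res$alternative == "dominant"], 1L)
    expect_equal(res$Q[res$alternative == "dominated"], 1)
    expect_equal(res$rank[res$alternative == "dominated"], nrow(D))
    # S and R bounds when weights sum to one
    expect_true(all(res$S >= 0 & res$S <= 1))
    expect_true(all(res$R >= 0 & res$R <= max(equal_weights(ncol(D)))))
  }
})

test_that("planted dominant/dominated alternatives hit the TOPSIS bounds", {
  D <- synth_decision_matrix(8, 5, with_dominant = TRUE, with_dominated = TRUE,
                             seed = 21)
  res <- topsis(D)
  expect_equal(res$C[res$alternative == "dominant"], 1)
  expect_equal(res$rank[res$alternative == "dominant"], 1L)
  expect_equal(res$C[res$alternative == "dominated"], 0)
  expect_equal(res$rank[res$alternative == "dominated"], nrow(D))
})

test_that("both methods agree with brute-force oracles on random matrices", {
  for (seed in 1:20) {
    D <- synth_decision_matrix(4, 3, seed = 400 + seed)
    w <- ratio_weights(with_seed(seed, stats::runif(3, 0.1, 1)))
    tr <- topsis(D, w)
    ot <- oracle_topsis(unclass(D), w)
    expect_equal(tr$C, ot$C, tolerance = 1e-12)
    expect_equal(tr$Dplus, ot$Dplus, tolerance = 1e-12)
    expect_equal(tr$Dminus, ot$Dminus, tolerance = 1e-12)
    vr <- vikor(D, w, v = 0.5)
    ov <- oracle_vikor(unclass(D), w, v = 0.5)
    expect_equal(vr$S, ov$S, tolerance = 1e-12)
    expect_equal(vr$R, ov$R, tolerance = 1e-12)
    expect_equal(vr$Q, ov$Q, tolerance = 1e-12)
  }
})

test_that("rank columns are permutations and the report collates them", {
  D <- synth_decision_matrix(9, 4, seed = 2)
  t1 <- topsis(D)
  v1 <- vikor(D)
  v2 <- vikor(D, v = 0.9)
  expect_setequal(t1$rank, 1:9)
  expect_setequal(v1$rank, 1:9)
  rep1 <- rank_report(t1, list(v05 = v1, v09 = v2))
  expect_named(rep1, c("drug", "TOPSIS", "v05", "v09"))
  expect_true(attr(rep1, "agreement") >= 0)
  single <- rank_report(NULL, list(only = v1))
  expect_equal(single$only, v1$rank[match(single$drug, v1$alternative)])
})
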
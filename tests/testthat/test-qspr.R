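test_that("pairwise-deletion Pearson correlation behaves as specified", {
  x <- c(1, 2, 3, 4, NA, 6)
  y <- c(2, 4.1, 5.9, 8, 10, NA)
  r <- pearson_correlation(x, y)
  expect_equal(attr(r, "n"), 4L)
  expect_equal(as.numeric(r), stats::cor(x[1:4], y[1:4]))
  expect_equal(as.numeric(pearson_correlation(x, x)), 1)
  expect_equal(as.numeric(pearson_correlation(x, -x)), -1)
  expect_error(pearson_correlation(1:2, 2:3), "fewer than 3")
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("the correlation screen reproduces published cells at printed precision", {
  ct <- correlation_table(load_index_table(), load_property_table())
  expect_equal(dim(ct), c(7L, 11L))
  expect_lt(abs(ct["P", "H"] - 0.993), 0.005)
  expect_lt(abs(ct["BP", "GA"] - 0.876), 0.005)
  expect_equal(round(ct["MW", "H"], 2), 0.99)
  n <- attr(ct, "n")
  expect_true(all(n["MR", ] == 22L))
  expect_true(all(n[c("BP", "P", "E", "C", "MW"), ] == 21L))
  # a property duplicating an index column correlates exactly 1
  it <- load_index_table()
  fake <- data.frame(drug = it$drug, fakeprop = it$GA)
  expect_equal(unname(correlation_table(it, fake)[1, "GA"]), 1)
})

test_that("single-regressor fits square to the screening correlation", {
  pt <- load_property_table(); it <- load_index_table()
  f <- fit_mlr(pt, it, model_spec(99, "P", "H"))
  st <- fit_statistics(f)
  expect_equal(st$r, abs(as.numeric(pearson_correlation(pt$P, it$H))),
               tolerance = 1e-12)
})

test_that("a noiseless linear response is recovered exactly", {
  it <- synth_qspr_dataset(synth_qspr_config(n_compounds = 15, sigma = 0,
                                             intercept = 3,
                                             coefficients = c(M1 = 2),
                                             seed = 11))
  pt <- data.frame(drug = it$indices$drug, Y = it$response)
  f <- fit_mlr(pt, it$indices, model_spec(0, "Y", "M1"))
  expect_equal(f$intercept, 3, tolerance = 1e-8)
  expect_equal(unname(f$coefficients), 2, tolerance = 1e-8)
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-8)
  st <- fit_statistics(f)
  expect_equal(st$R2, 1, tolerance = 1e-12)
  expect_equal(st$RMSE, 0, tolerance = 1e-6)
  expect_equal(unname(predict(f, it$indices)), unname(it$response),
               tolerance = 1e-8)
})

test_that("fit_mlr equals the normal-equations solution on random designs", {
  for (seed in 1:10) {
    d <- synth_qspr_dataset(synth_qspr_config(
      n_compounds = 12, sigma = 2, seed = seed,
      coefficients = c(M1 = 1.5, H = -4, GA = 0.3)))
    pt <- data.frame(drug = d$indices$drug, Y = d$response)
    f <- fit_mlr(pt, d$indices, model_spec(0, "Y", c("M1", "H", "GA")))
    beta <- oracle_ols(d$indices[, c("M1", "H", "GA")], d$response)
    expect_equal(unname(c(f$intercept, f$coefficients)), unname(beta),
                 tolerance = 1e-8)
    # residuals orthogonal to the design
    X <- cbind(1, as.matrix(d$indices[, c("M1", "H", "GA")]))
    expect_lt(max(abs(crossprod(X, f$residuals))), 1e-6)
  }
})

test_that("degenerate designs are refused with informative errors", {
  pt <- load_property_table(); it <- load_index_table()
  it$M1twin <- it$M1
  expect_error(
    fit_mlr(pt, transform(it, M1twin = M1),
            structure(list(id = 0, response = "P",
                           regressors = c("M1", "M1twin")),
                      class = "model_spec")),
    "rank deficient")
  small <- pt[1:3, ]
  expect_error(fit_mlr(small, it[1:3, ], model_spec(0, "P", c("M1", "H"))),
               "too few")
})

test_that("scale equivariance: rescaling a regressor rescales only its coefficient", {
  d <- synth_qspr_dataset(synth_qspr_config(n_compounds = 20, sigma = 1, seed = 5,
                                            coefficients = c(M1 = 1, SO = -2)))
  pt <- data.frame(drug = d$indices$drug, Y = d$response)
  f1 <- fit_mlr(pt, d$indices, model_spec(0, "Y", c("M1", "SO")))
  it2 <- d$indices; it2$SO <- it2$SO * 10
  f2 <- fit_mlr(pt, it2, model_spec(0, "Y", c("M1", "SO")))
  expect_equal(f2$coefficients[["SO"]], f1$coefficients[["SO"]] / 10,
               tolerance = 1e-10)
  expect_equal(f2$coefficients[["M1"]], f1$coefficients[["M1"]], tolerance = 1e-10)
  expect_equal(fit_statistics(f2), fit_statistics(f1), tolerance = 1e-10)
})

test_that("published models refit with the printed complete-case sizes", {
  rep_m <- reproduce_models()
  ns <- vapply(rep_m$statistics, `[[`, 0, "n")
  expect_equal(unname(ns), c(21, 22, 21, 22, 21, 21, 21))
  # Lifitegrast is the drop for BP, Cyclosporine for E
  expect_false("Lifitegrast" %in% rep_m$fits$model1$rows)
  expect_false("Cyclosporine" %in% rep_m$fits$model5$rows)
  cmp <- rep_m$comparison
  expect_equal(nrow(cmp), 7L * 7L)
  expect_true(all(cmp$abs_deviation[cmp$statistic == "n"] == 0))
  # RMSE convention: SE^2 (n-k-1)/n = RMSE^2 for every refit
  for (nm in names(rep_m$fits)) {
    f <- rep_m$fits[[nm]]; st <- rep_m$statistics[[nm]]
    expect_equal(st$SE^2 * (st$n - f$k - 1) / st$n, st$RMSE^2, tolerance = 1e-10)
  }
})

test_that("predictions cover all 22 drugs including fit-excluded ones", {
  rep_m <- reproduce_models()
  it <- load_index_table()
  pr3 <- predict(rep_m$fits$model3, it)
  expect_length(pr3, 22L)
  # Pranoprofen has no observed polarizability yet gets a prediction
  expect_false(is.na(pr3[["Pranoprofen"]]))
  # in-sample predictions equal fitted values
  expect_equal(pr3[rep_m$fits$model3$rows],
               rep_m$fits$model3$fitted, tolerance = 1e-10)
})
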
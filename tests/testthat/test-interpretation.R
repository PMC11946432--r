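test_that("split importance covers the feature set with true zeros", {
  sep <- make_fused_pair(n = 300, shift = 3, seed = 21)
  # f3 is pure noise but may still be split on; add a constant feature
  # that can never be used
  x <- cbind(sep$x, f4 = 0.5)
  em <- train_emissions(x, sep$labels, seed = 1)
  imp <- split_importance(em)
  expect_setequal(imp$feature, c("f1", "f2", "f3", "f4"))
  expect_equal(imp$gain[imp$feature == "f4"], 0)
  expect_equal(imp$frequency[imp$feature == "f4"], 0)
  expect_true(all(imp$frequency == round(imp$frequency)))
  expect_equal(imp$feature[1], "f1")  # the shifted feature dominates

  # conservation: table gain totals equal the summed tree split gains
  total <- sum(vapply(em$boosters, function(b) {
    tr <- xgboost::xgb.model.dt.tree(b)
    sum(tr$Gain[tr$Feature != "Leaf"])
  }, numeric(1)))
  expect_equal(sum(imp$gain), total, tolerance = 1e-8)
})

test_that("additive attributions sum to the prediction", {
  sep <- make_fused_pair(n = 200, shift = 2, seed = 22)
  em <- train_emissions(sep$x, sep$labels, seed = 1)
  att <- additive_attribution(sep$x[1:100, ], em, state = "hypnosis")
  resid <- att$base + rowSums(att$contributions) - att$prediction
  expect_lt(max(abs(resid)), 1e-6)

  # a feature no tree uses gets zero attribution everywhere
  x <- cbind(sep$x, f4 = 1)
  em2 <- train_emissions(x, sep$labels, seed = 1)
  att2 <- additive_attribution(x, em2)
  expect_true(all(att2$contributions$f4 == 0))
})

test_that("local surrogate recovers a linear model and is deterministic", {
  beta <- c(1.5, -2, 0.5)
  lin <- function(m) as.numeric(m %*% beta) + 0.3
  row <- c(f1 = 0.2, f2 = -0.1, f3 = 1)
  out <- local_surrogate(row, lin, n_perturbations = 5000, seed = 4)
  expect_lt(max(abs(out$weights$weight - beta) / abs(beta)), 0.1)
  expect_gt(out$r2, 0.99)

  const <- local_surrogate(row, function(m) rep(2, nrow(m)),
                           n_perturbations = 500, seed = 4)
  expect_lt(max(abs(const$weights$weight)), 1e-9)

  again <- local_surrogate(row, lin, n_perturbations = 5000, seed = 4)
  expect_identical(out, again)
})

test_that("l1_select recovers OLS at zero penalty and shrinks to zero", {
  set.seed(30)
  n <- 120
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  x <- scale(x) * sqrt(n / (n - 1))  # population standardization
  y <- 2 * x[, 1] - 1 * x[, 3] + rnorm(n, sd = 0.2)

  fit <- l1_select(x, y, seed = 1)
  # zero penalty: coordinate descent lands on the normal-equations solution
  b0 <- fit$path[fit$path$lambda == 0, ]
  xt <- cbind(1, x)
  ols <- solve(crossprod(xt), crossprod(xt, y))[-1]
  expect_lt(max(abs(b0$beta - ols)), 1e-6)

  # huge penalty: everything is zeroed
  big <- l1_select(x, y, lambda = c(100, 0), seed = 1)
  expect_true(all(big$path$beta[big$path$lambda == 100] == 0))

  # single-feature signal survives a moderate penalty alone
  y1 <- 3 * x[, 2]
  sel <- l1_select(x, y1, lambda = c(0.5), seed = 1)
  nz <- sel$path$feature[sel$path$beta != 0]
  expect_equal(nz, "f2")
})

test_that("l1_select agrees with an independent lasso solver", {
  set.seed(31)
  n <- 200
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  x <- scale(x) * sqrt(n / (n - 1))
  y <- x[, 1] - 0.5 * x[, 4] + rnorm(n, sd = 0.3)
  lam <- 0.1
  mine <- l1_select(x, y, lambda = c(lam), seed = 1)
  gl <- glmnet::glmnet(x, y, lambda = lam, standardize = FALSE,
                       thresh = 1e-14)
  expect_equal(unname(mine$path$beta),
               unname(as.numeric(gl$beta)), tolerance = 1e-4)
})

test_that("l1_select warns and standardizes unscaled input", {
  set.seed(32)
  x <- matrix(rnorm(200) * 5 + 3, 50, 4)
  y <- rnorm(50)
  expect_warning(l1_select(x, y, lambda = c(0.1)), "not standardized")
})

test_that("recursive elimination drops the noise feature first", {
  set.seed(35)
  eliminated_first <- 0
  for (i in 1:10) {
    n <- 150
    x <- cbind(s1 = rnorm(n), s2 = rnorm(n), noise = rnorm(n))
    y <- as.numeric(x[, "s1"] + 0.8 * x[, "s2"] + rnorm(n, sd = 0.3) > 0)
    rk <- recursive_elimination(x, y, nrounds = 40)
    if (rk$feature[rk$rank == 3] == "noise") {
      eliminated_first <- eliminated_first + 1
    }
  }
  expect_gte(eliminated_first, 9)

  x2 <- cbind(a = rnorm(50), b = rnorm(50))
  rk2 <- recursive_elimination(x2, rbinom(50, 1, 0.5), nrounds = 10)
  expect_setequal(rk2$rank, 1:2)
  expect_error(recursive_elimination(x2, rbinom(50, 1, 0.5), step = 2),
               "smaller than the number of features")
})
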
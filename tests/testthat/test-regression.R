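test_that("ols_fit matches the normal-equations oracle on random problems", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    p <- sample(1:3, 1)
    X <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(X) <- paste0("x", seq_len(p))
    y <- rnorm(n)
    fit <- ols_fit(X, y)
    orc <- ols_oracle(X, y)
    expect_equal(unname(fit$coefficients), unname(orc$beta), tolerance = 1e-10)
    expect_equal(unname(fit$se), unname(orc$se), tolerance = 1e-10)
    expect_equal(fit$r.squared, orc$r.squared, tolerance = 1e-10)
    expect_equal(fit$adj.r.squared, orc$adj.r.squared, tolerance = 1e-10)
  }
})

test_that("an exact linear response is recovered with zero error", {
  x <- c(0, 1, 2, 3, 4, 5)
  fit <- suppressWarnings(ols_fit(data.frame(x = x), 2 + 3 * x))
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-12)
  expect_equal(unname(fit$se), c(0, 0), tolerance = 1e-10)
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)
})

test_that("degenerate designs are refused with informative errors", {
  X <- data.frame(a = 1:6, b = 2 * (1:6))
  expect_error(ols_fit(X, rnorm(6)), "collinear.*b")
  expect_error(ols_fit(data.frame(x = 1:2), 1:2), "n > p \\+ 1")
  expect_error(ols_fit(data.frame(x = c(1, NA, 3, 4)), 1:4), "missing values")
  expect_error(ols_fit(data.frame(), 1:5), "no columns")
})

test_that("prediction identities hold on the training data", {
  m <- panel_models()
  fit <- m$model2
  X <- m$descriptors[, fit$xnames]
  yhat <- predict(fit, X)
  expect_equal(unname(yhat), unname(fit$fitted), tolerance = 1e-12)
  # squared correlation of fitted vs observed equals R^2
  expect_equal(cor(yhat, m$panel$inh)^2, fit$r.squared, tolerance = 1e-12)
  # all-zero descriptor row predicts the intercept
  zero <- data.frame(dis_N_C_norm = 0, am_2N = 0, Trl2_CN = 0)
  expect_equal(unname(predict(fit, zero)),
               unname(fit$coefficients["(Intercept)"]), tolerance = 1e-12)
  expect_error(predict(fit, data.frame(am_2N = 1)), "lacks predictor")
})

test_that("R^2 is invariant under affine rescaling of a predictor", {
  m <- panel_models()
  X <- m$descriptors[, c("dis_N_C_norm", "am_2N", "Trl2_CN")]
  X2 <- X
  X2$dis_N_C_norm <- 10 * X2$dis_N_C_norm - 3
  f1 <- ols_fit(X, m$panel$inh)
  f2 <- ols_fit(X2, m$panel$inh)
  expect_equal(f1$r.squared, f2$r.squared, tolerance = 1e-12)
  expect_equal(f2$coefficients[["dis_N_C_norm"]],
               f1$coefficients[["dis_N_C_norm"]] / 10, tolerance = 1e-10)
})

test_that("best-subset search ranks the three-variable panel model first", {
  m <- panel_models()
  X <- m$descriptors[, c("dis_N_C_norm", "am_2N", "Trl2_CN", "dis_N_C")]
  y <- m$panel$inh
  # subsets containing both distance codings are collinear and skipped
  w <- capture_warnings(ranked <- best_subset(X, y, k_max = 3))
  expect_true(all(grepl("skipping subset", w)) && length(w) > 0)
  top3 <- ranked[ranked$size == 3, ][1, ]
  eq1_fit <- ols_fit(m$descriptors[, c("dis_N_C_norm", "am_2N", "Trl2_CN")], y)
  # the raw and normalised distance are affine-equivalent, so the top
  # three-variable model is the published variable set up to that equivalence
  expect_equal(top3$r.squared, eq1_fit$r.squared, tolerance = 1e-10)
  expect_true(grepl("am_2N", top3$variables) && grepl("Trl2_CN", top3$variables)
              && grepl("dis_N_C", top3$variables))
  # the single best one-variable model is the distance descriptor
  best1 <- ranked[ranked$size == 1, ][1, ]
  expect_match(best1$variables, "dis_N_C")
  expect_error(best_subset(data.frame(), y), "no columns")
})

test_that("synthetic regeneration recovers the generating model", {
  m <- panel_models()
  desc <- m$descriptors
  beta <- c(8.6, 20.9, 8.7, 8.6)
  # noiseless: exact recovery
  act0 <- gen_activity_from_model(desc, beta, sigma = 0, seed = 9)
  fit0 <- suppressWarnings(
    ols_fit(desc[, c("dis_N_C_norm", "am_2N", "Trl2_CN")], act0$inh))
  expect_equal(unname(fit0$coefficients), beta, tolerance = 1e-10)
  expect_equal(fit0$r.squared, 1, tolerance = 1e-10)
  # at the calibrated noise level: ~95% coverage of +/- 2 SE intervals
  sigma <- calibrated_activity_sigma()
  n_rep <- 500
  covered <- matrix(NA, n_rep, 4)
  set.seed(2024)
  for (r in seq_len(n_rep)) {
    act <- suppressMessages(gen_activity_from_model(desc, beta, sigma = sigma))
    fit <- ols_fit(desc[, c("dis_N_C_norm", "am_2N", "Trl2_CN")], act$inh)
    covered[r, ] <- abs(fit$coefficients - beta) <= 2 * fit$se
  }
  coverage <- colMeans(covered)
  expect_true(all(coverage > 0.90 & coverage < 0.99))
})
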